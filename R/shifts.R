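# Ensembling of per-methyl chemical-shift predictions from two predictors
# and peak/prediction compatibility scoring.

#' Merge chemical-shift predictions from two predictors
#'
#' Combines two per-methyl prediction tables into a single set. For keys
#' (methyl id, nucleus) predicted by both sources the merged value is the
#' unweighted mean and the uncertainty is the larger of source A's stated
#' uncertainty and the absolute difference between the two predictions.
#' Keys present only in A keep A's value and uncertainty; keys present only
#' in B (which reports no uncertainties) receive a fallback uncertainty of
#' 0.2 ppm for 1H and 1.0 ppm for 13C. Keys in neither source are absent
#' from the output; missing keys are legal, not errors.
#'
#' @param records_a,records_b data.frames with columns \code{methyl_id},
#'   \code{nucleus} ("H" or "C"), \code{value} (ppm) and, for A,
#'   \code{uncertainty} (ppm, NA allowed).
#' @param fallback_unc_H,fallback_unc_C fallback uncertainties (ppm) for
#'   keys predicted only by source B.
#' @return data.frame with columns \code{methyl_id}, \code{nucleus},
#'   \code{value}, \code{uncertainty}, \code{provenance} ("both", "only-A",
#'   "only-B").
#' @examples
#' a <- data.frame(methyl_id = "L10-QD1", nucleus = "H",
#'                 value = 0.80, uncertainty = 0.10)
#' b <- data.frame(methyl_id = "L10-QD1", nucleus = "H", value = 1.00)
#' merge_predictions(a, b)  # 0.90 +/- 0.20
#' @export
merge_predictions <- function(records_a, records_b,
                              fallback_unc_H = 0.2, fallback_unc_C = 1.0) {
  chk <- function(r, who, need_unc) {
    if (nrow(r) == 0) return(r)
    if (!all(c("methyl_id", "nucleus", "value") %in% names(r)))
      stop("records ", who, " need columns methyl_id, nucleus, value")
    if (!all(r$nucleus %in% c("H", "C")))
      stop("nucleus must be 'H' or 'C'")
    if (any(!is.finite(r$value))) stop("non-finite predicted value in ", who)
    if (anyDuplicated(paste(r$methyl_id, r$nucleus)))
      stop("duplicate (methyl_id, nucleus) key in source ", who)
    if (is.null(r$uncertainty)) r$uncertainty <- NA_real_
    if (any(!is.na(r$uncertainty) & r$uncertainty < 0))
      stop("negative uncertainty in ", who)
    r
  }
  a <- chk(records_a, "A", TRUE)
  b <- chk(records_b, "B", FALSE)
  keya <- paste(a$methyl_id, a$nucleus)
  keyb <- paste(b$methyl_id, b$nucleus)
  keys <- union(keya, keyb)
  ia <- match(keys, keya); ib <- match(keys, keyb)
  fallback <- function(nuc) ifelse(nuc == "H", fallback_unc_H, fallback_unc_C)
  out <- lapply(seq_along(keys), function(k) {
    in_a <- !is.na(ia[k]); in_b <- !is.na(ib[k])
    if (in_a && in_b) {
      va <- a$value[ia[k]]; vb <- b$value[ib[k]]
      ua <- a$uncertainty[ia[k]]
      unc <- max(c(if (!is.na(ua)) ua, abs(va - vb)))
      nuc <- a$nucleus[ia[k]]
      if (unc <= 0) unc <- fallback(nuc)  # identical predictions, no stated unc
      data.frame(methyl_id = a$methyl_id[ia[k]], nucleus = nuc,
                 value = (va + vb) / 2, uncertainty = unc,
                 provenance = "both", stringsAsFactors = FALSE)
    } else if (in_a) {
      nuc <- a$nucleus[ia[k]]
      ua <- a$uncertainty[ia[k]]
      if (is.na(ua) || ua <= 0) ua <- fallback(nuc)
      data.frame(methyl_id = a$methyl_id[ia[k]], nucleus = nuc,
                 value = a$value[ia[k]], uncertainty = ua,
                 provenance = "only-A", stringsAsFactors = FALSE)
    } else {
      nuc <- b$nucleus[ib[k]]
      data.frame(methyl_id = b$methyl_id[ib[k]], nucleus = nuc,
                 value = b$value[ib[k]], uncertainty = fallback(nuc),
                 provenance = "only-B", stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(methyl_id = character(), nucleus = character(),
                      value = numeric(), uncertainty = numeric(),
                      provenance = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Peak/prediction compatibility score
#'
#' Uncertainty-normalized Euclidean distance in (1H, 13C) shift space:
#' \deqn{s = \sqrt{((\delta_H^{peak} - \delta_H^{pred})/u_H)^2 +
#'                 ((\delta_C^{peak} - \delta_C^{pred})/u_C)^2}}
#' Lower is better; 0 means the peak sits exactly on the prediction.
#'
#' @param peak_H,peak_C observed peak position (ppm).
#' @param pred_H,pred_C predicted shifts (ppm).
#' @param unc_H,unc_C prediction uncertainties (ppm, > 0).
#' @return dimensionless score (vectorized).
#' @export
shift_compatibility <- function(peak_H, peak_C, pred_H, pred_C,
                                unc_H, unc_C) {
  if (any(unc_H <= 0) || any(unc_C <= 0))
    stop("uncertainties must be strictly positive")
  sqrt(((peak_H - pred_H) / unc_H)^2 + ((peak_C - pred_C) / unc_C)^2)
}
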