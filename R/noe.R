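# Expected inter-methyl NOE contact graph and matching of observed NOESY
# cross-peaks against a candidate assignment.

#' Expected inter-methyl contacts from a structure
#'
#' All unordered methyl pairs closer than a cutoff, sorted by increasing
#' distance. The expected-intensity rank follows the r^-6 dependence of the
#' NOE (rank 1 = shortest distance = strongest expected cross-peak).
#'
#' @param methyls a methyl table.
#' @param dmat optional precomputed distance matrix
#'   (\code{\link{methyl_distance_matrix}}).
#' @param cutoff distance cutoff in \AA{} (default 8).
#' @return data.frame of class \code{contact_table} with columns
#'   \code{methyl_1}, \code{methyl_2}, \code{distance},
#'   \code{intensity_rank}.
#' @export
expected_contacts <- function(methyls, dmat = NULL, cutoff = 8) {
  if (is.null(dmat)) dmat <- methyl_distance_matrix(methyls)
  ids <- rownames(dmat)
  n <- length(ids)
  out <- data.frame(methyl_1 = character(), methyl_2 = character(),
                    distance = numeric(), intensity_rank = integer(),
                    stringsAsFactors = FALSE)
  if (n >= 2) {
    idx <- which(upper.tri(dmat) & dmat <= cutoff, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      out <- data.frame(methyl_1 = ids[idx[, 1]], methyl_2 = ids[idx[, 2]],
                        distance = dmat[idx], stringsAsFactors = FALSE)
      out <- out[order(out$distance, out$methyl_1, out$methyl_2), ,
                 drop = FALSE]
      out$intensity_rank <- seq_len(nrow(out))
      rownames(out) <- NULL
    } else {
      out$intensity_rank <- integer()
    }
  }
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Normalize a NOESY peak table
#'
#' Internal 4D representation: columns \code{H1}, \code{C1}, \code{C2},
#' \code{H2} (ppm; NA for the dimension a 3D layout lacks), plus
#' \code{intensity} and optional metadata. Layouts: \code{"hcch"} (4D),
#' \code{"hch"} (3D, no second carbon), \code{"cch"} (3D, no first proton).
#'
#' @param peaks data.frame whose shift columns depend on \code{layout}:
#'   hcch: H1, C1, C2, H2; hch: H1, C1, H2; cch: C1, C2, H2.
#' @param layout one of "hcch", "hch", "cch".
#' @param spectrum spectrum identifier.
#' @param mixing_time NOESY mixing time (s), metadata only.
#' @return data.frame of class \code{noe_peaks}.
#' @export
noe_peaks <- function(peaks, layout = c("hcch", "hch", "cch"),
                      spectrum = "noesy", mixing_time = 0.4) {
  layout <- match.arg(layout)
  need <- switch(layout, hcch = c("H1", "C1", "C2", "H2"),
                 hch = c("H1", "C1", "H2"), cch = c("C1", "C2", "H2"))
  if (!all(need %in% names(peaks)))
    stop("layout '", layout, "' needs columns ", paste(need, collapse = ", "))
  if (is.null(peaks$intensity)) peaks$intensity <- 1
  if (any(peaks$intensity <= 0)) stop("NOE intensities must be positive")
  n <- nrow(peaks)
  out <- data.frame(
    H1 = if ("H1" %in% need) peaks$H1 else rep(NA_real_, n),
    C1 = peaks$C1,
    C2 = if ("C2" %in% need) peaks$C2 else rep(NA_real_, n),
    H2 = peaks$H2,
    intensity = peaks$intensity, spectrum = rep(spectrum, length.out = n),
    mixing_time = rep(mixing_time, length.out = n),
    stringsAsFactors = FALSE)
  shifts <- as.matrix(out[, c("H1", "C1", "C2", "H2")])
  if (any(!is.finite(shifts[!is.na(shifts)])))
    stop("non-finite shift in NOE peak table")
  class(out) <- c("noe_peaks", "data.frame")
  out
}

# deviation of one NOE peak from the coordinates implied by an assigned
# methyl pair, in units of the tolerances; Inf if outside tolerance in any
# populated dimension. Both peak orientations are tried.
.noe_peak_dev <- function(peak, sh1, sh2, tol_H, tol_C) {
  dev_one <- function(a, b) {
    d <- c(abs(peak$H1 - a["dH"]) / tol_H, abs(peak$C1 - a["dC"]) / tol_C,
           abs(peak$C2 - b["dC"]) / tol_C, abs(peak$H2 - b["dH"]) / tol_H)
    d <- d[!is.na(d)]
    if (length(d) == 0 || any(d > 1)) Inf else sum(d)
  }
  min(dev_one(sh1, sh2), dev_one(sh2, sh1))
}

#' Match observed NOESY cross-peaks against an assignment
#'
#' A cross-peak is explained when its shift coordinates match, within
#' tolerances, the peak positions of two assigned methyls that form an
#' expected contact. Ambiguity is resolved by the smallest combined shift
#' deviation (in tolerance units).
#'
#' @param peaks a \code{\link{noe_peaks}} table (empty allowed).
#' @param assignment data.frame mapping \code{methyl_id} to assigned peak
#'   coordinates \code{dH}, \code{dC}.
#' @param contacts a \code{\link{expected_contacts}} table.
#' @param tol_H,tol_C matching tolerances (ppm; defaults 0.02 and 0.2).
#' @return list with \code{per_peak} (data.frame: peak row, explaining
#'   contact as "id1|id2" or NA, deviation) and \code{explained_fraction}.
#' @export
match_noe <- function(peaks, assignment, contacts,
                      tol_H = 0.02, tol_C = 0.2) {
  if (nrow(peaks) == 0)
    return(list(per_peak = data.frame(contact = character(),
                                      deviation = numeric()),
                explained_fraction = NA_real_))
  amap <- assignment[!is.na(assignment$dH) & !is.na(assignment$dC), ,
                     drop = FALSE]
  cc <- contacts[contacts$methyl_1 %in% amap$methyl_id &
                 contacts$methyl_2 %in% amap$methyl_id, , drop = FALSE]
  i1 <- match(cc$methyl_1, amap$methyl_id)
  i2 <- match(cc$methyl_2, amap$methyl_id)
  contact <- rep(NA_character_, nrow(peaks))
  deviation <- rep(NA_real_, nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    if (nrow(cc) == 0) break
    best <- Inf; best_c <- NA_character_
    for (k in seq_len(nrow(cc))) {
      sh1 <- c(dH = amap$dH[i1[k]], dC = amap$dC[i1[k]])
      sh2 <- c(dH = amap$dH[i2[k]], dC = amap$dC[i2[k]])
      d <- .noe_peak_dev(peaks[p, ], sh1, sh2, tol_H, tol_C)
      if (d < best) { best <- d; best_c <- paste(cc$methyl_1[k],
                                                 cc$methyl_2[k], sep = "|") }
    }
    if (is.finite(best)) { contact[p] <- best_c; deviation[p] <- best }
  }
  list(per_peak = data.frame(contact = contact, deviation = deviation,
                             stringsAsFactors = FALSE),
       explained_fraction = mean(!is.na(contact)))
}
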