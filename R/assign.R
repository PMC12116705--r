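# Formalized methyl assignment workflow: peak lists, assignment state,
# mutant anchor detection, geminal pairing, stereospecific labelling,
# evidence-weighted greedy propagation, minor-form bookkeeping and coverage
# reporting.

.scheme_types <- list(
  "I-only"     = "ILE",
  "LV[rac]"    = c("LEU", "VAL"),
  "ILV[rac]"   = c("ILE", "LEU", "VAL"),
  "IMLV[rac]"  = c("ILE", "MET", "LEU", "VAL"),
  "MV[pro-S]"  = c("MET", "VAL"),
  "LV[pro-R]"  = c("LEU", "VAL"))

#' Construct a 2D methyl peak list
#'
#' @param peaks data.frame with columns \code{id}, \code{dH}, \code{dC}
#'   (ppm), optional \code{intensity} (default 1) and \code{form} (one of
#'   "major", "minor", "exchange", "unknown"; default "unknown").
#' @param spectrum spectrum identifier.
#' @param scheme labelling-scheme tag: one of "I-only", "LV[rac]",
#'   "ILV[rac]", "IMLV[rac]", "MV[pro-S]", "LV[pro-R]", or NA.
#' @return data.frame of class \code{peaklist} with attributes
#'   \code{spectrum} and \code{scheme}.
#' @export
peaklist <- function(peaks, spectrum = "hmqc", scheme = NA_character_) {
  if (!all(c("id", "dH", "dC") %in% names(peaks)))
    stop("peaks need columns id, dH, dC")
  if (anyDuplicated(peaks$id)) stop("duplicate peak ids")
  if (any(!is.finite(peaks$dH)) || any(!is.finite(peaks$dC)))
    stop("non-finite peak shifts")
  if (is.null(peaks$intensity)) peaks$intensity <- 1
  if (any(peaks$intensity < 0)) stop("negative peak intensity")
  if (is.null(peaks$form)) peaks$form <- "unknown"
  if (!all(peaks$form %in% c("major", "minor", "exchange", "unknown")))
    stop("form must be major/minor/exchange/unknown")
  if (!is.na(scheme) && !scheme %in% names(.scheme_types))
    stop("unknown labelling scheme: ", scheme)
  out <- peaks[, c("id", "dH", "dC", "intensity", "form")]
  attr(out, "spectrum") <- spectrum
  attr(out, "scheme") <- scheme
  class(out) <- c("peaklist", "data.frame")
  out
}

#' Create an empty assignment state
#'
#' @param methyl_ids character vector of methyl ids (or a methyl table).
#' @param peaks a \code{\link{peaklist}}.
#' @return object of class \code{assignment_state}: list with \code{map}
#'   (data.frame methyl_id, peak_id, confidence, evidence), the full methyl
#'   and peak id universes, and the peak list.
#' @export
assignment_state <- function(methyl_ids, peaks) {
  if (is.data.frame(methyl_ids)) methyl_ids <- methyl_ids$methyl_id
  structure(list(
    map = data.frame(methyl_id = character(), peak_id = character(),
                     confidence = numeric(), evidence = character(),
                     stringsAsFactors = FALSE),
    methyl_ids = methyl_ids, peaks = peaks), class = "assignment_state")
}

#' Add one methyl-to-peak assignment
#'
#' Enforces injectivity: a methyl may carry one peak and a peak one methyl.
#'
#' @param state an \code{assignment_state}.
#' @param methyl_id,peak_id ids to link.
#' @param confidence confidence in [0, 1].
#' @param evidence character tag(s), e.g. "anchor", "noe;shift-prediction".
#' @return the updated state.
#' @export
add_assignment <- function(state, methyl_id, peak_id, confidence = 1,
                           evidence = "anchor") {
  if (!methyl_id %in% state$methyl_ids)
    stop("unknown methyl id: ", methyl_id)
  if (!peak_id %in% state$peaks$id) stop("unknown peak id: ", peak_id)
  if (methyl_id %in% state$map$methyl_id)
    stop("methyl ", methyl_id, " already assigned")
  if (peak_id %in% state$map$peak_id)
    stop("peak ", peak_id, " already assigned")
  if (confidence < 0 || confidence > 1) stop("confidence must be in [0, 1]")
  state$map <- rbind(state$map, data.frame(
    methyl_id = methyl_id, peak_id = peak_id, confidence = confidence,
    evidence = evidence, stringsAsFactors = FALSE))
  state
}

#' Unassigned methyls and peaks of a state
#'
#' Minor- and exchange-form peaks never count as assignable.
#'
#' @param state an \code{assignment_state}.
#' @return list with \code{methyls} and \code{peaks} (character vectors).
#' @export
unassigned <- function(state) {
  pool <- state$peaks$id[state$peaks$form %in% c("major", "unknown")]
  list(methyls = setdiff(state$methyl_ids, state$map$methyl_id),
       peaks = setdiff(pool, state$map$peak_id))
}

# assigned shift coordinates per methyl (for NOE matching)
.assigned_shifts <- function(state) {
  i <- match(state$map$peak_id, state$peaks$id)
  data.frame(methyl_id = state$map$methyl_id,
             dH = state$peaks$dH[i], dC = state$peaks$dC[i],
             stringsAsFactors = FALSE)
}

#' Detect anchor-point candidate peaks from a point-mutant spectrum
#'
#' Peaks present in the wild-type peak list with no counterpart in the
#' mutant list within the matching tolerances are candidates for the methyls
#' of the mutated residue (X -> Ala mutations remove them). The expected
#' number of candidates is 1 for Ile/Met and 2 for Leu/Val; surplus or
#' deficit is flagged via the \code{status} attribute and a warning, never
#' silently resolved.
#'
#' @param wt,mutant \code{\link{peaklist}}s from the same labelling scheme.
#' @param mutated_residue residue spec like "L159" (one-letter type +
#'   number).
#' @param tol_H,tol_C matching tolerances (ppm; defaults 0.02 and 0.2).
#' @return the candidate rows of \code{wt}, with attributes
#'   \code{expected_n} and \code{status} ("ok", "surplus", "deficit").
#' @export
detect_anchors <- function(wt, mutant, mutated_residue,
                           tol_H = 0.02, tol_C = 0.2) {
  rt1 <- substring(mutated_residue, 1, 1)
  restype <- names(.one_letter)[match(rt1, .one_letter)]
  if (is.na(restype) || !restype %in% c("ILE", "LEU", "VAL", "MET"))
    stop("mutated residue must be Ile/Leu/Val/Met, got: ", mutated_residue)
  sw <- attr(wt, "scheme"); sm <- attr(mutant, "scheme")
  if (!is.na(sw) && !is.na(sm) && sw != sm)
    stop("wild-type and mutant peak lists have different labelling schemes")
  scheme <- if (!is.na(sw)) sw else sm
  if (!is.na(scheme) && !restype %in% .scheme_types[[scheme]])
    stop("labelling scheme ", scheme, " does not observe ", restype,
         " methyls")
  # one-to-one greedy matching of wt against mutant peaks (closest pairs
  # first), so that a retained peak close to the deleted one cannot mask it
  pairs <- list()
  for (i in seq_len(nrow(wt))) {
    hit <- which(abs(mutant$dH - wt$dH[i]) <= tol_H &
                 abs(mutant$dC - wt$dC[i]) <= tol_C)
    if (length(hit) > 0)
      pairs[[length(pairs) + 1L]] <- data.frame(
        wt = i, mut = hit,
        dev = abs(mutant$dH[hit] - wt$dH[i]) / tol_H +
          abs(mutant$dC[hit] - wt$dC[i]) / tol_C)
  }
  has_match <- logical(nrow(wt))
  if (length(pairs) > 0) {
    pairs <- do.call(rbind, pairs)
    pairs <- pairs[order(pairs$dev), , drop = FALSE]
    used_mut <- logical(nrow(mutant))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$wt[k]; j <- pairs$mut[k]
      if (!has_match[i] && !used_mut[j]) {
        has_match[i] <- TRUE
        used_mut[j] <- TRUE
      }
    }
  }
  cand <- wt[!has_match, , drop = FALSE]
  expected <- if (restype %in% c("LEU", "VAL")) 2L else 1L
  status <- if (nrow(cand) == expected) "ok"
            else if (nrow(cand) > expected) "surplus" else "deficit"
  if (status != "ok")
    warning("anchor detection for ", mutated_residue, ": expected ",
            expected, " candidate peaks, found ", nrow(cand),
            " (", status, ")", call. = FALSE)
  attr(cand, "expected_n") <- expected
  attr(cand, "status") <- status
  cand
}

#' Record geminal pairing constraints
#'
#' Consumes a table of peak pairs sharing a CG (Leu) or CB (Val) frequency,
#' as provided by an HmCmCG/CB-type experiment, and validates that no peak
#' occurs in more than one pair.
#'
#' @param pairing_records data.frame (or 2-column matrix) with columns
#'   \code{peak_1}, \code{peak_2}.
#' @return data.frame of class \code{geminal_pairs} with a \code{pair_id}
#'   column added.
#' @export
pair_geminal <- function(pairing_records) {
  pr <- as.data.frame(pairing_records, stringsAsFactors = FALSE)
  if (nrow(pr) == 0)
    return(structure(data.frame(pair_id = integer(), peak_1 = character(),
                                peak_2 = character(),
                                stringsAsFactors = FALSE),
                     class = c("geminal_pairs", "data.frame")))
  names(pr)[1:2] <- c("peak_1", "peak_2")
  if (any(pr$peak_1 == pr$peak_2))
    stop("a geminal pair must link two distinct peaks")
  all_ids <- c(pr$peak_1, pr$peak_2)
  if (anyDuplicated(all_ids))
    stop("conflicting geminal pairing: peak(s) ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         " appear in more than one pair")
  out <- data.frame(pair_id = seq_len(nrow(pr)), peak_1 = pr$peak_1,
                    peak_2 = pr$peak_2, stringsAsFactors = FALSE)
  class(out) <- c("geminal_pairs", "data.frame")
  out
}

# does peak (dH, dC) occur in a stereo-filtered peak list?
.in_list <- function(dH, dC, plist, tol_H, tol_C) {
  any(abs(plist$dH - dH) <= tol_H & abs(plist$dC - dC) <= tol_C)
}

#' Resolve stereospecific labels within geminal pairs
#'
#' For each geminal pair, the member whose position matches a peak in the
#' pro-R list (from an LV[pro-R] sample: Leu-delta1 & Val-gamma1) is
#' labelled pro-R and the member matching the pro-S list (from an MV[pro-S]
#' sample: Val-gamma2) pro-S. A pair whose members match neither list stays
#' ambiguous; both members matching the same list is flagged a conflict.
#'
#' @param pairs a \code{\link{pair_geminal}} table.
#' @param peaks the \code{\link{peaklist}} the pair peak ids refer to.
#' @param pro_R_peaks,pro_S_peaks stereo-filtered \code{\link{peaklist}}s
#'   (either may be NULL).
#' @param tol_H,tol_C matching tolerances (ppm).
#' @return \code{pairs} with columns \code{pro_R}, \code{pro_S} (peak ids or
#'   NA) and \code{status} ("resolved", "ambiguous", "conflict").
#' @export
stereo_assign <- function(pairs, peaks, pro_R_peaks = NULL,
                          pro_S_peaks = NULL, tol_H = 0.02, tol_C = 0.2) {
  pro_R <- pro_S <- rep(NA_character_, nrow(pairs))
  status <- rep("ambiguous", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ids <- c(pairs$peak_1[i], pairs$peak_2[i])
    rows <- peaks[match(ids, peaks$id), , drop = FALSE]
    inR <- inS <- c(FALSE, FALSE)
    if (!is.null(pro_R_peaks))
      inR <- vapply(1:2, function(k) .in_list(rows$dH[k], rows$dC[k],
                                              pro_R_peaks, tol_H, tol_C),
                    logical(1))
    if (!is.null(pro_S_peaks))
      inS <- vapply(1:2, function(k) .in_list(rows$dH[k], rows$dC[k],
                                              pro_S_peaks, tol_H, tol_C),
                    logical(1))
    if (sum(inR) == 2 || sum(inS) == 2) {
      status[i] <- "conflict"
      next
    }
    r <- if (sum(inR) == 1) which(inR) else if (sum(inS) == 1)
      setdiff(1:2, which(inS)) else NA_integer_
    if (!is.na(r)) {
      pro_R[i] <- ids[r]
      pro_S[i] <- ids[setdiff(1:2, r)]
      status[i] <- "resolved"
    }
  }
  pairs$pro_R <- pro_R
  pairs$pro_S <- pro_S
  pairs$status <- status
  pairs
}

# is there an observed NOE cross-peak linking peak coordinates (h1,c1) and
# (h2,c2) within tolerances? Both orientations; NA dims of 3D peaks skipped.
.has_noe_link <- function(noe, h1, c1, h2, c2, tol_H, tol_C) {
  ok1 <- (is.na(noe$H1) | abs(noe$H1 - h1) <= tol_H) &
         (is.na(noe$C1) | abs(noe$C1 - c1) <= tol_C) &
         (is.na(noe$C2) | abs(noe$C2 - c2) <= tol_C) &
         (is.na(noe$H2) | abs(noe$H2 - h2) <= tol_H)
  if (any(ok1)) return(TRUE)
  ok2 <- (is.na(noe$H1) | abs(noe$H1 - h2) <= tol_H) &
         (is.na(noe$C1) | abs(noe$C1 - c2) <= tol_C) &
         (is.na(noe$C2) | abs(noe$C2 - c1) <= tol_C) &
         (is.na(noe$H2) | abs(noe$H2 - h1) <= tol_H)
  any(ok2)
}

#' Propagate assignments from anchors by combining NOE, shift-prediction
#' and PRE evidence
#'
#' Iterative greedy extension of a set of anchor assignments, mirroring
#' manual structure-guided assignment. Every (unassigned methyl, unassigned
#' peak) pair is scored as the weighted sum of three terms in [0, 1]:
#' \itemize{
#'   \item NOE support: the fraction of the methyl's expected contacts to
#'     already-assigned methyls for which an observed NOESY cross-peak links
#'     the candidate peak to the partner's assigned peak;
#'   \item shift-prediction compatibility: \eqn{\exp(-s^2/2)} of the
#'     uncertainty-normalized deviation \eqn{s}
#'     (\code{\link{shift_compatibility}});
#'   \item PRE consistency: mean over spin-label sites of
#'     \eqn{1 - |obs - pred|} clipped to [0, 1], where obs is the observed
#'     ratio of the candidate peak and pred the predicted ratio of the
#'     methyl.
#' }
#' The best-scoring pair is accepted if its score reaches \code{threshold}
#' and beats the runner-up for both its methyl and its peak by
#' \code{margin}; this repeats until no pair is acceptable. Deterministic;
#' ties are broken by residue number, then peak id. Minor/exchange-form
#' peaks never enter the pool.
#'
#' @param anchors data.frame with \code{methyl_id}, \code{peak_id} (the
#'   anchor-point assignments), or an existing \code{assignment_state}.
#' @param methyls methyl table (defines the methyl universe and residue
#'   numbers).
#' @param peaks a \code{\link{peaklist}}.
#' @param contacts expected contact graph (\code{\link{expected_contacts}}).
#' @param noe a \code{\link{noe_peaks}} table (may be empty).
#' @param merged merged shift predictions (\code{\link{merge_predictions}};
#'   may be empty).
#' @param pre list of per-site PRE evidence, each element a list with
#'   \code{pred} (data.frame methyl_id, ratio) and \code{obs} (data.frame
#'   peak_id, ratio, optional quantifiable); may be empty.
#' @param weights numeric, \code{c(noe =, shift =, pre =)}; normalized to
#'   sum to 1.
#' @param threshold minimum acceptable score (default 0.4).
#' @param margin required lead over the runner-up (default 0.1).
#' @param tol_H,tol_C NOE matching tolerances (ppm).
#' @param geminal optional geminal pairing constraints
#'   (\code{\link{pair_geminal}}, possibly stereo-resolved by
#'   \code{\link{stereo_assign}}). Used as hard constraints: a peak
#'   belonging to a geminal pair can only be a Leu/Val methyl; a
#'   stereo-resolved peak only the matching pro-R/pro-S methyl; and
#'   accepting one member of a pair deterministically assigns its partner
#'   peak to the geminal twin methyl (evidence "geminal", plus "stereo"
#'   when the pair is resolved).
#' @return an \code{assignment_state}.
#' @export
propagate_assignments <- function(anchors, methyls, peaks, contacts,
                                  noe = NULL, merged = NULL, pre = list(),
                                  weights = c(noe = 0.5, shift = 0.3,
                                              pre = 0.2),
                                  threshold = 0.4, margin = 0.1,
                                  tol_H = 0.02, tol_C = 0.2,
                                  geminal = NULL) {
  w <- weights / sum(weights)
  if (inherits(anchors, "assignment_state")) {
    state <- anchors
  } else {
    if (nrow(anchors) == 0) stop("empty anchor set")
    state <- assignment_state(methyls, peaks)
    for (i in seq_len(nrow(anchors)))
      state <- add_assignment(state, anchors$methyl_id[i],
                              anchors$peak_id[i], 1, "anchor")
  }
  if (nrow(state$map) == 0) stop("empty anchor set")
  if (is.null(noe)) noe <- noe_peaks(data.frame(H1 = numeric(),
                                                C1 = numeric(),
                                                C2 = numeric(),
                                                H2 = numeric())[0, ],
                                     layout = "hcch")

  # static per-(methyl, peak) evidence: shift predictions and PRE
  mh <- if (!is.null(merged)) merged[merged$nucleus == "H", ] else NULL
  mc <- if (!is.null(merged)) merged[merged$nucleus == "C", ] else NULL
  static_score <- function(mids, prows) {
    # matrix methyls x peaks of w_shift * shift + w_pre * pre
    S <- matrix(0, length(mids), nrow(prows))
    if (!is.null(mh) && nrow(mh) > 0) {
      ih <- match(mids, mh$methyl_id); ic <- match(mids, mc$methyl_id)
      for (a in seq_along(mids)) {
        if (is.na(ih[a]) || is.na(ic[a])) next
        s <- shift_compatibility(prows$dH, prows$dC, mh$value[ih[a]],
                                 mc$value[ic[a]], mh$uncertainty[ih[a]],
                                 mc$uncertainty[ic[a]])
        S[a, ] <- S[a, ] + w["shift"] * exp(-s^2 / 2)
      }
    }
    if (length(pre) > 0) {
      for (a in seq_along(mids)) {
        vals <- numeric(0)
        for (site in pre) {
          pm <- site$pred$ratio[match(mids[a], site$pred$methyl_id)]
          if (is.na(pm)) next
          ob <- site$obs
          if (!is.null(ob$quantifiable))
            ob <- ob[ob$quantifiable, , drop = FALSE]
          po <- ob$ratio[match(prows$id, ob$peak_id)]
          vals <- cbind(vals, pmin(pmax(1 - abs(po - pm), 0), 1))
        }
        if (length(vals) > 0) {
          v <- rowMeans(as.matrix(vals), na.rm = TRUE)
          v[is.nan(v)] <- 0
          S[a, ] <- S[a, ] + w["pre"] * v
        }
      }
    }
    S
  }

  resno_of <- stats::setNames(methyls$resno, methyls$methyl_id)

  # geminal lookups: partner peak of a paired peak, stereo role of a peak
  gem_partner <- character(0)
  gem_role <- character(0)
  if (!is.null(geminal) && nrow(geminal) > 0) {
    gem_partner <- stats::setNames(
      c(geminal$peak_2, geminal$peak_1), c(geminal$peak_1, geminal$peak_2))
    if (!is.null(geminal$pro_R)) {
      res <- geminal[!is.na(geminal$pro_R), , drop = FALSE]
      gem_role <- stats::setNames(
        rep(c("pro-R", "pro-S"), each = nrow(res)),
        c(res$pro_R, res$pro_S))
    }
  }
  stereo_of <- stats::setNames(methyls$stereo, methyls$methyl_id)
  twin_of <- vapply(methyls$methyl_id, function(m) {
    i <- match(m, methyls$methyl_id)
    j <- which(methyls$resno == methyls$resno[i] &
               methyls$methyl_id != m &
               methyls$restype[i] %in% c("LEU", "VAL"))
    if (length(j) == 1) methyls$methyl_id[j] else NA_character_
  }, character(1))

  # deterministic completion: assigning one member of a geminal pair fixes
  # the partner peak as the geminal twin methyl
  complete_geminal <- function(state, methyl_id, peak_id, confidence) {
    if (!peak_id %in% names(gem_partner)) return(state)
    twin <- twin_of[[methyl_id]]
    p2 <- gem_partner[[peak_id]]
    if (is.na(twin)) return(state)
    un <- unassigned(state)
    if (!(twin %in% un$methyls) || !(p2 %in% un$peaks)) return(state)
    ev <- if (peak_id %in% names(gem_role)) "geminal;stereo" else "geminal"
    add_assignment(state, twin, p2, confidence, ev)
  }

  # hard-constraint veto for a candidate (methyl, peak) pair
  gem_veto <- function(mids, prows) {
    V <- matrix(FALSE, length(mids), nrow(prows))
    if (length(gem_partner) == 0) return(V)
    paired <- prows$id %in% names(gem_partner)
    role <- ifelse(prows$id %in% names(gem_role),
                   gem_role[prows$id], NA_character_)
    for (a in seq_along(mids)) {
      st <- stereo_of[[mids[a]]]
      if (is.na(st)) {
        # Ile/Met methyl cannot take a peak known to be one of a Leu/Val
        # geminal pair
        V[a, ] <- paired
      } else {
        V[a, ] <- !is.na(role) & role != st
      }
    }
    V
  }

  # geminal completion of the anchor set itself
  if (length(gem_partner) > 0) {
    snap <- state$map
    for (i in seq_len(nrow(snap)))
      state <- complete_geminal(state, snap$methyl_id[i], snap$peak_id[i],
                                snap$confidence[i])
  }

  repeat {
    un <- unassigned(state)
    if (length(un$methyls) == 0 || length(un$peaks) == 0) break
    prows <- state$peaks[match(un$peaks, state$peaks$id), , drop = FALSE]
    score <- static_score(un$methyls, prows)
    veto <- gem_veto(un$methyls, prows)

    # NOE support, recomputed each round against the current state
    ash <- .assigned_shifts(state)
    nsup <- matrix(0, length(un$methyls), nrow(prows))
    if (nrow(noe) > 0 && nrow(ash) > 0) {
      for (a in seq_along(un$methyls)) {
        m <- un$methyls[a]
        part <- c(contacts$methyl_2[contacts$methyl_1 == m],
                  contacts$methyl_1[contacts$methyl_2 == m])
        part <- part[part %in% ash$methyl_id]
        if (length(part) == 0) next
        psh <- ash[match(part, ash$methyl_id), , drop = FALSE]
        for (b in seq_len(nrow(prows))) {
          hits <- vapply(seq_len(nrow(psh)), function(k)
            .has_noe_link(noe, prows$dH[b], prows$dC[b], psh$dH[k],
                          psh$dC[k], tol_H, tol_C), logical(1))
          nsup[a, b] <- mean(hits)
        }
      }
    }
    score <- score + w["noe"] * nsup
    score[veto] <- -Inf

    ok <- which(score >= threshold, arr.ind = TRUE)
    if (nrow(ok) == 0) break
    # margin test: best in row and column must lead runner-up
    accept <- logical(nrow(ok))
    for (k in seq_len(nrow(ok))) {
      a <- ok[k, 1]; b <- ok[k, 2]; s <- score[a, b]
      row_rest <- if (ncol(score) > 1) max(score[a, -b]) else -Inf
      col_rest <- if (nrow(score) > 1) max(score[-a, b]) else -Inf
      accept[k] <- (s - row_rest >= margin) && (s - col_rest >= margin)
    }
    ok <- ok[accept, , drop = FALSE]
    if (nrow(ok) == 0) break
    sc <- score[ok]
    pick <- order(-sc, resno_of[un$methyls[ok[, 1]]],
                  un$peaks[ok[, 2]])[1]
    a <- ok[pick, 1]; b <- ok[pick, 2]
    ev <- c(if (nsup[a, b] > 0) "noe",
            if (!is.null(mh) && nrow(mh) > 0) "shift-prediction",
            if (length(pre) > 0) "pre")
    conf <- min(max(score[a, b], 0), 1)
    state <- add_assignment(state, un$methyls[a], un$peaks[b], conf,
                            paste(ev, collapse = ";"))
    state <- complete_geminal(state, un$methyls[a], un$peaks[b], conf)
  }
  state
}

#' Flag minor-form / exchange peaks
#'
#' An unassigned peak whose 1H shift matches an assigned peak within
#' \code{tol_H} but whose 13C shift differs by more than \code{tol_C} is
#' flagged "minor-or-exchange" and linked to that methyl: slow
#' conformational exchange frequently shifts only the 13C resonance, and an
#' exchange peak mixes the 1H shift of one form with the 13C shift of the
#' other.
#'
#' @param peaks a \code{\link{peaklist}}.
#' @param state an \code{assignment_state} holding major-form assignments.
#' @param tol_H,tol_C tolerances (ppm; defaults 0.02 and 0.2).
#' @return data.frame: \code{peak_id}, \code{flag}
#'   ("minor-or-exchange" or "unknown"), \code{linked_methyl}.
#' @export
tag_minor_forms <- function(peaks, state, tol_H = 0.02, tol_C = 0.2) {
  unpk <- setdiff(peaks$id, state$map$peak_id)
  ash <- .assigned_shifts(state)
  out <- data.frame(peak_id = unpk, flag = "unknown",
                    linked_methyl = NA_character_, stringsAsFactors = FALSE)
  if (nrow(ash) == 0) return(out)
  for (i in seq_along(unpk)) {
    p <- peaks[match(unpk[i], peaks$id), ]
    cand <- which(abs(ash$dH - p$dH) <= tol_H & abs(ash$dC - p$dC) > tol_C)
    if (length(cand) > 0) {
      best <- cand[which.min(abs(ash$dH[cand] - p$dH))]
      out$flag[i] <- "minor-or-exchange"
      out$linked_methyl[i] <- ash$methyl_id[best]
    }
  }
  out
}

#' Rounded percentage coverage
#'
#' @param assigned,total non-negative counts, \code{assigned <= total}.
#' @return integer percentage, \code{round(100 * assigned / total)}.
#' @examples
#' coverage_percentage(224, 243) # 92
#' @export
coverage_percentage <- function(assigned, total) {
  if (any(assigned < 0) || any(total <= 0) || any(assigned > total))
    stop("need 0 <= assigned <= total, total > 0")
  as.integer(round(100 * assigned / total))
}

#' Assignment coverage report
#'
#' Counts of assigned vs total methyls per residue type and overall, with
#' the rounded overall percentage.
#'
#' @param state an \code{assignment_state}.
#' @param methyls the methyl table defining the totals.
#' @return object of class \code{coverage_report}: list with
#'   \code{per_type} (data.frame restype, assigned, total), \code{assigned},
#'   \code{total}, \code{percentage}.
#' @export
coverage_report <- function(state, methyls) {
  types <- c("ILE", "MET", "LEU", "VAL")
  assigned_res <- methyls$restype[methyls$methyl_id %in% state$map$methyl_id]
  per <- data.frame(
    restype = types,
    assigned = vapply(types, function(t) sum(assigned_res == t), integer(1)),
    total = vapply(types, function(t) sum(methyls$restype == t), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  per <- per[per$total > 0, , drop = FALSE]
  tot <- sum(per$total); asn <- sum(per$assigned)
  structure(list(per_type = per, assigned = asn, total = tot,
                 percentage = if (tot > 0) coverage_percentage(asn, tot)
                              else NA_integer_),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Methyl assignment coverage\n")
  for (i in seq_len(nrow(x$per_type)))
    cat(sprintf("  %-3s %3d / %3d\n", x$per_type$restype[i],
                x$per_type$assigned[i], x$per_type$total[i]))
  cat(sprintf("  all %3d / %3d  (%d%%)\n", x$assigned, x$total,
              x$percentage))
  invisible(x)
}
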