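# Ground-truth generators: methyl constellations and every derived
# observable (peak lists, point-mutant spectra, PRE profiles, NOESY
# cross-peaks, shift-prediction tables), for end-to-end validation of the
# assignment machinery without any external data.

.shift_ranges <- list(
  ILE = list(C = c(9, 16),  H = c(0.2, 1.2)),
  MET = list(C = c(15, 19), H = c(1.5, 2.3)),
  LEU = list(C = c(21, 27), H = c(0.3, 1.1)),
  VAL = list(C = c(19, 24), H = c(0.4, 1.1)))

#' Generate a synthetic methyl constellation with ground truth
#'
#' Places methyl groups by self-avoiding rejection sampling inside a sphere
#' sized for a realistic packing density of one methyl per ~600 cubic \AA.
#' Leu and Val residues contribute geminal pairs 3 \AA{} apart; Ile and Met
#' contribute single methyls. True 1H/13C shifts are drawn uniformly from
#' residue-type-specific ranges reflecting the dispersion of methyl-TROSY
#' spectra; a random subset of methyls is designated as exhibiting a minor
#' conformational form whose 13C shift is offset by 0.2-1.0 ppm (1H shift
#' unchanged, as typically observed for slow exchange in these systems).
#'
#' @param n_ile,n_leu,n_val,n_met residue counts (non-negative).
#' @param min_separation minimum distance between methyls of different
#'   residues (\AA, default 4).
#' @param geminal_separation distance between the two methyls of a Leu/Val
#'   residue (\AA, default 3).
#' @param volume_per_methyl sphere volume allotted per methyl (\AA^3).
#' @param minor_fraction fraction of methyls given a minor form.
#' @param seed integer random seed; the output is reproducible from it.
#' @return object of class \code{ground_truth}: list with \code{methyls}
#'   (a methyl table; pseudo-atom = carbon position), \code{shifts}
#'   (methyl_id, dH, dC), \code{minor} (methyl_id, ddH, ddC), \code{seed}.
#' @export
generate_constellation <- function(n_ile = 0, n_leu = 0, n_val = 0,
                                   n_met = 0, min_separation = 4,
                                   geminal_separation = 3,
                                   volume_per_methyl = 600,
                                   minor_fraction = 0.1, seed = 1) {
  if (any(c(n_ile, n_leu, n_val, n_met) < 0) || min_separation <= 0)
    stop("counts must be >= 0 and min_separation > 0")
  set.seed(seed)
  n_methyl <- n_ile + n_met + 2 * (n_leu + n_val)
  restypes <- c(rep("ILE", n_ile), rep("LEU", n_leu), rep("VAL", n_val),
                rep("MET", n_met))
  if (n_methyl == 0)
    return(structure(list(methyls = .empty_methyl_table(),
                          shifts = data.frame(methyl_id = character(),
                                              dH = numeric(), dC = numeric(),
                                              stringsAsFactors = FALSE),
                          minor = data.frame(methyl_id = character(),
                                             ddH = numeric(),
                                             ddC = numeric(),
                                             stringsAsFactors = FALSE),
                          seed = seed), class = "ground_truth"))
  radius <- (3 * n_methyl * volume_per_methyl / (4 * pi))^(1 / 3)
  runif_sphere <- function() {
    repeat {
      p <- stats::runif(3, -radius, radius)
      if (sum(p^2) <= radius^2) return(p)
    }
  }
  placed <- matrix(numeric(0), ncol = 3)
  rows <- list()
  max_tries <- 10000L
  for (i in seq_along(restypes)) {
    rt <- restypes[i]
    n_m <- if (rt %in% c("LEU", "VAL")) 2L else 1L
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place residue ", i,
             ": density infeasible for min_separation = ", min_separation)
      p1 <- runif_sphere()
      pts <- matrix(p1, ncol = 3)
      if (n_m == 2L) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        pts <- rbind(pts, p1 + geminal_separation * u)
      }
      ok <- TRUE
      if (nrow(placed) > 0) {
        for (k in seq_len(nrow(pts))) {
          d2 <- rowSums(sweep(placed, 2, pts[k, ])^2)
          if (min(d2) < min_separation^2) { ok <- FALSE; break }
        }
      }
      if (ok && n_m == 2L &&
          sum((pts[2, ])^2) > (radius + geminal_separation)^2) ok <- FALSE
      if (ok) break
    }
    placed <- rbind(placed, pts)
    def <- .methyl_def[.methyl_def$restype == rt &
                       !(.methyl_def$restype == "ILE" &
                         .methyl_def$label == "gamma2"), , drop = FALSE]
    for (k in seq_len(n_m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        methyl_id = .methyl_id(rt, i, def$pseudo[k]), chain = "A",
        resno = i, restype = rt, label = def$label[k],
        stereo = def$stereo[k],
        cx = pts[k, 1], cy = pts[k, 2], cz = pts[k, 3],
        px = pts[k, 1], py = pts[k, 2], pz = pts[k, 3],
        stringsAsFactors = FALSE)
    }
  }
  methyls <- do.call(rbind, rows)
  methyls <- methyls[order(methyls$resno, methyls$label), , drop = FALSE]
  rownames(methyls) <- NULL
  class(methyls) <- c("methyl_table", "data.frame")

  rng <- .shift_ranges[methyls$restype]
  shifts <- data.frame(
    methyl_id = methyls$methyl_id,
    dH = vapply(rng, function(r) stats::runif(1, r$H[1], r$H[2]), 0),
    dC = vapply(rng, function(r) stats::runif(1, r$C[1], r$C[2]), 0),
    stringsAsFactors = FALSE)
  rownames(shifts) <- NULL

  n_minor <- round(minor_fraction * nrow(methyls))
  minor_ids <- if (n_minor > 0)
    sample(methyls$methyl_id, n_minor) else character(0)
  minor <- data.frame(
    methyl_id = minor_ids, ddH = rep(0, n_minor),
    ddC = sample(c(-1, 1), n_minor, replace = TRUE) *
      stats::runif(n_minor, 0.2, 1.0),
    stringsAsFactors = FALSE)

  structure(list(methyls = methyls, shifts = shifts, minor = minor,
                 seed = seed), class = "ground_truth")
}

.empty_methyl_table <- function() {
  m <- data.frame(methyl_id = character(), chain = character(),
                  resno = integer(), restype = character(),
                  label = character(), stereo = character(),
                  cx = numeric(), cy = numeric(), cz = numeric(),
                  px = numeric(), py = numeric(), pz = numeric(),
                  stringsAsFactors = FALSE)
  class(m) <- c("methyl_table", "data.frame")
  m
}

#' Simulate a 2D HMQC peak list from ground truth
#'
#' One major peak per methyl at the true shifts plus Gaussian jitter;
#' methyls in the ground truth's minor-form subset additionally produce a
#' minor peak at the offset position with reduced intensity. Peak ids are
#' uninformative ("pk001", ...), in randomized order. All peaks are emitted
#' with \code{form = "unknown"}: which peaks are minor is what downstream
#' analysis has to establish.
#'
#' @param truth a \code{\link{generate_constellation}} object.
#' @param sigma_H,sigma_C shift jitter SD (ppm).
#' @param minor_intensity intensity of a minor peak relative to its major.
#' @param scheme labelling-scheme tag to stamp on the list.
#' @param seed integer random seed.
#' @return a \code{\link{peaklist}} with attribute \code{truth_map}: a
#'   data.frame (methyl_id, peak_id, form) giving the generating methyl and
#'   true form of every peak.
#' @export
simulate_peaklist <- function(truth, sigma_H = 0, sigma_C = 0,
                              minor_intensity = 0.3, scheme = "IMLV[rac]",
                              seed = 1) {
  set.seed(seed)
  sh <- truth$shifts
  n <- nrow(sh)
  rows <- data.frame(
    methyl_id = sh$methyl_id,
    dH = sh$dH + stats::rnorm(n, 0, sigma_H),
    dC = sh$dC + stats::rnorm(n, 0, sigma_C),
    intensity = stats::rlnorm(n, 0, 0.3),
    form = "major", stringsAsFactors = FALSE)
  if (nrow(truth$minor) > 0) {
    i <- match(truth$minor$methyl_id, sh$methyl_id)
    rows <- rbind(rows, data.frame(
      methyl_id = truth$minor$methyl_id,
      dH = sh$dH[i] + truth$minor$ddH +
        stats::rnorm(nrow(truth$minor), 0, sigma_H),
      dC = sh$dC[i] + truth$minor$ddC +
        stats::rnorm(nrow(truth$minor), 0, sigma_C),
      intensity = minor_intensity * rows$intensity[i],
      form = "minor", stringsAsFactors = FALSE))
  }
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rows$id <- sprintf("pk%03d", seq_len(nrow(rows)))
  pl <- peaklist(data.frame(id = rows$id, dH = rows$dH, dC = rows$dC,
                            intensity = rows$intensity, form = "unknown",
                            stringsAsFactors = FALSE),
                 spectrum = "hmqc-sim", scheme = scheme)
  attr(pl, "truth_map") <- data.frame(methyl_id = rows$methyl_id,
                                      peak_id = rows$id, form = rows$form,
                                      stringsAsFactors = FALSE)
  pl
}

#' Simulate the peak list of an X -> Ala point mutant
#'
#' Removes all peaks (major and minor) generated by the mutated residue's
#' methyls; optionally perturbs the shifts of peaks whose methyls lie within
#' a given radius of the mutated residue, emulating local structural
#' responses to the mutation.
#'
#' @param truth the \code{ground_truth} behind \code{wt}.
#' @param wt a \code{\link{simulate_peaklist}} output.
#' @param resno residue number to mutate.
#' @param perturb_radius radius (\AA) within which neighbouring methyls'
#'   peaks are jittered; 0 (default) disables perturbation.
#' @param perturb_H,perturb_C jitter SD (ppm) for perturbed peaks.
#' @param seed integer random seed.
#' @return a \code{\link{peaklist}} with updated \code{truth_map}.
#' @export
simulate_mutant <- function(truth, wt, resno, perturb_radius = 0,
                            perturb_H = 0.01, perturb_C = 0.1, seed = 1) {
  set.seed(seed)
  m <- truth$methyls
  gone <- m$methyl_id[m$resno == resno]
  if (length(gone) == 0) stop("residue ", resno, " has no methyls")
  map <- attr(wt, "truth_map")
  drop_ids <- map$peak_id[map$methyl_id %in% gone]
  keep <- !(wt$id %in% drop_ids)
  out <- as.data.frame(wt)[keep, , drop = FALSE]
  map <- map[map$peak_id %in% out$id, , drop = FALSE]
  if (perturb_radius > 0) {
    mut_xyz <- m[m$methyl_id %in% gone, c("px", "py", "pz"), drop = FALSE]
    near <- vapply(seq_len(nrow(m)), function(i) {
      d2 <- (mut_xyz$px - m$px[i])^2 + (mut_xyz$py - m$py[i])^2 +
        (mut_xyz$pz - m$pz[i])^2
      any(d2 <= perturb_radius^2)
    }, logical(1))
    near_ids <- setdiff(m$methyl_id[near], gone)
    hit <- out$id %in% map$peak_id[map$methyl_id %in% near_ids]
    out$dH[hit] <- out$dH[hit] + stats::rnorm(sum(hit), 0, perturb_H)
    out$dC[hit] <- out$dC[hit] + stats::rnorm(sum(hit), 0, perturb_C)
    attr_perturbed <- out$id[hit]
  } else attr_perturbed <- character(0)
  pl <- peaklist(out, spectrum = paste0("mutant-", resno),
                 scheme = attr(wt, "scheme"))
  attr(pl, "truth_map") <- map
  attr(pl, "perturbed") <- attr_perturbed
  pl
}

#' Simulate PRE intensity-ratio observations
#'
#' Applies the forward model (\code{\link{predict_pre_profile}}) to the
#' ground-truth methyls and adds Gaussian noise to the predicted ratios,
#' clipping at zero (ratios above 1 are retained, as noise produces them in
#' real data). A random fraction of observations is marked unquantifiable,
#' emulating overlapped or vanished peaks.
#'
#' @param truth a \code{ground_truth} object.
#' @param site a \code{\link{place_electron}} site.
#' @param params a \code{\link{pre_parameters}} object.
#' @param sigma ratio noise SD.
#' @param unquantifiable_fraction fraction flagged unquantifiable.
#' @param seed integer random seed.
#' @return data.frame: \code{methyl_id}, \code{ratio}, \code{quantifiable}.
#' @export
simulate_pre <- function(truth, site, params = pre_parameters(), sigma = 0,
                         unquantifiable_fraction = 0, seed = 1) {
  set.seed(seed)
  pred <- predict_pre_profile(truth$methyls, site, params)
  n <- nrow(pred)
  data.frame(methyl_id = pred$methyl_id,
             ratio = pmax(pred$ratio + stats::rnorm(n, 0, sigma), 0),
             quantifiable = stats::runif(n) >= unquantifiable_fraction,
             stringsAsFactors = FALSE)
}

#' Re-key methyl-wise PRE observations by peak id
#'
#' Experimental PRE ratios are measured on peaks; this helper converts
#' ground-truth (methyl-keyed) observations into peak-keyed ones via a
#' truth map, as needed by \code{\link{propagate_assignments}}.
#'
#' @param obs output of \code{\link{simulate_pre}}.
#' @param map a \code{truth_map} (methyl_id, peak_id, form); only major
#'   peaks are re-keyed.
#' @return data.frame: \code{peak_id}, \code{ratio}, \code{quantifiable}.
#' @export
pre_observations_by_peak <- function(obs, map) {
  mm <- map[map$form == "major", , drop = FALSE]
  i <- match(mm$methyl_id, obs$methyl_id)
  keep <- !is.na(i)
  data.frame(peak_id = mm$peak_id[keep], ratio = obs$ratio[i[keep]],
             quantifiable = obs$quantifiable[i[keep]],
             stringsAsFactors = FALSE)
}

#' Simulate inter-methyl NOESY cross-peaks
#'
#' One 4D cross-peak per expected contact retained by a Bernoulli
#' completeness draw, at the true shift coordinates of the two methyls plus
#' jitter, with intensity proportional to r^-6.
#'
#' @param truth a \code{ground_truth} object.
#' @param cutoff contact distance cutoff (\AA, default 8).
#' @param completeness probability that a contact yields an observed peak.
#' @param jitter_H,jitter_C shift jitter SD (ppm).
#' @param seed integer random seed.
#' @return a \code{\link{noe_peaks}} table with attribute
#'   \code{truth_contacts} (the generating contact table rows).
#' @export
simulate_noe <- function(truth, cutoff = 8, completeness = 1,
                         jitter_H = 0, jitter_C = 0, seed = 1) {
  set.seed(seed)
  contacts <- expected_contacts(truth$methyls, cutoff = cutoff)
  keep <- stats::runif(nrow(contacts)) <= completeness
  cc <- contacts[keep, , drop = FALSE]
  sh <- truth$shifts
  i1 <- match(cc$methyl_1, sh$methyl_id)
  i2 <- match(cc$methyl_2, sh$methyl_id)
  n <- nrow(cc)
  pk <- data.frame(
    H1 = sh$dH[i1] + stats::rnorm(n, 0, jitter_H),
    C1 = sh$dC[i1] + stats::rnorm(n, 0, jitter_C),
    C2 = sh$dC[i2] + stats::rnorm(n, 0, jitter_C),
    H2 = sh$dH[i2] + stats::rnorm(n, 0, jitter_H),
    intensity = (10 / cc$distance)^6, stringsAsFactors = FALSE)
  out <- noe_peaks(pk, layout = "hcch", spectrum = "noesy-sim")
  attr(out, "truth_contacts") <- cc
  out
}

#' Simulate geminal pairing records
#'
#' Emulates the output of an experiment correlating the two terminal
#' methyls of each Leu/Val residue through their shared CG/CB frequency:
#' one (peak id, peak id) record per Leu/Val residue whose two major peaks
#' are present in the peak list, each retained with probability
#' \code{completeness}.
#'
#' @param truth a \code{ground_truth} object.
#' @param peaks a \code{\link{simulate_peaklist}} output.
#' @param completeness probability a residue yields a pairing record.
#' @param seed integer random seed.
#' @return data.frame with columns \code{peak_1}, \code{peak_2}, suitable
#'   for \code{\link{pair_geminal}}.
#' @export
simulate_geminal_pairs <- function(truth, peaks, completeness = 1,
                                   seed = 1) {
  set.seed(seed)
  map <- attr(peaks, "truth_map")
  mm <- map[map$form == "major", , drop = FALSE]
  m <- truth$methyls
  out <- list()
  for (rn in unique(m$resno[m$restype %in% c("LEU", "VAL")])) {
    ids <- m$methyl_id[m$resno == rn]
    pk <- mm$peak_id[match(ids, mm$methyl_id)]
    if (length(pk) == 2 && !any(is.na(pk)) &&
        stats::runif(1) <= completeness)
      out[[length(out) + 1L]] <- data.frame(peak_1 = pk[1], peak_2 = pk[2],
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(peak_1 = character(), peak_2 = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Simulate stereospecific sample peak lists
#'
#' Emulates the spectra of stereospecifically labelled samples: the pro-R
#' list contains the Leu-delta1 and Val-gamma1 peaks (an LV[pro-R] sample),
#' the pro-S list the Met-epsilon and Val-gamma2 peaks (an MV[pro-S]
#' sample), each at the true shifts plus jitter.
#'
#' @param truth a \code{ground_truth} object.
#' @param sigma_H,sigma_C shift jitter SD (ppm).
#' @param seed integer random seed.
#' @return list with \code{pro_R} and \code{pro_S} \code{\link{peaklist}}s.
#' @export
simulate_stereo_lists <- function(truth, sigma_H = 0, sigma_C = 0,
                                  seed = 1) {
  set.seed(seed)
  m <- truth$methyls
  sh <- truth$shifts
  mk <- function(ids, scheme) {
    i <- match(ids, sh$methyl_id)
    n <- length(ids)
    peaklist(data.frame(
      id = sprintf("st%03d", seq_len(n)),
      dH = sh$dH[i] + stats::rnorm(n, 0, sigma_H),
      dC = sh$dC[i] + stats::rnorm(n, 0, sigma_C),
      stringsAsFactors = FALSE), spectrum = scheme, scheme = scheme)
  }
  list(pro_R = mk(m$methyl_id[!is.na(m$stereo) & m$stereo == "pro-R"],
                  "LV[pro-R]"),
       pro_S = mk(m$methyl_id[m$restype == "MET" |
                              (!is.na(m$stereo) & m$stereo == "pro-S" &
                               m$restype == "VAL")],
                  "MV[pro-S]"))
}

#' Simulate two chemical-shift prediction tables
#'
#' Emulates the outputs of two structure-based shift predictors: source A
#' reports per-shift uncertainties, source B does not. Predicted values are
#' the true shifts plus Gaussian predictor error.
#'
#' @param truth a \code{ground_truth} object.
#' @param error_H,error_C predictor error SD (ppm), applied independently to
#'   both sources.
#' @param unc_range_H,unc_range_C ranges from which source A's stated
#'   uncertainties are drawn (ppm). The defaults keep the stated
#'   uncertainties calibrated to the actual predictor error (1.5-3x the
#'   error SD, floored at 0.02 ppm for 1H and 0.1 ppm for 13C so that a
#'   perfect predictor still quotes a finite uncertainty).
#' @param coverage_A,coverage_B fraction of keys each source predicts.
#' @param seed integer random seed.
#' @return list with \code{a} and \code{b}: data.frames in the
#'   \code{\link{merge_predictions}} input format.
#' @export
simulate_shift_predictions <- function(truth, error_H = 0.1, error_C = 0.5,
                                       unc_range_H =
                                         0.02 + error_H * c(1.5, 3),
                                       unc_range_C =
                                         0.1 + error_C * c(1.5, 3),
                                       coverage_A = 1, coverage_B = 1,
                                       seed = 1) {
  set.seed(seed)
  sh <- truth$shifts
  long <- rbind(
    data.frame(methyl_id = sh$methyl_id, nucleus = "H", true = sh$dH,
               stringsAsFactors = FALSE),
    data.frame(methyl_id = sh$methyl_id, nucleus = "C", true = sh$dC,
               stringsAsFactors = FALSE))
  err <- function(nuc) ifelse(nuc == "H", error_H, error_C)
  mk <- function(coverage, with_unc) {
    keep <- stats::runif(nrow(long)) <= coverage
    r <- long[keep, , drop = FALSE]
    r$value <- r$true + stats::rnorm(nrow(r), 0, err(r$nucleus))
    if (with_unc)
      r$uncertainty <- ifelse(
        r$nucleus == "H",
        stats::runif(nrow(r), unc_range_H[1], unc_range_H[2]),
        stats::runif(nrow(r), unc_range_C[1], unc_range_C[2]))
    r$true <- NULL
    rownames(r) <- NULL
    r
  }
  list(a = mk(coverage_A, TRUE), b = mk(coverage_B, FALSE))
}
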