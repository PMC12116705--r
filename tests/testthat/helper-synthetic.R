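# Shared fixtures, all built in code.

# a full synthetic study: constellation, peak list, NOE, predictions, PRE,
# geminal/stereo constraints and anchor set, at either noise-free or the
# standard noisy settings (shift jitter 0.005/0.05 ppm, prediction error
# 0.1/0.5 ppm, PRE sigma 0.05, NOE completeness 0.9)
make_study <- function(seed, noisy = FALSE,
                       n_ile = 5, n_leu = 10, n_val = 7, n_met = 3) {
  gt <- generate_constellation(n_ile = n_ile, n_leu = n_leu, n_val = n_val,
                               n_met = n_met, seed = seed)
  jH <- if (noisy) 0.005 else 0
  jC <- if (noisy) 0.05 else 0
  pl <- simulate_peaklist(gt, sigma_H = jH, sigma_C = jC, seed = seed)
  map <- attr(pl, "truth_map")
  major <- map[map$form == "major", , drop = FALSE]
  contacts <- expected_contacts(gt$methyls)
  noe <- simulate_noe(gt, completeness = if (noisy) 0.9 else 1,
                      jitter_H = jH, jitter_C = jC, seed = seed)
  preds <- simulate_shift_predictions(
    gt, error_H = if (noisy) 0.1 else 0, error_C = if (noisy) 0.5 else 0,
    seed = seed)
  merged <- merge_predictions(preds$a, preds$b)
  site <- place_electron(mode = "explicit", coord = c(30, 0, 0))
  obs <- simulate_pre(gt, site, sigma = if (noisy) 0.05 else 0, seed = seed)
  pre <- list(list(pred = predict_pre_profile(gt$methyls, site),
                   obs = pre_observations_by_peak(obs, map)))
  gem <- pair_geminal(simulate_geminal_pairs(gt, pl, seed = seed))
  stl <- simulate_stereo_lists(gt, sigma_H = jH, sigma_C = jC, seed = seed)
  gem <- stereo_assign(gem, pl, stl$pro_R, stl$pro_S)
  anchor_rows <- major[round(seq(1, nrow(major), length.out = 4)),
                       c("methyl_id", "peak_id")]
  list(gt = gt, peaks = pl, map = map, major = major, contacts = contacts,
       noe = noe, merged = merged, pre = pre, geminal = gem,
       anchors = anchor_rows, site = site)
}

# fraction of methyls assigned to their true major peak
recovery_fraction <- function(state, study) {
  truthmap <- stats::setNames(study$major$peak_id, study$major$methyl_id)
  sum(state$map$peak_id == truthmap[state$map$methyl_id]) /
    nrow(study$gt$methyls)
}

run_propagation <- function(study, ...) {
  propagate_assignments(study$anchors, study$gt$methyls, study$peaks,
                        study$contacts, study$noe, study$merged, study$pre,
                        geminal = study$geminal, ...)
}

# minimal methyl table from bare coordinates (for geometry-only tests)
methyls_from_coords <- function(xyz, ids = NULL) {
  n <- nrow(xyz)
  if (is.null(ids)) ids <- sprintf("L%d-QD1", seq_len(n))
  data.frame(methyl_id = ids, chain = "A",
             resno = as.integer(sub("^[A-Z]([0-9]+)-.*$", "\\1", ids)),
             restype = "LEU", label = "delta1", stereo = "pro-R",
             cx = xyz[, 1], cy = xyz[, 2], cz = xyz[, 3],
             px = xyz[, 1], py = xyz[, 2], pz = xyz[, 3],
             stringsAsFactors = FALSE)
}

# a small PDB file with one Leu, one Val, one Ile, one Met, one Ala (text
# fixture written at test time)
write_toy_pdb <- function(path) {
  fmt <- function(serial, name, res, chain, resno, x, y, z)
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, res, chain, resno, x, y, z)
  lines <- c(
    # Leu 1: chi2 = 180 (trans) by construction
    fmt(1, " N", "LEU", "A", 1, 0, 0, 1.0),
    fmt(2, " CA", "LEU", "A", 1, 0, 0, 0),
    fmt(3, " CB", "LEU", "A", 1, 1.53, 0, 0),
    fmt(4, " CG", "LEU", "A", 1, 2.2, 1.3, 0),
    fmt(5, " CD1", "LEU", "A", 1, 3.7, 1.3, 0),
    fmt(6, " CD2", "LEU", "A", 1, 1.8, 2.1, 1.2),
    # Val 2
    fmt(7, " CA", "VAL", "A", 2, 10, 0, 0),
    fmt(8, " CB", "VAL", "A", 2, 11.5, 0, 0),
    fmt(9, " CG1", "VAL", "A", 2, 12.2, 1.3, 0),
    fmt(10, " CG2", "VAL", "A", 2, 12.2, -1.3, 0),
    # Ile 3
    fmt(11, " CA", "ILE", "A", 3, 20, 0, 0),
    fmt(12, " CB", "ILE", "A", 3, 21.5, 0, 0),
    fmt(13, " CG1", "ILE", "A", 3, 22.2, 1.3, 0),
    fmt(14, " CG2", "ILE", "A", 3, 22.0, -1.4, 0),
    fmt(15, " CD1", "ILE", "A", 3, 23.7, 1.3, 0),
    # Met 4
    fmt(16, " CA", "MET", "A", 4, 30, 0, 0),
    fmt(17, " CB", "MET", "A", 4, 31.5, 0, 0),
    fmt(18, " CG", "MET", "A", 4, 32.2, 1.3, 0),
    fmt(19, " SD", "MET", "A", 4, 33.9, 1.3, 0),
    fmt(20, " CE", "MET", "A", 4, 34.6, 2.9, 0),
    # Ala 5 (no methyl of interest)
    fmt(21, " CA", "ALA", "A", 5, 40, 0, 0),
    fmt(22, " CB", "ALA", "A", 5, 41.5, 0, 0),
    "END")
  writeLines(lines, path)
  path
}
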