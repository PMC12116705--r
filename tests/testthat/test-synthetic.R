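test_that("constellation generation is reproducible and self-avoiding", {
  gt1 <- generate_constellation(n_ile = 6, n_leu = 10, n_val = 8,
                                n_met = 4, seed = 5)
  gt2 <- generate_constellation(n_ile = 6, n_leu = 10, n_val = 8,
                                n_met = 4, seed = 5)
  expect_identical(gt1, gt2)
  gt3 <- generate_constellation(n_ile = 6, n_leu = 10, n_val = 8,
                                n_met = 4, seed = 6)
  expect_false(identical(gt1$methyls$px, gt3$methyls$px))
  # methyls of different residues at least min_separation apart
  d <- methyl_distance_matrix(gt1$methyls)
  res <- sub("-.*$", "", rownames(d))
  off <- d[outer(res, res, "!=")]
  expect_gte(min(off), 4)
  # geminal partners at the fixed separation
  gem <- d[outer(res, res, "==")]
  gem <- gem[gem > 0]
  expect_equal(unique(round(gem, 9)), 3)
  # empty request
  gt0 <- generate_constellation(seed = 1)
  expect_equal(nrow(gt0$methyls), 0)
  # infeasible density errors out
  expect_error(
    generate_constellation(n_leu = 50, min_separation = 40, seed = 1),
    "density")
})

test_that("true shifts fall in the residue-type ranges", {
  gt <- generate_constellation(n_ile = 10, n_leu = 10, n_val = 10,
                               n_met = 10, seed = 9)
  sh <- merge(gt$shifts, gt$methyls[, c("methyl_id", "restype")])
  rng <- list(ILE = list(C = c(9, 16), H = c(0.2, 1.2)),
              MET = list(C = c(15, 19), H = c(1.5, 2.3)),
              LEU = list(C = c(21, 27), H = c(0.3, 1.1)),
              VAL = list(C = c(19, 24), H = c(0.4, 1.1)))
  for (t in names(rng)) {
    s <- sh[sh$restype == t, ]
    expect_true(all(s$dC >= rng[[t]]$C[1] & s$dC <= rng[[t]]$C[2]))
    expect_true(all(s$dH >= rng[[t]]$H[1] & s$dH <= rng[[t]]$H[2]))
  }
  # minor-form offsets: 13C only, 0.2-1.0 ppm magnitude
  expect_true(all(gt$minor$ddH == 0))
  expect_true(all(abs(gt$minor$ddC) >= 0.2 & abs(gt$minor$ddC) <= 1.0))
})

test_that("peak simulation respects jitter and minor-form settings", {
  gt <- generate_constellation(n_ile = 5, n_leu = 5, n_val = 5, n_met = 5,
                               minor_fraction = 0, seed = 13)
  pl <- simulate_peaklist(gt, sigma_H = 0, sigma_C = 0, seed = 13)
  expect_equal(nrow(pl), nrow(gt$methyls))  # minor fraction 0
  map <- attr(pl, "truth_map")
  i <- match(map$methyl_id, gt$shifts$methyl_id)
  j <- match(map$peak_id, pl$id)
  expect_equal(pl$dH[j], gt$shifts$dH[i])  # jitter 0 -> exact
  expect_equal(pl$dC[j], gt$shifts$dC[i])
  # minor peaks appear once per minor-form methyl, weaker than majors
  gtm <- generate_constellation(n_ile = 5, n_leu = 5, n_val = 5, n_met = 5,
                                minor_fraction = 0.2, seed = 13)
  plm <- simulate_peaklist(gtm, seed = 13)
  mapm <- attr(plm, "truth_map")
  expect_equal(sum(mapm$form == "minor"), nrow(gtm$minor))
  expect_equal(nrow(plm), nrow(gtm$methyls) + nrow(gtm$minor))
  for (k in which(mapm$form == "minor")) {
    mid <- mapm$methyl_id[k]
    imaj <- mapm$peak_id[mapm$methyl_id == mid & mapm$form == "major"]
    expect_lt(plm$intensity[plm$id == mapm$peak_id[k]],
              plm$intensity[plm$id == imaj])
  }
})

test_that("simulated 13C jitter reproduces its nominal SD", {
  gt <- generate_constellation(n_ile = 10, n_leu = 10, n_val = 10,
                               n_met = 10, minor_fraction = 0, seed = 3)
  devs <- numeric(0)
  for (seed in 1:20) {
    pl <- simulate_peaklist(gt, sigma_H = 0.01, sigma_C = 0.1, seed = seed)
    map <- attr(pl, "truth_map")
    i <- match(map$methyl_id, gt$shifts$methyl_id)
    j <- match(map$peak_id, pl$id)
    devs <- c(devs, pl$dC[j] - gt$shifts$dC[i])
  }
  expect_equal(sd(devs), 0.1, tolerance = 0.1)
})

test_that("mutant simulation removes exactly the mutated residue's peaks", {
  gt <- generate_constellation(n_ile = 4, n_leu = 6, n_val = 4, n_met = 3,
                               minor_fraction = 0, seed = 19)
  wt <- simulate_peaklist(gt, seed = 19)
  met <- unique(gt$methyls$resno[gt$methyls$restype == "MET"])[1]
  leu <- unique(gt$methyls$resno[gt$methyls$restype == "LEU"])[1]
  expect_equal(nrow(wt) - nrow(simulate_mutant(gt, wt, met)), 1)
  expect_equal(nrow(wt) - nrow(simulate_mutant(gt, wt, leu)), 2)
  ala_free <- max(gt$methyls$resno) + 1
  expect_error(simulate_mutant(gt, wt, ala_free), "no methyls")
  # neighbour perturbation equals a brute-force radius scan
  mutp <- simulate_mutant(gt, wt, leu, perturb_radius = 5, seed = 19)
  m <- gt$methyls
  mut_xyz <- m[m$resno == leu, c("px", "py", "pz")]
  near <- vapply(seq_len(nrow(m)), function(i) {
    d2 <- (mut_xyz$px - m$px[i])^2 + (mut_xyz$py - m$py[i])^2 +
      (mut_xyz$pz - m$pz[i])^2
    any(d2 <= 25)
  }, logical(1))
  expected_ids <- setdiff(m$methyl_id[near], m$methyl_id[m$resno == leu])
  map <- attr(wt, "truth_map")
  expected_peaks <- map$peak_id[map$methyl_id %in% expected_ids]
  expect_setequal(attr(mutp, "perturbed"),
                  intersect(expected_peaks, mutp$id))
})

test_that("PRE simulation matches the forward model at zero noise", {
  gt <- generate_constellation(n_ile = 6, n_leu = 6, n_val = 6, n_met = 2,
                               seed = 27)
  site <- place_electron(mode = "explicit", coord = c(20, 0, 0))
  obs <- simulate_pre(gt, site, sigma = 0, seed = 27)
  pred <- predict_pre_profile(gt$methyls, site)
  expect_equal(obs$ratio, pred$ratio)
  expect_true(all(obs$quantifiable))
  far <- place_electron(mode = "explicit", coord = c(1e4, 0, 0))
  expect_true(all(simulate_pre(gt, far, seed = 1)$ratio > 0.999))
  # unquantifiable flagging
  obs2 <- simulate_pre(gt, site, unquantifiable_fraction = 0.5, seed = 27)
  expect_true(any(!obs2$quantifiable) && any(obs2$quantifiable))
  # noise is clipped at zero
  obs3 <- simulate_pre(gt, site, sigma = 2, seed = 27)
  expect_true(all(obs3$ratio >= 0))
})

test_that("NOE simulation tracks the contact graph", {
  gt <- generate_constellation(n_ile = 5, n_leu = 8, n_val = 5, n_met = 2,
                               seed = 37)
  contacts <- expected_contacts(gt$methyls)
  noe <- simulate_noe(gt, completeness = 1, jitter_H = 0, jitter_C = 0,
                      seed = 37)
  expect_equal(nrow(noe), nrow(contacts))
  expect_equal(nrow(simulate_noe(gt, completeness = 0, seed = 37)), 0)
  # intensity ordering matches inverse distance ordering at zero jitter
  cc <- attr(noe, "truth_contacts")
  expect_equal(order(noe$intensity, decreasing = TRUE),
               order(cc$distance))
})

test_that("geminal pair and stereo list simulation agree with truth", {
  gt <- generate_constellation(n_ile = 3, n_leu = 7, n_val = 5, n_met = 2,
                               minor_fraction = 0, seed = 41)
  pl <- simulate_peaklist(gt, seed = 41)
  pairs <- simulate_geminal_pairs(gt, pl, seed = 41)
  expect_equal(nrow(pairs), 7 + 5)   # one record per Leu/Val residue
  map <- attr(pl, "truth_map")
  res_of <- function(p) {
    mid <- map$methyl_id[match(p, map$peak_id)]
    sub("-.*$", "", mid)
  }
  expect_equal(res_of(pairs$peak_1), res_of(pairs$peak_2))
  stl <- simulate_stereo_lists(gt, seed = 41)
  m <- gt$methyls
  expect_equal(nrow(stl$pro_R), sum(m$stereo == "pro-R", na.rm = TRUE))
  expect_equal(nrow(stl$pro_S),
               sum(m$restype == "MET") +
                 sum(m$stereo == "pro-S" & m$restype == "VAL"))
})
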