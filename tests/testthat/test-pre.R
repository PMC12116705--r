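# Frozen reference values below were computed with an independent
# arbitrary-precision evaluation of the printed equations (50-digit decimal
# arithmetic) before this module was written.

test_that("kappa_H reproduces the published prefactor", {
  k <- kappa_H()
  expect_equal(k, 1.23107563617e16, tolerance = 1e-9)
  # published value 1.2311e16 A^6 s^-2, within 0.05%
  expect_lt(abs(k - 1.2311e16) / 1.2311e16, 5e-4)
})

test_that("kappa_H scales as stated in gamma_H and S", {
  c0 <- physical_constants()
  c2 <- physical_constants(gamma_H = 2 * c0$gamma_H)
  expect_equal(kappa_H(c2) / kappa_H(c0), 4)
  cS1 <- physical_constants(S_e = 1)
  expect_equal(kappa_H(cS1) / kappa_H(c0), (1 * 2) / (0.5 * 1.5))
  expect_error(physical_constants(g_e = -1), "positive")
})

test_that("gamma2_H follows the Solomon-Bloembergen form", {
  p <- pre_parameters()  # S2 0.8, tau 20 ns, 850 MHz
  expect_equal(gamma2_H(20, p), 12.3115655515, tolerance = 1e-9)
  expect_equal(gamma2_H(10, p), 787.9401953, tolerance = 1e-9)
  # r^-6 law: halving r multiplies by 64
  expect_equal(gamma2_H(10, p) / gamma2_H(20, p), 64, tolerance = 1e-12)
  # far-field limit
  expect_lt(gamma2_H(1e6, p), 1e-20)
  expect_error(gamma2_H(0, p), "positive")
  expect_error(gamma2_H(-3, p), "positive")
})

test_that("gamma2_H * r^6 is constant in r", {
  p <- pre_parameters()
  r <- c(seq(2, 100, by = 0.7), 500, 1000)
  prod <- gamma2_H(r, p) * r^6
  expect_lt(max(abs(prod / prod[1] - 1)), 1e-12)
})

test_that("multiple-quantum scaling factor is 1.063", {
  p <- pre_parameters()
  expect_equal(round(p$mq_factor, 3), 1.063)
  expect_equal(gamma2_MQ(0, p), 0)
  expect_equal(round(gamma2_MQ(100, p), 1), 106.3)
  expect_error(gamma2_MQ(-1, p), "non-negative")
})

test_that("intensity ratio is 1 at zero PRE and strictly decreasing", {
  p <- pre_parameters()
  expect_identical(intensity_ratio(0, p), 1)
  g <- seq(0, 500, by = 0.5)
  r <- intensity_ratio(g, p)
  expect_true(all(diff(r) < 0))
  expect_true(all(r > 0 & r <= 1))
  expect_lt(intensity_ratio(1e5, p), 1e-12)
  # frozen oracle: ratio at the 20-A default-parameter PRE
  expect_equal(intensity_ratio(gamma2_H(20, p), p), 0.60318789076,
               tolerance = 1e-9)
  expect_error(intensity_ratio(-1, p), "non-negative")
})

test_that("place_electron implements both placement modes", {
  s <- structure_from_atoms(data.frame(
    chain = "A", resno = c(1, 1, 2), restype = c("SER", "SER", "GLY"),
    atom = c("CA", "CB", "CA"), x = c(0, 1.5, 5), y = 0, z = 0,
    stringsAsFactors = FALSE))
  site <- place_electron(s, "A", 1, mode = "cb_offset", offset = 7)
  expect_equal(site$electron_coord, c(8.5, 0, 0))
  site0 <- place_electron(s, "A", 1, mode = "cb_offset", offset = 0)
  expect_equal(site0$electron_coord, c(1.5, 0, 0))
  ex <- place_electron(mode = "explicit", coord = c(1, 2, 3))
  expect_equal(ex$electron_coord, c(1, 2, 3))
  expect_error(place_electron(s, "A", 2, mode = "cb_offset"), "CB")
})

test_that("predict_pre_profile composes the scalar operations", {
  p <- pre_parameters()
  set.seed(3)
  xyz <- matrix(runif(60, -20, 20), ncol = 3)
  m <- methyls_from_coords(xyz)
  site <- place_electron(mode = "explicit", coord = c(40, 40, 40))
  prof <- predict_pre_profile(m, site, p)
  for (i in seq_len(nrow(m))) {
    r <- sqrt(sum((xyz[i, ] - c(40, 40, 40))^2))
    expect_equal(prof$r_eN[i], r)
    expect_equal(prof$gamma2_H[i], gamma2_H(r, p))
    expect_equal(prof$gamma2_MQ[i], gamma2_MQ(gamma2_H(r, p), p))
    expect_equal(prof$ratio[i], intensity_ratio(gamma2_H(r, p), p))
  }
  # permutation equivariance
  perm <- sample(nrow(m))
  prof2 <- predict_pre_profile(m[perm, ], site, p)
  expect_equal(prof2$ratio, prof$ratio[perm])
  # far-field: everything beyond 60 A barely attenuates
  far <- place_electron(mode = "explicit", coord = c(500, 0, 0))
  expect_true(all(predict_pre_profile(m, far, p)$ratio > 0.99))
})

test_that("compare_pre reports residuals and consistency", {
  p <- pre_parameters()
  set.seed(5)
  m <- methyls_from_coords(matrix(runif(45, -20, 20), ncol = 3))
  site <- place_electron(mode = "explicit", coord = c(25, 0, 0))
  pred <- predict_pre_profile(m, site, p)
  obs <- data.frame(methyl_id = pred$methyl_id, ratio = pred$ratio)
  cmp <- compare_pre(obs, pred)
  expect_equal(cmp$rms, 0)
  expect_equal(cmp$n_consistent, nrow(pred))
  # one perturbed observation becomes inconsistent at tolerance 0.2
  obs2 <- obs
  obs2$ratio[4] <- obs2$ratio[4] + 0.5
  cmp2 <- compare_pre(obs2, pred, tolerance = 0.2)
  expect_equal(cmp2$n_consistent, nrow(pred) - 1)
  # unquantifiable observations are excluded, not imputed
  obs3 <- obs
  obs3$quantifiable <- c(FALSE, rep(TRUE, nrow(obs) - 1))
  expect_equal(compare_pre(obs3, pred)$n, nrow(obs) - 1)
  expect_error(compare_pre(data.frame(methyl_id = "zz", ratio = 1), pred),
               "overlapping")
})

test_that("RMS residual tracks the injected noise level", {
  p <- pre_parameters()
  sigma <- 0.05
  rms <- numeric(40)
  for (seed in seq_along(rms)) {
    gt <- generate_constellation(n_ile = 10, n_leu = 10, n_val = 5,
                                 seed = seed)
    site <- place_electron(mode = "explicit", coord = c(25, 0, 0))
    obs <- simulate_pre(gt, site, params = p, sigma = sigma, seed = seed)
    pred <- predict_pre_profile(gt$methyls, site, p)
    rms[seed] <- compare_pre(obs, pred)$rms
  }
  expect_equal(mean(rms), sigma, tolerance = 0.1)
})

test_that("spin-label localization recovers the electron position", {
  p <- pre_parameters()
  set.seed(9)
  m <- methyls_from_coords(matrix(runif(120, -25, 25), ncol = 3))
  # noise-free, true electron on a grid node -> recovered exactly
  truth <- c(10, -6, 4)
  site <- place_electron(mode = "explicit", coord = truth)
  pred <- predict_pre_profile(m, site, p)
  obs <- data.frame(methyl_id = pred$methyl_id, ratio = pred$ratio)
  fit <- localize_spin_label(obs, m, p, grid = list(x = seq(-30, 30, 2),
                                                    y = seq(-30, 30, 2),
                                                    z = seq(-30, 30, 2)))
  expect_equal(fit$coord, truth)
  expect_lt(fit$objective, 1e-20)
  # off-grid electron, 1-A spacing -> within one lattice step
  truth2 <- c(7.4, -2.3, 11.8)
  pred2 <- predict_pre_profile(
    m, place_electron(mode = "explicit", coord = truth2), p)
  obs2 <- data.frame(methyl_id = pred2$methyl_id, ratio = pred2$ratio)
  fit2 <- localize_spin_label(obs2, m, p,
                              grid = list(x = seq(0, 15, 1),
                                          y = seq(-10, 5, 1),
                                          z = seq(5, 20, 1)))
  expect_true(all(abs(fit2$coord - truth2) <= 1))
  expect_error(localize_spin_label(obs2[1:3, ], m, p), "at least 4")
})

test_that("collinear methyl geometry triggers a degeneracy warning", {
  p <- pre_parameters()
  m <- methyls_from_coords(cbind(seq(0, 40, length.out = 8), 0, 0))
  site <- place_electron(mode = "explicit", coord = c(20, 10, 0))
  pred <- predict_pre_profile(m, site, p)
  obs <- data.frame(methyl_id = pred$methyl_id, ratio = pred$ratio)
  expect_warning(
    localize_spin_label(obs, m, p, grid = list(x = seq(10, 30, 5),
                                               y = seq(0, 20, 5),
                                               z = seq(-10, 10, 5))),
    "collinear")
})
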