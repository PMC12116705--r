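test_that("peaklist and assignment state enforce their invariants", {
  df <- data.frame(id = c("p1", "p2"), dH = c(0.5, 0.9), dC = c(22, 14),
                   stringsAsFactors = FALSE)
  pl <- peaklist(df, scheme = "ILV[rac]")
  expect_s3_class(pl, "peaklist")
  expect_error(peaklist(rbind(df, df)), "duplicate")
  expect_error(peaklist(data.frame(id = "p", dH = NA, dC = 1)), "finite")
  expect_error(peaklist(df, scheme = "bogus"), "scheme")
  st <- assignment_state(c("L1-QD1", "L1-QD2"), pl)
  st <- add_assignment(st, "L1-QD1", "p1")
  expect_error(add_assignment(st, "L1-QD1", "p2"), "already assigned")
  expect_error(add_assignment(st, "L1-QD2", "p1"), "already assigned")
  expect_error(add_assignment(st, "L9-QD1", "p2"), "unknown methyl")
  st <- add_assignment(st, "L1-QD2", "p2", confidence = 0.7, "noe")
  expect_equal(nrow(st$map), 2)
  expect_equal(length(unassigned(st)$methyls), 0)
})

test_that("anchor detection finds peaks that vanish in the mutant", {
  df <- data.frame(id = sprintf("p%d", 1:6),
                   dH = c(0.5, 0.9, 1.1, 0.3, 0.7, 1.5),
                   dC = c(22, 14, 24, 21, 23, 17),
                   stringsAsFactors = FALSE)
  wt <- peaklist(df, scheme = "IMLV[rac]")
  # identical lists -> no candidates (with a deficit warning)
  expect_warning(none <- detect_anchors(wt, wt, "L10"), "deficit")
  expect_equal(nrow(none), 0)
  # two removed peaks -> exactly those two, status ok
  mut <- peaklist(df[-c(1, 4), ], scheme = "IMLV[rac]")
  cand <- detect_anchors(wt, mut, "L10")
  expect_equal(sort(cand$id), c("p1", "p4"))
  expect_equal(attr(cand, "status"), "ok")
  # Ile expects one methyl; two missing peaks is a surplus
  expect_warning(s <- detect_anchors(wt, mut, "I10"), "surplus")
  expect_equal(attr(s, "status"), "surplus")
  # labelling scheme incompatible with the mutated residue type
  wt_lv <- peaklist(df, scheme = "LV[rac]")
  mut_lv <- peaklist(df[-2, ], scheme = "LV[rac]")
  expect_error(detect_anchors(wt_lv, mut_lv, "I10"), "scheme")
  expect_error(detect_anchors(wt, mut, "A10"), "Ile/Leu/Val/Met")
})

test_that("anchor detection recovers a deleted Leu under jitter", {
  hits <- logical(50)
  for (seed in seq_along(hits)) {
    gt <- generate_constellation(n_ile = 5, n_leu = 12, n_val = 8,
                                 n_met = 3, minor_fraction = 0,
                                 seed = seed)
    wt <- simulate_peaklist(gt, sigma_H = 0, sigma_C = 0, seed = seed)
    leu <- unique(gt$methyls$resno[gt$methyls$restype == "LEU"])
    target <- leu[1 + seed %% length(leu)]
    mut <- simulate_mutant(gt, wt, target, seed = seed)
    # re-jitter the mutant list to emulate sample-to-sample variation
    mdf <- as.data.frame(mut)
    set.seed(seed + 1000)
    mdf$dH <- mdf$dH + rnorm(nrow(mdf), 0, 0.005)
    mdf$dC <- mdf$dC + rnorm(nrow(mdf), 0, 0.05)
    mut2 <- peaklist(mdf, scheme = attr(wt, "scheme"))
    cand <- suppressWarnings(
      detect_anchors(wt, mut2, paste0("L", target)))
    map <- attr(wt, "truth_map")
    truth <- map$peak_id[map$methyl_id %in%
                           gt$methyls$methyl_id[gt$methyls$resno == target]]
    hits[seed] <- setequal(cand$id, truth)
  }
  expect_gte(mean(hits), 0.95)
})

test_that("geminal pairing accepts disjoint pairs and rejects conflicts", {
  expect_equal(nrow(pair_geminal(data.frame(peak_1 = character(),
                                            peak_2 = character()))), 0)
  pr <- data.frame(peak_1 = c("p1", "p3", "p5"),
                   peak_2 = c("p2", "p4", "p6"), stringsAsFactors = FALSE)
  gp <- pair_geminal(pr)
  expect_equal(nrow(gp), 3)
  bad <- data.frame(peak_1 = c("p1", "p2"), peak_2 = c("p2", "p3"),
                    stringsAsFactors = FALSE)
  expect_error(pair_geminal(bad), "conflict")
  expect_error(pair_geminal(data.frame(peak_1 = "p1", peak_2 = "p1")),
               "distinct")
})

test_that("stereo labels resolve from the stereospecific lists", {
  peaks <- peaklist(data.frame(id = c("p1", "p2", "p3", "p4"),
                               dH = c(0.5, 0.8, 1.0, 1.2),
                               dC = c(22, 24, 20, 21),
                               stringsAsFactors = FALSE))
  pairs <- pair_geminal(data.frame(peak_1 = c("p1", "p3"),
                                   peak_2 = c("p2", "p4"),
                                   stringsAsFactors = FALSE))
  proR <- peaklist(data.frame(id = "r1", dH = 0.5, dC = 22,
                              stringsAsFactors = FALSE))
  res <- stereo_assign(pairs, peaks, pro_R_peaks = proR)
  expect_equal(res$status, c("resolved", "ambiguous"))
  expect_equal(res$pro_R[1], "p1")
  expect_equal(res$pro_S[1], "p2")
  expect_true(is.na(res$pro_R[2]))
  # pro-S list resolves the complement
  proS <- peaklist(data.frame(id = "s1", dH = 1.2, dC = 21,
                              stringsAsFactors = FALSE))
  res2 <- stereo_assign(pairs, peaks, pro_S_peaks = proS)
  expect_equal(res2$status, c("ambiguous", "resolved"))
  expect_equal(res2$pro_R[2], "p3")
  # both members matching the same list -> conflict
  proRR <- peaklist(data.frame(id = c("r1", "r2"), dH = c(0.5, 0.8),
                               dC = c(22, 24), stringsAsFactors = FALSE))
  res3 <- stereo_assign(pairs, peaks, pro_R_peaks = proRR)
  expect_equal(res3$status[1], "conflict")
})

test_that("full noise-free stereo resolution on a synthetic Leu/Val set", {
  study <- make_study(17, noisy = FALSE)
  gem <- study$geminal
  lv <- gem[gem$status == "resolved", ]
  expect_equal(nrow(lv), nrow(gem))  # all pairs resolved
  # resolved labels agree with ground truth
  m <- study$gt$methyls
  map <- study$major
  for (i in seq_len(nrow(lv))) {
    mid <- map$methyl_id[match(lv$pro_R[i], map$peak_id)]
    expect_equal(m$stereo[match(mid, m$methyl_id)], "pro-R")
  }
})

test_that("propagation recovers a noise-free synthetic dataset exactly", {
  study <- make_study(11, noisy = FALSE)   # 42 methyls, 4 anchors
  st <- run_propagation(study)
  expect_equal(recovery_fraction(st, study), 1.0)
  # injectivity
  expect_false(anyDuplicated(st$map$methyl_id) > 0)
  expect_false(anyDuplicated(st$map$peak_id) > 0)
  # idempotence: rerunning on its own output changes nothing
  st2 <- propagate_assignments(st, study$gt$methyls, study$peaks,
                               study$contacts, study$noe, study$merged,
                               study$pre, geminal = study$geminal)
  expect_equal(st2$map, st$map)
})

test_that("without evidence only anchors (and their geminal twins) assign", {
  study <- make_study(13, noisy = FALSE)
  empty_noe <- study$noe[0, ]
  st <- propagate_assignments(study$anchors, study$gt$methyls, study$peaks,
                              study$contacts, noe = empty_noe,
                              merged = NULL, pre = list())
  expect_equal(sort(st$map$methyl_id), sort(study$anchors$methyl_id))
  expect_error(
    propagate_assignments(study$anchors[0, ], study$gt$methyls,
                          study$peaks, study$contacts),
    "empty anchor")
})

test_that("minor-form peaks are flagged and linked, majors are not", {
  gt <- generate_constellation(n_ile = 4, n_leu = 8, n_val = 6, n_met = 2,
                               minor_fraction = 0.15, seed = 23)
  pl <- simulate_peaklist(gt, seed = 23)
  map <- attr(pl, "truth_map")
  major <- map[map$form == "major", ]
  st <- assignment_state(gt$methyls, pl)
  for (i in seq_len(nrow(major)))
    st <- add_assignment(st, major$methyl_id[i], major$peak_id[i])
  flags <- tag_minor_forms(pl, st)
  minor <- map[map$form == "minor", ]
  got <- flags[flags$flag == "minor-or-exchange", ]
  expect_setequal(got$peak_id, minor$peak_id)
  expect_equal(got$linked_methyl[match(minor$peak_id, got$peak_id)],
               minor$methyl_id)
  # with nothing assigned there is nothing to link against
  st0 <- assignment_state(gt$methyls, pl)
  expect_true(all(tag_minor_forms(pl, st0)$flag == "unknown"))
})

test_that("coverage report counts per type and rounds the percentage", {
  expect_equal(coverage_percentage(224, 243), 92L)
  expect_equal(coverage_percentage(0, 10), 0L)
  expect_equal(coverage_percentage(10, 10), 100L)
  expect_error(coverage_percentage(11, 10), "assigned")
  study <- make_study(29, noisy = FALSE, n_ile = 3, n_leu = 5, n_val = 4,
                      n_met = 2)
  st <- run_propagation(study)
  rep <- coverage_report(st, study$gt$methyls)
  expect_equal(rep$total, nrow(study$gt$methyls))
  expect_equal(sum(rep$per_type$assigned), rep$assigned)
  expect_true(all(rep$per_type$assigned <= rep$per_type$total))
  expect_equal(rep$percentage,
               coverage_percentage(rep$assigned, rep$total))
  out <- capture.output(print(rep))
  expect_true(any(grepl("coverage", out)))
})
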