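# methylassign

Structure-guided assignment of methyl-TROSY NMR spectra of large,
selectively ILVM-methyl-labelled proteins.

Backbone-based assignment is impractical for proteins of ~50 kDa and
beyond; their Ile/Leu/Val/Met methyl groups are assigned instead by
combining point-mutant "anchor" peaks, inter-methyl NOESY networks,
paramagnetic relaxation enhancements (PREs) from engineered spin-label
sites, structure-based chemical-shift predictions, and geminal /
stereospecific labelling information against a crystal structure.
`methylassign` turns that manual workflow into tested, deterministic code:

* **PRE forward model** — the simplified Solomon–Bloembergen rate
  $\Gamma_2^H = \kappa_H r_{eN}^{-6} \mathcal{S}^2 \tau_1
  (4 + 3/(1+\omega_0^2\tau_1^2))$ with
  $\kappa_H = (\gamma_H g_e \beta)^2 (\mu_0/4\pi)^2 S(S+1)/15
  = 1.2311\times 10^{16}$ Å⁶ s⁻², the multiple-quantum scaling
  $1 + (\gamma_C/\gamma_H)^2 = 1.063$, the HMQC intensity-ratio predictor,
  observed-vs-predicted comparison, and grid-search spin-label
  localization.
* **Chemical-shift prediction merging** — ensemble of two predictors with
  the average-value / max-uncertainty rule and per-nucleus fallbacks.
* **NOE networks** — expected contact graphs at a distance cutoff and
  cross-peak explanation against a candidate assignment (3D and 4D
  layouts).
* **Assignment engine** — mutant anchor detection, geminal pairing,
  stereospecific pro-R/pro-S resolution, evidence-weighted greedy
  propagation with an abstention margin, minor-form/exchange-peak
  bookkeeping, and coverage reporting.
* **Geometry** — ILVM methyl enumeration with pseudo-atoms from PDB/mmCIF
  coordinates, distance matrices, nearest-methyl queries, χ2 dihedrals and
  rotamer classification.
* **Acquisition utilities** — effective NUS sparsity under spectral-width
  oversampling and coupling-transfer delays.
* **Synthetic data** — seeded generators for ground-truth constellations
  and every derived observable, so the whole pipeline is testable without
  external data.
* **I/O** — peak-list/prediction/PRE TSVs (plus a Sparky-like dialect) and
  an NMR-STAR 3.1 chemical-shift loop writer/reader for BMRB-style
  deposition.

## Worked example

Forward-model scalars and a full synthetic assignment run:

```r
library(methylassign)

p <- pre_parameters()            # S2 = 0.8, tau1 = 20 ns, 850 MHz, ...
kappa_H()                        # 1.2311e+16  (Å^6 s^-2)
round(p$mq_factor, 3)            # 1.063

# predicted HMQC intensity ratios at a few electron-methyl distances
prof <- data.frame(r = c(10, 15, 20, 30))
prof$ratio <- intensity_ratio(gamma2_H(prof$r, p), p)
prof
#>    r ratio
#> 1 10 0.000
#> 2 15 0.113
#> 3 20 0.603
#> 4 30 0.953
```

A methyl 10 Å from the tag is broadened beyond detection, one at 30 Å
barely attenuated — the distance window that makes PREs useful for
assignment. Now a synthetic study at realistic noise: 42 methyls, four
anchor points, 90%-complete NOE data, σ = 0.05 PRE noise and jittered
shifts:

```r
gt  <- generate_constellation(n_ile = 5, n_leu = 10, n_val = 7, n_met = 3,
                              seed = 11)
pl  <- simulate_peaklist(gt, sigma_H = 0.005, sigma_C = 0.05, seed = 11)
map <- attr(pl, "truth_map"); major <- map[map$form == "major", ]

contacts <- expected_contacts(gt$methyls)
noe  <- simulate_noe(gt, completeness = 0.9, jitter_H = 0.005,
                     jitter_C = 0.05, seed = 11)
pred <- simulate_shift_predictions(gt, seed = 11)
merged <- merge_predictions(pred$a, pred$b)
site <- place_electron(mode = "explicit", coord = c(30, 0, 0))
obs  <- simulate_pre(gt, site, sigma = 0.05, seed = 11)
pre  <- list(list(pred = predict_pre_profile(gt$methyls, site),
                  obs  = pre_observations_by_peak(obs, map)))
stl  <- simulate_stereo_lists(gt, seed = 11)
gem  <- stereo_assign(pair_geminal(simulate_geminal_pairs(gt, pl, seed = 11)),
                      pl, stl$pro_R, stl$pro_S)

anchors <- major[c(1, 14, 27, 40), c("methyl_id", "peak_id")]
state <- propagate_assignments(anchors, gt$methyls, pl, contacts, noe,
                               merged, pre, geminal = gem)
coverage_report(state, gt$methyls)
#> Methyl assignment coverage
#>   ILE   5 /   5
#>   MET   3 /   3
#>   LEU  20 /  20
#>   VAL  14 /  14
#>   all  42 /  42  (100%)

head(state$map, 3)
#>   methyl_id peak_id confidence evidence
#> 1   L15-QD1   pk001          1   anchor
#> 2   V18-QG1   pk014          1   anchor
#> 3    L7-QD2   pk029          1   anchor
```

Every assignment carries its evidence trail (`anchor`, `noe`,
`shift-prediction`, `pre`, `geminal`, `stereo`) and a confidence; the
engine abstains on genuinely ambiguous peaks rather than guessing. The
result exports to an NMR-STAR 3.1 chemical-shift loop with
`write_nmrstar(state, gt$methyls, "shifts.str")`.

The methods vignette (`vignettes/methyl-assignment.Rmd`) documents the
models, parameter defaults, the synthetic noise model and the design
decisions.

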