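---
title: "Structure-guided methyl assignment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided methyl assignment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylassign)
```

## The problem

In proteins beyond roughly 40 kDa, backbone-based NMR assignment becomes
impractical and the molecule is instead studied through selectively
protonated Ile/Leu/Val/Met (ILVM) methyl groups on a deuterated background.
Each methyl contributes one ^1^H,^13^C correlation peak to a methyl-TROSY
HMQC spectrum, but nothing in the spectrum says *which* methyl. Assignment
then rests on combining several independent, individually weak sources of
evidence against a crystal (or model) structure:

* **anchor points** — peaks that vanish in the spectrum of an X→Ala point
  mutant belong to the mutated residue;
* **NOE networks** — methyls closer than ~8 Å in the structure should share
  NOESY cross-peaks, so a candidate assignment must reproduce the observed
  cross-peak pattern;
* **PREs** — a nitroxide spin label attached at an engineered cysteine
  broadens nearby methyls with an r^−6^ distance dependence, giving
  coarse-grained distance information over tens of Å;
* **chemical-shift predictions** — structure-based predictors constrain
  which region of shift space a methyl can occupy;
* **geminal pairing and stereospecific labelling** — out-and-back
  ^13^C-COSY experiments identify which two peaks belong to one Leu/Val
  residue, and stereospecifically labelled samples identify which member is
  pro-R (Leu δ1, Val γ1) and which pro-S (Leu δ2, Val γ2).

This package formalizes that workflow as testable code, together with a
synthetic-data generator so every stage can be validated against a known
ground truth.

## The PRE forward model

For an unpaired electron at distance $r_{eN}$ from a methyl proton, the
transverse PRE follows a simplified Solomon–Bloembergen form

$$\Gamma_2^{\mathrm{H}} \;=\; \frac{\kappa_{\mathrm{H}}}{r_{eN}^{6}}\,
\mathcal{S}^2\,\tau_1 \left(4 + \frac{3}{1+\omega_0^2\tau_1^2}\right),
\qquad
\kappa_{\mathrm{H}} = \left(\gamma_{\mathrm{H}} g_e \beta\right)^2
\left(\frac{\mu_0}{4\pi}\right)^2 \frac{S(S+1)}{15},$$

with $\mathcal{S}^2$ the squared order parameter of the electron–nucleus
vector, $\tau_1$ its effective correlation time and $\omega_0$ the ^1^H
Larmor frequency. `kappa_H()` performs the SI → Å^6^ s^−2^ conversion in
one documented place (the factor $10^{60}$), so every other distance in the
package is a plain Ångström value. With $S = 1/2$ the prefactor evaluates
to $1.2311\times10^{16}$ Å^6^ s^−2^.

Two constant choices deserve comment:

* **electron g-factor** — the default is exactly 2, the value
  conventionally used for nitroxide PRE analysis and the one consistent
  with the prefactor above; the CODATA free-electron value (2.00231930436)
  can be passed to `physical_constants()` and shifts all rates by ~0.2%.
* **^13^C/^1^H gyromagnetic ratio** — the multiple-quantum coherence
  observed in HMQC relaxes faster than single-quantum ^1^H by
  $1+(\gamma_C/\gamma_H)^2 = 1.063$.

The observable is the paramagnetic/diamagnetic peak-height ratio

$$\frac{I_{\mathrm{para}}}{I_{\mathrm{dia}}}
 = e^{-\Gamma_2^{\mathrm{H}}\Delta}\,
 \frac{(R_{2}^{\mathrm{MQ}}+\pi\,\mathrm{LB}_{F1})
       (R_{2}^{\mathrm{HSQ}}+\pi\,\mathrm{LB}_{F2})}
      {(R_{2}^{\mathrm{MQ}}+\pi\,\mathrm{LB}_{F1}+\Gamma_2^{\mathrm{MQ}})
       (R_{2}^{\mathrm{HSQ}}+\pi\,\mathrm{LB}_{F2}+\Gamma_2^{\mathrm{H}})},$$

which equals 1 at zero PRE and decreases strictly monotonically. Defaults
(all configurable through `pre_parameters()`): $\mathcal{S}^2 = 0.8$,
$\tau_1 = 20$ ns, spectrometer frequency 850 MHz, total fixed HMQC delay
$\Delta = 7.7$ ms, diamagnetic rates 40 s^−1^, line-broadening 5 Hz. The
850-MHz default reflects the field at which methyl spectra of this protein
class are typically recorded; it only enters through the (weak) spectral
density term.

The spin label is modelled as a single point electron. `place_electron()`
either takes an explicit coordinate or extends the Cα→Cβ bond vector of the
attachment residue by a fixed offset (default 7 Å, approximately the reach
of a PROXYL tag). Conformational ensembles of the tag are out of scope;
this single-point simplification is the same one commonly applied when
interpreting methyl PREs semi-quantitatively.

`localize_spin_label()` inverts the forward model by exhaustive grid
search, minimizing the sum of squared ratio residuals. The search is
deterministic (ties broken in lexicographic grid order) and is validated to
recover a noise-free electron to within one lattice step.

## Merging chemical-shift predictions

Two predictor outputs are merged per (methyl, nucleus) key: when both
predict, the merged value is the unweighted mean and the uncertainty the
larger of predictor A's stated uncertainty and the inter-predictor
difference; keys only in A keep A's uncertainty; keys only in B (which
states none) receive fallbacks of 0.2 ppm (^1^H) and 1.0 ppm (^13^C).
Missing keys are legal — predictors differ in coverage — and
stereo-ambiguous output is the caller's responsibility to duplicate.
Peak–prediction compatibility is the uncertainty-normalized Euclidean
distance in (^1^H, ^13^C) space; the simplest metric consistent with using
predictions as a soft filter rather than a primary assignment source.

## NOE networks

`expected_contacts()` lists all methyl pairs within a cutoff (default 8 Å,
appropriate for methyl–methyl NOESY at 0.4-s mixing; configurable), and
`match_noe()` explains observed cross-peaks by assigned methyl pairs that
are expected contacts, resolving ambiguity by smallest combined shift
deviation. 3D (HCH/CCH) and 4D (HCCH) layouts share one internal
representation with absent dimensions unconstrained. Matching tolerances
default to 0.02 ppm ^1^H and 0.2 ppm ^13^C — typical methyl-TROSY
linewidths.

## The propagation engine

`propagate_assignments()` mimics the incremental manual workflow as a
deterministic greedy scheme. Every (unassigned methyl, unassigned peak)
pair is scored as a weighted sum of three terms in [0, 1]:

| term | content | default weight |
|---|---|---|
| NOE | fraction of the methyl's expected contacts to already-assigned methyls supported by an observed cross-peak at the candidate peak's coordinates | 0.5 |
| shift | $\exp(-s^2/2)$ of the compatibility score $s$ | 0.3 |
| PRE | mean over tag sites of $1-\lvert\mathrm{obs}-\mathrm{pred}\rvert$, clipped to [0, 1] | 0.2 |

The best pair is accepted if its score reaches the threshold (0.4) *and*
leads the runner-up for both its methyl and its peak by a margin (0.1);
this repeats until nothing is acceptable. The weights encode the
qualitative precedence of the manual workflow — NOESY primary, predictions
and PREs supplementary — and the margin makes the engine abstain rather
than guess: in validation it produces unassigned methyls but essentially no
wrong assignments. Ties are broken by residue number, then peak id, so
reruns are bit-identical, and rerunning the engine on its own output is a
no-op.

Geminal pairing and stereospecific information enter as **hard
constraints** rather than score terms, for a structural reason: the two
methyls of one Leu/Val are ~3 Å apart and therefore share essentially the
same contact set, so NOE support cannot distinguish them, and with shift
predictions alone the twins block each other at the runner-up margin.
Pairing removes the degeneracy exactly as it does in practice: a peak known
to be one of a geminal pair cannot be an Ile/Met methyl; a stereo-resolved
peak can only take the matching pro-R/pro-S methyl; and accepting one
member of a pair deterministically assigns the partner peak to the geminal
twin (evidence tags `geminal` and `stereo`). Minor- and exchange-form peaks
never enter the assignable pool.

`tag_minor_forms()` implements the bookkeeping for slow conformational
exchange: an unassigned peak sharing an assigned peak's ^1^H shift but
differing in ^13^C by more than the tolerance is flagged
"minor-or-exchange" and linked to that methyl — the signature of a minor
form whose ^1^H shift change is unresolved, or of an exchange peak mixing
the ^1^H shift of one form with the ^13^C shift of the other. The flag is
deliberately non-committal; separating the two cases needs relaxation
experiments outside this package's scope.

## Geometry

Methyl enumeration covers Ile δ1 (γ2 on request), Leu δ1/δ2, Val γ1/γ2 and
Met ε, with stereo descriptors fixed by (residue type, label). The
pseudo-atom is the centroid of the three methyl protons when protons exist
in the coordinates; for crystal structures without protons the default
fallback is the methyl carbon itself, with an idealized-proton option that
places the centroid 0.3633 Å beyond the carbon along the preceding-bond
axis (tetrahedral geometry, 1.09-Å C–H). Carbon-centred and
proton-centred distances differ by well under the rounding used when
comparing with published nearest-neighbour values, which is why both modes
are provided.

χ2 dihedrals (Leu: Cα–Cβ–Cγ–Cδ1; Ile: Cα–Cβ–Cγ1–Cδ1) use the IUPAC sign
convention, range (−180°, 180°], cross-checked against an independent
torsion implementation. Rotamer classes are half-open 120° bins — trans =
(120, 180] ∪ (−180, −120], gauche+ = (0, 120], gauche− = (−120, 0] — an
unambiguous total partition. Collinear atom triples raise an error rather
than returning an arbitrary angle.

## The synthetic-data generator

`generate_constellation()` places methyls by self-avoiding rejection
sampling in a sphere sized at ~600 Å^3^ per methyl (a realistic packing
density for a globular protein core), geminal pairs 3 Å apart, other
methyls ≥ 4 Å apart. True shifts are drawn uniformly from residue-type
ranges matching the dispersion seen in methyl-TROSY spectra of this protein
class (e.g. Ile δ1 ^13^C ∈ [9, 16] ppm, Met ε ^1^H ∈ [1.5, 2.3] ppm); only
the relative geometry of shift space matters for testing the machinery. A
configurable subset of methyls (default 10%) carries a minor form offset in
^13^C only (|Δδ~C~| ∈ [0.2, 1.0] ppm), emulating the empirically common
carbon-only exchange signature.

Derived observables reuse the package's own forward models: peak lists with
Gaussian jitter and uninformative randomized ids; mutant lists with the
mutated residue's peaks removed (optional neighbour perturbation); PRE
ratios from the forward model plus clipped Gaussian noise; NOESY
cross-peaks per contact with Bernoulli completeness and r^−6^ intensities;
geminal pairing records and stereospecific peak lists; and two
shift-prediction tables whose *stated* uncertainties are calibrated to the
injected predictor error (1.5–3× the error SD, floored at 0.02/0.1 ppm) —
an uncalibrated predictor would make the noise-free validation scenario
unsolvable for accidentally coincident peaks while claiming ±1 ppm
ignorance.

What the generator does **not** emulate: spin diffusion and NOE
volume-to-distance calibration; lineshapes, overlap and peak-picking
errors; tag rotamer ensembles; systematic (structure-correlated) predictor
error; exchange broadening. Passing the synthetic validation therefore
demonstrates the bookkeeping and inference machinery is correct under the
stated noise model, not that real spectra of a large dynamic protein can be
assigned automatically — on real data the engine's abstentions (and the
expert's judgment) matter far more.

## Validation problem sizes

The shipped validation uses constellations of 5 Ile / 10 Leu / 7 Val / 3
Met (42 methyls, 50 peaks including minor forms) with 4 anchor points;
noise-free recovery is exact, and under the standard noisy conditions
(shift jitter 0.005/0.05 ppm, predictor error 0.1/0.5 ppm, PRE σ = 0.05,
NOE completeness 0.9) mean recovery over 25 seeds stays above 90% with no
wrong assignments observed. Distance-matrix, localization and Monte-Carlo
noise checks use 100, 40 and 25 replicates respectively. These sizes keep
the full suite near 20 s while leaving every code path exercised; all
generators are bit-reproducible from their seed.

## Known limitations

* The PRE model omits Curie-spin and cross-correlated terms and never fits
  $\mathcal{S}^2$ or $\tau_1$ from data.
* The localization grid search scales cubically with box size; it is meant
  for coarse tag localization, not refinement.
* The NMR-STAR writer covers the assigned-chemical-shift loop subset only.
* The greedy engine is order-dependent by design (deterministic, auditable)
  and will abstain in truly degenerate spectral regions rather than
  optimize globally.
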