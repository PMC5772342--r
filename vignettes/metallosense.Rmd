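---
title: "Models and methods behind metallosense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metallosense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metallosense)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not demonstrate about
real data. The running example is a homodimeric copper/zinc-sensing
transcriptional repressor whose DNA binding is activated by Zn(ii) and
inhibited by Cu(i), but nothing in the code is specific to that system.

## Mass-action speciation and competition titrations

An `eq_model()` lists free components (metal, chelator, protein site) and
complexes with cumulative formation constants $\beta$ (log10, units
$M^{1-\Sigma s}$ for total stoichiometry $\Sigma s$). `solve_speciation()`
finds the free concentrations $x_j$ satisfying every mass balance

$$T_j = x_j + \sum_i s_{ij}\,\beta_i \prod_k x_k^{s_{ik}}$$

by damped Newton iteration on $u_j=\log x_j$ with the analytic Jacobian
$J_{jk} = \delta_{jk}x_j + \sum_i s_{ij}s_{ik}c_i$. Working in log space
keeps concentrations positive even with $\beta$ spanning $10^{19.8}$;
steps are capped at 10 log units and halved until the residual decreases.
A damped multiplicative mass-balance iteration provides the starting point,
and a small ladder of alternative starts guards against the rare stall; the
solver demands relative mass-balance error below $10^{-11}$ and errors out,
naming the offending point, if 200 iterations do not reach it. The test
suite checks the solution against an independent nested log-space bisection
oracle on two-component systems.

**Assumptions.** Activities equal concentrations (no ionic-strength
corrections), binding is at equilibrium at every titration point, and the
"two identical independent sites per dimer" model is encoded literally as a
site concentration equal to twice the dimer (i.e. the protomer)
concentration with a single per-site constant.

`fit_global_affinity()` fits shared log10 constants across experiments by
least squares. A chelator-competition experiment rarely pins the molar
response of the observed complex, so each experiment carries a nuisance
baseline and response scale; both enter the signal linearly and are
profiled out exactly by linear least squares, leaving a one-dimensional
optimisation over log K (Brent's method over start ± 6 decades by default).
Standard errors come from the curvature of the profiled objective at the
optimum.

**Stoichiometric regime.** When binding is much tighter than the
competition window the objective is flat above some K. The fit profiles the
objective on a grid over the scan width; if the upper end stays within an
objective increase of $4\hat\sigma^2$ (about a 2-sigma rise) of the
minimum, `lower_bound_only` is set and the reported bound is the value
where the profile crosses that threshold from below. With the mag-fura-2
design (12 µM dimer, 16 µM chelator of K = 5.0×10⁷ M⁻¹, 1% noise) the
crossing typically lands at log10 K ≈ 10.2–10.7: the chelator-side binding
strength $K_{mf2}[mf2] \approx 800$ means a K of 10⁹ M⁻¹ would leave
roughly 15% of sub-equivalence metal on the chelator, well above the noise,
so the data genuinely exclude constants below ~10¹⁰. A reported bound of
"at least 10⁹" is therefore implied but conservative.

`detect_stoichiometry_breakpoint()` fits the continuous two-segment model
$y = a + b_1x + (b_2-b_1)(x-c)_+$, linear given the break $c$, optimising
$c$ by Brent plus a 201-point grid guard (the RSS profile of a breakpoint
model is only piecewise smooth). The 95% interval is the F-criterion region
of the profile. A fit whose two slopes do not differ beyond twice their
standard error has no plateau and errors out rather than reporting a
meaningless equivalence point.

## DNA binding and allosteric coupling

`fraction_bound_1to1()` evaluates the single-site quadratic in the form
$f_b = 2K_aP_t/(b+\sqrt{b^2-4K_a^2P_tD_t})$, $b = K_aP_t+K_aD_t+1$, which
is algebraically identical to the textbook root but numerically stable in
the ligand-excess limit $D_t \to 0$, where it reduces to
$K_aP_t/(1+K_aP_t)$. The dimer is treated as non-dissociable — protein
concentrations are dimer units and no monomer–dimer equilibrium is
modelled. Anisotropy is taken as linear in the bound fraction
($r = r_{free} + \Delta r f_b$, no intensity-change correction), the
minimal reading of the model; fits parameterise $K_a$ in log10 and report
standard errors from the Levenberg–Marquardt Jacobian.

`coupling_free_energy()` computes $\Delta G_c = -RT\ln(K_{a,state}/K_{a,ref})$
with R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹ and T defaulting to 298.15 K. The sign
convention is stated prominently because magnitudes are often quoted:
negative means the comparison state binds DNA more tightly (activation).
For the reference constants 1.0×10⁷ and 2.8×10⁶ M⁻¹ the formula gives
|ΔG_c| ≈ 0.75 kcal mol⁻¹; a quoted magnitude of 0.6 kcal mol⁻¹ sometimes reported for this pair is
not reproducible from the two constants alone (it presumably reflects
unrounded inputs), and the package computes the formula rather than
matching a quoted figure.

**Precision at the reference design.** At the reference isotherm design
(20 log-spaced dimer totals over 10⁻⁹–10⁻⁵ M, 10 nM DNA, anisotropy noise
0.001 absolute against an amplitude Δr ≈ 0.014) the single-isotherm
sampling spread of $K_a$ is roughly 20–25% — comparable to the ±0.2×10⁷
uncertainty quoted for the reference fit. Recovery tests at a factor 1.2
therefore hold at typical seeds but are near the design's information
limit; that is a property of the experiment, not of the optimiser.

The DNA-total sensitivity of the fitted $K_a$ is below 2% under a two-fold
misspecification only when $D_t \ll 1/K_a$ (e.g. 2 nM against
$1/K_a$ = 100 nM); at $D_t$ = 10 nM the shift is ~3%, because 10 nM is not
deep in that regime.

## Pulsed-alkylation mass spectrometry

Masses are monoisotopic throughout: residue masses plus water (18.010565)
plus a proton (1.007276) for $[M+H]^+$; NEM Michael addition adds the full
adduct (C₆H₇NO₂ = 125.04768 Da; d5-NEM with ²H = 2.014102 gives 130.07906,
a 5.03138 Da code read as a nominal +5). The protiated reference masses
reproduce the digest table exactly at two decimals; the deuterated entries
in that table sit ~0.012 Da above the standard-deuterium computation per d5
adduct (the table's own spacing is +5.045 per adduct), so computed d5
species agree within 0.02 Da per adduct rather than exactly — the package
uses the standard constant and documents the gap. b/y fragment series obey
$b_i + y_{n-i} = [M+H]^+ + m_p$ exactly, with modifications carried by the
covering fragment.

The kinetic model is pseudo-first-order labelling per cysteine,
$f_i(t) = 1-e^{-k_it}$, with independent sites and an ideal instantaneous
chase; species fractions are products over sites and sum to one. Because
the two-cysteine species set is symmetric under site exchange, peptide-level
data identify the two rates only up to permutation: `fit_alkylation_rates()`
reports them sorted ascending, and attributing a rate to a specific
cysteine requires the MS/MS partition (`site_occupancy_from_fragments()`),
whose raw per-site occupancies are normalised to unit sum for the
singly-deuterated species. Equal ionisation efficiency of isotopologues is
assumed — the premise of the ratiometric design. A rate indistinguishable
from zero (a fully protected site) is reported as 0 with a finite upper
bound: the rate at which the RSS rises $4\hat\sigma^2$ above its minimum,
floored at the rate giving 1% labelling at the last time point so the bound
stays finite on noise-free input.

## SAXS

`guinier_fit()` fits $\ln I = \ln I_0 - q^2R_g^2/3 + cq^4$ over a
self-consistently chosen window $qR_g \le 1.3$ (iterated until the window
and the fitted $R_g$ agree). The quartic term exists because a pure
two-parameter Guinier fit of a sphere over that window overestimates $R_g$
by about 2% — a systematic, not statistical, error; with the correction the
sphere bias is ~0.1% and exact Gaussian input is recovered exactly. The
same term is the aggregation diagnostic: a significantly *positive*
curvature (t > 4) is the low-q upturn of a heterogeneous or aggregating
sample and raises a warning; compact single species give negative
curvature.

`ift_pr()` inverts $I(q) = 4\pi\int_0^{D_{max}} p(r)\,\mathrm{sinc}(qr)\,dr$
on a fixed 101-point r-grid by penalised least squares with a
second-difference roughness penalty (scaled by the trace ratio of the two
Gram matrices so the weight is dimensionless) and hard zero endpoints.
Negativity is not constrained but reported as the negative share of total
absolute area. The automatic weight is chosen by a bounded-misfit rule —
the largest (smoothest) weight whose weighted RSS stays within 5% of the
minimum attainable over a 40-point log grid — which collapses to
numerically unregularised inversion at zero noise (round-trip error
well under 1%) and picks the smoothest noise-consistent solution otherwise.

`estimate_dmax()` scans candidates (default 2–4 Guinier radii), scoring
each by fit residual times a negativity penalty, and returns the smallest
candidate within 5% of the best score — the onset of the plateau where
further envelope growth no longer helps. Residuals below 10⁻¹⁰ of the
weighted signal power are treated as converged so that discretisation
noise on ideal data does not break the plateau logic. The estimate is
flagged low-confidence when the score profile is featureless, the best fit
still leaves >5% of the centred signal power unexplained (e.g. pure noise
input), or the plateau starts at the grid edge.

`porod_mw()` evaluates the invariant $Q = \int q^2I\,dq$ with a Guinier
extension below $q_{min}$ and a Porod $K/q^4$ tail above $q_{max}$, with K
averaged over the top 30% of the q-range so that form-factor oscillations
of $q^4I$ average over full periods. The data must reach $q_{max}R_g \ge 5$
— shorter profiles cannot anchor the tail and error out. MW is
$V_p/1.66$ Da with the divisor exposed as an argument.

## IM-MS

`assign_oligomer_charges()` minimises $|m/z_{obs} - (nM + zm_p)/z|$ over a
candidate grid, ties broken toward the smaller oligomer (so numerically
degenerate pairs like 1/10 vs 2/20 resolve to the monomer). The monomer
neutral mass is a required input — native constructs rarely match the
sequence mass exactly.

`fit_mobility_components()` operationalises "the minimum number of
Gaussians required to describe the envelope" as: fit k = 1, 2, ... by
Levenberg–Marquardt and stop when the next component improves the RSS by
less than 5% (the threshold is an argument; component count is
non-decreasing as it tightens). Three numerical choices matter. First, a
constant baseline (capped at 20% of the peak) is fitted alongside the
Gaussians, because even nominally background-subtracted distributions carry
a pedestal that would otherwise be soaked up by a spurious very wide
component. Second, initial means come from the tallest local maxima of the
lightly smoothed envelope (deterministic), not from quantiles — quantile
starts strand minority components inside the majority peak. Third, fits
whose RSS is already at numerical zero stop the search so an exact single
Gaussian is not split. When one component is selected but its residuals are
strongly autocorrelated (lag-1 r > 0.5), the envelope deviates
systematically from a single Gaussian and a not-resolvable warning is
raised; mixtures whose widths rival their separation collapse silently,
because they are then statistically indistinguishable from one component.
`conformer_fractions()` sums area fractions on either side of a CCS
boundary (a mean exactly on the boundary counts as compact, with a
warning).

## Synthetic data: what it emulates and what it does not

Each generator draws from the same forward model its fitter assumes, plus
Gaussian noise at defaults chosen as typical instrument precision: 1%
relative on titration signals, 0.001 absolute on anisotropy, 3% relative on
MS intensities, and $\sigma_i \propto \sqrt{I_i}$ (Poisson-like, 1% of full
scale at zero angle) for SAXS; CCS envelopes get 2% of peak. Presets pin
the study conditions: the three Cu/BCS regimes (22/60, 25/75, 29/90 µM)
titrated with protein to 2.5 metal equivalents in 15 points, the Zn/mf2
design (12 µM dimer, 16 µM mf2, 15 points to 30 µM Zn), the two anisotropy
parameter sets (K_a = 1.0×10⁷, Δr = 0.014; K_a = 2.8×10⁶, Δr = 0.017),
pulse times {15, 30, 60, 240, 600} s with rates 0.005/0.02 s⁻¹, spheres on
q ∈ [0.005, 0.5] Å⁻¹, and bimodal CCS envelopes at 2500/3200 Å² (0.6/0.4,
widths 120 Å²). Every dataset carries its generating truth as an
attribute, and every fitter closes the loop exactly at zero noise.

What passing these tests shows: the estimators are consistent, unbiased at
the design points, and correctly propagate the assumed noise. What they do
not show: robustness to model misspecification. Real titrations have
drifting baselines and dilution; real anisotropy data have
intensity-weighting artefacts; real MALDI intensities are not perfectly
ratiometric; real SAXS has smearing, buffer-subtraction errors and
interparticle structure factors; real CCS envelopes are not Gaussian
mixtures. None of these are emulated, deliberately — the generators test
the inference machinery, not the instrument.

**Problem sizes.** The simulation studies in the test suite use the study
designs above at their natural sizes (45-point global fits, 20-point
isotherms, 50-replicate recovery studies, 201-point CCS grids, ~200-point
SAXS profiles); these are the sizes at which the reference experiments were
run and are comfortably informative for every estimator.

## Known limitations

No cooperative/Hill or sequential-site binding models; no monomer–dimer
coupling in the DNA isotherm; no activity corrections; no raw spectrum or
raw mobility file processing (inputs are peak lists and distributions); no
ab initio shape reconstruction or atomic-model curve prediction; the
equivalence-point CI assumes Gaussian residuals. Rates from two-cysteine
peptides are inherently unordered without MS/MS evidence, and the Zn-type
lower bound depends on the assumed noise model — both are reported
explicitly rather than silently resolved.
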