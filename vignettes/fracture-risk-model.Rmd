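---
title: "A stochastic multiscale model of absolute hip fracture risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic multiscale model of absolute hip fracture risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arfsim)
```

## The model

`arfsim` predicts a subject's *current absolute risk of femoral fracture*
(`ARF0`): the probability of suffering at least one hip fracture within a
year, given the subject's anthropometrics and the orientation-dependent
strength of their proximal femur under side-fall loading. The chain has
four stages.

**Fall dynamics.** A fall is idealised as an inverted pendulum of length
$cH$ (the standing centre-of-mass elevation, $c = 0.554$) rotating in a
vertical plane from an initial inclination $\theta_i$ to a final
inclination $\theta_f$. With initial linear velocity
$v_i = cH\,\dot\theta_i$ and acceleration $a_i = cH\,\ddot\theta_i$, the
kinetic energy per unit mass available when the hip strikes the ground is

$$ e = cH\,a_i\,(\theta_f - \theta_i) + \tfrac12 v_i^2
      + g\,cH\,(\cos\theta_i - \cos\theta_f), $$

with the angle difference in radians. Protective responses and partial
interruption of the fall remove a fraction $\eta_P$ of this energy, so
the hip impact velocity is $u = \sqrt{2(1-\eta_P)e}$. The impact force
pulse is triangular in time over a duration $\Delta t = 0.09$ s, giving a
peak unattenuated force $F^* = k\,2mu/\Delta t$; experimental calibration
(a 61.2 kg synthetic pelvis striking a rigid floor at 3 m/s with a
2.05 kN peak) puts $k$ at 0.5, so the simplified $F^* = mu/\Delta t$ is
used throughout.

**Force transfer.** Only part of $F^*$ reaches the skeleton. Flooring,
hip protectors and active muscle combine multiplicatively in the
transmitted fractions, $1-\eta_I =
(1-\eta_I^{floor})(1-\eta_I^{ext})(1-\eta_I^{act})$; the active-muscle
component can be negative (contraction amplifies the transmitted force),
which is why $\eta_I$'s default range is $[-2.55, 0.914]$. Passive
trochanteric soft tissue attenuates by a subject-fixed factor
$\eta_{ST} = \max(0,\, 0.0231\,\mathrm{BMI} - 0.330)$, obtained by
composing a soft-tissue-thickness-on-BMI regression with cadaveric
impact measurements. The force on the greater trochanter is
$F = (1-\eta_I)(1-\eta_{ST})F^*$.

**Strength and fracture.** The femur fractures in a given fall when $F
\ge S(\alpha', \beta')$, where $S$ is the side-fall strength at the
realised impact orientation, represented on a lattice of $M$ points
covering $[-30^\circ, 30^\circ] \times [0^\circ, 30^\circ]$.

**Risk integration.** The six fall parameters
$(\theta_i, \theta_f, v_i, a_i, \eta_P, \eta_I)$ are random across falls,
each following a normal distribution truncated at $\pm 3$ SD, fully
specified by its truncation limits $(a, b)$ (untruncated mean $(a+b)/2$,
SD $(b-a)/6$). Impact orientations are uniform over their rectangle and
independent of the rest. The per-fall fracture probability is

$$ P = \int p^{\alpha'} p^{\beta'} \prod_x p^x \, \chi \; d\mathbf{x}, $$

estimated by Latin-hypercube Monte Carlo over the fall parameters
(default $N = 10^4$) and triangular-grid quadrature of the fall-averaged
fracture indicator over orientation (default $M = 33$). With an annual
fall rate $n = 0.65$ common to all subjects, the annual risk is
$ARF0 = 100\,(1-(1-P)^n)$ %.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `c` | 0.554 | – | COM-height ratio (pendulum length $cH$) |
| `dt` | 0.09 | s | impact pulse duration |
| `n_fall` | 0.65 | /yr | annual fall rate |
| `g` | 9.81 | m s⁻² | gravitational acceleration |
| `k` | 0.5 | – | impact proportionality factor |
| `theta_i` | [0, 30] | deg | initial inclination from vertical |
| `theta_f` | [60, 120] | deg | final inclination (stairs to chair-height falls) |
| `v_i` | [0, 1.40] | m s⁻¹ | initial linear COM velocity $cH\dot\theta_i$ |
| `a_i` | [0, 5.10] | m s⁻² | initial linear COM acceleration $cH\ddot\theta_i$ |
| `eta_P` | [0.500, 0.800] | – | postural reflex energy attenuation |
| `eta_I` | [−2.55, 0.914] | – | combined impact force attenuation |

The stochastic bounds are the model's canonical truncation values; all
are overridable through a YAML configuration (`load_config()`). The
angular-rate parameters are represented as the linear quantities
$cH\dot\theta_i$, $cH\ddot\theta_i$ because their bounds are stated in
linear units, which makes the distributions subject-independent; the
energy expression only ever needs the products $cH \cdot a_i$ and
$v_i^2$, so the angular form is never required. Angles are stored in
degrees at all I/O boundaries and converted to radians inside every
trigonometric or arc-length computation. The value of $g$ is a package
choice (standard 9.81 m s⁻²); it reproduces all the worked values we
checked and is exposed in the configuration.

## Sampling machinery

`lh_sample()` draws inverse-transformed Latin-hypercube samples: one
uniformly jittered draw per probability stratum of width $1/N$, strata
independently permuted per column, mapped through the truncated-normal
(or uniform) quantile function. Jitter rather than stratum midpoints is
used so that sample moments are unbiased; either choice meets the
moment-error bounds quoted below. Each column draws from a substream
derived from the root seed, so adding or removing a parameter never
reshuffles the draws of another.

`iman_conover()` induces a target Spearman correlation structure without
touching the column marginals (it only reorders rows): van der Waerden
score columns are decorrelated by a Cholesky factor of their empirical
correlation and recombined by the factor of the target. Because the
scores are Gaussian, the Spearman target is first converted to the
equivalent Pearson score correlation $2\sin(\pi r/6)$; without this
correction the achieved rank correlation is biased low by about 4% of
the target (0.429 would come out near 0.413).

## Verification tools

Three convergence studies mirror how the numerical approximations are
controlled:

- `lh_moment_errors()` compares LH sample moments against the truncated
  distribution's *theoretical* moments
  ($\varepsilon^\mu = |\mu^* - \mu|/\sigma$,
  $\varepsilon^\sigma = |\sigma^{*2} - \sigma^2|/\sigma^2$). The
  truncated variance is the closed form
  $\sigma^2 (1 - 6\varphi(3)/(\Phi(3)-\Phi(-3))) \approx 0.97334\,\sigma^2$;
  comparing against the untruncated variance instead would stall at the
  2.7% truncation deficit. Both errors fall below $10^{-3}$ at
  $N = 10^4$ for every default parameter.
- `quadrature_convergence()` refines the orientation grid through the
  supported ladder $M = 4, 15, 33, 66$ against a 231-point reference,
  holding the falls fixed. The supported layouts are rectangular
  lattices ($2{\times}2$, $5{\times}3$, $11{\times}3$, $11{\times}6$,
  $21{\times}11$), each triangulated with the lower-left-to-upper-right
  diagonal; the quadrature is exact for fields linear in orientation.
- `mc_convergence()` reports the median and maximum absolute ARF0
  deviation over a cohort against an *independently seeded* reference
  run at a larger $N$ (rather than a nested sample), so the reported
  error includes the full Monte Carlo variability.

## Sensitivity analysis and uncertainty bands

`saltelli_first_order()` implements the radial Saltelli scheme for
independent inputs ($(d+2)N$ model evaluations,
$S_i = \overline{Y_B (Y_{AB_i} - Y_A)} / \mathrm{Var}(Y)$).
`correlated_first_order()` handles rank-correlated inputs with a
rank-correlation-preserving LH sample and a binned
conditional-expectation estimator of $\mathrm{Var}[E(Y|X_i)]/\mathrm{Var}(Y)$
(25 equal-count bins by default; the within-bin noise bias is below
0.3% at $N = 10^4$). A frequency-domain estimator in the FAST family
would be a faithful alternative for the correlated case; the binned
estimator was chosen because it is transparent, has no tuning beyond the
bin count, and matches the Saltelli estimates within estimator noise on
independent inputs. `select_sensitive()` screens the inputs whose
descending-ordered indices sum to just over 80%, with alphabetical
tie-breaks.

`uncertainty_band()` propagates measurement uncertainties of the
screened inputs through the location-independent band

$$ \tilde{s} = \sqrt{\textstyle\sum_X s_X^2}\;
   \frac{\langle Y\rangle_{max} - \langle Y\rangle_{min}}
        {|\mathbf{X}_{max} - \mathbf{X}_{min}|}, $$

where the extrema are bin means over a regular grid (10 per axis by
default, `bin_extrema()`) in the screened-input space. **All
angle-valued quantities enter in radians**, in both $s_X$ and the
Euclidean distance; this is the only convention that reproduces the
reference worked value of 166 N for the impact-force band (degrees give
about 170 N).

Two modelling choices in the screening models deserve a note. First,
when screening the attenuated force $F$, the soft-tissue factor
$\eta_{ST}$ is held fixed: it is a deterministic per-subject quantity,
not a measured stochastic input, and because
$m\,(1-\eta_{ST}(m/H^2))$ is nearly flat in $m$ over 31–101 kg, leaving
the BMI link active would suppress the mass index to a few percent —
inconsistent with the reference behaviour this screening is meant to
mirror. For the same reason, fracture probability is monotone in body
mass only below the soft-tissue turnover near 72 kg (at average
stature); above it, added mass buys proportionally more soft-tissue
attenuation than force. Second, the ARF0 screening parameterises the
strength surface by its orientation-average $\langle S \rangle$ scaling
the population-mean shape, with $(m, H, \langle S\rangle)$ drawn as
$\pm3$ SD truncated normals carrying the weak rank correlations
$r(m,H) = 0.429$, $r(m,\langle S\rangle) = 0.264$,
$r(H,\langle S\rangle) = 0.294$.

## The synthetic cohort generator

The CT-based finite-element strength pipeline is out of scope here; in
its place `synthesize_surface()` builds
$S(\alpha', \beta') = \langle S\rangle \cdot f(\alpha', \beta')$, where
$f$ is a smooth population-mean anisotropy shape perturbed by a
low-order polynomial in the normalised orientation coordinates with
per-subject coefficients (amplitude 0.08), renormalised to unit mean so
$\langle S\rangle$ is exact. `generate_cohort()` assembles a case-control
cohort of 98 subjects: pooled anthropometrics (mass 63.75 ± 13.2 kg,
height 1.58 ± 0.062 m, ±3 SD truncated — the two groups of the emulated
cohort are pair-matched, so pooling is appropriate), mean strengths
normal with mean 2800 N and SD 1000 N truncated to [390, 6330] N, rank
correlations induced by Iman–Conover, and fracture labels drawn
Bernoulli in each subject's ARF0 and rebalanced to exactly half cases by
risk-weighted resampling.

What the generator reproduces: per-orientation strengths approximately
normal across subjects (the Anderson–Darling test retains normality at
well over 75% of orientations), most subjects at least moderately
correlated ($r \ge 0.5$) with the population-mean surface, the weak
anthropometric-strength correlations above, and a cohort ARF0
distribution spanning roughly 1–93% with a median near 27–36% at the
default calibration. What it does not reproduce: real CT-derived
strength geometry (so cohort-specific published statistics such as a
particular subject's risk or a clinical AUC are out of reach by design),
clinical fracture labels (ours are generated from the model's own risk,
so validation statistics demonstrate the machinery, not clinical
performance), and any fall-risk heterogeneity across subjects (the fall
rate is common). Passing tests on synthetic cohorts therefore verify the
statistical machinery and the calibration targets, not clinical
accuracy.

## Numerical choices and degenerate inputs

- Fracture at exactly $F = S$ counts as fracture (inclusive comparison);
  measure-zero for continuous inputs.
- The kinetic energy is clamped at zero with a warning if a pathological
  parameter combination makes it negative; inside the default ranges the
  gravity term dominates and the clamp never fires.
- Both orders of computing $P$ (average the indicator over falls then
  integrate over orientation, or integrate per fall then average) are
  algebraically identical by linearity of the quadrature; the test suite
  holds them to $10^{-12}$.
- A constant risk model yields all-zero sensitivity indices by
  convention; empty bins are excluded from band extrema with a warning;
  degenerate Hosmer–Lemeshow groups are merged with a warning.
- Default problem sizes — $N = 10^4$ falls, $M = 33$ orientations for
  risk runs; $10^5$ samples for sensitivity and uncertainty summaries;
  98-subject cohorts — are the verified settings of the model chain: LH
  moment errors $< 10^{-3}$, quadrature refinement stable to about 2 pp,
  Monte Carlo ARF0 repeatability well under 1 pp, and a full cohort run
  completes in seconds.

## Known limitations

Joint torques, segment dynamics and the pelvic transient are not
modelled (the pendulum abstraction carries only their energetic
consequences through $\eta_P$). Soft-tissue thickness is treated as
homogeneous over the hip. $\eta_P$ and the active-muscle component of
$\eta_I$ are sampled independently although both derive from muscle
activation. The fall rate is population-level; subject-specific fall
risk is not represented. Multi-year risk (and with it bone remodelling
and ageing of fall parameters) is out of scope.

## A worked example

```{r example, eval = FALSE}
library(arfsim)
coh <- generate_cohort(cohort_config(), seed = 42)
risk <- run_cohort(coh$subjects, coh$surfaces, N = 1e4, seed = 43)
summary(risk$ARF0_percent)
rep <- validate_cohort(risk$ARF0_percent, coh$subjects$fracture_label)
rep$roc
```
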