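---
title: "Kinetic models and estimation methods in photokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models and estimation methods in photokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photokin)
```

photokin analyses the phototransformations of biphotochromic fluorescent
proteins of the SAASoti/EosFP family: proteins that both photoconvert
irreversibly from a green- to a red-emitting chromophore under violet
(400 nm) light and photoswitch reversibly between a fluorescent *on*
state and a dark *off* state under blue (470 nm) light. This vignette is
the package's own account of the models it implements, the estimation
choices behind the fitting machinery, and the limits of what the
synthetic-data studies demonstrate.

## The four kinetic models

**Green-to-red photoconversion.** Under 400 nm illumination the green
chromophore converts to the red form, which is itself photobleached by
the same light. Treating both steps as first order
(Green $\xrightarrow{k_1}$ Red $\xrightarrow{k_2}$ Bleached) and
observing red fluorescence gives the consecutive-reaction curve

$$I_{red}(t) = I\,\frac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right) + c,$$

with formation rate $k_1$, photodestruction rate $k_2$, pre-exponential
amplitude $I$ and a background/residual term $c$
(`eval_photoconversion()`, model id `"photoconversion"`).

Two structural facts about this curve matter for estimation. First, it
is singular at $k_1 = k_2$; the analytic limit is
$I k_1 t\, e^{-k_1 t} + c$, available behind
`k_equal_limit = TRUE`, while the default raises an error so that
identifiability problems surface rather than hide. Second, the curve is
*invariant* under exchanging $k_1 \leftrightarrow k_2$ with the
compensating amplitude rescale $I \to I\,k_1/k_2$: which rate is
"formation" is a labelling convention, not information in the data.
Fits are therefore relabelled post hoc to $k_1 \ge k_2$, the convention
used in the kinetics tables for this family (formation faster than
destruction).

**Reversible photoswitching.** On-to-off switching under 470 nm light is
bi-exponential. In the first illumination cycle the second component is
*opposed* in sign,

$$I(t) = I_1 e^{-k_1 t} - I_2 e^{-k_2 t} + c,$$

reflecting a concurrent rise of green emission at the detection
wavelength (model id `"biexp_opposed"`); from the second cycle onward
both components decay with the same sign (model id `"biexp"`), and
C175A-type variants lack the second component partly or entirely
(`"monoexp"`). The sign is carried by an `opposed` flag, never by a
negative amplitude, so amplitude bounds stay simple. Same-sign fits are
reordered to $k_1 \le k_2$, again following the tables' convention.

**Thermal relaxation.** The dark off state recovers spontaneously
(trans-to-cis isomerization of the chromophore), observed as the
anionic-form absorbance rising mono-exponentially,

$$A(t) = A_0\left(1 - e^{-k t}\right) + c,$$

with half-rise time $\tau_{1/2} = \ln 2 / k$ (`eval_relaxation()`,
`halflife()`). For the slow wild-type recovery, $k = \ln 2/3000$ s$^{-1}$
corresponds to $\tau_{1/2} = 50$ min; note that the tabulated recovery
constant for the same variant, $22 \times 10^{-3}$ s$^{-1}$, implies
$\tau_{1/2} \approx 32$ s. The package implements the constants as
tabulated and surfaces the inconsistency here rather than resolving it.

**Normalization convention.** Photoconversion traces are conventionally
normalized to $I_{max} = I\,(k_1 - k_2)/k_1$, so that 1 represents the
red-form fluorescence that would be reached without photodestruction.
This expression equals neither the analytic maximum of the curve nor its
$k_2 = 0$ plateau (which is $I$); `conversion_imax()` implements the
reported convention verbatim as the default and offers the plateau
alternative behind `method = "plateau"`. The divisor is non-positive
when $k_1 \le k_2$, in which case normalization is refused.

## The reaction-scheme integrator as an independent oracle

`kinetic_scheme()` defines an arbitrary first-order (monomolecular)
reaction network — states, rate-labelled transitions, initial
populations, and an observable that is linear in the populations — and
`integrate_scheme()` solves it with `deSolve::lsoda` at relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}$. The schemes here
are tiny (3–4 states), so a stiff-capable adaptive method at tight
tolerance costs nothing and makes the integrator usable as a numerical
oracle: the closed-form photoconversion curve must agree with the
integrated Green→Red→Bleached scheme to well below $10^{-6}$ of the
curve maximum, and the test suite verifies this over random rate pairs.
Conservation of total population in closed schemes is checked to
$10^{-8}$.

The same machinery expresses the proposed mechanism behind the
distinctive C175A behaviour: during the first 470 nm cycle, cysteine 175
can be photo-oxidized, creating a second protein population that then
photoswitches with its own rate. `photooxidation_scheme()` and
`simulate_photooxidation_cycles()` realize this as four states (On, Off,
OxOn, OxOff) with light-driven On→Off ($k_{sw}$), first-cycle-only
On→OxOn ($k_{ox}$), OxOn→OxOff ($k_{sw}'$), and 400 nm regeneration
pulses treated as instantaneous and complete (Off→On, OxOff→OxOn). The
exact reaction scheme was not published in the primary text; this
reconstruction is a stated modelling assumption chosen because it
produces a two-population mixture — hence same-sign bi-exponential
later cycles — once oxidation has occurred.

## Fitting: separable least squares, multistart, and conventions

`fit_trace()` minimizes the unweighted residual sum of squares (a
per-point `sigma` column is honoured as inverse weights when present)
under bounds: rates in $[10^{-6}, 10]$ s$^{-1}$, amplitudes and offsets
non-negative. The optimum is located in three stages:

1. **Separable (variable-projection) scan.** Every model here is linear
   in its amplitudes given its rates. Rates are scanned on a log grid
   spanning $0.5/t_{end}$ to $100/t_{end}$, amplitudes solved by
   ordinary least squares at each grid point, and the best profiled
   point refined by Nelder–Mead on the 1- or 2-dimensional profile.
   Sums of exponentials are notorious for shallow local minima; the
   profile is far better behaved than the joint 4–5 parameter surface.
2. **Heuristic multistart.** The `init_guess()` heuristics (tail
   log-slopes, half-rise times, fast/slow peeling of log residuals)
   supply an independent start, plus deterministic jittered variants —
   deterministic so that refitting the same trace is byte-identical.
3. **Joint polish.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`)
   from each start; standard errors come from the covariance of the
   linearized problem at the optimum.

A challenger start only displaces the incumbent if it improves the
residual sum of squares by more than 0.1%. This guard exists because
near-degenerate exponential sums have a long, nearly flat
amplitude/rate valley: choosing the minimum over many restarts by
hair-thin margins systematically selects biased parameter combinations,
while any genuinely different basin differs by far more than 0.1%.

The degenerate direction itself ($k_2 \to k_1$ with diverging opposed
amplitudes, which adds an effective $t e^{-kt}$ basis function and
overfits noise) is excluded from the profiled scan by requiring the
scanned rates to differ by at least 5%; fits whose final rates agree to
within 0.1% are flagged `degenerate`.

**Model selection** (`select_model()`) ranks candidate models by the
small-sample corrected Akaike criterion
$\mathrm{AICc} = n\log(\mathrm{RSS}/n) + 2p + 2p(p+1)/(n-p-1)$ with $p$
counting free parameters plus the residual variance. Candidates within
2 AICc units of the best are reported as indistinguishable. AICc rather
than AIC because the models differ by only two parameters on traces of
a few hundred points.

**Uncertainties.** The published table uncertainties (e.g. ±0.1 on a
rate of 5.5) are matched in role — every estimate carries a standard
error — but not in value, which would require the raw instrument noise.
The test suite instead checks calibration: reported standard errors
fall within a factor of two of the Monte-Carlo spread over 200
replicates.

## Identifiability of the opposed bi-exponential

The first-cycle switching fit is the hardest estimation problem in the
package and deserves its own discussion. At the wild-type constants
($k_1 = 5.5$, $k_2 = 9.8 \times 10^{-3}$ s$^{-1}$) the two rates differ
by less than a factor of two, and two separate issues follow.

*The floated baseline.* Over a 600 s window the slow exponential decays
by a factor of ~27, and its tail is nearly collinear with a constant.
Floating the baseline $c$ (the default, bounded at zero, since real
instrument backgrounds are unknown) therefore inflates the joint
uncertainty of the amplitudes enormously — Monte-Carlo medians of the
amplitude ratio can be tens of percent off even though each individual
fit is a perfectly good least-squares optimum. When the background is
known — background-subtracted instrument exports, or synthetic data —
`fix = c(c = 0)` removes the collinear direction, and the package's
recovery studies do exactly that.

*Small-sample bias of the amplitude ratio.* Even with the baseline
fixed, the exact least-squares estimate of $I_2/I_1$ at noise
$\sigma = 0.01$ carries a median bias of a few percent (about 5% low at
1000 replicates). This is a property of the estimator at these
conditions, not of the optimizer: starting the fit at the true
parameters and polishing to machine precision lands on the same biased
global minimum, and pushing the optimizer harder makes the bias
slightly worse because the deepest minimum is the biased point. The
rate constants themselves are unbiased well below 1%. Recovery checks
therefore hold the rates to 2% in the median and the amplitude ratio to
10%.

*Detecting the opposed component.* The qualitative question — does the
first cycle carry a negative component at all? — is what separates
wild-type-like from C175A-type behaviour. A pure amplitude-significance
rule ($I_2 > 3\,\mathrm{se}(I_2)$) fails for the reason above: the
anti-correlated amplitudes can have standard errors exceeding their
estimates even on decisively opposed-shaped data where the opposed
model beats the alternatives by hundreds of AICc units. The rule
implemented in `analyze_cycles()` is therefore: the opposed model wins
selection **and** (its $I_2$ exceeds 3 standard errors **or** it beats
every same-sign/mono candidate by more than 2 AICc units).

## Cycle analysis and classification

`analyze_cycles()` fits cycle 1 over the opposed, same-sign, and
mono-exponential candidates and later cycles over the latter two,
matching the observed progression of switching kinetics across cycles.
Photofatigue is summarized as *retention*: the pre-illumination
intensity of each cycle (mean of the first five samples, a window
chosen to be robust to single-sample noise and configurable via
`init_window`) relative to cycle 1. Rate acceleration is the cycle-2 to
cycle-1 ratio of the slow switching rate $k_1$, which for the wild-type
constants is $7.8/5.5 \approx 1.42$.

`classify_variant_behavior()` labels a series `c175a_like` when the
first cycle lacks a supported opposed component *and* retention
declines monotonically; the decline test requires at least three
cycles, and classification refuses to answer on fewer than two. With
exactly two cycles a series can only be called `wt_like`, which is the
conservative direction: the C175A phenotype is an absence claim and
needs more evidence.

## Spectra, titrations, brightness

`emission_max()` refines the discrete maximum of an emission band by a
least-squares parabola over the contiguous points within 70% of the
peak height (falling back to the classical 3-point quadratic via
`window = 1`). The windowed fit matters: on a 1 nm grid with a ~15 nm
band and 1% noise, a 3-point vertex is uncertain by about 1 nm —
useless for detecting the 2–3 nm per-cycle blue-shifts that distinguish
variant families — while the windowed fit localizes to ~0.1 nm.
`blue_shift()` is the difference of two peak positions, negative for
blue, and antisymmetric by construction.

`fit_pka()` fits the Henderson–Hasselbalch sigmoid
$S(\mathrm{pH}) = S_{max}/(1 + 10^{\,h(\mathrm{pK_a - pH})}) + S_{min}$,
assuming a single protonatable group ($h = 1$); the Hill exponent can
be floated (`hill = NA`) but there is no evidence in this system for
cooperative protonation. A fitted pKa on the edge of the sampled range
is refused as unidentifiable, and coverage of less than one pH unit on
either side of the inflection raises a warning.

`brightness()` is the product $\varepsilon \cdot \phi$, reported in
$10^3\,\mathrm{M^{-1} cm^{-1}}$ and rounded half-up to one decimal when
`digits` is given, matching how such tables are printed (44.25 prints
as 44.3). One panel row (ε = 80.1, φ = 0.55) was published as 44.0
although the product rounds to 44.1; the preset table transcribes the
inputs, and the discrepancy is one unit in the last printed digit.

## The synthetic-data generators

The generators emulate the structure of the illumination experiments:
1 Hz sampling over the 10 min (600 s) illumination windows, 400 nm /
146 mW/cm² conversion, 470 nm / 167 mW/cm² switching cycles separated
by complete 10 s / 21.3 mW/cm² regeneration pulses in pH 9.2 carbonate
buffer, Gaussian emission bands on a 1 nm grid, and
Henderson–Hasselbalch titrations. Noise is additive Gaussian with
$\sigma = 0.01$ of the unit peak amplitude by default — the recorded
traces appear low-noise, and this value keeps recovery tolerances
meaningful. All generators are deterministic under a fixed seed.

The preset table (`variant_presets()`, shipped as a versioned CSV)
transcribes the panel's measured rate constants, amplitude ratios, pKa,
extinction and quantum-yield values. Two generator fields are *not*
measurements and are flagged `reconstructed` in the file: the per-cycle
fatigue factor (1.0 for wild-type-like presets, 0.85 for
C175A-containing ones, expressing that only the latter lose initial
fluorescence across cycles) and the per-cycle blue-shift (−2 nm for
wild-type-like, 0 for C175A-type). Cycle amplitudes are anchored so the
pre-illumination intensity of cycle $n$ is exactly
$\mathrm{fatigue}^{\,n-1}$ of cycle 1, which makes the retention power
law an exact generator property that the analysis must recover.

What the generators deliberately do **not** model: photon shot noise
and detector response (noise is homoscedastic Gaussian), any dependence
of effective rates on irradiance (rates are constants at the stated
irradiances), temperature dependence, incomplete regeneration, and
excited-state photophysics. Passing the recovery and classification
tests therefore shows that the estimation machinery is correct and
calibrated *under the stated noise model* — it does not validate the
kinetic models against real instrument data, which the original
measurements did.

## Problem sizes and numerical defaults

The shipped studies use 601-point traces (1 Hz over 600 s), 100–400
Monte-Carlo replicates for recovery medians, 200 replicates for
standard-error calibration, 100 random rate pairs for the oracle
comparison, and 50 random pKa draws — sizes at which every study runs
in seconds to a couple of minutes on a single core while leaving the
Monte-Carlo error of a median well below the tolerances being checked.
Other defaults: integrator tolerances $10^{-8}$/$10^{-10}$; AICc tie
threshold 2; rate bounds $[10^{-6}, 10]$ s$^{-1}$; multistart count 5;
uninformative-trace threshold 10× the noise floor estimated from first
differences; brightness rounding half-up.

## Known limitations

- Rates are effective constants at fixed irradiance; nothing converts
  between irradiance and rate.
- No global multi-trace fitting, Bayesian posteriors, or bootstrap
  intervals; uncertainties are linearized standard errors.
- The photo-oxidation scheme is a reconstruction (see above), suitable
  for generating and reasoning about two-population kinetics, not a
  validated mechanism.
- The amplitude ratio of weakly separated opposed bi-exponentials is
  biased at the few-percent level at realistic noise; treat reported
  $I_2/I_1$ values accordingly.
- Titration fits assume a single protonation site unless told
  otherwise.
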