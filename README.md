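# photokin

Kinetic analysis of photochromic fluorescent proteins.

Biphotochromic fluorescent proteins of the SAASoti/EosFP family undergo
two light-driven transformations: irreversible green-to-red
**photoconversion** under violet (400 nm) light, and reversible on/off
**photoswitching** under blue (470 nm) light, with spontaneous thermal
recovery of the fluorescent state in the dark. Characterizing a mutant
panel of such a protein means fitting a handful of closed-form kinetic
models to time-resolved fluorescence and absorbance traces, comparing
nested exponential models, tracking photofatigue and spectral shifts
across repeated switching cycles, and measuring steady-state
photophysics (chromophore pKa, brightness). photokin packages that
entire workflow for people doing exactly this kind of protein
engineering or photophysics, together with seeded synthetic-data
generators so every stage is testable without instrument data.

## The models

Green-to-red photoconversion is a consecutive first-order process
(Green → Red → Bleached) observed on the red form:

$$I_{red}(t) = I\,\frac{k_1}{k_2-k_1}\left(e^{-k_1 t}-e^{-k_2 t}\right)+c$$

On-to-off switching is bi-exponential, with an opposed second component
in the first illumination cycle and same-sign components afterwards:

$$I(t) = I_1 e^{-k_1 t} \mp I_2 e^{-k_2 t} + c$$

Thermal recovery of the anionic-form absorbance is mono-exponential,
$A(t) = A_0(1-e^{-kt})+c$, with half-life $\tau_{1/2} = \ln 2/k$; the
chromophore's acid-base equilibrium follows Henderson–Hasselbalch,
$S(\mathrm{pH}) = S_{max}/(1+10^{\,\mathrm{p}K_a-\mathrm{pH}})+S_{min}$;
and brightness is $\varepsilon\cdot\phi$.

Fitting is bounded Levenberg–Marquardt seeded by a
variable-projection scan (rates on a log grid, amplitudes solved
linearly), with AICc model selection across nested candidates. A
generic first-order reaction-scheme integrator (`deSolve`) acts as an
independent numerical oracle for every closed form and simulates the
proposed two-population cysteine photo-oxidation mechanism. See the
methods vignette (`vignettes/photokin-methods.Rmd`) for the estimation
details and identifiability analysis.

## Worked example

Simulate a wild-type-like photoconversion experiment (10 min of 400 nm
illumination sampled at 1 Hz), fit it, and read off the kinetics:

```r
library(photokin)

tr  <- gen_conversion_trace("mSAASoti", sigma = 0.01, seed = 11)
fit <- fit_trace(tr, "photoconversion")
fit
#> <kin_fit: photoconversion, 601 points, rss = 0.05971, AICc = -5529.24>
#>   I = 1.002000 ± 4.1e-03
#>   k1 = 0.010960 ± 1.1e-04
#>   k2 = 0.002004 ± 2.4e-05
#>   c = 0.000000 ± 2.5e-03
```

The fitted formation and photodestruction rates, 11.0 and
2.0 ×10⁻³ s⁻¹, recover the preset's generating constants (the values
tabulated for this variant). `tidy(fit)`, `glance(fit)`,
`augment(fit)` and `autoplot(fit)` expose the fit the usual broom/ggplot2
way.

Repeated switching cycles, photofatigue, and variant classification:

```r
cs <- gen_cycle_series("mSAASoti", n_cycles = 3, sigma = 0.01, seed = 11)
m  <- analyze_cycles(cs)
glance(m)
#> # A tibble: 1 × 5
#>   n_cycles acceleration first_cycle_opposed mono_second_cycle final_retention
#>      <int>        <dbl> <lgl>               <lgl>                       <dbl>
#> 1        3         1.39 TRUE                FALSE                       1.000
classify_variant_behavior(m)
#> [1] "wt_like"
```

The first cycle carries the opposed (negative) second exponential and
switching accelerates from cycle 1 to cycle 2 by a factor ≈ 1.4
(7.8/5.5 for these constants); a C175A-type series instead shows a
same-sign first cycle and monotonically decaying retention, and
classifies as `"c175a_like"`.

Steady-state photophysics:

```r
fit_pka(gen_titration(6.3, sigma = 0.01, seed = 11))
#> <pka_fit: pKa = 6.273 ± 0.0107 (Hill 1.00, 15 points)>
brightness(75.0, 0.59, digits = 1)
#> [1] 44.3
halflife(log(2) / 3000) / 60   # minutes
#> [1] 50
```

A thin command-line wrapper over the same functions lives at
`inst/cli/photokin` (subcommands `simulate`, `fit`, `convert`,
`cycles`, `pka`, `report`); `photokin::run_cli()` drives it in-process.

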