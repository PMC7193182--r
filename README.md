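# vestsim

Reduced-order simulation of hydrops-enhanced vestibulo-ocular responses
during head impulse testing.

## What it is for

The video head impulse test (vHIT) quantifies the angular vestibulo-ocular
reflex (aVOR) as the gain between slow-phase eye velocity and head velocity
during brief passive head rotations. Gains below 1 flag canal hypofunction;
*enhanced* responses (gains ≳ 1.1) have been proposed as a sign of
endolymphatic hydrops, the labyrinth dilation underlying Menière disease.
`vestsim` is for vestibular researchers who want a transparent, desk-scale
mechanistic model of that enhancement: it predicts how much the aVOR
response grows when the horizontal semicircular duct (canal hydrops) or the
utricle (utricular hydrops) dilates while the cupula-to-eye chain stays
intact.

## The model in brief

The membranous horizontal canal is reduced to a planar loop (centerline
radius R; duct, utricle and ampulla segments with lumen radii b_i). With
rigid walls and a rigid cupula sealing the loop, incompressibility forbids
relative endolymph flow, and the transcupular pressure along the closed
path through sensor i is

    dP_i(t) = 2 * rho * A_i * dOmega/dt

with A_i the enclosed planar area (middle sensor: pi R^2; superior sensor:
the outer-wall path 1/2 * sum (R + b_i)^2 dtheta_i) and Omega the head
angular velocity. The sensor-mean pressure drives the overdamped
torsion-pendulum cupula,

    Vc(t) = (1/gamma) * int_{-inf}^{t} dPc(t') exp(-(t - t')/tau_c) dt'
    tau_c = 8 mu beta_d R / (pi b_d^4 K),   gamma = tau_c * K

whose volume displacement Vc maps to an equivalent head velocity through
the human cupular sensitivity Omega_0/Vc ~ 5.6e-2 deg/(pL s), then to eye
velocity through a normofunctional aVOR gain of 1. The aVOR gain of a run
is the area-under-curve ratio |eye| / |head| over the impulse window
(20 deg/s on/off threshold). Dilating the duct (0.45 -> 1.3 mm, inside the
1.53 mm bony canal) or the utricle (x3) enlarges the enclosed areas, and —
the whole chain being linear — multiplies the response by the area ratio:
1.140 for canal hydrops, 1.100 for utricular hydrops on the frozen default
geometry. See `vignettes/hydrops-avor-model.Rmd` for the full derivation,
the calibration of the geometric free parameters, and the model's limits.

## Worked example

```r
library(vestsim)

report <- run_experiment()   # 6 synthetic impulses x 3 geometries
glance(report)
#> # A tibble: 1 x 7
#>   mean_gain_none mean_gain_canal mean_gain_utricular sd_gain_none sd_gain_canal
#>            <dbl>           <dbl>               <dbl>        <dbl>         <dbl>
#> 1          1.000            1.14                1.10     0.000108      0.000123

dplyr::filter(tidy(report), impulse_label == "VI")
#> # A tibble: 3 x 6
#>   model     impulse_label head_peak eye_peak pressure_increment avor_gain
#>   <fct>     <chr>             <dbl>    <dbl>              <dbl>     <dbl>
#> 1 none      VI                 249.     250.               4.06     1.000
#> 2 canal     VI                 249.     285.               4.63     1.14
#> 3 utricular VI                 249.     275.               4.46     1.10
```

The mean gains read: a no-hydrops labyrinth reproduces its head impulses
with gain 1.000 (the calibration convention), while canal and utricular
hydrops enhance every response by 14% and 10% respectively. For the fastest
impulse (peak 249.47 deg/s) the canal-hydrops model predicts a 285 deg/s
eye-velocity peak. The `pressure_increment` column is the peak sensor-mean
transcupular pressure of the reduced model; only its ratios between models
are meaningful, not its absolute scale.

Individual stages are ordinary functions on tibbles:

```r
imp  <- synth_impulse(173.81)                        # one vHIT-like impulse
geo  <- apply_canal_hydrops(make_normal_geometry())  # hydropic labyrinth
pres <- transcupular_pressure(imp, geo)              # dP(t) per sensor
autoplot(pres)
```

A thin CLI covering the same pipeline lives at `inst/cli/vestsim.R`
(`grid`, `simulate`, `fixtures` subcommands).

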