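# photonmc

Monte Carlo photon transport in non-absorbing media with a built-in,
purely analytic two-step verification.

## Who this is for

Developers and users of Monte Carlo (MC) forward solvers in biomedical
optics. MC codes in this field are usually verified by comparison against
older MC codes, which propagates whatever bias the reference carries and is
limited by its statistical noise. `photonmc` instead checks a simulator
against *exact* consequences of the radiative transfer equation (RTE),
scoring every comparison with a one-sample t-test so agreement is
quantified, not eyeballed. The package contains both halves: the simulators
(an infinite-medium trajectory generator and a layered-slab transport code
with Fresnel/Snell boundaries) and the closed-form benchmarks they are
tested against, so it can serve as a reference implementation or as a
harness whose fixtures you reproduce in your own code.

## The two steps

**Step 1 — trajectory extraction.** For a pencil beam at the origin of an
infinite non-absorbing medium with scattering coefficient μs and a
rotationally symmetric phase function with cosine moments
g = ⟨cos θ⟩ and g₂ = ⟨cos² θ⟩, the moments of the k-th scattering event
coordinates are known in closed form, e.g.

    ⟨z₁⟩ = 1/μs            ⟨z₁²⟩ = 2/μs²          ⟨z₂⟩ = (1+g)/μs
    ⟨zₖ⟩ = (1−g^k)/(μs(1−g))
    ⟨dₖ²⟩ = 2(k−(k+1)g+g^(k+1))/(μs²(1−g)²)
    ⟨lₖ^m⟩ = k(k+1)⋯(k+m−1)/μs^m

with the complete set up to order four (`infinite_moments()`) and, for
isotropic scattering, every second moment at every order
(`isotropic_second_moments()`, where ⟨zₖ²⟩ − ⟨xₖ²⟩ = 2/μs² exactly).
Comparing `run_step1()` tallies with these values tests the free-path
sampler, the phase-function sampler (Henyey–Greenstein and Rayleigh are
built in) and the direction rotation — no boundary code involved.

**Step 2 — boundary handling.** A non-absorbing medium under Lambertian
illumination of radiance I₀ has invariant solutions: in a region of
refractive index n_j inside external index n_e,

    I_j = (n_j/n_e)² I₀         Φ_j = 4π (n_j/n_e)² I₀
    ⟨L_j⟩ = 2 s_j (n_j/n_e)²    (slab layer of thickness s_j)

independent of position, direction and *all* scattering properties — so any
deviation indicts the interface code specifically. For non-scattering
layers with n_j above the external index, trapped directions are
unreachable and the solutions gain a (1 − cos θ_jMax) support factor with
sin θ_jMax = min(n_e, intervening indices)/n_j; the radiance becomes a step
that the simulator must reproduce exactly (`nonscattering_solutions()`,
`theta_max()`). `run_step2()` realises the Lambertian source by reciprocity
(alternating-face, cosine-weighted point injection) and estimates radiance,
fluence rate and partial path lengths by track length.

`run_verification()` drives either step and reports the normalized
deviation t = (MC − RTE)/SE and a two-sided p-value per quantity, plus the
number of rejections expected by chance.

## Worked example

```r
library(photonmc)

# exact benchmarks: third scattering order, HG phase function g = 0.9
round(infinite_moments(3, g = 0.9, g2 = 2.62/3), 6)
#>         x         y         z        x2        y2        z2      rho2
#>  0.000000  0.000000  2.710000  0.469933  0.469933 10.280133  0.939867
#>        d2         l        l2
#> 11.220000  3.000000 12.000000

# step 1: one million trajectories, orders 1..4
v <- run_verification(1, mus = 1, phase = hg_phase(0.9),
                      n_photons = 1e6, k_max = 4, seed = 42)
v
#> Step-1 verification report (alpha = 0.05)
#>   t-tests: 35 tested, 1 rejected (expected ~1.8 false rejections)
#>   exact-equality checks: 6, failures: 0
#>   max |t| = 2.112; share of |t| < 2: 97.1%
#>   RESULT: consistent with the benchmarks
```

The 35 t-tests cover every tallied moment; one rejection against ~1.8
expected false alarms at α = 0.05 is exactly the behaviour of an unbiased
code. A sample of the records:

```r
subset(v$records, quantity == "z")[, c("label", "estimate", "se", "benchmark", "t")]
#>     label estimate          se benchmark          t
#> 1  z[k=1]  1.00001 0.000999844     1.000  0.0076153
#> 8  z[k=2]  1.89910 0.001391411     1.900 -0.6453844
#> 18 z[k=3]  2.70851 0.001713197     2.710 -0.8701559
#> 28 z[k=4]  3.43776 0.002023180     3.439 -0.6149297
```

Step 2 on a four-layer 10-mm slab (each layer 2.5 mm, μs = 1 mm⁻¹, HG
g = 0, indices ramping 1.1 → 2.0, external index 1): every layer fluence
must sit at 4(n_j/n_e)² W m⁻² and every layer path length at
2 s_j (n_j/n_e)² mm, whatever the scattering:

```r
v2 <- run_verification(2, slab = slab_profile("up4"), n_photons = 1e6, seed = 42)
v2$records[, c("label", "estimate", "se", "benchmark", "t")]
#>                     label estimate        se benchmark          t
#> 1        fluence[layer=1]   4.8382 0.0071513      4.84 -0.2526679
#> 2        fluence[layer=2]   7.8399 0.0154938      7.84 -0.0082439
#> 3        fluence[layer=3]  11.5741 0.0215104     11.56  0.6577170
#> 4        fluence[layer=4]  15.9977 0.0261277     16.00 -0.0885998
#> 5     pathlength[layer=1]   6.0477 0.0089391      6.05 -0.2526679
#> 6     pathlength[layer=2]   9.7998 0.0193672      9.80 -0.0082439
#> 7     pathlength[layer=3]  14.4677 0.0268881     14.45  0.6577170
#> 8     pathlength[layer=4]  19.9971 0.0326596     20.00 -0.0885998
#> 9 pathlength[layer=total]  50.3124 0.0726313     50.30  0.1703508
```

A command-line driver ships in `inst/cli/photonmc-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","photonmc-cli.R",package="photonmc"))')" \
  step1 --phase hg --g 0.9 --mus 1 -N 1e6 --kmax 4 --seed 1 --out report.json
```

It exits 0 when the verification passes, 1 when it fails and 2 on usage
errors.

## Scope

Non-absorbing media only (absorption is a multiplicative path-length weight
that leaves trajectories unchanged); Henyey–Greenstein, isotropic and
Rayleigh phase functions (exact moments required); slab geometry for
step 2; unpolarized Fresnel boundaries. See the vignette
(`vignettes/two-step-verification.Rmd`) for the model, the design decisions
and the limitations in detail.
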