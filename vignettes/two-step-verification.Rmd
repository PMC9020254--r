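---
title: "Verifying a photon-transport Monte Carlo code in two steps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying a photon-transport Monte Carlo code in two steps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(photonmc)
```

## The problem

Monte Carlo (MC) simulation is the reference forward solver of the radiative
transfer equation (RTE) in biomedical optics: photon packets are propagated
through tissue-like media by sampling free paths from the exponential law
set by the scattering coefficient $\mu_s$, deflection angles from a phase
function $p(\theta)$, and reflection/refraction at refractive-index
boundaries from Fresnel's and Snell's laws.  Before such a code can be
trusted it must be *verified* — shown to agree with exact consequences of
the RTE — and in practice most codes are only cross-checked against older
codes, inheriting whatever biases those carry.

`photonmc` implements a verification scheme built entirely from closed-form
RTE solutions, organised in two steps that isolate the two halves of any
transport code:

1. **Trajectory extraction.**  In an infinite non-absorbing medium the
   moments of the coordinates of the $k$-th scattering event are known
   exactly as functions of $\mu_s$ and of the first two cosine moments of
   the phase function, $g = \langle\cos\theta\rangle$ and
   $g_2 = \langle\cos^2\theta\rangle$.  Comparing tallied moments with
   these formulas tests the free-path sampler, the phase-function sampler
   and the direction-rotation algebra, with no boundary code involved.
2. **Boundary handling.**  A non-absorbing medium whose surface receives
   Lambertian (direction-independent) radiance $I_0$ admits invariant
   solutions: the internal radiance in a region of index $n_j$ is the
   constant $(n_j/n_e)^2 I_0$ regardless of position, direction and of all
   scattering properties; the fluence rate is $4\pi$ times that; and the
   mean path length in a slab layer of thickness $s_j$ is
   $2 s_j (n_j/n_e)^2$.  Because these values do not depend on the phase
   function, any deviation points specifically at the interface code.

Each comparison is scored by the normalized deviation
$t = (\hat m - m_{RTE})/SE(\hat m)$ and a two-sided one-sample t-test.  For
an unbiased simulator the $t$ values are standard normal: about 95% fall
within $\pm 2$, and at significance level $\alpha$ about $\alpha$ of the
tests reject by chance.  The report therefore prints the expected number of
false rejections next to the observed count rather than applying a
multiple-testing correction, which would only obscure the calibration
check.

## Step 1: infinite-medium moments

A pencil beam enters at the origin along $+z$.  With
$g_2 = \langle\cos^2\theta\rangle$, the implemented closed forms give, for
example,

$$\langle z_1\rangle = \tfrac{1}{\mu_s},\qquad
  \langle z_1^2\rangle = \tfrac{2}{\mu_s^2},\qquad
  \langle z_2\rangle = \tfrac{1+g}{\mu_s},\qquad
  \langle x_2^2\rangle = \tfrac{1-g_2}{\mu_s^2},$$

with the full set up to order four in `infinite_moments()`, and for every
order

$$\langle z_k\rangle = \frac{1-g^k}{\mu_s(1-g)},\qquad
  \langle d_k^2\rangle = 2\,\frac{k-(k+1)g+g^{k+1}}{\mu_s^2(1-g)^2},\qquad
  \langle l_k^m\rangle = \frac{k(k+1)\cdots(k+m-1)}{\mu_s^m},$$

plus the complete second-moment set for isotropic scattering
(`isotropic_second_moments()`), where
$\langle z_k^2\rangle - \langle x_k^2\rangle = 2/\mu_s^2$ holds at every
order.  Three families of identities tie the formulas together and are
asserted in the tests: $\langle d^2\rangle =
\langle z^2\rangle + \langle\rho^2\rangle$ exactly; the any-order formulas
agree with the order-specific ones for $k \le 4$; and the anisotropic
formulas reduce to the isotropic set at $(g, g_2) = (0, 1/3)$.  These
identities also fix how the second cosine moment enters each term, which
matters because $g_2$ and $g^2$ are easily conflated when transcribing the
formulas.

```{r}
benchmark_table(hg_phase(0.9))[c(23, 24, 33, 36), ]
```

The simulator `run_step1()` follows every trajectory to exactly `k_max`
scattering events — in an infinite non-absorbing medium nothing can
terminate early, so each order receives exactly $N$ samples and no
termination bias is possible.  Tallies are running sums and sums of squares
per (order, quantity), $O(k_{max})$ in memory, accumulated in chunks of
$2^{16}$ photons that are folded into the global sums, which keeps the
relative rounding error of sums over $10^8$ photons far below the
statistical error.

```{r}
v <- run_verification(1, mus = 1, phase = hg_phase(0.9),
                      n_photons = 1e5, k_max = 4, seed = 7)
v
```

## Step 2: layered slab under Lambertian illumination

`run_step2()` propagates photons through a laterally infinite,
non-absorbing layered slab.  Uniform Lambertian illumination of both faces
is realised by reciprocity: photons are injected at a single point with a
cosine-weighted direction ($\cos\theta = \sqrt{u}$), alternating faces
photon by photon so both sides are illuminated evenly.  Radiance is
estimated by track length per (layer, polar-angle bin), fluence from
$\hat\Phi_j = 2\langle L_j\rangle / s_j$ (the unit-incident-flux
normalisation, equivalent to $I_0 = 1/\pi$), and the two reductions are
algebraically consistent: summing radiance bins times their solid angles
reproduces the fluence estimate identically.

For a *non-scattering* slab with $n_j > n_e$ part of the direction sphere
cannot be reached by refraction from outside: directions with
$|\cos\theta| < \cos\theta_{jMax}$, where
$\sin\theta_{jMax} = \min(n_e, n_{between})/n_j$ along the less restrictive
face, are trapped.  The invariant solutions then gain a
$1-\cos\theta_{jMax}$ support factor (`nonscattering_solutions()`), and the
radiance becomes a step that the simulator must reproduce *exactly* — bins
beyond the support must contain zero track length, which the verification
checks by equality, not by a t-test.

```{r}
up <- slab_profile("up4")     # 4 x 2.5 mm, n ramping 1.1 -> 2, ne = 1
run_verification(2, slab = up, n_photons = 1e5, seed = 7)
```

## What the generator emulates, and design choices

**Study conditions.**  The default configurations mirror the conditions the
benchmarks are stated for: unit scattering coefficient
$\mu_s = 1\,\mathrm{mm^{-1}}$, the three phase functions whose moments are
known exactly — Henyey–Greenstein with $g = 0$ ($g_2 = 1/3$) and $g = 0.9$
($g_2 = 2.62/3$), and Rayleigh ($g = 0$, $g_2 = 2/5$) — and 10-mm slabs cut
into 4 layers of 2.5 mm or 100 layers of 0.1 mm with monotone
refractive-index profiles ("up": ascending with $n_e = 1$; "dw": descending
with $n_e = 2$).  The published figures do not tabulate their index
profiles, so `slab_profile()` ships a synthetic linear ramp over
$[1.1, 2.0]$; the invariant benchmarks hold for *any* profile, so nothing
in the verification depends on that choice.  The ramp endpoints bracket the
range of soft-tissue and coupling-medium indices.

**Random numbers.**  One sequential R Mersenne–Twister stream per run,
seeded from the configuration.  Chunked accumulation only groups additions
and never changes the draw order, so a run is bit-reproducible for a given
(seed, configuration) pair.  Per-photon substreams were considered and
rejected: they buy parallel reproducibility this package does not need, at
the cost of a nonstandard generator.

**Numerical choices.**

* The Rayleigh cosine CDF $F(\mu) = (3\mu + \mu^3 + 4)/8$ is inverted by
  Cardano's formula; the cubic's discriminant is $\ge 1$, so the closed
  form is unconditionally stable and no iterative fallback is needed.
* The direction rotation switches to its degenerate ($\pm\hat z$) branch
  when $|\mu_z| > 1 - 10^{-12}$, avoiding catastrophic cancellation, and
  renormalises whenever the squared norm drifts by more than $10^{-12}$.
* A uniform deviate of exactly 0 is remapped to the smallest positive
  double before $-\ln u$, so no free path is infinite.
* Interface crossings carry the *residual optical depth* $\tau$ across the
  boundary (exponential memorylessness makes this equivalent to resampling,
  with fewer draws).  The photon's layer index is explicit simulator state:
  after a reflection or refraction the position sits exactly on the
  boundary and the next intersection test uses the direction sign, so the
  same plane cannot be re-detected and no $\epsilon$-nudge along the ray is
  needed.
* Photons specularly rejected at the entry face count in $N$ with zero
  internal path: the invariant solutions describe the physical boundary
  including what it reflects, so re-launching them would bias every
  estimate upward.
* An event cap (default $10^7$ per photon) guards against index profiles
  that make escape astronomically slow; an aborted photon is counted and
  any abort marks the whole verification failed, making truncation bias
  loud instead of silent.
* Radiance uses 180 uniform-in-$\theta$ bins by default, normalised by each
  bin's exact solid angle, so a flat benchmark is compared without binning
  bias.  Standard errors for every estimator come from per-photon
  contributions (sum and sum of squares), never from bin counts.

**Sensitivity fixtures.**  Three synthetic defects can be injected to show
the battery detects real bugs: an HG asymmetry bias of $+0.005$ (flagged by
$\langle z_2\rangle$ at roughly eleven standard errors for $N = 10^7$); a
Fresnel reflectance evaluated with the index order swapped; and a missing
total-internal-reflection branch.  Choosing these exposed a physical
subtlety worth recording: *any* reflectance that is reciprocal and
energy-conserving — for instance using the s-polarised reflectance for both
polarisations — preserves the Lambertian invariants exactly, because the
equilibrium radiance field is maintained by detailed balance.  Step-2 tests
therefore cannot see polarisation mix-ups; they detect bugs that break
reciprocity (the index-order swap) or leak trapped photons (the missing TIR
branch), and the latter only in configurations where TIR actually fires —
in the ascending profile with $\mu_s = 0$ every externally injected ray has
a Snell invariant below every layer index, so the trapped-direction step is
produced by refraction alone and a missing TIR branch is invisible there.
The shipped fixtures use the descending-index non-scattering slab and the
scattering ascending slab, where detection is overwhelming.

**Problem sizes.**  The test suite runs the full stochastic battery at
$N = 10^6$ (orders 1–4, three phase functions), the error-scaling check at
$N = 10^8$ (first order only), the ten-order distance check at $N = 10^7$
per phase function, and the slab checks at $N = 10^6$; unit and property
tests use $10^4$–$10^5$ photons.  These sizes put every standard error two
to four orders of magnitude below the quantities themselves while keeping
the whole suite around a minute of CPU time; the same machinery scales to
$10^{10}$ photons unchanged, the tallies being $O(k_{max})$ and
$O(\text{layers} \times \text{bins})$.

## Limitations

* Absorption is out of scope.  Trajectories in a non-absorbing medium are
  unchanged by absorption, which standard codes apply as a multiplicative
  Beer–Lambert weight on the partial path lengths this package verifies,
  but the weighting itself is not exercised here.
* Only phase functions with exactly known $(g, g_2)$ are included; Mie
  phase functions require numerical moments and would blur the line between
  benchmark and simulation.
* The slab is the only geometry: the invariants hold for any smooth convex
  body, but the reciprocity shortcut that replaces full-surface Lambertian
  illumination by point injection is used here in its plane-parallel form.
* Passing the battery is evidence, not proof: a null result bounds bias
  relative to the statistical error of the run, and only a failed test is
  conclusive.
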