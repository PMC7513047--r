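---
title: "Two-temperature polymer blends: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-temperature polymer blends: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activeblend)
```

## The model

`activeblend` simulates a coarse-grained melt of `M` fully flexible
bead-spring chains of `N = 40` monomers at number density 0.85 sigma^-3 in a
periodic box, in reduced Lennard-Jones units (sigma, epsilon,
tau = sigma sqrt(m/epsilon), m = kB = 1). Excluded volume is the purely
repulsive shifted-truncated Lennard-Jones (WCA) pair potential

U_LJ(r) = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ] + eps,   r < rc = 2^(1/6) sigma,

and connectivity is maintained by FENE springs

U_FENE(r) = -(K rmax^2 / 2) log(1 - (r/rmax)^2),

with the standard melt parameters K = 30 eps/sigma^2 and rmax = 1.5 sigma.
Half of the chains ("hot", the scalar-active species) are coupled to a
Langevin thermostat at temperature `Th`, the other half ("cold", passive) to
one at `Tc = 1`; both use the same friction `zeta = 1.5 / tau` and time step
`dt = 0.005 tau`. Above a critical temperature ratio this two-temperature
melt phase-separates into a hot-dilute and a cold-dense phase — a
non-equilibrium steady state with persistent heat flux through the
interface, the minimal "scalar activity" picture of how transcriptionally
active and silent chromatin might demix in the nucleus.

Because heat flows from the hot species to the cold one, neither subset sits
at its reservoir temperature. The kinetic (effective) temperatures
`Theff`/`Tceff` — one third of the mean squared velocity of each subset —
define the control parameter used throughout,

chi = (Theff - Tceff) / Tceff,

which is far less sensitive to the choice of friction than `Th` itself. The
`zeta`-dependence that remains is exposed through the `zeta` argument and
not otherwise addressed.

## Integrator, neighbor search, and randomness

The Langevin dynamics uses the Gronbech-Jensen–Farago discretization, chosen
for its accurate configurational sampling at finite time step; with
`zeta = 0` it reduces exactly to velocity Verlet, which is how the
energy-conservation test exercises the force kernels. Pair interactions are
found through a linked-cell grid that seeds a Verlet pair list with a
0.3 sigma skin, rebuilt whenever some particle has moved more than half the
skin since the last build. Thermal noise comes from a xoshiro256++ generator
(polar Box-Muller for Gaussians) seeded from R's RNG stream, so `set.seed()`
— or the `seed` field of `integrator_config()` — makes trajectories exactly
reproducible; the simulation kernels are single-threaded.

Melt preparation (`initialize_melt()`) grows chains as random walks with
bond length 0.97 sigma, removes overlaps with a capped soft cosine potential
whose prefactor ramps up over the push-off (the cap escalates in repeated
rounds until no pair sits below 0.9 sigma), and equilibrates the mixed state
with both thermostats at T = 1 — the starting point of every activity sweep.

## Slab profiles and the pressure tensor

Profile observables (`density_profile()`, `msv_profile()`,
`effective_temperatures()`, `msv_decomposition()`) operate on snapshots
aligned by `align_snapshots()`: the interface normal is the axis with the
strongest species contrast (measured as the first circular harmonic of the
hot-fraction profile, which discriminates separated from mixed states even
with heavy counting noise), and each frame is shifted so the circular mean
of the hot particles sits at the box center. Plain averaging of a periodic
coordinate is wrong across the boundary; the circular mean is not.

The default slab count of 100 resolves interfaces a few sigma wide in
melt-sized boxes. Mass is conserved exactly: the slab density integral times
the cross-section recovers the particle count per frame. The msv profile
satisfies, per snapshot and slab, the identity
`<v^2>/3 = Theff phi_h + Tceff (1 - phi_h)` with `phi_h` the hot number
fraction; `msv_decomposition()` also returns the uncorrelated combination
`<Theff><phi_h> + <Tceff>(1 - <phi_h>)` whose difference isolates the
composition–velocity correlation (positive in the hot phase, negative in
the cold phase of separated states).

`pressure_profiles()` computes the kinetic tensor per slab as
`rho(z) <v_i v_j>`, which reduces to `rho T` on the diagonal for Maxwell
velocities; a printed convention that folds the 3-fold trace average into
the kinetic term (an extra /3) is available behind `as_printed = TRUE`. The
virial part assigns to each slab the contribution `(r (x) F) / (2A)` of
every pair whose minimum-image segment crosses the slab's mid-plane. The
tension integral `gamma = 1/2 \int (pN - pT) dz` is reported with a
frame-spread uncertainty and is a diagnostic only — for melts of accessible
size it does not converge to a useful precision, and no result in the
package depends on it.

The contact order parameter `Phi = 2x - 1` uses the interaction cutoff `rc`
as the neighborhood radius; `x` is the same-species fraction among
inter-chain neighbors, averaged over monomers that have at least one such
neighbor (monomer-weighted; a contact-weighted average was the other
defensible choice and differs only at interfaces).

## Critical-point estimators

Three independent estimators target the critical asymmetry `chi*`.

**Entropy production.** In the steady state each reservoir absorbs a net
heat flux, and the entropy production per hot particle is
`Sdot/(3 zeta) = Theff/Th + Tceff/Tc - 2` (`entropy_production()`). Below
the transition it grows as `chi^2`; once the two-dimensional interface
exists it plateaus. `crossover_chi_star()` scans every admissible split of
the curve into a low window (fit `a chi^2`, through the origin because the
flux vanishes at equal effective temperatures) and a high window (constant),
keeps the branch intersections that fall between the windows, and reports
their mean and spread. Scanning windows rather than fixing one acknowledges
that the estimate is sensitive to the fitting range.

**Sub-box cumulants.** `fourth_order_cumulant()` divides the box into `n^3`
sub-boxes on wrapped, unaligned coordinates (the statistic must not depend
on where the interface happens to sit) and forms the ratio of the ensemble
mean fourth central moment of the hot density to the squared ensemble mean
second moment. Gaussian fluctuations give 3, a symmetric two-state mixture
gives 1, and curves for different `n` cross near criticality
(`cumulant_crossings()`, pairwise linear interpolation — no spline
smoothing, so the estimator is exactly reproducible). The mean-field
reference level Gamma(1/4)^4 / (8 pi^2) ~ 2.188 is provided by
`mean_field_cumulant()`. Sub-box sizes are a user choice: all requested `n`
are reported rather than auto-selected, since the defensible range (larger
than the correlation length, smaller than the box) is not knowable a
priori.

**Binodal power law.** `binodal_from_profiles()` reads coexisting-phase
plateaus as the mean over slabs farther than 1.5 interfacial widths from
both interfaces, with the width taken from the 25–75% crossing distance of
the hot-fraction profile converted to the equivalent tanh width.
`power_law_fit()` fits `delta_rho = A (chi - chi*)^beta` by weighted least
squares in log–log space, with any subset of the three parameters fixed —
the three variants used in practice are all free, `beta` pinned to the
mean-field 1/2, and `chi*` pinned to the entropy-production estimate.

## Capillary-wave analysis

`interface_heights()` divides the interface plane into `nB x nB` blocks and
assigns each block a height from the z-profile of the signed species count:
the changepoint that extremizes the cumulative sum (CUSUM). A plain
interpolated zero crossing was the first candidate, but with a few dozen
particles per block column the count profile crosses zero many times and
the nearest-crossing rule biases heights toward the reference plane; the
CUSUM extremum is the zero crossing that maximizes the segregated mass on
either side and stays well defined in the sparse regime. Blocks whose CUSUM
depth does not exceed twice the counting-noise scale `sqrt(count)` are
rejected, and a snapshot is dropped entirely (with a warning) when more
than 20% of its blocks fail — overhangs and bubbles violate the small-
gradient picture behind the height representation. Both interfaces of the
periodic box are accumulated as independent samples.

`fourier_amplitudes()` expands a height field over the unique half-plane
modes resolvable on the grid (the grid Nyquist row/column is excluded),
`h = <h> + sum A cos(q r) + B sin(q r)` with `q = 2 pi (n, m)/L`, and
`C^2 = (A^2 + B^2)/2`. With this normalization the mode sum satisfies
Parseval exactly for band-limited fields — `sum C^2` equals the height
variance — and the equilibrium-like spectrum reads
`<C^2> = 2 / (gamma_beta L^2 q^2)`. These two statements fix the third:
the apparent width grows as `w^2 = ln(nB/c) / (2 pi gamma_beta)`. (Printed
conventions that carry the mode sum over both half-planes differ by a
factor 2 in the Parseval statement; the package uses the internally
consistent set above, and both estimator routes below recover the generator
truth under it.)

The stiffness `gamma_beta` is estimated two ways: a weighted one-parameter
fit of the spectrum prefactor (`stiffness_from_spectrum()`, optionally
dropping the slowest mode, whose correlation time is longest), averaged
over block counts when several are supplied; and the two-parameter
`(c, gamma_beta)` fit of `w^2` against `ln nB` over the log-linear regime,
by default `nB` in [5, 9] (`width_vs_blocks()`). Spectrum snapshots should
be spaced by more than the correlation time of the slowest mode, measured
by `mode_autocorrelation()`: the normalized autocovariance of `C_01` is
fitted with `exp(-t/tau_c)` through the origin, restricted to lags with
autocorrelation above 0.2 — the logarithm amplifies sampling noise once the
signal is small, and the floor keeps the estimator's spread near 7% on
AR(1) benchmarks where an 0.05 floor gave 25%.

`chi_star_from_stiffness()` exploits the empirically linear growth of
`gamma_beta` with `sqrt(chi)`: the root of a weighted line fit, squared
back, is a third `chi*` estimate with a delta-method uncertainty. At large
asymmetry the width shrinks as `chi^(-1/2)`; `width_chi_scaling()` tabulates
`w sqrt(chi)` so that flatness can be inspected rather than fitted.

## Synthetic generators, and what passing tests do not show

Every estimator is testable without molecular dynamics through seeded
generators that emit their ground truth alongside the data:

- `make_two_phase()` places particles uniformly at per-phase densities with
  purity-controlled species labels (tanh crossover of settable width),
  Maxwell velocities at per-species temperatures, and optional cosine
  corrugations of the dividing surfaces. Chains are label-topological —
  contiguous blocks of `N` spatially sorted labels — sufficient for the
  order parameter, profiles, cumulants and interface analyses, none of
  which evaluate bonded forces; bond lengths in these fixtures are not
  mechanical.
- `make_height_ensemble()` draws independent Gaussian mode amplitudes with
  `Var(A) = Var(B) = 2/(gamma_beta L^2 q^2)`.
- `make_ar1_series()` produces a stationary AR(1) series with per-step
  autocorrelation `exp(-spacing/tau_c)`.
- `make_critical_curves()` produces the three observable-versus-chi shapes
  (power-law binodal with defaults A = 0.143 sigma^-3, chi* = 0.36,
  beta = 0.47 and Gaussian noise 0.02 sigma^-3, the realistic binodal
  fluctuation scale; quadratic-to-plateau entropy curves with crossover
  0.43; cumulant families crossing at 0.46 at level 2.0).

What these fixtures deliberately omit: mechanical equilibrium (the
two-phase fixture is not force-balanced, so its full pressure tensor is not
flat), interfacial velocity anisotropy (exclusively a simulator
observable), correlations between snapshots, and capillary roughening of
the fixture interfaces beyond the imposed corrugations. Passing the
round-trip suites therefore certifies the estimators, not the physics; the
physics is exercised by the scaled-down simulation checks below.

## Scaled-down simulation checks

The full campaigns behind the phase diagrams (M = 5000 chains observed for
2 x 10^6 tau, sampled every 5000 tau, at least 400 configurations per
thermostat setting, spectra from configurations 3 x 10^4 tau apart) are
cluster-scale. The package's own simulation checks run desk-scale versions
whose sizes were chosen as the smallest systems in which the physics is
visible: energy conservation and equipartition on ~100-particle melts
(10^4 steps), Maxwell stationarity of a single free hot particle over
10^6 steps, and a two-temperature demonstration with M = 64 chains of
N = 40 at Th = 3, zeta = 1.5 run for 2 x 10^3 tau.

The demonstration size deserves an honest caveat. The critical asymmetry is
a finite-size quantity — the interface is a finite fraction of a finite
box, and the effective temperatures (hence chi itself) depend on the system
size. At M = 64 and Th = 3 the measured mixed-state asymmetry is only
chi ~ 0.6, and exploratory runs show that even an artificially
pre-separated slab relaxes back toward the mixed state, while the same
protocol at M = 200 keeps the slab stable (chi ~ 1.06) and a stronger
quench (Th = 6) separates M = 64 from a mixed start. In other words, at
M = 64 the finite-size-shifted critical point lies above Th = 3: the
demonstration robustly shows the driven-blend signatures — the temperature
ordering Tc < Tceff <= Theff < Th and strictly positive entropy production
— but full phase separation (order parameter above 0.5, two density
plateaus) is not reachable at that size and thermostat setting, and the
corresponding check in the acceptance suite documents exactly that.

## Numerical choices and limitations

- Crossing and crossover estimators interpolate linearly; no smoothing.
- The power-law fit optimizes `chi*` by golden-section search on the
  profiled weighted RSS (tolerance 1e-12), then reports a covariance from
  the numerical Hessian; noiseless data are inverted to ~1e-6.
- Block heights are quantized at the z-histogram resolution `Lz/nslab`,
  which adds a flat noise floor to measured spectra; generator-based tests
  avoid it, simulator spectra inherit it.
- The interfacial tension route (pressure-tensor anisotropy integral) is
  reported but known not to converge at accessible sizes.
- `chi` depends on system size in the separated state (the interface is a
  finite fraction of a finite system), so critical-point estimates from
  different `M` are estimates for that size; the package always measures
  `chi` from effective temperatures and never assumes it transfers across
  sizes.
- No vectorial self-propulsion, no constant-pressure coupling, no attempt
  to separate `gamma` and `beta` within the stiffness product, and no
  grand-canonical universality-class analysis.
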