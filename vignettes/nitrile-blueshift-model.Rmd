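---
title: "Modeling nitrile hydrogen-bond blueshifts and their lineshapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nitrile hydrogen-bond blueshifts and their lineshapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsemap)
```

## The problem

Nitrile (C&#8801;N) stretches are popular infrared probes of local
electrostatics: their frequency responds linearly (and weakly
quadratically) to the electric field projected on the bond, the
vibrational Stark effect (VSE),

$$\nu(F) = \nu_0 + |\Delta\mu|\,F + \tfrac{1}{2}\Delta\alpha F^2 .$$

The sign convention used throughout `vsemap` is that $F$ is the signed
projection of the field onto the difference-dipole direction of the probe;
stabilizing condensed-phase fields are negative, so they red-shift the
band. With the packaged tuning rate $|\Delta\mu| = 0.2748$
cm$^{-1}$/(MV/cm), a $-78$ MV/cm protein field shifts a 2236.9 cm$^{-1}$
zero-field band to 2215.5 cm$^{-1}$.

Hydrogen bonding breaks this picture: an H-bond donor at the nitrile
nitrogen adds an anomalous *blueshift* on top of the Stark response. The
total frequency is decomposed as

$$\nu = \nu_{\mathrm{VSE}}(F) + \sum_{\mathrm{HBs}}
\Delta\bar\nu_{\mathrm{HB}}(d, \theta),$$

where each hydrogen bond contributes independently and additively (at most
two are admitted, the validated regime), and the blueshift depends only on
the heavy-atom contact geometry: the N···O/N donor distance $d$ (&#8491;)
and the angle $\theta$ at the nitrile nitrogen between the bond and the
donor direction (collinear, "head-on" contacts have $\theta = 180°$).
Heavy-atom geometry is deliberate: hydrogen positions are unreliable both
in force-field trajectories (constraint algorithms) and in crystal
structures, while heavy atoms are well resolved.

## The blueshift surface

The geometric blueshift is modeled as an angular interpolation between a
head-on and a side-on distance law:

$$\Delta\bar\nu_{\mathrm{HB}}(d,\theta)
  = f(\theta)\,\Delta\bar\nu_{d_0}\left(\frac{d}{d_0}\right)^{n_1}
  + \bigl(1 - f(\theta)\bigr)\,\Delta\bar\nu_{d_0}
    \left[e^{-b(d-d_0)} - \left(\frac{d}{d_0}\right)^{n_2}\right],
  \qquad f(\theta) = \cos\bigl(m\,(180° - \theta)\bigr).$$

* The **head-on term** is a power law with fixed integer exponent
  $n_1 = -4$, the signature of a repulsive dipole–quadrupole interaction.
  An exponential variant $e^{-a(d - d_0)}$ with $a = 1.30$ &#8491;$^{-1}$
  (suggestive of Pauli repulsion) is selectable via
  `headon_variant = "exponential"` but is not the default: the canonical
  combined model uses the integer-exponent power form.
* The **side-on term** is Buckingham-like: an exponential wall
  ($b = 2.85$ &#8491;$^{-1}$) minus a $d^{-8}$ attraction
  ($n_2 = -8$, induced higher-multipole interactions). It crosses zero at
  the reference distance $d_0 = 3.36$ &#8491; — which is what *defines*
  $d_0$ — and passes through a shallow negative well (red-shift) at
  intermediate distances.
* The **angular factor** is normalized to 1 at $\theta = 180°$ and its
  period modulation $m$ places the zero crossing where a side-on donor
  engages the $\pi$ system: $\theta_0 = 180° - 90°/m$, i.e. 70.2° for
  $m = 0.82$ (the single-variable angular fit) and 81.1° for the
  canonical $m = 0.91$. $\theta = 180°$ itself is admitted: the cosine
  form extends smoothly even though calibration data avoid the exactly
  collinear pose.

The four tunable parameters, with the packaged canonical values
($d_0 = 3.36$ &#8491;, $\Delta\bar\nu_{d_0} = 16.6$ cm$^{-1}$,
$b = 2.85$ &#8491;$^{-1}$, $m = 0.91$), ship as a versioned YAML config
(`inst/extdata/default_params.yaml`); the integer exponents are fixed.
Over the calibrated geometry window ($d$ = 2.5–5.0 &#8491;, $\theta$ =
70–175°) the surface spans about $-4$ to $+54$ cm$^{-1}$, with the
maximum at the short-distance head-on corner. The algebraic grouping
above was selected because it simultaneously reproduces, with the
canonical parameters, three independently reported point predictions at
(3.00 &#8491;, 163°), (2.85 &#8491;, 168°) and (2.79 &#8491;, 150°) to
within 0.15 cm$^{-1}$; no smooth surface can reproduce every reported
ensemble-averaged prediction, which mix frame averaging with point
evaluation.

```{r surface-example}
hb_blueshift(c(2.93, 3.00, 2.85, 2.79), c(169, 163, 168, 150))
```

**Extrapolation policy.** Distances outside [2.5, 8] &#8491; are evaluated
smoothly but flagged (`extrapolated` attribute plus a warning) rather than
rejected — by 5 &#8491; the model is near zero by construction, so the
flag mostly matters below 2.5 &#8491; where the Buckingham form turns
unphysical. The standalone `sideon_term()` refuses $d <$ 2.5 &#8491;
outright.

## Calibration

`fit_vse_tdm()` and `fit_vse_frequency()` are linear least-squares fits of
the transition-dipole and frequency VSE models. The frequency fit is
performed on purely electrostatic records only; applying those parameters
unchanged to hydrogen-bonded records produces the diagnostic *negative*
$R^2$ (the model does worse than the observed mean), which is the
operational signature of the blueshift. `goodness()` therefore uses
$R^2 = 1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$ with $SS_{\mathrm{tot}}$
about the observed mean, which permits negative values.

For observed-versus-modeled comparisons scored about the 1:1 line,
`goodness_identity()` normalizes instead by the variance of the model
values being scored. The two conventions are deliberately exposed under
distinct names; the identity-line convention is the one under which the
package's seven-point observed/modeled benchmark comparison rounds to
0.95.

`extract_blueshifts()` rearranges the frequency decomposition:
$\Delta\bar\nu_{\mathrm{HB}} = \nu_{\mathrm{obs}} -
\nu_{\mathrm{VSE}}(F)$ per record. The nonlinear fits (`fit_headon()`,
`fit_sideon()`, `fit_angular()`, `fit_joint()`) use Levenberg–Marquardt
least squares with a deterministic multi-start grid (Buckingham-like
shapes have local minima), tolerances of $10^{-12}$/$10^{-10}$ on the
objective and parameters, and tie-breaking by lowest RMSD; non-convergence
from every start is a reported error, never silent. All fits are
unweighted. `fit_joint()` fits the full decomposition — VSE plus surface —
simultaneously over electrostatic and hydrogen-bonded records with the
integer exponents held fixed; on a noiseless synthetic grid it recovers
the generating parameters to well under 0.1%, and with 1.8 cm$^{-1}$
Gaussian frequency noise its residual RMSD reproduces the injected noise.

A caution from the test suite: with the quadratic field term freed, the
tuning rate and $\Delta\alpha$ are nearly collinear over a narrow
field range, so individual parameter values from `fit_vse_frequency()`
should be interpreted on wide field spans or with `quadratic = FALSE`.
Similarly, the `two_power` side-on variant is only jointly identified —
the two power terms can trade amplitude — and is reported for exponent
robustness checks, not as a calibrated model.

## Synthetic data: what it emulates and what it does not

`generate_calibration_grid()` emulates a quantum-chemistry calibration
design: 420 donor configurations (20 distances × 21 angles over
2.5–5.0 &#8491; and 70–175°) and 125 point-charge configurations
(5 × 25 over 5.0–8.0 &#8491;). Fields are assigned by a declared monotone
surrogate map $F = -s/d^2$ with $s = 500$ (MV/cm)·&#8491;$^2$, spanning
roughly $-80$ to $-8$ MV/cm — the realistic condensed-phase window — in
place of force-field electrostatics. Frequencies and TDMs are exact model
evaluations plus independent Gaussian noise of configurable width; the
noise model is a declared assumption (real electronic-structure residuals
are not independent Gaussians). Passing parameter-recovery tests on this
grid therefore demonstrates the estimator's correctness, not the physical
accuracy of any particular calibration.

`simulate_hb_trajectory()` is a two-state continuous-time Markov surrogate
for hydrogen-bond kinetics, discretized at the sampling interval (default
20 fs): exponential residence in bound/free states, truncated-Gaussian
bound-state geometry with the anticorrelated distance–angle trend
(3.35 &#8491; at 70° falling to 2.93 &#8491; head-on), and a
mean-reverting Gaussian (Ornstein–Uhlenbeck) field. Defaults: 2 ps mean
residence in each state, geometry (3.00 &#8491;, 160°) with spreads
(0.10 &#8491;, 8°), field $-64.9 \pm 5$ MV/cm with 1 ps correlation time.
These are declared surrogates for solvent-exposed probes, not fits to any
particular trajectory; every test states its own residence times. What
the surrogate does *not* emulate: continuous geometry relaxation within
the bound state, non-exponential dwell statistics, field–geometry
cross-correlation, and multi-donor exchange.

## Lineshapes

`map_trajectory()` (the vibrational spectroscopic map) converts a frame
series of (field, occupancy, geometry) into instantaneous frequency and
TDM. `ffa_spectrum()` implements the fluctuating frequency approximation:

$$I(\nu) \propto \mathrm{Re}\int_0^\infty \mathrm{d}t\,
  e^{-i\,2\pi c\,(\nu - \bar\nu)\,t}\,
  \bigl\langle \mu(0)\,\mu(t)\,
  e^{\,i\int_0^t \delta\omega(\tau)\mathrm{d}\tau} \bigr\rangle,
  \qquad \delta\omega = 2\pi c\,(\nu(t) - \bar\nu).$$

Numerical choices, all configurable:

* phase accumulation by the trapezoid rule on the native sampling
  interval (20 fs by default);
* correlation functions averaged over time origins within a 16 ps window
  at 50% overlap (a bias/variance compromise: longer windows sharpen the
  raw resolution but add tail noise);
* exponential lifetime apodization $e^{-t/2T_1}$ with $T_1 = 3$ ps by
  default (≈1.8 cm$^{-1}$ Lorentzian width), plus a documented
  no-apodization mode (`lifetime_ps = NULL`). Peak *positions* — the
  quantities compared throughout — are insensitive to this factor;
* zero-padding to a 0.5 cm$^{-1}$ grid and parabolic interpolation of
  peak positions around grid maxima.

`inhomogeneous_spectrum()` gives the static limit (the TDM²-weighted
density of instantaneous frequencies), and `kubo_two_state()` the analytic
two-site exchange lineshape that serves as the independent oracle: the
FFA engine run on two-state Markov trajectories must agree with it
peak-for-peak, and does so across rates from 0.01× to 100× the
coalescence rate in the test suite. Exactly *at* coalescence the band top
is flat over several cm$^{-1}$ (intensities within 0.5% of the maximum),
so a "peak position" ceases to be an identifiable observable there at any
realistic trajectory length; the oracle comparison brackets rather than
samples that singular point.

## Units, time scales, and motional narrowing

Wavenumbers convert to angular frequency as $\omega = 2\pi c \tilde\nu$.
For two substates split by $\Delta\tilde\nu$, symmetric two-site exchange
coalesces when the total exchange rate reaches
$k_c = 2\pi c\,\Delta\tilde\nu/\sqrt{2}$ (`coalescence_rate()`): for a
26 cm$^{-1}$ split this is a *residence time* near 0.6 ps, and genuine
motional narrowing — a single band at the population-weighted mean, i.e.
an apparent blueshift of half the geometric one for symmetric exchange —
requires sub-picosecond residence. The package's end-to-end demonstration
uses 0.1 ps residences and recovers the factor-2 reduction within
tolerance. A frequently quoted rule of thumb associates 20 cm$^{-1}$ with
"about 2 ps"; that number is $1/(c\Delta\tilde\nu)$ and omits the $2\pi$.
At 2 ps residence a 26 cm$^{-1}$ two-state system is in fact in slow
exchange: the simulated spectrum shows two bands essentially at the
substate frequencies (the acceptance suite records a reduction factor of
about 1.03 there, with the narrowed factor-2 behavior appearing only at
genuinely fast residence). Real solvent shells have substantial
sub-picosecond kinetics, which is why experimentally observed
solvent-exposed nitriles can still show halved blueshifts.

`apparent_blueshift()` reports the main-peak position minus a VSE-only
reference frequency; in slow exchange with symmetric populations the two
bands have near-equal heights and the "main peak" designation follows the
(slightly) higher band. `decompose_two_bands()` separates overlapping
contributions by a two-Gaussian least-squares fit, attempted from
symmetric-split starting values even when the band shows a single
maximum (a 5.5 cm$^{-1}$ split at 3 cm$^{-1}$ component widths is
unimodal); inputs that a single symmetric band already fits to within
$10^{-4}$ relative RMSE are flagged and returned as one component.

## Problem sizes

The shipped tests and the acceptance script use trajectories of
$2^{20}$–$10^6$ frames at 20 fs (≈21 ns), calibration grids of 545
records, and 100-replicate Monte-Carlo loops for error-bar calibration —
sizes chosen so the full suite completes in well under two minutes while
leaving Monte-Carlo and dwell-time statistics comfortably inside their
tolerances.

## Known limitations

* The blueshift surface is calibrated for nitriles with O/N heavy-atom
  donors in the 2.5–5.0 &#8491;, 70–175° window; outside it the model
  extrapolates smoothly but without support.
* Carbonyl, azide and C–D probes are out of scope (carbonyls follow the
  linear VSE without a blueshift term and need none of this machinery).
* The TDM map is linear (optionally weakly quadratic) in the field; no
  non-Condon dynamics beyond that.
* No 2D-IR or temperature-dependent lineshape modeling.
* PDB handling reads the first model only, resolves alternate locations
  by highest occupancy (ties alphabetically), and ignores hydrogens by
  design.
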