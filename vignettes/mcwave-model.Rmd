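---
title: "A Monte Carlo-wave model of diffuse correlation spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Monte Carlo-wave model of diffuse correlation spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Diffuse correlation spectroscopy (DCS) infers tissue dynamics — chiefly
cerebral blood flow — from the temporal fluctuations of multiply
scattered coherent light. A detector a few centimetres from the source
collects a speckle field whose intensity autocorrelation
$g_2(\tau) = \langle I(t)I(t+\tau)\rangle / \langle I\rangle^2$ decays on
a timescale $\tau_c$ set by the motion of red blood cells. The
time-domain variant (TD-DCS) uses a pulsed source and gates photons by
arrival time, selecting pathlength — and hence depth — at a single
source–detector separation, at the price of photon flux and source
coherence. `dcswave` simulates both modalities from first principles, so
that signal-to-noise, contrast-to-noise and depth specificity can be
predicted for arbitrary instrument parameters rather than assumed from
continuous-wave noise models.

## The model

The simulator factors the physics into stages that mirror a real
measurement:

1. **Photon transport.** An isotropic-scattering Monte Carlo
   (`simulate_photons()`) tracks photons through a layered semi-infinite
   medium and records, for each detected photon $n$, the per-layer
   scattering counts $N_{n,\ell}$ and pathlengths $L_{n,\ell}$.
   Absorption is *not* applied during transport; it enters later as a
   deterministic weight $e^{-\sum_\ell \mu_{a,\ell} L_{n,\ell}}$ on the
   photon intensity, so one transport run serves any absorption setting.
2. **Arrival times and gating.** The transit time is $t_L = L/v$ with
   $v = c/n$; an instrument-response delay drawn from the IRF density by
   inverse-transform sampling (`sample_irf_times()`) is added, and a gate
   $[t_s - t_w/2,\, t_s + t_w/2)$ selects the time-domain photon subset
   (`gate_records()`). Continuous-wave operation simply keeps all
   photons.
3. **Speckle synthesis.** Each photon contributes a partial wave
   $S(k_i)\, w_n\, e^{i(\phi_n + k_i L_n - k_i X_n(t))}$ per spectral
   line $k_i$; the detected intensity is the incoherent sum over lines of
   the coherent sum over photons, $I(t) = \sum_i \lvert \sum_n E_{n,i}(t)
   \rvert^2$ (`synthesize_intensity()`). The initial phases $\phi_n$ are
   uniform on $[0, 2\pi)$, and the dynamic phase driver $X_n(t)$
   accumulates $\hat q \cdot \Delta \vec r$ over the photon's scattering
   events as the scatterers diffuse.
4. **Counting.** Intensity is rescaled to a target mean count per bin
   and Poisson-sampled (`to_counts()`), adding shot noise.
5. **Estimation.** The lagged-product estimator (`g2_estimate()`) and a
   Siegert-model fit (`fit_tau_c()`) recover $\tau_c$ and the coherence
   factor $\beta$.

Closed-form references for each stage — the semi-infinite
correlation-diffusion solution `g1_semi_infinite()`, the pathlength
density `pathlength_pdf()`, the coherence integral `beta_of_coherence()`,
the gated two-pathlength quadrature `gated_g2_theory()` and the
photon-counting noise model `sigma_noise_cw()` — validate the simulator,
and `run_replicates()` orchestrates replicate ensembles for the
performance metrics (SNR $= \bar\tau_c/\mathrm{sd}(\tau_c)$, contrast
$\Delta\tau_c$, CNR, specificity $\Delta\tau_c / \Delta\tau_{c,h}$).

## Brownian phase dynamics, exactly but cheaply

Each scattering event $s$ of photon $n$ carries a momentum transfer
$\vec q_{ns} = k_i(\hat n_{\mathrm{out}} - \hat n_{\mathrm{in}})$; with
isotropic scattering $|\hat n_{\mathrm{out}} - \hat n_{\mathrm{in}}|^2 =
2(1 - \cos\theta)$ with $\cos\theta$ uniform on $[-1, 1]$ (mean 2). The
scatterer displacement is Brownian with per-axis increments
$\mathcal N(0, 2 D_B \Delta t)$. Because every term
$\hat q_{ns}\cdot\Delta\vec r_{ns}(t)$ is an independent Gaussian
increment process, their sum is itself a Wiener process with variance
rate $2\sum_\ell D_{B,\ell} \sum_{s\in\ell} |\Delta\hat n_{ns}|^2$ — so
the package generates $X_n(t)$ directly at that rate (the *aggregated*
mode), which is exact in distribution and reduces the cost from (events ×
bins) to (photons × bins). The literal construction, with one 3-D random
walk per scatterer (`simulate_dynamic_phases(mode = "explicit")`), is
retained as an oracle; the test suite checks the two are
distributionally indistinguishable and produce the same speckle
statistics. Brownian updates occur at the bin resolution $T_b$: the
intensity is only observed per bin, and the self-similarity of the
Wiener process makes sub-bin updates statistically redundant.

Setting $\langle|\Delta\hat n|^2\rangle = 2$ and $\mathbb E[N_n] =
\mu_s' L_n$ recovers the pathlength-resolved correlation $g_1(L, \tau) =
\exp(-2\mu_s' D_B k_0^2 L \tau)$ used by the analytic references, which
ties the wave stage to the transport stage with no free parameter.

## Study conditions and defaults

The defaults encode the two-layer head model used throughout the
package's validation: a 15 mm superficial layer over a semi-infinite
deep layer, $\mu_s' = 1\,\mathrm{mm}^{-1}$, $\mu_a =
0.01\,\mathrm{mm}^{-1}$, $g = 0$, $n = 1.33$, detector diameter 2 mm,
$\lambda_0 = 800$ nm, baseline $D_B = 10^{-6}\,\mathrm{mm^2/s}$ in both
layers, activation $D_B = 2.25\times10^{-6}\,\mathrm{mm^2/s}$ in the
deep layer, $T_b = 1\,\mu s$, $T = 10$ ms, and a reference detected flux
of $10^5$ photons/s for ungated detection at $\rho = 20$ mm
(`flux_for_condition()` scales other conditions by their detected photon
count). Gates of width 0.2 ns at delays 0.5–2.5 ns and a coherence
length of 90 mm define the time-domain conditions.

Parameters a user will most often touch:

* `DB` (mm$^2$/s): effective Brownian diffusion coefficient of the
  scatterers; the decay rate of $g_1$ is proportional to it.
* `lc` (mm): source coherence length. The Gaussian spectral amplitude is
  $S(k) = e^{-(k-k_0)^2/2k_c^2}$ with $k_c = \pi/(2 l_c)$; `lc = Inf`
  collapses to a single line and $\beta = 1$.
* `gate(ts, tw)` (ns): arrival-time window. Later gates select longer
  paths, hence deeper sensitivity and faster decay.
* `Tb`, `T_total` (s): correlator bin time and measurement window; they
  control both the lag resolution and the speckle-noise floor
  ($\sigma \propto \sqrt{T_b/T}$).
* `flux` (photons/s): detected photon budget for the counting stage.

## Numerical choices

* **Boundary condition.** The tissue–air interface is index-mismatched:
  at each surface contact the photon reflects with the unpolarized
  Fresnel probability (total internal reflection included) and escapes
  otherwise. This is consistent with the effective reflectivity
  $R_{\mathrm{eff}} = 0.493$ that the analytic pathlength density uses
  for $n = 1.33$ — an index-matched (absorbing) boundary, kept as an
  option, corresponds to $R_{\mathrm{eff}} \approx 0$ and yields
  detected fractions an order of magnitude lower and a mismatched
  $P(L)$. Detection reads "size 2 mm" as a disc of *diameter* 2 mm
  centred at $(\rho, 0)$; photons are counted when they escape through
  the disc, with no numerical-aperture cut.
* **Pathlength cutoff.** Transport terminates photons beyond 3000 mm of
  accumulated path: at $\mu_a = 0.01\,\mathrm{mm^{-1}}$ such paths carry
  intensity weights below $10^{-13}$.
* **Ring tally.** By rotational symmetry, an escaping photon at exit
  radius $r$ lands in the detector disc with probability
  $\phi(r)/\pi$, the azimuthal overlap fraction. The `"ring"` tally
  records every escape with that weight instead of the Bernoulli
  outcome, an exact-in-expectation variance reduction worth roughly two
  orders of magnitude in effective photons per launch; `"direct"`
  reproduces the physical detector literally. Weighted record sets are
  thinned for synthesis by Bernoulli subsampling
  (`subsample_records()`), never by resampling with replacement —
  duplicated trajectories would fake perfectly coherent photon pairs and
  bias $\beta$ upward at finite coherence length.
* **Absorption on the field.** A field weight $e^{-\mu_a L}$ would make
  photon intensities scale as $e^{-2\mu_a L}$, inconsistent with the
  pathlength density it must reproduce; the default therefore puts the
  square root of the intensity attenuation on the field
  (`absorption = "intensity"`), and the literal field-attenuation
  convention remains available for comparison.
* **Coherence envelope.** With amplitude weights $S(k_i)$, pairs of
  spectral lines drawn from the power spectrum $S^2$ have wavevector
  differences of variance $k_c^2$, giving the interference envelope
  $e^{-k_c^2 (L - L')^2/2}$. The analytic coherence and gated-g2
  integrals use this self-consistent envelope by default
  (`envelope = "spectrum"`); the conventional closed-form envelope
  $e^{-16 (L-L')^2/\pi^2 l_c^2}$ — a different coherence-length
  convention — is implemented verbatim as `envelope = "printed"`. At
  $l_c = 90$ mm and $\rho = 20$ mm the two give $\beta = 0.553$ and
  $0.506$ respectively; the simulator reproduces the former, as the
  test suite verifies.
* **Spectrum discretization.** 21 lines spanning $\pm 3.5$ spectral
  widths; doubling either changes the predicted $\beta$ by less than
  0.005.
* **Boundary distance in the field model.** The `5/3` extrapolation
  factor of the semi-infinite correlation solution is implemented as
  $(5/3)/\mu_s'$ (dimensionally a length); the dimensionally
  inconsistent literal $(5/3)\mu_s'$ is available as
  `zb_convention = "printed"` and is identical at $\mu_s' = 1$.
* **Fit conventions.** `fit_tau_c()` fits
  $g_2 = 1 + \beta e^{-2\tau/\tau_c}$ (so $g_1 = e^{-\tau/\tau_c}$) over
  a window that stops where a 5-point moving average of $g_2 - 1$ falls
  below $5\%$ of the pre-fit intercept, with uniform weights and free
  $\beta$ (both overridable). It also reports
  $\tau_{\mathrm{decay}} = \tau_c/2$, the 1/e time of $g_2 - 1$ itself,
  which is the number a direct exponential fit of the measured curve
  quotes; at the default continuous-wave condition the theory curve
  gives $\tau_c = 67\,\mu s$, i.e. $\tau_{\mathrm{decay}} = 34\,\mu s$.
* **Seeds.** Every stochastic stage (transport, instrument delays,
  initial phases, direction changes, Brownian paths, Poisson counting,
  replicate loops) draws from its own sub-stream derived via
  `derive_seed()` from one master seed, so stages can be re-run or
  replicated independently and reproducibly.
* **Degenerate inputs.** Zero launches return an empty record set; an
  empty gate warns and returns an empty subset, and synthesis of an
  empty set is an error; `D_B = 0` freezes the speckle; a flat
  correlation curve makes the fit fail distinctly rather than return a
  spurious decay.

## Replicate experiments

`run_replicates()` re-runs the wave stage (fresh phases, direction
changes, Brownian paths, and Poisson draws when a flux is given) on one
shared photon-record set, so ensemble spreads isolate speckle and shot
noise from transport noise. Passing the *same* master seed to a baseline
and an activated condition pairs their replicates through common random
numbers, which cancels most speckle noise from contrast estimates — the
package's tests exploit this to resolve depth-specificity orderings with
tens rather than hundreds of replicates. Fit failures are excluded and
logged; an ensemble with more than 20% failures is flagged invalid.

`shot_noise_decomposition()` separates counting noise from speckle
noise: for each fresh intensity series, many Poisson count realizations
are drawn, their g2 curves averaged, and the averaged curve fitted;
across outer repeats $\mathrm{Var}(\tau_{c,\mathrm{avg}}) =
\mathrm{Var}_{\mathrm{speckle}} + \mathrm{Var}_{\mathrm{shot}}/N_{\mathrm{avg}}$.
Because the conventional linear scaling
$N_{\mathrm{avg}}\,\mathrm{sd}(\tau_{c,\mathrm{avg}})$ is dimensionally
ambiguous (the $1/N_{\mathrm{avg}}$ suppression applies to the
variance), both that quantity and the variance-consistent
$\sqrt{N_{\mathrm{avg}}(\mathrm{Var}(\tau_{c,\mathrm{avg}}) -
\mathrm{Var}_{\mathrm{speckle}})}$ are returned. A caveat applies to both:
the fitted decay time is a nonlinear functional of the noisy correlation
curve, so the linear $1/N_{\mathrm{avg}}$ variance scaling — and hence
strict additivity against a single-draw ensemble — holds only
approximately once single-draw curves are dominated by shot noise (the
fit window rule and parameter bounds shrink single-draw variance below
the linear extrapolation, by roughly a factor of two at a mean count of
0.1 per bin).

## What the synthetic data does and does not emulate

The generator reproduces: diffusive photon migration in layered media
with index-mismatched boundaries; per-photon pathlength and
momentum-transfer bookkeeping; Brownian (shear-induced diffusive)
scatterer motion; finite source coherence via a discretized Gaussian
spectrum; instrument-response broadening of arrival times; gating;
fully developed speckle statistics; and Poisson counting. It does not
model convective or ordered flow components, anisotropic phase
functions (reduced optics stand in via $\mu_s' $), polarization (a
$\beta < 1$ from multimode detection must be imposed through `fix_beta`
or a finite $l_c$), detector afterpulsing, dead time or dark counts, or
curved anatomical geometries. Passing tests therefore certify the
model's internal consistency and its agreement with homogeneous
semi-infinite diffusion theory — not fidelity to any particular
instrument, which enters only through a measured IRF table and the
user's parameter choices.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script size their simulations for a
single CPU: transport runs of $10^6$–$4\times10^6$ launched photons with
the ring tally (effective detected samples of order $10^4$–$10^5$),
speckle ensembles of 10–100 replicates at 500–1500 photons and $10^4$
time bins, and a 500-replicate counting-noise ensemble. These sizes keep
every stochastic comparison inside its stated tolerance with margin;
users reproducing figure-quality curves would typically raise the
replicate counts by an order of magnitude.

## Known limitations

* Detected-photon counts depend on the surface model: the absorbing
  (index-matched) option lowers them by an order of magnitude relative
  to the Fresnel default. Comparisons across codes must match this
  convention first.
* The homogeneous semi-infinite analytic references are used to
  validate a two-layer medium with identical optical properties per
  layer; truly heterogeneous optics have no closed-form reference here
  and are validated only by internal consistency.
* The speckle stage shares one transport run across replicates;
  transport (photon-sampling) noise is deliberately excluded from the
  reported ensembles and would add at very low detected counts.
* Values of $\tau_c$ from fits depend on the fit window when the decay
  is multi-exponential; the window rule is fixed and reported in
  `fit_result$window` precisely so that comparisons are reproducible.
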