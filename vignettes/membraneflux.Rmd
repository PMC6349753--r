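---
title: "An ionic-concentration model of passive transmembrane transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ionic-concentration model of passive transmembrane transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membraneflux)
```

## The model

`membraneflux` simulates a spherical cell (default radius 10 µm) whose
state is the vector of average internal ion concentrations together with
the gating state of every channel population. The membrane potential is
not a state variable: it is computed at every instant from the ion
densities on the two membrane surfaces.

**Surface densities.** The net internal charge per membrane area,
$Q = F \sum_i z_i q_i$ with $q_i = (r/3)\,[i]_\mathrm{in}$, accumulates
within one effective ion diameter $\lambda_i$ of the membrane and
generates a near-membrane field $Q/\varepsilon_m$. Tilting each ion's
Boltzmann profile across its own surface layer and writing
$X_i = \chi (Q/F) \lambda_i z_i$ with
$\chi = F^2 / (2RT\varepsilon_m)$ gives the closed forms

$$T_{\mathrm{in},i} = \lambda_i [i]_\mathrm{in}
  \frac{1+X_i}{1-X_i}, \qquad
  T_{\mathrm{ex},i} = \lambda_i [i]_\mathrm{ex}
  \frac{1-X_i}{1+X_i}.$$

The two correction factors are reciprocal, so
$T_\mathrm{in} T_\mathrm{ex} = \lambda^2 [i]_\mathrm{in} [i]_\mathrm{ex}$
independently of $Q$; a positive internal charge enriches cations on the
inner face and depletes them on the outer face. The orientation of the
factors was chosen so that $T_{\mathrm{in},i}$ of a cation increases
monotonically with $Q$ and positive charge produces positive
inside-minus-outside potential; the opposite orientation would make the
potential independent of the charge. The approximation is valid for
$|X_i| < 1$; `surface_densities()` raises a *double-layer overload* error
beyond that, and the integrator soft-clamps trial steps instead (a
clamped accepted sample is reported via the trace bounds).

**Membrane potential.** Each species present on both sides contributes
$V_i = \frac{RT}{Fz_i}\ln(T_{\mathrm{in},i}/T_{\mathrm{ex},i})$. A single
measured scalar must summarize this vector; we use the mean of $V_i$
weighted by $\min([i]_\mathrm{in}, [i]_\mathrm{ex})$, which reduces to
the single-ion value in a one-ion system, gives negligible weight to
trace ions, and excludes ions absent from either side (avoiding
logarithmic singularities). Other defensible collapses exist (e.g.
permeability weighting); the choice only reparameterizes the charge axis
and is documented here as the package's convention.

**Channels.** A channel population is a sensor, a gate and a filter:

* *Sensor*: detected density $\sigma = \sum_i s_i T_{\mathrm{in},i}$
  (channels sense only the inner surface) and detected flux
  $\psi = \sum_i s_i \zeta_i$ through the channel itself. Two
  dimensionless indicators follow: $\vartheta = 2\,\mathrm{atan}
  (\sigma/\bar\sigma) - \pi/2$ (zero at the optimum $\bar\sigma$,
  saturating at $\pm\pi/2$) and $\phi = \tau\psi/\bar\sigma$.
* *Gate*: the exploring variable relaxes at rate $\alpha$ toward
  $\bar v = 1 - \cos(\eta\vartheta)$ — the channel opens whenever the
  sensed density deviates in *either* direction — and the judging
  variable relaxes at rate $\beta(v + \delta)$ toward
  $\bar w = \mathrm{acot}(\phi/\vartheta)/\pi$, which closes the gate
  when the flux deepens the deviation and holds it open when the flux
  restores the optimum. At zero flux $\bar w = 1/2$. The branch
  $\mathrm{acot}: \mathbb{R} \to (0,\pi)$ is the unique one satisfying
  all three limits. At exactly $\vartheta = 0$ the ratio uses
  $\mathrm{sign}(\vartheta)\max(|\vartheta|, 10^{-9})$, with a
  `prev_sign` argument on the pure function for the measure-zero
  ambiguous case; the ODE right-hand side stays stateless.
* *Filter*: per-ion conductive state relaxing at rate $\gamma$ toward
  $\bar f_i = \exp(-\kappa_i \phi^{2m_i} \vartheta^{2n_i})$, i.e.
  occupancy-and-stimulation-driven inactivation that recovers when either
  indicator returns to its optimum.

Channel flux is $\zeta_i = -f_i v w \varrho_i (T_{\mathrm{in},i} -
T_{\mathrm{ex},i})$; the recorded membrane current is $-F\sum_i z_i
\sum_h \zeta_{h,i}$ (outward-positive). Within one right-hand-side
evaluation the order is fixed and algebraic: surface densities →
permeability from the current $(v, w, f)$ → fluxes → indicators → targets
→ derivatives.

**Stimulation.** The pipette drives
$i_s = (V_s - V_m)/(R_s S)$ (the printed form of the electrode relation
is dimensionally inconsistent; division by the surface area $S$ is the
only reading that yields a current density, and it reproduces realistic
series-resistance clamp lag). Voltage clamp is implemented through this
physical feedback, never by algebraically pinning $V_m$. The Ag/AgCl
redox reaction carries the whole stimulation current as chloride flux,
$j_{s,\mathrm{Cl}} = -i_s/F$, which closes the charge bookkeeping:
$dQ/dt = F\sum z_i u_i$ including the electrode term.

**Resting state.** A membrane rests when every channel senses its
optimum. `find_resting_state()` root-finds the net charge $Q^*$ at which
$V_m$ equals the requested resting potential ($V_m(Q)$ is strictly
increasing), realizes $Q^*$ by adjusting the impermeant internal anion by
a few µM, and sets $\bar\sigma_h = \sum_i s_{h,i} T_{\mathrm{in},i}(Q^*)$
with $v = 0$, $w = 1/2$, $f = 1$. All gate drives then vanish, which the
tests verify both analytically and by clamping a resting cell for 50 ms.

## Parameters and calibration

Physical constants are CODATA; the default temperature is 290 K, the
default relative membrane permittivity 4 (plausible range roughly
1.4–20), the default radius 10 µm.

**Effective diameters λ.** These are the model's only coupling between
charge and potential scale, and no measured values exist for the
"effective adsorption layer" they describe; they are calibration
constants. They were set once so that the committed standard solutions
give a mean membrane capacitance $C_m = dQ/dV_m \approx 1\,\mu F/cm^2$
over $V_m \in (-100, 100)$ mV at $\varepsilon_r = 4$ — the canonical
measured value — yielding 1.40 nm (K⁺, Cl⁻, A⁻), 1.39 nm (Cs⁺), 1.00 nm
(Na⁺) and 0.30 nm (Ca²⁺). Two deliberate asymmetries: $\lambda_{Na}$ is
kept below the K/Cl scale so the sodium driving force does not collapse
at depolarized potentials (the step-family peak then falls just below
0 mV, as in classical sodium current families), and $\lambda_{Ca} z_{Ca}$ is
kept below the monovalent scale so the divalent does not hit the
$|X| \ge 1$ overload inside the ±120 mV protocols.

**Solutions.** The recipes are standard electrophysiology compositions
committed as fixtures: a mammalian-style bath (Na 145, K 1, Ca 2, Cl 150
mM) and K-rich pipette (K 140, Na 10, Cl 20, A 130 mM); a plant pipette
(K 100, Cl 30, A 70) with K-rich (K 100, Cl 100) and Cs-substituted
baths; and an oocyte pair with internal Ca²⁺ imposed by a virtual
Ca-EGTA clamp (`with_internal_ca()` holds [Ca²⁺]in constant and
charge-compensates, and the engine excludes buffered-ion flux from the
charge balance, mirroring the buffering). Bath K⁺ is 1 mM — a nominally
low-K saline — because the density-ratio potential map compresses
Nernst-type reversals: at 5 mM bath K⁺ the model's K⁺ flux reversal sits
near −53 mV, *above* the −70 mV rest, no current can then repolarize
below rest, and sodium never de-inactivates (DC stimulation gives a
single spike and a stable plateau). At 1 mM the K⁺ reversal is ≈ −91 mV,
restoring the physiological ordering $E_K < V_{rest}$ that sustained
spiking requires.

**Channel parameters.** No published values exist for
$s, \varrho, \bar\sigma, \tau, \alpha, \beta, \gamma, \delta, \kappa$ —
only qualitative orderings. The committed sets were calibrated once
against the behaviour each channel must show and then frozen; the
orderings hold: the sodium channel has $\alpha/\beta = 6 > 0.1$ (the
exploring gate opens very fast relative to judgement); the transient
outward channel (Kv4.3-like) gates much faster than its filter
inactivates ($\beta \gg \alpha$, moderate $\gamma$, $\kappa = 2$); the
hERG-like delayed rectifier has slow activation and a strong fast filter
($\kappa = 20 \gg$ the activation scale), which is what produces tail
currents on repolarization and instant inward currents at −150 mV
(the K⁺ reversal lies above −150 mV, so the briefly re-conducting
channel passes *inward* K⁺). Two parameters deserve comment:

* $\tau_K = 50$ ms makes the delayed rectifier's judging variable a slow
  relaxation variable — it builds toward 1 while efflux is restoring the
  optimum above rest and collapses below rest — which, with
  $E_K < V_{rest}$, creates the limit cycle behind periodic spiking and
  bursting. $\eta = 1$ everywhere.
* The CACC is sensitive to Ca²⁺ but permeant to Cl⁻, *plus* a small Ca²⁺
  permeability ($\varrho_{Ca} = 20$/s against $\varrho_{Cl} = 100$/s).
  Without any sensed Ca²⁺ flux the judging variable would sit at 1/2 and
  a low-Ca²⁺ cell would conduct; the small Ca²⁺ efflux is what the
  sensor uses to keep the gate shut when $\sigma \ll \bar\sigma$, which
  is the published low-Ca²⁺ phenomenology. Its $\bar\sigma$ is
  calibrated at the 600 nM reference level and reused across levels.

## What the fixtures do and do not emulate

The experiment registry (`list_experiments()`, figures 1–15) reproduces
protocol *families* and asserts qualitative, machine-checkable
properties: monotonicities (peak vs step, recovery vs interval, tail vs
depolarization), abolition ratios (Cs⁺ substitution), silence thresholds
(CACC at 70 nM), overshoots (anode break), and spiking/bursting
statistics (mean crossings, spike clustering in depolarizing
half-cycles, inter-spike-interval bimodality). They do not reproduce
published figure curves point-by-point — the published parameterizations
are not available — so a passing suite shows the mechanism produces the
right phenomenology under these committed conditions, not that any real
cell's trace is matched. Pumps are absent, so ion loading from long
protocols is never cleared; the paired-pulse recovery protocol keeps its
conditioning pulse short for exactly this reason. The sodium step-family
monotonicity is asserted from threshold up to +10 mV; above the I–V peak
the driving force vanishes toward the reversal and the peak current
declines, as in real families. The CACC Ca²⁺-monotonicity is asserted on
the depolarized limb plus dominance of 2 µM over 600 nM at both
extremes; intermediate-Ca²⁺ hyperpolarized currents are near zero and
unordered (outward rectification).

## Numerical choices

* Integrator: `deSolve::lsoda` (automatic stiff/non-stiff switching);
  the judging dynamics and the 30 µs clamp feedback make the system
  stiff. Defaults `rtol = 1e-6`, `atol = 1e-9`; a refinement test checks
  the terminal potential moves < 0.1 mV when both are halved.
* Integration is split at protocol segment boundaries so discontinuities
  are never stepped across; within a segment the protocol is evaluated
  at the clamped time so solver trial steps cannot leave the segment.
* Gate variables are analytically forward-invariant in
  $[0,1]$/$(0,1]$; accepted samples are clipped for round-off and drift
  beyond $10^{-6}$ warns.
* The double-layer oracle (`double_layer_oracle()`, tests only) solves
  the zero-flux profile $d\ln c_i/dx = E(x)Fz_i/RT$ with the field from
  the spherical Gauss integral of the *bulk* charge profile — the model's
  own premise is that the diffuse layer stays at bulk while the net
  charge sits adsorbed at the wall. A self-consistent Poisson–Boltzmann
  treatment at membrane permittivity would screen the field within
  picometers and is outside the model's regime. Profiles are normalized
  to bulk at the far edge of each ion's window; windowed integrals give
  the oracle densities, which agree with the closed forms to within a
  few percent for $|X| \le 0.05$.
* Capacitance: uniform $V_m$ grid, per-point root-find of $Q$
  (`uniroot` to near machine precision), centered differences. The
  curve's asymmetry about 0 mV arises because $dV_m/dQ$ is smallest at
  $Q = 0$, which maps to the weighted quasi-Nernst potential (≈ +20 mV
  for the standard solutions), not to 0 mV.

## Problem sizes

Default test and experiment runs use 0.2 ms sampling, protocols of
40 ms–1 s, step families of 4–6 levels and the 20-case oracle comparison
at 400 grid points per side — sizes chosen so the whole suite exercises
every experiment end-to-end while remaining routine on a laptop.

## Known limitations

* No pumps: concentrations drift under sustained flux and never recover;
  resting states are fixed points only because all channels are shut.
* The scalar $V_m$ weighting is a modeling convention; observables that
  depend on the per-ion potential vector should use
  `membrane_potential(..., components = TRUE)`.
* The linearized double layer fails at $|X| \ge 1$; protocols beyond
  roughly ±200 mV from the weighted quasi-Nernst point are out of range.
* Spatial structure (cables, dendrites, local patches), stochastic
  single-channel gating and ligand kinetics beyond the linear sensor are
  out of scope.
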