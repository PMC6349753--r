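# membraneflux

Deterministic whole-cell simulation of passive transmembrane ion transport
driven by ionic concentrations, for computational electrophysiologists who
want one gating formalism to span plant root cells, oocytes,
cardiomyocytes and neurons.

Conductance-based models treat the cell as a capacitor and make the
membrane potential the state variable. `membraneflux` inverts that
picture: the state is the set of average internal ion concentrations
[i]<sub>in</sub>, and the membrane potential is a *readout* of the ion
densities adsorbed on the two membrane surfaces. For a spherical cell of
radius r, the per-area amount of ion i inside is q<sub>i</sub> =
(r/3)[i]<sub>in</sub> and the net internal charge is Q = F Σ z<sub>i</sub>
q<sub>i</sub>. Borrowing from electrical double-layer theory, the
surface densities within one effective ion diameter λ<sub>i</sub> of the
membrane are

    T_in,i = λ_i [i]_in (1 + X_i)/(1 − X_i),
    T_ex,i = λ_i [i]_ex (1 − X_i)/(1 + X_i),
    X_i    = χ (Q/F) λ_i z_i,    χ = F² / (2 R T ε_m),

and the membrane potential is the concentration-weighted mean of the
per-ion values V<sub>i</sub> = (RT / F z<sub>i</sub>) ln(T<sub>in,i</sub>
/ T<sub>ex,i</sub>). Ion channels are a **sensor** (a linear readout σ =
Σ s<sub>i</sub> T<sub>in,i</sub> of the inner surface and ψ = Σ
s<sub>i</sub> ζ<sub>i</sub> of their own flux), a two-part **gate** (an
exploring variable v drawn open by the deviation indicator ϑ =
2 atan(σ/σ̄) − π/2, and a judging variable w that keeps the gate open only
when the flux restores the optimum, w̄ = acot(ϕ/ϑ)/π), and a selectivity
**filter** f that inactivates under sustained stimulation, f̄ =
exp(−κ ϕ<sup>2m</sup> ϑ<sup>2n</sup>). Channel flux is ζ<sub>i</sub> =
−f<sub>i</sub> v w ϱ<sub>i</sub> (T<sub>in,i</sub> − T<sub>ex,i</sub>),
and an Ag/AgCl electrode converts stimulation current into chloride flux,
j<sub>s,Cl</sub> = −i<sub>s</sub>/F. Everything integrates as one stiff
ODE system (deSolve).

## Worked example

```r
library(membraneflux)

# standard solutions + Nav/Kv/Clv channel set, calibrated to rest at -70 mV
rest <- neuron_model()
sprintf("resting Vm: %.1f mV, net charge Q*: %.3e C/m^2", 1e3 * rest$Vm, rest$Q)
#> "resting Vm: -70.0 mV, net charge Q*: -9.465e-04 C/m^2"

# voltage-clamp step from -70 mV to +10 mV through a 2.4 MOhm pipette
prot <- voltage_clamp(data.frame(t0 = c(-0.01, 0), t1 = c(0, 0.04),
                                 Vs = c(-0.070, 0.010)), Rs = 2.4e6)
tr <- simulate_protocol(rest$model, rest$y0, prot, sim_config(sample_dt = 2e-4))
sprintf("peak inward current: %.2f A/m^2 at t = %.1f ms", min(tr$I), 1e3 * tr$t[which.min(tr$I)])
#> "peak inward current: -2.78 A/m^2 at t = 0.4 ms"
sprintf("current at end of step: %.2f A/m^2", tr$I[nrow(tr)])
#> "current at end of step: 5.77 A/m^2"
```

The negative peak is the transient sodium influx (the judging gate closes
as the channel senses its own inward flux deepening the density
deviation — inactivation without a separate inactivation particle); the
positive late current is the delayed-rectifier potassium efflux.

Membrane capacitance falls out of the statics alone:

```r
sol <- fixture_solutions()
m <- cell_model(internal = sol$pipette_standard, bath = sol$bath_standard)
cm <- estimate_capacitance(m, c(-0.1, 0.1), 81)
sprintf("mean Cm: %.2f uF/cm^2", mean(cm$Cm_uFcm2))
#> "mean Cm: 1.02 uF/cm^2"
```

Fifteen runnable experiments with machine-checkable assertions (plant
root K⁺ currents and their Cs⁺ block, Na⁺ refractory recovery, transient
outward K⁺, hERG-like tail currents, calcium-activated chloride currents,
anode-break excitation, periodic spiking, bursting) live in a registry:

```r
list_experiments()
run_experiment("fig13")   # DC current clamp, periodic spiking
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/membraneflux.R simulate -c inst/extdata/sodium_step.yaml -o out/
Rscript inst/cli/membraneflux.R figure fig2 --out out/
Rscript inst/cli/membraneflux.R list-figures
```

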