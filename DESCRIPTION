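Package: membraneflux
Title: Ionic-Concentration-Based Simulation of Passive Transmembrane Ion Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic whole-cell simulator of passive transmembrane ion
    transport driven by ionic concentrations rather than by an equivalent
    electrical circuit. Membrane-surface ion densities are estimated from bulk
    averages and the cell's net internal charge through a linearized electrical
    double-layer approximation; the membrane potential is a density-ratio
    readout, and ion channels are modelled as a sensor (detected inner-surface
    density and flux), a two-part gate (exploring and judging variables), and a
    selectivity filter subject to occupancy-driven inactivation. Includes an
    Ag/AgCl electrode stimulation model, voltage- and current-clamp protocol
    simulation with a stiff ODE integrator, membrane capacitance estimation,
    and a registry of runnable experiments (plant root K+ channel, Na+
    refractory period, transient outward K+, delayed-rectifier tail currents,
    calcium-activated chloride currents, spiking and bursting) with
    machine-checkable qualitative assertions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
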