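# Minimal model: one permeant ion pair, no channels, short flat trace.
schema_version: 1
cell: {radius_um: 10, eps_r: 4, temperature_K: 290}
solutions:
  internal: {K: 100, Cl: 100}
  bath: {K: 100, Cl: 100}
protocol:
  mode: current
  segments:
    - {t0_ms: 0, t1_ms: 10, Is_Am2: 0}
sim: {sample_dt_ms: 1}
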