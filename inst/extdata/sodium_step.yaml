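# Sodium-channel voltage step: standard solutions, Nav/Kv/Clv channel set,
# hold -70 mV then step to +30 mV (the committed fixture parameters).
schema_version: 1
cell: {radius_um: 10, eps_r: 4, temperature_K: 290}
solutions:
  internal: {K: 140, Na: 10, Cl: 20, A: 130}
  bath: {Na: 145, K: 1, Ca: 2, Cl: 150}
rest_Vm_mV: -70
channels:
  - name: Nav
    s: {Na: 1}
    rho0: {Na: 1500}
    tau_ms: 2
    alpha: 6000
    beta: 1000
    gamma: 1
    delta: 0.05
  - name: Kv
    s: {K: 1}
    rho0: {K: 1000}
    tau_ms: 50
    alpha: 200
    beta: 300
    gamma: 1
    delta: 0.30
  - name: Clv
    s: {Cl: 1}
    rho0: {Cl: 10}
    tau_ms: 1
    alpha: 150
    beta: 1000
    gamma: 1
    delta: 0.1
protocol:
  mode: voltage
  Rs_MOhm: 2.4
  segments:
    - {t0_ms: -10, t1_ms: 0, Vs_mV: -70}
    - {t0_ms: 0, t1_ms: 40, Vs_mV: 30}
sim: {rtol: 1.0e-6, atol: 1.0e-9, sample_dt_ms: 0.2}
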