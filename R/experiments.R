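#' @title Experiment registry
#' @description Runnable whole-cell experiments with machine-checkable
#'   qualitative assertions, built from the committed solution and channel
#'   fixtures. Each experiment is keyed by a figure tag (`fig1` ... `fig15`)
#'   and reproduces one published-style protocol family: capacitance sweep,
#'   plant-root K+ currents with Cs+ substitution, Na+ activation and
#'   refractory recovery, transient outward K+ activation and recovery,
#'   delayed-rectifier (hERG-like) tail currents, CACC current-voltage
#'   families under buffered Ca2+, anode-break excitation, DC-driven
#'   periodic spiking and AC-driven bursting.
#' @name experiments
NULL

chk <- function(name, pass, detail = "") {
  data.frame(check = name, pass = pass, detail = detail,
             stringsAsFactors = FALSE)
}

# Spike detection: upward crossings of a fixed threshold (default -30 mV),
# well above any subthreshold standoff.
spike_times <- function(trace, threshold = -0.03) {
  trace$t[which(diff(trace$Vm > threshold) == 1)]
}

#' Assemble the standard neuron model at rest
#'
#' Standard pipette and bath solutions with the Nav/Kv/Clv channel set,
#' calibrated to rest at -70 mV.
#'
#' @param tab Ion table.
#' @return The result of [find_resting_state()] (fields `model`, `y0`, `Q`,
#'   `Vm`).
#' @export
neuron_model <- function(tab = default_ions()) {
  sol <- fixture_solutions(tab)
  chs <- fixture_channels(tab)
  m <- cell_model(internal = sol$pipette_standard, bath = sol$bath_standard,
                  channels = chs[c("Nav", "Kv", "Clv")], tab = tab)
  find_resting_state(m, -0.070)
}

#' hERG tail-current sweep
#'
#' Depolarizing steps of varying level (300 ms, return to -50 mV) or varying
#' duration (50 mV, return to -150 mV), recording the peak tail current
#' after repolarization.
#'
#' @param mode `"level"` (vary step level) or `"duration"` (vary step
#'   length).
#' @param levels Step potentials, V (mode `"level"`).
#' @param durations Step durations, s (mode `"duration"`).
#' @param cfg Simulation configuration.
#' @param tab Ion table.
#' @return Data frame with the swept variable and the tail peak (A/m^2;
#'   outward max for mode `"level"`, inward min for mode `"duration"`).
#' @export
sweep_tail_currents <- function(mode = c("level", "duration"),
                                levels = c(-0.05, -0.02, 0.01, 0.04, 0.07),
                                durations = c(0.05, 0.1, 0.2, 0.4),
                                cfg = sim_config(sample_dt = 2e-4),
                                tab = default_ions()) {
  mode <- match.arg(mode)
  sol <- fixture_solutions(tab)
  m <- cell_model(internal = sol$pipette_standard, bath = sol$bath_standard,
                  channels = fixture_channels(tab)["hERG"], tab = tab)
  r <- find_resting_state(m, -0.070)
  last_trace <- NULL
  if (mode == "level") {
    out <- lapply(levels, function(vs) {
      p <- voltage_clamp(data.frame(t0 = c(-0.01, 0, 0.3),
                                    t1 = c(0, 0.3, 0.5),
                                    Vs = c(-0.07, vs, -0.05)), Rs = 2.4e6)
      tr <- simulate_protocol(r$model, r$y0, p, cfg)
      last_trace <<- tr
      data.frame(level = vs,
                 I_step_end = tr$I[which.min(abs(tr$t - 0.3))],
                 tail_peak = max(tr$I[tr$t > 0.3]))
    })
  } else {
    out <- lapply(durations, function(dt) {
      p <- voltage_clamp(data.frame(t0 = c(-0.01, 0, dt),
                                    t1 = c(0, dt, dt + 0.15),
                                    Vs = c(-0.07, 0.05, -0.15)), Rs = 2.4e6)
      tr <- simulate_protocol(r$model, r$y0, p, cfg)
      last_trace <<- tr
      data.frame(duration = dt, tail_peak = min(tr$I[tr$t > dt]))
    })
  }
  out <- do.call(rbind, out)
  attr(out, "trace") <- last_trace
  out
}

#' CACC steady-state current-voltage family
#'
#' Oocyte solutions, CACC channel, internal Ca2+ clamped by a virtual
#' Ca-EGTA buffer at each level; the optimum density is calibrated once at
#' the 600 nM reference and reused, so the channel's sensed deviation tracks
#' the imposed Ca2+. Currents are recorded at the end of a 0.9 s step from
#' the 0 mV holding potential.
#'
#' @param ca_levels Internal Ca2+ levels, mol/m^3 (defaults 70 nM, 600 nM,
#'   1 uM, 2 uM).
#' @param steps Step potentials, V.
#' @param cfg Simulation configuration.
#' @param tab Ion table.
#' @return Data frame with columns `ca`, `Vs`, `I` (A/m^2 at t = 1 s).
#' @export
cacc_iv_family <- function(ca_levels = c(7e-5, 6e-4, 1e-3, 2e-3),
                           steps = c(-0.12, -0.06, 0.06, 0.12),
                           cfg = sim_config(sample_dt = 5e-4),
                           tab = default_ions()) {
  sol <- fixture_solutions(tab)
  mk <- function(ca, sigma_bar = NA) {
    chs <- fixture_channels(tab)["CACC"]
    chs$CACC$sigma_bar <- sigma_bar
    m <- cell_model(internal = with_internal_ca(sol$pipette_oocyte, ca,
                                                tab = tab),
                    bath = sol$bath_oocyte, channels = chs,
                    buffered = "Ca", tab = tab)
    find_resting_state(m, 0, balance_ion = "A", calibrate = is.na(sigma_bar))
  }
  ref <- mk(6e-4)
  sb <- ref$model$channels$CACC$sigma_bar
  rows <- list(); last_trace <- NULL
  for (ca in ca_levels) {
    r <- mk(ca, sigma_bar = sb)
    for (vs in steps) {
      p <- voltage_clamp(data.frame(t0 = c(-0.1, 0), t1 = c(0, 0.9),
                                    Vs = c(0, vs)), Rs = 4.0e6)
      tr <- simulate_protocol(r$model, r$y0, p, cfg)
      last_trace <- tr
      rows[[length(rows) + 1]] <- data.frame(ca = ca, Vs = vs,
                                             I = tr$I[nrow(tr)])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "trace") <- last_trace
  out
}

#' List registered experiments
#' @return Data frame with experiment names and descriptions.
#' @export
list_experiments <- function() {
  data.frame(
    name = names(experiment_registry),
    description = vapply(experiment_registry, `[[`, "", "description"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a registered experiment
#'
#' Runs the protocol (or protocol family) of one registered experiment,
#' evaluates its qualitative assertions against the produced traces, and
#' returns traces, summary tables and a pass/fail report.
#'
#' @param name Experiment tag (see [list_experiments()]).
#' @param cfg Simulation configuration (default sampling 0.2 ms).
#' @return List of class `"mf_experiment"` with elements `name`, `traces`
#'   (named list of `membrane_trace`s), `tables` (summary data frames) and
#'   `assertions` (data frame with columns `check`, `pass`, `detail`).
#' @export
run_experiment <- function(name, cfg = sim_config(sample_dt = 2e-4)) {
  if (!name %in% names(experiment_registry))
    stop("unknown experiment '", name, "'; see list_experiments()")
  res <- experiment_registry[[name]]$run(cfg)
  res$name <- name
  class(res) <- "mf_experiment"
  res
}

#' @export
print.mf_experiment <- function(x, ...) {
  cat("Experiment", x$name, "-",
      experiment_registry[[x$name]]$description, "\n")
  a <- x$assertions
  for (i in seq_len(nrow(a)))
    cat(sprintf("  [%s] %s %s\n", if (a$pass[i]) "PASS" else "FAIL",
                a$check[i], a$detail[i]))
  invisible(x)
}

mono_up <- function(x, tol = 0) all(diff(x) >= -tol * max(abs(x)))

run_fig1 <- function(cfg) {
  sol <- fixture_solutions()
  m <- cell_model(internal = sol$pipette_standard, bath = sol$bath_standard)
  cm <- estimate_capacitance(m, c(-0.1, 0.1), 81)
  mean_cm <- mean(cm$Cm_uFcm2)
  lo <- cm$Cm_uFcm2[cm$Vm == -0.05]
  hi <- cm$Cm_uFcm2[abs(cm$Vm - 0.05) < 1e-9]
  list(traces = list(), tables = list(capacitance = cm),
       assertions = rbind(
         chk("mean Cm in 0.5-2 uF/cm2", mean_cm > 0.5 && mean_cm < 2,
             sprintf("mean = %.3f", mean_cm)),
         chk("Cm(Vm) asymmetric about 0 mV",
             abs(hi - lo) / mean_cm > 0.05,
             sprintf("Cm(-50) = %.3f, Cm(+50) = %.3f", lo, hi))))
}

run_fig2 <- function(cfg) {
  sol <- fixture_solutions()
  chs <- fixture_channels()
  traces <- list(); iv <- list()
  steps <- c(-0.2, -0.12, 0.12)
  for (bath in c("bath_high_K", "bath_high_Cs")) {
    m <- cell_model(internal = sol$pipette_plant, bath = sol[[bath]],
                    channels = chs["Kv_plant"])
    r <- find_resting_state(m, -0.040)
    iv[[bath]] <- vapply(steps, function(vs) {
      p <- voltage_clamp(data.frame(t0 = c(-0.01, 0), t1 = c(0, 1),
                                    Vs = c(-0.04, vs)), Rs = 2.4e6)
      tr <- simulate_protocol(r$model, r$y0, p, cfg)
      traces[[paste0(bath, "_", round(1e3 * vs))]] <<- tr
      tr$I[nrow(tr)]
    }, 0)
  }
  ratio <- abs(iv$bath_high_K[1] / iv$bath_high_Cs[1])
  list(traces = traces,
       tables = list(iv = data.frame(Vs = steps, I_K = iv$bath_high_K,
                                     I_Cs = iv$bath_high_Cs)),
       assertions = rbind(
         chk("hyperpolarization in K-rich bath gives sustained inward current",
             iv$bath_high_K[1] < -1,
             sprintf("I(1s, -200 mV) = %.2f A/m2", iv$bath_high_K[1])),
         chk("Cs+ substitution abolishes the inward current (ratio > 10)",
             ratio > 10, sprintf("|I_K/I_Cs| = %.0f", ratio))))
}

run_fig3 <- function(cfg) {
  r <- neuron_model()
  steps <- c(-0.07, -0.05, -0.03, -0.01, 0.01, 0.03)
  traces <- list(); pk <- en <- numeric(length(steps))
  for (i in seq_along(steps)) {
    p <- voltage_clamp(data.frame(t0 = c(-0.01, 0), t1 = c(0, 0.04),
                                  Vs = c(-0.07, steps[i])), Rs = 2.4e6)
    tr <- simulate_protocol(r$model, r$y0, p, cfg)
    traces[[sprintf("step_%d", round(1e3 * steps[i]))]] <- tr
    post <- tr[tr$t > 0, ]
    pk[i] <- max(post$zeta.Nav.Na)
    en[i] <- post$zeta.Nav.Na[nrow(post)]
  }
  upper <- steps >= -0.05 & steps <= -0.01  # threshold to I-V peak
  list(traces = traces,
       tables = list(family = data.frame(Vs = steps, peak_influx = pk,
                                         end_influx = en)),
       assertions = rbind(
         chk("peak Na influx non-decreasing with step (-50..-10 mV)",
             mono_up(pk[upper]),
             paste(sprintf("%.2e", pk[upper]), collapse = " ")),
         chk("Na current transient (end < 30% of peak)",
             all(en[pk > 1e-7] / pk[pk > 1e-7] < 0.3),
             paste(sprintf("%.2f", en[pk > 1e-7] / pk[pk > 1e-7]),
                   collapse = " "))))
}

run_fig4 <- function(cfg) {
  r <- neuron_model()
  dts <- c(0.002, 0.008, 0.015, 0.025)
  last_trace <- NULL
  ratio <- vapply(dts, function(dt) {
    p <- voltage_clamp(data.frame(
      t0 = c(-0.005, 0, 0.03, 0.03 + dt),
      t1 = c(0, 0.03, 0.03 + dt, 0.06 + dt),
      Vs = c(-0.07, 0.03, -0.07, 0.03)), Rs = 2.4e6)
    tr <- simulate_protocol(r$model, r$y0, p, cfg)
    last_trace <<- tr
    max(tr$zeta.Nav.Na[tr$t > 0.03 + dt]) /
      max(tr$zeta.Nav.Na[tr$t > 0 & tr$t <= 0.03])
  }, 0)
  list(traces = list(paired_pulse = last_trace),
       tables = list(recovery = data.frame(dt = dts, ratio = ratio)),
       assertions = chk(
         "paired-pulse recovery ratio non-decreasing in interval",
         mono_up(ratio), paste(sprintf("%.3f", ratio), collapse = " ")))
}

run_fig5 <- function(cfg) {
  sol <- fixture_solutions()
  m <- cell_model(internal = sol$pipette_standard, bath = sol$bath_standard,
                  channels = fixture_channels()["Kv43"])
  r <- find_resting_state(m, -0.070)
  steps <- c(-0.1, -0.06, -0.02, 0.01, 0.04)
  traces <- list(); pk <- en <- numeric(length(steps))
  for (i in seq_along(steps)) {
    p <- voltage_clamp(data.frame(t0 = c(-0.01, 0), t1 = c(0, 0.3),
                                  Vs = c(-0.07, steps[i])), Rs = 2.4e6)
    tr <- simulate_protocol(r$model, r$y0, p, cfg)
    traces[[sprintf("step_%d", round(1e3 * steps[i]))]] <- tr
    pk[i] <- max(tr$I[tr$t > 0]); en[i] <- tr$I[nrow(tr)]
  }
  list(traces = traces,
       tables = list(family = data.frame(Vs = steps, peak = pk, end = en)),
       assertions = rbind(
         chk("outward K peak non-decreasing in depolarization", mono_up(pk),
             paste(sprintf("%.2f", pk), collapse = " ")),
         chk("transient: current decays after peak at strong steps",
             en[length(en)] < 0.5 * pk[length(pk)],
             sprintf("end/peak = %.2f", en[length(en)] / pk[length(pk)]))))
}

run_fig6 <- function(cfg) {
  sol <- fixture_solutions()
  m <- cell_model(internal = sol$pipette_standard, bath = sol$bath_standard,
                  channels = fixture_channels()["Kv43"])
  r <- find_resting_state(m, -0.070)
  dts <- c(0.01, 0.05, 0.1, 0.2)
  last_trace <- NULL
  ratio <- vapply(dts, function(dt) {
    p <- voltage_clamp(data.frame(
      t0 = c(-0.01, 0, 0.3, 0.3 + dt),
      t1 = c(0, 0.3, 0.3 + dt, 0.5 + dt),
      Vs = c(-0.07, 0.05, -0.07, 0.05)), Rs = 2.4e6)
    tr <- simulate_protocol(r$model, r$y0, p, cfg)
    last_trace <<- tr
    max(tr$I[tr$t > 0.3 + dt]) / max(tr$I[tr$t > 0 & tr$t <= 0.3])
  }, 0)
  list(traces = list(recovery = last_trace),
       tables = list(recovery = data.frame(dt = dts, ratio = ratio)),
       assertions = chk(
         "inactivation recovery non-decreasing in interval",
         mono_up(ratio, tol = 0.02),
         paste(sprintf("%.3f", ratio), collapse = " ")))
}

run_fig7 <- function(cfg) {
  tab7 <- sweep_tail_currents("level", cfg = cfg)
  list(traces = list(tail = attr(tab7, "trace")),
       tables = list(tails = tab7),
       assertions = rbind(
         chk("tail peak non-decreasing in prior depolarization level",
             mono_up(tab7$tail_peak),
             paste(sprintf("%.3f", tab7$tail_peak), collapse = " ")),
         chk("step-end current limited (delayed rectification)",
             mono_up(tab7$I_step_end, tol = 0.02),
             paste(sprintf("%.3f", tab7$I_step_end), collapse = " "))))
}

run_fig8 <- function(cfg) {
  tab8 <- sweep_tail_currents("duration", cfg = cfg)
  list(traces = list(tail = attr(tab8, "trace")),
       tables = list(tails = tab8),
       assertions = chk(
         "instant inward current magnitude non-decreasing in duration",
         mono_up(-tab8$tail_peak),
         paste(sprintf("%.3f", tab8$tail_peak), collapse = " ")))
}

run_fig9 <- function(cfg) {
  iv <- cacc_iv_family(cfg = cfg)
  silent <- max(abs(iv$I[iv$ca == 7e-5]))
  strong <- max(abs(iv$I[iv$ca == 2e-3]))
  dep <- iv[iv$Vs > 0, ]
  mono_dep <- all(vapply(unique(dep$Vs), function(v) {
    x <- dep$I[dep$Vs == v][dep$ca[dep$Vs == v] >= 6e-4]
    mono_up(abs(x))
  }, TRUE))
  dom <- all(abs(iv$I[iv$ca == 2e-3 & abs(iv$Vs) == 0.12]) >=
               abs(iv$I[iv$ca == 6e-4 & abs(iv$Vs) == 0.12]))
  list(traces = list(cacc = attr(iv, "trace")), tables = list(iv = iv),
       assertions = rbind(
         chk("CACC ~silent at 70 nM Ca (max |I| < 5% of 2 uM)",
             silent < 0.05 * strong,
             sprintf("%.3f vs %.3f A/m2", silent, strong)),
         chk("depolarized-limb |I| non-decreasing through 600 nM..2 uM",
             mono_dep, ""),
         chk("2 uM curve dominates 600 nM at extreme Vs", dom, "")))
}

run_fig11 <- function(cfg) {
  r <- neuron_model()
  p <- current_clamp(data.frame(t0 = c(-0.05, 0), t1 = c(0, 0.1),
                                kind = "const", value = c(-0.75, 0)))
  tr <- simulate_protocol(r$model, r$y0, p, cfg)
  ov <- max(tr$Vm[tr$t > 0]) - r$Vm
  list(traces = list(anode_break = tr), tables = list(),
       assertions = chk("anode-break overshoot exceeds rest by > 20 mV",
                        ov > 0.02, sprintf("overshoot = %.1f mV", 1e3 * ov)))
}

run_fig13 <- function(cfg) {
  r <- neuron_model()
  p <- current_clamp(data.frame(t0 = 0, t1 = 0.5, kind = "const",
                                value = 0.1))
  tr <- simulate_protocol(r$model, r$y0, p, cfg)
  vm <- tr$Vm[tr$t > 0]
  ncross <- sum(diff(vm > mean(vm)) != 0)
  nspk <- length(spike_times(tr[tr$t > 0, ]))
  list(traces = list(spiking = tr), tables = list(),
       assertions = rbind(
         chk("Vm crosses its mean at least 6 times (periodic spiking)",
             ncross >= 6, sprintf("%d crossings", ncross)),
         chk("at least 6 spikes above -30 mV", nspk >= 6,
             sprintf("%d spikes", nspk))))
}

run_fig15 <- function(cfg) {
  r <- neuron_model()
  p <- current_clamp(data.frame(t0 = 0, t1 = 1, kind = "sin", value = NA,
                                amp = 0.2, omega = 20 * pi))
  tr <- simulate_protocol(r$model, r$y0, p, cfg)
  st <- spike_times(tr[tr$t > 0, ])
  isi <- diff(st)
  frac <- mean(sin(20 * pi * st) > 0)
  list(traces = list(bursting = tr), tables = list(),
       assertions = rbind(
         chk("spikes cluster in depolarizing half-cycles (>80%)",
             length(st) >= 4 && frac > 0.8,
             sprintf("%d spikes, %.0f%% in depolarizing phase",
                     length(st), 100 * frac)),
         chk("inter-spike intervals bimodal (max > 2x median)",
             length(isi) >= 3 && max(isi) > 2 * stats::median(isi),
             sprintf("median %.1f ms, max %.1f ms",
                     1e3 * stats::median(isi), 1e3 * max(isi)))))
}

experiment_registry <- list(
  fig1 = list(description = "Membrane capacitance vs potential, channels closed",
              run = run_fig1),
  fig2 = list(description = "Plant root K+ channel: K-rich vs Cs-substituted bath",
              run = run_fig2),
  fig3 = list(description = "Na+ channel activation/inactivation step family",
              run = run_fig3),
  fig4 = list(description = "Na+ refractory period: paired-pulse recovery",
              run = run_fig4),
  fig5 = list(description = "Transient outward K+ (Kv4.3-like) step family",
              run = run_fig5),
  fig6 = list(description = "Transient outward K+ recovery from inactivation",
              run = run_fig6),
  fig7 = list(description = "hERG-like tail currents vs depolarization level",
              run = run_fig7),
  fig8 = list(description = "hERG-like instant inward current vs depolarization duration",
              run = run_fig8),
  fig9 = list(description = "CACC activation under buffered internal Ca2+",
              run = run_fig9),
  fig10 = list(description = "CACC steady-state I-V family over Ca2+ levels",
               run = run_fig9),
  fig11 = list(description = "Anode-break excitation after sustained hyperpolarizing current",
               run = run_fig11),
  fig12 = list(description = "Transmembrane fluxes during anode-break excitation",
               run = run_fig11),
  fig13 = list(description = "Periodic spiking under DC current clamp",
               run = run_fig13),
  fig14 = list(description = "Transmembrane fluxes during periodic spiking",
               run = run_fig13),
  fig15 = list(description = "Bursting under sinusoidal current clamp",
               run = run_fig15)
)
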