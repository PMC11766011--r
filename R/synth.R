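# Synthetic whole-cell Nav currents from a known gating truth, under the four
# voltage protocols of the study design: IV, steady-state inactivation (SSI,
# 500 ms prepulse), fast inactivation (20 ms prepulse) and two-pulse recovery.
#
# Generative model (single activation gate, exponent 1, so the steady-state
# conductance-voltage relation is exactly the Boltzmann the analysis fits):
#   I(t) = g_max * (V - v_rev) * m(t) * h(t) + Gaussian noise
#   m(t) = m_inf(V) + (m0 - m_inf(V)) * exp(-t / tau_m(V))
#   h(t) = h_inf(V) + (h0 - h_inf(V)) * exp(-t / tau_h(V))
#   m_inf(V) = 1 / (1 + exp((act_v_half - V) / act_k))          (activation)
#   h_inf(V) = 1 / (1 + exp((V - inact_v_half) / inact_k))      (availability)
# Recovery from inactivation is generated from an explicit two-population
# mixture, 1 - A_fast*exp(-dt/tau_fast) - (1-A_fast)*exp(-dt/tau_slow),
# because a single h gate cannot produce two time constants.

default_tau_m <- function(v) 0.15 + 2.0 * exp(-((v + 45) / 15)^2)

# Fast component proportional to tau_m (voltage-independent peak attenuation of
# m*h at test potentials => the extracted G-V equals the generating Boltzmann)
# plus a slow hyperpolarized component that separates the 20 ms and 500 ms
# prepulse availability curves; the slow lobe is kept below -80 mV so it does
# not leak into either preset's activation range. See the methods vignette.
default_tau_h <- function(v) 10 * default_tau_m(v) + 40 * exp(-((v + 95) / 12)^2)

#' Gating truth for the synthetic current generator
#'
#' @param g_max maximal conductance, nS.
#' @param v_rev reversal potential, mV.
#' @param act_v_half,act_k activation Boltzmann parameters, mV (k > 0).
#' @param inact_v_half,inact_k availability (steady-state inactivation)
#'   Boltzmann parameters, mV (k > 0, decreasing form).
#' @param tau_m,tau_h activation / inactivation time-constant functions of
#'   voltage, ms.
#' @param a_fast,tau_fast,tau_slow two-exponential recovery mixture:
#'   fast-component amplitude (0..1) and time constants, ms
#'   (tau_fast < tau_slow).
#' @param noise_sd additive Gaussian noise per sample, pA; `NA` means 2% of
#'   the protocol's maximal noiseless peak current.
#' @param capacitance cell capacitance, pF.
#' @return List of class `gating_params`.
#' @export
gating_params <- function(g_max = 95, v_rev = 40,
                          act_v_half = -38.4, act_k = 5.4,
                          inact_v_half = -86.6, inact_k = 5.6,
                          tau_m = default_tau_m, tau_h = default_tau_h,
                          a_fast = 0.8, tau_fast = 24.51, tau_slow = 241.1,
                          noise_sd = NA_real_, capacitance = 8.6) {
  stopifnot(g_max > 0, act_k > 0, inact_k > 0, a_fast >= 0, a_fast <= 1,
            tau_fast > 0, tau_fast < tau_slow, capacitance > 0)
  structure(list(g_max = g_max, v_rev = v_rev, act_v_half = act_v_half,
                 act_k = act_k, inact_v_half = inact_v_half, inact_k = inact_k,
                 tau_m = tau_m, tau_h = tau_h, a_fast = a_fast,
                 tau_fast = tau_fast, tau_slow = tau_slow, noise_sd = noise_sd,
                 capacitance = capacitance),
            class = "gating_params")
}

#' Gating-parameter presets for the wild-type and charge-reversed channels
#'
#' Activation, availability and recovery values follow the study's fitted
#' biophysical characteristics; g_max is set so the simulated maximal peak
#' current density matches the reported value at the preset capacitance.
#' `fast_v_half`/`fast_k` (the 20 ms prepulse curve) are carried as attributes
#' and activated with [fast_inactivation_params()].
#'
#' @param name `"WT"` or `"R219E"`.
#' @return A `gating_params` object.
#' @export
nav_preset <- function(name = c("WT", "R219E")) {
  name <- match.arg(name)
  p <- if (name == "WT") {
    gating_params(g_max = 95, act_v_half = -38.4, act_k = 5.4,
                  inact_v_half = -86.6, inact_k = 5.6,
                  a_fast = 0.8, tau_fast = 24.51, tau_slow = 241.1,
                  capacitance = 8.6)
  } else {
    gating_params(g_max = 70, act_v_half = -46.1, act_k = 5.8,
                  inact_v_half = -92.0, inact_k = 5.5,
                  a_fast = 0.8, tau_fast = 59.12, tau_slow = 404.7,
                  capacitance = 9.2)
  }
  attr(p, "preset") <- name
  attr(p, "fast_v_half") <- if (name == "WT") -65.9 else -77.0
  attr(p, "fast_k") <- if (name == "WT") 8.5 else 9.8
  p
}

#' Parameterize a preset so the 20 ms availability curve is its fast-inactivation truth
#'
#' Returns the preset with the availability Boltzmann replaced by the
#' fast-inactivation (20 ms prepulse) curve and `tau_h` replaced by a fast,
#' voltage-flat time constant (default 2.5 ms). A 20 ms prepulse then
#' equilibrates at every prepulse voltage (20/2.5 = 8 time constants), so the
#' simulated 20 ms availability curve IS that Boltzmann, while the test-pulse
#' current still rises an order of magnitude faster than it inactivates
#' (tau_m(-15) = 0.19 ms), keeping the test peak proportional to
#' availability.
#'
#' @param params a preset from [nav_preset()].
#' @param tau_h_fast flat fast-inactivation time constant, ms.
#' @return A modified `gating_params` object.
#' @export
fast_inactivation_params <- function(params, tau_h_fast = 2.5) {
  fv <- attr(params, "fast_v_half"); fk <- attr(params, "fast_k")
  if (is.null(fv)) stop("params carries no fast-inactivation attributes")
  params$inact_v_half <- fv
  params$inact_k <- fk
  params$tau_h <- function(v) rep_len(tau_h_fast, length(v))
  params
}

#' Steady-state activation and availability curves
#'
#' @param params a `gating_params`.
#' @param v voltage, mV.
#' @return `m_inf`/`h_inf` value in `[0, 1]`.
#' @export
m_inf <- function(params, v) boltzmann(v, params$act_v_half, params$act_k, "activation")

#' @rdname m_inf
#' @export
h_inf <- function(params, v) boltzmann(v, params$inact_v_half, params$inact_k,
                                       "availability")

#' Boltzmann function (activation or availability form)
#'
#' Activation: `1 / (1 + exp((v_half - V) / k))`, increasing in V and equal to
#' 1/2 at `V = v_half` (50% of channels activated). Availability:
#' `1 / (1 + exp((V - v_half) / k))`, decreasing form with k > 0.
#'
#' @param v voltage, mV (vectorized).
#' @param v_half half-point, mV.
#' @param k slope factor, mV (> 0).
#' @param form `"activation"` or `"availability"`.
#' @export
boltzmann <- function(v, v_half, k, form = c("activation", "availability")) {
  form <- match.arg(form)
  if (k <= 0) stop("slope factor k must be > 0")
  if (form == "activation") 1 / (1 + exp((v_half - v) / k))
  else 1 / (1 + exp((v - v_half) / k))
}

#' Closed-form gate states m(t), h(t)
#'
#' @param params a `gating_params`.
#' @param v clamped voltage, mV.
#' @param t time since the voltage step, ms (vectorized, >= 0).
#' @param m0,h0 gate values at t = 0.
#' @return List with numeric vectors `m`, `h` in `[0, 1]`.
#' @export
gate_states <- function(params, v, t, m0 = 0, h0 = 1) {
  stopifnot(all(t >= 0))
  mi <- m_inf(params, v); hi <- h_inf(params, v)
  list(m = mi + (m0 - mi) * exp(-t / params$tau_m(v)),
       h = hi + (h0 - hi) * exp(-t / params$tau_h(v)))
}

#' Voltage-protocol specification
#'
#' Defaults follow the study's stimulation design: holding -100 mV; IV steps
#' -80..+60 mV in 5 mV increments, 40 ms; SSI 500 ms prepulse -120..+10 mV in
#' 5 mV steps with a -15 mV / 20 ms test pulse; FAST_SSI the same with a 20 ms
#' prepulse; RECOVERY conditioning -15 mV / 500 ms, interpulse at holding over
#' 12 log-spaced intervals 1..3000 ms, test -15 mV / 20 ms. Sampling 20 kHz.
#'
#' @param kind one of `"IV"`, `"SSI"`, `"FAST_SSI"`, `"RECOVERY"`.
#' @param holding holding potential, mV.
#' @param sample_rate kHz.
#' @param ... overrides: `v_steps`, `dur` (IV); `prepulse_v`, `prepulse_dur`,
#'   `test_v`, `test_dur` (SSI/FAST_SSI); `cond_v`, `cond_dur`, `intervals`,
#'   `test_v`, `test_dur` (RECOVERY).
#' @return List of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = c("IV", "SSI", "FAST_SSI", "RECOVERY"),
                          holding = -100, sample_rate = 20, ...) {
  kind <- match.arg(kind)
  stopifnot(sample_rate > 0)
  dots <- list(...)
  base <- switch(kind,
    IV = list(v_steps = seq(-80, 60, by = 5), dur = 40),
    SSI = list(prepulse_v = seq(-120, 10, by = 5), prepulse_dur = 500,
               test_v = -15, test_dur = 20),
    FAST_SSI = list(prepulse_v = seq(-120, 10, by = 5), prepulse_dur = 20,
                    test_v = -15, test_dur = 20),
    RECOVERY = list(cond_v = -15, cond_dur = 500,
                    intervals = exp(seq(log(1), log(3000), length.out = 12)),
                    test_v = -15, test_dur = 20))
  bad <- setdiff(names(dots), names(base))
  if (length(bad)) stop("unknown protocol fields: ", paste(bad, collapse = ", "))
  base[names(dots)] <- dots
  structure(c(list(kind = kind, holding = holding, sample_rate = sample_rate),
              base),
            class = "protocol_spec")
}

sweep_current <- function(params, v, t, m0, h0) {
  g <- gate_states(params, v, t, m0 = m0, h0 = h0)
  params$g_max * (v - params$v_rev) * g$m * g$h
}

#' Simulate a voltage protocol
#'
#' Produces a `trace_set`: a shared time base starting at the test-pulse onset
#' (t = 0), one current sweep per voltage step (IV, SSI, FAST_SSI) or per
#' recovery interval (RECOVERY), seeded Gaussian noise, and the generating
#' truth attached. For SSI/FAST_SSI the availability entering the test pulse
#' is `h_inf(Vpre) + (h0 - h_inf(Vpre)) * exp(-L / tau_h(Vpre))` with `L` the
#' prepulse duration; for RECOVERY the available fraction after an interval
#' `dt` is the two-exponential mixture, and the conditioning-pulse sweep is
#' stored as `reference`.
#'
#' @param params a [gating_params()].
#' @param protocol a [protocol_spec()].
#' @param seed integer RNG seed for the noise.
#' @return List of class `trace_set`: `kind`, `time` (ms), `sweeps` (matrix,
#'   samples x sweeps), `levels` (mV or ms), `reference` (RECOVERY only),
#'   `protocol`, `truth`, `seed`, `noise_sd`.
#' @export
simulate_protocol <- function(params, protocol, seed = 1) {
  stopifnot(inherits(params, "gating_params"), inherits(protocol, "protocol_spec"))
  dt <- 1 / protocol$sample_rate
  m_hold <- m_inf(params, protocol$holding)
  h_hold <- h_inf(params, protocol$holding)

  make <- function(dur) seq(0, dur, by = dt)

  if (protocol$kind == "IV") {
    time <- make(protocol$dur)
    levels <- protocol$v_steps
    clean <- vapply(levels, function(v) {
      sweep_current(params, v, time, m0 = m_hold, h0 = h_hold)
    }, numeric(length(time)))
    reference <- NULL
  } else if (protocol$kind %in% c("SSI", "FAST_SSI")) {
    time <- make(protocol$test_dur)
    levels <- protocol$prepulse_v
    L <- protocol$prepulse_dur
    clean <- vapply(levels, function(vp) {
      hp <- h_inf(params, vp) +
        (h_hold - h_inf(params, vp)) * exp(-L / params$tau_h(vp))
      mp <- m_inf(params, vp)   # m equilibrates during the long prepulse
      sweep_current(params, protocol$test_v, time, m0 = mp, h0 = hp)
    }, numeric(length(time)))
    reference <- NULL
  } else { # RECOVERY
    time <- make(protocol$test_dur)
    levels <- protocol$intervals
    clean <- vapply(levels, function(gap) {
      frac <- 1 - params$a_fast * exp(-gap / params$tau_fast) -
        (1 - params$a_fast) * exp(-gap / params$tau_slow)
      sweep_current(params, protocol$test_v, time,
                    m0 = m_hold, h0 = frac * h_hold)
    }, numeric(length(time)))
    reference <- sweep_current(params, protocol$cond_v, make(protocol$cond_dur),
                               m0 = m_hold, h0 = h_hold)
  }

  noise_sd <- params$noise_sd
  if (is.na(noise_sd)) {
    peak_scale <- max(abs(clean), if (!is.null(reference)) abs(reference) else 0)
    noise_sd <- 0.02 * peak_scale
  }
  set.seed(seed)
  if (noise_sd > 0) {
    clean <- clean + matrix(stats::rnorm(length(clean), 0, noise_sd),
                            nrow(clean), ncol(clean))
    if (!is.null(reference)) {
      reference <- reference + stats::rnorm(length(reference), 0, noise_sd)
    }
  }
  structure(list(kind = protocol$kind, time = time, sweeps = clean,
                 levels = levels, reference = reference, protocol = protocol,
                 truth = params, seed = seed, noise_sd = noise_sd),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", x$kind, ": ", ncol(x$sweeps), " sweeps x ",
      nrow(x$sweeps), " samples (", x$protocol$sample_rate, " kHz), noise sd ",
      signif(x$noise_sd, 3), " pA\n", sep = "")
  invisible(x)
}

#' Export / import trace sets as long-format CSV
#'
#' Columns: sweep_id, level, time_ms, current_pA. A JSON sidecar
#' (`<path>.meta.json`) stores the protocol, noise, seed and (for synthetic
#' sets) the generating truth.
#'
#' @param ts a `trace_set`.
#' @param path CSV output path.
#' @export
write_traces <- function(ts, path) {
  n <- nrow(ts$sweeps); k <- ncol(ts$sweeps)
  df <- data.frame(sweep_id = rep(seq_len(k), each = n),
                   level = rep(ts$levels, each = n),
                   time_ms = rep(ts$time, k),
                   current_pA = as.vector(ts$sweeps))
  if (!is.null(ts$reference)) {
    nr <- length(ts$reference)
    df <- rbind(df, data.frame(sweep_id = 0L, level = NA_real_,
                               time_ms = seq(0, by = ts$time[2] - ts$time[1],
                                             length.out = nr),
                               current_pA = ts$reference))
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(kind = ts$kind, protocol = ts$protocol[-1], seed = ts$seed,
               noise_sd = ts$noise_sd,
               truth = Filter(Negate(is.function), unclass(ts$truth)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @param params optional `gating_params` to attach as truth on import.
#' @export
read_traces <- function(path, params = NULL) {
  df <- utils::read.csv(path)
  need <- c("sweep_id", "level", "time_ms", "current_pA")
  if (!all(need %in% names(df))) {
    stop("traces CSV must have columns: ", paste(need, collapse = ", "))
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  ref <- NULL
  if (any(df$sweep_id == 0L)) {
    ref <- df$current_pA[df$sweep_id == 0L]
    df <- df[df$sweep_id != 0L, , drop = FALSE]
  }
  ids <- sort(unique(df$sweep_id))
  time <- sort(unique(df$time_ms))
  sweeps <- vapply(ids, function(i) {
    d <- df[df$sweep_id == i, , drop = FALSE]
    d$current_pA[order(d$time_ms)]
  }, numeric(length(time)))
  levels <- vapply(ids, function(i) df$level[df$sweep_id == i][1], numeric(1))
  if (is.null(params) && !is.null(meta$truth)) params <- meta$truth
  structure(list(kind = if (!is.null(meta)) meta$kind else "IV",
                 time = time, sweeps = sweeps, levels = levels,
                 reference = ref, protocol = meta$protocol, truth = params,
                 seed = meta$seed,
                 noise_sd = if (!is.null(meta)) meta$noise_sd else NA_real_),
            class = "trace_set")
}
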