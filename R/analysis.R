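# Whole-cell gating analysis: sweep features, IV / current density, chord
# conductance, Boltzmann activation/availability fits, bi-exponential recovery
# fits, and two-group statistics.

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  if (window %% 2 == 0) window <- window + 1
  k <- rep(1 / window, window)
  n <- length(x)
  out <- stats::filter(x, k, sides = 2)
  # shrink the window at the edges instead of dropping samples
  half <- (window - 1) / 2
  for (i in seq_len(half)) {
    out[i] <- mean(x[1:(i + half)])
    out[n - i + 1] <- mean(x[(n - i + 1 - half):n])
  }
  as.numeric(out)
}

#' Unbiased peak-current estimator (split-sample, quadratic read-out)
#'
#' Taking the raw extremum of a noisy sweep overestimates the peak magnitude
#' (the extremum selects the largest noise excursion), with a bias that
#' depends on peak sharpness and signal size and therefore distorts
#' normalized curves. This estimator decouples selection from read-out: the
#' peak sample is located on the (lightly smoothed) even-indexed samples, and
#' the value is read from a local quadratic fitted to the odd-indexed samples
#' around that location, evaluated at the selected index. Because the read-out
#' noise is independent of the selection, the estimate is first-order unbiased
#' in the noise for any signal shape.
#'
#' @param current numeric sweep, pA (signed; inward negative).
#' @param select_smooth moving-average window (in even-subsample units) used
#'   for peak location.
#' @param read_half half-width (raw samples) of the quadratic read-out window.
#' @return Signed peak estimate, pA.
#' @export
robust_peak <- function(current, select_smooth = 3, read_half = 5) {
  n <- length(current)
  if (n < 12) return(current[which.max(abs(current))])
  ev <- seq(1, n, by = 2); od <- seq(2, n, by = 2)
  ye <- current[ev]
  if (select_smooth > 1) {
    ye <- stats::filter(ye, rep(1 / select_smooth, select_smooth), sides = 2)
    ye[is.na(ye)] <- 0
  }
  i0 <- ev[which.max(abs(ye))]
  w <- od[abs(od - i0) <= read_half]
  if (length(w) < 4) return(current[od[which.min(abs(od - i0))]])
  tt <- w - i0
  unname(stats::lm.fit(cbind(1, tt, tt^2), current[w])$coefficients[1])
}

#' Per-sweep features: peak, time to peak, 50% decay
#'
#' The peak is the signed extremum of the current after `onset` (inward
#' currents are negative). `decay50` is the time from the peak until the
#' current first returns to 50% of the peak, or `NA` (flagged) if it never
#' does. An optional centered moving average can emulate the recording
#' chain's low-pass filter; for noise-robust peak magnitudes used in curve
#' fitting see [robust_peak()].
#'
#' @param time time base, ms.
#' @param current current, pA.
#' @param onset pulse onset, ms (time is measured from it).
#' @param smooth moving-average window in samples (1 = none).
#' @return List: `peak` (pA, signed), `time_to_peak` (ms), `decay50` (ms),
#'   `decay50_defined`, `defined` (FALSE for an all-zero/degenerate trace).
#' @export
sweep_features <- function(time, current, onset = 0, smooth = 1) {
  stopifnot(length(time) == length(current))
  keep <- time >= onset
  if (sum(keep) < 10) stop("trace must cover the onset with >= 10 samples")
  t <- time[keep]
  y <- moving_average(current[keep], smooth)
  if (all(y == 0)) {
    return(list(peak = NA_real_, time_to_peak = NA_real_, decay50 = NA_real_,
                decay50_defined = FALSE, defined = FALSE))
  }
  ipk <- which.max(abs(y))
  peak <- y[ipk]
  ttp <- t[ipk] - onset
  post <- y[ipk:length(y)]
  hit <- which(abs(post) <= 0.5 * abs(peak))
  if (length(hit)) {
    decay50 <- t[ipk + hit[1] - 1L] - t[ipk]
    d_def <- TRUE
  } else {
    decay50 <- NA_real_; d_def <- FALSE
  }
  list(peak = peak, time_to_peak = ttp, decay50 = decay50,
       decay50_defined = d_def, defined = TRUE)
}

#' Feature table of a trace set
#'
#' @param ts a `trace_set`.
#' @param smooth passed to [sweep_features()] (time-to-peak / decay50 path).
#' @param peak_method `"split"` (default; [robust_peak()], noise-unbiased) or
#'   `"extremum"` (raw signed extremum).
#' @return data.frame: level, peak, time_to_peak, decay50, decay50_defined.
#' @export
trace_features <- function(ts, smooth = 1, peak_method = c("split", "extremum")) {
  peak_method <- match.arg(peak_method)
  rows <- lapply(seq_len(ncol(ts$sweeps)), function(k) {
    f <- sweep_features(ts$time, ts$sweeps[, k], onset = 0, smooth = smooth)
    pk <- if (peak_method == "split" && f$defined) {
      robust_peak(ts$sweeps[, k])
    } else {
      f$peak
    }
    data.frame(level = ts$levels[k], peak = pk, time_to_peak = f$time_to_peak,
               decay50 = f$decay50, decay50_defined = f$decay50_defined)
  })
  do.call(rbind, rows)
}

#' IV curve with current density
#'
#' @param ts an IV `trace_set`.
#' @param capacitance cell capacitance, pF (> 0); defaults to the attached
#'   truth's value when present.
#' @param peak_method passed to [trace_features()].
#' @return data.frame of class `iv_curve`: voltage, peak (pA, signed),
#'   density (pA/pF).
#' @export
iv_curve <- function(ts, capacitance = NULL, peak_method = "split") {
  if (is.null(capacitance)) capacitance <- ts$truth$capacitance
  if (is.null(capacitance) || capacitance <= 0) stop("capacitance must be > 0")
  f <- trace_features(ts, peak_method = peak_method)
  out <- data.frame(voltage = f$level, peak = f$peak,
                    density = f$peak / capacitance)
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Estimate the reversal potential from an IV curve
#'
#' Linear interpolation between the two most depolarized points bracketing
#' zero current (an exact zero at a grid point is returned as-is).
#'
#' @param iv an `iv_curve` (or data.frame with voltage/peak).
#' @return Reversal potential, mV.
#' @export
estimate_vrev <- function(iv) {
  ok <- is.finite(iv$peak)   # all-zero sweeps carry NA peaks; treat as absent
  o <- order(iv$voltage[ok])
  v <- iv$voltage[ok][o]; i <- iv$peak[ok][o]
  zero <- which(i == 0)
  if (length(zero)) return(v[max(zero)])
  cross <- which(i[-length(i)] * i[-1] < 0)
  if (!length(cross)) {
    stop("IV has no sign change on its depolarized limb; supply v_rev explicitly")
  }
  k <- max(cross)
  v[k] + (v[k + 1] - v[k]) * (-i[k]) / (i[k + 1] - i[k])
}

#' Chord-conductance transform of an IV curve
#'
#' `G(V) = I(V) / (V - v_rev)`, normalized by the maximal conductance. Points
#' within `exclude_mV` of the reversal potential are dropped (the chord
#' denominator is unstable there).
#'
#' @param iv an `iv_curve`.
#' @param v_rev reversal potential, mV.
#' @param exclude_mV half-width of the exclusion window around `v_rev`.
#' @return data.frame: voltage, g (nS), g_norm.
#' @export
conductance_curve <- function(iv, v_rev, exclude_mV = 5) {
  keep <- abs(iv$voltage - v_rev) >= exclude_mV
  if (any(!keep)) {
    warning(sum(!keep), " point(s) within ", exclude_mV,
            " mV of v_rev dropped from the conductance curve")
  }
  v <- iv$voltage[keep]
  g <- iv$peak[keep] / (v - v_rev)
  gmax <- max(g)
  if (gmax <= 0) {
    warning("all-zero or negative conductance curve; normalization undefined")
    return(data.frame(voltage = v, g = g, g_norm = rep(NA_real_, length(g))))
  }
  data.frame(voltage = v, g = g, g_norm = g / gmax)
}

boltzmann_rss <- function(par, v, y, form, free_amplitude, w) {
  vh <- par[1]; k <- exp(par[2])
  A <- if (free_amplitude) par[3] else 1
  sum(w * (y - A * boltzmann(v, vh, k, form))^2)
}

#' Fit a Boltzmann function to (V, y) points
#'
#' Least squares of `y = A / (1 + exp((v_half - V)/k))` (activation) or
#' `y = A / (1 + exp((V - v_half)/k))` (availability), with `k > 0` under the
#' decreasing-availability sign convention. Initialization is deterministic:
#' `v_half0` = voltage of the point closest to half-amplitude; multi-start
#' `k0` in {2, 5, 10} mV; lowest residual sum of squares wins, ties to the
#' smallest k. With `free_amplitude` (default) the amplitude A is a fitted
#' nuisance parameter, which removes the bias a noisy normalization maximum
#' would otherwise impose; reported `v_half`, `k` are unchanged by y-scaling.
#'
#' @param v voltages, mV.
#' @param y normalized response.
#' @param form `"activation"` or `"availability"`.
#' @param free_amplitude fit the amplitude (TRUE) or pin A = 1.
#' @param weights optional least-squares weights (e.g. inverse response
#'   variances); default uniform.
#' @return List of class `boltzmann_fit`: `v_half`, `k`, `amplitude`,
#'   `se_v_half`, `se_k`, `rss`, `n`, `form`, `low_confidence`, `converged`.
#' @export
fit_boltzmann <- function(v, y, form = c("activation", "availability"),
                          free_amplitude = TRUE, weights = NULL) {
  form <- match.arg(form)
  ok <- is.finite(v) & is.finite(y)
  if (is.null(weights)) weights <- rep(1, length(v))
  w <- weights[ok] / mean(weights[ok])
  v <- v[ok]; y <- y[ok]
  if (length(v) < 5) stop("need >= 5 finite points to fit a Boltzmann")
  low_conf <- !(min(y) < 0.3 && max(y) > 0.7)
  v0 <- v[which.min(abs(y - 0.5 * max(abs(y))))]
  fits <- lapply(c(2, 5, 10), function(k0) {
    par0 <- c(v0, log(k0), if (free_amplitude) max(y))
    stats::optim(par0, boltzmann_rss, v = v, y = y, form = form,
                 free_amplitude = free_amplitude, w = w, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
  })
  rsss <- vapply(fits, function(f) f$value, numeric(1))
  ks <- vapply(fits, function(f) exp(f$par[2]), numeric(1))
  best <- order(round(rsss, 12), ks)[1]
  fit <- fits[[best]]
  vh <- fit$par[1]; k <- exp(fit$par[2])
  A <- if (free_amplitude) fit$par[3] else 1
  # standard errors from the Gauss-Newton Jacobian in (v_half, k[, A])
  s <- if (form == "activation") 1 else -1
  e <- exp(s * (vh - v) / k)
  f0 <- 1 / (1 + e)
  d_vh <- -A * s / k * e * f0^2
  d_k <- A * s * (vh - v) / k^2 * e * f0^2
  J <- cbind(d_vh, d_k, if (free_amplitude) f0) * sqrt(w)
  p <- ncol(J)
  sigma2 <- fit$value / max(length(v) - p, 1)
  cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  ses <- if (is.null(cv)) rep(NA_real_, p) else sqrt(pmax(diag(cv), 0))
  structure(list(v_half = vh, k = k, amplitude = A,
                 se_v_half = ses[1], se_k = ses[2],
                 rss = fit$value, n = length(v), form = form,
                 low_confidence = low_conf,
                 converged = fit$convergence == 0),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("<boltzmann_fit> ", x$form, ": V1/2 = ", sprintf("%.2f", x$v_half),
      " +/- ", sprintf("%.2f", x$se_v_half), " mV, k = ",
      sprintf("%.2f", x$k), " +/- ", sprintf("%.2f", x$se_k),
      " mV (n = ", x$n, ")\n", sep = "")
  if (x$low_confidence) cat("  note: points do not span both tails\n")
  invisible(x)
}

recovery_model <- function(par, t, free_plateau) {
  af <- stats::plogis(par[1]); tf <- exp(par[2]); ts <- tf * (1 + exp(par[3]))
  A <- if (free_plateau) par[4] else 1
  A * (1 - af * exp(-t / tf) - (1 - af) * exp(-t / ts))
}

#' Fit a bi-exponential recovery-from-inactivation curve
#'
#' Constrained least squares of
#' `R(dt) = A * (1 - a_fast*exp(-dt/tau_fast) - (1 - a_fast)*exp(-dt/tau_slow))`
#' with `0 <= a_fast <= 1` and `tau_fast < tau_slow` enforced by
#' parameterization. The plateau `A` (default free) absorbs normalization
#' error in the conditioning-pulse peak, which would otherwise skew
#' `tau_slow`; pin it with `free_plateau = FALSE`. A fitted time-constant
#' ratio below 3 triggers a single-exponential warning (the fit is still
#' returned).
#'
#' @param dt recovery intervals, ms (>= 6 points spanning >= one decade).
#' @param r recovered fractions.
#' @param free_plateau fit the plateau amplitude (TRUE) or pin A = 1.
#' @return List of class `recovery_fit`: `a_fast`, `tau_fast`, `tau_slow`,
#'   `plateau`, standard errors, `rss`, `n`, `converged`.
#' @export
fit_recovery <- function(dt, r, free_plateau = TRUE) {
  ok <- is.finite(dt) & is.finite(r)
  dt <- dt[ok]; r <- r[ok]
  if (length(dt) < 6) stop("need >= 6 recovery intervals")
  if (max(dt) / min(dt) < 10) stop("recovery intervals must span at least one decade")
  if (stats::sd(r) < 1e-12) {
    warning("degenerate recovery data (constant fractions); fit is unreliable")
  }
  rss <- function(par) sum((r - recovery_model(par, dt, free_plateau))^2)
  starts <- list()
  for (tf0 in c(10, 30, 100)) {
    for (af0 in c(0.5, 0.8)) {
      starts[[length(starts) + 1L]] <-
        c(stats::qlogis(af0), log(tf0), log(10 - 1),      # tau_slow = 10 * tau_fast
          if (free_plateau) max(r))
    }
  }
  fits <- lapply(starts, function(p0) {
    stats::optim(p0, rss, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-14))
  })
  fit <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  # polish with BFGS from the best simplex solution
  fit <- stats::optim(fit$par, rss, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  af <- stats::plogis(fit$par[1]); tf <- exp(fit$par[2])
  ts_ <- tf * (1 + exp(fit$par[3]))
  A <- if (free_plateau) fit$par[4] else 1
  if (ts_ / tf < 3) {
    warning("time-constant ratio < 3; data may be single-exponential")
  }
  # Jacobian in the natural parameters (a_fast, tau_fast, tau_slow[, A])
  ef <- exp(-dt / tf); es <- exp(-dt / ts_)
  J <- cbind(A * (-ef + es),
             -A * af * ef * dt / tf^2,
             -A * (1 - af) * es * dt / ts_^2,
             if (free_plateau) 1 - af * ef - (1 - af) * es)
  p <- ncol(J)
  sigma2 <- fit$value / max(length(dt) - p, 1)
  cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  ses <- if (is.null(cv)) rep(NA_real_, p) else sqrt(pmax(diag(cv), 0))
  structure(list(a_fast = af, tau_fast = tf, tau_slow = ts_, plateau = A,
                 se_a_fast = ses[1], se_tau_fast = ses[2], se_tau_slow = ses[3],
                 rss = fit$value, n = length(dt),
                 converged = fit$convergence == 0),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("<recovery_fit> a_fast = ", sprintf("%.3f", x$a_fast),
      ", tau_fast = ", sprintf("%.2f", x$tau_fast),
      " ms, tau_slow = ", sprintf("%.2f", x$tau_slow), " ms (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Unpaired two-group comparison (Student/Welch t)
#'
#' Raw value lists are compared with the pooled-variance two-sample t test.
#' Summary-statistics input (`list(mean =, sem =, n =)`) uses the Welch-style
#' statistic `(m_a - m_b)/sqrt(sem_a^2 + sem_b^2)` with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param a,b numeric vectors, or lists with `mean`, `sem`, `n`.
#' @return List of class `group_comparison`: group means/SEMs/n, `t`, `df`,
#'   `p` (two-sided).
#' @export
compare_groups <- function(a, b) {
  summ <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("mean", "sem", "n") %in% names(x)))
      list(mean = x$mean, sem = x$sem, n = x$n, raw = NULL)
    } else {
      if (length(x) < 2) stop("raw groups need n >= 2")
      list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
           n = length(x), raw = x)
    }
  }
  sa <- summ(a); sb <- summ(b)
  if (!is.null(sa$raw) && !is.null(sb$raw)) {
    va <- stats::var(sa$raw); vb <- stats::var(sb$raw)
    if (va + vb == 0) {
      tt <- 0; df <- sa$n + sb$n - 2
      p <- 1
      if (sa$mean != sb$mean) { tt <- Inf; p <- 0 }
    } else {
      ht <- stats::t.test(sa$raw, sb$raw, var.equal = TRUE)
      tt <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
    }
  } else {
    se2a <- sa$sem^2; se2b <- sb$sem^2
    tt <- (sa$mean - sb$mean) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (sa$n - 1) + se2b^2 / (sb$n - 1))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  structure(list(mean_a = sa$mean, sem_a = sa$sem, n_a = sa$n,
                 mean_b = sb$mean, sem_b = sb$sem, n_b = sb$n,
                 t = tt, df = df, p = min(max(p, .Machine$double.xmin), 1)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", sprintf("%.3g +/- %.2g (n=%d)", x$mean_a, x$sem_a, x$n_a),
      " vs ", sprintf("%.3g +/- %.2g (n=%d)", x$mean_b, x$sem_b, x$n_b),
      ": t = ", sprintf("%.3g", x$t), ", p = ", sprintf("%.3g", x$p), "\n", sep = "")
  invisible(x)
}

# ---- pipeline wrappers ------------------------------------------------------

#' Full steady-state activation analysis of an IV trace set
#'
#' Peak currents per voltage ([robust_peak()]), reversal-potential estimate
#' (unless supplied), chord-conductance transform, and activation Boltzmann
#' fit. The fit is weighted by `(V - v_rev)^2`: the chord transform divides
#' the peak current by the driving force, so conductance points have variance
#' proportional to `1/(V - v_rev)^2` and generalized least squares restores
#' homoscedasticity.
#'
#' @param ts an IV `trace_set`.
#' @param capacitance pF; defaults to the attached truth's value.
#' @param v_rev mV; estimated by [estimate_vrev()] when `NULL`.
#' @param peak_method passed to [trace_features()].
#' @return List: `iv` (`iv_curve`), `v_rev`, `gv` (conductance curve),
#'   `fit` (`boltzmann_fit`).
#' @export
analyze_iv <- function(ts, capacitance = NULL, v_rev = NULL,
                       peak_method = "split") {
  iv <- iv_curve(ts, capacitance = capacitance, peak_method = peak_method)
  if (is.null(v_rev)) v_rev <- estimate_vrev(iv)
  gv <- suppressWarnings(conductance_curve(iv, v_rev))
  fit <- fit_boltzmann(gv$voltage, gv$g_norm, form = "activation",
                       weights = (gv$voltage - v_rev)^2)
  list(iv = iv, v_rev = v_rev, gv = gv, fit = fit)
}

#' Steady-state (or fast) inactivation analysis of an SSI trace set
#'
#' Normalizes test-pulse peaks by the maximal-magnitude peak (signed ratio:
#' rectifying near-zero peaks would lift the depolarized tail) and fits the
#' availability Boltzmann with a free amplitude.
#'
#' @param ts an SSI or FAST_SSI `trace_set`.
#' @return List: `points` (voltage, norm), `fit` (`boltzmann_fit`).
#' @export
analyze_ssi <- function(ts) {
  f <- trace_features(ts, peak_method = "split")
  ref <- f$peak[which.max(abs(f$peak))]
  norm <- f$peak / ref
  fit <- fit_boltzmann(f$level, norm, form = "availability")
  list(points = data.frame(voltage = f$level, norm = norm), fit = fit)
}

#' Recovery-from-inactivation analysis of a RECOVERY trace set
#'
#' Recovered fraction per interval = test-pulse peak / conditioning-pulse
#' peak (signed ratio, [robust_peak()]); bi-exponential fit with a free
#' plateau.
#'
#' @param ts a RECOVERY `trace_set` (with `reference` conditioning sweep).
#' @return List: `points` (interval, fraction), `fit` (`recovery_fit`).
#' @export
analyze_recovery <- function(ts) {
  if (is.null(ts$reference)) stop("RECOVERY trace set lacks the conditioning sweep")
  p1 <- robust_peak(ts$reference)
  f <- trace_features(ts, peak_method = "split")
  frac <- f$peak / p1
  fit <- fit_recovery(f$level, frac)
  list(points = data.frame(interval = f$level, fraction = frac), fit = fit)
}
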