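#' One backward-difference step of a two-element windkessel
#'
#' A two-element windkessel relates outlet pressure and flow through a
#' resistance R (absorption) and compliance C (storage) in parallel:
#' \code{Q = (P - P_out)/R + C d(P - P_out)/dt}. Discretizing the derivative
#' with a backward difference of step \code{dt} and solving for the current
#' pressure gives
#' \deqn{P_n = P_{out} + \frac{Q_n R + (P_{n-1} - P_{out}) C R / \Delta t}
#'                            {1 + C R / \Delta t}.}
#' With \code{C = 0} this reduces exactly to the resistor law
#' \code{P = P_out + Q R}.
#'
#' @param P_prev pressure at the previous time step (mmHg).
#' @param Q_n inflow at the current step (ml/s).
#' @param R resistance (mmHg.s/ml), \code{> 0}.
#' @param C compliance (ml/mmHg), \code{>= 0}.
#' @param dt time step (s), \code{> 0}.
#' @param P_out external (venous/lymphatic) pressure (mmHg), default 0.
#' @return Pressure at the current step (mmHg).
#' @export
#' @examples
#' wk_update(P_prev = 0, Q_n = 1, R = 1000, C = 0.1, dt = 0.05)  # 1000/2001
wk_update <- function(P_prev, Q_n, R, C, dt, P_out = 0) {
  if (!is.finite(R) || R <= 0) stop("'R' must be > 0")
  if (!is.finite(C) || C < 0) stop("'C' must be >= 0")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  a <- C * R / dt
  P_out + (Q_n * R + (P_prev - P_out) * a) / (1 + a)
}

#' Total absorption resistance from mean pressure and production
#'
#' At steady state all produced CSF is absorbed, so the mean intracranial
#' pressure is \code{ICP_avg = Q_production * R_tot}; inverting gives the
#' total absorption resistance. With the defaults ICP 10 mmHg and production
#' 0.00667 ml/s this is approximately 1500 mmHg.s/ml.
#'
#' @param ICP_avg target mean intracranial pressure (mmHg), \code{> 0}.
#' @param Q_production mean CSF production (ml/s), \code{> 0}.
#' @return Total resistance (mmHg.s/ml).
#' @export
total_resistance_from_physiology <- function(ICP_avg, Q_production) {
  if (!is.finite(ICP_avg) || ICP_avg <= 0) stop("'ICP_avg' must be > 0")
  if (!is.finite(Q_production) || Q_production <= 0)
    stop("'Q_production' must be > 0")
  ICP_avg / Q_production
}

#' Outlet allocation of total resistance and compliance
#'
#' Describes how total absorption resistance and total craniospinal
#' compliance are distributed over the absorption outlets. \code{q} gives
#' the fraction of net outflow through each outlet (must sum to 1); since
#' the outlet resistances combine in parallel, \code{R_i = R_tot / q_i}.
#' \code{c} gives the compliance fraction per outlet (capacitors in
#' parallel, \code{C_i = c_i * C_tot}); a zero fraction makes that outlet a
#' pure resistor.
#'
#' @param R_tot total resistance (mmHg.s/ml), \code{> 0}.
#' @param C_tot total compliance (ml/mmHg), \code{>= 0}.
#' @param q named numeric vector of outflow fractions, all \code{> 0},
#'   summing to 1 (within 1e-9).
#' @param c named numeric vector of compliance fractions, all \code{>= 0},
#'   over the same outlet names, summing to 1 (within 1e-9) when all
#'   compliance is allocated.
#' @return An object of class \code{"outlet_allocation"}.
#' @export
#' @examples
#' outlet_allocation(1500, 0.17,
#'                   q = c(int = 0.2, sp = 0.2, lym = 0.3, av = 0.3),
#'                   c = c(int = 0.33, sp = 0.67, lym = 0, av = 0))
outlet_allocation <- function(R_tot, C_tot, q, c) {
  if (!is.finite(R_tot) || R_tot <= 0) stop("'R_tot' must be > 0")
  if (!is.finite(C_tot) || C_tot < 0) stop("'C_tot' must be >= 0")
  if (is.null(names(q)) || any(!nzchar(names(q))))
    stop("'q' must be a named vector of outflow fractions")
  if (any(q <= 0))
    stop("zero outflow fractions are not allowed: omit the outlet instead (",
         paste(names(q)[q <= 0], collapse = ", "), ")")
  if (abs(sum(q) - 1) > 1e-9)
    stop(sprintf("outflow fractions must sum to 1, got %.12g (%s)",
                 sum(q), paste(sprintf("%s=%g", names(q), q), collapse = ", ")))
  if (!identical(sort(names(q)), sort(names(c))))
    stop("'c' must be named over the same outlets as 'q'")
  c <- c[names(q)]
  if (any(c < 0)) stop("compliance fractions must be >= 0")
  if (abs(sum(c) - 1) > 1e-9)
    stop(sprintf("compliance fractions must sum to 1, got %.12g", sum(c)))
  structure(list(R_tot = R_tot, C_tot = C_tot, q = q, c = c),
            class = "outlet_allocation")
}

#' @export
print.outlet_allocation <- function(x, ...) {
  cat(sprintf("<outlet_allocation> R_tot = %g mmHg.s/ml, C_tot = %g ml/mmHg\n",
              x$R_tot, x$C_tot))
  tab <- data.frame(outlet = names(x$q), q = unname(x$q), c = unname(x$c),
                    R = unname(x$R_tot / x$q), C = unname(x$c * x$C_tot))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Allocate outlet resistances
#'
#' \code{R_i = R_tot / q_i}. The parallel combination of the allocated
#' resistances recovers \code{R_tot} exactly because the fractions sum to 1.
#'
#' @param a an [outlet_allocation()].
#' @return Named numeric vector of resistances (mmHg.s/ml).
#' @export
allocate_resistances <- function(a) {
  stopifnot(inherits(a, "outlet_allocation"))
  a$R_tot / a$q
}

#' Allocate outlet compliances
#'
#' \code{C_i = c_i * C_tot}; the allocated compliances sum to \code{C_tot}.
#'
#' @param a an [outlet_allocation()].
#' @return Named numeric vector of compliances (ml/mmHg).
#' @export
allocate_compliances <- function(a) {
  stopifnot(inherits(a, "outlet_allocation"))
  a$c * a$C_tot
}

#' 0D lumped intracranial pressure model
#'
#' Single pressure node: all inflow sources discharge into one two-element
#' windkessel with total resistance \code{R_tot} and total compliance
#' \code{C_tot}. Pressure follows the backward-difference recurrence of
#' [wk_update()] at fixed step \code{dt}.
#'
#' @param sources list of [inlet_source()] objects (combined inflow).
#' @param R_tot total resistance (mmHg.s/ml).
#' @param C_tot total compliance (ml/mmHg).
#' @param dt time step (s), default 0.05.
#' @param P0 initial pressure (mmHg), default 0.
#' @param P_out external pressure (mmHg), default 0.
#' @return An object of class \code{"zero_d_model"}.
#' @seealso [simulate_0d()], [tune_total_compliance()]
#' @export
zero_d_model <- function(sources, R_tot, C_tot, dt = 0.05, P0 = 0,
                         P_out = 0) {
  stopifnot(is.list(sources), length(sources) >= 1L)
  lapply(sources, function(s) stopifnot(inherits(s, "inlet_source")))
  if (!is.finite(R_tot) || R_tot <= 0) stop("'R_tot' must be > 0")
  if (!is.finite(C_tot) || C_tot < 0) stop("'C_tot' must be >= 0")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  structure(list(sources = sources, R_tot = R_tot, C_tot = C_tot,
                 dt = dt, P0 = P0, P_out = P_out),
            class = "zero_d_model")
}

#' Integrate the 0D pressure model
#'
#' Steps the backward-difference recurrence from \code{P0} for
#' \code{duration} seconds; inflow is evaluated at the current (implicit)
#' time level. The trace starts with the initial condition at \code{t = 0}.
#'
#' @param m a [zero_d_model()].
#' @param duration simulated time (s), \code{>= dt}.
#' @return A data frame with columns \code{time} (s) and \code{pressure}
#'   (mmHg), \code{duration/dt + 1} rows.
#' @export
#' @examples
#' m <- zero_d_model(default_inlet_sources(respiration = FALSE),
#'                   R_tot = 1500, C_tot = 0.17)
#' tr <- simulate_0d(m, 5)
#' pulsation_amplitude(tr, c(0, 5))
simulate_0d <- function(m, duration) {
  stopifnot(inherits(m, "zero_d_model"))
  if (duration < m$dt) stop("'duration' must be >= dt")
  n <- round(duration / m$dt)
  t <- (0:n) * m$dt
  Q <- combined_inflow(m$sources, t)
  P <- numeric(n + 1L)
  P[1L] <- m$P0
  a <- m$C_tot * m$R_tot / m$dt
  denom <- 1 + a
  for (i in seq_len(n) + 1L) {
    P[i] <- m$P_out + (Q[i] * m$R_tot + (P[i - 1L] - m$P_out) * a) / denom
  }
  data.frame(time = t, pressure = P)
}

#' Pulsation amplitude of a trace
#'
#' Half of the peak-to-peak excursion, \code{(max - min)/2}, over a time
#' window. This half-amplitude convention is used for all pressure and flow
#' pulsation metrics in the package (a pure sinusoid of amplitude a returns
#' a). The window must span at least one full period of the slowest active
#' component for the value to be meaningful.
#'
#' @param trace data frame with a \code{time} column and one value column
#'   (e.g. the output of [simulate_0d()]), or a numeric vector (then
#'   \code{window} indexes nothing and the whole vector is used).
#' @param window numeric length-2, closed time interval \code{[t0, t1]}.
#'   Ignored for plain numeric input.
#' @return Amplitude (same units as the values), \code{>= 0}.
#' @export
pulsation_amplitude <- function(trace, window = NULL) {
  if (is.numeric(trace)) {
    x <- trace
  } else {
    stopifnot(is.data.frame(trace), "time" %in% names(trace))
    vcol <- setdiff(names(trace), "time")[1L]
    if (is.null(window)) {
      x <- trace[[vcol]]
    } else {
      stopifnot(length(window) == 2L, window[2L] > window[1L])
      keep <- trace$time >= window[1L] & trace$time <= window[2L]
      x <- trace[[vcol]][keep]
    }
  }
  if (length(x) == 0L) stop("empty window")
  (max(x) - min(x)) / 2
}

#' Fit total compliance to a target pressure pulsation amplitude
#'
#' Scans a grid of total compliance values, simulating the 0D model for a
#' fixed evaluation window from zero initial pressure and measuring the
#' pressure pulsation amplitude ([pulsation_amplitude()], half
#' peak-to-peak) over that window. Amplitude is strictly decreasing in
#' compliance, so the compliance whose amplitude equals the target is
#' located by linear interpolation between the two bracketing grid points.
#'
#' The default evaluation protocol simulates t in [0, 5] s (five cardiac
#' cycles) at dt = 0.05 s with P0 = 0 and measures the amplitude over the
#' whole window, start-up drift included.
#'
#' @param sources list of [inlet_source()] objects.
#' @param target_amplitude target pressure pulsation amplitude (mmHg),
#'   \code{> 0}. Default 5.
#' @param R_tot total resistance (mmHg.s/ml). Default 1500.
#' @param C_range interval of compliance values (ml/mmHg); the lower
#'   endpoint is excluded as an evaluation point (C = 0 is a pure resistor).
#'   Default \code{c(0, 1.2)}.
#' @param n_grid number of grid points. Default 1000.
#' @param dt time step (s). Default 0.05.
#' @param window evaluation window (s). Default \code{c(0, 5)}.
#' @param P0 initial pressure (mmHg). Default 0.
#' @return An object of class \code{"compliance_fit"}: a list with
#'   \code{C_tot} (the fitted compliance), \code{target_amplitude},
#'   \code{achieved_amplitude} (amplitude re-simulated at the fitted value),
#'   \code{grid} (data frame \code{C_tot}, \code{amplitude} mirroring the
#'   amplitude-versus-compliance curve) and the protocol settings.
#' @export
#' @examples
#' fit <- tune_total_compliance(default_inlet_sources(respiration = FALSE),
#'                              n_grid = 100)
#' fit$C_tot
tune_total_compliance <- function(sources, target_amplitude = 5,
                                  R_tot = 1500, C_range = c(0, 1.2),
                                  n_grid = 1000, dt = 0.05,
                                  window = c(0, 5), P0 = 0) {
  if (!is.finite(target_amplitude) || target_amplitude <= 0)
    stop("'target_amplitude' must be > 0")
  stopifnot(length(C_range) == 2L, C_range[2L] > C_range[1L],
            C_range[1L] >= 0, n_grid >= 2L)
  grid <- C_range[1L] + (C_range[2L] - C_range[1L]) * seq_len(n_grid) / n_grid
  amp_at <- function(C) {
    m <- zero_d_model(sources, R_tot = R_tot, C_tot = C, dt = dt, P0 = P0)
    pulsation_amplitude(simulate_0d(m, window[2L]), window)
  }
  amps <- vapply(grid, amp_at, numeric(1L))
  below <- which(amps < target_amplitude)
  if (length(below) == 0L || below[1L] == 1L) {
    stop(sprintf(
      "target amplitude %.4g mmHg is outside the achieved range [%.4g, %.4g] mmHg on C in (%.4g, %.4g]",
      target_amplitude, min(amps), max(amps), C_range[1L], C_range[2L]))
  }
  i <- below[1L]
  # amplitude is monotone decreasing; interpolate the unique crossing
  C_fit <- grid[i - 1L] +
    (amps[i - 1L] - target_amplitude) / (amps[i - 1L] - amps[i]) *
    (grid[i] - grid[i - 1L])
  structure(
    list(C_tot = C_fit,
         target_amplitude = target_amplitude,
         achieved_amplitude = amp_at(C_fit),
         R_tot = R_tot, dt = dt, window = window, P0 = P0,
         C_range = C_range, n_grid = n_grid,
         grid = data.frame(C_tot = grid, amplitude = amps)),
    class = "compliance_fit"
  )
}

#' @export
print.compliance_fit <- function(x, ...) {
  cat(sprintf(
    "<compliance_fit> C_tot = %.4f ml/mmHg (target %.3g mmHg, achieved %.4g mmHg)\n",
    x$C_tot, x$target_amplitude, x$achieved_amplitude))
  cat(sprintf("  grid: %d points on (%g, %g], dt = %g s, window [%g, %g] s, P0 = %g\n",
              x$n_grid, x$C_range[1L], x$C_range[2L], x$dt,
              x$window[1L], x$window[2L], x$P0))
  invisible(x)
}
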