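#' Report metrics for a case run
#'
#' Computes, over a time window covering whole periods of the active
#' sources: mean pressure per compartment; intracranial pressure pulsation
#' amplitude (cranial SAS compartment, the interstitial-outlet reference);
#' aqueduct and foramen-magnum (spinal SAS cross-section) flow amplitudes
#' and means; the amplitude of the pointwise pressure difference between
#' the ventricles and the spinal SAS (the spatial "lateral ventricle to
#' upper spinal SAS" probe); per-outlet flow amplitudes and means; peak
#' aqueduct velocity (max |flow| / area); and two clinical range checks:
#' mean intracranial pressure within 7-15 mmHg and maximum pressure below
#' the 22 mmHg traumatic-brain-injury management threshold.
#'
#' All amplitudes use the half peak-to-peak convention of
#' [pulsation_amplitude()].
#'
#' @param result a \code{"csf_result"} from [run_network()].
#' @param case a \code{"case_definition"} (for bookkeeping; stored in the
#'   output). May be \code{NULL}.
#' @param window closed time interval \code{[t0, t1]} (s); must lie within
#'   the simulated span and should cover whole periods of every active
#'   source.
#' @return An object of class \code{"case_metrics"} (a list; see Details).
#' @export
compute_metrics <- function(result, case = NULL, window) {
  stopifnot(inherits(result, "csf_result"), length(window) == 2L,
            window[2L] > window[1L])
  if (window[1L] < min(result$time) - attr(result, "dt") ||
      window[2L] > max(result$time) + 1e-9)
    stop(sprintf("window [%g, %g] is outside the simulated span [%g, %g]",
                 window[1L], window[2L], min(result$time), max(result$time)))
  keep <- result$time >= window[1L] - 1e-9 & result$time <= window[2L] + 1e-9
  w <- result[keep, , drop = FALSE]
  amp <- function(x) (max(x) - min(x)) / 2

  pcols <- grep("^P_", names(w), value = TRUE)
  mean_pressure <- vapply(w[pcols], mean, numeric(1L))
  names(mean_pressure) <- sub("^P_", "", names(mean_pressure))

  icp <- w[["P_cranialSAS"]]
  if (is.null(icp)) icp <- w[[pcols[1L]]]

  ocols <- grep("^Qout_", names(w), value = TRUE)
  outlet_amp <- vapply(w[ocols], amp, numeric(1L))
  outlet_mean <- vapply(w[ocols], mean, numeric(1L))
  names(outlet_amp) <- names(outlet_mean) <- sub("^Qout_", "", ocols)

  area <- attr(result, "conduit_area")
  aq <- w[["Q_aqueduct"]]
  fm <- w[["Q_foramen_magnum"]]
  dP <- if (all(c("P_ventricles", "P_spinalSAS") %in% names(w)))
    w[["P_ventricles"]] - w[["P_spinalSAS"]] else NULL

  structure(list(
    case_id = if (!is.null(case)) case$id else NA_character_,
    window = window,
    mean_pressure = mean_pressure,
    pressure_pulsation_amplitude = amp(icp),
    aqueduct_flow_amplitude = if (!is.null(aq)) amp(aq) else NA_real_,
    aqueduct_flow_mean = if (!is.null(aq)) mean(aq) else NA_real_,
    spinal_flow_amplitude = if (!is.null(fm)) amp(fm) else NA_real_,
    spinal_flow_mean = if (!is.null(fm)) mean(fm) else NA_real_,
    lv_to_sas_pressure_difference_amplitude =
      if (!is.null(dP)) amp(dP) else NA_real_,
    outlet_flow_amplitudes = outlet_amp,
    outlet_flow_means = outlet_mean,
    total_outflow_mean = sum(outlet_mean),
    peak_aqueduct_velocity = if (!is.null(aq))
      max(abs(aq)) / (area[["aqueduct"]] * 1e-2) else NA_real_,  # cm/s
    in_physiological_range =
      mean(icp) >= 7 && mean(icp) <= 15,
    below_tbi_threshold = max(icp) < 22
  ), class = "case_metrics")
}

#' @export
print.case_metrics <- function(x, ...) {
  cat(sprintf("<case_metrics> case %s, window [%g, %g] s\n",
              x$case_id, x$window[1L], x$window[2L]))
  cat("  mean pressures (mmHg):",
      paste(sprintf("%s=%.3f", names(x$mean_pressure), x$mean_pressure),
            collapse = ", "), "\n")
  cat(sprintf("  ICP pulsation amplitude: %.3f mmHg\n",
              x$pressure_pulsation_amplitude))
  cat(sprintf("  aqueduct flow: amplitude %.4f ml/s, mean %.4f ml/min, peak velocity %.2f cm/s\n",
              x$aqueduct_flow_amplitude, 60 * x$aqueduct_flow_mean,
              x$peak_aqueduct_velocity))
  cat(sprintf("  spinal (foramen magnum) flow amplitude: %.3f ml/s\n",
              x$spinal_flow_amplitude))
  cat(sprintf("  ventricle-to-spinal-SAS pressure difference amplitude: %.4f mmHg\n",
              x$lv_to_sas_pressure_difference_amplitude))
  cat("  outlet flow amplitudes (ml/s):",
      paste(sprintf("%s=%.3f", names(x$outlet_flow_amplitudes),
                    x$outlet_flow_amplitudes), collapse = ", "), "\n")
  cat(sprintf("  total mean outflow: %.4f ml/min\n",
              60 * x$total_outflow_mean))
  cat(sprintf("  mean ICP in 7-15 mmHg: %s; max below 22 mmHg: %s\n",
              x$in_physiological_range, x$below_tbi_threshold))
  invisible(x)
}

#' Run a reference case end to end
#'
#' Composes [build_case()], [run_network()] and [compute_metrics()]. The
#' metrics window is the last 5 s of the run: the last five cardiac cycles
#' for case A (no respiration) and the last full respiratory cycle for
#' cases B-E (the respiratory period, 1/0.2 Hz, is 5 s).
#'
#' @param id case id \code{"A"}-\code{"E"} or a \code{"case_definition"}.
#' @param duration simulated time (s), default 25 (25 cardiac cycles).
#' @param dt time step (s), default 0.05.
#' @param solver \code{"monolithic"} or \code{"partitioned"}.
#' @param initial_pressure mmHg, default 10 (the target mean).
#' @param ... further arguments to [run_network()].
#' @return List with \code{definition}, \code{network}, \code{result}
#'   (the time series) and \code{metrics}.
#' @export
#' @examples
#' \donttest{
#' caseA <- run_case("A")
#' caseA$metrics
#' }
run_case <- function(id, duration = 25, dt = 0.05,
                     solver = c("monolithic", "partitioned"),
                     initial_pressure = 10, ...) {
  solver <- match.arg(solver)
  cs <- build_case(id)
  result <- run_network(cs$network, duration = duration, dt = dt,
                        solver = solver,
                        initial_pressure = initial_pressure, ...)
  window <- c(duration - 5, duration)
  metrics <- compute_metrics(result, cs$definition, window)
  c(cs, list(result = result, metrics = metrics))
}
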