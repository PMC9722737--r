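#' Write a simulation time series as CSV
#'
#' One row per step with a fixed column order (time, compartment pressures,
#' conduit flows, outlet flows), full precision (up to 15 significant
#' digits). Re-running the same configuration and re-writing yields a
#' byte-identical file.
#'
#' @param result a \code{"csf_result"} from [run_network()] or the
#'   time/pressure data frame from [simulate_0d()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(result, path) {
  stopifnot(is.data.frame(result), nrow(result) >= 1L)
  df <- as.data.frame(lapply(result, function(x)
    formatC(x, digits = 15, format = "g")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#'
#' @param path CSV path.
#' @param conduit_area optional named vector of conduit areas (mm^2) to
#'   restore the metadata needed by [compute_metrics()] (velocity).
#' @param dt time step (s); inferred from the time column when omitted.
#' @return A \code{"csf_result"} data frame.
#' @export
read_timeseries <- function(path, conduit_area = NULL, dt = NULL) {
  df <- utils::read.csv(path)
  if (!"time" %in% names(df)) stop("time series file has no 'time' column")
  if (is.null(dt)) dt <- stats::median(diff(df$time))
  attr(df, "dt") <- dt
  qcols <- grep("^Q_", names(df), value = TRUE)
  if (is.null(conduit_area) && length(qcols)) {
    conduit_area <- stats::setNames(rep(NA_real_, length(qcols)),
                                    sub("^Q_", "", qcols))
  }
  attr(df, "conduit_area") <- conduit_area
  class(df) <- c("csf_result", "data.frame")
  df
}

#' Write a structured run summary
#'
#' Serializes a metrics object ([compute_metrics()]) or a compliance fit
#' ([tune_total_compliance()]) to YAML. For a fit, the
#' amplitude-versus-compliance curve can additionally be written as CSV
#' (one row per grid point) for plotting.
#'
#' @param x a \code{"case_metrics"} or \code{"compliance_fit"} object.
#' @param path output YAML path.
#' @param curve_path optional CSV path for the tuning curve (fits only).
#' @return \code{path}, invisibly.
#' @export
write_run_summary <- function(x, path, curve_path = NULL) {
  if (inherits(x, "compliance_fit")) {
    rec <- list(
      fitted_C_tot = x$C_tot,
      target_amplitude = x$target_amplitude,
      achieved_amplitude = x$achieved_amplitude,
      R_tot = x$R_tot, dt = x$dt, P0 = x$P0,
      window = as.list(x$window),
      grid = list(range = as.list(x$C_range), n = x$n_grid))
    if (!is.null(curve_path))
      utils::write.csv(x$grid, curve_path, row.names = FALSE)
  } else if (inherits(x, "case_metrics")) {
    rec <- lapply(unclass(x), function(v)
      if (length(v) > 1L) as.list(v) else v)
  } else {
    stop("'x' must be a case_metrics or compliance_fit object")
  }
  writeLines(yaml::as.yaml(rec, precision = 15L), path)
  invisible(path)
}

#' Plot a network time series
#'
#' Base-graphics overview: compartment pressures (top) and conduit/outlet
#' flows (bottom) against time.
#'
#' @param x a \code{"csf_result"}.
#' @param which \code{"pressure"}, \code{"flow"} or \code{"both"}.
#' @param ... ignored.
#' @return \code{x}, invisibly.
#' @export
plot.csf_result <- function(x, which = c("both", "pressure", "flow"), ...) {
  which <- match.arg(which)
  pcols <- grep("^P_", names(x), value = TRUE)
  qcols <- grep("^(Q_|Qout_|pressure)", names(x), value = TRUE)
  panels <- (which == "both") + 1L
  op <- graphics::par(mfrow = c(panels, 1L), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  if (which %in% c("both", "pressure") && length(pcols)) {
    graphics::matplot(x$time, as.matrix(x[pcols]), type = "l", lty = 1,
                      xlab = "time (s)", ylab = "pressure (mmHg)")
    graphics::legend("topright", legend = sub("^P_", "", pcols),
                     col = seq_along(pcols), lty = 1, cex = 0.8, bty = "n")
  }
  if (which %in% c("both", "flow") && length(qcols)) {
    graphics::matplot(x$time, as.matrix(x[qcols]), type = "l", lty = 1,
                      xlab = "time (s)", ylab = "flow (ml/s)")
    graphics::legend("topright", legend = qcols, col = seq_along(qcols),
                     lty = 1, cex = 0.8, bty = "n")
  }
  invisible(x)
}
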