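#' Inlet flow source
#'
#' A volumetric flow boundary condition attached to a network compartment.
#' The signal is \code{mean_flow + amplitude * sin(2*pi*frequency*t + phase)};
#' a constant source (e.g. CSF production) has \code{amplitude = 0}.
#'
#' The default physiological sources are: constant production 6.67e-3 ml/s at
#' the ventricles; a 1 Hz cardiac source of amplitude 0.11 ml/s at the
#' ventricles (periventricular arterial pulsation); a 1 Hz cardiac source of
#' amplitude 5.05 ml/s in the basilar region (large-artery volume change);
#' and a 0.2 Hz respiratory venous source of amplitude 1.01 ml/s at the
#' cranial subarachnoid space. See [default_inlet_sources()].
#'
#' @param name identifier, e.g. \code{"production"}.
#' @param node identifier of the compartment the source discharges into.
#' @param mean_flow mean volumetric flow (ml/s).
#' @param amplitude sinusoid amplitude (ml/s), \code{>= 0}.
#' @param frequency sinusoid frequency (Hz), \code{>= 0}.
#' @param phase phase at \code{t = 0} (radians). All stock sources use 0.
#' @return An object of class \code{"inlet_source"}.
#' @seealso [evaluate_source()], [combined_inflow()]
#' @export
#' @examples
#' prod <- inlet_source("production", "ventricles", mean_flow = 6.67e-3)
#' evaluate_source(prod, 3.2)
inlet_source <- function(name, node, mean_flow = 0, amplitude = 0,
                         frequency = 0, phase = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(node), length(node) == 1L)
  if (!is.finite(mean_flow)) stop("'mean_flow' must be finite")
  if (!is.finite(amplitude) || amplitude < 0)
    stop("'amplitude' must be finite and >= 0")
  if (!is.finite(frequency) || frequency < 0)
    stop("'frequency' must be finite and >= 0")
  structure(
    list(name = name, node = node, mean_flow = mean_flow,
         amplitude = amplitude, frequency = frequency, phase = phase),
    class = "inlet_source"
  )
}

#' @export
print.inlet_source <- function(x, ...) {
  if (x$amplitude == 0) {
    cat(sprintf("<inlet_source> %s @ %s: constant %.4g ml/s\n",
                x$name, x$node, x$mean_flow))
  } else {
    cat(sprintf(
      "<inlet_source> %s @ %s: %.4g + %.4g*sin(2*pi*%g*t%s) ml/s\n",
      x$name, x$node, x$mean_flow, x$amplitude, x$frequency,
      if (x$phase != 0) sprintf(" + %.3g", x$phase) else ""))
  }
  invisible(x)
}

#' Evaluate an inlet source at time t
#'
#' @param source an [inlet_source()].
#' @param t time (s), scalar or vector, \code{>= 0}.
#' @return Volumetric flow (ml/s), same length as \code{t}.
#' @export
evaluate_source <- function(source, t) {
  stopifnot(inherits(source, "inlet_source"))
  if (any(t < 0)) stop("'t' must be >= 0")
  source$mean_flow +
    source$amplitude * sin(2 * pi * source$frequency * t + source$phase)
}

#' Flow measurement inputs behind the cardiac source amplitudes
#'
#' Bundles the phase-contrast flow measurements and the spinal compliance
#' fraction from which the two cardiac source amplitudes are derived:
#' \code{Q_v3}, the aqueduct/third-ventricle stroke flow amplitude;
#' \code{Q_c}, the cervical (foramen magnum) flow amplitude; and
#' \code{c_sp}, the fraction of total craniospinal compliance attributed to
#' the spinal compartment (0.63-0.73 supine in vivo).
#'
#' @param Q_v3 aqueduct flow amplitude (ml/s), \code{>= 0}.
#' @param Q_c cervical flow amplitude (ml/s), \code{>= Q_v3}.
#' @param c_sp spinal compliance fraction, in (0, 1].
#' @return An object of class \code{"measurement_inputs"}.
#' @seealso [arterial1_from_aqueduct()], [arterial2_from_measurements()]
#' @export
measurement_inputs <- function(Q_v3, Q_c, c_sp) {
  if (!is.finite(Q_v3) || Q_v3 < 0) stop("'Q_v3' must be >= 0")
  if (!is.finite(Q_c) || Q_c < Q_v3) stop("'Q_c' must be >= Q_v3")
  if (!is.finite(c_sp) || c_sp <= 0 || c_sp > 1)
    stop("'c_sp' must lie in (0, 1]")
  structure(list(Q_v3 = Q_v3, Q_c = Q_c, c_sp = c_sp),
            class = "measurement_inputs")
}

#' Periventricular cardiac source amplitude from aqueduct flow
#'
#' By conservation of mass through the ventricles, the amplitude of the
#' periventricular arterial source equals the measured aqueduct stroke-flow
#' amplitude: \code{Q_arterial1 = Q_v3}.
#'
#' @param m a [measurement_inputs()].
#' @return Amplitude (ml/s).
#' @export
arterial1_from_aqueduct <- function(m) {
  stopifnot(inherits(m, "measurement_inputs"))
  m$Q_v3
}

#' Basilar cardiac source amplitude from cervical measurements
#'
#' The large-artery volume change driving cervical CSF pulsation is estimated
#' as \code{Q_arterial2 = (Q_c - Q_v3) / c_sp}: only the fraction
#' \code{c_sp} of the total arterial volume change is buffered through the
#' spinal canal where \code{Q_c} is measured.
#'
#' @param m a [measurement_inputs()].
#' @return Amplitude (ml/s).
#' @export
#' @examples
#' arterial2_from_measurements(measurement_inputs(0.11, 3.5, 0.67))
arterial2_from_measurements <- function(m) {
  stopifnot(inherits(m, "measurement_inputs"))
  (m$Q_c - m$Q_v3) / m$c_sp
}

#' Default inlet source set
#'
#' The four stock physiological sources at their default amplitudes,
#' attached to their default compartments. The respiratory venous source is
#' dropped (amplitude 0 case) when \code{respiration = FALSE}.
#'
#' @param respiration include the 0.2 Hz venous source? Default \code{TRUE}.
#' @param production mean production (ml/s). Default 6.67e-3 (0.4 ml/min).
#' @param arterial1,arterial2 cardiac (1 Hz) amplitudes (ml/s).
#' @param venous1 respiratory (0.2 Hz) amplitude (ml/s).
#' @param cardiac_frequency,respiratory_frequency Hz.
#' @return Named list of [inlet_source()] objects.
#' @export
default_inlet_sources <- function(respiration = TRUE,
                                  production = 6.67e-3,
                                  arterial1 = 0.11,
                                  arterial2 = 5.05,
                                  venous1 = 1.01,
                                  cardiac_frequency = 1,
                                  respiratory_frequency = 0.2) {
  src <- list(
    production = inlet_source("production", "ventricles",
                              mean_flow = production),
    arterial1 = inlet_source("arterial1", "ventricles",
                             amplitude = arterial1,
                             frequency = cardiac_frequency),
    arterial2 = inlet_source("arterial2", "basilar",
                             amplitude = arterial2,
                             frequency = cardiac_frequency)
  )
  if (respiration)
    src$venous1 <- inlet_source("venous1", "cranialSAS",
                                amplitude = venous1,
                                frequency = respiratory_frequency)
  src
}

#' Combined 0D inflow
#'
#' Sum of all inlet source signals at time \code{t}: the single inflow seen
#' by the lumped 0D pressure model, in which the spatial placement of the
#' sources is ignored.
#'
#' @param sources list of [inlet_source()] objects.
#' @param t time (s), scalar or vector.
#' @return Volumetric flow (ml/s), same length as \code{t}.
#' @export
combined_inflow <- function(sources, t) {
  stopifnot(is.list(sources), length(sources) >= 1L)
  out <- 0
  for (s in sources) out <- out + evaluate_source(s, t)
  out
}
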