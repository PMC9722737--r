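# Reference cases A-E.
#
# A: cardiac pulsations only (no respiration); compliance on the
#    interstitial (33%) and spinal (67%) outlets; C_tot = 0.17 ml/mmHg.
# B: A + respiratory venous source; C_tot = 0.51 ml/mmHg.
# C: as B, compliance spread over all four outlets (11/67/11/11).
# D: as B with interstitial and spinal compliance swapped (67/33).
# E: as B with total compliance doubled (1.01 ml/mmHg).
# Outflow fractions are 20/20/30/30 (int/sp/lym/av) with R_tot = 1500
# mmHg.s/ml in every case.

.case_table <- list(
  A = list(venous1 = 0,    C_tot = 0.17,
           c = c(int = 0.33, sp = 0.67, lym = 0, av = 0)),
  B = list(venous1 = 1.01, C_tot = 0.51,
           c = c(int = 0.33, sp = 0.67, lym = 0, av = 0)),
  C = list(venous1 = 1.01, C_tot = 0.51,
           c = c(int = 0.11, sp = 0.67, lym = 0.11, av = 0.11)),
  D = list(venous1 = 1.01, C_tot = 0.51,
           c = c(int = 0.67, sp = 0.33, lym = 0, av = 0)),
  E = list(venous1 = 1.01, C_tot = 1.01,
           c = c(int = 0.33, sp = 0.67, lym = 0, av = 0))
)

#' Case definition (A-E)
#'
#' Returns the full parameterization of one reference case: source
#' amplitudes, outflow fractions, compliance fractions and total
#' resistance/compliance.
#'
#' @param id one of \code{"A"} to \code{"E"}.
#' @return An object of class \code{"case_definition"}: a list with
#'   \code{id}, \code{production}, \code{arterial1}, \code{arterial2},
#'   \code{venous1} (ml/s), \code{q}, \code{c} (fractions), \code{R_tot}
#'   (mmHg.s/ml), \code{C_tot} (ml/mmHg).
#' @export
case_definition <- function(id) {
  id <- as.character(id)
  if (!id %in% names(.case_table))
    stop("unknown case id '", id, "' (expected one of A, B, C, D, E)")
  row <- .case_table[[id]]
  structure(
    list(id = id,
         production = 6.67e-3, arterial1 = 0.11, arterial2 = 5.05,
         venous1 = row$venous1,
         q = c(int = 0.2, sp = 0.2, lym = 0.3, av = 0.3),
         c = row$c, R_tot = 1500, C_tot = row$C_tot),
    class = "case_definition"
  )
}

#' @export
print.case_definition <- function(x, ...) {
  cat(sprintf("<case_definition> case %s\n", x$id))
  cat(sprintf("  sources (ml/s): production %.3g, arterial1 %.3g, arterial2 %.3g, venous1 %.3g\n",
              x$production, x$arterial1, x$arterial2, x$venous1))
  cat(sprintf("  R_tot %g mmHg.s/ml, C_tot %g ml/mmHg\n", x$R_tot, x$C_tot))
  cat("  q:", paste(sprintf("%s=%g", names(x$q), x$q), collapse = ", "), "\n")
  cat("  c:", paste(sprintf("%s=%g", names(x$c), x$c), collapse = ", "), "\n")
  invisible(x)
}

#' Build a case: definition plus configured network
#'
#' Wires the case parameters onto the default craniospinal network:
#' per-outlet resistances from the outflow fractions
#' ([allocate_resistances()]) and per-outlet compliances from the
#' compliance fractions ([allocate_compliances()]); outlets with a zero
#' compliance fraction become pure resistors. The respiratory source is
#' present only when the case's venous amplitude is nonzero.
#'
#' @param id case id, \code{"A"} to \code{"E"}, or a
#'   \code{"case_definition"}.
#' @return List with elements \code{definition} and \code{network}.
#' @export
#' @examples
#' cs <- build_case("A")
#' cs$definition
build_case <- function(id) {
  def <- if (inherits(id, "case_definition")) id else case_definition(id)
  alloc <- outlet_allocation(def$R_tot, def$C_tot, q = def$q, c = def$c)
  src <- default_inlet_sources(respiration = def$venous1 > 0,
                               production = def$production,
                               arterial1 = def$arterial1,
                               arterial2 = def$arterial2,
                               venous1 = def$venous1)
  net <- default_network(sources = src,
                         outlet_R = allocate_resistances(alloc),
                         outlet_C = allocate_compliances(alloc))
  list(definition = def, network = net)
}
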