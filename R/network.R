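#' Fluid properties
#'
#' CSF is modeled as water at body-ish conditions.
#'
#' @param density kg/m^3, default 998.2.
#' @param viscosity dynamic viscosity, kg/(m.s), default 0.001003.
#' @return An object of class \code{"fluid_properties"}.
#' @export
fluid_properties <- function(density = 998.2, viscosity = 0.001003) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Poiseuille resistance of a circular conduit
#'
#' Fully developed laminar flow in a circular tube: \code{R = 8 mu L /
#' (pi r^4)}, converted from Pa.s/m^3 to clinical units (mmHg.s/ml).
#'
#' @param length conduit length (mm), \code{> 0}.
#' @param radius conduit radius (mm), \code{> 0}.
#' @param fluid a [fluid_properties()].
#' @return Hydraulic resistance (mmHg.s/ml).
#' @export
#' @examples
#' poiseuille_resistance(15, sqrt(10 / pi))  # the aqueduct default
poiseuille_resistance <- function(length, radius, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.finite(length) || length <= 0) stop("'length' must be > 0")
  if (!is.finite(radius) || radius <= 0) stop("'radius' must be > 0")
  L <- length * 1e-3
  r <- radius * 1e-3
  R_si <- 8 * fluid$viscosity * L / (pi * r^4)  # Pa.s/m^3
  R_si * 1e-6 / PA_PER_MMHG
}

#' Laminar resistance of a thin annular slit
#'
#' The subarachnoid passages are annular gaps around the brainstem and
#' spinal cord rather than circular tubes; a thin gap of height h unrolled
#' over circumference l behaves as plane Poiseuille flow with
#' \code{R = 12 mu L / (l h^3)}.
#'
#' @param length slit length in the flow direction (mm), \code{> 0}.
#' @param gap gap height (mm), \code{> 0}.
#' @param circumference unrolled width of the gap (mm), \code{> 0}.
#' @param fluid a [fluid_properties()].
#' @return Hydraulic resistance (mmHg.s/ml).
#' @export
slit_resistance <- function(length, gap, circumference,
                            fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(!is.finite(c(length, gap, circumference))) ||
      any(c(length, gap, circumference) <= 0))
    stop("'length', 'gap' and 'circumference' must be > 0")
  L <- length * 1e-3
  h <- gap * 1e-3
  l <- circumference * 1e-3
  R_si <- 12 * fluid$viscosity * L / (l * h^3)
  R_si * 1e-6 / PA_PER_MMHG
}

#' Rigid compartment
#'
#' A lumped CSF space with no storage of its own: all compliance lives in
#' the windkessel outlets, as in a rigid-walled model.
#'
#' @param name identifier, e.g. \code{"ventricles"}.
#' @return An object of class \code{"compartment"}.
#' @export
compartment <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name), class = "compartment")
}

#' Conduit between two compartments
#'
#' A hydraulic connection with a linear (laminar) resistance. Positive flow
#' runs from \code{from} to \code{to}. Resistance may be given explicitly or
#' derived from geometry via [poiseuille_resistance()] /
#' [slit_resistance()] by the caller. The cross-sectional area is used only
#' for velocity and Reynolds-number diagnostics.
#'
#' @param name identifier.
#' @param from,to compartment names.
#' @param resistance hydraulic resistance (mmHg.s/ml), \code{> 0}.
#' @param area cross-sectional area (mm^2), \code{> 0}.
#' @param hydraulic_diameter mm; defaults to the circular-equivalent
#'   diameter \code{2*sqrt(area/pi)}.
#' @return An object of class \code{"conduit"}.
#' @export
conduit <- function(name, from, to, resistance, area,
                    hydraulic_diameter = 2 * sqrt(area / pi)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(from), is.character(to))
  if (!is.finite(resistance) || resistance <= 0)
    stop("'resistance' must be > 0")
  if (!is.finite(area) || area <= 0) stop("'area' must be > 0")
  structure(list(name = name, from = from, to = to,
                 resistance = resistance, area = area,
                 hydraulic_diameter = hydraulic_diameter),
            class = "conduit")
}

#' Windkessel absorption outlet
#'
#' One absorption pathway attached to a compartment: resistance R and
#' compliance C in parallel against external pressure \code{P_out}
#' (venous/lymphatic side, taken as 0). \code{C = 0} gives a pure resistor.
#'
#' @param name identifier (\code{int}, \code{sp}, \code{lym}, \code{av}).
#' @param node compartment the outlet drains.
#' @param R resistance (mmHg.s/ml), \code{> 0}.
#' @param C compliance (ml/mmHg), \code{>= 0}.
#' @param P_out external pressure (mmHg), default 0.
#' @return An object of class \code{"windkessel_outlet"}.
#' @export
windkessel_outlet <- function(name, node, R, C = 0, P_out = 0) {
  stopifnot(is.character(name), length(name) == 1L, is.character(node))
  if (!is.finite(R) || R <= 0) stop("'R' must be > 0")
  if (!is.finite(C) || C < 0) stop("'C' must be >= 0")
  structure(list(name = name, node = node, R = R, C = C, P_out = P_out),
            class = "windkessel_outlet")
}

#' Hydraulic network of rigid compartments
#'
#' Assembles compartments, conduits, windkessel outlets and inlet sources
#' into a connected network and validates the topology: every conduit,
#' outlet and source must reference an existing compartment; the graph must
#' be connected; and at least one outlet must exist (otherwise pressure is
#' undefined under net production).
#'
#' @param compartments list of [compartment()] objects.
#' @param conduits list of [conduit()] objects.
#' @param outlets list of [windkessel_outlet()] objects.
#' @param sources list of [inlet_source()] objects.
#' @param fluid a [fluid_properties()].
#' @return An object of class \code{"hydraulic_network"}.
#' @seealso [default_network()], [run_network()]
#' @export
hydraulic_network <- function(compartments, conduits, outlets, sources,
                              fluid = fluid_properties()) {
  stopifnot(is.list(compartments), length(compartments) >= 1L,
            is.list(conduits), is.list(outlets), is.list(sources))
  comp_names <- vapply(compartments, function(x) {
    stopifnot(inherits(x, "compartment")); x$name
  }, character(1L))
  if (anyDuplicated(comp_names)) stop("duplicate compartment names")
  ref_check <- function(what, node) {
    if (!node %in% comp_names)
      stop(sprintf("%s references unknown compartment '%s'", what, node))
  }
  for (cd in conduits) {
    stopifnot(inherits(cd, "conduit"))
    ref_check(paste0("conduit '", cd$name, "'"), cd$from)
    ref_check(paste0("conduit '", cd$name, "'"), cd$to)
    if (cd$from == cd$to) stop("conduit '", cd$name, "' is a self-loop")
  }
  if (length(outlets) == 0L)
    stop("network needs at least one outlet: pressure is undefined under net production")
  for (o in outlets) {
    stopifnot(inherits(o, "windkessel_outlet"))
    ref_check(paste0("outlet '", o$name, "'"), o$node)
  }
  for (s in sources) {
    stopifnot(inherits(s, "inlet_source"))
    ref_check(paste0("source '", s$name, "'"), s$node)
  }
  # connectivity over conduit edges
  if (length(comp_names) > 1L) {
    reach <- comp_names[1L]
    repeat {
      grew <- FALSE
      for (cd in conduits) {
        if (cd$from %in% reach && !(cd$to %in% reach)) {
          reach <- c(reach, cd$to); grew <- TRUE
        } else if (cd$to %in% reach && !(cd$from %in% reach)) {
          reach <- c(reach, cd$from); grew <- TRUE
        }
      }
      if (!grew) break
    }
    if (length(reach) < length(comp_names))
      stop("network is not connected: unreachable compartment(s) ",
           paste(setdiff(comp_names, reach), collapse = ", "))
  }
  names(outlets) <- vapply(outlets, `[[`, character(1L), "name")
  names(conduits) <- vapply(conduits, `[[`, character(1L), "name")
  names(sources) <- vapply(sources, `[[`, character(1L), "name")
  structure(list(compartments = comp_names, conduits = conduits,
                 outlets = outlets, sources = sources, fluid = fluid),
            class = "hydraulic_network")
}

#' @export
print.hydraulic_network <- function(x, ...) {
  cat(sprintf("<hydraulic_network> %d compartments, %d conduits, %d outlets, %d sources\n",
              length(x$compartments), length(x$conduits),
              length(x$outlets), length(x$sources)))
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  for (cd in x$conduits)
    cat(sprintf("  conduit %s: %s -> %s, R = %.4g mmHg.s/ml, area = %g mm^2\n",
                cd$name, cd$from, cd$to, cd$resistance, cd$area))
  for (o in x$outlets)
    cat(sprintf("  outlet %s @ %s: R = %g, C = %g\n", o$name, o$node, o$R, o$C))
  invisible(x)
}

#' Default craniospinal network geometry
#'
#' Four compartments: ventricles, basilar region, cranial subarachnoid
#' space (SAS) and spinal SAS. Conduits: the cerebral aqueduct (ventricles
#' to basilar; circular, length 15 mm, area 10 mm^2), the tentorial passage
#' (basilar to cranial SAS; annular slit, length 30 mm, gap 3 mm,
#' circumference 50 mm) and the foramen magnum passage (basilar to spinal
#' SAS; annular slit, length 30 mm, gap 1.5 mm, circumference 100 mm).
#' Slit passages use [slit_resistance()]; the aqueduct uses
#' [poiseuille_resistance()]. Sources attach per the physiological layout:
#' production and arterial1 at the ventricles, arterial2 at the basilar
#' region, venous1 at the cranial SAS. Outlets int, lym and av drain the
#' cranial SAS; sp drains the spinal SAS.
#'
#' @param sources named list of [inlet_source()] objects; default
#'   [default_inlet_sources()].
#' @param outlet_R named numeric vector of outlet resistances (mmHg.s/ml).
#' @param outlet_C named numeric vector of outlet compliances (ml/mmHg),
#'   same names.
#' @param fluid a [fluid_properties()].
#' @return A [hydraulic_network()].
#' @export
default_network <- function(sources = default_inlet_sources(),
                            outlet_R = c(int = 7500, sp = 7500,
                                         lym = 5000, av = 5000),
                            outlet_C = c(int = 0.33 * 0.51, sp = 0.67 * 0.51,
                                         lym = 0, av = 0),
                            fluid = fluid_properties()) {
  stopifnot(identical(sort(names(outlet_R)), sort(names(outlet_C))))
  outlet_node <- c(int = "cranialSAS", sp = "spinalSAS",
                   lym = "cranialSAS", av = "cranialSAS")
  comps <- lapply(c("ventricles", "basilar", "cranialSAS", "spinalSAS"),
                  compartment)
  conduits <- list(
    conduit("aqueduct", "ventricles", "basilar",
            resistance = poiseuille_resistance(15, sqrt(10 / pi), fluid),
            area = 10),
    conduit("tentorial", "basilar", "cranialSAS",
            resistance = slit_resistance(30, 3, 50, fluid),
            area = 150, hydraulic_diameter = 6),
    conduit("foramen_magnum", "basilar", "spinalSAS",
            resistance = slit_resistance(30, 1.5, 100, fluid),
            area = 150, hydraulic_diameter = 3)
  )
  outlets <- lapply(names(outlet_R), function(nm) {
    node <- if (nm %in% names(outlet_node)) outlet_node[[nm]] else "cranialSAS"
    windkessel_outlet(nm, node, R = outlet_R[[nm]], C = outlet_C[[nm]])
  })
  hydraulic_network(comps, conduits, outlets, unname(sources), fluid)
}

#' Reynolds number in a conduit
#'
#' \code{Re = rho v D_h / mu} with mean velocity \code{v = Q / A}. Used to
#' check the laminar-flow assumption (craniospinal values are at most of
#' order 100).
#'
#' @param flow volumetric flow (ml/s).
#' @param cond a [conduit()].
#' @param fluid a [fluid_properties()].
#' @return Dimensionless Reynolds number (same sign handling as
#'   \code{|flow|}).
#' @export
reynolds_number <- function(flow, cond, fluid = fluid_properties()) {
  stopifnot(inherits(cond, "conduit"), inherits(fluid, "fluid_properties"))
  v <- abs(flow) * 1e-6 / (cond$area * 1e-6)       # m/s
  fluid$density * v * (cond$hydraulic_diameter * 1e-3) / fluid$viscosity
}
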