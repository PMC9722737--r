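# Run configuration: a single human-readable YAML file per run.
#
# Either a case shorthand
#     case: B
#     run: {duration: 25}
# or a fully explicit specification with sections `sources`, `allocation`
# and (optionally) `network`. Unknown keys are rejected by name so typos
# fail loudly instead of silently running defaults.

.check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(NULL))
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s (allowed: %s)", where,
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  invisible(NULL)
}

.default_run_settings <- function() {
  list(dt = 0.05, duration = 25, solver = "monolithic",
       initial_pressure = 10)
}

.parse_source_entry <- function(e, i) {
  .check_keys(e, c("name", "node", "mean", "amplitude", "frequency", "phase"),
              sprintf("sources[%d]", i))
  if (is.null(e$name) || is.null(e$node))
    stop(sprintf("sources[%d] needs 'name' and 'node'", i))
  inlet_source(e$name, e$node,
               mean_flow = e$mean %||% 0,
               amplitude = e$amplitude %||% 0,
               frequency = e$frequency %||% 0,
               phase = e$phase %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_allocation <- function(a) {
  .check_keys(a, c("R_tot", "C_tot", "q", "c"), "allocation")
  for (f in c("R_tot", "C_tot", "q", "c"))
    if (is.null(a[[f]])) stop("allocation needs '", f, "'")
  outlet_allocation(a$R_tot, a$C_tot,
                    q = unlist(a$q), c = unlist(a$c))
}

.parse_conduit_entry <- function(e, i, fluid) {
  .check_keys(e, c("name", "from", "to", "area", "hydraulic_diameter",
                   "resistance", "geometry"), sprintf("conduits[%d]", i))
  for (f in c("name", "from", "to", "area"))
    if (is.null(e[[f]])) stop(sprintf("conduits[%d] needs '%s'", i, f))
  R <- e$resistance
  if (is.null(R)) {
    g <- e$geometry
    if (is.null(g))
      stop(sprintf("conduits[%d] needs 'resistance' or 'geometry'", i))
    .check_keys(g, c("type", "length", "radius", "gap", "circumference"),
                sprintf("conduits[%d]$geometry", i))
    R <- switch(g$type %||% "circular",
                circular = poiseuille_resistance(g$length, g$radius, fluid),
                slit = slit_resistance(g$length, g$gap, g$circumference,
                                       fluid),
                stop(sprintf("conduits[%d]: unknown geometry type '%s'",
                             i, g$type)))
  }
  hd <- e$hydraulic_diameter %||% (2 * sqrt(e$area / pi))
  conduit(e$name, e$from, e$to, resistance = R, area = e$area,
          hydraulic_diameter = hd)
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, validates it against the schema
#' (unknown keys are rejected with a named error) and expands it into ready
#' simulation objects. A \code{case:} shorthand expands to the full default
#' parameterization of that case; it cannot be combined with explicit
#' \code{sources}/\code{allocation}/\code{network} sections.
#'
#' @param path path to a YAML file (or a YAML string).
#' @return An object of class \code{"run_config"}: a list with
#'   \code{sources}, \code{allocation}, \code{network}
#'   ([hydraulic_network()]), \code{run} (dt, duration, solver,
#'   initial_pressure) and \code{metrics} (window).
#' @seealso [write_config()], [write_case_fixtures()]
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    yaml::yaml.load(path)
  if (!is.list(raw)) stop("configuration must be a YAML mapping")
  .check_keys(raw, c("case", "sources", "allocation", "network", "run",
                     "metrics"), "configuration")
  run <- utils::modifyList(.default_run_settings(), raw$run %||% list())
  .check_keys(run, names(.default_run_settings()), "run")
  if (!run$solver %in% c("monolithic", "partitioned"))
    stop("run$solver must be 'monolithic' or 'partitioned'")

  if (!is.null(raw$case)) {
    if (!is.null(raw$sources) || !is.null(raw$allocation) ||
        !is.null(raw$network))
      stop("'case' shorthand cannot be combined with explicit sources/allocation/network")
    cs <- build_case(raw$case)
    def <- cs$definition
    alloc <- outlet_allocation(def$R_tot, def$C_tot, q = def$q, c = def$c)
    sources <- cs$network$sources
    network <- cs$network
  } else {
    if (is.null(raw$sources) || is.null(raw$allocation))
      stop("configuration needs 'case' or both 'sources' and 'allocation'")
    sources <- lapply(seq_along(raw$sources), function(i)
      .parse_source_entry(raw$sources[[i]], i))
    names(sources) <- vapply(sources, `[[`, character(1L), "name")
    alloc <- .parse_allocation(raw$allocation)
    net_spec <- raw$network
    if (is.null(net_spec)) {
      network <- default_network(sources = sources,
                                 outlet_R = allocate_resistances(alloc),
                                 outlet_C = allocate_compliances(alloc))
    } else {
      .check_keys(net_spec, c("compartments", "conduits", "outlets", "fluid"),
                  "network")
      fl <- net_spec$fluid
      .check_keys(fl, c("density", "viscosity"), "network$fluid")
      fluid <- fluid_properties(fl$density %||% 998.2,
                                fl$viscosity %||% 0.001003)
      comps <- lapply(net_spec$compartments, compartment)
      conduits <- lapply(seq_along(net_spec$conduits), function(i)
        .parse_conduit_entry(net_spec$conduits[[i]], i, fluid))
      R_i <- allocate_resistances(alloc)
      C_i <- allocate_compliances(alloc)
      outlets <- lapply(net_spec$outlets, function(o) {
        .check_keys(o, c("name", "node", "P_out"), "network$outlets[]")
        if (is.null(o$name) || is.null(o$node))
          stop("each outlet needs 'name' and 'node'")
        if (!o$name %in% names(R_i))
          stop("outlet '", o$name, "' has no entry in allocation$q")
        windkessel_outlet(o$name, o$node, R = R_i[[o$name]],
                          C = C_i[[o$name]], P_out = o$P_out %||% 0)
      })
      network <- hydraulic_network(comps, conduits, outlets,
                                   unname(sources), fluid)
    }
  }
  metrics <- raw$metrics %||% list()
  .check_keys(metrics, "window", "metrics")
  window <- metrics$window %||% c(run$duration - 5, run$duration)
  if (length(window) != 2L || window[2L] <= window[1L])
    stop("metrics$window must be an increasing length-2 interval")
  structure(list(sources = sources, allocation = alloc, network = network,
                 run = run, metrics = list(window = as.numeric(window))),
            class = "run_config")
}

#' Write a run configuration
#'
#' Serializes a \code{"run_config"} (or a case id) to the explicit YAML
#' form. \code{load_config(write_config(cfg, path))} reproduces the
#' configuration.
#'
#' @param config a \code{"run_config"} from [load_config()], or a case id
#'   \code{"A"}-\code{"E"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  if (is.character(config) && length(config) == 1L &&
      config %in% c("A", "B", "C", "D", "E")) {
    config <- .case_run_config(config)
  }
  stopifnot(inherits(config, "run_config"))
  srcs <- lapply(config$sources, function(s) list(
    name = s$name, node = s$node, mean = s$mean_flow,
    amplitude = s$amplitude, frequency = s$frequency, phase = s$phase))
  a <- config$allocation
  net <- config$network
  spec <- list(
    sources = unname(srcs),
    allocation = list(R_tot = a$R_tot, C_tot = a$C_tot,
                      q = as.list(a$q), c = as.list(a$c)),
    network = list(
      compartments = as.list(net$compartments),
      conduits = unname(lapply(net$conduits, function(cd) list(
        name = cd$name, from = cd$from, to = cd$to,
        resistance = cd$resistance, area = cd$area,
        hydraulic_diameter = cd$hydraulic_diameter))),
      outlets = unname(lapply(net$outlets, function(o) list(
        name = o$name, node = o$node, P_out = o$P_out))),
      fluid = list(density = net$fluid$density,
                   viscosity = net$fluid$viscosity)
    ),
    run = config$run,
    metrics = list(window = as.list(config$metrics$window))
  )
  writeLines(yaml::as.yaml(spec, precision = 15L), path)
  invisible(path)
}

# expand a case id into a normalized run_config (internal)
.case_run_config <- function(id) {
  cs <- build_case(id)
  def <- cs$definition
  structure(list(
    sources = cs$network$sources,
    allocation = outlet_allocation(def$R_tot, def$C_tot,
                                   q = def$q, c = def$c),
    network = cs$network,
    run = .default_run_settings(),
    metrics = list(window = c(20, 25))
  ), class = "run_config")
}

#' Write the default case fixture configurations
#'
#' Emits one explicit YAML configuration per reference case
#' (\code{case_A.yaml} ... \code{case_E.yaml}) containing the default
#' source table, outlet allocation and network geometry.
#'
#' @param dir output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
write_case_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(c("A", "B", "C", "D", "E"), function(id) {
    p <- file.path(dir, paste0("case_", id, ".yaml"))
    write_config(id, p)
    p
  }, character(1L))
  invisible(paths)
}
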