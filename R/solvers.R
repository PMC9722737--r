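# Per-step solvers for the rigid hydraulic network.
#
# Unknowns are the compartment pressures P at the current time level.
# Conduits contribute a resistive Laplacian G; each windkessel outlet i at
# node k contributes flow Q_i = (P_k - P_out_i)/R_i + C_i (P_k - P_i,prev)/dt,
# i.e. an admittance 1/R_i + C_i/dt on the diagonal plus a history source.
# Node mass balance S + (conduit inflow) - (outlet flow) = 0 closes the
# linear system; compartments are rigid so they store nothing themselves.

# conductance Laplacian and index bookkeeping (internal)
.net_assembly <- function(net) {
  comp <- net$compartments
  n <- length(comp)
  idx <- stats::setNames(seq_len(n), comp)
  G <- matrix(0, n, n, dimnames = list(comp, comp))
  for (cd in net$conduits) {
    g <- 1 / cd$resistance
    i <- idx[[cd$from]]; j <- idx[[cd$to]]
    G[i, i] <- G[i, i] + g
    G[j, j] <- G[j, j] + g
    G[i, j] <- G[i, j] - g
    G[j, i] <- G[j, i] - g
  }
  list(idx = idx, G = G,
       outlet_node = vapply(net$outlets, function(o) idx[[o$node]],
                            integer(1L)),
       outlet_R = vapply(net$outlets, `[[`, numeric(1L), "R"),
       outlet_C = vapply(net$outlets, `[[`, numeric(1L), "C"),
       outlet_Pout = vapply(net$outlets, `[[`, numeric(1L), "P_out"))
}

# source vector at time t (internal)
.net_sources_at <- function(net, idx, t) {
  S <- numeric(length(idx))
  for (s in net$sources) {
    k <- idx[[s$node]]
    S[k] <- S[k] + evaluate_source(s, t)
  }
  S
}

# per-outlet flows given node pressures and previous windkessel states
.outlet_flows <- function(asm, P, P_state, dt) {
  Pn <- P[asm$outlet_node]
  (Pn - asm$outlet_Pout) / asm$outlet_R + asm$outlet_C * (Pn - P_state) / dt
}

.conduit_flows <- function(net, idx, P) {
  vapply(net$conduits,
         function(cd) (P[idx[[cd$from]]] - P[idx[[cd$to]]]) / cd$resistance,
         numeric(1L))
}

#' Initial solver state for a network run
#'
#' The state carries the windkessel pressure of every outlet at the previous
#' accepted time step (the storage memory of the scheme) plus the node
#' pressures used to seed the partitioned iteration.
#'
#' @param net a [hydraulic_network()].
#' @param initial_pressure scalar, or named vector over compartments (mmHg).
#' @return A list with \code{node_pressures} and \code{outlet_pressures}.
#' @export
network_state <- function(net, initial_pressure = 10) {
  stopifnot(inherits(net, "hydraulic_network"))
  comp <- net$compartments
  if (length(initial_pressure) == 1L && is.null(names(initial_pressure))) {
    Pn <- stats::setNames(rep(initial_pressure, length(comp)), comp)
  } else {
    if (!all(comp %in% names(initial_pressure)))
      stop("'initial_pressure' must name every compartment")
    Pn <- initial_pressure[comp]
  }
  Po <- vapply(net$outlets, function(o) unname(Pn[o$node]), numeric(1L))
  list(node_pressures = Pn, outlet_pressures = Po)
}

#' One monolithic implicit step
#'
#' Solves the full linear system in compartment pressures in which conduit
#' flows obey linear resistance laws and every outlet flow obeys the
#' backward-difference windkessel relation, all at the current time level.
#' The windkessel pressure of each outlet equals the pressure of its
#' compartment.
#'
#' @param net a [hydraulic_network()].
#' @param state solver state from [network_state()] or a previous step.
#' @param t current time (s); sources are evaluated at \code{t}.
#' @param dt time step (s).
#' @return A list: \code{node_pressures}, \code{outlet_pressures} (updated
#'   states), \code{outlet_flows}, \code{conduit_flows}, \code{iterations}
#'   (always 1).
#' @export
step_monolithic <- function(net, state, t, dt) {
  stopifnot(inherits(net, "hydraulic_network"), dt > 0)
  asm <- .net_assembly(net)
  A <- asm$G
  b <- .net_sources_at(net, asm$idx, t)
  for (i in seq_along(net$outlets)) {
    k <- asm$outlet_node[i]
    A[k, k] <- A[k, k] + 1 / asm$outlet_R[i] + asm$outlet_C[i] / dt
    b[k] <- b[k] + asm$outlet_Pout[i] / asm$outlet_R[i] +
      asm$outlet_C[i] * state$outlet_pressures[i] / dt
  }
  P <- tryCatch(drop(solve(A, b)),
                error = function(e) stop(
                  "singular pressure system (is an outlet missing?): ",
                  conditionMessage(e)))
  names(P) <- net$compartments
  Qout <- .outlet_flows(asm, P, state$outlet_pressures, dt)
  list(node_pressures = P,
       outlet_pressures = stats::setNames(P[asm$outlet_node],
                                          names(net$outlets)),
       outlet_flows = Qout,
       conduit_flows = .conduit_flows(net, asm$idx, P),
       iterations = 1L)
}

#' One partitioned implicit-coupling step
#'
#' Mirrors the coupling used when the flow solver is a black box: the flow
#' solve maps prescribed pressures at the outlet-bearing compartments to the
#' net outflow of each such compartment; the windkessel relations map flows
#' back to pressures. The scheme first probes each outlet pressure with a
#' small perturbation to estimate the outlet-flow/outlet-pressure
#' sensitivity matrix, then solves the linearized coupled problem and
#' iterates until the interface imbalance (expressed in mmHg) falls below
#' \code{tol}. Because the network is linear the linearization is exact and
#' the scheme converges in two iterations to the monolithic answer.
#'
#' Outlets co-located on one compartment share one interface pressure (the
#' compartment pressure); their individual flows are recovered from their
#' own windkessel relations. With \code{tol = Inf} the step returns after a
#' single explicit (Picard) update - the loosely coupled scheme whose
#' drawbacks motivate the implicit coupling.
#'
#' @inheritParams step_monolithic
#' @param tol convergence tolerance on the interface pressure imbalance
#'   (mmHg). Default 1e-9.
#' @param max_iter maximum coupling iterations. Default 50.
#' @param probe pressure perturbation used to estimate the sensitivity
#'   matrix (mmHg). Default 1e-3.
#' @return As [step_monolithic()]; \code{iterations} reports the number of
#'   coupling iterations (flow solves excluding probes).
#' @export
step_partitioned <- function(net, state, t, dt, tol = 1e-9, max_iter = 50,
                             probe = 1e-3) {
  stopifnot(inherits(net, "hydraulic_network"), dt > 0, max_iter >= 1)
  asm <- .net_assembly(net)
  S <- .net_sources_at(net, asm$idx, t)
  bnodes <- sort(unique(asm$outlet_node))
  inodes <- setdiff(seq_along(net$compartments), bnodes)
  G <- asm$G
  G_II <- G[inodes, inodes, drop = FALSE]
  G_IB <- G[inodes, bnodes, drop = FALSE]
  G_BI <- G[bnodes, inodes, drop = FALSE]
  G_BB <- G[bnodes, bnodes, drop = FALSE]

  # black-box flow solve: prescribed pressures at outlet nodes -> net
  # outflow of each outlet node (and the interior pressure field)
  flow_solve <- function(p) {
    if (length(inodes)) {
      P_I <- drop(solve(G_II, S[inodes] - G_IB %*% p))
      Q_B <- S[bnodes] - drop(G_BI %*% P_I) - drop(G_BB %*% p)
    } else {
      P_I <- numeric(0)
      Q_B <- S[bnodes] - drop(G_BB %*% p)
    }
    list(Q = Q_B, P_I = P_I)
  }

  # aggregated windkessel admittance and history offset per outlet node
  nb <- length(bnodes)
  s_adm <- numeric(nb)
  offs <- numeric(nb)
  for (i in seq_along(net$outlets)) {
    j <- match(asm$outlet_node[i], bnodes)
    s_adm[j] <- s_adm[j] + 1 / asm$outlet_R[i] + asm$outlet_C[i] / dt
    offs[j] <- offs[j] + asm$outlet_Pout[i] / asm$outlet_R[i] +
      asm$outlet_C[i] * state$outlet_pressures[i] / dt
  }

  p <- unname(state$node_pressures[bnodes])
  fs <- flow_solve(p)
  iter <- 1L
  if (identical(tol, Inf)) {
    # explicit coupling: single Picard update of the outlet pressures,
    # interior flow field kept at the old pressures
    p <- (fs$Q + offs) / s_adm
  } else {
    M <- NULL
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      residual <- max(abs((fs$Q + offs - s_adm * p) / s_adm))
      if (residual < tol) { converged <- TRUE; break }
      if (iter == max_iter) break
      if (is.null(M)) {
        # probe the sensitivity of outlet flows to outlet pressures
        M <- matrix(0, nb, nb)
        for (j in seq_len(nb)) {
          pp <- p
          pp[j] <- pp[j] + probe
          M[, j] <- (flow_solve(pp)$Q - fs$Q) / probe
        }
      }
      # linearized coupled solve: s*p - offs = Q(p) ~ fs$Q + M (p - p_cur)
      p <- drop(solve(diag(s_adm, nb) - M, fs$Q - M %*% p + offs))
      fs <- flow_solve(p)
    }
    if (!converged) {
      residual <- max(abs((fs$Q + offs - s_adm * p) / s_adm))
      stop(sprintf(
        "partitioned coupling did not converge in %d iterations (residual %.3g mmHg, tol %.3g)",
        max_iter, residual, tol))
    }
  }

  P <- numeric(length(net$compartments))
  P[bnodes] <- p
  if (length(inodes)) P[inodes] <- fs$P_I
  names(P) <- net$compartments
  Qout <- .outlet_flows(asm, P, state$outlet_pressures, dt)
  list(node_pressures = P,
       outlet_pressures = stats::setNames(P[asm$outlet_node],
                                          names(net$outlets)),
       outlet_flows = Qout,
       conduit_flows = .conduit_flows(net, asm$idx, P),
       iterations = iter)
}

#' Run a network simulation
#'
#' Sequential fixed-step integration of the network from \code{t = dt} to
#' \code{t = duration}. Deterministic: repeated runs of the same
#' configuration are bit-for-bit identical.
#'
#' @param net a [hydraulic_network()].
#' @param duration simulated time (s), \code{>= dt}.
#' @param dt time step (s), default 0.05.
#' @param solver \code{"monolithic"} (default) or \code{"partitioned"}.
#' @param initial_pressure scalar or named vector (mmHg); initializes node
#'   pressures and outlet windkessel states. Default 10 (the target mean),
#'   appropriate for steady-cycle metrics; use 0 for transient studies.
#' @param tol,max_iter,probe passed to [step_partitioned()].
#' @return A data frame of class \code{"csf_result"} with one row per step
#'   and columns \code{time}, \code{P_<compartment>} (mmHg),
#'   \code{Q_<conduit>} (ml/s), \code{Qout_<outlet>} (ml/s). Attributes
#'   \code{conduit_area} (mm^2, named), \code{dt}, \code{solver},
#'   \code{initial_state}.
#' @export
#' @examples
#' net <- build_case("A")$network
#' res <- run_network(net, duration = 2)
#' head(res)
run_network <- function(net, duration, dt = 0.05,
                        solver = c("monolithic", "partitioned"),
                        initial_pressure = 10,
                        tol = 1e-9, max_iter = 50, probe = 1e-3) {
  solver <- match.arg(solver)
  stopifnot(duration >= dt)
  state <- network_state(net, initial_pressure)
  n <- round(duration / dt)
  comp <- net$compartments
  cond <- if (length(net$conduits)) names(net$conduits) else character(0)
  outl <- if (length(net$outlets)) names(net$outlets) else character(0)
  prefix <- function(p, x) if (length(x)) paste0(p, x) else character(0)
  out <- matrix(NA_real_, n, 1L + length(comp) + length(cond) + length(outl))
  colnames(out) <- c("time", prefix("P_", comp), prefix("Q_", cond),
                     prefix("Qout_", outl))
  for (k in seq_len(n)) {
    t <- k * dt
    st <- if (solver == "monolithic") {
      step_monolithic(net, state, t, dt)
    } else {
      step_partitioned(net, state, t, dt, tol = tol, max_iter = max_iter,
                       probe = probe)
    }
    out[k, ] <- c(t, st$node_pressures, st$conduit_flows, st$outlet_flows)
    state$node_pressures <- st$node_pressures
    state$outlet_pressures <- st$outlet_pressures
  }
  res <- as.data.frame(out)
  attr(res, "conduit_area") <- vapply(net$conduits, `[[`, numeric(1L), "area")
  attr(res, "dt") <- dt
  attr(res, "solver") <- solver
  attr(res, "initial_state") <- network_state(net, initial_pressure)
  class(res) <- c("csf_result", "data.frame")
  res
}

#' Node mass-balance residuals of a run
#'
#' Recomputes, per step and compartment, the imbalance between source
#' inflow, signed conduit flow and outlet flow. For a rigid network the
#' residual is zero to linear-solver precision at every step; this is the
#' core conservation invariant of the scheme.
#'
#' @param net the [hydraulic_network()] that produced \code{result}.
#' @param result a \code{"csf_result"} from [run_network()].
#' @return Matrix (steps x compartments) of residuals (ml/s).
#' @export
mass_balance_residuals <- function(net, result) {
  stopifnot(inherits(result, "csf_result"))
  comp <- net$compartments
  res <- matrix(0, nrow(result), length(comp),
                dimnames = list(NULL, comp))
  for (s in net$sources)
    res[, s$node] <- res[, s$node] + evaluate_source(s, result$time)
  for (cd in net$conduits) {
    q <- result[[paste0("Q_", cd$name)]]
    res[, cd$from] <- res[, cd$from] - q
    res[, cd$to] <- res[, cd$to] + q
  }
  for (o in net$outlets)
    res[, o$node] <- res[, o$node] - result[[paste0("Qout_", o$name)]]
  res
}
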