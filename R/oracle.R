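## Closed-form steady-state solver for the passive reduction of a network.
##
## With all voltage-gated channels zeroed, the steady state of the membrane
## equation is a linear nodal system: for deflections dV from the leak
## reversal, G dV = I, where G has the leak on the diagonal plus the edge
## conductances. Directional gap junctions make G asymmetric but still
## uniquely solvable whenever every node leaks. This solver is the
## independent verification oracle for all subthreshold coupling results:
## it linearizes at the leak reversal, and is compared against simulations
## whose channels are likewise zeroed.

#' Build the passive conductance network of a model
#'
#' @param model \code{network_model}.
#' @return object of class \code{conductance_network}: node labels, the
#'   (possibly asymmetric) nodal conductance matrix \code{G} (mS/cm2) and the
#'   per-node leak vector. Channels are ignored (passive linearization at the
#'   leak reversal).
#' @export
passive_conductance_network <- function(model) {
  fl <- flatten_network(model)
  n <- fl$n
  if (any(fl$gleak <= 0))
    stop("analytic oracle requires positive leak at every node; node ",
         fl$labels[which(fl$gleak <= 0)[1]], " has none")
  G <- diag(fl$gleak, n)
  add_edge <- function(G, tgt, src, g) {
    # current into tgt = g * (V_src - V_tgt)
    G[tgt, tgt] <- G[tgt, tgt] + g
    G[tgt, src] <- G[tgt, src] - g
    G
  }
  ie <- fl$internal   # engine edge tables are 0-based
  for (r in seq_len(nrow(ie))) {
    G <- add_edge(G, ie[r, 1] + 1, ie[r, 2] + 1, ie[r, 3])
    G <- add_edge(G, ie[r, 2] + 1, ie[r, 1] + 1, ie[r, 3])
  }
  ge <- fl$gj
  for (r in seq_len(nrow(ge)))
    G <- add_edge(G, ge[r, 1] + 1, ge[r, 2] + 1, ge[r, 3])
  dimnames(G) <- list(fl$labels, fl$labels)
  structure(list(labels = fl$labels, G = G, g_leak = fl$gleak),
            class = "conductance_network")
}

#' Solve the passive steady state
#'
#' @param net \code{conductance_network}.
#' @param injections named numeric vector of steady currents (uA/cm2) keyed
#'   by node label (\code{cell<i>.<label>}), or a full-length vector.
#' @return named vector of steady-state voltage deflections (mV) from rest.
#' @examples
#' m <- network_model(list(zero_channels(make_single_compartment_trn())))
#' net <- passive_conductance_network(m)
#' solve_steady_state(net, c(cell1.S = -1))  # -10 mV for g_leak = 0.1
#' @export
solve_steady_state <- function(net, injections) {
  stopifnot(inherits(net, "conductance_network"))
  n <- length(net$labels)
  I <- numeric(n)
  if (!is.null(names(injections))) {
    miss <- setdiff(names(injections), net$labels)
    if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "))
    I[match(names(injections), net$labels)] <- injections
  } else {
    stopifnot(length(injections) == n)
    I <- injections
  }
  dv <- tryCatch(solve(net$G, I), error = function(e)
    stop("singular nodal system (disconnected or leak-free node): ",
         conditionMessage(e)))
  stats::setNames(as.numeric(dv), net$labels)
}

#' Analytic coupling coefficient of a two-cell passive network
#'
#' Injects a unit steady current at \code{inject_site} of the source cell and
#' returns \code{cc = dV(other cell, record_site) / dV(source, record_site)}.
#'
#' @param model two-cell \code{network_model} (channels ignored).
#' @param direction \code{"12"} (inject cell 1) or \code{"21"}.
#' @param site compartment used for both injection and recording, unless
#'   overridden.
#' @param inject_site,record_site optional overrides.
#' @return dimensionless coupling coefficient.
#' @export
analytic_cc <- function(model, direction = c("12", "21"), site = "S",
                        inject_site = site, record_site = site) {
  direction <- match.arg(direction)
  stopifnot(length(model$cells) == 2)
  src <- if (direction == "12") 1 else 2
  dst <- 3 - src
  net <- passive_conductance_network(model)
  inj <- stats::setNames(-1, paste0("cell", src, ".", inject_site))
  dv <- solve_steady_state(net, inj)
  dv[[paste0("cell", dst, ".", record_site)]] /
    dv[[paste0("cell", src, ".", record_site)]]
}

#' Analytic coupling-coefficient ratio cc_12 / cc_21
#'
#' @inheritParams analytic_cc
#' @return dimensionless ratio from two solves of the nodal system.
#' @export
analytic_cc_ratio <- function(model, site = "S", inject_site = site,
                              record_site = site) {
  analytic_cc(model, "12", inject_site = inject_site,
              record_site = record_site) /
    analytic_cc(model, "21", inject_site = inject_site,
                record_site = record_site)
}

#' Analytic input resistance at a node of the passive network
#' @param model \code{network_model} (channels ignored).
#' @param cell,comp node selector.
#' @return resistance (mV per uA/cm2).
#' @export
analytic_input_resistance <- function(model, cell = 1, comp = "S") {
  net <- passive_conductance_network(model)
  lab <- paste0("cell", cell, ".", comp)
  dv <- solve_steady_state(net, stats::setNames(-1, lab))
  dv[[lab]] / -1
}
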