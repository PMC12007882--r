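#' Validation configuration for FBA-based seed checking
#'
#' @param flux_epsilon threshold above which an objective flux counts as
#'   positive; must dominate LP solver noise.
#' @param injected_sink_bounds bounds of the reversible sinks created for
#'   seeds without an exchange reaction (`lower < 0 < upper`).
#' @param lp_tolerance numeric tolerance granted to the LP solver on
#'   steady-state residuals and bound violations.
#' @return An object of class `validation_config`.
#' @export
validation_config <- function(flux_epsilon = 1e-6,
                              injected_sink_bounds = c(-DEFAULT_BOUND, DEFAULT_BOUND),
                              lp_tolerance = 1e-9) {
  stopifnot(flux_epsilon > 0, lp_tolerance > 0, flux_epsilon > lp_tolerance,
            length(injected_sink_bounds) == 2L,
            injected_sink_bounds[1] < 0, injected_sink_bounds[2] > 0)
  structure(list(flux_epsilon = flux_epsilon,
                 injected_sink_bounds = as.numeric(injected_sink_bounds),
                 lp_tolerance = lp_tolerance),
            class = "validation_config")
}

#' Solve the flux balance analysis linear program
#'
#' Maximizes (or minimizes) the flux through the objective reaction subject to
#' steady state (`X v = 0`) and the flux bounds. Infinite bounds are encoded
#' as +/- 1000, the conventional COBRA default. Every variable is therefore
#' finitely bounded and the program can never be unbounded; solver failure on
#' a feasible-looking model is reported as status `"error"`.
#'
#' @param net a [metabolic_network()].
#' @param objective reaction id; defaults to the network's objective.
#' @param sense `"max"` or `"min"`.
#' @param tol numeric tolerance for the a-posteriori feasibility audit of the
#'   returned vertex.
#' @return An object of class `flux_result`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"error"`), `objective_flux`, `fluxes` (named vector),
#'   `message`.
#' @export
solve_fba <- function(net, objective = net$objective, sense = c("max", "min"),
                      tol = 1e-6) {
  stopifnot(inherits(net, "metnet"))
  sense <- match.arg(sense)
  if (is.na(objective) || !objective %in% rxn_ids(net)) {
    stop("objective reaction '", objective, "' not in the network",
         call. = FALSE)
  }
  S <- build_stoich_matrix(net)
  rids <- colnames(S)
  lb <- vapply(net$reactions[rids], `[[`, numeric(1), "lower_bound")
  ub <- vapply(net$reactions[rids], `[[`, numeric(1), "upper_bound")
  lb <- pmax(lb, -DEFAULT_BOUND)
  ub <- pmin(ub, DEFAULT_BOUND)
  n <- length(rids)

  # shift to x = v - lb >= 0; upper bounds become inequality rows
  Sm <- as.matrix(S)
  keep <- rowSums(abs(Sm)) > 0
  Aeq <- Sm[keep, , drop = FALSE]
  beq <- as.numeric(-Aeq %*% lb)
  cc <- numeric(n)
  cc[match(objective, rids)] <- if (sense == "max") -1 else 1

  res <- simplex_box(-cc, Aeq, beq, upper = ub - lb, maximize = TRUE)

  flux_err <- function(msg, status = "error") {
    structure(list(status = status, objective_flux = NA_real_,
                   fluxes = setNames(rep(NA_real_, n), rids),
                   message = msg), class = "flux_result")
  }
  if (res$status != "optimal") {
    if (res$status == "infeasible") {
      return(flux_err("LP infeasible", status = "infeasible"))
    }
    return(flux_err(paste("LP solver status:", res$status)))
  }
  v <- as.numeric(res$x) + lb
  names(v) <- rids
  scale <- max(1, max(abs(v)))
  if (max(abs(Aeq %*% v)) > tol * scale ||
      any(v < lb - tol * scale) || any(v > ub + tol * scale)) {
    return(flux_err("LP solution violates constraints beyond tolerance"))
  }
  structure(list(status = "optimal", objective_flux = v[[objective]],
                 fluxes = v, message = "ok"), class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("FBA:", x$status)
  if (x$status == "optimal") cat(", objective flux", format(x$objective_flux))
  cat("\n")
  invisible(x)
}

# Close every pre-existing import route so inferred seeds become the only
# inputs: productless boundary reactions lose their negative lower bound,
# reactantless import reactions lose their positive upper bound.
close_imports <- function(net) {
  for (id in rxn_ids(net)) {
    r <- net$reactions[[id]]
    if (length(r$products) == 0L && r$lower_bound < 0) {
      net$reactions[[id]]$lower_bound <- 0
    }
    if (length(r$reactants) == 0L && r$upper_bound > 0) {
      net$reactions[[id]]$upper_bound <- max(0, r$lower_bound)
    }
  }
  net
}

#' Inject seeds into a validation network
#'
#' For each extracellular seed with an existing exchange reaction -- a
#' productless reaction whose sole participant is the seed -- the import bound
#' is reopened (lower bound set to the configured sink lower bound). Every
#' other seed gets a new reversible sink `m <-> 0`; pre-existing demands and
#' sinks stay closed. Non-seed metabolites acquire no import route.
#'
#' @param net the validation copy of the network, with all pre-existing
#'   imports closed (see [validate_seeds_fba()]).
#' @param seeds character vector of metabolite ids.
#' @param cfg a [validation_config()].
#' @return The modified [metabolic_network()].
#' @export
inject_seeds <- function(net, seeds, cfg = validation_config()) {
  stopifnot(inherits(net, "metnet"))
  unknown <- setdiff(seeds, met_ids(net))
  if (length(unknown)) {
    stop("unknown seed metabolite(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # map extracellular metabolite -> its exchange reaction(s); only true
  # exchanges are reopened -- demands and old sinks of cytosolic seeds stay
  # closed and such seeds get a fresh sink instead
  boundary_of <- list()
  for (id in rxn_ids(net)) {
    r <- net$reactions[[id]]
    if (length(r$products) == 0L && length(r$reactants) == 1L) {
      m <- names(r$reactants)
      if (is_extracellular_met(net, m)) {
        boundary_of[[m]] <- c(boundary_of[[m]], id)
      }
    }
  }
  new_rxns <- list()
  for (m in sort(seeds)) {
    ex <- boundary_of[[m]]
    if (!is.null(ex)) {
      rid <- sort(ex)[1L]
      net$reactions[[rid]]$lower_bound <- cfg$injected_sink_bounds[1]
      if (net$reactions[[rid]]$upper_bound < 0) {
        net$reactions[[rid]]$upper_bound <- 0
      }
    } else {
      rid <- make.unique(c(rxn_ids(net), paste0("SK_", m, "_seed")))[
        length(rxn_ids(net)) + 1L]
      new_rxns[[rid]] <- reaction(rid, reactants = setNames(1, m),
                                  lower_bound = cfg$injected_sink_bounds[1],
                                  upper_bound = cfg$injected_sink_bounds[2])
    }
  }
  if (length(new_rxns)) {
    net <- metabolic_network(net$metabolites,
                             c(net$reactions, new_rxns),
                             objective = net$objective,
                             extracellular = net$extracellular)
  }
  net
}

#' Validate a seed set by flux balance analysis
#'
#' Builds the validation copy of the original (pre-normalization) model --
#' all imports closed, seeds injected as reopened exchanges or fresh sinks --
#' then maximizes the objective. The seed set is valid when the LP is optimal
#' with objective flux above `flux_epsilon`.
#'
#' @param original_net the original [metabolic_network()] as parsed, so that
#'   stoichiometry and reversibility match the published model semantics.
#' @param seeds character vector of metabolite ids.
#' @param objective objective reaction id; defaults to the model's.
#' @param cfg a [validation_config()].
#' @return List with `verdict` (logical) and `result` (a `flux_result`).
#' @export
validate_seeds_fba <- function(original_net, seeds,
                               objective = original_net$objective,
                               cfg = validation_config()) {
  stopifnot(inherits(original_net, "metnet"))
  if (is.na(objective)) {
    stop("FBA validation needs an objective reaction", call. = FALSE)
  }
  vnet <- inject_seeds(close_imports(original_net), seeds, cfg)
  res <- solve_fba(vnet, objective, sense = "max")
  list(verdict = res$status == "optimal" &&
         res$objective_flux > cfg$flux_epsilon,
       result = res)
}
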