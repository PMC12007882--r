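as_network <- function(net) {
  if (inherits(net, "norm_metnet")) net$network else net
}

# Precomputed integer-index view of a network for repeated scope calls.
scope_index <- function(net) {
  net <- as_network(net)
  mids <- met_ids(net)
  rids <- rxn_ids(net)
  r_react <- lapply(net$reactions, function(r) match(names(r$reactants), mids))
  r_prod <- lapply(net$reactions, function(r) match(names(r$products), mids))
  # for each metabolite, the reactions consuming it (reactant incidence)
  consumers <- vector("list", length(mids))
  producers <- vector("list", length(mids))
  for (j in seq_along(rids)) {
    for (i in r_react[[j]]) consumers[[i]] <- c(consumers[[i]], j)
    for (i in r_prod[[j]]) producers[[i]] <- c(producers[[i]], j)
  }
  list(mids = mids, rids = rids, r_react = r_react, r_prod = r_prod,
       consumers = consumers, producers = producers)
}

# Counting propagation to the least fixed point: a reaction activates once
# all its reactants are reachable; its products then become reachable.
scope_fixpoint <- function(idx, seed_idx) {
  nM <- length(idx$mids); nR <- length(idx$rids)
  need <- lengths(idx$r_react)
  reach <- logical(nM)
  active <- logical(nR)
  queue <- unique(seed_idx)
  reach[queue] <- TRUE
  iterations <- 0L
  # zero-reactant reactions (e.g. kept imports) activate unconditionally
  ready <- which(need == 0L)
  repeat {
    ready <- ready[!active[ready]]
    if (!length(ready) && !length(queue)) break
    iterations <- iterations + 1L
    new_mets <- integer()
    for (j in ready) {
      active[j] <- TRUE
      pr <- idx$r_prod[[j]]
      new_mets <- c(new_mets, pr[!reach[pr]])
    }
    front <- unique(c(queue, new_mets))
    front <- front[front > 0L]
    reach[front] <- TRUE
    queue <- integer()
    # reactions whose last missing reactant just arrived
    cand <- unique(unlist(idx$consumers[front], use.names = FALSE))
    if (length(cand)) {
      cand <- cand[!active[cand]]
      ready <- cand[vapply(cand, function(j) all(reach[idx$r_react[[j]]]),
                           logical(1))]
    } else {
      ready <- integer()
    }
    if (!length(ready)) break
  }
  list(reach = reach, active = active, iterations = iterations)
}

#' Compute the scope of a seed set
#'
#' Network expansion: starting from the seeds, a reaction activates as soon as
#' all its reactants are reachable, and its products then become reachable;
#' the scope is the least fixed point of this operator. The computation is
#' purely structural -- stoichiometric coefficients and bound magnitudes play
#' no role. Reactions with no reactants (retained imports `0 -> m`) activate
#' from the first iteration.
#'
#' @param net a normalized network ([normalize_network()]) or a
#'   [metabolic_network()] whose reactions are all irreversible.
#' @param seeds character vector of metabolite ids.
#' @return An object of class `scope_result`: list with `reachable`
#'   (metabolite ids), `activated_reactions` (reaction ids), `iterations`.
#' @export
compute_scope <- function(net, seeds) {
  idx <- scope_index(net)
  compute_scope_idx(idx, seeds)
}

compute_scope_idx <- function(idx, seeds) {
  seed_idx <- match(seeds, idx$mids)
  if (anyNA(seed_idx)) {
    stop("unknown seed metabolite(s): ",
         paste(seeds[is.na(seed_idx)], collapse = ", "), call. = FALSE)
  }
  fx <- scope_fixpoint(idx, seed_idx)
  structure(
    list(reachable = idx$mids[fx$reach],
         activated_reactions = idx$rids[fx$active],
         iterations = fx$iterations),
    class = "scope_result"
  )
}

#' @export
print.scope_result <- function(x, ...) {
  cat("Scope:", length(x$reachable), "reachable metabolites,",
      length(x$activated_reactions), "activated reactions in",
      x$iterations, "iterations\n")
  invisible(x)
}

#' Check the no-accumulation constraint on a scope
#'
#' A qualitative surrogate of flux steady state: every metabolite in the scope
#' (seeds included) must be consumed by at least one reaction whose reactants
#' all lie in the scope (i.e. an activated reaction).
#'
#' @param net the network the scope was computed on.
#' @param scope a [compute_scope()] result.
#' @return List with `ok` (logical) and `violators` (metabolite ids in the
#'   scope consumed by no activated reaction).
#' @export
check_no_accumulation <- function(net, scope) {
  network <- as_network(net)
  consumed <- unique(unlist(
    lapply(network$reactions[scope$activated_reactions],
           function(r) names(r$reactants)),
    use.names = FALSE))
  violators <- setdiff(scope$reachable, consumed)
  list(ok = length(violators) == 0L, violators = violators)
}

#' Derive the target metabolites of a run
#'
#' In target mode a reaction objective is translated into its reactants in the
#' normalized network (reaching them is what makes the reaction activable); an
#' explicit metabolite list is passed through. In full-network mode every
#' metabolite of the normalized network is a target.
#'
#' @param net a [normalize_network()] result.
#' @param mode `"target"` or `"full_network"`.
#' @param objective reaction id (looked up through normalization provenance,
#'   preferring the forward copy) or character vector of metabolite ids;
#'   ignored in full-network mode.
#' @return An object of class `target_set`: list with `metabolite_targets`,
#'   `objective_reaction` (or `NA`), `mode`.
#' @export
derive_targets <- function(net, mode = c("target", "full_network"),
                           objective = NULL) {
  stopifnot(inherits(net, "norm_metnet"))
  mode <- match.arg(mode)
  mids <- met_ids(net$network)
  if (mode == "full_network") {
    return(structure(list(metabolite_targets = mids,
                          objective_reaction = NA_character_,
                          mode = mode), class = "target_set"))
  }
  if (is.null(objective) || !length(objective)) {
    stop("target mode needs an objective reaction or metabolite list",
         call. = FALSE)
  }
  prov <- net$provenance
  if (length(objective) == 1L && objective %in% prov$original_id &&
      !all(objective %in% mids)) {
    rows <- prov[prov$original_id == objective, , drop = FALSE]
    fwd <- rows[rows$direction == "forward", , drop = FALSE]
    rid <- if (nrow(fwd)) fwd$id[1L] else rows$id[1L]
    targets <- names(net$network$reactions[[rid]]$reactants)
    if (!length(targets)) {
      stop("objective reaction '", objective,
           "' has no reactants: nothing to reach", call. = FALSE)
    }
    return(structure(list(metabolite_targets = targets,
                          objective_reaction = objective,
                          mode = mode), class = "target_set"))
  }
  unknown <- setdiff(objective, mids)
  if (length(unknown)) {
    stop("objective is neither a reaction id nor a metabolite list; unknown: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(metabolite_targets = unique(objective),
                 objective_reaction = NA_character_,
                 mode = mode), class = "target_set")
}

#' Backward closure of seed candidates
#'
#' The least set containing the targets and, for every reaction producing a
#' member of the set, all that reaction's reactants. Every subset-minimal seed
#' set of the Boolean reachability problem is contained in this closure, so it
#' is the candidate pool the solvers draw from.
#'
#' @param net a normalized network or `metnet` with irreversible reactions.
#' @param targets a [derive_targets()] result or character vector of
#'   metabolite ids.
#' @return Character vector of candidate metabolite ids.
#' @export
backward_candidates <- function(net, targets) {
  idx <- scope_index(net)
  if (inherits(targets, "target_set")) targets <- targets$metabolite_targets
  if (!length(targets)) stop("empty target set", call. = FALSE)
  t_idx <- match(targets, idx$mids)
  if (anyNA(t_idx)) {
    stop("unknown target metabolite(s): ",
         paste(targets[is.na(t_idx)], collapse = ", "), call. = FALSE)
  }
  inset <- logical(length(idx$mids))
  inset[t_idx] <- TRUE
  queue <- t_idx
  while (length(queue)) {
    m <- queue[[1L]]; queue <- queue[-1L]
    for (j in idx$producers[[m]]) {
      newm <- idx$r_react[[j]]
      newm <- newm[!inset[newm]]
      if (length(newm)) {
        inset[newm] <- TRUE
        queue <- c(queue, newm)
      }
    }
  }
  idx$mids[inset]
}

# TRUE for reactions moving the same base molecule between compartments
is_transport_reaction <- function(net, r) {
  mets <- net$metabolites
  rb <- mets$base_id[match(names(r$reactants), mets$id)]
  rc <- mets$compartment[match(names(r$reactants), mets$id)]
  pb <- mets$base_id[match(names(r$products), mets$id)]
  pc <- mets$compartment[match(names(r$products), mets$id)]
  shared <- intersect(rb, pb)
  for (b in shared) {
    if (length(union(rc[rb == b], pc[pb == b])) > 1L) return(TRUE)
  }
  FALSE
}

#' Detect external metabolites
#'
#' For full-network searches: metabolites that are consumed somewhere but are
#' produced by no reaction at all, or only through transport reactions (a
#' reaction carrying the same base molecule across compartments). These can
#' only originate outside the system and are forced to be seeds.
#'
#' @param net a normalized network.
#' @return Character vector of metabolite ids.
#' @export
detect_external_metabolites <- function(net) {
  network <- as_network(net)
  idx <- scope_index(network)
  out <- character()
  for (i in seq_along(idx$mids)) {
    if (!length(idx$consumers[[i]])) next        # never a reactant
    prods <- idx$producers[[i]]
    if (!length(prods)) {
      out <- c(out, idx$mids[i])
    } else {
      all_transport <- all(vapply(prods, function(j) {
        is_transport_reaction(network, network$reactions[[j]])
      }, logical(1)))
      if (all_transport) out <- c(out, idx$mids[i])
    }
  }
  out
}
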