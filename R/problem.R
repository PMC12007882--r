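#' Define a seed-inference problem
#'
#' Bundles everything the solving engines need: the original model (for FBA
#' validation), its normalization (for scope computation), the target set, the
#' candidate pools, forced/forbidden seeds, the optimization criterion and the
#' run limits.
#'
#' Candidate pools: for the Boolean (network-expansion) problem, every
#' subset-minimal seed set lives inside the backward closure of the targets,
#' which is therefore the reasoning candidate pool. Hybrid modes additionally
#' need seeds that act purely as flux outlets (a sink for an accumulating
#' by-product); such metabolites necessarily lie in the scope of the backward
#' closure, so the hybrid pool is the closure united with its own scope. In
#' full-network mode external metabolites (never produced, or produced only by
#' transport) are forced seeds and the pool is every metabolite outside their
#' scope, plus the forced seeds themselves.
#'
#' @param net the original [metabolic_network()].
#' @param mode `"target"` or `"full_network"`.
#' @param objective objective reaction id or character vector of target
#'   metabolite ids (target mode); defaults to the network's objective.
#' @param forced_seeds,forbidden_seeds metabolite id vectors.
#' @param optimization `"subset_minimal"` or `"minimize"` (globally smallest
#'   cardinality).
#' @param no_accumulation enforce that every scope metabolite is consumed by
#'   an activated reaction. Defaults to `FALSE` in target mode and `TRUE` in
#'   full-network mode.
#' @param keep_import keep import directions during normalization.
#' @param validation a [validation_config()].
#' @param max_solutions cap on the number of emitted solutions.
#' @param time_budget solving budget in seconds (`Inf` for none).
#' @return An object of class `seed_problem`.
#' @export
seed_problem <- function(net,
                         mode = c("target", "full_network"),
                         objective = NULL,
                         forced_seeds = character(),
                         forbidden_seeds = character(),
                         optimization = c("subset_minimal", "minimize"),
                         no_accumulation = NULL,
                         keep_import = FALSE,
                         validation = validation_config(),
                         max_solutions = 10L,
                         time_budget = Inf) {
  stopifnot(inherits(net, "metnet"), max_solutions >= 1)
  mode <- match.arg(mode)
  optimization <- match.arg(optimization)
  if (is.null(no_accumulation)) no_accumulation <- mode == "full_network"
  if (is.null(objective) && mode == "target") {
    if (is.na(net$objective)) {
      stop("target mode needs an objective (model declares none)",
           call. = FALSE)
    }
    objective <- net$objective
  }

  norm <- normalize_network(net, keep_import = keep_import)
  targets <- derive_targets(norm, mode, objective)
  idx <- scope_index(norm$network)
  mids <- idx$mids

  bad <- intersect(forced_seeds, forbidden_seeds)
  if (length(bad)) {
    stop("seeds both forced and forbidden: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(c(forced_seeds, forbidden_seeds), mids)
  if (length(unknown)) {
    stop("unknown forced/forbidden metabolite(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  if (mode == "full_network") {
    auto_external <- detect_external_metabolites(norm)
    forced <- sort(union(forced_seeds, setdiff(auto_external,
                                               forbidden_seeds)))
    initial_scope <- compute_scope_idx(idx, forced)$reachable
    candidates <- sort(union(setdiff(mids, initial_scope), forced))
    candidates <- sort(union(setdiff(candidates, forbidden_seeds), forced))
    candidates_hybrid <- sort(union(setdiff(mids, forbidden_seeds), forced))
  } else {
    forced <- sort(forced_seeds)
    cand0 <- backward_candidates(norm, targets)
    candidates <- sort(union(setdiff(cand0, forbidden_seeds), forced))
    reach <- compute_scope_idx(idx, candidates)$reachable
    candidates_hybrid <- sort(union(
      setdiff(union(candidates, reach), forbidden_seeds), forced))
  }

  fba_objective <- if (!is.na(targets$objective_reaction)) {
    targets$objective_reaction
  } else {
    net$objective
  }

  structure(
    list(net = norm, original_net = net, targets = targets,
         candidates = candidates, candidates_hybrid = candidates_hybrid,
         forced_seeds = forced, forbidden_seeds = sort(forbidden_seeds),
         optimization = optimization, no_accumulation = no_accumulation,
         validation = validation, fba_objective = fba_objective,
         limits = list(max_solutions = max_solutions,
                       time_budget = time_budget),
         idx = idx),
    class = "seed_problem"
  )
}

#' @export
print.seed_problem <- function(x, ...) {
  cat("Seed-inference problem (", x$targets$mode, " mode, ",
      x$optimization, ")\n", sep = "")
  cat("targets:", length(x$targets$metabolite_targets),
      "| candidates:", length(x$candidates),
      "(hybrid:", length(x$candidates_hybrid), ")",
      "| forced:", length(x$forced_seeds),
      "| forbidden:", length(x$forbidden_seeds), "\n")
  cat("no-accumulation:", x$no_accumulation, "\n")
  invisible(x)
}

# --- shared predicate helpers -------------------------------------------

target_idx <- function(problem) {
  match(problem$targets$metabolite_targets, problem$idx$mids)
}

# NE feasibility: targets reachable from seeds (forced are part of seeds).
ne_feasible <- function(problem, seeds) {
  fx <- scope_fixpoint(problem$idx, match(seeds, problem$idx$mids))
  all(fx$reach[target_idx(problem)])
}

# no-accumulation on the scope of `seeds`
no_accum_ok <- function(problem, seeds) {
  idx <- problem$idx
  fx <- scope_fixpoint(idx, match(seeds, idx$mids))
  consumed <- logical(length(idx$mids))
  for (j in which(fx$active)) consumed[idx$r_react[[j]]] <- TRUE
  !any(fx$reach & !consumed)
}

fba_flux_of <- function(problem, seeds) {
  v <- validate_seeds_fba(problem$original_net, seeds,
                          objective = problem$fba_objective,
                          cfg = problem$validation)
  list(ok = v$verdict,
       flux = if (v$result$status == "optimal") v$result$objective_flux
              else NA_real_)
}

seed_solution <- function(seeds, minimality,
                          ne_valid = TRUE, no_accumulation_valid = NA,
                          fba_flux = NA_real_) {
  structure(
    list(seeds = sort(seeds), ne_valid = ne_valid,
         no_accumulation_valid = no_accumulation_valid,
         fba_flux = fba_flux, minimality = minimality),
    class = "seed_solution"
  )
}

#' @export
print.seed_solution <- function(x, ...) {
  cat("{", paste(x$seeds, collapse = ", "), "} [", x$minimality, "]",
      sep = "")
  if (!is.na(x$fba_flux)) cat(" flux =", format(x$fba_flux))
  cat("\n")
  invisible(x)
}

solution_set <- function(solutions, status, engine) {
  structure(list(solutions = solutions, status = status, engine = engine),
            class = "seed_solution_set")
}

#' @export
print.seed_solution_set <- function(x, ...) {
  cat(length(x$solutions), " seed solution(s) [", x$engine, ", ",
      x$status, "]\n", sep = "")
  for (s in x$solutions) print(s)
  invisible(x)
}

#' Extract solution seed sets as a list of character vectors
#'
#' @param x a `seed_solution_set`.
#' @return List of sorted character vectors.
#' @export
solution_seed_sets <- function(x) {
  lapply(x$solutions, `[[`, "seeds")
}

set_key <- function(s) paste(sort(s), collapse = "\r")

# set-of-sets equality helper used by tests and the oracle comparisons
#' Compare two collections of seed sets for equality, ignoring order
#' @param a,b lists of character vectors.
#' @return `TRUE` or `FALSE`.
#' @export
same_set_family <- function(a, b) {
  setequal(vapply(a, set_key, character(1)),
           vapply(b, set_key, character(1)))
}
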