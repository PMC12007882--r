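# Guess-and-check machinery shared by the hybrid modes (and by reasoning
# under the no-accumulation constraint).
#
# The queue holds candidate seed sets, all NE-feasible, processed in
# increasing cardinality (ties broken by a diversification score and then
# lexicographically). It is primed with every NE-subset-minimal set. A popped
# set that passes the secondary check (FBA and/or no-accumulation) is
# accepted and emitted; supersets of accepted sets are discarded. A set that
# fails is rejected exactly -- its one-element extensions re-enter the queue,
# so strict supersets of a rejected set become candidate minimal solutions of
# the residual problem. Because processing is cardinality-ordered, every
# accepted set is subset-minimal for the joint problem, and a run to
# exhaustion accepts exactly the globally subset-minimal joint solutions.

gc_queue_engine <- function(problem, base_sets, push_candidates, check_fn,
                            max_solutions, deadline, diversify = FALSE,
                            stop_after_min_card = FALSE) {
  usage <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  queue <- list()

  push <- function(s) {
    s <- sort(s)
    k <- set_key(s)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      queue[[length(queue) + 1L]] <<- list(seeds = s, key = k,
                                           card = length(s))
    }
  }
  for (s in base_sets) push(s)

  score <- function(s) {
    if (!diversify) return(0)
    sum(vapply(s, function(m) {
      u <- usage[[m]]
      if (is.null(u)) 0 else u
    }, numeric(1)))
  }

  accepted <- list()
  rejected <- 0L
  status <- "exhausted"
  min_card_accept <- NA_integer_

  while (length(queue)) {
    if (Sys.time() > deadline) {
      status <- "timeout"
      break
    }
    cards <- vapply(queue, `[[`, integer(1), "card")
    pool <- which(cards == min(cards))
    if (length(pool) > 1L && diversify) {
      sc <- vapply(pool, function(i) score(queue[[i]]$seeds), numeric(1))
      pool <- pool[sc == min(sc)]
    }
    if (length(pool) > 1L) {
      keys <- vapply(pool, function(i) queue[[i]]$key, character(1))
      pool <- pool[order(keys)]
    }
    i <- pool[[1L]]
    item <- queue[[i]]
    queue[[i]] <- NULL

    if (stop_after_min_card && !is.na(min_card_accept) &&
        item$card > min_card_accept) {
      status <- "exhausted"
      break
    }
    if (any(vapply(accepted, function(a) all(a$seeds %in% item$seeds),
                   logical(1)))) {
      next  # superset of an accepted solution
    }
    res <- check_fn(item$seeds)
    if (isTRUE(res$ok)) {
      accepted[[length(accepted) + 1L]] <-
        list(seeds = item$seeds, flux = res$flux)
      if (is.na(min_card_accept)) min_card_accept <- item$card
      for (m in item$seeds) {
        u <- usage[[m]]
        usage[[m]] <- if (is.null(u)) 1 else u + 1
      }
      if (length(accepted) >= max_solutions) {
        status <- "solution_limit"
        break
      }
    } else {
      rejected <- rejected + 1L
      for (x in setdiff(push_candidates, item$seeds)) {
        push(c(item$seeds, x))
      }
    }
  }
  list(accepted = accepted, status = status, rejected = rejected)
}

hybrid_check_fn <- function(problem) {
  function(s) {
    if (problem$no_accumulation && !no_accum_ok(problem, s)) {
      return(list(ok = FALSE, flux = NA_real_))
    }
    fba_flux_of(problem, s)
  }
}

finalize_hybrid <- function(problem, eng, engine_name) {
  minimize <- problem$optimization == "minimize"
  acc <- eng$accepted
  minimality <- "hybrid_subset_minimal"
  status <- eng$status
  if (minimize && length(acc)) {
    k <- min(vapply(acc, function(a) length(a$seeds), integer(1)))
    acc <- Filter(function(a) length(a$seeds) == k, acc)
    if (length(acc) > problem$limits$max_solutions) {
      acc <- acc[seq_len(problem$limits$max_solutions)]
      status <- "solution_limit"
    }
    minimality <- "cardinality_minimal"
  }
  sols <- lapply(acc, function(a) {
    seed_solution(a$seeds, minimality,
                  no_accumulation_valid =
                    if (problem$no_accumulation) TRUE else NA,
                  fba_flux = a$flux)
  })
  solution_set(sols, status, engine_name)
}

#' Hybrid guess-and-check seed inference
#'
#' Repeatedly obtains a subset-minimal solution of the Boolean problem
#' constrained by the blocking store; a solution failing FBA validation is
#' rejected exactly (its strict supersets become candidate minimal solutions
#' of the residual problem), a passing one is emitted and all its supersets
#' are excluded from future solutions. Emitted sets pass FBA and are
#' subset-minimal for the joint Boolean + flux problem -- typically not
#' minimal for the Boolean problem alone. With `diversify = TRUE`,
#' tie-breaking among equal-cardinality candidates prefers seeds used least
#' in previously emitted solutions, widening the explored union without
#' affecting soundness or minimality.
#'
#' @param problem a [seed_problem()]; FBA validation needs an objective
#'   reaction.
#' @param diversify bias enumeration towards unexplored seeds.
#' @return A `seed_solution_set`.
#' @export
hybrid_gc <- function(problem, diversify = FALSE) {
  stopifnot(inherits(problem, "seed_problem"))
  deadline <- Sys.time() + problem$limits$time_budget
  if (precheck_unsat(problem)) {
    return(solution_set(list(), "unsatisfiable",
                        if (diversify) "hybrid_gc_div" else "hybrid_gc"))
  }
  minimize <- problem$optimization == "minimize"
  base <- all_ne_minimal(problem, deadline)
  if (base$status == "timeout") {
    return(solution_set(list(), "timeout",
                        if (diversify) "hybrid_gc_div" else "hybrid_gc"))
  }
  eng <- gc_queue_engine(
    problem, base$sets, problem$candidates_hybrid, hybrid_check_fn(problem),
    max_solutions = if (minimize) Inf else problem$limits$max_solutions,
    deadline = deadline, diversify = diversify,
    stop_after_min_card = minimize)
  finalize_hybrid(problem, eng,
                  if (diversify) "hybrid_gc_div" else "hybrid_gc")
}

#' Hybrid-filter seed inference
#'
#' Runs the reasoning enumeration and emits, in order, only the solutions
#' whose seed sets pass FBA validation, annotated with the validated
#' objective flux. Stops at `max_solutions` validated solutions, budget
#' exhaustion, or exhaustion of the reasoning stream (status
#' `"exhausted_without_valid"` when nothing validated).
#'
#' @param problem a [seed_problem()].
#' @return A `seed_solution_set`.
#' @export
hybrid_filter <- function(problem) {
  stopifnot(inherits(problem, "seed_problem"))
  deadline <- Sys.time() + problem$limits$time_budget
  base <- enumerate_reasoning(within_limits(problem, max_solutions = Inf))
  if (base$status %in% c("unsatisfiable", "timeout")) {
    return(solution_set(list(), base$status, "hybrid_filter"))
  }
  out <- list()
  status <- base$status
  for (sol in base$solutions) {
    if (Sys.time() > deadline) {
      status <- "timeout"
      break
    }
    v <- fba_flux_of(problem, sol$seeds)
    if (isTRUE(v$ok)) {
      sol$fba_flux <- v$flux
      out[[length(out) + 1L]] <- sol
      if (length(out) >= problem$limits$max_solutions) {
        status <- "solution_limit"
        break
      }
    }
  }
  if (!length(out) && status == "exhausted") {
    status <- "exhausted_without_valid"
  }
  solution_set(out, status, "hybrid_filter")
}

within_limits <- function(problem, max_solutions = NULL,
                          time_budget = NULL) {
  if (!is.null(max_solutions)) problem$limits$max_solutions <- max_solutions
  if (!is.null(time_budget)) problem$limits$time_budget <- time_budget
  problem
}

#' Full hybrid search (direct Boolean + linear encoding)
#'
#' Explores candidate in/out assignments directly, checking linear
#' feasibility on partial assignments: a branch is pruned as soon as the
#' optimistic seed set (included plus undecided candidates) either fails to
#' reach the targets or cannot carry positive objective flux -- both checks
#' are monotone, so no solution is lost. A node whose included set is already
#' jointly feasible is recorded and its supersets are skipped. Run to
#' completion the solution set equals exhaustive [hybrid_gc()] under
#' subset-minimal optimization. Intended for small networks: inputs with more
#' than `max_reactions` reactions are refused unless `force = TRUE`, the
#' direct encoding being known not to scale to genome-sized models.
#'
#' @param problem a [seed_problem()].
#' @param max_reactions refusal threshold on the normalized reaction count.
#' @param force search anyway.
#' @return A `seed_solution_set`.
#' @export
full_hybrid_solve <- function(problem, max_reactions = 200L, force = FALSE) {
  stopifnot(inherits(problem, "seed_problem"))
  nR <- length(problem$net$network$reactions)
  if (nR > max_reactions && !force) {
    stop("full hybrid search refused: ", nR, " reactions (> ",
         max_reactions, "); this mode does not scale beyond small ",
         "networks. Use force = TRUE to override.", call. = FALSE)
  }
  deadline <- Sys.time() + problem$limits$time_budget
  if (precheck_unsat(problem)) {
    return(solution_set(list(), "unsatisfiable", "full_hybrid"))
  }
  cand <- sort(setdiff(problem$candidates_hybrid, problem$forced_seeds))
  forced <- problem$forced_seeds
  check <- hybrid_check_fn(problem)
  lp_memo <- new.env(parent = emptyenv())
  lp_ok <- function(s) {  # optimistic monotone flux bound
    k <- set_key(s)
    v <- lp_memo[[k]]
    if (is.null(v)) {
      v <- fba_flux_of(problem, s)$ok
      lp_memo[[k]] <- v
    }
    v
  }
  feasible_sets <- list()
  timed_out <- FALSE

  rec <- function(i, included) {
    if (timed_out || Sys.time() > deadline) {
      timed_out <<- TRUE
      return(invisible())
    }
    S_inc <- union(included, forced)
    if (ne_feasible(problem, S_inc)) {
      res <- check(S_inc)
      if (isTRUE(res$ok)) {
        feasible_sets[[length(feasible_sets) + 1L]] <<-
          list(seeds = sort(S_inc), flux = res$flux)
        return(invisible())    # supersets cannot be minimal
      }
    }
    if (i > length(cand)) return(invisible())
    optimistic <- union(S_inc, cand[i:length(cand)])
    if (!ne_feasible(problem, optimistic)) return(invisible())
    if (!lp_ok(optimistic)) return(invisible())
    rec(i + 1L, c(included, cand[i]))          # include cand[i]
    rec(i + 1L, included)                      # exclude cand[i]
  }
  rec(1L, character())

  if (timed_out && !length(feasible_sets)) {
    return(solution_set(list(), "timeout", "full_hybrid"))
  }
  # keep the subset-minimal family among the recorded feasible sets
  keys <- vapply(feasible_sets, function(f) set_key(f$seeds), character(1))
  feasible_sets <- feasible_sets[!duplicated(keys)]
  minimal <- Filter(function(f) {
    !any(vapply(feasible_sets, function(g) {
      length(g$seeds) < length(f$seeds) && all(g$seeds %in% f$seeds)
    }, logical(1)))
  }, feasible_sets)
  ord <- order(vapply(minimal, function(f) length(f$seeds), integer(1)),
               vapply(minimal, function(f) set_key(f$seeds), character(1)))
  minimal <- minimal[ord]
  eng <- list(accepted = minimal,
              status = if (timed_out) "timeout" else "exhausted")
  out <- finalize_hybrid(problem, eng, "full_hybrid")
  if (!timed_out && out$status == "exhausted" &&
      length(out$solutions) > problem$limits$max_solutions) {
    out$solutions <- out$solutions[seq_len(problem$limits$max_solutions)]
    out$status <- "solution_limit"
  }
  out
}
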