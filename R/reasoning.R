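# Solving engines for the Boolean (network-expansion) seed problem.
#
# The NE feasibility predicate is monotone: supersets of feasible seed sets
# are feasible. Subset-minimal models of a monotone predicate are enumerated
# by a hitting-set search: each already-found solution must lose at least one
# non-forced element, the remaining candidate pool is checked for
# feasibility, and a feasible pool is shrunk to a minimal set. Failures are
# memoized (they stay failures as more solutions accumulate).

TIMEOUT_SENTINEL <- structure(list(), class = "sk_timeout")

is_timeout <- function(x) inherits(x, "sk_timeout")

#' Shrink a feasible seed superset to a minimal seed set
#'
#' Greedily removes non-forced seeds (in lexicographic order, repeated until
#' stable) while the problem's feasibility predicate -- target reachability,
#' plus no-accumulation when enabled -- keeps holding. The result is
#' 1-minimal: removing any single non-forced element breaks feasibility. For
#' the purely monotone reachability predicate 1-minimality coincides with
#' subset-minimality.
#'
#' @param problem a [seed_problem()].
#' @param superset feasible seed set (character vector) containing the forced
#'   seeds.
#' @return A minimal feasible subset (character vector, sorted).
#' @export
shrink_to_minimal <- function(problem, superset) {
  feas <- function(s) {
    ne_feasible(problem, s) &&
      (!problem$no_accumulation || no_accum_ok(problem, s))
  }
  if (!feas(superset)) {
    stop("shrink_to_minimal: superset is not feasible", call. = FALSE)
  }
  shrink_with(superset, problem$forced_seeds, feas)
}

shrink_with <- function(superset, forced, feas) {
  s <- sort(unique(superset))
  repeat {
    removed <- FALSE
    for (x in setdiff(s, forced)) {
      trial <- setdiff(s, x)
      if (feas(trial)) {
        s <- trial
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  s
}

# One new NE-minimal solution not previously found, NULL when exhausted,
# TIMEOUT_SENTINEL when the deadline passed. `found` is a list of seed sets.
find_new_ne_minimal <- function(problem, found, deadline, memo) {
  cand <- problem$candidates
  forced <- problem$forced_seeds
  feas <- function(U) ne_feasible(problem, U)

  rec <- function(i, excluded) {
    if (Sys.time() > deadline) return(TIMEOUT_SENTINEL)
    key <- paste(i, paste(sort(excluded), collapse = ","))
    if (!is.null(memo[[key]])) return(NULL)
    U <- setdiff(cand, excluded)
    if (!feas(U)) {          # monotone: deeper exclusions cannot help
      memo[[key]] <- TRUE
      return(NULL)
    }
    if (i > length(found)) {
      return(shrink_with(U, forced, feas))
    }
    Si <- found[[i]]
    if (length(intersect(Si, excluded))) {
      res <- rec(i + 1L, excluded)
      if (!is.null(res)) return(res)
      memo[[key]] <- TRUE
      return(NULL)
    }
    for (x in setdiff(Si, forced)) {
      res <- rec(i + 1L, c(excluded, x))
      if (!is.null(res)) return(res)
    }
    memo[[key]] <- TRUE
    NULL
  }
  rec(1L, character())
}

# All subset-minimal NE solutions (each includes the forced seeds), up to
# `cap` of them and within `deadline`.
all_ne_minimal <- function(problem, deadline = Sys.time() + Inf, cap = Inf) {
  found <- list()
  memo <- new.env(parent = emptyenv())
  status <- "exhausted"
  repeat {
    if (length(found) >= cap) {
      status <- "solution_limit"
      break
    }
    s <- find_new_ne_minimal(problem, found, deadline, memo)
    if (is_timeout(s)) {
      status <- "timeout"
      break
    }
    if (is.null(s)) break
    found[[length(found) + 1L]] <- s
  }
  list(sets = found, status = status)
}

precheck_unsat <- function(problem) {
  top <- union(problem$candidates, problem$forced_seeds)
  fx <- scope_fixpoint(problem$idx, match(top, problem$idx$mids))
  missing <- problem$targets$metabolite_targets[
    !fx$reach[target_idx(problem)]]
  if (length(missing)) {
    message("unsatisfiable: targets unreachable even from the full ",
            "candidate pool: ", paste(missing, collapse = ", "))
    return(TRUE)
  }
  FALSE
}

#' Enumerate seed solutions under the Boolean semantics (reasoning mode)
#'
#' Emits distinct subset-minimal seed sets drawn from the candidate pool,
#' each making every target reachable (and, when the problem enables it,
#' satisfying the no-accumulation constraint; minimality is then with respect
#' to the joint predicate). With `optimization = "minimize"` only sets of
#' globally minimal cardinality are emitted. An infeasible problem yields an
#' empty set with status `"unsatisfiable"`, distinct from `"timeout"`.
#'
#' @param problem a [seed_problem()].
#' @return A `seed_solution_set`.
#' @export
enumerate_reasoning <- function(problem) {
  stopifnot(inherits(problem, "seed_problem"))
  deadline <- Sys.time() + problem$limits$time_budget
  if (precheck_unsat(problem)) {
    return(solution_set(list(), "unsatisfiable", "reasoning"))
  }
  max_sol <- problem$limits$max_solutions
  minimize <- problem$optimization == "minimize"

  if (!problem$no_accumulation) {
    cap <- if (minimize) Inf else max_sol
    base <- all_ne_minimal(problem, deadline, cap = cap)
    sets <- base$sets
    status <- base$status
    minimality <- "ne_subset_minimal"
  } else {
    # the joint NE + no-accumulation predicate is not monotone: guess
    # NE-minimal sets, check accumulation, and on failure re-open the
    # search above the rejected set (cardinality-ordered guess-and-check)
    base <- all_ne_minimal(problem, deadline)
    if (base$status == "timeout") {
      return(solution_set(list(), "timeout", "reasoning"))
    }
    check_fn <- function(s) list(ok = no_accum_ok(problem, s), flux = NA_real_)
    eng <- gc_queue_engine(problem, base$sets, problem$candidates, check_fn,
                           max_solutions = if (minimize) Inf else max_sol,
                           deadline = deadline,
                           stop_after_min_card = minimize)
    sets <- lapply(eng$accepted, `[[`, "seeds")
    status <- eng$status
    minimality <- "ne_subset_minimal"
  }

  if (minimize && length(sets)) {
    k <- min(lengths(sets))
    sets <- sets[lengths(sets) == k]
    if (length(sets) > max_sol) {
      sets <- sets[seq_len(max_sol)]
      status <- "solution_limit"
    }
    minimality <- "cardinality_minimal"
  }

  sols <- lapply(sets, function(s) {
    seed_solution(s, minimality,
                  no_accumulation_valid =
                    if (problem$no_accumulation) TRUE else NA)
  })
  solution_set(sols, status, "reasoning")
}
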