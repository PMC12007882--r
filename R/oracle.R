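#' Brute-force enumeration of all subset-minimal seed sets
#'
#' The independent testing oracle: walks every subset of the candidate pool
#' in increasing cardinality, skipping supersets of already-confirmed minimal
#' sets, and checks the full feasibility predicate directly -- target
#' reachability, the no-accumulation constraint when the problem enables it,
#' and FBA validation when `with_fba`. Shares no search machinery with the
#' enumeration engines.
#'
#' @param problem a [seed_problem()].
#' @param with_fba also require a positive objective flux (the pool is then
#'   the hybrid candidate pool).
#' @param max_candidates refusal threshold; the walk is exponential.
#' @return List of sorted character vectors (each includes the forced seeds).
#' @export
brute_force_minimal_seed_sets <- function(problem, with_fba = FALSE,
                                          max_candidates = 16L) {
  stopifnot(inherits(problem, "seed_problem"))
  pool <- if (with_fba) problem$candidates_hybrid else problem$candidates
  free <- sort(setdiff(pool, problem$forced_seeds))
  if (length(free) > max_candidates) {
    stop("brute force refused: ", length(free), " free candidates (> ",
         max_candidates, ")", call. = FALSE)
  }
  feas <- function(s) {
    if (!ne_feasible(problem, s)) return(FALSE)
    if (problem$no_accumulation && !no_accum_ok(problem, s)) return(FALSE)
    if (with_fba && !fba_flux_of(problem, s)$ok) return(FALSE)
    TRUE
  }
  found <- list()
  for (k in 0:length(free)) {
    combs <- if (k == 0L) list(character()) else
      utils::combn(free, k, simplify = FALSE)
    for (cs in combs) {
      s <- sort(union(cs, problem$forced_seeds))
      if (any(vapply(found, function(f) all(f %in% s), logical(1)))) next
      if (feas(s)) found[[length(found) + 1L]] <- s
    }
  }
  found
}
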