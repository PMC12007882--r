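#' Diversity statistics over a collection of seed solutions
#'
#' Summarizes an enumeration the way reverse-ecology analyses consume it:
#' solution sizes, the union of seed metabolites, the de-replicated union
#' (the same base molecule in different compartments counted once),
#' per-metabolite frequencies across solutions, and the partition of union
#' members into metabolites that had an import route in the input model
#' (exchange or sink) versus internal ones.
#'
#' @param solutions a `seed_solution_set` or list of seed id vectors.
#' @param net the original [metabolic_network()] (for base ids and boundary
#'   classes).
#' @return An object of class `solution_stats`: list with `n_solutions`,
#'   `sizes`, `union` (ids), `union_size`, `union_size_dereplicated`,
#'   `frequency` (named integer vector, decreasing), `imported`, `internal`.
#' @export
compute_solution_stats <- function(solutions, net) {
  stopifnot(inherits(net, "metnet"))
  if (inherits(solutions, "seed_solution_set")) {
    solutions <- solution_seed_sets(solutions)
  }
  if (!length(solutions)) stop("no solutions to summarize", call. = FALSE)
  sizes <- lengths(solutions)
  all_ids <- unlist(solutions, use.names = FALSE)
  freq <- sort(table(all_ids), decreasing = TRUE)
  freq <- setNames(as.integer(freq), names(freq))
  union_ids <- sort(unique(all_ids))
  base <- net$metabolites$base_id[match(union_ids, net$metabolites$id)]

  classes <- classify_boundaries(net)
  imported_mets <- character()
  for (id in names(classes)[classes %in% c("exchange", "sink")]) {
    imported_mets <- c(imported_mets, names(net$reactions[[id]]$reactants))
  }
  # reactant-less import reactions also feed their product from outside
  for (r in net$reactions) {
    if (length(r$reactants) == 0L && r$upper_bound > 0) {
      imported_mets <- c(imported_mets, names(r$products))
    }
  }
  imported_base <- unique(
    net$metabolites$base_id[match(unique(imported_mets), net$metabolites$id)])

  structure(
    list(n_solutions = length(solutions),
         sizes = sizes,
         union = union_ids,
         union_size = length(union_ids),
         union_size_dereplicated = length(unique(base)),
         frequency = freq,
         imported = union_ids[base %in% imported_base],
         internal = union_ids[!base %in% imported_base]),
    class = "solution_stats"
  )
}

#' @export
print.solution_stats <- function(x, ...) {
  cat("Solution statistics:", x$n_solutions, "solutions, sizes",
      min(x$sizes), "-", max(x$sizes), "\n")
  cat("union:", x$union_size, "metabolites (",
      x$union_size_dereplicated, "de-replicated ),",
      length(x$imported), "originally imported /",
      length(x$internal), "internal\n")
  invisible(x)
}
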