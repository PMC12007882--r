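# Independent oracles, deliberately sharing no code with the package
# internals: plain character-set computations restarted from scratch.

# Naive scope: rescan every reaction until nothing changes.
naive_scope <- function(net, seeds) {
  if (inherits(net, "norm_metnet")) net <- net$network
  reach <- sort(unique(seeds))
  repeat {
    before <- length(reach)
    for (r in net$reactions) {
      if (all(names(r$reactants) %in% reach)) {
        reach <- union(reach, names(r$products))
      }
    }
    if (length(reach) == before) break
  }
  sort(reach)
}

# Reverse reachability in the reactant -> product bipartite digraph:
# a metabolite is a candidate iff it is a target or has a directed path to
# one.
naive_backward <- function(net, targets) {
  if (inherits(net, "norm_metnet")) net <- net$network
  edges <- list()
  for (r in net$reactions) {
    for (p in names(r$products)) {
      edges[[p]] <- union(edges[[p]], names(r$reactants))
    }
  }
  out <- sort(unique(targets))
  queue <- out
  while (length(queue)) {
    m <- queue[[1L]]; queue <- queue[-1L]
    preds <- edges[[m]]
    new <- setdiff(preds, out)
    out <- union(out, new)
    queue <- c(queue, new)
  }
  sort(out)
}

# linear3 with an outlet for C so that every Boolean solution also carries
# flux (used where NE and FBA must agree)
linear3_with_demand <- function() {
  metabolic_network(
    c("A", "B", "C"),
    list(reaction("r1", c(A = 1), c(B = 1), 0, 10),
         reaction("r2", c(B = 1), c(C = 1), 0, 10),
         reaction("DM_C", c(C = 1), numeric(), 0, 10)),
    objective = "r2")
}

# the seeded fixture used for diversity comparisons (>= 20 hybrid solutions)
diversity_network <- function() {
  generate_random_network(18, 36, reversible_fraction = 0.35,
                          exchange_fraction = 0.3, seed = 9)
}

random_problem <- function(seed, n = 10, r = 15, ...) {
  net <- generate_random_network(n, r, seed = seed)
  seed_problem(net, mode = "target", max_solutions = 1000, ...)
}
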