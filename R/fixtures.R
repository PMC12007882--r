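#' Canonical hand-specified toy networks
#'
#' Small networks with known, hand-verified solution families, used
#' throughout the test-suite and documentation:
#' \describe{
#'   \item{linear3}{`r1: A -> B [0,10]`, `r2: B -> C [0,10]`, objective `r2`.
#'     Targets `{B}` (reactant of the objective); with explicit target `{C}`
#'     the subset-minimal Boolean seed sets are `{A}`, `{B}`, `{C}`.}
#'   \item{trap}{`r1: A -> B + C [0,10]`, `r2: B -> T [0,10]`, demand
#'     `DM_T: T -> 0 [0,10]`, objective the demand. Boolean solutions for
#'     target `{T}`: `{T}`, `{B}`, `{A}`. Seeding `A` strands the by-product
#'     `C` (consumed by nothing): it fails no-accumulation and FBA; the
#'     hybrid solutions are `{T}`, `{B}` and `{A,C}` (a sink on `C` restores
#'     steady state), the last being hybrid-minimal but not Boolean-minimal.}
#'   \item{fig1_like}{exercises all four normalization categories: an
#'     exchange with open import (blocked), a reversible conversion (split),
#'     a backwards-written reaction (reversed), a zero-bounds reaction
#'     (deleted). Inspired by the usual textbook toy GSMN; not a claimed
#'     reproduction of any published figure's solution set.}
#'   \item{accumulation_chain}{`r1: A -> B`, `r2: B -> C + X`,
#'     `r3: C -> T`, demand on `T`; `X` is consumed by nothing, so every
#'     seeding through `r2` violates no-accumulation.}
#' }
#'
#' @param name fixture name.
#' @param sbml_path optional path; when given the fixture is also serialized
#'   to SBML there.
#' @return A [metabolic_network()].
#' @export
generate_fixture <- function(name = c("linear3", "trap", "fig1_like",
                                      "accumulation_chain"),
                             sbml_path = NULL) {
  name <- match.arg(name)
  net <- switch(
    name,
    linear3 = metabolic_network(
      c("A", "B", "C"),
      list(reaction("r1", c(A = 1), c(B = 1), 0, 10),
           reaction("r2", c(B = 1), c(C = 1), 0, 10)),
      objective = "r2"),
    trap = metabolic_network(
      c("A", "B", "C", "T"),
      list(reaction("r1", c(A = 1), c(B = 1, C = 1), 0, 10),
           reaction("r2", c(B = 1), c(T = 1), 0, 10),
           reaction("DM_T", c(T = 1), numeric(), 0, 10)),
      objective = "DM_T"),
    fig1_like = metabolic_network(
      data.frame(
        id = c("S1_e", "A_c", "B_c", "C_c", "F_c", "G_c"),
        compartment = c("e", "c", "c", "c", "c", "c"),
        stringsAsFactors = FALSE),
      list(reaction("EX_S1", c(S1_e = 1), numeric(), -10, 1000),
           reaction("T_S1", c(S1_e = 1), c(A_c = 1), 0, 1000),
           reaction("R1", c(A_c = 1), c(B_c = 1), -10, 100),
           reaction("R2", c(C_c = 1), c(B_c = 1), -100, 0),
           reaction("R0", c(A_c = 1), c(F_c = 1), 0, 0),
           reaction("R3", c(C_c = 1), c(F_c = 1), 0, 100),
           reaction("OBJ", c(F_c = 1), c(G_c = 1), 0, 1000)),
      objective = "OBJ"),
    accumulation_chain = metabolic_network(
      c("A", "B", "C", "X", "T"),
      list(reaction("r1", c(A = 1), c(B = 1), 0, 10),
           reaction("r2", c(B = 1), c(C = 1, X = 1), 0, 10),
           reaction("r3", c(C = 1), c(T = 1), 0, 10),
           reaction("DM_T", c(T = 1), numeric(), 0, 10)),
      objective = "DM_T")
  )
  if (!is.null(sbml_path)) write_sbml(net, sbml_path)
  net
}

#' Generate a random metabolic network
#'
#' Property-test input source: a connected random reactant/product structure
#' grown outward from a set of importable (exchanged) metabolites, so that
#' the designated biomass reaction is always reachable from the exchange set
#' -- at least one Boolean seed solution is guaranteed to exist. Reactions
#' draw 1-3 reactants and 1-3 products with small integer stoichiometry.
#' Fully determined by `seed`; the caller's RNG state is left untouched.
#'
#' @param n_metabolites number of metabolites (>= 2, biomass species
#'   excluded).
#' @param n_reactions number of internal reactions (>= 1, exchanges and the
#'   biomass reaction excluded).
#' @param reversible_fraction fraction of internal reactions made reversible.
#' @param exchange_fraction fraction of metabolites given an exchange
#'   reaction (> 0: the growth frontier must start somewhere).
#' @param seed integer driving all random choices.
#' @return A [metabolic_network()] with objective `"BIOMASS"`.
#' @export
generate_random_network <- function(n_metabolites, n_reactions,
                                    reversible_fraction = 0.2,
                                    exchange_fraction = 0.3,
                                    seed = 0L) {
  stopifnot(n_metabolites >= 2, n_reactions >= 1,
            reversible_fraction >= 0, reversible_fraction <= 1)
  n_ex <- max(1L, round(exchange_fraction * n_metabolites))
  if (exchange_fraction <= 0) {
    stop("exchange_fraction must be positive: the network is grown from ",
         "its importable metabolites", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")

  ids <- sprintf("m%02d", seq_len(n_metabolites))
  ex_mets <- sort(sample(ids, n_ex))
  comp <- ifelse(ids %in% ex_mets, "e", "c")
  mets <- data.frame(id = ids, compartment = comp, stringsAsFactors = FALSE)

  rxns <- list()
  for (m in ex_mets) {
    rid <- paste0("EX_", m)
    rxns[[rid]] <- reaction(rid, setNames(1, m), numeric(), -10, 1000)
  }

  reachable <- ex_mets
  for (j in seq_len(n_reactions)) {
    from_reach <- stats::runif(1) < 0.8 || length(reachable) == n_metabolites
    pool_r <- if (from_reach) reachable else ids
    nr <- sample(1:min(3, length(pool_r)), 1)
    reactants <- sample(pool_r, nr)
    pool_p <- setdiff(ids, reactants)
    not_reached <- setdiff(pool_p, reachable)
    prefer <- if (length(not_reached)) not_reached else pool_p
    np <- sample(1:min(3, length(prefer)), 1)
    products <- sample(prefer, np)
    coefs_r <- sample(1:2, nr, replace = TRUE)
    coefs_p <- sample(1:2, np, replace = TRUE)
    rev <- stats::runif(1) < reversible_fraction
    rid <- sprintf("r%02d", j)
    rxns[[rid]] <- reaction(rid, setNames(coefs_r, reactants),
                            setNames(coefs_p, products),
                            if (rev) -10 else 0, 10)
    if (all(reactants %in% reachable)) {
      reachable <- union(reachable, products)
    }
  }

  n_bio <- sample(1:min(3, length(reachable)), 1)
  bio_reactants <- sample(reachable, n_bio)
  mets <- rbind(mets, data.frame(id = "biomass_c", compartment = "c",
                                 stringsAsFactors = FALSE))
  rxns[["BIOMASS"]] <- reaction("BIOMASS",
                                setNames(rep(1, n_bio), bio_reactants),
                                c(biomass_c = 1), 0, 1000)
  rxns[["DM_biomass"]] <- reaction("DM_biomass", c(biomass_c = 1),
                                   numeric(), 0, 1000)
  metabolic_network(mets, rxns, objective = "BIOMASS")
}
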