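#' Normalize a metabolic network
#'
#' Reconciles the flux view and the Boolean (graph) view of a model so that
#' reactants and products are well defined for scope computation:
#' \enumerate{
#'   \item reactions with `lb < 0 < ub` (reversible) are split into a forward
#'     copy with bounds `[max(0, lb), ub]` and a reverse copy with bounds
#'     `[0, -lb]`;
#'   \item reactions with `ub <= 0` and `lb < 0` are written backwards with
#'     bounds `[-ub, -lb]` (they only ever consume their nominal products);
#'   \item reactions with `lb = ub = 0` are deleted;
#'   \item for exchange and sink reactions the import direction (the reverse
#'     copy `0 -> m`) is blocked, because an open import would silently act as
#'     a seed during inference. With `keep_import = TRUE` the import copy is
#'     retained instead and recorded in `kept_imports`.
#' }
#' Demand reactions only consume and are never import-blocked.
#'
#' @param net a [metabolic_network()].
#' @param keep_import keep the import direction of exchange/sink reactions as
#'   separate `0 -> m` reactions instead of dropping it.
#' @return An object of class `norm_metnet` with components:
#'   \item{network}{the normalized [metabolic_network()] (all `lb >= 0`,
#'     `ub > 0`)}
#'   \item{provenance}{data.frame with `id`, `original_id`, `direction`
#'     (`"forward"`/`"reverse"`) for every surviving reaction}
#'   \item{kept_imports}{ids of retained import reactions}
#'   \item{report}{counts of split/reversed/deleted/blocked reactions}
#' @export
normalize_network <- function(net, keep_import = FALSE) {
  stopifnot(inherits(net, "metnet"))
  classes <- classify_boundaries(net)
  existing <- rxn_ids(net)

  rev_name <- function(id) {
    cand <- paste0(id, "_rev")
    n <- 2L
    while (cand %in% existing) {
      cand <- paste0(id, "_rev", n)
      n <- n + 1L
    }
    existing <<- c(existing, cand)
    cand
  }

  out <- list()
  prov <- list()
  kept_imports <- character()
  n_split <- n_rev <- n_del <- n_block <- 0L

  for (r in net$reactions) {
    lb <- r$lower_bound; ub <- r$upper_bound
    if (lb == 0 && ub == 0) {
      n_del <- n_del + 1L
      next
    }
    if (ub <= 0) {
      n_rev <- n_rev + 1L
      out[[r$id]] <- reaction(r$id, reactants = r$products,
                              products = r$reactants,
                              lower_bound = -ub, upper_bound = -lb)
      prov[[r$id]] <- c(r$id, "reverse")
      next
    }
    if (lb >= 0) {
      out[[r$id]] <- r
      prov[[r$id]] <- c(r$id, "forward")
      next
    }
    # reversible: split
    n_split <- n_split + 1L
    out[[r$id]] <- reaction(r$id, reactants = r$reactants,
                            products = r$products,
                            lower_bound = max(0, lb), upper_bound = ub)
    prov[[r$id]] <- c(r$id, "forward")
    import_like <- classes[[r$id]] %in% c("exchange", "sink")
    if (import_like && !keep_import) {
      n_block <- n_block + 1L
      next
    }
    rid2 <- rev_name(r$id)
    out[[rid2]] <- reaction(rid2, reactants = r$products,
                            products = r$reactants,
                            lower_bound = 0, upper_bound = -lb)
    prov[[rid2]] <- c(r$id, "reverse")
    if (import_like) kept_imports <- c(kept_imports, rid2)
  }

  provenance <- data.frame(
    id = names(prov),
    original_id = vapply(prov, `[[`, character(1), 1L),
    direction = vapply(prov, `[[`, character(1), 2L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  network <- metabolic_network(
    net$metabolites, out,
    objective = if (!is.na(net$objective) && net$objective %in% names(out))
      net$objective else NA_character_,
    extracellular = net$extracellular)

  structure(
    list(network = network, provenance = provenance,
         kept_imports = kept_imports,
         report = list(split = n_split, reversed = n_rev, deleted = n_del,
                       blocked_imports = n_block,
                       kept_imports = length(kept_imports))),
    class = "norm_metnet"
  )
}

#' @export
print.norm_metnet <- function(x, ...) {
  cat("Normalized metabolic network\n")
  print(x$network)
  r <- x$report
  cat(sprintf("split: %d, reversed: %d, deleted: %d, blocked imports: %d, kept imports: %d\n",
              r$split, r$reversed, r$deleted, r$blocked_imports,
              r$kept_imports))
  invisible(x)
}

#' Build the stoichiometric matrix
#'
#' Rows are metabolites, columns reactions, both ordered lexicographically by
#' id; an entry is the net gain of the metabolite when the reaction fires
#' positively (product coefficient minus reactant coefficient, so shared
#' participants are net-balanced).
#'
#' @param net a [metabolic_network()].
#' @return A sparse `dgCMatrix` of dimension `|M| x |R|` with dimnames.
#' @export
build_stoich_matrix <- function(net) {
  stopifnot(inherits(net, "metnet"))
  mids <- sort(met_ids(net))
  rids <- sort(rxn_ids(net))
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(rids)) {
    r <- net$reactions[[rids[j]]]
    net_coef <- setNames(numeric(), character())
    for (m in names(r$reactants)) {
      net_coef[m] <- -r$reactants[[m]]
    }
    for (m in names(r$products)) {
      net_coef[m] <- (if (m %in% names(net_coef)) net_coef[[m]] else 0) +
        r$products[[m]]
    }
    net_coef <- net_coef[net_coef != 0]
    if (!length(net_coef)) next
    ii <- c(ii, match(names(net_coef), mids))
    jj <- c(jj, rep.int(j, length(net_coef)))
    xx <- c(xx, as.numeric(net_coef))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}
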