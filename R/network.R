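#' @importFrom stats setNames
NULL

DEFAULT_BOUND <- 1000

#' Construct a reaction
#'
#' A reaction converts reactants into products with strictly positive
#' stoichiometric coefficients and carries lower/upper flux bounds. A
#' metabolite may appear on both sides; it is then net-balanced in the
#' stoichiometric matrix.
#'
#' @param id character scalar, unique reaction identifier.
#' @param reactants named numeric vector of strictly positive coefficients
#'   (names are metabolite ids); may be empty.
#' @param products named numeric vector, as `reactants`.
#' @param lower_bound,upper_bound flux bounds, `lower_bound <= upper_bound`.
#' @return An object of class `skreaction`.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     lower_bound = 0, upper_bound = DEFAULT_BOUND) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  reactants <- as_coefs(reactants, id, "reactant")
  products <- as_coefs(products, id, "product")
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound) ||
      is.na(lower_bound) || is.na(upper_bound)) {
    stop("reaction '", id, "': bounds must be numeric", call. = FALSE)
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound", call. = FALSE)
  }
  structure(
    list(id = id, reactants = reactants, products = products,
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound)),
    class = "skreaction"
  )
}

as_coefs <- function(x, rid, side) {
  if (length(x) == 0L) return(setNames(numeric(), character()))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("reaction '", rid, "': ", side, " coefficients must be named",
         call. = FALSE)
  }
  nm <- names(x)
  x <- as.numeric(x)
  names(x) <- nm
  if (any(x <= 0) || anyNA(x)) {
    stop("reaction '", rid, "': ", side,
         " coefficients must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    x <- tapply(x, names(x), sum)
    x <- setNames(as.numeric(x), names(x))
  }
  x
}

#' Construct a metabolic network
#'
#' The central container: a set of metabolites, a set of reactions over them,
#' and an optional objective reaction (typically biomass). Reversibility is
#' represented purely through flux bounds.
#'
#' @param metabolites a data.frame with columns `id` and `compartment`
#'   (optionally `name`), or a character vector of ids in which case all
#'   metabolites are placed in compartment `"c"`.
#' @param reactions a list of [reaction()] objects.
#' @param objective id of the objective reaction, or `NA`.
#' @param extracellular compartment ids regarded as extracellular; used for
#'   boundary classification and transport detection.
#' @return An object of class `metnet` with components `metabolites`
#'   (data.frame with `id`, `compartment`, `name`, `base_id`), `reactions`
#'   (named list), `objective`, `extracellular`.
#' @export
metabolic_network <- function(metabolites, reactions = list(),
                              objective = NA_character_,
                              extracellular = c("e", "extracellular")) {
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites, compartment = "c",
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(metabolites),
            all(c("id", "compartment") %in% names(metabolites)))
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (anyDuplicated(metabolites$id)) {
    stop("duplicated metabolite ids", call. = FALSE)
  }
  if (any(!nzchar(metabolites$compartment) | is.na(metabolites$compartment))) {
    stop("every metabolite needs a non-empty compartment", call. = FALSE)
  }
  metabolites$base_id <- base_ids(metabolites$id, metabolites$compartment)
  rownames(metabolites) <- NULL

  if (inherits(reactions, "skreaction")) reactions <- list(reactions)
  rids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids)) stop("duplicated reaction ids", call. = FALSE)
  names(reactions) <- rids
  referenced <- unique(unlist(lapply(reactions, function(r) {
    c(names(r$reactants), names(r$products))
  }), use.names = FALSE))
  unknown <- setdiff(referenced, metabolites$id)
  if (length(unknown)) {
    stop("reactions reference unknown metabolites: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.na(objective) && !objective %in% rids) {
    stop("objective reaction '", objective, "' not in the network",
         call. = FALSE)
  }
  structure(
    list(metabolites = metabolites[, c("id", "compartment", "name", "base_id")],
         reactions = reactions,
         objective = as.character(objective),
         extracellular = extracellular),
    class = "metnet"
  )
}

# species id stripped of its trailing "_<compartment>" token, used only for
# de-replicated statistics (same molecule, different compartment)
base_ids <- function(ids, compartments) {
  suffix <- paste0("_", compartments)
  has <- substring(ids, nchar(ids) - nchar(suffix) + 1L) == suffix
  out <- ids
  out[has] <- substring(ids[has], 1L, nchar(ids[has]) - nchar(suffix[has]))
  out[!nzchar(out)] <- ids[!nzchar(out)]
  out
}

met_ids <- function(net) net$metabolites$id
rxn_ids <- function(net) names(net$reactions)

met_compartment <- function(net, ids) {
  net$metabolites$compartment[match(ids, net$metabolites$id)]
}

is_extracellular_met <- function(net, ids) {
  met_compartment(net, ids) %in% net$extracellular
}

#' @export
print.metnet <- function(x, ...) {
  cat("Metabolic network: ", nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions\n", sep = "")
  if (!is.na(x$objective)) cat("Objective reaction:", x$objective, "\n")
  rev <- sum(vapply(x$reactions, function(r) r$lower_bound < 0 & r$upper_bound > 0,
                    logical(1)))
  cat("Reversible reactions:", rev, "\n")
  invisible(x)
}

#' @export
format.skreaction <- function(x, ...) {
  side <- function(v) {
    if (!length(v)) return("∅")
    paste(ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
  }
  sprintf("%s: %s -> %s [%g, %g]", x$id, side(x$reactants), side(x$products),
          x$lower_bound, x$upper_bound)
}

#' @export
print.skreaction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Test two networks for equality on the modelled fields
#'
#' Compares id sets, stoichiometries, bounds, objective and compartments,
#' ignoring ordering. Used by round-trip tests of the SBML layer.
#'
#' @param a,b `metnet` objects.
#' @return `TRUE` or `FALSE`.
#' @export
networks_equal <- function(a, b) {
  ma <- a$metabolites[order(a$metabolites$id), c("id", "compartment")]
  mb <- b$metabolites[order(b$metabolites$id), c("id", "compartment")]
  rownames(ma) <- rownames(mb) <- NULL
  if (!identical(ma, mb)) return(FALSE)
  if (!identical(sort(rxn_ids(a)), sort(rxn_ids(b)))) return(FALSE)
  same_obj <- (is.na(a$objective) && is.na(b$objective)) ||
    identical(a$objective, b$objective)
  if (!same_obj) return(FALSE)
  for (id in rxn_ids(a)) {
    ra <- a$reactions[[id]]; rb <- b$reactions[[id]]
    srt <- function(v) v[order(names(v))]
    if (!isTRUE(all.equal(srt(ra$reactants), srt(rb$reactants))) ||
        !isTRUE(all.equal(srt(ra$products), srt(rb$products))) ||
        !isTRUE(all.equal(c(ra$lower_bound, ra$upper_bound),
                          c(rb$lower_bound, rb$upper_bound)))) {
      return(FALSE)
    }
  }
  TRUE
}
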