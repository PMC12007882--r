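#' Classify boundary pseudo-reactions
#'
#' Boundary reactions are unbalanced pseudo-reactions used to add or remove a
#' metabolite at the system boundary. Each reaction is assigned exactly one
#' class:
#' \describe{
#'   \item{exchange}{no products, negative lower bound and positive upper
#'     bound, sole participant extracellular (`m_e <-> 0`)}
#'   \item{demand}{no products, zero lower bound, positive upper bound,
#'     participant intracellular (`m_c -> 0`)}
#'   \item{sink}{no products, negative lower bound, positive upper bound,
#'     participant intracellular (`m_c <-> 0`)}
#'   \item{internal}{everything else}
#' }
#' Productless reactions with several participants match no pseudo-reaction
#' pattern and are classified internal (a message is emitted).
#'
#' @param net a [metabolic_network()].
#' @return Named character vector (one of `"exchange"`, `"demand"`, `"sink"`,
#'   `"internal"`), named by reaction id.
#' @export
classify_boundaries <- function(net) {
  stopifnot(inherits(net, "metnet"))
  out <- setNames(rep("internal", length(net$reactions)), rxn_ids(net))
  ambiguous <- character()
  for (r in net$reactions) {
    if (length(r$products) > 0L) next
    if (length(r$reactants) != 1L) {
      if (length(r$reactants) > 1L) ambiguous <- c(ambiguous, r$id)
      next
    }
    m <- names(r$reactants)
    extr <- is_extracellular_met(net, m)
    if (r$lower_bound < 0 && r$upper_bound > 0) {
      out[r$id] <- if (extr) "exchange" else "sink"
    } else if (r$lower_bound == 0 && r$upper_bound > 0 && !extr) {
      out[r$id] <- "demand"
    }
  }
  if (length(ambiguous)) {
    message("productless reactions with several participants kept internal: ",
            paste(ambiguous, collapse = ", "))
  }
  out
}
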