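SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic network from SBML
#'
#' Parses SBML level 2 or 3. Flux bounds are taken, in order of precedence,
#' from fbc `lowerFluxBound`/`upperFluxBound` parameter references, from
#' COBRA-style `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters, or from the
#' `reversible` flag (reversible reactions default to \[-1000, 1000\],
#' irreversible to \[0, 1000\]). The declared fbc objective is read; when a
#' model weights several reactions, the one with the largest absolute
#' coefficient is kept with a warning. A negative objective coefficient
#' (minimization) is flagged with a warning and otherwise kept as declared.
#'
#' @param path path to an SBML file.
#' @param objective_override reaction id to use as objective instead of the
#'   model's declared one, or `NULL`.
#' @param extracellular compartment ids regarded as extracellular.
#' @return A [metabolic_network()].
#' @export
read_sbml <- function(path, objective_override = NULL,
                      extracellular = c("e", "extracellular")) {
  if (!file.exists(path)) stop("SBML file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)

  sp <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp) == 0L) stop("no species in SBML model", call. = FALSE)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    compartment = xml2::xml_attr(sp, "compartment"),
    name = xml2::xml_attr(sp, "name"),
    stringsAsFactors = FALSE
  )
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  mets$compartment[is.na(mets$compartment)] <- "c"

  # global parameters, used by fbc bound references
  par_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_vals <- setNames(
    sbml_num(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id")
  )

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    reactions[[i]] <- parse_reaction_node(rx_nodes[[i]], par_vals)
  }

  objective <- parse_fbc_objective(doc)
  if (!is.null(objective_override)) objective <- objective_override
  if (is.na(objective)) {
    message("model declares no objective reaction; ",
            "only full-network mode is possible without an override")
  }

  metabolic_network(mets, reactions, objective = objective,
                    extracellular = extracellular)
}

sbml_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x %in% c("INF", "inf", "Inf")] <- Inf
  out[x %in% c("-INF", "-inf", "-Inf")] <- -Inf
  out
}

parse_reaction_node <- function(node, par_vals) {
  id <- xml2::xml_attr(node, "id")
  attrs <- xml2::xml_attrs(node)
  nm <- names(attrs)

  refs <- function(which) {
    sr <- xml2::xml_find_all(
      node, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", which))
    if (length(sr) == 0L) return(setNames(numeric(), character()))
    st <- xml2::xml_attr(sr, "stoichiometry")
    st[is.na(st)] <- "1"
    setNames(as.numeric(st), xml2::xml_attr(sr, "species"))
  }
  reactants <- refs("listOfReactants")
  products <- refs("listOfProducts")

  pick_attr <- function(local) {
    hit <- grepl(paste0("(^|:)", local, "$"), nm)
    if (any(hit)) attrs[[which(hit)[1L]]] else NA_character_
  }
  lb_ref <- pick_attr("lowerFluxBound")
  ub_ref <- pick_attr("upperFluxBound")
  lb <- ub <- NA_real_
  if (!is.na(lb_ref)) lb <- resolve_bound(lb_ref, par_vals, id)
  if (!is.na(ub_ref)) ub <- resolve_bound(ub_ref, par_vals, id)

  if (is.na(lb) || is.na(ub)) {
    # COBRA SBML level-2 convention: kinetic-law parameters
    kl <- xml2::xml_find_all(
      node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
    if (length(kl)) {
      kid <- xml2::xml_attr(kl, "id")
      kval <- sbml_num(xml2::xml_attr(kl, "value"))
      if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kval[match("LOWER_BOUND", kid)]
      if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kval[match("UPPER_BOUND", kid)]
    }
  }

  if (is.na(lb) || is.na(ub)) {
    rev_attr <- pick_attr("reversible")
    if (is.na(rev_attr)) {
      stop("reaction '", id,
           "' has neither flux bounds nor a reversibility flag", call. = FALSE)
    }
    rev <- tolower(rev_attr) %in% c("true", "1")
    if (is.na(lb)) lb <- if (rev) -DEFAULT_BOUND else 0
    if (is.na(ub)) ub <- DEFAULT_BOUND
  }

  reaction(id, reactants = reactants, products = products,
           lower_bound = lb, upper_bound = ub)
}

resolve_bound <- function(ref, par_vals, rid) {
  if (ref %in% names(par_vals)) return(par_vals[[ref]])
  val <- sbml_num(ref)
  if (is.na(val)) {
    stop("reaction '", rid, "': flux-bound reference '", ref,
         "' resolves to no parameter", call. = FALSE)
  }
  val
}

parse_fbc_objective <- function(doc) {
  lo <- xml2::xml_find_first(doc, ".//*[local-name()='listOfObjectives']")
  if (inherits(lo, "xml_missing")) return(NA_character_)
  active <- xml2::xml_attrs(lo)
  active_id <- {
    hit <- grepl("(^|:)activeObjective$", names(active))
    if (any(hit)) active[[which(hit)[1L]]] else NA_character_
  }
  objs <- xml2::xml_find_all(lo, ".//*[local-name()='objective']")
  if (length(objs) == 0L) return(NA_character_)
  pick <- objs[[1L]]
  if (!is.na(active_id)) {
    ids <- vapply(objs, function(o) {
      a <- xml2::xml_attrs(o)
      hit <- grepl("(^|:)id$", names(a))
      if (any(hit)) a[[which(hit)[1L]]] else NA_character_
    }, character(1))
    if (active_id %in% ids) pick <- objs[[match(active_id, ids)]]
  }
  fo <- xml2::xml_find_all(pick, ".//*[local-name()='fluxObjective']")
  if (length(fo) == 0L) return(NA_character_)
  get_qattr <- function(nodes, local) {
    vapply(nodes, function(n) {
      a <- xml2::xml_attrs(n)
      hit <- grepl(paste0("(^|:)", local, "$"), names(a))
      if (any(hit)) a[[which(hit)[1L]]] else NA_character_
    }, character(1))
  }
  rids <- get_qattr(fo, "reaction")
  coefs <- suppressWarnings(as.numeric(get_qattr(fo, "coefficient")))
  coefs[is.na(coefs)] <- 1
  if (length(rids) > 1L) {
    warning("objective weights several reactions; keeping '",
            rids[which.max(abs(coefs))], "' (largest |coefficient|)",
            call. = FALSE)
  }
  best <- which.max(abs(coefs))
  if (coefs[best] < 0) {
    warning("objective coefficient of '", rids[best],
            "' is negative (minimization objective declared); kept as is",
            call. = FALSE)
  }
  rids[best]
}

#' Write a metabolic network to SBML
#'
#' Serializes to SBML level 3 version 1 with the fbc version 2 package: flux
#' bounds become global parameters referenced per reaction, and the objective
#' reaction (if any) becomes the active fbc objective. Metabolite and reaction
#' ids are written verbatim.
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  stopifnot(inherits(net, "metnet"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "false")

  comps <- unique(net$metabolites$compartment)
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in comps) {
    xml2::xml_add_child(loc, "compartment", id = cid, constant = "true")
  }

  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$metabolites))) {
    xml2::xml_add_child(
      los, "species", id = net$metabolites$id[i],
      name = net$metabolites$name[i],
      compartment = net$metabolites$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }

  lop <- xml2::xml_add_child(model, "listOfParameters")
  fmtb <- function(v) {
    if (is.infinite(v)) (if (v > 0) "INF" else "-INF") else
      format(v, scientific = FALSE, digits = 15)
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (r in net$reactions) {
    lb_id <- paste0("bnd_", r$id, "_lb")
    ub_id <- paste0("bnd_", r$id, "_ub")
    xml2::xml_add_child(lop, "parameter", id = lb_id,
                        value = fmtb(r$lower_bound), constant = "true")
    xml2::xml_add_child(lop, "parameter", id = ub_id,
                        value = fmtb(r$upper_bound), constant = "true")
    rn <- xml2::xml_add_child(
      lor, "reaction", id = r$id,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = lb_id, "fbc:upperFluxBound" = ub_id)
    add_refs <- function(which, v) {
      if (!length(v)) return(invisible())
      lst <- xml2::xml_add_child(rn, which)
      for (m in names(v)) {
        xml2::xml_add_child(lst, "speciesReference", species = m,
                            stoichiometry = format(v[[m]], digits = 15),
                            constant = "true")
      }
    }
    add_refs("listOfReactants", r$reactants)
    add_refs("listOfProducts", r$products)
  }

  if (!is.na(net$objective)) {
    loo <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = net$objective,
                        "fbc:coefficient" = "1")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}
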