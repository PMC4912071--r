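#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Ontology graph (is_a DAG)
#'
#' Directed acyclic graph of ontology terms connected by `is_a`
#' child-to-parent edges, as obtained from an OBO file. Only terms and
#' `is_a` relations are represented; gene annotation is kept separately
#' as a long-format `data.frame` (columns `gene_id`, `term_id`).
#'
#' @slot terms `data.frame` with columns `id`, `name`, one row per term.
#' @slot edges `data.frame` with columns `child`, `parent`; each row is an
#'   `is_a` relation pointing from the more specific to the more general term.
#'
#' @seealso [readOBO()], [goGeneSet()], [termDescendants()]
#' @export
setClass("OntologyGraph",
         representation(terms = "data.frame", edges = "data.frame"))

setValidity("OntologyGraph", function(object) {
  msg <- character()
  if (!all(c("id", "name") %in% names(object@terms)))
    msg <- c(msg, "terms must have columns 'id' and 'name'")
  if (!all(c("child", "parent") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns 'child' and 'parent'")
  if (length(msg)) return(msg)
  if (anyDuplicated(object@terms$id))
    msg <- c(msg, "duplicated term ids")
  known <- object@terms$id
  bad <- !(object@edges$child %in% known & object@edges$parent %in% known)
  if (any(bad))
    msg <- c(msg, "edge endpoints must be declared terms")
  if (nrow(object@edges) > 0 && !any(bad)) {
    g <- igraph::graph_from_data_frame(object@edges, directed = TRUE,
                                       vertices = known)
    if (!igraph::is_dag(g)) {
      cyc <- .findCycle(object@edges)
      msg <- c(msg, paste0("is_a relations contain a cycle: ",
                           paste(cyc, collapse = " -> ")))
    }
  }
  if (length(msg)) msg else TRUE
})

# locate one directed cycle among child->parent edges, for error reporting
.findCycle <- function(edges) {
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  for (v in igraph::V(g)$name) {
    ego <- igraph::subcomponent(g, v, mode = "out")
    preds <- igraph::neighbors(g, v, mode = "in")$name
    hit <- intersect(preds, ego$name)
    if (length(hit)) {
      p <- igraph::shortest_paths(g, from = v, to = hit[1],
                                  mode = "out")$vpath[[1]]$name
      return(c(p, v))
    }
  }
  character()
}

#' Compartmentalised stoichiometric metabolic model
#'
#' Container for a small constraint-based metabolic model: metabolites with
#' optional SMILES strings and compartment labels, reactions with signed
#' stoichiometry (negative coefficients denote substrates), reversibility,
#' gene associations and pathway membership, plus a designated biomass
#' reaction and the exchange (boundary) reactions.
#'
#' @slot metabolites `data.frame` with columns `id`, `name`, `smiles`,
#'   `compartment` (one row per metabolite; empty strings for absent fields).
#' @slot reactions `data.frame` with columns `id`, `reversible` (logical),
#'   `compartment`, and list-columns `stoichiometry` (named numeric vectors,
#'   metabolite id to signed coefficient), `genes` (character vectors) and
#'   `pathways` (character vectors of pathway ids).
#' @slot pathways `data.frame` with columns `id`, `name` and a list-column
#'   `reactions` of member reaction ids.
#' @slot biomassReaction id of the biomass (objective) reaction.
#' @slot exchanges ids of exchange reactions crossing the system boundary.
#'
#' @seealso [readModel()], [fbaSolve()], [stoichiometricMatrix()]
#' @export
setClass("MetabolicModel",
         representation(metabolites = "data.frame",
                        reactions = "data.frame",
                        pathways = "data.frame",
                        biomassReaction = "character",
                        exchanges = "character"))

setValidity("MetabolicModel", function(object) {
  msg <- character()
  if (!all(c("id", "name", "smiles", "compartment") %in%
           names(object@metabolites)))
    msg <- c(msg, "metabolites must have columns id, name, smiles, compartment")
  req <- c("id", "reversible", "compartment", "stoichiometry", "genes",
           "pathways")
  if (!all(req %in% names(object@reactions)))
    msg <- c(msg, paste("reactions must have columns",
                        paste(req, collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(object@metabolites$id))
    msg <- c(msg, paste("duplicated metabolite id(s):",
                        paste(unique(object@metabolites$id[
                          duplicated(object@metabolites$id)]), collapse = ", ")))
  if (anyDuplicated(object@reactions$id))
    msg <- c(msg, paste("duplicated reaction id(s):",
                        paste(unique(object@reactions$id[
                          duplicated(object@reactions$id)]), collapse = ", ")))
  mids <- object@metabolites$id
  for (i in seq_len(nrow(object@reactions))) {
    st <- object@reactions$stoichiometry[[i]]
    unknown <- setdiff(names(st), mids)
    if (length(unknown))
      msg <- c(msg, paste0("reaction '", object@reactions$id[i],
                           "' references undeclared metabolite(s): ",
                           paste(unknown, collapse = ", ")))
  }
  if (length(object@biomassReaction) != 1L ||
      !object@biomassReaction %in% object@reactions$id)
    msg <- c(msg, "biomass reaction must be a declared reaction id")
  if (!all(object@exchanges %in% object@reactions$id))
    msg <- c(msg, "exchange ids must be declared reaction ids")
  if (nrow(object@pathways)) {
    for (i in seq_len(nrow(object@pathways))) {
      unknown <- setdiff(object@pathways$reactions[[i]], object@reactions$id)
      if (length(unknown))
        msg <- c(msg, paste0("pathway '", object@pathways$id[i],
                             "' references undeclared reaction(s): ",
                             paste(unknown, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Bootstrap background table for enrichment scoring
#'
#' For each gene-set size `k`, the mean and standard deviation of the total
#' Z-score of random size-`k` gene sets sampled (without replacement) from a
#' stated gene universe. These are the background moments entering the
#' enrichment score `(total Z - mean) / sd`.
#'
#' @slot stats `data.frame` with columns `k`, `mean`, `sd`.
#' @slot nBoot number of random sets sampled per size.
#' @slot seed integer seed that generated the table.
#' @slot universe label of the sampling universe (`"all_genes"` or
#'   `"enzyme_genes"`).
#'
#' @seealso [computeBackground()], [enrichmentScore()]
#' @export
setClass("BackgroundTable",
         representation(stats = "data.frame", nBoot = "integer",
                        seed = "integer", universe = "character"))

setValidity("BackgroundTable", function(object) {
  msg <- character()
  if (!all(c("k", "mean", "sd") %in% names(object@stats)))
    msg <- c(msg, "stats must have columns k, mean, sd")
  else {
    if (any(object@stats$sd < 0, na.rm = TRUE)) msg <- c(msg, "sd must be >= 0")
    if (any(object@stats$k < 1)) msg <- c(msg, "k must be positive")
    if (anyDuplicated(object@stats$k)) msg <- c(msg, "duplicated k entries")
  }
  if (object@nBoot < 1L) msg <- c(msg, "nBoot must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Flux distribution for one condition
#'
#' A steady-state flux vector returned by [fbaSolve()]: one signed flux per
#' reaction (units follow the measured exchange rates, conventionally
#' mmol h^-1 gDW^-1) together with the attained objective (biomass) flux.
#'
#' @slot condition label of the condition the fluxes describe.
#' @slot fluxes named numeric vector, reaction id to flux.
#' @slot objective attained biomass flux.
#'
#' @seealso [fbaSolve()], [differentialFlux()]
#' @export
setClass("FluxState",
         representation(condition = "character", fluxes = "numeric",
                        objective = "numeric"))

setValidity("FluxState", function(object) {
  msg <- character()
  if (is.null(names(object@fluxes)) && length(object@fluxes))
    msg <- c(msg, "fluxes must be named by reaction id")
  if (any(!is.finite(object@fluxes))) msg <- c(msg, "fluxes must be finite")
  if (length(msg)) msg else TRUE
})
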