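#' Enzyme-gene neighbourhood of a metabolite
#'
#' The deduplicated union of the gene associations of every reaction whose
#' stoichiometry involves the metabolite, on either side. This is the gene
#' set whose collective differential expression defines a reporter
#' metabolite.
#'
#' @param metaboliteId a metabolite id present in the model.
#' @param model a [MetabolicModel-class].
#' @return character vector of gene ids (sorted, deduplicated).
#' @export
metaboliteNeighbourhood <- function(metaboliteId, model) {
  stopifnot(is(model, "MetabolicModel"))
  if (!metaboliteId %in% metabolites(model)$id)
    stop("unknown metabolite: ", metaboliteId)
  rxn <- reactions(model)
  touches <- vapply(rxn$stoichiometry,
                    function(st) metaboliteId %in% names(st), logical(1))
  sort(unique(as.character(unlist(rxn$genes[touches]))))
}

#' Reporter-metabolite enrichment scores
#'
#' Scores every metabolite by the enrichment of differential expression in
#' its neighbouring enzyme genes, using the same size-corrected total
#' Z-score as gene-set enrichment but with the bootstrap background drawn
#' from enzyme-encoding genes only (genes mapped to at least one reaction).
#' Metabolic genes are often collectively more differentially expressed
#' than the genome at large, so an all-genes background would inflate every
#' metabolite's score; the enzyme-only background corrects for this.
#'
#' Currency metabolites (water, protons, redox and energy cofactors) are
#' scored like any other metabolite by default; pass their ids in
#' `excludeMetabolites` to opt out. When the model declares compartments,
#' each compartment-tagged metabolite instance is scored separately; set
#' `mergeCompartments = TRUE` to pool neighbourhoods by base compound.
#'
#' @param model a [MetabolicModel-class].
#' @param zmap named numeric vector, gene id to Z-score.
#' @param de differential-expression `data.frame` for direction summaries.
#' @param nBoot bootstrap iterations per neighbourhood size (default 1000).
#' @param seed integer seed.
#' @param excludeMetabolites metabolite ids to skip (opt-in currency list).
#' @param mergeCompartments pool compartment instances by base id?
#' @return `data.frame` with one row per scored metabolite: `metabolite_id`,
#'   `name`, `compartment`, `smiles`, `k`, `total_z`, `bg_mean`, `bg_sd`,
#'   `score`, `n_up`, `n_down`, `dominant_fraction`, `score_defined`.
#'   Metabolites with empty neighbourhoods are skipped.
#' @export
reporterScores <- function(model, zmap, de = NULL, nBoot = 1000L, seed = 1L,
                           excludeMetabolites = character(),
                           mergeCompartments = FALSE) {
  stopifnot(is(model, "MetabolicModel"))
  universe <- intersect(enzymeGenes(model), names(zmap))
  if (!length(universe)) stop("no enzyme gene has a Z-score")
  met <- metabolites(model)
  met <- met[!met$id %in% excludeMetabolites, , drop = FALSE]
  rxn <- reactions(model)
  rxnMets <- lapply(rxn$stoichiometry, names)
  neighbours <- lapply(met$id, function(m) {
    touches <- vapply(rxnMets, function(x) m %in% x, logical(1))
    unique(unlist(rxn$genes[touches]))
  })
  names(neighbours) <- met$id
  ids <- met$id
  labels <- met
  if (mergeCompartments) {
    base <- baseMetaboliteIds(model)[met$id]
    merged <- split(unlist(neighbours, use.names = FALSE),
                    rep(base, lengths(neighbours)))
    merged <- lapply(merged, unique)
    ids <- names(merged)
    neighbours <- merged
    labels <- data.frame(id = ids, name = ids, compartment = "",
                         smiles = "", stringsAsFactors = FALSE)
  }
  neighbours <- lapply(neighbours, function(g) intersect(g, universe))
  keep <- lengths(neighbours) > 0L
  if (!any(keep)) return(.emptyReporter())
  neighbours <- neighbours[keep]
  ids <- ids[keep]
  labels <- labels[match(ids, labels$id), , drop = FALSE]
  if (max(lengths(neighbours)) > length(universe))
    stop("enzyme universe smaller than largest neighbourhood")
  bg <- computeBackground(zmap, unique(lengths(neighbours)), nBoot = nBoot,
                          seed = seed, universe = universe,
                          universeLabel = "enzyme_genes")
  rows <- lapply(seq_along(ids), function(i) {
    r <- enrichmentScore(neighbours[[i]], zmap, bg, de)
    cbind(data.frame(metabolite_id = ids[i], name = labels$name[i],
                     compartment = labels$compartment[i],
                     smiles = labels$smiles[i], stringsAsFactors = FALSE),
          r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyReporter <- function() {
  data.frame(metabolite_id = character(), name = character(),
             compartment = character(), smiles = character(), k = integer(),
             total_z = numeric(), bg_mean = numeric(), bg_sd = numeric(),
             score = numeric(), n_up = integer(), n_down = integer(),
             dominant_fraction = numeric(), score_defined = logical(),
             stringsAsFactors = FALSE)
}

#' Reporter metabolite-enzyme network
#'
#' Projects the metabolic hypergraph onto a bipartite graph that retains
#' only the interactions between enriched reporter metabolites and
#' differentially expressed enzyme genes: metabolite nodes with enrichment
#' score at or above `scoreThreshold`, gene nodes with `q < qThreshold`
#' that neighbour at least one retained metabolite, and edges wherever a
#' gene belongs to a retained metabolite's neighbourhood.
#'
#' @param scores reporter score `data.frame` from [reporterScores()].
#' @param de differential-expression `data.frame`.
#' @param model the [MetabolicModel-class] supplying the adjacency.
#' @param scoreThreshold minimum metabolite enrichment score (default 3.0,
#'   the focused-network cut; 1.64 gives the permissive variant).
#' @param qThreshold maximum gene q-value (default 0.05).
#' @return undirected bipartite `igraph`; metabolite nodes carry `score`,
#'   `direction` and `dominant_fraction`, gene nodes carry `log2_fc`;
#'   all nodes carry `type` (`"metabolite"` or `"gene"`).
#' @export
reporterEnzymeNetwork <- function(scores, de, model, scoreThreshold = 3.0,
                                  qThreshold = 0.05) {
  stopifnot(is(model, "MetabolicModel"))
  keepMet <- scores[!is.na(scores$score) & scores$score >= scoreThreshold, ,
                    drop = FALSE]
  sigGenes <- de$gene_id[de$q_value < qThreshold]
  edges <- list()
  for (i in seq_len(nrow(keepMet))) {
    nb <- intersect(metaboliteNeighbourhood(keepMet$metabolite_id[i], model),
                    sigGenes)
    if (length(nb))
      edges[[length(edges) + 1L]] <-
        data.frame(metabolite = keepMet$metabolite_id[i], gene = nb,
                   stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(metabolite = character(), gene = character(),
               stringsAsFactors = FALSE)
  genes <- unique(edges$gene)
  mets <- keepMet$metabolite_id
  g <- igraph::make_empty_graph(directed = FALSE)
  if (length(mets)) {
    dirn <- ifelse(keepMet$n_up > keepMet$n_down, "up",
                   ifelse(keepMet$n_down > keepMet$n_up, "down", "mixed"))
    g <- igraph::add_vertices(g, length(mets), name = mets,
                              type = "metabolite", score = keepMet$score,
                              direction = dirn,
                              dominant_fraction = keepMet$dominant_fraction,
                              log2_fc = NA_real_)
  }
  if (length(genes)) {
    lfc <- de$log2_fc[match(genes, de$gene_id)]
    g <- igraph::add_vertices(g, length(genes), name = genes, type = "gene",
                              score = NA_real_,
                              direction = ifelse(lfc > 0, "up", "down"),
                              dominant_fraction = NA_real_, log2_fc = lfc)
  }
  if (nrow(edges))
    g <- igraph::add_edges(
      g, rbind(match(edges$metabolite, igraph::V(g)$name),
               match(edges$gene, igraph::V(g)$name)))
  g
}
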