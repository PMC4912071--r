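#' Pathway-to-pathway overlap network
#'
#' Clusters pathways by their shared metabolites: for every pathway pair the
#' number of common metabolites is normalised by the size of the smaller of
#' the two metabolite sets, and pairs at or above `threshold` become edges.
#' Pathways left without any retained edge are attached to a designated
#' `"Self"` sink node, so every pathway remains visible in the rendering.
#' Metabolite sets are compartment-stripped (see [pathwayMetaboliteSets()]),
#' since reference pathway definitions are compartment-naive.
#'
#' @param model a [MetabolicModel-class].
#' @param enrich optional pathway enrichment `data.frame` from [enrichAll()]
#'   (matched on `set_id`); when given, pathway nodes carry `score`,
#'   `direction` and `dominant_fraction` attributes for rendering.
#' @param threshold minimum normalised overlap for an edge (default 0.3).
#' @return undirected weighted `igraph`; edge `weight` is the normalised
#'   overlap `|A intersect B| / min(|A|, |B|)` in `[0, 1]`.
#' @export
pathwayNetwork <- function(model, enrich = NULL, threshold = 0.3) {
  stopifnot(is(model, "MetabolicModel"))
  sets <- pathwayMetaboliteSets(model)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("excluding pathway(s) with empty metabolite set: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  ids <- names(sets)
  n <- length(ids)
  edges <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      norm <- shared / min(length(sets[[i]]), length(sets[[j]]))
      if (norm >= threshold)
        edges[[length(edges) + 1L]] <-
          data.frame(from = ids[i], to = ids[j], shared = shared,
                     weight = norm, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), shared = integer(),
               weight = numeric(), stringsAsFactors = FALSE)
  orphans <- setdiff(ids, unique(c(edges$from, edges$to)))
  vnames <- c(ids, if (length(orphans)) "Self")
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(vnames), name = vnames)
  igraph::V(g)$score <- NA_real_
  igraph::V(g)$direction <- NA_character_
  igraph::V(g)$dominant_fraction <- NA_real_
  if (!is.null(enrich)) {
    m <- match(igraph::V(g)$name, enrich$set_id)
    hit <- !is.na(m)
    igraph::V(g)$score[hit] <- enrich$score[m[hit]]
    igraph::V(g)$direction[hit] <-
      ifelse(enrich$n_up[m[hit]] > enrich$n_down[m[hit]], "up",
             ifelse(enrich$n_down[m[hit]] > enrich$n_up[m[hit]], "down",
                    "mixed"))
    igraph::V(g)$dominant_fraction[hit] <- enrich$dominant_fraction[m[hit]]
  }
  allEdges <- edges
  if (length(orphans))
    allEdges <- rbind(edges,
                      data.frame(from = orphans, to = "Self", shared = 0L,
                                 weight = 0, stringsAsFactors = FALSE))
  if (nrow(allEdges)) {
    g <- igraph::add_edges(g, rbind(match(allEdges$from, vnames),
                                    match(allEdges$to, vnames)))
    igraph::E(g)$weight <- allEdges$weight
    igraph::E(g)$shared <- allEdges$shared
  }
  g
}

#' Normalised SMILES string similarity
#'
#' Similarity between two molecules by plain string matching of their SMILES
#' representations: the Levenshtein edit distance (unit-cost insertions,
#' deletions, substitutions) normalised to the length of the longer string,
#' `1 - d / max(|s1|, |s2|)`. The comparison is purely textual; no SMILES
#' canonicalisation is attempted.
#'
#' @param s1,s2 non-empty character vectors (recycled to a common length).
#' @return numeric vector of similarities in `[0, 1]`; identical strings
#'   score 1.
#' @examples
#' smilesSimilarity("CCO", "CC")   # 1 - 1/3
#' @export
smilesSimilarity <- function(s1, s2) {
  if (any(!nzchar(s1)) || any(!nzchar(s2)))
    stop("empty SMILES string")
  n <- max(length(s1), length(s2))
  s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  d <- diag(utils::adist(s1, s2))
  1 - d / pmax(nchar(s1), nchar(s2))
}

#' Molecular similarity network of reporter metabolites
#'
#' Builds the closest-match molecular network: each reporter metabolite with
#' enrichment score at or above `minScore` is linked to its single most
#' similar partner by normalised SMILES edit distance, provided that
#' similarity reaches `simThreshold`; otherwise (or when the molecule has no
#' SMILES string) it is attached to the `"Self"` sink node. Reciprocal
#' closest-match pairs collapse to one undirected edge. Ties for the closest
#' partner break lexicographically by partner id.
#'
#' @param reporters reporter score `data.frame` (needs `metabolite_id`,
#'   `score`, `smiles`; `n_up`/`n_down`/`dominant_fraction` are carried as
#'   node attributes when present).
#' @param minScore minimum enrichment score for inclusion (default 1.64).
#' @param simThreshold minimum normalised similarity for a real edge
#'   (default 0.4).
#' @return undirected weighted `igraph`; edge `weight` is the similarity
#'   (0 for Self edges).
#' @export
molecularNetwork <- function(reporters, minScore = 1.64, simThreshold = 0.4) {
  keep <- reporters[!is.na(reporters$score) & reporters$score >= minScore, ,
                    drop = FALSE]
  keep <- keep[order(keep$metabolite_id), , drop = FALSE]
  ids <- keep$metabolite_id
  smi <- keep$smiles
  hasSmiles <- !is.na(smi) & nzchar(smi)
  if (any(!hasSmiles) && nrow(keep))
    warning("attaching ", sum(!hasSmiles),
            " molecule(s) without SMILES to 'Self': ",
            paste(ids[!hasSmiles], collapse = ", "))
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  selfLinked <- ids[!hasSmiles]
  withS <- which(hasSmiles)
  if (length(withS) >= 2L) {
    d <- utils::adist(smi[withS], smi[withS])
    len <- nchar(smi[withS])
    sim <- 1 - d / outer(len, len, pmax)
    diag(sim) <- -Inf  # no self-matching
    for (a in seq_along(withS)) {
      best <- max(sim[a, ])
      if (best >= simThreshold) {
        # lexicographically smallest partner id among ties
        cand <- ids[withS][which(sim[a, ] == best)]
        partner <- sort(cand)[1]
        pair <- sort(c(ids[withS][a], partner))
        edges <- rbind(edges, data.frame(from = pair[1], to = pair[2],
                                         weight = best,
                                         stringsAsFactors = FALSE))
      } else {
        selfLinked <- c(selfLinked, ids[withS][a])
      }
    }
    edges <- unique(edges)
  } else if (length(withS) == 1L) {
    selfLinked <- c(selfLinked, ids[withS])
  }
  vnames <- c(ids, if (length(selfLinked)) "Self")
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(vnames), name = vnames)
  m <- match(igraph::V(g)$name, keep$metabolite_id)
  igraph::V(g)$score <- keep$score[m]
  if (all(c("n_up", "n_down") %in% names(keep))) {
    igraph::V(g)$direction <-
      ifelse(is.na(m), NA_character_,
             ifelse(keep$n_up[m] > keep$n_down[m], "up",
                    ifelse(keep$n_down[m] > keep$n_up[m], "down", "mixed")))
  }
  if ("dominant_fraction" %in% names(keep))
    igraph::V(g)$dominant_fraction <- keep$dominant_fraction[m]
  allEdges <- edges
  if (length(selfLinked))
    allEdges <- rbind(edges,
                      data.frame(from = unique(selfLinked), to = "Self",
                                 weight = 0, stringsAsFactors = FALSE))
  if (nrow(allEdges)) {
    g <- igraph::add_edges(g, rbind(match(allEdges$from, vnames),
                                    match(allEdges$to, vnames)))
    igraph::E(g)$weight <- allEdges$weight
  }
  g
}
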