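#' Convert a q-value to a Z-score
#'
#' The per-gene statistic underlying all enrichment scoring: the negative of
#' the standard-normal inverse CDF of the q-value, `z = -qnorm(q)`. A q-value
#' of 0.5 maps to 0; small q-values map to large positive deviates
#' (q = 0.05 to 1.64). q is clamped to `[1e-12, 1 - 1e-12]` before
#' inversion so the score stays finite for floored q-values.
#'
#' @param q numeric vector of probabilities in `[0, 1]`.
#' @return numeric vector of Z-scores, monotone non-increasing in `q`.
#' @examples
#' qToZ(c(0.5, 0.05, 0.001))
#' @export
qToZ <- function(q) {
  if (any(is.na(q)) || any(q < 0 | q > 1))
    stop("q must lie in [0, 1]")
  qc <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  -stats::qnorm(qc)
}

#' Gene Z-score map from a differential-expression table
#'
#' @param de a differential-expression `data.frame` (see [readDETable()]).
#' @return named numeric vector, gene id to Z-score.
#' @export
geneZMap <- function(de) {
  stats::setNames(qToZ(de$q_value), de$gene_id)
}

#' Descendant terms in an ontology
#'
#' All terms from which the query term is reachable along `is_a`
#' child-to-parent edges (i.e. the query term and every more specific term
#' below it).
#'
#' @param ontology an [OntologyGraph-class].
#' @param termId a term id present in the ontology.
#' @return character vector of term ids, including `termId` itself.
#' @export
termDescendants <- function(ontology, termId) {
  stopifnot(is(ontology, "OntologyGraph"))
  terms <- ontologyTerms(ontology)$id
  if (!termId %in% terms) stop("unknown term: ", termId)
  edges <- isaEdges(ontology)
  if (nrow(edges) == 0L) return(termId)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = terms)
  sort(igraph::subcomponent(g, termId, mode = "in")$name)
}

#' Gene set of an ontology term
#'
#' Collects all genes annotated to a term or to any of its descendants
#' (more specific terms reached against the `is_a` child-to-parent
#' direction), deduplicated. This descendant closure is what makes narrowly
#' annotated genes count towards the broad terms of a slim ontology.
#'
#' @param termId a term id present in the ontology.
#' @param ontology an [OntologyGraph-class].
#' @param annotations long-format `data.frame` with columns `gene_id`,
#'   `term_id`.
#' @return character vector of gene ids (sorted, deduplicated).
#' @export
goGeneSet <- function(termId, ontology, annotations) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
  desc <- termDescendants(ontology, termId)
  sort(unique(annotations$gene_id[annotations$term_id %in% desc]))
}

# per-size RNG stream offset: results independent of evaluation order
.kSeed <- function(seed, k) {
  (as.integer(seed) + 104729L * (as.integer(k) %% 10007L)) %% 2147483629L
}

#' Bootstrap background moments for enrichment scoring
#'
#' For each requested set size `k`, draws `nBoot` random gene sets of size
#' `k` without replacement from the universe and records the mean and
#' standard deviation of their total Z-scores. Each size uses its own
#' seeded RNG stream derived from `seed`, so the table is reproducible and
#' independent of the order in which sizes are requested.
#'
#' @param zmap named numeric vector, gene id to Z-score (see [geneZMap()]).
#' @param sizes integer vector of set sizes to tabulate.
#' @param nBoot number of random sets per size (default 1000).
#' @param seed integer seed.
#' @param universe gene ids to sample from; defaults to `names(zmap)`.
#'   Genes without a Z-score are dropped.
#' @param universeLabel label stored in the result (`"all_genes"` or
#'   `"enzyme_genes"`).
#' @return a [BackgroundTable-class].
#' @export
computeBackground <- function(zmap, sizes, nBoot = 1000L, seed = 1L,
                              universe = names(zmap),
                              universeLabel = "all_genes") {
  stopifnot(nBoot >= 1L, length(sizes) >= 1L)
  zu <- zmap[intersect(universe, names(zmap))]
  n <- length(zu)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L)) stop("set sizes must be positive")
  if (any(sizes > n))
    stop("set size ", max(sizes), " exceeds universe size ", n)
  zu <- unname(zu)
  rows <- lapply(sizes, function(k) {
    set.seed(.kSeed(seed, k))
    totals <- vapply(seq_len(nBoot),
                     function(i) sum(zu[sample.int(n, k)]), numeric(1))
    data.frame(k = k, mean = mean(totals),
               sd = if (nBoot > 1L) stats::sd(totals) else 0)
  })
  new("BackgroundTable", stats = do.call(rbind, rows),
      nBoot = as.integer(nBoot), seed = as.integer(seed),
      universe = universeLabel)
}

#' Enrichment score of one gene set
#'
#' Scores a gene set by the size-corrected total Z-score: the sum of member
#' Z-scores, centred and scaled by the bootstrap background moments for the
#' same set size, `S = (total Z - mean) / sd`. Members outside the Z-map
#' domain are dropped before scoring; duplicated member ids count once.
#' Direction is summarised separately as the counts of significant members
#' with positive (`n_up`) and negative (`n_down`) log2 fold change, plus
#' the fraction regulated in the dominant direction.
#'
#' @param members character vector of gene ids.
#' @param zmap named numeric vector, gene id to Z-score.
#' @param background a [BackgroundTable-class] containing the member count
#'   (after intersection with the Z-map domain) among its sizes.
#' @param de differential-expression `data.frame` used for the direction
#'   summary; may be `NULL` to skip it.
#' @return one-row `data.frame` with columns `k`, `total_z`, `bg_mean`,
#'   `bg_sd`, `score`, `n_up`, `n_down`, `dominant_fraction`,
#'   `score_defined`. A zero background sd yields `score = NA` with
#'   `score_defined = FALSE` rather than an infinite score.
#' @export
enrichmentScore <- function(members, zmap, background, de = NULL) {
  stopifnot(is(background, "BackgroundTable"))
  members <- unique(members)
  members <- members[members %in% names(zmap)]
  k <- length(members)
  st <- backgroundStats(background)
  row <- st[st$k == k, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("background table has no entry for set size ", k)
  totalZ <- sum(zmap[members])
  defined <- row$sd > 0
  score <- if (defined) (totalZ - row$mean) / row$sd else NA_real_
  nUp <- nDown <- 0L
  if (!is.null(de) && k > 0L) {
    sub <- de[de$gene_id %in% members & de$significant, , drop = FALSE]
    nUp <- sum(sub$log2_fc > 0)
    nDown <- sum(sub$log2_fc < 0)
  }
  domFrac <- if (nUp + nDown > 0L) max(nUp, nDown) / (nUp + nDown) else
    NA_real_
  data.frame(k = k, total_z = totalZ, bg_mean = row$mean, bg_sd = row$sd,
             score = score, n_up = nUp, n_down = nDown,
             dominant_fraction = domFrac, score_defined = defined)
}

#' Score a collection of gene sets
#'
#' Computes the bootstrap-calibrated enrichment score for every gene set in
#' a collection, computing the background once per distinct set size and
#' reusing it. Sets that are empty after intersection with the Z-map domain
#' are skipped with a warning.
#'
#' @param sets named list of character vectors (set id to member gene ids).
#' @param zmap named numeric vector, gene id to Z-score.
#' @param de differential-expression `data.frame` for direction summaries.
#' @param nBoot bootstrap iterations per set size (default 1000).
#' @param seed integer seed.
#' @param cutoff score at or above which a set is flagged enriched
#'   (default 1.64, the deviate of p = 0.05).
#' @param universe sampling universe for the background; defaults to all
#'   genes in `zmap`.
#' @param universeLabel label recorded for the background universe.
#' @param setNames optional named character vector of display names.
#' @return `data.frame` with one row per scored set: `set_id`, `name`, `k`,
#'   `total_z`, `bg_mean`, `bg_sd`, `score`, `n_up`, `n_down`,
#'   `dominant_fraction`, `flagged`.
#' @export
enrichAll <- function(sets, zmap, de = NULL, nBoot = 1000L, seed = 1L,
                      cutoff = 1.64, universe = names(zmap),
                      universeLabel = "all_genes", setNames = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  eff <- lapply(sets, function(m) unique(m[m %in% names(zmap)]))
  empty <- vapply(eff, length, integer(1)) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty gene set(s): ",
            paste(names(sets)[empty], collapse = ", "))
    eff <- eff[!empty]
  }
  if (!length(eff)) return(.emptyEnrichment())
  ks <- unique(vapply(eff, length, integer(1)))
  bg <- computeBackground(zmap, ks, nBoot = nBoot, seed = seed,
                          universe = universe, universeLabel = universeLabel)
  rows <- lapply(names(eff), function(id) {
    r <- enrichmentScore(eff[[id]], zmap, bg, de)
    cbind(data.frame(set_id = id,
                     name = if (!is.null(setNames) && id %in% names(setNames))
                       unname(setNames[id]) else id,
                     stringsAsFactors = FALSE),
          r)
  })
  out <- do.call(rbind, rows)
  out$flagged <- !is.na(out$score) & out$score >= cutoff
  rownames(out) <- NULL
  out
}

.emptyEnrichment <- function() {
  data.frame(set_id = character(), name = character(), k = integer(),
             total_z = numeric(), bg_mean = numeric(), bg_sd = numeric(),
             score = numeric(), n_up = integer(), n_down = integer(),
             dominant_fraction = numeric(), score_defined = logical(),
             flagged = logical(), stringsAsFactors = FALSE)
}
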