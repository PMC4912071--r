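#' Read a differential-expression table
#'
#' Reads a tab-separated two-condition differential-expression table in the
#' canonical layout produced by CuffDiff-style callers: one row per gene with
#' its abundance in each condition, a log2 fold change, a p-value and a
#' multiple-testing-corrected q-value. Significance is always recomputed as
#' `q_value < qCutoff`; a `significant` column present in the file is ignored
#' except to report how often it disagrees with the recomputed flag. The
#' log2 fold change is likewise recomputed as `log2(value_b / value_a)`
#' whenever both abundances are strictly positive, falling back to the
#' column value otherwise.
#'
#' @param path path to a TSV file with header columns `gene_id`, `value_a`,
#'   `value_b`, `log2_fc`, `p_value`, `q_value` and optionally `significant`,
#'   `protein_names`, `gene_names`, `go_terms` (semicolon-separated term ids).
#' @param qCutoff significance threshold on the q-value (default 0.05).
#' @return `data.frame` with columns `gene_id`, `value_a`, `value_b`,
#'   `log2_fc`, `p_value`, `q_value`, `significant`, `protein_names`,
#'   `gene_names` and a list-column `go_terms`.
#' @export
readDETable <- function(path, qCutoff = 0.05) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  stopifnot(is.numeric(qCutoff), length(qCutoff) == 1L)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  required <- c("gene_id", "value_a", "value_b", "log2_fc", "p_value",
                "q_value")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) return(.emptyDETable())

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  va <- num("value_a"); vb <- num("value_b")
  lfc <- num("log2_fc"); p <- num("p_value"); q <- num("q_value")
  badAb <- which(is.na(va) | is.na(vb))
  if (length(badAb)) {
    warning("rejecting ", length(badAb),
            " row(s) with non-numeric abundances (row index ",
            paste(badAb, collapse = ", "), ")")
    keep <- setdiff(seq_len(nrow(raw)), badAb)
    raw <- raw[keep, , drop = FALSE]
    va <- va[keep]; vb <- vb[keep]; lfc <- lfc[keep]
    p <- p[keep]; q <- q[keep]
  }
  if (anyDuplicated(raw$gene_id))
    stop("duplicate gene_id(s): ",
         paste(unique(raw$gene_id[duplicated(raw$gene_id)]), collapse = ", "))
  if (any(q < 0 | q > 1, na.rm = TRUE))
    stop("q_value outside [0, 1]")
  if (any(va < 0 | vb < 0, na.rm = TRUE))
    stop("negative abundance")

  recompute <- !is.na(va) & !is.na(vb) & va > 0 & vb > 0
  lfc[recompute] <- log2(vb[recompute] / va[recompute])
  significant <- !is.na(q) & q < qCutoff
  if ("significant" %in% names(raw)) {
    fileFlag <- tolower(raw$significant) %in% c("yes", "true", "1")
    ndis <- sum(fileFlag != significant)
    if (ndis > 0)
      message(ndis, " row(s) where the file's significance flag disagrees ",
              "with q < ", qCutoff, "; recomputed flag used")
  }
  goCol <- if ("go_terms" %in% names(raw)) raw$go_terms else
    rep("", nrow(raw))
  goTerms <- lapply(strsplit(goCol, ";", fixed = TRUE),
                    function(x) x[nzchar(trimws(x))] |> trimws())
  out <- data.frame(gene_id = raw$gene_id, value_a = va, value_b = vb,
                    log2_fc = lfc, p_value = p, q_value = q,
                    significant = significant,
                    protein_names = if ("protein_names" %in% names(raw))
                      raw$protein_names else "",
                    gene_names = if ("gene_names" %in% names(raw))
                      raw$gene_names else "",
                    stringsAsFactors = FALSE)
  out$go_terms <- goTerms
  rownames(out) <- NULL
  out
}

.emptyDETable <- function() {
  out <- data.frame(gene_id = character(), value_a = numeric(),
                    value_b = numeric(), log2_fc = numeric(),
                    p_value = numeric(), q_value = numeric(),
                    significant = logical(), protein_names = character(),
                    gene_names = character(), stringsAsFactors = FALSE)
  out$go_terms <- list()
  out
}

#' Write a differential-expression table
#'
#' Inverse of [readDETable()]: writes the canonical TSV layout, collapsing
#' the `go_terms` list-column to semicolon-separated ids.
#'
#' @param de a differential-expression `data.frame` as returned by
#'   [readDETable()] or [generateDETable()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeDETable <- function(de, path) {
  out <- de
  out$significant <- ifelse(de$significant, "yes", "no")
  out$go_terms <- vapply(de$go_terms, paste, character(1), collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ontology from an OBO file
#'
#' Parses the subset of OBO 1.2 used for `is_a` ontology graphs: `[Term]`
#' stanzas with `id:`, `name:`, `is_a:` and `is_obsolete:` lines. Obsolete
#' terms are dropped; `is_a` edges pointing at undeclared terms are dropped
#' with a warning (slim ontology subsets routinely reference absent
#' parents). A cyclic `is_a` closure is an error naming one cycle.
#'
#' @param path path to an OBO file.
#' @return an [OntologyGraph-class].
#' @export
readOBO <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  termStarts <- which(trimws(lines) == "[Term]")
  stanzaEnds <- c(which(grepl("^\\[", trimws(lines))), length(lines) + 1L)
  ids <- character(); nms <- character()
  edges <- list()
  for (s in termStarts) {
    e <- min(stanzaEnds[stanzaEnds > s]) - 1L
    block <- lines[(s + 1L):e]
    field <- function(tag) {
      hits <- block[startsWith(block, paste0(tag, ":"))]
      vals <- sub(paste0("^", tag, ":\\s*"), "", hits)
      sub("\\s*!.*$", "", vals)  # strip trailing OBO comments
    }
    id <- field("id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (any(tolower(field("is_obsolete")) == "true")) next
    ids <- c(ids, id)
    nm <- field("name")[1]
    nms <- c(nms, if (is.na(nm)) "" else nm)
    parents <- field("is_a")
    parents <- parents[nzchar(trimws(parents))]
    if (length(parents))
      edges[[length(edges) + 1L]] <-
        data.frame(child = id, parent = parents, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  dangling <- !(edges$parent %in% ids) | !(edges$child %in% ids)
  if (any(dangling)) {
    warning("dropping ", sum(dangling),
            " is_a edge(s) referencing undeclared term(s): ",
            paste(unique(edges$parent[dangling]), collapse = ", "))
    edges <- edges[!dangling, , drop = FALSE]
  }
  rownames(edges) <- NULL
  new("OntologyGraph",
      terms = data.frame(id = ids, name = nms, stringsAsFactors = FALSE),
      edges = edges)
}

#' Read a metabolic model from JSON
#'
#' Reads the package's flat JSON model schema: top-level keys `metabolites`
#' (id to `{name, smiles, compartment}`), `reactions` (id to
#' `{stoichiometry, reversible, genes, compartment, pathways}` with
#' stoichiometric coefficients negative for substrates), `pathways` (id to
#' `{name, reactions}`), `biomass_reaction` and `exchanges`. All referential
#' invariants are checked on load; nothing is silently dropped.
#'
#' @param path path to a model JSON file.
#' @return a [MetabolicModel-class].
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("metabolites", "reactions", "biomass_reaction"))
    if (is.null(doc[[key]])) stop("model JSON lacks required key '", key, "'")
  if (anyDuplicated(names(doc$reactions)))
    stop("duplicate reaction id(s): ",
         paste(unique(names(doc$reactions)[duplicated(names(doc$reactions))]),
               collapse = ", "))
  if (anyDuplicated(names(doc$metabolites)))
    stop("duplicate metabolite id(s): ",
         paste(unique(names(doc$metabolites)[
           duplicated(names(doc$metabolites))]), collapse = ", "))
  chr1 <- function(x) if (is.null(x)) "" else as.character(x)
  met <- data.frame(
    id = names(doc$metabolites),
    name = vapply(doc$metabolites, function(m) chr1(m$name), character(1)),
    smiles = vapply(doc$metabolites, function(m) chr1(m$smiles), character(1)),
    compartment = vapply(doc$metabolites, function(m) chr1(m$compartment),
                         character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  rxn <- data.frame(
    id = names(doc$reactions),
    reversible = vapply(doc$reactions,
                        function(r) isTRUE(r$reversible), logical(1)),
    compartment = vapply(doc$reactions, function(r) chr1(r$compartment),
                         character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  rxn$stoichiometry <- lapply(doc$reactions, function(r) {
    st <- vapply(r$stoichiometry, as.numeric, numeric(1))
    if (!length(st)) stop("reaction with empty stoichiometry")
    st
  })
  rxn$genes <- lapply(doc$reactions,
                      function(r) as.character(unlist(r$genes)))
  rxn$pathways <- lapply(doc$reactions,
                         function(r) as.character(unlist(r$pathways)))
  # explicit check so the error names both reaction and metabolite
  for (i in seq_len(nrow(rxn))) {
    unknown <- setdiff(names(rxn$stoichiometry[[i]]), met$id)
    if (length(unknown))
      stop("reaction '", rxn$id[i], "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  pw <- if (is.null(doc$pathways)) {
    d <- data.frame(id = character(), name = character(),
                    stringsAsFactors = FALSE)
    d$reactions <- list(); d
  } else {
    d <- data.frame(
      id = names(doc$pathways),
      name = vapply(doc$pathways, function(p) chr1(p$name), character(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    d$reactions <- lapply(doc$pathways,
                          function(p) as.character(unlist(p$reactions)))
    d
  }
  new("MetabolicModel", metabolites = met, reactions = rxn, pathways = pw,
      biomassReaction = as.character(doc$biomass_reaction),
      exchanges = as.character(unlist(doc$exchanges)))
}

#' Write a metabolic model to JSON
#'
#' Serialises a [MetabolicModel-class] in the schema read by [readModel()].
#'
#' @param model a [MetabolicModel-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeModel <- function(model, path) {
  met <- metabolites(model)
  rxn <- reactions(model)
  pw <- pathways(model)
  doc <- list(
    metabolites = stats::setNames(lapply(seq_len(nrow(met)), function(i)
      list(name = met$name[i], smiles = met$smiles[i],
           compartment = met$compartment[i])), met$id),
    reactions = stats::setNames(lapply(seq_len(nrow(rxn)), function(i)
      list(stoichiometry = as.list(rxn$stoichiometry[[i]]),
           reversible = rxn$reversible[i],
           genes = I(rxn$genes[[i]]),
           compartment = rxn$compartment[i],
           pathways = I(rxn$pathways[[i]]))), rxn$id),
    pathways = stats::setNames(lapply(seq_len(nrow(pw)), function(i)
      list(name = pw$name[i], reactions = I(pw$reactions[[i]]))), pw$id),
    biomass_reaction = biomassReaction(model),
    exchanges = I(exchangeReactions(model)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a network to GraphML or edge TSV
#'
#' Writes an [igraph::igraph] graph (as produced by the network-construction
#' functions, with numeric node attributes such as `score` and
#' `dominant_fraction`) either as GraphML or as a three-column
#' `from`/`to`/`weight` edge TSV.
#'
#' @param graph an `igraph` object.
#' @param path output file path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return invisibly, `path`.
#' @seealso [readNetwork()]
#' @export
writeNetwork <- function(graph, path, format = c("graphml", "edge-tsv")) {
  stopifnot(igraph::is_igraph(graph))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    w <- if ("weight" %in% igraph::edge_attr_names(graph))
      igraph::E(graph)$weight else rep(1, nrow(el))
    utils::write.table(
      data.frame(from = el[, 1], to = el[, 2], weight = w),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [writeNetwork()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return an `igraph` object.
#' @export
readNetwork <- function(path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(tab[, c("from", "to")], directed = FALSE)
  igraph::E(g)$weight <- tab$weight
  g
}
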