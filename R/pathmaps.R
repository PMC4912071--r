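#' Reaction-level differential-expression summaries
#'
#' Summarises a two-condition differential-expression table at the reaction
#' level for pathway-map rendering. For every reaction, transcript
#' abundances of all member genes (isozymes from paralogs or
#' multi-functional proteins) are summed per condition; the representative
#' log2 fold change is that of the member gene with the largest magnitude
#' (sign preserved); expression change counts as significant when at least
#' one member gene is significant. Each reaction is classified as:
#'
#' * `up` / `down` - at least one significant gene, all significant genes
#'   sharing that sign;
#' * `isozyme_switching` - significant genes in both directions;
#' * `constitutive` - member genes present but none significant;
#' * `no_gene` - no member gene found in the table.
#'
#' @param model a [MetabolicModel-class].
#' @param de differential-expression `data.frame` (see [readDETable()]).
#' @param restrictGenes optional character vector; when given, only member
#'   genes in this set are used (the compartment views rely on this).
#' @return `data.frame` with columns `reaction_id`, `n_genes` (member genes
#'   found in the table), `total_a`, `total_b`, `rep_log2_fc`,
#'   `any_significant`, `class`.
#' @export
summariseReactions <- function(model, de, restrictGenes = NULL) {
  stopifnot(is(model, "MetabolicModel"))
  rxn <- reactions(model)
  missing <- setdiff(unlist(rxn$genes), de$gene_id)
  if (length(missing))
    message(length(missing), " model gene(s) absent from the DE table ",
            "skipped: ", paste(utils::head(missing, 10), collapse = ", "),
            if (length(missing) > 10) ", ...")
  rows <- lapply(seq_len(nrow(rxn)), function(i) {
    genes <- sort(unique(rxn$genes[[i]]))
    if (!is.null(restrictGenes)) genes <- intersect(genes, restrictGenes)
    sub <- de[match(intersect(genes, de$gene_id), de$gene_id), ,
              drop = FALSE]
    .summariseOne(rxn$id[i], sub)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.summariseOne <- function(reactionId, sub) {
  if (nrow(sub) == 0L)
    return(data.frame(reaction_id = reactionId, n_genes = 0L,
                      total_a = NA_real_, total_b = NA_real_,
                      rep_log2_fc = NA_real_, any_significant = FALSE,
                      class = "no_gene", stringsAsFactors = FALSE))
  # stable under gene reordering: order by id, pick first maximal magnitude
  sub <- sub[order(sub$gene_id), , drop = FALSE]
  rep_lfc <- sub$log2_fc[which.max(abs(sub$log2_fc))]
  sig <- sub[sub$significant, , drop = FALSE]
  cls <- if (nrow(sig) == 0L) "constitutive"
  else if (any(sig$log2_fc > 0) && any(sig$log2_fc < 0)) "isozyme_switching"
  else if (all(sig$log2_fc > 0)) "up"
  else "down"
  data.frame(reaction_id = reactionId, n_genes = nrow(sub),
             total_a = sum(sub$value_a), total_b = sum(sub$value_b),
             rep_log2_fc = rep_lfc, any_significant = nrow(sig) > 0L,
             class = cls, stringsAsFactors = FALSE)
}

#' Default GO cellular_component to compartment map
#'
#' Maps slim cellular_component term ids to the subcellular compartment
#' labels used in compartmentalised pathway maps: cytoplasm, mitochondrion,
#' peroxisome, nucleus, plasma membrane (the general membrane term is
#' folded into it) and the extracellular region (including cell wall).
#' Terms outside the map fall back to `other` in [assignCompartments()].
#'
#' @return named character vector, GO term id to compartment label.
#' @export
defaultCompartmentMap <- function() {
  c("GO:0005737" = "cytoplasm",
    "GO:0005829" = "cytoplasm",        # cytosol
    "GO:0005739" = "mitochondrion",
    "GO:0005777" = "peroxisome",
    "GO:0005634" = "nucleus",
    "GO:0005886" = "plasma_membrane",
    "GO:0016020" = "plasma_membrane",  # membrane
    "GO:0005576" = "extracellular",
    "GO:0005618" = "extracellular")    # cell wall
}

#' Compartment labels known to the compartment views
#' @return character vector of valid compartment labels.
#' @export
compartmentLabels <- function() {
  c("cytoplasm", "mitochondrion", "peroxisome", "nucleus",
    "plasma_membrane", "extracellular", "other", "unknown")
}

#' Assign genes to subcellular compartments via GO cellular_component
#'
#' Maps every gene through all of its cellular_component annotations: each
#' annotated term contributes the compartment it maps to (or `other` when
#' the term is outside the map), so multi-localised genes appear in every
#' mapped compartment. Genes with no cellular_component annotation get
#' `unknown`.
#'
#' @param annotations long-format `data.frame` with columns `gene_id`,
#'   `term_id`, restricted to cellular_component terms.
#' @param ccTermMap named character vector, term id to compartment label
#'   (default [defaultCompartmentMap()]).
#' @param genes optional gene universe; genes absent from `annotations`
#'   are reported as `unknown`.
#' @return named list, gene id to character vector of compartment labels.
#' @export
assignCompartments <- function(annotations, ccTermMap = defaultCompartmentMap(),
                               genes = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
  labs <- ifelse(annotations$term_id %in% names(ccTermMap),
                 ccTermMap[annotations$term_id], "other")
  out <- lapply(split(labs, annotations$gene_id),
                function(x) sort(unique(unname(x))))
  if (!is.null(genes)) {
    absent <- setdiff(genes, names(out))
    out <- c(out, stats::setNames(rep(list("unknown"), length(absent)),
                                  absent))
    out <- out[intersect(c(names(out)), genes)]
  }
  out
}

#' Compartment-restricted reaction summary
#'
#' Re-summarises reaction-level differential expression using only the
#' member genes assigned to one target compartment, so that e.g. a reaction
#' with a cytosolic up-regulated isozyme and a mitochondrial down-regulated
#' one reads `up` in the cytoplasm view, `down` in the mitochondrion view
#' and `isozyme_switching` only in the uncompartmentalised view. Reactions
#' with no gene in the target compartment are omitted.
#'
#' @param model a [MetabolicModel-class].
#' @param de differential-expression `data.frame`.
#' @param compartments named list from [assignCompartments()].
#' @param target one label from [compartmentLabels()].
#' @return `data.frame` as from [summariseReactions()], plus a
#'   `compartment` column, restricted to reactions with genes in `target`.
#' @export
compartmentView <- function(model, de, compartments, target) {
  if (!target %in% compartmentLabels())
    stop("unknown compartment label: ", target)
  inTarget <- names(compartments)[vapply(compartments,
                                         function(x) target %in% x,
                                         logical(1))]
  res <- summariseReactions(model, de, restrictGenes = inTarget)
  res <- res[res$class != "no_gene", , drop = FALSE]
  if (nrow(res)) res$compartment <- target
  else res$compartment <- character(0)
  rownames(res) <- NULL
  res
}
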