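#' @rdname MetabolicModel-class
#' @aliases metabolites reactions pathways biomassReaction exchangeReactions
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)

#' @rdname MetabolicModel-class
setMethod("reactions", "MetabolicModel", function(x) x@reactions)

#' @rdname MetabolicModel-class
setMethod("pathways", "MetabolicModel", function(x) x@pathways)

#' @rdname MetabolicModel-class
setMethod("biomassReaction", "MetabolicModel", function(x) x@biomassReaction)

#' @rdname MetabolicModel-class
setMethod("exchangeReactions", "MetabolicModel", function(x) x@exchanges)

#' @rdname OntologyGraph-class
setMethod("ontologyTerms", "OntologyGraph", function(x) x@terms)

#' @rdname OntologyGraph-class
setMethod("isaEdges", "OntologyGraph", function(x) x@edges)

#' @rdname BackgroundTable-class
#' @param x a `BackgroundTable`.
setMethod("backgroundStats", "BackgroundTable", function(x) x@stats)

#' @rdname FluxState-class
#' @param x a `FluxState`.
setMethod("fluxes", "FluxState", function(x) x@fluxes)

#' @rdname FluxState-class
setMethod("objectiveValue", "FluxState", function(x) x@objective)

#' @rdname FluxState-class
setMethod("condition", "FluxState", function(x) x@condition)

setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph with", nrow(object@terms), "terms and",
      nrow(object@edges), "is_a edges\n")
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions,",
      nrow(object@pathways), "pathways\n")
  cat("  biomass:", object@biomassReaction,
      " exchanges:", length(object@exchanges), "\n")
  comps <- unique(object@metabolites$compartment)
  comps <- comps[nzchar(comps)]
  if (length(comps)) cat("  compartments:", paste(comps, collapse = ", "), "\n")
})

setMethod("show", "BackgroundTable", function(object) {
  cat("BackgroundTable (", object@universe, " universe): ",
      nrow(object@stats), " set sizes, nBoot = ", object@nBoot,
      ", seed = ", object@seed, "\n", sep = "")
})

setMethod("show", "FluxState", function(object) {
  nz <- sum(abs(object@fluxes) > 1e-9)
  cat("FluxState '", object@condition, "': ", length(object@fluxes),
      " reactions (", nz, " carrying flux), objective = ",
      signif(object@objective, 6), "\n", sep = "")
})

#' Stoichiometric matrix of a model
#'
#' Builds the metabolite-by-reaction matrix S whose signed entries are the
#' stoichiometric coefficients; a steady-state flux vector v satisfies
#' S v = 0.
#'
#' @param model a [MetabolicModel-class].
#' @return numeric matrix with metabolite ids as rownames and reaction ids
#'   as colnames.
#' @export
stoichiometricMatrix <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  mids <- metabolites(model)$id
  rxn <- reactions(model)
  S <- matrix(0, nrow = length(mids), ncol = nrow(rxn),
              dimnames = list(mids, rxn$id))
  for (i in seq_len(nrow(rxn))) {
    st <- rxn$stoichiometry[[i]]
    S[names(st), i] <- unname(st)
  }
  S
}

#' Genes encoding enzymes of a model
#'
#' Union of the gene associations over all reactions; this is the sampling
#' universe for reporter-metabolite backgrounds.
#'
#' @param model a [MetabolicModel-class].
#' @return character vector of gene ids (sorted, deduplicated).
#' @export
enzymeGenes <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  sort(unique(as.character(unlist(reactions(model)$genes))))
}

#' Compartment-stripped metabolite identifiers
#'
#' Maps each metabolite id to a base identifier with its compartment tag
#' removed, so that e.g. cytosolic and mitochondrial instances of the same
#' compound compare equal in pathway-overlap calculations. A tag is only
#' stripped when the id ends in `_<compartment>` or `[<compartment>]` for
#' that metabolite's own declared compartment; other ids pass through.
#'
#' @param model a [MetabolicModel-class].
#' @return named character vector, metabolite id to base id.
#' @export
baseMetaboliteIds <- function(model) {
  met <- metabolites(model)
  out <- met$id
  comp <- met$compartment
  has <- nzchar(comp)
  suf1 <- paste0("_", comp)
  suf2 <- paste0("[", comp, "]")
  for (i in which(has)) {
    if (endsWith(out[i], suf1[i]))
      out[i] <- substr(out[i], 1L, nchar(out[i]) - nchar(suf1[i]))
    else if (endsWith(out[i], suf2[i]))
      out[i] <- substr(out[i], 1L, nchar(out[i]) - nchar(suf2[i]))
  }
  names(out) <- met$id
  out
}

#' Derived metabolite sets of pathways
#'
#' A pathway's metabolite set is the union of the metabolites of its member
#' reactions, optionally after stripping compartment tags (the default, as
#' reference pathway databases are compartment-naive).
#'
#' @param model a [MetabolicModel-class].
#' @param stripCompartments strip compartment tags via [baseMetaboliteIds()]?
#' @return named list of character vectors, pathway id to metabolite ids.
#' @export
pathwayMetaboliteSets <- function(model, stripCompartments = TRUE) {
  stopifnot(is(model, "MetabolicModel"))
  base <- if (stripCompartments) baseMetaboliteIds(model) else
    stats::setNames(metabolites(model)$id, metabolites(model)$id)
  rxn <- reactions(model)
  rxnMets <- lapply(rxn$stoichiometry, names)
  names(rxnMets) <- rxn$id
  pw <- pathways(model)
  out <- lapply(seq_len(nrow(pw)), function(i) {
    sort(unique(unname(base[unlist(rxnMets[pw$reactions[[i]]])])))
  })
  names(out) <- pw$id
  out
}
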