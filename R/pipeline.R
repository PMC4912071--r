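#' Run the full analysis pipeline
#'
#' Orchestrates every stage over one set of inputs: gene-set enrichment for
#' ontology terms and pathways, reporter-metabolite scoring, the
#' pathway-overlap and molecular similarity networks, the reporter
#' metabolite-enzyme network, FBA for both conditions, differential-flux
#' classification, metabolic regulation analysis and the reaction-level
#' pathway-map summaries (uncompartmentalised and per compartment). Inputs
#' are either read from the paths in `config` or, when `config$simulate` is
#' `TRUE`, generated by [simulateStudy()]. Every stage writes its result
#' under `config$outDir`, and a run manifest (package version, seed,
#' thresholds, per-stage row counts) is written as `manifest.json`. A stage
#' failure aborts with an error naming the stage.
#'
#' @param config list with entries `outDir` (required), `seed`, `nBoot`,
#'   and either `simulate = TRUE` (plus optional `synthConfig`) or input
#'   paths `de`, `model`, `annotations`, `ccAnnotations`, `obo`, `ratesA`,
#'   `ratesB`. Thresholds live in `config$thresholds`:
#'   `q` (0.05), `score` (1.64), `focus` (3.0), `sim` (0.4), `pathway`
#'   (0.3), `fluxTolerance` (0.10).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = list()) {
  defaults <- list(seed = 1L, nBoot = 1000L, simulate = FALSE,
                   thresholds = list())
  config <- utils::modifyList(defaults, config)
  thr <- utils::modifyList(list(q = 0.05, score = 1.64, focus = 3.0,
                                sim = 0.4, pathway = 0.3,
                                fluxTolerance = 0.10),
                           config$thresholds)
  if (is.null(config$outDir)) stop("config$outDir is required")
  bad <- vapply(list(q = thr$q, sim = thr$sim, pathway = thr$pathway,
                     fluxTolerance = thr$fluxTolerance),
                function(x) !is.numeric(x) || x < 0 || x > 1, logical(1))
  if (any(bad))
    stop("threshold(s) out of range: ", paste(names(bad)[bad],
                                              collapse = ", "))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      cfg <- if (is.null(config$synthConfig)) synthConfig() else
        config$synthConfig
      simulateStudy(cfg, config$seed)
    } else {
      for (p in c("de", "model", "annotations", "obo", "ratesA", "ratesB"))
        if (is.null(config[[p]]) || !file.exists(config[[p]]))
          stop("missing input file for '", p, "': ",
               if (is.null(config[[p]])) "(not set)" else config[[p]])
      list(de = readDETable(config$de, qCutoff = thr$q),
           model = readModel(config$model),
           ontology = readOBO(config$obo),
           annotations = utils::read.delim(config$annotations,
                                           stringsAsFactors = FALSE),
           ccAnnotations = if (!is.null(config$ccAnnotations))
             utils::read.delim(config$ccAnnotations,
                               stringsAsFactors = FALSE) else NULL,
           ratesA = jsonlite::fromJSON(config$ratesA),
           ratesB = jsonlite::fromJSON(config$ratesB))
    }
  })
  de <- inputs$de
  model <- inputs$model
  zmap <- geneZMap(de)
  out <- function(f) file.path(config$outDir, f)
  wtsv <- function(x, f) {
    utils::write.table(x, out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nrow(x)
  }

  counts$enrich_go <- stage("enrich", {
    sets <- lapply(ontologyTerms(inputs$ontology)$id, goGeneSet,
                   ontology = inputs$ontology,
                   annotations = inputs$annotations)
    names(sets) <- ontologyTerms(inputs$ontology)$id
    sets <- sets[lengths(sets) > 0]
    enrichGo <- enrichAll(sets, zmap, de, nBoot = config$nBoot,
                          seed = config$seed, cutoff = thr$score)
    wtsv(enrichGo, "enrichment_go.tsv")
  })
  pwEnrich <- stage("enrich", {
    pw <- pathways(model)
    rxn <- reactions(model)
    sets <- lapply(pw$reactions, function(rs)
      unique(unlist(rxn$genes[match(rs, rxn$id)])))
    names(sets) <- pw$id
    sets <- sets[lengths(sets) > 0]
    enrichAll(sets, zmap, de, nBoot = config$nBoot, seed = config$seed,
              cutoff = thr$score)
  })
  counts$enrich_pathways <- wtsv(pwEnrich, "enrichment_pathways.tsv")

  reporters <- stage("reporter", {
    reporterScores(model, zmap, de, nBoot = config$nBoot,
                   seed = config$seed)
  })
  counts$reporter <- wtsv(reporters, "reporter_scores.tsv")
  counts$reporter_network <- stage("reporter", {
    g <- reporterEnzymeNetwork(reporters, de, model,
                               scoreThreshold = thr$focus,
                               qThreshold = thr$q)
    writeNetwork(g, out("reporter_enzyme_network.graphml"))
    igraph::vcount(g)
  })

  counts$pathway_network <- stage("networks", {
    g <- pathwayNetwork(model, enrich = pwEnrich, threshold = thr$pathway)
    writeNetwork(g, out("pathway_network.graphml"))
    igraph::vcount(g)
  })
  counts$molecular_network <- stage("networks", {
    g <- molecularNetwork(reporters, minScore = thr$score,
                          simThreshold = thr$sim)
    writeNetwork(g, out("molecular_network.graphml"))
    igraph::vcount(g)
  })

  stateA <- stage("fba", fbaSolve(model, inputs$ratesA, condition = "A"))
  stateB <- stage("fba", fbaSolve(model, inputs$ratesB, condition = "B"))
  counts$fba <- wtsv(data.frame(reaction_id = names(fluxes(stateA)),
                                flux_a = unname(fluxes(stateA)),
                                flux_b = unname(fluxes(stateB))),
                     "fluxes.tsv")
  dflux <- stage("diff-flux",
                 differentialFlux(stateA, stateB,
                                  tolerance = thr$fluxTolerance))
  counts$diff_flux <- wtsv(dflux, "differential_flux.tsv")

  rxnExpr <- stage("maps", summariseReactions(model, de))
  counts$maps <- wtsv(rxnExpr, "reaction_expression.tsv")
  counts$mra <- stage("mra", wtsv(mra(dflux, rxnExpr), "mra.tsv"))

  counts$compartment_views <- stage("maps", {
    if (!is.null(inputs$ccAnnotations) && nrow(inputs$ccAnnotations)) {
      comp <- assignCompartments(inputs$ccAnnotations)
      views <- do.call(rbind, lapply(
        intersect(compartmentLabels(),
                  unique(unlist(comp))),
        function(lab) compartmentView(model, de, comp, lab)))
      wtsv(views, "compartment_views.tsv")
    } else 0L
  })

  manifest <- list(package = "compartomics",
                   version = as.character(utils::packageVersion("compartomics")),
                   seed = config$seed, n_boot = config$nBoot,
                   thresholds = thr, simulate = isTRUE(config$simulate),
                   stages = counts,
                   objective_a = objectiveValue(stateA),
                   objective_b = objectiveValue(stateB),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
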