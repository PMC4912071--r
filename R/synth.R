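#' Configuration for the synthetic-study generator
#'
#' Collects every tunable of the seeded synthetic data: the size and planted
#' signal of the differential-expression table, the effect-size distribution,
#' the shape of the toy compartmentalised metabolic model and the measured
#' exchange rates of the two conditions.
#'
#' The default DE table emulates a genome of 4953 analysed genes in which
#' the q < 0.05 rule recovers about 329 up- and 251 down-regulated genes.
#' Null genes draw q uniformly on (0, 1) - the property that makes the
#' q-to-Z conversion exactly standard normal under the null - so about 2.5%
#' of null genes land below 0.05 on each side; the planted fractions
#' (214 up, 136 down) are set so that planted plus expected uniform-null
#' false positives reproduce the 329/251 totals in expectation.
#'
#' @param nGenes number of genes (default 4953).
#' @param fracUp,fracDown fractions of genes planted as up-/down-regulated
#'   (defaults 214/4953 and 136/4953; see above).
#' @param effectMean,effectSd mean and sd of the magnitude of planted log2
#'   fold changes (truncated below at 0.5).
#' @param nullFcSd sd of null-gene log2 fold changes around zero.
#' @param baseMeanLog,baseSdLog log-normal parameters of baseline transcript
#'   abundance.
#' @param plantedGoSize genes in the planted enriched ontology term.
#' @param plantedReporterNeighbours enzyme genes around the planted reporter
#'   metabolite.
#' @param nDecoyEnzymes null-expressed genes attached to decoy dead-end
#'   reactions, so the enzyme-only reporter background is dominated by
#'   unregulated enzymes as in a real metabolic gene complement.
#' @param chainLength backbone metabolites in the toy model.
#' @param nPathways pathways the backbone reactions are split into.
#' @param smilesAlphabet,smilesLenRange token alphabet and length range of
#'   the synthetic SMILES-like strings (syntactic only, no chemical validity
#'   implied).
#' @param uptakeA,uptakeB substrate uptake magnitudes of conditions A and B.
#' @param productRateA secreted-product rate in condition A; the product is
#'   fixed to zero in condition B, so its pathway's flux disappears there.
#' @param rhoH hierarchical regulation coefficient planted on the backbone
#'   reactions: their transcript totals scale as the flux ratio to the power
#'   `rhoH`.
#' @return an object of class `SynthConfig` (a validated list).
#' @export
synthConfig <- function(nGenes = 4953L,
                        fracUp = 214 / 4953, fracDown = 136 / 4953,
                        effectMean = 2.5, effectSd = 1.0,
                        nullFcSd = 0.25,
                        baseMeanLog = log(50), baseSdLog = 1.2,
                        plantedGoSize = 12L,
                        plantedReporterNeighbours = 5L,
                        nDecoyEnzymes = 30L,
                        chainLength = 12L, nPathways = 4L,
                        smilesAlphabet = c("C", "O", "N", "(", ")", "=", "1"),
                        smilesLenRange = c(8L, 14L),
                        uptakeA = 9.4, uptakeB = 5.0, productRateA = 2.0,
                        rhoH = 0.7) {
  cfg <- list(nGenes = as.integer(nGenes), fracUp = fracUp,
              fracDown = fracDown, effectMean = effectMean,
              effectSd = effectSd, nullFcSd = nullFcSd,
              baseMeanLog = baseMeanLog, baseSdLog = baseSdLog,
              plantedGoSize = as.integer(plantedGoSize),
              plantedReporterNeighbours =
                as.integer(plantedReporterNeighbours),
              nDecoyEnzymes = as.integer(nDecoyEnzymes),
              chainLength = as.integer(chainLength),
              nPathways = as.integer(nPathways),
              smilesAlphabet = smilesAlphabet,
              smilesLenRange = as.integer(smilesLenRange),
              uptakeA = uptakeA, uptakeB = uptakeB,
              productRateA = productRateA, rhoH = rhoH)
  if (cfg$fracUp < 0 || cfg$fracDown < 0 || cfg$fracUp + cfg$fracDown > 1)
    stop("fracUp and fracDown must be non-negative and sum to at most 1")
  if (cfg$nGenes < 1L || cfg$chainLength < 4L || cfg$nPathways < 1L)
    stop("sizes must be positive (chainLength >= 4)")
  if (cfg$uptakeA <= 0 || cfg$uptakeB <= 0 || cfg$productRateA < 0)
    stop("rates must be positive (productRateA >= 0)")
  if (cfg$productRateA >= cfg$uptakeA)
    stop("productRateA must be below uptakeA")
  class(cfg) <- "SynthConfig"
  cfg
}

.randomSmiles <- function(cfg, n) {
  lens <- sample(seq(cfg$smilesLenRange[1], cfg$smilesLenRange[2]), n,
                 replace = TRUE)
  vapply(lens, function(l)
    paste(sample(cfg$smilesAlphabet, l, replace = TRUE), collapse = ""),
    character(1))
}

# One coherent synthetic study: model + annotations + DE table + rates +
# machine-readable truth. All randomness flows from `seed`.
#' Generate a complete synthetic study
#'
#' Builds, from one seed, every input the pipeline consumes: a toy
#' compartmentalised metabolic model (a substrate-to-biomass backbone with a
#' secreted-product branch, a reporter-metabolite hub, isozymes and
#' pathways with controlled metabolite overlap), a small `is_a` ontology
#' with gene annotations, a two-condition differential-expression table
#' with planted signal tied to the model, measured exchange rates for both
#' conditions, and a ground-truth record naming everything that was
#' planted.
#'
#' Planted structure: the genes of the backbone reactions are down-regulated
#' so that their transcript totals scale as the flux ratio raised to
#' `rhoH` (exact hierarchical-coefficient recovery); the product branch
#' carries an isozyme-switching reaction (one significant gene up, one
#' down, in different compartments) and disappears in condition B; the hub
#' metabolite's neighbour genes and one ontology term's genes are strongly
#' up-regulated; two pathways share two of minimum three metabolites
#' (overlap 2/3); one SMILES pair differs by a single edit.
#'
#' @param config a [synthConfig()] object.
#' @param seed integer seed; the same seed reproduces the study exactly.
#' @return list with elements `de`, `model`, `ontology`, `annotations`
#'   (gene/term pairs), `ccAnnotations` (cellular_component pairs),
#'   `ratesA`, `ratesB`, `truth`.
#' @export
simulateStudy <- function(config = synthConfig(), seed = 1L) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(as.integer(seed))
  cfg <- config
  K <- cfg$chainLength

  ## ---- model topology (deterministic given config) ----
  half <- ceiling(K / 2)
  metComp <- c(rep("c", half), rep("m", K - half))
  metIds <- sprintf("M%02d_%s", seq_len(K), metComp)
  nH <- cfg$plantedReporterNeighbours
  deadIds <- sprintf("D%d_c", seq_len(nH))
  nZ <- ceiling(cfg$nDecoyEnzymes / 2)
  decoyMet <- sprintf("W%d_p", seq_len(nZ))
  mets <- data.frame(
    id = c("S_e", metIds, "B1_c", "P_e", "HUB_c", deadIds, decoyMet),
    name = c("substrate", sprintf("intermediate %d", seq_len(K)),
             "branch intermediate", "product", "hub metabolite",
             sprintf("hub satellite %d", seq_len(nH)),
             sprintf("decoy metabolite %d", seq_len(nZ))),
    smiles = "", compartment = c("e", metComp, "c", "e", "c",
                                 rep("c", nH), rep("p", nZ)),
    stringsAsFactors = FALSE)
  smi <- .randomSmiles(cfg, nrow(mets))
  # planted near-duplicate SMILES pair: intermediates 1 and 2 differ by one
  # substitution
  s1 <- smi[2]
  sub <- strsplit(s1, "")[[1]]
  pos <- sample(length(sub), 1)
  alt <- setdiff(cfg$smilesAlphabet, sub[pos])
  sub[pos] <- sample(alt, 1)
  smi[3] <- paste(sub, collapse = "")
  mets$smiles <- smi

  backbone <- sprintf("R%02d", seq_len(K - 1))
  hubRxns <- sprintf("RH%d", seq_len(nH))
  decoyRxns <- sprintf("RZ%d", seq_len(nZ))
  decoyGenes <- sprintf("gN%04d", seq_len(cfg$nDecoyEnzymes))
  rxnIds <- c("EX_S", "T_S", backbone, "R_BR", "R_P", "EX_P", "BIOMASS",
              "R_H0", hubRxns, decoyRxns)
  # the hub hangs off the backbone by a single gene-less link and otherwise
  # feeds dead-end satellites, so it can never carry steady-state flux and
  # never shortcuts the backbone
  stoich <- c(
    list(EX_S = c(S_e = -1), T_S = stats::setNames(c(-1, 1),
                                                   c("S_e", metIds[1]))),
    stats::setNames(lapply(seq_len(K - 1), function(i)
      stats::setNames(c(-1, 1), c(metIds[i], metIds[i + 1]))), backbone),
    list(R_BR = stats::setNames(c(-1, 1), c(metIds[2], "B1_c")),
         R_P = c(B1_c = -1, P_e = 1),
         EX_P = c(P_e = -1),
         BIOMASS = stats::setNames(-1, metIds[K]),
         R_H0 = stats::setNames(c(-1, 1), c(metIds[1], "HUB_c"))),
    stats::setNames(lapply(seq_len(nH), function(j)
      stats::setNames(c(-1, 1), c("HUB_c", deadIds[j]))), hubRxns),
    stats::setNames(lapply(seq_len(nZ), function(j)
      stats::setNames(c(-1, 1), c(metIds[3], decoyMet[j]))), decoyRxns))
  hubGenes <- sprintf("g_HUB%d", seq_len(nH))
  decoySplit <- split(decoyGenes,
                      rep(seq_len(nZ), each = 2L)[seq_along(decoyGenes)])
  genes <- c(list(EX_S = character(), T_S = "g_TS"),
             stats::setNames(lapply(backbone, function(r)
               paste0("g_", r)), backbone),
             list(R_BR = c("g_BR_up", "g_BR_dn"), R_P = "g_P",
                  EX_P = character(), BIOMASS = character(),
                  R_H0 = character()),
             stats::setNames(as.list(hubGenes), hubRxns),
             stats::setNames(unname(decoySplit), decoyRxns))
  rxnComp <- vapply(stoich, function(st) {
    comps <- mets$compartment[match(names(st), mets$id)]
    comps <- setdiff(unique(comps), "e")
    if (length(comps) == 1L) comps else ""
  }, character(1))
  rxns <- data.frame(id = rxnIds,
                     reversible = rxnIds %in% c("EX_S", "R_H0", hubRxns,
                                                decoyRxns),
                     compartment = unname(rxnComp[rxnIds]),
                     stringsAsFactors = FALSE)
  rxns$stoichiometry <- unname(stoich[rxnIds])
  rxns$genes <- unname(genes[rxnIds])

  # pathways: overlap-planted pair on the first backbone reactions, the rest
  # split into consecutive blocks
  pwList <- list(PWY1 = c("T_S", backbone[1]),
                 PWY2 = backbone[1:2])
  rest <- c(backbone[-(1:2)], "R_BR", "R_P")
  blocks <- split(rest, cut(seq_along(rest), max(1L, cfg$nPathways - 2L),
                            labels = FALSE))
  for (b in seq_along(blocks))
    pwList[[sprintf("PWY%d", b + 2L)]] <- unname(blocks[[b]])
  pw <- data.frame(id = names(pwList),
                   name = paste("pathway", seq_along(pwList)),
                   stringsAsFactors = FALSE)
  pw$reactions <- unname(pwList)
  rxns$pathways <- lapply(rxns$id, function(r)
    names(pwList)[vapply(pwList, function(x) r %in% x, logical(1))])

  model <- new("MetabolicModel", metabolites = mets, reactions = rxns,
               pathways = pw, biomassReaction = "BIOMASS",
               exchanges = c("EX_S", "EX_P"))

  ratesA <- list(EX_S = -cfg$uptakeA, EX_P = cfg$productRateA)
  ratesB <- list(EX_S = -cfg$uptakeB, EX_P = 0)

  ## ---- expected backbone fluxes (by conservation along the chain) ----
  fluxA <- c(T_S = cfg$uptakeA,
             stats::setNames(c(cfg$uptakeA,
                               rep(cfg$uptakeA - cfg$productRateA, K - 2)),
                             backbone))
  fluxB <- c(T_S = cfg$uptakeB,
             stats::setNames(rep(cfg$uptakeB, K - 1), backbone))
  rhoReactions <- names(fluxA)

  ## ---- gene table with planted roles ----
  nUpTarget <- round(cfg$fracUp * cfg$nGenes)
  nDownTarget <- round(cfg$fracDown * cfg$nGenes)
  modelUp <- c(hubGenes, "g_BR_up")
  modelDown <- c("g_TS", paste0("g_", backbone), "g_BR_dn")
  goGenes <- sprintf("gGO%03d", seq_len(cfg$plantedGoSize))
  nFillUp <- nUpTarget - length(modelUp) - cfg$plantedGoSize
  nFillDown <- nDownTarget - length(modelDown)
  if (nFillUp < 0 || nFillDown < 0)
    stop("planted fractions too small for the model's own planted genes")
  fillUp <- sprintf("gUP%04d", seq_len(nFillUp))
  fillDown <- sprintf("gDN%04d", seq_len(nFillDown))
  constitutiveModel <- "g_P"
  nNull <- cfg$nGenes - length(modelUp) - length(modelDown) -
    cfg$plantedGoSize - nFillUp - nFillDown - length(constitutiveModel)
  if (nNull < cfg$nDecoyEnzymes)
    stop("nGenes too small for the decoy enzyme complement")
  nullGenes <- sprintf("gN%04d", seq_len(nNull))  # first ones double as
                                                  # decoy enzyme genes

  plantQ <- function(n) pmax(0.05 * exp(-stats::rexp(n, rate = 0.7)), 1e-6)
  plantFc <- function(n) pmax(abs(stats::rnorm(n, cfg$effectMean,
                                               cfg$effectSd)), 0.5)
  base <- function(n) stats::rlnorm(n, cfg$baseMeanLog, cfg$baseSdLog)

  rows <- list()
  addGenes <- function(ids, fc, q) {
    a <- base(length(ids))
    data.frame(gene_id = ids, value_a = a, value_b = a * 2^fc,
               log2_fc = fc, p_value = q / 2, q_value = q,
               stringsAsFactors = FALSE)
  }
  # backbone genes: totals scale as (flux ratio)^rhoH, significant
  ratio <- fluxB[rhoReactions] / fluxA[rhoReactions]
  bbGenes <- c("g_TS", paste0("g_", backbone))
  rows$backbone <- addGenes(bbGenes, cfg$rhoH * log2(unname(ratio)),
                            rep(0.001, length(bbGenes)))
  rows$iso <- addGenes(c("g_BR_up", "g_BR_dn"), c(2.0, -4.0), c(0.001, 0.001))
  rows$hub <- addGenes(hubGenes, plantFc(length(hubGenes)),
                       rep(0.001, length(hubGenes)))
  rows$go <- addGenes(goGenes, plantFc(length(goGenes)),
                      rep(0.001, cfg$plantedGoSize))
  rows$fillUp <- addGenes(fillUp, plantFc(nFillUp), plantQ(nFillUp))
  rows$fillDown <- addGenes(fillDown, -plantFc(nFillDown), plantQ(nFillDown))
  rows$constit <- addGenes(constitutiveModel, stats::rnorm(1, 0, 0.05),
                           stats::runif(1, 0.5, 1))
  rows$null <- addGenes(nullGenes, stats::rnorm(nNull, 0, cfg$nullFcSd),
                        stats::runif(nNull))
  de <- do.call(rbind, rows)
  rownames(de) <- NULL
  de$significant <- de$q_value < 0.05
  de$protein_names <- ""
  de$gene_names <- de$gene_id

  ## ---- ontology + annotations ----
  terms <- data.frame(
    id = c("T:0001", "T:0100", "T:0101", "T:0200", "T:0300"),
    name = c("root process", "planted process", "planted subprocess",
             "decoy process A", "decoy process B"),
    stringsAsFactors = FALSE)
  edges <- data.frame(child = c("T:0100", "T:0101", "T:0200", "T:0300"),
                      parent = c("T:0001", "T:0100", "T:0001", "T:0001"),
                      stringsAsFactors = FALSE)
  ontology <- new("OntologyGraph", terms = terms, edges = edges)
  nHalf <- floor(cfg$plantedGoSize / 2)
  decoyA <- sample(nullGenes, min(15L, nNull))
  decoyB <- sample(nullGenes, min(15L, nNull))
  annotations <- rbind(
    data.frame(gene_id = goGenes[seq_len(nHalf)], term_id = "T:0100",
               stringsAsFactors = FALSE),
    data.frame(gene_id = goGenes[(nHalf + 1):cfg$plantedGoSize],
               term_id = "T:0101", stringsAsFactors = FALSE),
    data.frame(gene_id = decoyA, term_id = "T:0200",
               stringsAsFactors = FALSE),
    data.frame(gene_id = decoyB, term_id = "T:0300",
               stringsAsFactors = FALSE))
  de$go_terms <- unname(lapply(
    split(annotations$term_id, annotations$gene_id)[de$gene_id],
    function(x) if (is.null(x)) character(0) else sort(unique(x))))

  ccOf <- c(c = "GO:0005737", m = "GO:0005739", p = "GO:0005777")
  geneComp <- list()
  for (i in seq_len(nrow(rxns))) {
    comp <- rxns$compartment[i]
    if (nzchar(comp))
      for (gn in rxns$genes[[i]])
        geneComp[[gn]] <- union(geneComp[[gn]], unname(ccOf[comp]))
  }
  # the isozyme pair sits in different compartments
  geneComp[["g_BR_up"]] <- "GO:0005737"
  geneComp[["g_BR_dn"]] <- "GO:0005739"
  ccAnnotations <- data.frame(
    gene_id = rep(names(geneComp), lengths(geneComp)),
    term_id = unlist(geneComp, use.names = FALSE),
    stringsAsFactors = FALSE)

  truth <- list(
    planted_up = c(modelUp, goGenes, fillUp),
    planted_down = c(modelDown, fillDown),
    planted_go_term = "T:0100",
    planted_go_genes = goGenes,
    planted_reporter_metabolite = "HUB_c",
    planted_reporter_genes = hubGenes,
    isozyme_switching_reaction = "R_BR",
    disappeared_reactions = if (cfg$productRateA > 0)
      c("R_BR", "R_P", "EX_P") else character(0),
    rho_h = cfg$rhoH,
    rho_reactions = rhoReactions,
    pathway_overlap_pair = c("PWY1", "PWY2"),
    pathway_overlap_norm = 2 / 3,
    smiles_pair = mets$id[2:3],
    expected_up = nUpTarget + 0.025 * nNull,
    expected_down = nDownTarget + 0.025 * nNull,
    seed = as.integer(seed))

  list(de = de, model = model, ontology = ontology,
       annotations = annotations, ccAnnotations = ccAnnotations,
       ratesA = ratesA, ratesB = ratesB, truth = truth)
}

#' Generate a synthetic differential-expression table
#'
#' The DE-table component of [simulateStudy()]: null genes draw
#' q ~ Uniform(0, 1) with small symmetric fold changes, planted genes draw
#' q from an exponential tail below 0.05 with signed effect sizes, and
#' abundances are reconstructed as `(base, base * 2^fc)`.
#'
#' @inheritParams simulateStudy
#' @return a differential-expression `data.frame` (see [readDETable()]).
#' @export
generateDETable <- function(config = synthConfig(), seed = 1L) {
  simulateStudy(config, seed)$de
}

#' Generate the synthetic metabolic model and its annotations
#'
#' @inheritParams simulateStudy
#' @return list with `model` (a [MetabolicModel-class]), `annotations`,
#'   `ccAnnotations`, `ratesA`, `ratesB`. The model is checked to be
#'   feasible under both rate sets.
#' @export
generateModel <- function(config = synthConfig(), seed = 1L) {
  st <- simulateStudy(config, seed)
  for (r in list(st$ratesA, st$ratesB))
    fbaSolve(st$model, r)  # errors if the declared rates are infeasible
  st[c("model", "annotations", "ccAnnotations", "ratesA", "ratesB")]
}

#' Ground truth of a synthetic study
#'
#' @inheritParams simulateStudy
#' @return named list recording every planted feature: up/down gene ids,
#'   the enriched ontology term and its genes, the reporter metabolite and
#'   its neighbours, the isozyme-switching reaction, reactions whose flux
#'   disappears in condition B, the planted hierarchical coefficient and
#'   the reactions carrying it, the pathway-overlap pair, the near-duplicate
#'   SMILES pair and the expected significant-gene counts.
#' @export
generateTruth <- function(config = synthConfig(), seed = 1L) {
  simulateStudy(config, seed)$truth
}

.writeOBO <- function(ontology, path) {
  terms <- ontologyTerms(ontology)
  edges <- isaEdges(ontology)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(terms))) {
    writeLines(c("", "[Term]", paste0("id: ", terms$id[i]),
                 paste0("name: ", terms$name[i])), con)
    for (p in edges$parent[edges$child == terms$id[i]])
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Write a synthetic study to disk
#'
#' Writes every component of a [simulateStudy()] result in the formats the
#' readers consume: `de.tsv`, `model.json`, `annotations.tsv`,
#' `cc_annotations.tsv`, `ontology.obo`, `rates_a.json`, `rates_b.json`
#' and `truth.json`.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(de = file.path(dir, "de.tsv"),
             model = file.path(dir, "model.json"),
             annotations = file.path(dir, "annotations.tsv"),
             cc = file.path(dir, "cc_annotations.tsv"),
             obo = file.path(dir, "ontology.obo"),
             ratesA = file.path(dir, "rates_a.json"),
             ratesB = file.path(dir, "rates_b.json"),
             truth = file.path(dir, "truth.json"))
  writeDETable(study$de, paths["de"])
  writeModel(study$model, paths["model"])
  utils::write.table(study$annotations, paths["annotations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$ccAnnotations, paths["cc"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeOBO(study$ontology, paths["obo"])
  jsonlite::write_json(study$ratesA, paths["ratesA"], auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(study$ratesB, paths["ratesB"], auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
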