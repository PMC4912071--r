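overlapModel <- function() {
  # pathway metabolite sets: P1 = {A,B,C,D}, P2 = {C,D,E}, P3 = {X,Y}
  makeModel(c("A", "B", "C", "D", "E", "X", "Y"),
            list(list(id = "r1", stoich = c(A = -1, B = 1)),
                 list(id = "r2", stoich = c(C = -1, D = 1)),
                 list(id = "r3", stoich = c(C = -1, D = 1, E = 1)),
                 list(id = "r4", stoich = c(X = -1, Y = 1))),
            biomass = "r1",
            pathwayList = list(P1 = c("r1", "r2"), P2 = "r3", P3 = "r4"))
}

test_that("pathway overlap normalises by the smaller metabolite set", {
  g <- pathwayNetwork(overlapModel(), threshold = 0.3)
  e <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  i <- which(apply(e, 1, function(r) setequal(r, c("P1", "P2"))))
  expect_length(i, 1L)
  expect_equal(w[i], 2 / 3)   # |{C,D}| / min(4, 3)
  # the disjoint pathway hangs off Self
  j <- which(apply(e, 1, function(r) "P3" %in% r))
  expect_true(all(e[j, ] %in% c("P3", "Self")))
})

test_that("identical metabolite sets score 1 and disjoint ones go to Self", {
  m <- makeModel(c("A", "B"),
                 list(list(id = "r1", stoich = c(A = -1, B = 1)),
                      list(id = "r2", stoich = c(B = -1, A = 1)),
                      list(id = "r3", stoich = c(A = -1, B = 1))),
                 biomass = "r1",
                 pathwayList = list(Pa = "r1", Pb = "r2"))
  g <- pathwayNetwork(m, threshold = 0.5)
  expect_equal(igraph::E(g)$weight, 1)
  disj <- makeModel(c("A", "B", "C", "D", "E", "F"),
                    list(list(id = "r1", stoich = c(A = -1, B = 1)),
                         list(id = "r2", stoich = c(C = -1, D = 1)),
                         list(id = "r3", stoich = c(E = -1, F = 1))),
                    biomass = "r1",
                    pathwayList = list(P1 = "r1", P2 = "r2", P3 = "r3"))
  g2 <- pathwayNetwork(disj, threshold = 0.1)
  el <- igraph::as_edgelist(g2)
  expect_equal(nrow(el), 3L)
  expect_true(all(el[, 2] == "Self" | el[, 1] == "Self"))
})

test_that("pathway overlap equals a set-operations oracle on random models", {
  set.seed(71)
  mets <- sprintf("m%02d", 1:20)
  rxns <- lapply(1:12, function(i) {
    pair <- sample(mets, 2)
    list(id = paste0("r", i), stoich = setNames(c(-1, 1), pair))
  })
  pws <- lapply(1:5, function(i) sample(sprintf("r%d", 1:12), 4))
  names(pws) <- paste0("P", 1:5)
  model <- makeModel(mets, rxns, biomass = "r1", pathwayList = pws)
  g <- pathwayNetwork(model, threshold = 0)
  sets <- pathwayMetaboliteSets(model)
  el <- igraph::as_edgelist(g); w <- igraph::E(g)$weight
  for (i in seq_len(nrow(el))) {
    if ("Self" %in% el[i, ]) next
    a <- sets[[el[i, 1]]]; b <- sets[[el[i, 2]]]
    expect_equal(w[i], length(intersect(a, b)) / min(length(a), length(b)))
  }
})

test_that("compartment tags are stripped before pathway overlap", {
  m <- makeModel(c("glc_c", "glc_m", "pyr_c"),
                 list(list(id = "r1", stoich = c(glc_c = -1, pyr_c = 1)),
                      list(id = "r2", stoich = c(glc_m = -1, pyr_c = 1))),
                 biomass = "r1", compartments = c("c", "m", "c"),
                 pathwayList = list(Pc = "r1", Pm = "r2"))
  g <- pathwayNetwork(m, threshold = 0.5)
  # cytosolic and mitochondrial glucose count as the same compound
  expect_equal(igraph::E(g)$weight, 1)
})

test_that("SMILES similarity is a normalised edit distance", {
  expect_equal(smilesSimilarity("CCO", "CCO"), 1)
  expect_equal(smilesSimilarity("CCO", "CC"), 1 - 1 / 3)
  expect_equal(smilesSimilarity("NNN", "CCO"), 0)
  expect_error(smilesSimilarity("", "CC"), "empty")
  # symmetry and agreement with the DP oracle on random pairs
  set.seed(12)
  alpha <- c("C", "O", "N", "(", ")", "=", "1")
  rnd <- function() paste(sample(alpha, sample(3:12, 1), replace = TRUE),
                          collapse = "")
  for (i in 1:200) {
    s1 <- rnd(); s2 <- rnd()
    sim <- smilesSimilarity(s1, s2)
    expect_equal(sim, smilesSimilarity(s2, s1))
    expect_equal(sim, 1 - dpEditDistance(s1, s2) /
                   max(nchar(s1), nchar(s2)))
  }
})

molFixture <- function() {
  data.frame(metabolite_id = c("molA", "molB", "molC"),
             score = c(2.5, 3.1, 1.7),
             smiles = c("CCCCCCO", "CCCCCCN", "O=1=1=1"),
             n_up = c(2L, 1L, 0L), n_down = c(0L, 0L, 2L),
             dominant_fraction = c(1, 1, 1), stringsAsFactors = FALSE)
}

test_that("molecular network links each molecule to its closest match", {
  rep <- molFixture()
  # A and B are 6/7 similar; C matches nothing at or above 0.4
  g <- molecularNetwork(rep, minScore = 1.64, simThreshold = 0.4)
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "|")
  expect_setequal(el, c("molA|molB", "molC|Self"))
  w <- igraph::E(g)$weight[el == "molA|molB"]
  expect_equal(w, smilesSimilarity("CCCCCCO", "CCCCCCN"))
  # below the inclusion score the molecule disappears entirely
  g2 <- molecularNetwork(rep, minScore = 3.0)
  expect_false("molA" %in% igraph::V(g2)$name)
  # a single molecule can only attach to Self
  g3 <- molecularNetwork(rep[1, ], minScore = 1.64)
  expect_setequal(igraph::V(g3)$name, c("molA", "Self"))
})

test_that("lowering the similarity threshold never removes an edge", {
  rep <- molFixture()
  gHi <- molecularNetwork(rep, minScore = 1, simThreshold = 0.6)
  gLo <- molecularNetwork(rep, minScore = 1, simThreshold = 0.2)
  elHi <- apply(igraph::as_edgelist(gHi), 1, paste, collapse = "|")
  elLo <- apply(igraph::as_edgelist(gLo), 1, paste, collapse = "|")
  expect_true(all(setdiff(elHi, grep("Self", elHi, value = TRUE)) %in% elLo))
})

test_that("each non-Self node commits to exactly one closest match", {
  set.seed(55)
  alpha <- c("C", "O", "N", "=")
  n <- 12
  rep <- data.frame(metabolite_id = sprintf("mol%02d", 1:n),
                    score = rep(2, n),
                    smiles = vapply(1:n, function(i)
                      paste(sample(alpha, 8, replace = TRUE), collapse = ""),
                      character(1)),
                    stringsAsFactors = FALSE)
  g <- molecularNetwork(rep, minScore = 1.64, simThreshold = 0)
  deg <- igraph::degree(g)
  # with threshold 0 everyone finds a partner; reciprocal pairs merge, so
  # every molecule has degree >= 1 and no molecule links to Self
  expect_false("Self" %in% igraph::V(g)$name)
  expect_true(all(deg[setdiff(names(deg), "Self")] >= 1))
  # molecules without SMILES go to Self with a warning
  rep$smiles[1] <- ""
  expect_warning(g2 <- molecularNetwork(rep, minScore = 1.64), "mol01")
  expect_true(igraph::are_adjacent(g2, "mol01", "Self"))
})
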