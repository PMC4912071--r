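writeTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
deHeader <- paste("gene_id", "value_a", "value_b", "log2_fc", "p_value",
                  "q_value", "significant", "protein_names", "gene_names",
                  "go_terms", sep = "\t")

test_that("DE tables round-trip through write/read on all fields", {
  set.seed(11)
  de <- makeDe(sprintf("g%03d", 1:40), q = runif(40), fc = rnorm(40, 0, 2),
               value_a = rlnorm(40, 3, 1))
  de$go_terms[[1]] <- c("T:1", "T:2")
  f <- tempfile(fileext = ".tsv")
  writeDETable(de, f)
  back <- readDETable(f)
  expect_equal(back$gene_id, de$gene_id)
  for (col in c("value_a", "value_b", "log2_fc", "p_value", "q_value"))
    expect_equal(signif(back[[col]], 6), signif(de[[col]], 6))
  expect_equal(back$significant, de$significant)
  expect_equal(back$go_terms[[1]], c("T:1", "T:2"))
})

test_that("fold changes are recomputed from abundances and flags from q", {
  f <- writeTsv(c(deHeader,
    paste("GK5S-1542", "5.2", "1512.1", "8.2", "0.0005", "0.001", "yes",
          "Citrate synthase 3", "CIT3", "", sep = "\t"),
    paste("gNull", "10", "11", "0.1", "0.3", "0.5", "no", "", "", "",
          sep = "\t")))
  de <- readDETable(f)
  expect_equal(de$value_a[1], 5.2)
  expect_equal(de$value_b[1], 1512.1)
  expect_equal(round(de$log2_fc[1], 1), 8.2)  # log2(1512.1 / 5.2)
  expect_true(de$significant[1])
  expect_false(de$significant[2])              # q = 0.5 at cutoff 0.05
})

test_that("an empty table with a valid header yields an empty result", {
  de <- readDETable(writeTsv(deHeader))
  expect_equal(nrow(de), 0L)
  expect_true(all(c("gene_id", "q_value", "significant") %in% names(de)))
})

test_that("malformed DE tables are rejected with informative errors", {
  f <- writeTsv(c("gene_id\tvalue_a\tvalue_b\tlog2_fc\tp_value",
                  "g1\t1\t2\t1\t0.1"))
  expect_error(readDETable(f), "q_value")
  f2 <- writeTsv(c(deHeader,
                   paste("g1", 1, 2, 1, .1, .2, "no", "", "", "", sep = "\t"),
                   paste("g1", 1, 2, 1, .1, .2, "no", "", "", "", sep = "\t")))
  expect_error(readDETable(f2), "duplicate.*g1")
  f3 <- writeTsv(c(deHeader,
                   paste("g1", "abc", 2, 1, .1, .2, "no", "", "", "",
                         sep = "\t"),
                   paste("g2", 1, 2, 1, .1, .2, "no", "", "", "", sep = "\t")))
  expect_warning(de <- readDETable(f3), "row index 1")
  expect_equal(de$gene_id, "g2")
})

writeObo <- function(stanzas) {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", stanzas), f)
  f
}
stanza <- function(id, name = id, isa = character(), obsolete = FALSE) {
  c("", "[Term]", paste0("id: ", id), paste0("name: ", name),
    if (length(isa)) paste0("is_a: ", isa),
    if (obsolete) "is_obsolete: true")
}

test_that("OBO parsing keeps is_a edges, drops obsolete and dangling", {
  ont <- readOBO(writeObo(c(stanza("A"), stanza("B", isa = "A"))))
  expect_equal(nrow(ontologyTerms(ont)), 2L)
  expect_equal(isaEdges(ont),
               data.frame(child = "B", parent = "A",
                          stringsAsFactors = FALSE))
  # DAG diamond: both parents retained
  dia <- readOBO(writeObo(c(stanza("R"), stanza("P1", isa = "R"),
                            stanza("P2", isa = "R"),
                            stanza("C", isa = c("P1", "P2")))))
  e <- isaEdges(dia)
  expect_setequal(e$parent[e$child == "C"], c("P1", "P2"))
  # obsolete terms vanish entirely
  obs <- readOBO(writeObo(c(stanza("A"), stanza("B", isa = "A",
                                                obsolete = TRUE))))
  expect_equal(ontologyTerms(obs)$id, "A")
  # dangling parent dropped with a warning, not an error
  expect_warning(dang <- readOBO(writeObo(stanza("A", isa = "GHOST"))),
                 "GHOST")
  expect_equal(nrow(isaEdges(dang)), 0L)
})

test_that("a cyclic is_a closure is refused, naming a cycle", {
  f <- writeObo(c(stanza("A", isa = "B"), stanza("B", isa = "A")))
  expect_error(readOBO(f), "cycle")
})

chainModelJson <- function() {
  f <- tempfile(fileext = ".json")
  writeLines('{
    "metabolites": {
      "S": {"name": "substrate", "compartment": "e"},
      "A": {"name": "a", "compartment": "c"},
      "B": {"name": "b", "compartment": "c"}
    },
    "reactions": {
      "EX_S": {"stoichiometry": {"S": -1}, "reversible": true},
      "R1": {"stoichiometry": {"S": -1, "A": 1}, "genes": ["g1"],
             "pathways": ["P1"]},
      "R2": {"stoichiometry": {"A": -1, "B": 1}, "genes": ["g2"],
             "pathways": ["P1"]},
      "GROW": {"stoichiometry": {"B": -1}}
    },
    "pathways": {"P1": {"name": "chain", "reactions": ["R1", "R2"]}},
    "biomass_reaction": "GROW",
    "exchanges": ["EX_S"]
  }', f)
  f
}

test_that("model JSON loads with correct derived pathway metabolite sets", {
  model <- readModel(chainModelJson())
  expect_s4_class(model, "MetabolicModel")
  expect_equal(nrow(reactions(model)), 4L)
  expect_equal(pathwayMetaboliteSets(model)$P1, c("A", "B", "S"))
  expect_equal(enzymeGenes(model), c("g1", "g2"))
})

test_that("model loading refuses unknown metabolites and duplicate ids", {
  f <- tempfile(fileext = ".json")
  writeLines('{"metabolites": {"A": {}},
    "reactions": {"R1": {"stoichiometry": {"A": -1, "GHOST": 1}}},
    "biomass_reaction": "R1", "exchanges": []}', f)
  expect_error(readModel(f), "R1.*GHOST")
  f2 <- tempfile(fileext = ".json")
  writeLines('{"metabolites": {"A": {}},
    "reactions": {"R1": {"stoichiometry": {"A": -1}},
                  "R1": {"stoichiometry": {"A": 1}}},
    "biomass_reaction": "R1", "exchanges": []}', f2)
  expect_error(readModel(f2), "duplicate reaction")
  f3 <- tempfile(fileext = ".json")
  writeLines('{"metabolites": {"A": {}},
    "reactions": {"R1": {"stoichiometry": {"A": -1}}},
    "exchanges": []}', f3)
  expect_error(readModel(f3), "biomass")
})

test_that("networks round-trip through GraphML and edge TSV", {
  set.seed(5)
  g <- igraph::sample_gnp(50, 0.08)
  igraph::V(g)$name <- sprintf("n%02d", 1:50)
  igraph::V(g)$score <- rnorm(50)
  igraph::E(g)$weight <- runif(igraph::ecount(g))
  f <- tempfile(fileext = ".graphml")
  writeNetwork(g, f, "graphml")
  g2 <- readNetwork(f, "graphml")
  expect_equal(sort(igraph::V(g2)$name), sort(igraph::V(g)$name))
  el <- function(x) {
    e <- apply(igraph::as_edgelist(x), 1, function(r)
      paste(sort(r), collapse = "|"))
    sort(e)
  }
  expect_equal(el(g2), el(g))
  expect_equal(signif(igraph::V(g2)$score[match(igraph::V(g)$name,
                                                igraph::V(g2)$name)], 6),
               signif(igraph::V(g)$score, 6))
  f2 <- tempfile(fileext = ".tsv")
  writeNetwork(g, f2, "edge-tsv")
  g3 <- readNetwork(f2, "edge-tsv")
  expect_equal(el(g3), el(g))
  expect_error(writeNetwork(g, tempfile(), "dot"))
})

test_that("an empty graph still writes a valid GraphML document", {
  g <- igraph::make_empty_graph(directed = FALSE)
  f <- tempfile(fileext = ".graphml")
  writeNetwork(g, f)
  expect_equal(igraph::vcount(readNetwork(f)), 0L)
})
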