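# Independent oracles and fixture builders shared across the suite.

# Levenshtein distance by explicit dynamic programming (independent of the
# implementation route used by the package).
dpEditDistance <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (a[i] != b[j]))
  d[n + 1, m + 1]
}

# Exhaustive background moments: total Z over every size-k subset of z.
# Population standard deviation (the quantity the bootstrap sd estimates).
exhaustiveBackground <- function(z, k) {
  totals <- utils::combn(z, k, sum)
  list(mean = mean(totals),
       sd = sqrt(mean((totals - mean(totals))^2)),
       totals = totals)
}

# Brute-force LP oracle: enumerate basic solutions of {x : A x = b, x >= 0}
# and return the maximal objective over feasible vertices.
lpVertexOracle <- function(obj, A, b, tol = 1e-8) {
  A <- as.matrix(A)
  keep <- qr(t(A))$pivot[seq_len(qr(t(A))$rank)]
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  m <- nrow(A); n <- ncol(A)
  best <- -Inf; bestX <- NULL
  for (S in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, S, drop = FALSE]
    if (abs(det(B)) < tol) next
    xb <- solve(B, b)
    if (any(xb < -1e-8)) next
    x <- numeric(n); x[S] <- xb
    v <- sum(obj * x)
    if (v > best + 1e-12) { best <- v; bestX <- x }
  }
  list(value = best, x = bestX)
}

# Compact model constructor for hand-built fixtures. `reactionList` entries:
# list(id, stoich (named numeric), rev, genes, comp, pathways).
makeModel <- function(metaboliteIds, reactionList, biomass,
                      exchanges = character(), compartments = NULL,
                      smiles = NULL, pathwayList = list()) {
  met <- data.frame(id = metaboliteIds, name = metaboliteIds,
                    smiles = if (is.null(smiles)) "" else smiles,
                    compartment = if (is.null(compartments)) "" else
                      compartments,
                    stringsAsFactors = FALSE)
  rdf <- data.frame(
    id = vapply(reactionList, `[[`, "", "id"),
    reversible = vapply(reactionList,
                        function(r) isTRUE(r$rev), logical(1)),
    compartment = vapply(reactionList,
                         function(r) if (is.null(r$comp)) "" else r$comp,
                         character(1)),
    stringsAsFactors = FALSE)
  rdf$stoichiometry <- lapply(reactionList, `[[`, "stoich")
  rdf$genes <- lapply(reactionList, function(r)
    if (is.null(r$genes)) character(0) else r$genes)
  rdf$pathways <- lapply(reactionList, function(r)
    if (is.null(r$pathways)) character(0) else r$pathways)
  pw <- data.frame(id = names(pathwayList),
                   name = names(pathwayList), stringsAsFactors = FALSE)
  pw$reactions <- unname(pathwayList)
  if (!nrow(pw)) { pw <- data.frame(id = character(), name = character(),
                                    stringsAsFactors = FALSE)
                   pw$reactions <- list() }
  new("MetabolicModel", metabolites = met, reactions = rdf, pathways = pw,
      biomassReaction = biomass, exchanges = exchanges)
}

# Minimal DE table builder.
makeDe <- function(gene_id, q, fc, value_a = NULL) {
  a <- if (is.null(value_a)) rep(100, length(gene_id)) else value_a
  de <- data.frame(gene_id = gene_id, value_a = a, value_b = a * 2^fc,
                   log2_fc = fc, p_value = q / 2, q_value = q,
                   significant = q < 0.05, protein_names = "",
                   gene_names = gene_id, stringsAsFactors = FALSE)
  de$go_terms <- rep(list(character(0)), nrow(de))
  de
}

# Random small feasible flux model: a substrate-to-sink chain with random
# extra branches, fixed uptake 1. Used against the vertex-enumeration oracle.
randomToyModel <- function(nExtra = 3) {
  mets <- c("X_e", paste0("A", 1:3))
  rxns <- list(
    list(id = "EX", stoich = c(X_e = -1), rev = TRUE),
    list(id = "T", stoich = c(X_e = -1, A1 = 1)),
    list(id = "C1", stoich = c(A1 = -1, A2 = 1)),
    list(id = "C2", stoich = c(A2 = -1, A3 = 1)),
    list(id = "SINK", stoich = c(A3 = -1)))
  for (i in seq_len(nExtra)) {
    from <- sample(paste0("A", 1:3), 1)
    to <- sample(setdiff(paste0("A", 1:3), from), 1)
    # branches stay irreversible with sub-unit yields: a reversible branch
    # run backwards would amplify mass around a cycle and unbound the LP
    st <- stats::setNames(c(-1, stats::runif(1, 0.3, 0.95)), c(from, to))
    rxns[[length(rxns) + 1L]] <- list(id = paste0("B", i), stoich = st)
  }
  makeModel(mets, rxns, biomass = "SINK", exchanges = "EX")
}

# Bisection inverse of the standard-normal CDF (oracle for qToZ).
bisectQnorm <- function(p, lo = -10, hi = 10, iter = 200) {
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
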