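chainModel <- function() {
  makeModel(c("S", "A", "B"),
            list(list(id = "EX", stoich = c(S = -1), rev = TRUE),
                 list(id = "T", stoich = c(S = -1, A = 1)),
                 list(id = "C", stoich = c(A = -1, B = 1)),
                 list(id = "GROW", stoich = c(B = -1))),
            biomass = "GROW", exchanges = "EX")
}

test_that("a linear chain carries the fixed uptake straight to biomass", {
  st <- fbaSolve(chainModel(), list(EX = -10), condition = "test")
  expect_equal(objectiveValue(st), 10)
  expect_equal(unname(fluxes(st)[c("T", "C", "GROW")]), c(10, 10, 10))
  zero <- fbaSolve(chainModel(), list(EX = 0))
  expect_equal(max(abs(fluxes(zero))), 0)
})

test_that("flux states satisfy mass balance and irreversibility", {
  set.seed(31)
  for (i in 1:10) {
    model <- randomToyModel(nExtra = sample(1:3, 1))
    st <- fbaSolve(model, list(EX = -1))
    S <- stoichiometricMatrix(model)
    v <- fluxes(st)
    expect_lt(max(abs(S %*% v)), 1e-8 * max(1, max(abs(S))))
    irrev <- !reactions(model)$reversible
    expect_true(all(v[irrev] >= -1e-9))
  }
})

test_that("FBA matches brute-force vertex enumeration on random toys", {
  set.seed(97)
  for (i in 1:20) {
    model <- randomToyModel(nExtra = sample(1:3, 1))
    st <- fbaSolve(model, list(EX = -1))
    # rebuild the same split-variable LP and enumerate its vertices
    rxn <- reactions(model)
    S <- stoichiometricMatrix(model)
    revIdx <- which(rxn$reversible)
    A <- cbind(S, -S[, revIdx, drop = FALSE])
    expand <- function(co) c(co, -co[revIdx])
    ex <- rep(0, nrow(rxn)); ex[match("EX", rxn$id)] <- 1
    A <- rbind(A, expand(ex))
    b <- c(rep(0, nrow(S)), -1)
    obj <- rep(0, nrow(rxn)); obj[match("SINK", rxn$id)] <- 1
    oracle <- lpVertexOracle(expand(obj), A, b)
    expect_equal(objectiveValue(st), oracle$value, tolerance = 1e-6)
  }
})

test_that("infeasible and ill-posed measurements fail loudly", {
  m <- chainModel()
  # uptake is irreversible inside the chain: demanding net production of
  # biomass with zero uptake but a positive secreted rate cannot balance
  m2 <- makeModel(c("S", "A"),
                  list(list(id = "EX", stoich = c(S = -1), rev = TRUE),
                       list(id = "T", stoich = c(S = -1, A = 1)),
                       list(id = "EX_A", stoich = c(A = -1)),
                       list(id = "GROW", stoich = c(A = -1))),
                  biomass = "GROW", exchanges = c("EX", "EX_A"))
  expect_error(fbaSolve(m2, list(EX = 0, EX_A = 5)), "EX_A = 5")
  # a negative rate on an irreversible reaction is rejected at solve time
  expect_error(fbaSolve(m2, list(EX_A = -2)), "irreversible")
  expect_error(fbaSolve(m, list(GHOST = 1)), "unknown exchange")
  # soft mode relaxes the equalities into feasible bands
  st <- fbaSolve(m2, list(EX = -5, EX_A = 2), soft = TRUE)
  expect_gte(objectiveValue(st), 0)
})

test_that("unconstrained uptake with a biomass objective is unbounded", {
  expect_error(fbaSolve(chainModel(), list(EX = "free")), "unbounded")
})

test_that("differential flux classes follow the 10% constitutive rule", {
  mk <- function(v, cond) new("FluxState", condition = cond,
                              fluxes = v, objective = 0)
  a <- c(r1 = 10, r2 = 3, r3 = 2.7, r4 = 0, r5 = 0, r6 = 5)
  b <- c(r1 = 9.5, r2 = -2, r3 = 0, r4 = 4, r5 = 0, r6 = 9)
  df <- differentialFlux(mk(a, "A"), mk(b, "B"))
  cls <- setNames(df$class, df$reaction_id)
  expect_equal(cls[["r1"]], "constitutive")   # 5% < 10%
  expect_equal(cls[["r2"]], "reversed")
  expect_equal(cls[["r3"]], "disappeared")
  expect_equal(cls[["r4"]], "appeared")
  expect_equal(cls[["r5"]], "zero_both")
  expect_equal(cls[["r6"]], "up")
  # antisymmetry under swapping conditions
  swap <- differentialFlux(mk(b, "B"), mk(a, "A"))
  map <- c(up = "down", down = "up", appeared = "disappeared",
           disappeared = "appeared", constitutive = "constitutive",
           reversed = "reversed", zero_both = "zero_both")
  expect_equal(unname(map[df$class]), swap$class)
})

mraInputs <- function(ja, jb, ta, tb, sig = TRUE, cls = NULL) {
  mk <- function(v, cond) new("FluxState", condition = cond,
                              fluxes = c(r = v), objective = 0)
  df <- differentialFlux(mk(ja, "A"), mk(jb, "B"))
  rx <- data.frame(reaction_id = "r", n_genes = 1L, total_a = ta,
                   total_b = tb, rep_log2_fc = log2(tb / ta),
                   any_significant = sig,
                   class = if (is.null(cls)) if (sig) "up" else
                     "constitutive" else cls,
                   stringsAsFactors = FALSE)
  mra(df, rx)
}

test_that("MRA quantifies hierarchical and metabolic shares", {
  # expression doubles and flux doubles: purely hierarchical
  r <- mraInputs(ja = 2, jb = 4, ta = 100, tb = 200)
  expect_equal(r$class, "quantified")
  expect_equal(r$rho_h, 1)
  expect_equal(r$rho_m, 0)
  # expression unchanged (not significant), flux halves: purely metabolic
  r2 <- mraInputs(ja = 4, jb = 2, ta = 100, tb = 100, sig = FALSE)
  expect_equal(r2$rho_h, 0)
  expect_equal(r2$rho_m, 1)
  # a vanished flux is purely metabolic whatever the transcripts did
  r3 <- mraInputs(ja = 2.7, jb = 0, ta = 100, tb = 900)
  expect_equal(r3$class, "purely_metabolic")
  expect_equal(r3$rho_h, 0)
  expect_equal(r3$rho_m, 1)
  # identity holds exactly for every quantified record
  set.seed(8)
  for (i in 1:20) {
    r4 <- mraInputs(ja = runif(1, 1, 5), jb = runif(1, 6, 12),
                    ta = runif(1, 10, 100), tb = runif(1, 10, 100))
    if (r4$class == "quantified") {
      expect_identical(r4$rho_m, 1 - r4$rho_h)  # exact by construction
      expect_equal(r4$rho_h + r4$rho_m, 1, tolerance = 1e-12)
    }
  }
})

test_that("MRA refuses division by a near-zero flux change", {
  r <- mraInputs(ja = 10, jb = 9.8, ta = 100, tb = 400)
  expect_equal(r$class, "not_applicable")
  expect_match(r$note, "division by ~0")
  r2 <- mraInputs(ja = 3, jb = -2, ta = 100, tb = 50)
  expect_equal(r2$class, "not_applicable")
  r3 <- mraInputs(ja = 0, jb = 3, ta = 100, tb = 50)
  expect_equal(r3$class, "not_applicable")   # appeared flux
})

test_that("planted hierarchical coefficients are recovered exactly", {
  # fluxes scale by f, transcripts by f^alpha: recovered rho_h equals alpha
  alpha <- 0.7; f <- 0.4
  mk <- function(v, cond) new("FluxState", condition = cond, fluxes = v,
                              objective = 0)
  ja <- c(r1 = 2, r2 = 5, r3 = 8)
  df <- differentialFlux(mk(ja, "A"), mk(ja * f, "B"))
  rx <- data.frame(reaction_id = names(ja), n_genes = 1L,
                   total_a = c(10, 20, 30),
                   total_b = c(10, 20, 30) * f^alpha,
                   rep_log2_fc = alpha * log2(f), any_significant = TRUE,
                   class = "down", stringsAsFactors = FALSE)
  r <- mra(df, rx)
  expect_equal(r$rho_h, rep(alpha, 3), tolerance = 1e-9)
  expect_equal(r$rho_m, rep(1 - alpha, 3), tolerance = 1e-9)
})
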