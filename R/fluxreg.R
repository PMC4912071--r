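# Internal LP front-end: max/min obj'x s.t. Aeq x = beq, Ain x <= bin, x >= 0.
# Backed by the package's two-phase Bland-rule simplex (see R/lp.R).
solveLP <- function(obj, Aeq, beq, Ain = NULL, bin = NULL, maximize = TRUE) {
  r <- simplexSolve(obj, Aeq, beq, Ain = Ain, bin = bin, maximize = maximize)
  if (r$status != "optimal")
    stop("linear program ", r$status)
  r
}

#' Flux balance analysis with measured exchange constraints
#'
#' Estimates a condition-specific steady-state flux distribution by linear
#' optimisation: maximise the biomass reaction flux subject to mass balance
#' (`S v = 0` over all metabolites), irreversibility bounds (`v >= 0` for
#' irreversible reactions) and equality constraints fixing each measured
#' exchange rate. After the biomass optimum is found, a parsimonious second
#' stage minimises the total absolute flux at that optimum, so the reported
#' distribution is unique in the common alternate-optima situations and
#' reproducible across solvers.
#'
#' Exchange fluxes follow the boundary convention: an exchange reaction
#' exports its metabolite at positive flux, so uptake rates are negative.
#' Rates are in consistent specific units, conventionally
#' mmol h^-1 gDW^-1.
#'
#' @param model a [MetabolicModel-class].
#' @param rates named list or numeric vector of measured exchange rates:
#'   exchange reaction id to a number (0 fixes a species to zero) or the
#'   string `"free"` to leave it unconstrained. Exchanges not mentioned are
#'   free.
#' @param condition label stored in the result.
#' @param parsimonious apply the minimal-total-flux secondary objective
#'   (default `TRUE`).
#' @param soft relax measured rates from equalities to `rate * (1 +/- softBand)`
#'   bands, for measurement sets that are jointly infeasible as equalities.
#' @param softBand half-width of the relative band in soft mode (default 0.05).
#' @return a [FluxState-class].
#' @export
fbaSolve <- function(model, rates, condition = "", parsimonious = TRUE,
                     soft = FALSE, softBand = 0.05) {
  stopifnot(is(model, "MetabolicModel"))
  rates <- as.list(rates)
  unknown <- setdiff(names(rates), exchangeReactions(model))
  if (length(unknown))
    stop("measured rate(s) for unknown exchange reaction(s): ",
         paste(unknown, collapse = ", "))
  measured <- rates[!vapply(rates, function(x) identical(x, "free"),
                            logical(1))]
  measured <- vapply(measured, as.numeric, numeric(1))

  rxn <- reactions(model)
  S <- stoichiometricMatrix(model)
  rev <- rxn$reversible
  # negative measured rate on an irreversible exchange is a contradiction
  bad <- names(measured)[measured < 0 &
                           !rev[match(names(measured), rxn$id)]]
  if (length(bad))
    stop("negative rate requested for irreversible reaction(s): ",
         paste(bad, collapse = ", "))

  # split reversible reactions: v = f - r with f, r >= 0
  nR <- nrow(rxn)
  fwdCol <- seq_len(nR)
  revIdx <- which(rev)
  revCol <- if (length(revIdx)) nR + seq_along(revIdx) else integer(0)
  A <- cbind(S, if (length(revIdx)) -S[, revIdx, drop = FALSE])
  nVar <- ncol(A)
  beq <- rep(0, nrow(A))

  expand <- function(coefPerRxn) {
    # map a per-reaction coefficient vector into split-variable space
    c(coefPerRxn, if (length(revIdx)) -coefPerRxn[revIdx])
  }
  Ain <- NULL; bin <- NULL
  if (length(measured)) {
    for (ex in names(measured)) {
      coef <- rep(0, nR); coef[match(ex, rxn$id)] <- 1
      row <- expand(coef)
      if (!soft) {
        A <- rbind(A, row); beq <- c(beq, measured[[ex]])
      } else {
        lo <- min(measured[[ex]] * (1 - softBand),
                  measured[[ex]] * (1 + softBand))
        hi <- max(measured[[ex]] * (1 - softBand),
                  measured[[ex]] * (1 + softBand))
        Ain <- rbind(Ain, row, -row); bin <- c(bin, hi, -lo)
      }
    }
  }
  objCoef <- rep(0, nR)
  objCoef[match(biomassReaction(model), rxn$id)] <- 1
  obj <- expand(objCoef)

  stage1 <- tryCatch(solveLP(obj, A, beq, Ain, bin, maximize = TRUE),
                     error = function(e)
                       stop("FBA infeasible or unbounded under measured ",
                            "rates [",
                            paste(names(measured), signif(unlist(measured), 6),
                                  sep = " = ", collapse = ", "), "]: ",
                            conditionMessage(e), call. = FALSE))
  x <- stage1$x
  if (parsimonious) {
    A2 <- rbind(A, obj); beq2 <- c(beq, stage1$value)
    stage2 <- tryCatch(solveLP(rep(1, nVar), A2, beq2, Ain, bin,
                               maximize = FALSE),
                       error = function(e) NULL)
    if (!is.null(stage2)) x <- stage2$x
  }
  v <- x[fwdCol]
  if (length(revIdx)) v[revIdx] <- v[revIdx] - x[revCol]
  names(v) <- rxn$id
  # steady-state check (LP solutions are near-exact; tolerance is generous)
  resid <- max(abs(S %*% v))
  if (resid > 1e-6 * max(1, max(abs(S))))
    warning("mass-balance residual ", signif(resid, 3),
            " exceeds tolerance")
  new("FluxState", condition = condition, fluxes = v,
      objective = unname(v[biomassReaction(model)]))
}

#' Cross-condition differential flux classification
#'
#' Compares two flux distributions reaction by reaction. Fluxes whose
#' magnitudes lie below `zeroTol` (the LP noise floor) are treated as zero.
#' Classes:
#'
#' * `constitutive` - both nonzero, same sign, relative difference
#'   `|j_b - j_a| / max(|j_a|, |j_b|)` below `tolerance` (default 10%);
#' * `up` / `down` - both nonzero, same sign, magnitude increased /
#'   decreased by at least `tolerance`;
#' * `reversed` - both nonzero with opposite signs;
#' * `appeared` / `disappeared` - zero in exactly one condition;
#' * `zero_both` - zero in both.
#'
#' Swapping the two conditions swaps `up` with `down` and `appeared` with
#' `disappeared`.
#'
#' @param stateA,stateB [FluxState-class] objects over the same model.
#' @param tolerance relative difference below which a flux is constitutive
#'   (default 0.10).
#' @param zeroTol absolute magnitude below which a flux counts as zero
#'   (default 1e-6).
#' @return `data.frame` with columns `reaction_id`, `j_a`, `j_b`, `class`,
#'   `log2_ratio` (log2 of `|j_b| / |j_a|`, defined when both are nonzero
#'   with the same sign).
#' @export
differentialFlux <- function(stateA, stateB, tolerance = 0.10,
                             zeroTol = 1e-6) {
  stopifnot(is(stateA, "FluxState"), is(stateB, "FluxState"))
  ids <- union(names(fluxes(stateA)), names(fluxes(stateB)))
  ja <- fluxes(stateA)[ids]; jb <- fluxes(stateB)[ids]
  ja[is.na(ja)] <- 0; jb[is.na(jb)] <- 0
  ja[abs(ja) < zeroTol] <- 0; jb[abs(jb) < zeroTol] <- 0
  cls <- character(length(ids)); lr <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    a <- ja[i]; b <- jb[i]
    if (a == 0 && b == 0) cls[i] <- "zero_both"
    else if (a == 0) cls[i] <- "appeared"
    else if (b == 0) cls[i] <- "disappeared"
    else if (sign(a) != sign(b)) cls[i] <- "reversed"
    else {
      lr[i] <- log2(abs(b) / abs(a))
      cls[i] <- if (abs(b - a) / max(abs(a), abs(b)) < tolerance)
        "constitutive" else if (abs(b) > abs(a)) "up" else "down"
    }
  }
  data.frame(reaction_id = ids, j_a = unname(ja), j_b = unname(jb),
             class = cls, log2_ratio = lr, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Metabolic regulation analysis
#'
#' Decomposes each reaction's flux change into a hierarchical coefficient
#' `rho_h = delta ln(e) / delta ln(J)` - the share explained by the change
#' in enzyme level, proxied by the summed transcript abundance of all genes
#' mapping to the reaction - and a metabolic coefficient obtained by
#' difference from the identity `rho_h + rho_m = 1`. A reaction is
#' `quantified` when its flux is nonzero with the same sign in both
#' conditions and its flux change exceeds the constitutive tolerance; when
#' no member gene is significantly differentially expressed, the transcript
#' change is taken as zero (`rho_h = 0`, fully metabolic regulation of the
#' flux change). A flux that disappears (for instance because a fermentation
#' product is absent in the second condition) is classified
#' `purely_metabolic` regardless of expression: no finite expression change
#' can shut a flux off entirely. Reactions with reversed, vanished-in-both
#' or newly appeared fluxes, with a constitutive flux (division by a
#' near-zero `delta ln J`), or without usable expression totals are
#' `not_applicable`, with the reason in `note`.
#'
#' @param diffFlux `data.frame` from [differentialFlux()].
#' @param rxnExpr `data.frame` from [summariseReactions()].
#' @return `data.frame` with columns `reaction_id`, `delta_ln_e`,
#'   `delta_ln_j`, `rho_h`, `rho_m`, `class`
#'   (`quantified` / `purely_metabolic` / `not_applicable`) and `note`.
#' @export
mra <- function(diffFlux, rxnExpr) {
  m <- match(diffFlux$reaction_id, rxnExpr$reaction_id)
  n <- nrow(diffFlux)
  out <- data.frame(reaction_id = diffFlux$reaction_id,
                    delta_ln_e = NA_real_, delta_ln_j = NA_real_,
                    rho_h = NA_real_, rho_m = NA_real_,
                    class = "not_applicable", note = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fc <- diffFlux$class[i]
    ex <- if (!is.na(m[i])) rxnExpr[m[i], , drop = FALSE] else NULL
    exOk <- !is.null(ex) && ex$class != "no_gene" &&
      is.finite(ex$total_a) && is.finite(ex$total_b) &&
      ex$total_a > 0 && ex$total_b > 0
    dle <- if (exOk) {
      if (ex$any_significant) log(ex$total_b / ex$total_a) else 0
    } else NA_real_
    if (fc == "disappeared") {
      out$class[i] <- "purely_metabolic"
      out$rho_h[i] <- 0; out$rho_m[i] <- 1
      out$delta_ln_e[i] <- dle
      out$note[i] <- "flux vanished; metabolic shutdown"
    } else if (fc %in% c("zero_both", "reversed", "appeared")) {
      out$note[i] <- switch(fc,
        zero_both = "no flux in either condition",
        reversed = "flux direction reversed",
        appeared = "flux appeared; no finite flux ratio")
      out$delta_ln_e[i] <- dle
    } else if (fc == "constitutive") {
      out$delta_ln_e[i] <- dle
      out$delta_ln_j[i] <- log(abs(diffFlux$j_b[i]) / abs(diffFlux$j_a[i]))
      out$note[i] <- if (exOk && !is.na(dle) && dle != 0)
        "constitutive flux with changed expression (division by ~0)"
      else "flux change below tolerance"
    } else {  # up or down: quantifiable flux ratio
      dlj <- log(abs(diffFlux$j_b[i]) / abs(diffFlux$j_a[i]))
      out$delta_ln_j[i] <- dlj
      out$delta_ln_e[i] <- dle
      if (!exOk) {
        out$note[i] <- "no usable expression totals"
      } else {
        out$class[i] <- "quantified"
        out$rho_h[i] <- dle / dlj
        out$rho_m[i] <- 1 - out$rho_h[i]
      }
    }
  }
  out
}
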