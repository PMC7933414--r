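# Genotype-phenotype association statistics for dental traits.

.rootCodes <- c("1", "2", "3", "4", "m", "C")
.genotypes <- c("VV", "VA", "AA")

# Side-combination groupings defining the dichotomized root classes.
# Keys are unordered side pairs in canonical code order.
.toothGroups <- list(
  UP1 = list("1" = c("1|1"), "2<=" = c("1|2", "2|2", "2|3")),
  UP2 = list("1" = c("1|1", "1|m"), "2<=" = c("1|2", "2|2", "1|3")),
  UM2 = list("<=2" = c("1|1", "1|2", "2|2", "1|3", "2|3"),
             "3<=" = c("3|3", "4|4")),
  LM1 = list("2" = c("2|2"), "3" = c("2|3", "3|3")),
  LM2 = list("C" = c("2|C", "C|C"), "2" = c("2|2")))

#' Dichotomized class levels per tooth
#' @param tooth one of `"UP1", "UP2", "UM2", "LM1", "LM2"`
#' @return character vector of the two class labels, in table order
#' @export
toothClasses <- function(tooth) {
  if (!tooth %in% names(.toothGroups)) stop("unknown tooth: ", tooth)
  names(.toothGroups[[tooth]])
}

.comboKey <- function(left, right) {
  o <- match(c(left, right), .rootCodes)
  paste(.rootCodes[sort(o)], collapse = "|")
}

#' Dichotomize per-side root codes into a two-class phenotype
#'
#' Combines the left and right root codes of one tooth into the published
#' two-class groupings. Discordant side pairs belong to the group listing
#' that combination (the group of the less common side phenotype);
#' combinations outside the listed groups, and individuals with either side
#' absent (extraction/treatment), are missing.
#'
#' @param tooth one of `"UP1", "UP2", "UM2", "LM1", "LM2"`
#' @param left,right character vectors of side codes from
#'   `1, 2, 3, 4, m, C`, `"absent"`, or `NA`
#' @return character vector of class labels (see [toothClasses()]) with `NA`
#'   for missing
#' @examples
#' dichotomizeRoot("UP1", "1", "1")   # "1"
#' dichotomizeRoot("LM2", "2", "C")   # "C"
#' dichotomizeRoot("LM1", "2", "absent")   # NA
#' @export
dichotomizeRoot <- function(tooth, left, right) {
  if (!tooth %in% names(.toothGroups)) stop("unknown tooth: ", tooth)
  groups <- .toothGroups[[tooth]]
  lookup <- unlist(lapply(names(groups), function(g)
    setNames(rep(g, length(groups[[g]])), groups[[g]])))
  n <- max(length(left), length(right))
  left <- rep_len(as.character(left), n)
  right <- rep_len(as.character(right), n)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    l <- left[i]; r <- right[i]
    if (is.na(l) || is.na(r) || l == "absent" || r == "absent") next
    if (!l %in% .rootCodes) stop("invalid root code: '", l, "'")
    if (!r %in% .rootCodes) stop("invalid root code: '", r, "'")
    key <- .comboKey(l, r)
    if (!is.na(lookup[key])) out[i] <- lookup[[key]]
  }
  out
}

#' Genotype-by-trait contingency table for one tooth
#'
#' 3 x 2 counts of genotype (rows VV, VA, AA) against the dichotomized root
#' class of the given tooth, over individuals with a non-missing phenotype.
#'
#' @param cohort cohort data.frame with columns `genotype` and
#'   `<tooth>_L`, `<tooth>_R` (see [generateCohort()] for the schema)
#' @param tooth one of `"UP1", "UP2", "UM2", "LM1", "LM2"`
#' @return integer matrix with genotype rows and class columns
#' @export
genotypeTraitTable <- function(cohort, tooth) {
  cls <- dichotomizeRoot(tooth, cohort[[paste0(tooth, "_L")]],
                         cohort[[paste0(tooth, "_R")]])
  tab <- table(factor(cohort$genotype, levels = .genotypes),
               factor(cls, levels = toothClasses(tooth)))
  m <- matrix(as.integer(tab), nrow = 3,
              dimnames = list(genotype = .genotypes,
                              class = toothClasses(tooth)))
  m
}

# -- Freeman-Halton exact test -------------------------------------------------

#' Exact r x c contingency test (Freeman-Halton)
#'
#' Generalization of Fisher's exact test to r x c tables: enumerates every
#' table with the observed margins and sums the hypergeometric probabilities
#' of tables no more probable than the observed one (tie tolerance 1e-12 on
#' the log scale). A table with a zero row or column margin is degenerate
#' and returns P = 1.
#'
#' @param table non-negative integer matrix of counts
#' @return list with `p` (two-sided P value) and `nTables` (number of
#'   margin-preserving tables enumerated)
#' @examples
#' fisherExactRxC(matrix(c(12, 63, 80, 9, 48, 26), nrow = 3))$p
#' @export
fisherExactRxC <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    return(list(p = 1, nTables = 1L))
  logConst <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(sum(tab))
  lpObs <- logConst - sum(lfactorial(tab))

  r <- nrow(tab); cc <- ncol(tab)
  nTables <- 0L
  pSum <- 0

  # recursive enumeration, row by row; within a row, cells left to right.
  # colRem: column margins not yet consumed; acc: -sum(lfactorial(cells)) so far
  recurseRow <- function(i, colRem, acc) {
    if (i == r) {
      # last row is fully determined by the remaining column margins
      lp <- logConst + acc - sum(lfactorial(colRem))
      nTables <<- nTables + 1L
      if (lp <= lpObs + 1e-12) pSum <<- pSum + exp(lp)
      return(invisible())
    }
    fillCell <- function(j, left, colRem, acc) {
      if (j == cc) {
        # last cell of the row takes the remainder
        if (left > colRem[cc]) return(invisible())
        colRem[cc] <- colRem[cc] - left
        recurseRow(i + 1L, colRem, acc - lfactorial(left))
        return(invisible())
      }
      lo <- max(0, left - sum(colRem[(j + 1L):cc]))
      hi <- min(left, colRem[j])
      if (lo > hi) return(invisible())
      for (v in lo:hi) {
        colRem2 <- colRem
        colRem2[j] <- colRem2[j] - v
        fillCell(j + 1L, left - v, colRem2, acc - lfactorial(v))
      }
    }
    fillCell(1L, rs[i], colRem, acc)
  }
  recurseRow(1L, cs, 0)
  list(p = min(pSum, 1), nTables = nTables)
}

# -- logistic regression -------------------------------------------------------

#' Logistic regression with Wald tests
#'
#' Maximum-likelihood fit (binomial IRLS via [stats::glm()]) of a binary
#' outcome on a covariate matrix, intercept included. Wald chi-square is
#' `(coef/SE)^2` with P from the chi-square distribution on 1 df. Fits with
#' any |coefficient| > 15 are flagged as likely separation.
#'
#' @param y binary 0/1 (or logical) outcome vector
#' @param X numeric covariate matrix or data.frame (no intercept column)
#' @return list with `coefficients` (data.frame: term, logOR, se, chisq, p),
#'   `converged`, and `separation`
#' @export
logisticFit <- function(y, X) {
  y <- as.numeric(y)
  if (length(unique(y[!is.na(y)])) < 2) stop("outcome is constant")
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("y and X lengths differ")
  if (length(y) <= ncol(X) + 1) stop("more terms than observations")
  dat <- cbind(.y = y, X)
  fit <- glm(.y ~ ., data = dat, family = binomial())
  sm <- summary(fit)$coefficients
  est <- sm[, 1]; se <- sm[, 2]
  chisq <- (est / se)^2
  list(coefficients = data.frame(term = rownames(sm), logOR = est, se = se,
                                 chisq = chisq,
                                 p = pchisq(chisq, df = 1, lower.tail = FALSE),
                                 row.names = NULL),
       converged = fit$converged,
       separation = any(abs(est) > 15))
}

#' Logistic model of one root trait on genotype and covariates
#'
#' Regresses the dichotomized root class (test class = 1) on age, sex
#' (male = 0, female = 1), region (0-4) and the genotype A-allele dosage
#' (VV = 0, VA = 1, AA = 2); missing phenotypes are dropped.
#'
#' @param cohort cohort data.frame (schema of [generateCohort()])
#' @param tooth one of `"UP1", "UP2", "UM2", "LM1", "LM2"`
#' @param testClass class modelled as the outcome 1; defaults to the
#'   published test class for the tooth (UP1 "1", LM1 "3", LM2 "C",
#'   otherwise the first class)
#' @return as [logisticFit()], plus `tooth`, `testClass` and `n`
#' @export
rootTraitLogistic <- function(cohort, tooth, testClass = NULL) {
  if (is.null(testClass)) {
    testClass <- switch(tooth, UP1 = "1", LM1 = "3", LM2 = "C",
                        toothClasses(tooth)[1])
  }
  cls <- dichotomizeRoot(tooth, cohort[[paste0(tooth, "_L")]],
                         cohort[[paste0(tooth, "_R")]])
  keep <- !is.na(cls)
  y <- as.numeric(cls[keep] == testClass)
  X <- data.frame(
    age = cohort$age[keep],
    sex = as.numeric(cohort$sex[keep] == "female"),
    region = cohort$region[keep],
    genotype = match(cohort$genotype[keep], .genotypes) - 1)
  out <- logisticFit(y, X)
  out$tooth <- tooth
  out$testClass <- testClass
  out$n <- sum(keep)
  out
}

# -- Spearman rank correlation -------------------------------------------------

.tApproxP <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of mid-ranks (ties get average ranks); P value by the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 df.
#'
#' @param x,y equal-length vectors (numeric or ordered-codable) of length >= 3
#' @return list with `rho` and `p`
#' @export
spearmanRank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop("constant vector: correlation undefined")
  rho <- cor(rx, ry)
  list(rho = rho, p = .tApproxP(rho, length(x)))
}

#' Spearman rank correlation computed directly from a contingency table
#'
#' Equivalent to expanding the table to individual-level ordinal pairs and
#' calling [spearmanRank()], but computed in closed form from the counts:
#' each row/column category gets its mid-rank from the margins and the
#' correlation is the count-weighted Pearson correlation of the mid-ranks.
#'
#' @param table non-negative count matrix; row and column order define the
#'   category orderings
#' @return list with `rho`, `p` and `n`
#' @examples
#' tab <- matrix(c(12, 63, 80, 9, 48, 26), nrow = 3)
#' spearmanFromTable(tab)$rho   # genotype vs root class
#' @export
spearmanFromTable <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  if (n < 3) stop("need at least 3 individuals")
  rs <- rowSums(tab); cs <- colSums(tab)
  midrank <- function(m) cumsum(m) - m + (m + 1) / 2
  rr <- midrank(rs); rc <- midrank(cs)
  W <- tab / n
  mx <- sum(rowSums(W) * rr); my <- sum(colSums(W) * rc)
  vx <- sum(rowSums(W) * (rr - mx)^2); vy <- sum(colSums(W) * (rc - my)^2)
  if (vx == 0 || vy == 0) stop("constant margin: correlation undefined")
  cxy <- sum(W * outer(rr - mx, rc - my))
  rho <- cxy / sqrt(vx * vy)
  list(rho = rho, p = .tApproxP(rho, n), n = n)
}

#' @importFrom stats sd
NULL

#' Full association summary of a cohort
#'
#' Runs the whole association battery on a cohort: per-tooth genotype-class
#' contingency tables with exact P values, logistic fits for the teeth with
#' published effect estimates, and genotype-vs-trait Spearman correlations.
#'
#' @param cohort cohort data.frame (schema of [generateCohort()])
#' @return list with `tables` (named list of matrices), `fisher`
#'   (data.frame tooth/p/nTables), `logistic` (named list of
#'   [rootTraitLogistic()] results) and `spearman` (data.frame tooth/rho/p/n)
#' @export
associationSummary <- function(cohort) {
  teeth <- names(.toothGroups)
  tables <- lapply(teeth, function(t) genotypeTraitTable(cohort, t))
  names(tables) <- teeth
  fisher <- do.call(rbind, lapply(teeth, function(t) {
    f <- fisherExactRxC(tables[[t]])
    data.frame(tooth = t, p = f$p, nTables = f$nTables)
  }))
  spearman <- do.call(rbind, lapply(teeth, function(t) {
    s <- spearmanFromTable(tables[[t]])
    data.frame(tooth = t, rho = s$rho, p = s$p, n = s$n)
  }))
  logistic <- lapply(c("UP1", "LM1", "LM2"), function(t)
    tryCatch(rootTraitLogistic(cohort, t), error = function(e) NULL))
  names(logistic) <- c("UP1", "LM1", "LM2")
  list(tables = tables, fisher = fisher, logistic = logistic,
       spearman = spearman)
}
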