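# Synthetic cohorts with the statistical structure the association
# analyses assume, and deterministic expansion of printed tables.

.cohortColumns <- c("id", "age", "sex", "region", "genotype",
                    "UP1_L", "UP1_R", "UP2_L", "UP2_R", "UM2_L", "UM2_R",
                    "LM1_L", "LM1_R", "LM2_L", "LM2_R",
                    "UI1_shovel", "UM1_carabelli", "UM2_cusp", "LM2_cusp")

# one concordant representative side pair per class, plus the discordant
# pairs available for the class (used at the configured discordant rate)
.classCombos <- list(
  UP1 = list("1" = list(conc = c("1", "1"), disc = list()),
             "2<=" = list(conc = c("2", "2"),
                          disc = list(c("1", "2"), c("2", "3")))),
  UP2 = list("1" = list(conc = c("1", "1"), disc = list(c("1", "m"))),
             "2<=" = list(conc = c("2", "2"),
                          disc = list(c("1", "2"), c("1", "3")))),
  UM2 = list("<=2" = list(conc = c("2", "2"),
                          disc = list(c("1", "2"), c("1", "3"), c("2", "3"))),
             "3<=" = list(conc = c("3", "3"), disc = list())),
  LM1 = list("2" = list(conc = c("2", "2"), disc = list()),
             "3" = list(conc = c("3", "3"), disc = list(c("2", "3")))),
  LM2 = list("C" = list(conc = c("C", "C"), disc = list(c("2", "C"))),
             "2" = list(conc = c("2", "2"), disc = list())))

.emptyCohort <- function(n) {
  df <- data.frame(id = seq_len(n), age = rep(NA_real_, n),
                   sex = rep(NA_character_, n), region = rep(NA_integer_, n),
                   genotype = rep(NA_character_, n))
  for (col in .cohortColumns[6:15]) df[[col]] <- rep(NA_character_, n)
  for (col in .cohortColumns[16:19]) df[[col]] <- rep(NA_integer_, n)
  df
}

#' Expand a contingency table into individual-level records
#'
#' Deterministic inverse of [genotypeTraitTable()]: one record per count
#' unit, with genotype and concordant side codes set to a representative
#' combination of the class, and all other fields defaulted. Satisfies
#' `genotypeTraitTable(expandTable(tab, tooth), tooth) == tab`.
#'
#' @param table 3 x 2 count matrix (rows VV, VA, AA; columns in
#'   [toothClasses()] order)
#' @param tooth one of `"UP1", "UP2", "UM2", "LM1", "LM2"`
#' @return cohort data.frame with `sum(table)` rows
#' @examples
#' nrow(expandTable(edarRootCounts()$UP1, "UP1"))   # 238
#' @export
expandTable <- function(table, tooth) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  classes <- toothClasses(tooth)
  if (!all(dim(tab) == c(3, 2))) stop("expected a 3 x 2 genotype-by-class table")
  n <- sum(tab)
  df <- .emptyCohort(n)
  if (n == 0) return(df)
  genotype <- character(0); cls <- character(0)
  for (j in 1:2) for (i in 1:3) {
    genotype <- c(genotype, rep(.genotypes[i], tab[i, j]))
    cls <- c(cls, rep(classes[j], tab[i, j]))
  }
  df$genotype <- genotype
  df$age <- 45; df$sex <- "male"; df$region <- 0L
  sides <- t(vapply(cls, function(cl) .classCombos[[tooth]][[cl]]$conc,
                    character(2)))
  df[[paste0(tooth, "_L")]] <- sides[, 1]
  df[[paste0(tooth, "_R")]] <- sides[, 2]
  df
}

#' Generative model of the reference dental cohort
#'
#' Defaults emulate the published study design: n = 255 with genotype
#' frequencies 25/120/112 (VV/VA/AA), ages uniform on 20-69 years, 157/255
#' female, region (0-4 Ryukyu grandparents) uniform, and per-tooth logistic
#' effects equal to the published covariate-adjusted estimates for UP1, LM1
#' and LM2 (zero genotype effect for UP2 and UM2, whose associations were
#' not significant). Marginal test-class prevalences default to the observed
#' class proportions. Discordant left/right side pairs are generated at 5%,
#' matching the observed frequency of mixed two/three-rooted LM1s.
#'
#' @param n cohort size
#' @param genotypeProbs probabilities of VV, VA, AA
#' @param ageRange min and max age (years)
#' @param femaleProb probability of female sex
#' @param regionProbs probabilities of region scores 0..4
#' @param rootEffects data.frame as in [CohortModel-class]; defaults built
#'   from [edarLogisticEffects()] and [edarRootCounts()]
#' @param discordantRate probability of a discordant side pair
#' @return a [CohortModel-class]
#' @export
cohortModel <- function(n = 255,
                        genotypeProbs = c(25, 120, 112) / 257,
                        ageRange = c(20, 69),
                        femaleProb = 157 / 255,
                        regionProbs = rep(0.2, 5),
                        rootEffects = NULL,
                        discordantRate = 0.05) {
  if (is.null(rootEffects)) {
    counts <- edarRootCounts()
    eff <- edarLogisticEffects()
    prevOf <- function(tooth, test) {
      tab <- counts[[tooth]]
      sum(tab[, test]) / sum(tab)
    }
    pick <- function(tooth, term) eff$logOR[eff$tooth == tooth & eff$term == term]
    rootEffects <- do.call(rbind, lapply(
      list(c("UP1", "1"), c("UP2", "1"), c("UM2", "3<="),
           c("LM1", "3"), c("LM2", "C")),
      function(tt) {
        tooth <- tt[1]; test <- tt[2]
        known <- tooth %in% eff$tooth
        data.frame(tooth = tooth, test = test,
                   prevalence = prevOf(tooth, test),
                   betaGenotype = if (known) pick(tooth, "genotype") else 0,
                   betaAge = if (known) pick(tooth, "age") else 0,
                   betaSex = if (known) pick(tooth, "sex") else 0,
                   betaRegion = if (known) pick(tooth, "region") else 0)
      }))
  }
  new("CohortModel", n = n, genotypeProbs = genotypeProbs,
      ageRange = ageRange, femaleProb = femaleProb,
      regionProbs = regionProbs, rootEffects = rootEffects,
      discordantRate = discordantRate)
}

setMethod("show", "CohortModel", function(object) {
  cat(sprintf("CohortModel: n=%d, genotype probs %.3f/%.3f/%.3f, %d teeth\n",
              as.integer(object@n), object@genotypeProbs[1],
              object@genotypeProbs[2], object@genotypeProbs[3],
              nrow(object@rootEffects)))
})

#' Generate a synthetic cohort
#'
#' Genotypes are multinomial draws; age, sex and region follow the model's
#' covariate distributions; each tooth's dichotomized class is drawn from
#' the logistic model (the intercept is set so the marginal test-class
#' prevalence matches the model's `prevalence` under the covariate
#' distribution); side codes are synthesized consistently with the class,
#' discordant pairs at the configured rate where the class has one. Crown
#' trait grades are generated with a strong genotype effect on incisor
#' shoveling and weak or absent genotype effects elsewhere. Deterministic
#' per seed.
#'
#' @param model a [CohortModel-class]
#' @param seed integer seed
#' @return cohort data.frame (columns: id, age, sex, region, genotype,
#'   per-tooth `_L`/`_R` root codes, and crown trait grades
#'   `UI1_shovel` 0-6, `UM1_carabelli` 0-7, `UM2_cusp` 3-4, `LM2_cusp` 4-6)
#' @examples
#' cohort <- generateCohort(cohortModel(n = 255), seed = 7)
#' table(cohort$genotype)
#' @export
generateCohort <- function(model, seed) {
  validObject(model)
  set.seed(as.integer(seed))
  n <- as.integer(model@n)
  df <- .emptyCohort(n)
  df$genotype <- sample(.genotypes, n, replace = TRUE, prob = model@genotypeProbs)
  g <- match(df$genotype, .genotypes) - 1
  df$age <- as.numeric(sample(seq(model@ageRange[1], model@ageRange[2]), n,
                              replace = TRUE))
  df$sex <- ifelse(runif(n) < model@femaleProb, "female", "male")
  df$region <- sample(0:4, n, replace = TRUE, prob = model@regionProbs)
  sexNum <- as.numeric(df$sex == "female")

  # model-implied covariate means, used to centre the intercept on the
  # requested marginal prevalence
  meanG <- sum((0:2) * model@genotypeProbs)
  meanAge <- mean(model@ageRange)
  meanSex <- model@femaleProb
  meanRegion <- sum((0:4) * model@regionProbs)

  for (k in seq_len(nrow(model@rootEffects))) {
    e <- model@rootEffects[k, ]
    tooth <- e$tooth
    b0 <- qlogis(e$prevalence) -
      (e$betaGenotype * meanG + e$betaAge * meanAge +
         e$betaSex * meanSex + e$betaRegion * meanRegion)
    p <- plogis(b0 + e$betaGenotype * g + e$betaAge * df$age +
                  e$betaSex * sexNum + e$betaRegion * df$region)
    isTest <- runif(n) < p
    classes <- toothClasses(tooth)
    cls <- ifelse(isTest, e$test, setdiff(classes, e$test))
    sides <- matrix(NA_character_, n, 2)
    useDisc <- runif(n) < model@discordantRate
    swap <- runif(n) < 0.5
    for (i in seq_len(n)) {
      combos <- .classCombos[[tooth]][[cls[i]]]
      pair <- if (useDisc[i] && length(combos$disc))
        combos$disc[[sample.int(length(combos$disc), 1)]] else combos$conc
      if (swap[i]) pair <- rev(pair)
      sides[i, ] <- pair
    }
    df[[paste0(tooth, "_L")]] <- sides[, 1]
    df[[paste0(tooth, "_R")]] <- sides[, 2]
  }

  # crown traits: shoveling strongly genotype-dependent; the rest weak/none
  df$UI1_shovel <- pmin(6L, pmax(0L, as.integer(round(
    1.0 + 1.1 * g + rnorm(n, 0, 1.2)))))
  df$UM1_carabelli <- pmin(7L, pmax(0L, as.integer(round(rnorm(n, 2, 1.6)))))
  df$UM2_cusp <- 3L + rbinom(n, 1L, 0.85)
  df$LM2_cusp <- 4L + rbinom(n, 2L, 0.25)
  df
}
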