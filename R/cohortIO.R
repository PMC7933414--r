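# Typed CSV I/O for cohort tables.

#' Write a cohort to CSV
#' @param cohort cohort data.frame (schema of [generateCohort()])
#' @param path output file
#' @return `path`, invisibly
#' @export
writeCohortCSV <- function(cohort, path) {
  missing <- setdiff(.cohortColumns, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  write.csv(cohort[, .cohortColumns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Enforces the fixed schema (same columns as [generateCohort()] output) and
#' validates every field, naming the offending row and column on failure.
#' Empty root-code fields become `NA` (phenotype unobserved); the literal
#' code `"absent"` marks a tooth lost to extraction or treatment.
#'
#' @param path CSV file
#' @return typed cohort data.frame
#' @export
readCohortCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, colClasses = "character")
  if (!identical(names(df), .cohortColumns))
    stop("header mismatch: expected columns ",
         paste(.cohortColumns, collapse = ", "))
  fail <- function(row, col, msg)
    stop("row ", row, ", column ", col, ": ", msg, call. = FALSE)
  n <- nrow(df)
  if (n == 0) return(.emptyCohort(0))

  out <- df
  out$id <- as.integer(df$id)
  out$age <- suppressWarnings(as.numeric(df$age))
  for (i in seq_len(n)) {
    if (is.na(out$age[i]) || out$age[i] < 0) fail(i, "age", "must be a non-negative number")
    if (!df$sex[i] %in% c("male", "female")) fail(i, "sex", paste0("invalid sex '", df$sex[i], "'"))
    if (!df$region[i] %in% as.character(0:4)) fail(i, "region", paste0("invalid region '", df$region[i], "'"))
    if (!df$genotype[i] %in% .genotypes) fail(i, "genotype", paste0("invalid genotype '", df$genotype[i], "'"))
  }
  out$region <- as.integer(df$region)
  rootCols <- .cohortColumns[6:15]
  okCodes <- c(.rootCodes, "absent")
  for (col in rootCols) {
    v <- df[[col]]
    v[v == ""] <- NA_character_
    bad <- which(!is.na(v) & !v %in% okCodes)
    if (length(bad))
      fail(bad[1], col, paste0("invalid root code '", v[bad[1]], "'"))
    out[[col]] <- v
  }
  for (col in .cohortColumns[16:19]) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
    if (length(bad))
      fail(bad[1], col, paste0("invalid grade '", df[[col]][bad[1]], "'"))
    out[[col]] <- v
  }
  out
}
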