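#' @title Cohorts of product records
#' @description
#' Score-level product records: product identity, normative group (N327,
#' products with temporary trade permits in Brazilian pharmacies; N660,
#' imported products), pharmaceutical presentation, and the preliminary and
#' final labeling-quality scores. The package ships the published table of
#' the 105 evaluated products as `table1.csv`; see the accompanying
#' `table1-NOTES.md` for documented inconsistencies of the printed table.
#' @name fixtures-io
NULL

cohort_columns <- function() {
  c("product_name", "manufacturer", "normative", "product_type",
    "preliminary_score", "final_score")
}

normative_groups <- function() c("N327", "N660")

product_types <- function() c("oil", "capsule", "extract", "tincture", "spray")

#' Construct and validate a cohort of product records
#'
#' @param records A data.frame with columns `product_name`, `manufacturer`,
#'   `normative` (`"N327"` or `"N660"`), `product_type` (`oil`, `capsule`,
#'   `extract`, `tincture` or `spray`), `preliminary_score`, `final_score`.
#' @param provenance Free-text description of where the records come from.
#'
#' @return An object of class `cbd_cohort` (a validated data.frame with a
#'   `provenance` attribute). Validation enforces: unique product names;
#'   non-negative integer scores; `final_score >= preliminary_score` for
#'   every row (the follow-up can only add information). Violations raise
#'   row-addressed errors.
#' @export
cohort <- function(records, provenance = "user") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(cohort_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records[cohort_columns()],
                           stringsAsFactors = FALSE)
  rownames(records) <- NULL
  row_err <- function(rows, what) {
    stop(what, " at row(s): ", paste(rows, collapse = ", "), call. = FALSE)
  }
  bad <- which(!records$normative %in% normative_groups())
  if (length(bad) > 0) row_err(bad, "unknown normative value")
  bad <- which(!records$product_type %in% product_types())
  if (length(bad) > 0) row_err(bad, "unknown product_type value")
  for (col in c("preliminary_score", "final_score")) {
    v <- records[[col]]
    bad <- which(is.na(v) | !is.numeric(v) | v < 0 | v != round(v))
    if (length(bad) > 0) row_err(bad, paste(col, "not a non-negative integer"))
    records[[col]] <- as.integer(v)
  }
  bad <- which(records$final_score < records$preliminary_score)
  if (length(bad) > 0) {
    row_err(bad, "final_score below preliminary_score")
  }
  dup <- which(duplicated(records$product_name))
  if (length(dup) > 0) row_err(dup, "duplicated product_name")
  structure(records, provenance = as.character(provenance)[1],
            class = c("cbd_cohort", "data.frame"))
}

#' Load a cohort from CSV
#'
#' Expected dialect: UTF-8, comma-separated, quoted fields where needed,
#' mandatory header `product_name,manufacturer,normative,product_type,`
#' `preliminary_score,final_score`.
#'
#' @param path CSV file path.
#' @param provenance Provenance string recorded on the cohort (defaults to
#'   the path).
#'
#' @return A validated [cohort()].
#' @export
load_cohort <- function(path, provenance = path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  records <- utils::read.csv(path, check.names = FALSE,
                             fileEncoding = "UTF-8",
                             stringsAsFactors = FALSE)
  cohort(records, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' `load_cohort(write_cohort(x, path))` reproduces `x` record for record.
#'
#' @param x A [cohort()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cbd_cohort"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' The packaged table of the 105 evaluated products
#'
#' Loads the shipped transcription of the published product table
#' (descending by final score). Documented inconsistencies of the printed
#' source are listed in `system.file("extdata", "table1-NOTES.md",
#' package = "cbdscore")`.
#'
#' @return A validated [cohort()] of 105 records.
#' @export
table1_cohort <- function() {
  load_cohort(system.file("extdata", "table1.csv", package = "cbdscore",
                          mustWork = TRUE),
              provenance = "packaged table1.csv (published product table)")
}

#' @export
print.cbd_cohort <- function(x, ...) {
  tab <- table(factor(x$normative, levels = normative_groups()))
  cat(sprintf("<cbd_cohort> %d products (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat("  provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

#' Tally classification bands in a cohort
#'
#' @param x A [cohort()].
#' @param stage `"final"` (default) or `"preliminary"`: which score column
#'   to classify.
#'
#' @return Named integer vector over the three bands (ascending quality
#'   order); counts always sum to the cohort size.
#' @export
#' @examples
#' count_band(table1_cohort(), "final")
count_band <- function(x, stage = c("final", "preliminary")) {
  stopifnot(inherits(x, "cbd_cohort"))
  stage <- match.arg(stage)
  if (nrow(x) == 0) stop("empty cohort", call. = FALSE)
  scores <- x[[paste0(stage, "_score")]]
  tab <- table(factor(classify(scores), levels = score_bands()))
  stats::setNames(as.integer(tab), score_bands())
}

#' Count products whose score increased at follow-up
#'
#' @param x A [cohort()].
#' @return Number of records with `final_score > preliminary_score`.
#' @export
count_score_increases <- function(x) {
  stopifnot(inherits(x, "cbd_cohort"))
  sum(x$final_score > x$preliminary_score)
}
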