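#' @title Analysis pipeline
#' @description
#' Orchestrates the full labeling-quality analysis over a cohort: band
#' counts, per-band summaries, per-normative-group summaries and
#' Mann-Whitney comparisons (overall, and per domain when criterion-level
#' data are available), and follow-up accounting. Per-domain statistics
#' are computed only from criterion-level data; they are never fabricated
#' from a score-level table.
#' @name pipeline
NULL

summary_as_list <- function(s) {
  list(n = s$n, median = s$median, p25 = s$p25, p75 = s$p75)
}

test_as_list <- function(t) {
  list(u_statistic = t$u_statistic, method = t$method,
       p_two_sided = t$p_two_sided, n1 = t$n1, n2 = t$n2,
       tie_correction_applied = t$tie_correction_applied,
       degenerate = t$degenerate)
}

#' Run the full labeling-quality analysis
#'
#' @param cohort A [cohort()] of score-level product records.
#' @param criterion_data Optional criterion-level data, as produced by
#'   [generate_cohort()]: a list with fulfillment matrices `initial` and
#'   `post_followup` (and optionally `events`). When present, per-domain
#'   group summaries and tests are computed from the post-follow-up
#'   matrix; `rubric` is then required.
#' @param rubric A [rubric()]; required with `criterion_data`.
#' @param quantile_type Quantile convention for IQR endpoints (see
#'   [median_iqr()]).
#' @param test_mode Mann-Whitney mode (see [mann_whitney_u()]).
#' @param alpha Two-tailed significance level, fixed at 0.05 by
#'   convention.
#'
#' @return An object of class `cbd_report`: a named list with `n`,
#'   `band_counts` (final stage), `band_counts_preliminary`,
#'   `band_summaries`, `group_summaries`, `group_tests` (overall on final
#'   scores; per-domain only with criterion-level data, otherwise marked
#'   unavailable), `followup` (`responses` is `NA` unless an event log is
#'   supplied; `upgrades` counts final > preliminary) and `config`.
#'   Deterministic given inputs and configuration.
#' @export
#' @examples
#' rep <- run_analysis(table1_cohort())
#' rep$band_counts
run_analysis <- function(cohort, criterion_data = NULL, rubric = NULL,
                         quantile_type = 7,
                         test_mode = c("auto", "exact", "normal_approx"),
                         alpha = 0.05) {
  test_mode <- match.arg(test_mode)
  stopifnot(inherits(cohort, "cbd_cohort"))
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  if (!is.null(criterion_data) && is.null(rubric)) {
    stop("`rubric` is required with criterion-level data", call. = FALSE)
  }

  final <- cohort$final_score
  bands <- classify(final)

  band_counts <- count_band(cohort, "final")
  band_counts_preliminary <- count_band(cohort, "preliminary")

  band_summaries <- lapply(stats::setNames(nm = score_bands()), function(b) {
    v <- final[bands == b]
    if (length(v) == 0) NULL else
      summary_as_list(median_iqr(v, type = quantile_type))
  })

  groups <- sort(unique(cohort$normative))
  group_summaries <- lapply(stats::setNames(nm = groups), function(g) {
    list(total = summary_as_list(
      median_iqr(final[cohort$normative == g], type = quantile_type)))
  })

  group_tests <- list()
  diagnostics <- character(0)
  if (length(groups) == 2) {
    x <- final[cohort$normative == groups[1]]
    y <- final[cohort$normative == groups[2]]
    group_tests$overall <- test_as_list(
      mann_whitney_u(x, y, mode = test_mode))
  } else {
    group_tests$overall <- NULL
    diagnostics <- c(diagnostics, sprintf(
      "group tests skipped: %d normative group(s) present", length(groups)))
  }

  domain_available <- !is.null(criterion_data)
  if (domain_available) {
    post <- criterion_data$post_followup
    dom_scores <- score_matrix(post, rubric, stage = "post_followup")
    # align to the cohort's rows by product name
    idx <- match(cohort$product_name, dom_scores$product_id)
    if (anyNA(idx)) {
      stop("criterion-level data do not cover every cohort product",
           call. = FALSE)
    }
    dom_scores <- dom_scores[idx, ]
    for (g in groups) {
      for (d in rubric_domains()) {
        group_summaries[[g]][[d]] <- summary_as_list(median_iqr(
          dom_scores[[d]][cohort$normative == g], type = quantile_type))
      }
    }
    if (length(groups) == 2) {
      for (d in rubric_domains()) {
        x <- dom_scores[[d]][cohort$normative == groups[1]]
        y <- dom_scores[[d]][cohort$normative == groups[2]]
        group_tests[[d]] <- test_as_list(mann_whitney_u(x, y, mode = test_mode))
      }
    }
  }

  responses <- NA_integer_
  ev <- criterion_data$events
  if (!is.null(ev)) {
    cases <- replay_followup_log(ev)
    responses <- sum(vapply(cases, function(cs)
      cs$state == "closed_with_response", logical(1)))
  }

  structure(list(
    n = nrow(cohort),
    band_counts = as.list(band_counts),
    band_counts_preliminary = as.list(band_counts_preliminary),
    band_summaries = band_summaries,
    group_summaries = group_summaries,
    group_tests = group_tests,
    domain_tests_available = domain_available,
    followup = list(responses = responses,
                    upgrades = count_score_increases(cohort)),
    diagnostics = diagnostics,
    config = list(quantile_type = quantile_type, test_mode = test_mode,
                  alpha = alpha, provenance = attr(cohort, "provenance"))
  ), class = "cbd_report")
}

#' @export
print.cbd_report <- function(x, ...) {
  cat(sprintf("<cbd_report> %d products\n", x$n))
  cat("  bands (final): ",
      paste(sprintf("%s=%d", names(x$band_counts),
                    unlist(x$band_counts)), collapse = ", "), "\n")
  if (!is.null(x$group_tests$overall)) {
    cat(sprintf("  overall group test: U = %g, p = %.4g (%s)\n",
                x$group_tests$overall$u_statistic,
                x$group_tests$overall$p_two_sided,
                x$group_tests$overall$method))
  }
  cat(sprintf("  follow-up: %s responses, %d score increases\n",
              ifelse(is.na(x$followup$responses), "?",
                     x$followup$responses), x$followup$upgrades))
  invisible(x)
}

report_tables <- function(report) {
  counts <- data.frame(band = names(report$band_counts),
                       final = unlist(report$band_counts),
                       preliminary = unlist(report$band_counts_preliminary),
                       row.names = NULL)
  summ_rows <- list()
  for (b in names(report$band_summaries)) {
    s <- report$band_summaries[[b]]
    if (!is.null(s)) {
      summ_rows[[length(summ_rows) + 1]] <-
        data.frame(scope = "band", group = b, domain = "total",
                   n = s$n, median = s$median, p25 = s$p25, p75 = s$p75)
    }
  }
  for (g in names(report$group_summaries)) {
    for (d in names(report$group_summaries[[g]])) {
      s <- report$group_summaries[[g]][[d]]
      summ_rows[[length(summ_rows) + 1]] <-
        data.frame(scope = "group", group = g, domain = d,
                   n = s$n, median = s$median, p25 = s$p25, p75 = s$p75)
    }
  }
  summaries <- do.call(rbind, summ_rows)
  test_rows <- lapply(names(report$group_tests), function(k) {
    t <- report$group_tests[[k]]
    data.frame(comparison = k, u_statistic = t$u_statistic,
               method = t$method, p_two_sided = t$p_two_sided,
               n1 = t$n1, n2 = t$n2)
  })
  tests <- if (length(test_rows) > 0) do.call(rbind, test_rows) else
    data.frame(comparison = character(0), u_statistic = numeric(0),
               method = character(0), p_two_sided = numeric(0),
               n1 = integer(0), n2 = integer(0))
  list(band_counts = counts, summaries = summaries, tests = tests)
}

md_table <- function(df) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = 4, format = "g") else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Render an analysis report
#'
#' @param report A `cbd_report` from [run_analysis()].
#' @param format `"json"` (lossless round-trippable document), `"csv"`
#'   (one table per results element, written to `path`, which must be a
#'   directory) or `"markdown"` (human-readable tables: band counts,
#'   summaries, group comparisons).
#' @param path Output file (json/markdown) or directory (csv); when NULL
#'   the rendered text is returned instead of written (json/markdown
#'   only).
#'
#' @return The rendered text, or (for csv) the vector of files written.
#' @export
render_report <- function(report, format = c("json", "csv", "markdown"),
                          path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(report, "cbd_report"))
  if (format == "json") {
    txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                            null = "null", pretty = 2)
    if (!is.null(path)) {
      writeLines(txt, path, useBytes = TRUE)
      return(invisible(path))
    }
    return(as.character(txt))
  }
  if (format == "csv") {
    if (is.null(path)) stop("`path` (a directory) is required for csv",
                            call. = FALSE)
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    tabs <- report_tables(report)
    files <- character(0)
    for (nm in names(tabs)) {
      f <- file.path(path, paste0(nm, ".csv"))
      utils::write.csv(tabs[[nm]], f, row.names = FALSE,
                       fileEncoding = "UTF-8")
      files <- c(files, f)
    }
    return(invisible(files))
  }
  # markdown
  tabs <- report_tables(report)
  parts <- c(
    sprintf("# Labeling-quality analysis report (%d products)", report$n),
    "", "## Classification bands", "", md_table(tabs$band_counts),
    "", "## Median (IQR) summaries", "", md_table(tabs$summaries),
    "", "## Group comparisons (Mann-Whitney U, two-tailed)", "",
    if (nrow(tabs$tests) > 0) md_table(tabs$tests) else
      "_Group tests unavailable (fewer than two normative groups)._",
    "", "## Follow-up", "",
    sprintf("- responses: %s",
            ifelse(is.na(report$followup$responses), "not recorded",
                   report$followup$responses)),
    sprintf("- score increases: %d", report$followup$upgrades),
    "",
    sprintf("_Config: quantile type %d, test mode %s, alpha %.2f._",
            report$config$quantile_type, report$config$test_mode,
            report$config$alpha))
  txt <- paste(parts, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(path))
  }
  txt
}
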