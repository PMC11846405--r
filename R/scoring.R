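#' @title Scoring engine
#' @description Score binary criterion-fulfillment records against a rubric
#'   and classify totals into the three satisfaction bands.
#' @name scoring-engine
NULL

#' Band labels in ascending order of quality
#' @return Character vector of the three classification bands.
#' @export
score_bands <- function() {
  c("not_very_satisfactory", "satisfactory", "very_satisfactory")
}

#' Construct a fulfillment vector
#'
#' A fulfillment vector records, for one product at one evaluation stage,
#' whether each rubric criterion is met (the required information is
#' publicly available) or unmet. Status is strictly binary: the instrument
#' scores availability of information, with no partial credit.
#'
#' @param product_id Product identifier (length-one character).
#' @param status Named logical vector, one element per rubric criterion id
#'   (TRUE = met). Names must match the rubric's criterion ids exactly when
#'   a rubric is supplied.
#' @param stage `"initial"` (before the e-mail follow-up) or
#'   `"post_followup"`.
#' @param rubric Optional [rubric()]; when given, status names are checked
#'   against (and reordered to) the rubric's criterion order.
#'
#' @return An object of class `cbd_fulfillment`.
#' @export
fulfillment <- function(product_id, status, stage = c("initial", "post_followup"),
                        rubric = NULL) {
  stage <- match.arg(stage)
  if (!is.logical(status) || is.null(names(status)) || anyNA(status)) {
    stop("`status` must be a complete named logical vector", call. = FALSE)
  }
  if (anyDuplicated(names(status))) {
    stop("duplicated criterion ids in `status`", call. = FALSE)
  }
  if (!is.null(rubric)) {
    stopifnot(inherits(rubric, "cbd_rubric"))
    ids <- rubric$criteria$id
    missing_ids <- setdiff(ids, names(status))
    extra_ids <- setdiff(names(status), ids)
    if (length(missing_ids) > 0 || length(extra_ids) > 0) {
      stop("fulfillment status does not cover the rubric exactly",
           if (length(missing_ids) > 0)
             paste0("; missing: ", paste(missing_ids, collapse = ", ")),
           if (length(extra_ids) > 0)
             paste0("; extraneous: ", paste(extra_ids, collapse = ", ")),
           call. = FALSE)
    }
    status <- status[ids]
  }
  structure(list(product_id = as.character(product_id)[1], stage = stage,
                 status = status),
            class = "cbd_fulfillment")
}

#' @export
print.cbd_fulfillment <- function(x, ...) {
  cat(sprintf("<cbd_fulfillment> %s [%s]: %d/%d criteria met\n",
              x$product_id, x$stage, sum(x$status), length(x$status)))
  invisible(x)
}

#' Classify a total score into a satisfaction band
#'
#' Bands are closed integer ranges on the raw point scale, never rescaled
#' to the rubric maximum: 0-24 not very satisfactory, 25-49 satisfactory,
#' 50 points or more very satisfactory.
#'
#' @param total Vector of non-negative integer total scores.
#'
#' @return Character vector of band labels (see [score_bands()]).
#' @export
#' @examples
#' classify(c(0, 24, 25, 49, 50, 68))
classify <- function(total) {
  if (length(total) == 0) {
    return(character(0))
  }
  if (!is.numeric(total) || anyNA(total) || any(total < 0) ||
      any(total != round(total))) {
    stop("`total` must be non-negative integer score(s)", call. = FALSE)
  }
  ifelse(total >= 50, "very_satisfactory",
         ifelse(total >= 25, "satisfactory", "not_very_satisfactory"))
}

#' Score one product against a rubric
#'
#' The total is the sum of the weights of the met criteria; per-domain
#' sub-scores are the same sum restricted to each domain, so they always
#' add up to the total.
#'
#' @param fulfillment A [fulfillment()] vector.
#' @param rubric A [rubric()] object; the fulfillment must cover exactly
#'   the rubric's criterion ids.
#'
#' @return An object of class `cbd_score`: list with `product_id`, `stage`,
#'   `total`, `by_domain` (named integer vector over the four domains) and
#'   `band`.
#' @export
score_product <- function(fulfillment, rubric) {
  stopifnot(inherits(fulfillment, "cbd_fulfillment"),
            inherits(rubric, "cbd_rubric"))
  # re-validate coverage against this rubric (the vector may have been built
  # against another instrument)
  fulfillment <- fulfillment(fulfillment$product_id, fulfillment$status,
                             stage = fulfillment$stage, rubric = rubric)
  met <- fulfillment$status
  w <- rubric$criteria$weight
  dom <- rubric$criteria$domain
  by_domain <- vapply(rubric_domains(), function(d) {
    sum(w[met & dom == d])
  }, numeric(1))
  total <- as.integer(sum(by_domain))
  structure(list(product_id = fulfillment$product_id,
                 stage = fulfillment$stage,
                 total = total,
                 by_domain = as.integer(by_domain) |>
                   stats::setNames(rubric_domains()),
                 band = classify(total)),
            class = "cbd_score")
}

#' @export
print.cbd_score <- function(x, ...) {
  cat(sprintf("<cbd_score> %s [%s]: total %d (%s)\n", x$product_id, x$stage,
              x$total, x$band))
  cat("  ", paste(sprintf("%s=%d", names(x$by_domain), x$by_domain),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Score a fulfillment matrix
#'
#' @param mat A fulfillment matrix as returned by [read_fulfillment_csv()]:
#'   a data.frame with a `product_id` column and one 0/1 column per rubric
#'   criterion id.
#' @param rubric A [rubric()] object.
#' @param stage Evaluation stage recorded in the result.
#'
#' @return A data.frame with one row per product: `product_id`, `total`,
#'   one column per domain, and `band`.
#' @export
score_matrix <- function(mat, rubric, stage = c("initial", "post_followup")) {
  stage <- match.arg(stage)
  stopifnot(is.data.frame(mat), inherits(rubric, "cbd_rubric"))
  if (!"product_id" %in% names(mat)) {
    stop("fulfillment matrix lacks a `product_id` column", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    fv <- fulfillment_from_row(mat[i, , drop = FALSE], rubric, stage = stage)
    sc <- score_product(fv, rubric)
    c(list(product_id = sc$product_id, total = sc$total),
      as.list(sc$by_domain), list(band = sc$band))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

fulfillment_from_row <- function(row, rubric, stage = "initial") {
  ids <- setdiff(names(row), "product_id")
  vals <- as.numeric(row[1, ids])
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    stop("fulfillment cells must be 0 or 1 (product ",
         row$product_id[1], ")", call. = FALSE)
  }
  fulfillment(row$product_id[1], stats::setNames(vals == 1, ids),
              stage = stage, rubric = rubric)
}

#' Read / write fulfillment matrices as CSV
#'
#' The on-disk format is UTF-8 comma-separated text with a mandatory header
#' row: a `product_id` column followed by one column per criterion id,
#' cells 0 (unmet) or 1 (met).
#'
#' @param path CSV file path.
#' @param rubric Optional [rubric()]; when supplied the columns are checked
#'   against its criterion ids.
#'
#' @return `read_fulfillment_csv()`: the fulfillment matrix data.frame.
#' @export
read_fulfillment_csv <- function(path, rubric = NULL) {
  mat <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"product_id" %in% names(mat)) {
    stop("fulfillment CSV lacks a `product_id` header column", call. = FALSE)
  }
  if (!is.null(rubric)) {
    ids <- rubric$criteria$id
    have <- setdiff(names(mat), "product_id")
    if (!setequal(have, ids)) {
      stop("fulfillment CSV columns do not match the rubric's criterion ids",
           call. = FALSE)
    }
    mat <- mat[c("product_id", ids)]
  }
  mat
}

#' @param mat Fulfillment matrix data.frame (see [read_fulfillment_csv()]).
#' @rdname read_fulfillment_csv
#' @return `write_fulfillment_csv()`: the path, invisibly.
#' @export
write_fulfillment_csv <- function(mat, path) {
  utils::write.csv(mat, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}
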