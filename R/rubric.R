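#' @title Rubric: the weighted scoring instrument
#' @description
#' A rubric is an ordered collection of binary quality criteria, each with a
#' short unique id, a human-readable label, one of four domains
#' (`prescription`, `gmp`, `safety_of_use`, `laboratory_testing`) and an
#' integer weight in \{1, 2, 3\}. A product's score is the sum of the weights
#' of the criteria it meets, so the rubric fully determines the achievable
#' score range and the per-domain maxima.
#' @name rubric-model
NULL

#' The four scoring domains
#'
#' Domain names in canonical order: items essential for prescription and
#' clinical indication; good manufacturing practices; safety of use
#' (leaflet-type information); and laboratory testing (certificate of
#' analysis items).
#'
#' @return Character vector of the four domain names.
#' @export
rubric_domains <- function() {
  c("prescription", "gmp", "safety_of_use", "laboratory_testing")
}

#' Construct and validate a rubric
#'
#' @param criteria A data.frame with columns `id`, `label`, `domain`,
#'   `weight` (one row per criterion, in scoring order).
#' @param name Instrument name.
#' @param version Instrument version string.
#'
#' @return An object of class `cbd_rubric`: a list with elements `name`,
#'   `version` and `criteria` (the validated data.frame).
#' @export
#' @examples
#' r <- rubric(data.frame(id = c("a", "b"), label = c("A", "B"),
#'                        domain = "prescription", weight = c(3, 1)))
#' max_scores(r)$max_total
rubric <- function(criteria, name = "unnamed", version = "0") {
  if (!is.data.frame(criteria)) {
    stop("`criteria` must be a data.frame", call. = FALSE)
  }
  needed <- c("id", "label", "domain", "weight")
  missing_cols <- setdiff(needed, names(criteria))
  if (length(missing_cols) > 0) {
    stop("rubric criteria lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  criteria <- as.data.frame(criteria[needed], stringsAsFactors = FALSE)
  criteria$id <- as.character(criteria$id)
  criteria$label <- as.character(criteria$label)
  criteria$domain <- as.character(criteria$domain)
  if (nrow(criteria) == 0) {
    stop("rubric must contain at least one criterion", call. = FALSE)
  }
  dup <- unique(criteria$id[duplicated(criteria$id)])
  if (length(dup) > 0) {
    stop("duplicate criterion id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_dom <- unique(criteria$id[!criteria$domain %in% rubric_domains()])
  if (length(bad_dom) > 0) {
    stop("unknown domain for criterion(s): ",
         paste(bad_dom, collapse = ", "),
         " (allowed: ", paste(rubric_domains(), collapse = ", "), ")",
         call. = FALSE)
  }
  w <- criteria$weight
  bad_w <- unique(criteria$id[!(is.numeric(w) & !is.na(w) & w == round(w) &
                                  w %in% c(1, 2, 3))])
  if (length(bad_w) > 0) {
    stop("weight outside {1,2,3} for criterion(s): ",
         paste(bad_w, collapse = ", "), call. = FALSE)
  }
  criteria$weight <- as.integer(criteria$weight)
  rownames(criteria) <- NULL
  structure(
    list(name = as.character(name)[1], version = as.character(version)[1],
         criteria = criteria),
    class = "cbd_rubric"
  )
}

#' Load a rubric from its JSON definition
#'
#' The rubric file format is a small JSON dialect:
#' `{"name": ..., "version": ..., "criteria": [{"id", "label", "domain",
#' "weight"}, ...]}`. Unknown top-level fields (e.g. `notes`) are ignored.
#'
#' @param source Path to a rubric JSON file, or a length-one character
#'   string holding JSON text.
#'
#' @return A validated [rubric()] object.
#' @export
#' @examples
#' r <- load_rubric(system.file("extdata", "default_rubric.json",
#'                              package = "cbdscore"))
#' nrow(r$criteria)
load_rubric <- function(source) {
  if (!is.character(source) || length(source) != 1) {
    stop("`source` must be a file path or a JSON string", call. = FALSE)
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(source, simplifyDataFrame = TRUE),
    error = function(e) stop("rubric definition does not parse as JSON: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(parsed$criteria)) {
    stop("rubric definition has no `criteria` field", call. = FALSE)
  }
  rubric(parsed$criteria,
         name = if (is.null(parsed$name)) "unnamed" else parsed$name,
         version = if (is.null(parsed$version)) "0" else parsed$version)
}

#' The packaged default rubric
#'
#' A synthetic placeholder instrument with the published shape of the
#' labeling-quality score: 45 binary criteria across the four domains with
#' weights 1-3. The true criterion texts and their exact weight/domain
#' allocation are not published, so the shipped items are invented but
#' field-plausible; per-domain maxima are prescription 25, gmp 8,
#' safety_of_use 37, laboratory_testing 12 (maximum total 82). Replace with
#' a user-supplied rubric for any real evaluation.
#'
#' @return A validated [rubric()] object with 45 criteria.
#' @export
default_rubric <- function() {
  load_rubric(system.file("extdata", "default_rubric.json",
                          package = "cbdscore", mustWork = TRUE))
}

#' Serialize a rubric to canonical JSON
#'
#' Output is byte-stable for a fixed rubric (fixed field order, two-space
#' indentation, trailing newline), so serialized rubrics can be diffed and
#' versioned. `load_rubric(serialize_rubric(r))` reproduces `r`.
#'
#' @param rubric A [rubric()] object.
#' @param path Optional file path; when given the JSON is written there
#'   (UTF-8) and the path is returned invisibly.
#'
#' @return JSON text (length-one character), or the path invisibly.
#' @export
serialize_rubric <- function(rubric, path = NULL) {
  stopifnot(inherits(rubric, "cbd_rubric"))
  obj <- list(name = rubric$name, version = rubric$version,
              criteria = rubric$criteria)
  txt <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                          pretty = 2)
  txt <- paste0(txt, "\n")
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path, useBytes = TRUE, sep = "")
  invisible(path)
}

#' Maximum achievable scores of a rubric
#'
#' @param rubric A [rubric()] object.
#'
#' @return A list with `max_total` (sum of all weights) and `max_domain`
#'   (named integer vector over the four domains; domains with no criteria
#'   have maximum 0). The per-domain maxima always sum to `max_total`.
#' @export
max_scores <- function(rubric) {
  stopifnot(inherits(rubric, "cbd_rubric"))
  by_dom <- vapply(rubric_domains(), function(d) {
    sum(rubric$criteria$weight[rubric$criteria$domain == d])
  }, integer(1))
  list(max_total = sum(rubric$criteria$weight), max_domain = by_dom)
}

#' @export
print.cbd_rubric <- function(x, ...) {
  ms <- max_scores(x)
  cat(sprintf("<cbd_rubric> %s (version %s): %d criteria, max total %d\n",
              x$name, x$version, nrow(x$criteria), ms$max_total))
  tab <- table(factor(x$criteria$domain, levels = rubric_domains()))
  for (d in rubric_domains()) {
    cat(sprintf("  %-18s %2d criteria, max %2d\n", d, tab[[d]],
                ms$max_domain[[d]]))
  }
  invisible(x)
}
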