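#' @title Synthetic criterion-level cohorts
#' @description
#' The criterion-level evaluations behind the published score table are
#' unpublished, so the package can generate synthetic stand-ins with the
#' statistical structure the analysis assumes: binary fulfillment vectors
#' whose weighted sums hit prescribed totals exactly. Vectors are drawn
#' uniformly over the subset-sum solutions for a target via dynamic
#' programming on achievable partial sums followed by backward sampling
#' proportional to solution counts (rejection sampling would be
#' exponentially slow for extreme targets). Criteria are independent given
#' the total; real criterion correlations are not modeled.
#' @name synthetic-data
NULL

# counts[i, s+1] = number of subsets of weights[i..n] summing to s,
# i ranging over 1..n+1 (row n+1 is the empty suffix). Counts are exact in
# doubles (bounded by 2^n < 2^53 for n <= 52).
subset_sum_counts <- function(weights) {
  n <- length(weights)
  s_max <- sum(weights)
  counts <- matrix(0, nrow = n + 1, ncol = s_max + 1)
  counts[n + 1, 1] <- 1
  if (n >= 1) {
    for (i in n:1) {
      w <- weights[i]
      counts[i, ] <- counts[i + 1, ]
      counts[i, (w + 1):(s_max + 1)] <-
        counts[i, (w + 1):(s_max + 1)] + counts[i + 1, 1:(s_max + 1 - w)]
    }
  }
  counts
}

#' Achievable total scores of a rubric
#'
#' The achievable totals are exactly the subset sums of the rubric's
#' weight multiset.
#'
#' @param rubric A [rubric()] object.
#' @return Sorted integer vector of all achievable totals (always
#'   including 0 and the rubric maximum).
#' @export
achievable_totals <- function(rubric) {
  stopifnot(inherits(rubric, "cbd_rubric"))
  counts <- subset_sum_counts(rubric$criteria$weight)
  which(counts[1, ] > 0) - 1L
}

# round to the nearest achievable total, ties toward the lower total
nearest_achievable <- function(x, achievable) {
  vapply(x, function(v) {
    d <- abs(achievable - v)
    cand <- achievable[d == min(d)]
    as.integer(min(cand))
  }, integer(1))
}

# uniform draw over subsets of `weights` summing to `target`; returns a
# logical inclusion vector. `counts` is the suffix-count table.
sample_subset_for_sum <- function(weights, target, counts = NULL) {
  n <- length(weights)
  if (is.null(counts)) counts <- subset_sum_counts(weights)
  take <- logical(n)
  t <- target
  for (i in seq_len(n)) {
    w <- weights[i]
    c_incl <- if (t >= w) counts[i + 1, t - w + 1] else 0
    c_excl <- counts[i + 1, t + 1]
    if (c_incl + c_excl <= 0) stop("internal: dead end in backward sampling")
    if (stats::runif(1) < c_incl / (c_incl + c_excl)) {
      take[i] <- TRUE
      t <- t - w
    }
  }
  stopifnot(t == 0)
  take
}

#' Draw a fulfillment vector achieving an exact target total
#'
#' Conditional on the target, every solution vector (subset of criteria
#' whose weights sum to the target) is returned with equal probability.
#' Randomness comes from R's global RNG; call [set.seed()] for
#' reproducibility.
#'
#' @param rubric A [rubric()] object.
#' @param target Desired total score (must be an achievable subset sum).
#' @param product_id Product id recorded on the vector.
#' @param stage Evaluation stage recorded on the vector.
#' @param by_domain Optional named vector of per-domain sub-targets
#'   (names from [rubric_domains()], missing domains target 0). When
#'   supplied, sampling runs per domain so the vector satisfies the domain
#'   sub-targets and (hence) their total exactly; `target`, if also given,
#'   must equal their sum.
#'
#' @return A [fulfillment()] vector whose weighted sum equals `target`.
#' @export
#' @examples
#' set.seed(1)
#' r <- default_rubric()
#' fv <- sample_fulfillment_for_target(r, 35)
#' score_product(fv, r)$total
sample_fulfillment_for_target <- function(rubric, target = NULL,
                                          product_id = "product",
                                          stage = c("initial", "post_followup"),
                                          by_domain = NULL) {
  stopifnot(inherits(rubric, "cbd_rubric"))
  stage <- match.arg(stage)
  ids <- rubric$criteria$id
  take <- logical(length(ids))
  if (!is.null(by_domain)) {
    if (is.null(names(by_domain)) ||
        !all(names(by_domain) %in% rubric_domains())) {
      stop("`by_domain` must be named with rubric domains", call. = FALSE)
    }
    full <- stats::setNames(rep(0L, 4), rubric_domains())
    full[names(by_domain)] <- as.integer(by_domain)
    if (!is.null(target) && sum(full) != target) {
      stop("`target` (", target, ") differs from the sum of `by_domain` (",
           sum(full), ")", call. = FALSE)
    }
    for (d in rubric_domains()) {
      sel <- rubric$criteria$domain == d
      w <- rubric$criteria$weight[sel]
      counts <- subset_sum_counts(w)
      ach <- which(counts[1, ] > 0) - 1L
      if (!full[[d]] %in% ach) {
        stop("domain sub-target ", full[[d]], " unachievable for domain `",
             d, "`; nearest achievable: ",
             paste(nearest_neighbours(full[[d]], ach), collapse = ", "),
             call. = FALSE)
      }
      take[sel] <- sample_subset_for_sum(w, full[[d]], counts)
    }
  } else {
    if (is.null(target)) stop("supply `target` or `by_domain`", call. = FALSE)
    w <- rubric$criteria$weight
    counts <- subset_sum_counts(w)
    ach <- which(counts[1, ] > 0) - 1L
    if (length(target) != 1 || is.na(target) || target != round(target) ||
        !target %in% ach) {
      stop("target ", target, " is not an achievable subset sum of the ",
           "rubric's weights; nearest achievable: ",
           paste(nearest_neighbours(target, ach), collapse = ", "),
           call. = FALSE)
    }
    take <- sample_subset_for_sum(w, as.integer(target), counts)
  }
  fulfillment(product_id, stats::setNames(take, ids), stage = stage,
              rubric = rubric)
}

nearest_neighbours <- function(x, achievable) {
  lo <- suppressWarnings(max(achievable[achievable <= x]))
  hi <- suppressWarnings(min(achievable[achievable >= x]))
  unique(c(lo[is.finite(lo)], hi[is.finite(hi)]))
}

#' Configuration for the synthetic cohort generator
#'
#' @param rubric A [rubric()] object.
#' @param target_totals Explicit per-product targets: either a numeric
#'   vector of totals (used as both preliminary and final), or a
#'   data.frame with columns `preliminary` and `final` (`final >=
#'   preliminary`) and optional `product_name`, `manufacturer`,
#'   `normative`, `product_type` columns (e.g. the packaged product table).
#'   Mutually exclusive with `group_spec`.
#' @param group_spec Distribution spec: a data.frame with columns
#'   `normative`, `n`, `location`, `spread`; per group, `n` final totals
#'   are drawn from Normal(location, spread) and rounded to the nearest
#'   achievable subset sum (ties toward the lower total); preliminary
#'   totals equal final ones. Realized totals are reported in the output.
#' @param followup_response_fraction Fraction of products that answer the
#'   follow-up e-mail, in `[0, 1]`. Every product whose final target
#'   exceeds its preliminary target necessarily responds; if the fraction
#'   implies more responders, the surplus respond without adding criteria.
#' @param seed Integer seed recorded in the config and used by
#'   [generate_cohort()].
#' @param base_date Date of the first e-mail in the generated event log.
#'
#' @return An object of class `cbd_generator_config`. Target achievability
#'   is validated here, before any generation.
#' @export
generator_config <- function(rubric, target_totals = NULL, group_spec = NULL,
                             followup_response_fraction = 0, seed = 1L,
                             base_date = as.Date("2023-01-01")) {
  stopifnot(inherits(rubric, "cbd_rubric"))
  if (is.null(target_totals) == is.null(group_spec)) {
    stop("supply exactly one of `target_totals` or `group_spec`",
         call. = FALSE)
  }
  if (!is.numeric(followup_response_fraction) ||
      followup_response_fraction < 0 || followup_response_fraction > 1) {
    stop("`followup_response_fraction` must be in [0, 1]", call. = FALSE)
  }
  ach <- achievable_totals(rubric)
  if (!is.null(target_totals)) {
    if (is.numeric(target_totals)) {
      target_totals <- data.frame(preliminary = as.integer(target_totals),
                                  final = as.integer(target_totals))
    }
    stopifnot(is.data.frame(target_totals),
              all(c("preliminary", "final") %in% names(target_totals)))
    bad <- which(!(target_totals$preliminary %in% ach) |
                   !(target_totals$final %in% ach))
    if (length(bad) > 0) {
      stop("unachievable target total(s) at row(s): ",
           paste(bad, collapse = ", "), "; achievable totals range ",
           min(ach), "-", max(ach), call. = FALSE)
    }
    if (any(target_totals$final < target_totals$preliminary)) {
      stop("final targets must be >= preliminary targets", call. = FALSE)
    }
  } else {
    stopifnot(is.data.frame(group_spec),
              all(c("normative", "n", "location", "spread") %in%
                    names(group_spec)))
  }
  structure(list(rubric = rubric, target_totals = target_totals,
                 group_spec = group_spec,
                 followup_response_fraction = followup_response_fraction,
                 seed = as.integer(seed), base_date = as.Date(base_date)),
            class = "cbd_generator_config")
}

#' Generate a synthetic criterion-level cohort
#'
#' For each product a post-follow-up fulfillment vector is drawn uniformly
#' over the subset-sum solutions of its final target; when the preliminary
#' target is lower, the initial vector is drawn uniformly over the
#' subset-sum solutions of the preliminary target *within* the final
#' vector's met set, so the post-follow-up vector is a superset of the
#' initial one and both totals are hit exactly. The e-mail consultation
#' is emitted as an event log consistent with the follow-up state machine
#' (responders reply within the first 14-day window; non-responders pass
#' both deadlines).
#'
#' @param config A [generator_config()].
#'
#' @return A list with elements `initial` and `post_followup` (fulfillment
#'   matrices as in [read_fulfillment_csv()]), `cohort` (a validated
#'   [cohort()] whose scores are obtained by re-scoring the matrices),
#'   `events` (the follow-up event log), `realized_totals` (data.frame of
#'   the totals actually generated) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cbd_generator_config"))
  rubric <- config$rubric
  set.seed(config$seed)
  ach <- achievable_totals(rubric)

  if (!is.null(config$target_totals)) {
    tt <- config$target_totals
  } else {
    gs <- config$group_spec
    draws <- lapply(seq_len(nrow(gs)), function(i) {
      raw <- stats::rnorm(gs$n[i], gs$location[i], gs$spread[i])
      raw <- pmin(pmax(raw, 0), max(ach))
      data.frame(normative = gs$normative[i],
                 final = nearest_achievable(raw, ach))
    })
    tt <- do.call(rbind, draws)
    tt$preliminary <- tt$final
  }
  n <- nrow(tt)
  if (is.null(tt$product_name)) tt$product_name <- sprintf("SYN%03d", seq_len(n))
  if (is.null(tt$manufacturer)) tt$manufacturer <- "synthetic"
  if (is.null(tt$normative)) tt$normative <- "N660"
  if (is.null(tt$product_type)) tt$product_type <- "oil"

  ids <- rubric$criteria$id
  w <- rubric$criteria$weight
  counts_all <- subset_sum_counts(w)
  init_mat <- matrix(0L, nrow = n, ncol = length(ids),
                     dimnames = list(NULL, ids))
  post_mat <- init_mat
  responses <- vector("list", n)
  for (i in seq_len(n)) {
    f_take <- sample_subset_for_sum(w, tt$final[i], counts_all)
    if (tt$preliminary[i] == tt$final[i]) {
      i_take <- f_take
    } else {
      # preliminary must be realizable inside the final met set; resample
      # the final support until it is (cheap: the weight multiset is
      # dominated by small weights, so gaps are rare)
      i_take <- NULL
      for (attempt in seq_len(1000)) {
        sub_w <- w[f_take]
        sub_counts <- subset_sum_counts(sub_w)
        if (tt$preliminary[i] + 1 <= ncol(sub_counts) &&
            sub_counts[1, tt$preliminary[i] + 1] > 0) {
          sub_take <- sample_subset_for_sum(sub_w, tt$preliminary[i],
                                            sub_counts)
          i_take <- f_take
          i_take[f_take] <- sub_take
          break
        }
        f_take <- sample_subset_for_sum(w, tt$final[i], counts_all)
      }
      if (is.null(i_take)) {
        stop("could not realize preliminary target ", tt$preliminary[i],
             " inside a final support of total ", tt$final[i],
             " (row ", i, ")", call. = FALSE)
      }
    }
    post_mat[i, ] <- as.integer(f_take)
    init_mat[i, ] <- as.integer(i_take)
    responses[[i]] <- ids[f_take & !i_take]
  }

  upgraded <- which(tt$final > tt$preliminary)
  n_resp <- max(length(upgraded),
                round(config$followup_response_fraction * n))
  extra <- setdiff(seq_len(n), upgraded)
  responders <- sort(c(upgraded,
                       if (n_resp > length(upgraded) && length(extra) > 0)
                         sample(extra, min(n_resp - length(upgraded),
                                           length(extra)))))

  base <- config$base_date
  events <- do.call(rbind, lapply(seq_len(n), function(i) {
    pid <- tt$product_name[i]
    if (i %in% responders) {
      data.frame(product_id = pid,
                 event = c("send_first", "receive_response"),
                 date = as.character(c(base, base + 7)),
                 response = c("", paste(responses[[i]], collapse = ";")),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(product_id = pid,
                 event = c("send_first", "deadline_passed", "deadline_passed"),
                 date = as.character(c(base, base + 14, base + 21)),
                 response = "", stringsAsFactors = FALSE)
    }
  }))

  init_df <- data.frame(product_id = tt$product_name, init_mat,
                        check.names = FALSE, stringsAsFactors = FALSE)
  post_df <- data.frame(product_id = tt$product_name, post_mat,
                        check.names = FALSE, stringsAsFactors = FALSE)

  prelim_scores <- score_matrix(init_df, rubric, stage = "initial")
  final_scores <- score_matrix(post_df, rubric, stage = "post_followup")
  stopifnot(identical(prelim_scores$total, as.integer(tt$preliminary)),
            identical(final_scores$total, as.integer(tt$final)))

  records <- data.frame(product_name = tt$product_name,
                        manufacturer = tt$manufacturer,
                        normative = tt$normative,
                        product_type = tt$product_type,
                        preliminary_score = prelim_scores$total,
                        final_score = final_scores$total,
                        stringsAsFactors = FALSE)
  list(initial = init_df,
       post_followup = post_df,
       cohort = cohort(records,
                       provenance = sprintf("synthetic (seed %d)", config$seed)),
       events = events,
       realized_totals = data.frame(product_name = tt$product_name,
                                    preliminary = tt$preliminary,
                                    final = tt$final),
       config = config)
}
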