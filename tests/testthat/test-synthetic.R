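test_that("degenerate targets have unique solutions", {
  r <- toy_rubric(c(1, 2, 3))
  set.seed(1)
  expect_true(all(!sample_fulfillment_for_target(r, 0)$status))
  expect_true(all(sample_fulfillment_for_target(r, 6)$status))
})

test_that("unachievable targets fail fast, naming the nearest achievable totals", {
  r <- toy_rubric(c(3, 3))
  expect_error(sample_fulfillment_for_target(r, 4), "nearest achievable: 3, 6")
  expect_error(sample_fulfillment_for_target(r, 7), "nearest achievable: 6")
  expect_error(generator_config(r, target_totals = c(3, 4)),
               "unachievable target total\\(s\\) at row\\(s\\): 2")
})

test_that("sampled vectors hit their target exactly, for every achievable target", {
  set.seed(31)
  r <- default_rubric()
  for (target in sample(achievable_totals(r), 15)) {
    fv <- sample_fulfillment_for_target(r, target)
    expect_equal(score_product(fv, r)$total, target)
  }
})

test_that("conditional on the target, solutions are drawn uniformly", {
  # weights (1,2,3), target 3: exhaustive enumeration of the 8 subsets
  # gives exactly two solutions, {w3} and {w1,w2}
  weights <- c(1, 2, 3)
  sums <- enumerate_subset_sums(weights)
  expect_equal(sum(sums == 3), 2)

  r <- toy_rubric(weights)
  set.seed(20240601)
  draws <- replicate(4000, {
    fv <- sample_fulfillment_for_target(r, 3)
    paste(r$criteria$id[fv$status], collapse = "+")
  })
  tab <- table(draws)
  expect_setequal(names(tab), c("w3", "w1+w2"))
  expect_equal(unname(tab[["w3"]]) / 4000, 0.5, tolerance = 0.04)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  # a richer rubric: every solution of the enumerated solution set appears
  # with uniform frequency
  weights2 <- c(1, 1, 2, 3)
  r2 <- toy_rubric(weights2)
  n_solutions <- sum(enumerate_subset_sums(weights2) == 4)
  expect_equal(n_solutions, 3) # {1a,3}, {1b,3}, {1a,1b,2}
  set.seed(7)
  draws2 <- replicate(3000, {
    fv <- sample_fulfillment_for_target(r2, 4)
    paste(r2$criteria$id[fv$status], collapse = "+")
  })
  tab2 <- table(draws2)
  expect_equal(length(tab2), 3)
  expect_gt(stats::chisq.test(tab2)$p.value, 0.001)
})

test_that("domain-conditional sampling satisfies domain and total constraints", {
  r <- default_rubric()
  set.seed(3)
  targets <- c(prescription = 12, gmp = 4, safety_of_use = 20,
               laboratory_testing = 2)
  fv <- sample_fulfillment_for_target(r, by_domain = targets)
  sc <- score_product(fv, r)
  expect_equal(sc$by_domain, setNames(as.integer(targets), names(targets)))
  expect_equal(sc$total, sum(targets))
  expect_error(
    sample_fulfillment_for_target(r, target = 10, by_domain = targets),
    "differs from the sum")
})

test_that("generated cohorts re-score to their requested totals exactly", {
  r <- default_rubric()
  co <- table1_cohort()
  cfg <- generator_config(
    r, target_totals = data.frame(preliminary = co$preliminary_score,
                                  final = co$final_score,
                                  product_name = co$product_name,
                                  normative = co$normative),
    followup_response_fraction = 12 / 105, seed = 424242)
  g <- generate_cohort(cfg)
  expect_equal(g$cohort$preliminary_score, co$preliminary_score)
  expect_equal(g$cohort$final_score, co$final_score)
  # supersets: the post-followup matrix dominates the initial one pointwise
  ids <- r$criteria$id
  expect_true(all(as.matrix(g$post_followup[ids]) >=
                    as.matrix(g$initial[ids])))
  # the event log is consistent with the protocol state machine
  cases <- replay_followup_log(g$events)
  expect_equal(length(cases), 105)
  n_resp <- sum(vapply(cases, function(cs) cs$state == "closed_with_response",
                       logical(1)))
  expect_equal(n_resp, 12)
})

test_that("generation is deterministic under a fixed seed", {
  r <- default_rubric()
  cfg <- generator_config(r, target_totals = c(10, 35, 60), seed = 99)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$initial, g2$initial)
  expect_identical(g1$post_followup, g2$post_followup)
  expect_identical(g1$events, g2$events)
  g3 <- generate_cohort(generator_config(r, target_totals = c(10, 35, 60),
                                         seed = 100))
  expect_false(identical(g1$initial, g3$initial))
})

test_that("a zero response fraction leaves initial and post-followup identical", {
  r <- default_rubric()
  cfg <- generator_config(r, target_totals = c(5, 22, 47), seed = 12,
                          followup_response_fraction = 0)
  g <- generate_cohort(cfg)
  expect_identical(g$initial, g$post_followup)
  expect_true(all(g$events$event != "receive_response"))
})

test_that("distribution specs draw totals rounded to achievable subset sums", {
  r <- toy_rubric(c(3, 3, 3)) # achievable: 0, 3, 6, 9
  cfg <- generator_config(
    r, group_spec = data.frame(normative = c("N327", "N660"), n = c(8, 12),
                               location = c(6, 3), spread = 1.5),
    seed = 5)
  g <- generate_cohort(cfg)
  expect_equal(nrow(g$cohort), 20)
  expect_true(all(g$cohort$final_score %in% c(0, 3, 6, 9)))
  expect_equal(as.vector(table(g$cohort$normative)[c("N327", "N660")]),
               c(8, 12))
  # ties toward the lower total: 1.5 between 0 and 3 rounds to 0
  expect_equal(cbdscore:::nearest_achievable(c(1.5, 4.5), c(0L, 3L, 6L)),
               c(0L, 3L))
})
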