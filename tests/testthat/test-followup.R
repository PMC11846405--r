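test_that("the consultation state machine enforces the 14+7 day protocol", {
  cs <- followup_case("p1")
  expect_equal(cs$state, "evaluated")

  cs <- advance_state(cs, "send_first", "2023-01-01")
  expect_equal(cs$state, "awaiting_first_reply")
  expect_equal(cs$deadline, as.Date("2023-01-01") + 14)

  cs2 <- advance_state(cs, "deadline_passed", "2023-01-15")
  expect_equal(cs2$state, "awaiting_reminder_reply")
  expect_equal(cs2$deadline, as.Date("2023-01-15") + 7)

  done <- advance_state(cs2, "deadline_passed", "2023-01-22")
  expect_equal(done$state, "closed_no_response")

  # responses close from either awaiting state
  expect_equal(advance_state(cs, "receive_response", "2023-01-10",
                             response = "w1")$state, "closed_with_response")
  expect_equal(advance_state(cs2, "receive_response", "2023-01-20")$state,
               "closed_with_response")
})

test_that("illegal events are protocol errors", {
  cs <- followup_case("p1")
  expect_error(advance_state(cs, "receive_response", "2023-01-01"),
               "protocol error")
  expect_error(advance_state(cs, "deadline_passed", "2023-01-01"),
               "protocol error")
  closed <- advance_state(
    advance_state(cs, "send_first", "2023-01-01"),
    "receive_response", "2023-01-05")
  expect_error(advance_state(closed, "receive_response", "2023-01-06"),
               "terminal state")
  # premature deadline or out-of-order dates are contract errors
  open <- advance_state(cs, "send_first", "2023-01-01")
  expect_error(advance_state(open, "deadline_passed", "2023-01-10"),
               "before the deadline")
  expect_error(advance_state(open, "receive_response", "2022-12-31"),
               "out-of-order")
})

test_that("follow-up responses act by pointwise union and never lower scores", {
  r <- toy_rubric(c(3, 2, 1, 2))
  init <- toy_fulfillment(r, c("w2"))

  upgraded <- apply_followup(init, c("w1", "w3"))
  expect_equal(upgraded$stage, "post_followup")
  expect_equal(score_product(upgraded, r)$total, 6)

  # empty response: identical status
  same <- apply_followup(init, character(0))
  expect_identical(same$status, init$status)
  # idempotence / absorption of already-met ids
  expect_identical(apply_followup(init, "w2")$status, init$status)
  again <- apply_followup(upgraded, c("w1", "w3"))
  expect_identical(again$status, upgraded$status)
  # order independence over response subsets
  ab <- apply_followup(apply_followup(init, "w1"), "w4")
  ba <- apply_followup(apply_followup(init, "w4"), "w1")
  expect_identical(ab$status, ba$status)

  expect_error(apply_followup(init, "nope"), "unknown criterion")
})

test_that("every response set yields a post-followup score >= the initial one", {
  set.seed(7)
  r <- toy_rubric(sample(1:3, 9, replace = TRUE),
                  domains = sample(rubric_domains(), 9, replace = TRUE))
  ids <- r$criteria$id
  for (rep in 1:30) {
    init <- toy_fulfillment(r, sample(ids, sample(0:9, 1)))
    response <- sample(ids, sample(0:9, 1))
    post <- apply_followup(init, response)
    expect_gte(score_product(post, r)$total, score_product(init, r)$total)
    expect_true(all(init$status <= post$status))
  }
})

test_that("event logs round-trip through CSV and replay to consistent cases", {
  log <- data.frame(
    product_id = c("a", "a", "b", "b", "b"),
    event = c("send_first", "receive_response",
              "send_first", "deadline_passed", "deadline_passed"),
    date = c("2023-01-01", "2023-01-09",
             "2023-01-01", "2023-01-15", "2023-01-22"),
    response = c("", "w1;w2", "", "", ""),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_followup_log(log, path)
  back <- read_followup_log(path)
  expect_equal(back$response[[2]], c("w1", "w2"))

  cases <- replay_followup_log(back)
  expect_equal(cases$a$state, "closed_with_response")
  expect_equal(cases$a$response, c("w1", "w2"))
  expect_equal(cases$b$state, "closed_no_response")
})
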