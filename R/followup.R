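#' @title Follow-up protocol
#' @description
#' The manufacturer e-mail consultation modeled as a deterministic state
#' machine. Products are first evaluated from public sources; an e-mail
#' then requests the missing information, with a 14-day response window,
#' followed (if unanswered) by a reminder with a 7-day window. A response
#' can only add newly evidenced criteria, so a product's score can increase
#' or stay unchanged, never decrease. Deadlines are counted in calendar
#' days, inclusive of the start day and exclusive of the end: a response
#' dated exactly 14 days after the first e-mail is within the deadline.
#' @name followup-protocol
NULL

followup_states <- function() {
  c("evaluated", "awaiting_first_reply", "awaiting_reminder_reply",
    "closed_with_response", "closed_no_response")
}

followup_terminal <- function(state) {
  state %in% c("closed_with_response", "closed_no_response")
}

#' Open a follow-up case for a product
#'
#' @param product_id Product identifier.
#'
#' @return An object of class `cbd_followup_case` in state `"evaluated"`,
#'   with fields `state`, `first_email_date`, `reminder_date`, `deadline`,
#'   `response` (character vector of newly evidenced criterion ids, once
#'   closed with a response) and `last_event_date`.
#' @export
followup_case <- function(product_id) {
  structure(list(product_id = as.character(product_id)[1],
                 state = "evaluated",
                 first_email_date = as.Date(NA),
                 reminder_date = as.Date(NA),
                 deadline = as.Date(NA),
                 response = NULL,
                 last_event_date = as.Date(NA)),
            class = "cbd_followup_case")
}

#' @export
print.cbd_followup_case <- function(x, ...) {
  cat(sprintf("<cbd_followup_case> %s: %s", x$product_id, x$state))
  if (!is.na(x$deadline) && !followup_terminal(x$state)) {
    cat(sprintf(" (deadline %s)", format(x$deadline)))
  }
  if (!is.null(x$response)) {
    cat(sprintf(" [%d criteria evidenced]", length(x$response)))
  }
  cat("\n")
  invisible(x)
}

#' Advance a follow-up case by one event
#'
#' Legal transitions:
#' \itemize{
#'   \item `evaluated` + `send_first` -> `awaiting_first_reply`
#'     (deadline = date + 14 days);
#'   \item `awaiting_first_reply` + `deadline_passed` ->
#'     `awaiting_reminder_reply` (reminder sent; deadline = reminder date +
#'     7 days; legal only on/after the first deadline);
#'   \item either awaiting state + `receive_response` ->
#'     `closed_with_response`;
#'   \item `awaiting_reminder_reply` + `deadline_passed` ->
#'     `closed_no_response`.
#' }
#' Events in a closed state raise a protocol error; event dates must be
#' non-decreasing.
#'
#' @param case A [followup_case()].
#' @param event One of `"send_first"`, `"receive_response"`,
#'   `"deadline_passed"`.
#' @param date Event date (`Date` or ISO-8601 string).
#' @param response For `receive_response`: character vector of criterion
#'   ids newly evidenced by the reply (may be empty).
#'
#' @return The updated `cbd_followup_case`.
#' @export
advance_state <- function(case, event, date,
                          response = character(0)) {
  stopifnot(inherits(case, "cbd_followup_case"))
  event <- match.arg(event, c("send_first", "receive_response",
                              "deadline_passed"))
  date <- as.Date(date)
  if (is.na(date)) stop("invalid event date", call. = FALSE)
  if (!is.na(case$last_event_date) && date < case$last_event_date) {
    stop("out-of-order event date for product ", case$product_id,
         ": ", format(date), " precedes ", format(case$last_event_date),
         call. = FALSE)
  }
  if (followup_terminal(case$state)) {
    stop("protocol error: event `", event, "` in terminal state `",
         case$state, "` (product ", case$product_id, ")", call. = FALSE)
  }
  bad <- function() {
    stop("protocol error: event `", event, "` illegal in state `",
         case$state, "` (product ", case$product_id, ")", call. = FALSE)
  }
  if (event == "send_first") {
    if (case$state != "evaluated") bad()
    case$first_email_date <- date
    case$deadline <- date + 14L
    case$state <- "awaiting_first_reply"
  } else if (event == "receive_response") {
    if (!case$state %in% c("awaiting_first_reply", "awaiting_reminder_reply")) bad()
    case$response <- as.character(response)
    case$state <- "closed_with_response"
  } else { # deadline_passed
    if (case$state == "awaiting_first_reply") {
      if (date < case$deadline) {
        stop("deadline_passed dated ", format(date),
             " before the deadline ", format(case$deadline),
             " (product ", case$product_id, ")", call. = FALSE)
      }
      case$reminder_date <- date
      case$deadline <- date + 7L
      case$state <- "awaiting_reminder_reply"
    } else if (case$state == "awaiting_reminder_reply") {
      if (date < case$deadline) {
        stop("deadline_passed dated ", format(date),
             " before the deadline ", format(case$deadline),
             " (product ", case$product_id, ")", call. = FALSE)
      }
      case$state <- "closed_no_response"
    } else {
      bad()
    }
  }
  case$last_event_date <- date
  case
}

#' Apply a follow-up response to an initial evaluation
#'
#' The response is the set of criteria newly evidenced by the
#' manufacturer's reply; the post-follow-up status is the pointwise union
#' of the initially met criteria and the response. Union semantics make
#' the update monotone (the score can only increase or stay unchanged),
#' idempotent, and order-independent over response subsets.
#'
#' @param initial A [fulfillment()] vector at stage `"initial"`.
#' @param response Character vector of criterion ids (subset of the
#'   initial vector's criterion ids; may be empty).
#'
#' @return A `cbd_fulfillment` at stage `"post_followup"` whose met set is
#'   a superset of the initial one.
#' @export
apply_followup <- function(initial, response) {
  stopifnot(inherits(initial, "cbd_fulfillment"))
  response <- as.character(response)
  unknown <- setdiff(response, names(initial$status))
  if (length(unknown) > 0) {
    stop("response names unknown criterion id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  status <- initial$status
  status[response] <- TRUE
  fulfillment(initial$product_id, status, stage = "post_followup")
}

#' Read / write follow-up event logs as CSV
#'
#' Columns: `product_id`, `event`, `date` (ISO-8601), `response`
#' (semicolon-separated criterion ids, empty when not applicable).
#'
#' @param path CSV file path.
#' @return `read_followup_log()`: data.frame with `response` parsed into a
#'   list-column of character vectors.
#' @export
read_followup_log <- function(path) {
  log <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character")
  needed <- c("product_id", "event", "date")
  missing_cols <- setdiff(needed, names(log))
  if (length(missing_cols) > 0) {
    stop("follow-up log lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(log$response)) log$response <- ""
  log$response <- lapply(log$response, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  log
}

#' @param log Event log data.frame (as from [read_followup_log()] or
#'   [generate_cohort()]); a list-column `response` is flattened with `;`.
#' @rdname read_followup_log
#' @return `write_followup_log()`: the path, invisibly.
#' @export
write_followup_log <- function(log, path) {
  out <- log
  if (is.list(out$response)) {
    out$response <- vapply(out$response, paste, character(1), collapse = ";")
  }
  out$date <- as.character(out$date)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Replay an event log through the state machine
#'
#' Validates every event against the protocol (errors on any illegal
#' transition or out-of-order date) and returns the final case per
#' product.
#'
#' @param log Event log data.frame with columns `product_id`, `event`,
#'   `date`, and optionally `response` (list-column or `;`-separated).
#'
#' @return Named list of final `cbd_followup_case` objects, keyed by
#'   product id.
#' @export
replay_followup_log <- function(log) {
  stopifnot(is.data.frame(log))
  if (is.null(log$response)) log$response <- vector("list", nrow(log))
  if (!is.list(log$response)) {
    log$response <- lapply(as.character(log$response), function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  cases <- list()
  for (i in seq_len(nrow(log))) {
    pid <- log$product_id[i]
    if (is.null(cases[[pid]])) cases[[pid]] <- followup_case(pid)
    resp <- log$response[[i]]
    if (is.null(resp)) resp <- character(0)
    cases[[pid]] <- advance_state(cases[[pid]], log$event[i], log$date[i],
                                  response = resp)
  }
  cases
}
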