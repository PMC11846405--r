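# Shared fixtures and independent oracles, all built in code.

# A small rubric with the given weights (ids w1, w2, ...), one domain by
# default; `domains` may be a vector recycled over the weights.
toy_rubric <- function(weights, domains = "prescription") {
  n <- length(weights)
  rubric(data.frame(id = paste0("w", seq_len(n)),
                    label = paste("criterion", seq_len(n)),
                    domain = rep(domains, length.out = n),
                    weight = weights),
         name = "toy", version = "t")
}

toy_fulfillment <- function(rubric, met, product_id = "p1",
                            stage = "initial") {
  ids <- rubric$criteria$id
  status <- stats::setNames(ids %in% met, ids)
  fulfillment(product_id, status, stage = stage, rubric = rubric)
}

# All 2^n achievable totals of a weight vector, by explicit enumeration of
# every met/unmet combination (independent of the scoring engine and of
# the subset-sum DP).
enumerate_subset_sums <- function(weights) {
  n <- length(weights)
  sums <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    s <- 0
    for (i in seq_len(n)) if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0) {
      s <- s + weights[i]
    }
    sums[mask + 1] <- s
  }
  sums
}

# Independent Mann-Whitney oracle: U by direct pair counting (not
# midranks), exact two-sided p by enumeration of every group assignment.
brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

brute_force_mw <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  assignments <- utils::combn(n, n1)
  us <- apply(assignments, 2, function(idx) {
    brute_force_u(pooled[idx], pooled[-idx])
  })
  u_obs <- brute_force_u(x, y)
  eps <- 1e-9
  p <- 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps))
  list(u = u_obs, p = min(1, p))
}

# Fulfillment matrix row helper
matrix_row <- function(rubric, met, product_id = "p1") {
  ids <- rubric$criteria$id
  df <- as.data.frame(as.list(as.integer(ids %in% met)))
  names(df) <- ids
  cbind(data.frame(product_id = product_id, stringsAsFactors = FALSE), df)
}
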