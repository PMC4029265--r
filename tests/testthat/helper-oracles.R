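# Independent oracles used across the suite. These deliberately share no
# code with the package: brute-force enumeration for k-means, a direct
# per-event-time evaluation of the hypergeometric moments for the log-rank
# test, and the survival package as an external reference for Cox fits.

options(cimpanel.verbose = FALSE)

# Globally optimal 2-partition by exhaustive enumeration (n <= ~15).
enum_kmeans2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  best_assign <- NULL
  for (code in 1:(2^(n - 1) - 1)) { # sample 1 fixed in cluster 1; both non-empty
    assign <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    wss <- 0
    for (g in 1:2) {
      Xi <- X[assign == g, , drop = FALSE]
      wss <- wss + sum(sweep(Xi, 2, colMeans(Xi), "-")^2)
    }
    if (wss < best) {
      best <- wss
      best_assign <- assign
    }
  }
  list(wss = best, assign = best_assign)
}

# Step-by-step log-rank evaluation: O, E, V sums per distinct event time.
logrank_oracle <- function(times, events, x01) {
  evt <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (tt in evt) {
    at <- times >= tt
    n <- sum(at)
    n1 <- sum(at & x01 == 1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & x01 == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Small paired cohort written as TSV fixtures on the fly.
write_tiny_matrix <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_surv_data <- function(n, seed) {
  withr::with_seed(seed, {
    list(times = round(rexp(n, 0.05), 1) + 0.1,
         events = rbinom(n, 1, 0.7),
         groups = sample(c("A", "B"), n, replace = TRUE, prob = c(0.5, 0.5)))
  })
}
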