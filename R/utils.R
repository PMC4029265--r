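#' @keywords internal
cgp_log <- function(fmt, ...) {
  if (isTRUE(getOption("cimpanel.verbose", TRUE))) {
    message("[cimpanel] ", sprintf(fmt, ...))
  }
}

# One user-facing seed per run; stage seeds are derived arithmetically so that
# stages stay decoupled (changing bootstrap iterations must not perturb the
# clustering stream). Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483399) * 48271 + as.double(stage) * 10007
  as.integer(s %% 2147483399) + 1L
}

stop_cgp <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_binary01 <- function(x) {
  !anyNA(x) && all(x %in% c(0, 1))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 means identical partitions (up to label names), 0 is the expected
#' agreement of random partitions. Used to score phenotype recovery against
#' planted truth.
#'
#' @param a,b vectors of equal length; any label types.
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_cgp("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
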