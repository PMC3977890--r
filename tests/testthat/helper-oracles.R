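# Shared fixtures and independent oracles for the test suite.

# Brute-force Cohen's kappa: expand the table into the two raters' call
# vectors and estimate observed and chance agreement by direct counting,
# independently of the marginal algebra used in the package.
kappa_bruteforce <- function(counts) {
  K <- nrow(counts)
  a <- integer(0)
  b <- integer(0)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    a <- c(a, rep(i, counts[i, j]))
    b <- c(b, rep(j, counts[i, j]))
  }
  pr_a <- mean(a == b)
  pr_e <- sum(vapply(seq_len(K),
                     function(k) mean(a == k) * mean(b == k), 0))
  (pr_a - pr_e) / (1 - pr_e)
}

# Random K x K contingency table with n pairs and non-degenerate chance
# agreement (pr_e < 1).
random_table <- function(K, n) {
  repeat {
    p <- stats::runif(K * K)
    counts <- matrix(as.integer(stats::rmultinom(1, n, p)), K, K)
    pe <- sum((rowSums(counts) / n) * (colSums(counts) / n))
    if (pe < 1 - 1e-9) return(counts)
  }
}

# Score-record sheet for two operators scoring the same objects once.
# a / b may contain NA (object not scored by that side).
records_two_ops <- function(a, b, run = "R1", ops = c("A", "B")) {
  n <- length(a)
  stopifnot(length(b) == n)
  obj <- sprintf("c%02d", seq_len(n))
  rbind(
    data.frame(patient_id = "P1", spot_id = "S1", object_id = obj,
               operator_id = ops[1], run_id = run, score = as.integer(a)),
    data.frame(patient_id = "P1", spot_id = "S1", object_id = obj,
               operator_id = ops[2], run_id = run, score = as.integer(b)))
}

paired_two_ops <- function(a, b, ...) {
  pair_scores(records_two_ops(a, b, ...), "operator", "A", "B")
}

# True normal content of an interval [lo, up] under N(mu, sd).
normal_content <- function(lo, up, mu = 0, sd = 1) {
  stats::pnorm(up, mu, sd) - stats::pnorm(lo, mu, sd)
}
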