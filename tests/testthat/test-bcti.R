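# Tolerance factors, BCTIs, accuracy profiles, bias and the ISR benchmark.

test_that("paired differences follow the stated conventions", {
  # identical scores differ by 0 on both scales
  p <- paired_two_ops(2, 2)
  expect_equal(compute_differences(p, "absolute")$all$values, 0)
  expect_equal(compute_differences(p, "percent")$all$values, 0)

  # (2, 3) on the percent scale: 100 * 1 / 2.5 = 40
  expect_equal(compute_differences(paired_two_ops(2, 3),
                                   "percent")$all$values, 40)
  # double-negative pair: 0 by convention, never NaN
  expect_equal(compute_differences(paired_two_ops(0, 0),
                                   "percent")$all$values, 0)

  # grouping by the reference (side A) category, plus the pooled group
  d <- compute_differences(paired_two_ops(c(2, 2, 3, 0), c(3, 2, 2, 1)),
                           "absolute")
  expect_setequal(names(d), c("all", "0", "2", "3"))
  expect_equal(d$`2`$values, c(1, 0))
  expect_equal(d$`3`$values, -1)
  expect_equal(d$all$n, 4L)

  # incomplete pairs are excluded and counted
  dm <- compute_differences(paired_two_ops(c(2, NA), c(2, 1)), "absolute")
  expect_equal(dm$all$n, 1L)
  expect_equal(attr(dm, "n_excluded"), 1L)
})

test_that("swapping sides negates every difference", {
  set.seed(31)
  a <- sample(0:3, 30, replace = TRUE)
  b <- sample(0:3, 30, replace = TRUE)
  rec <- records_two_ops(a, b)
  for (sc in c("absolute", "percent")) {
    dab <- compute_differences(pair_scores(rec, "operator", "A", "B"), sc)
    dba <- compute_differences(pair_scores(rec, "operator", "B", "A"), sc)
    expect_equal(sort(dba$all$values), sort(-dab$all$values))
  }
})

test_that("Howe's tolerance factor matches its hand-derived values", {
  # asymptotically the factor collapses to the normal quantile
  expect_equal(tolerance_factor(1e6, 0.95, 0.90), qnorm(0.975),
               tolerance = 0.01)
  # frozen hand evaluation of the closed form at n = 30
  expect_equal(tolerance_factor(30, 0.95, 0.90), 2.413175,
               tolerance = 1e-6)
  expect_error(tolerance_factor(1, 0.95, 0.90), "n >= 2")
  expect_error(tolerance_factor(10, 1.2, 0.9))
  expect_error(tolerance_factor(10, 0.95, 0))
})

test_that("tolerance factor is monotone in n, beta and gamma", {
  ks <- vapply(c(10, 30, 100), tolerance_factor, 0,
               beta = 0.95, gamma = 0.90)
  expect_true(all(diff(ks) < 0))
  expect_lt(tolerance_factor(20, 0.67, 0.90),
            tolerance_factor(20, 0.95, 0.90))
  expect_lt(tolerance_factor(20, 0.95, 0.90),
            tolerance_factor(20, 0.95, 0.99))
})

test_that("Monte-Carlo calibration reproduces the closed form", {
  set.seed(32)
  for (n in c(10, 30)) {
    k_howe <- tolerance_factor(n, 0.95, 0.90)
    k_mc <- tolerance_factor(n, 0.95, 0.90, method = "montecarlo",
                             mc_samples = 30000L)
    expect_equal(k_mc, k_howe, tolerance = 0.03)
  }
})

test_that("BCTI matches the hand-evaluated five-point example", {
  ti <- bcti(c(0, 0, 40, -40, 0), beta = 0.95, gamma = 0.90)
  expect_equal(ti$center, 0)
  expect_equal(ti$sd, sqrt(800), tolerance = 1e-12)
  expect_equal(ti$k, 4.163656, tolerance = 1e-6)
  expect_equal(ti$upper, 117.766, tolerance = 1e-4)
  expect_equal(ti$lower, -ti$upper)
  expect_false(ti$degenerate)
})

test_that("degenerate and invalid difference sets are handled", {
  ti <- bcti(rep(0, 5), beta = 0.95, gamma = 0.90)
  expect_true(ti$degenerate)
  expect_equal(c(ti$lower, ti$center, ti$upper), c(0, 0, 0))
  expect_error(bcti(1), "at least 2")
})

test_that("BCTI is translation-equivariant", {
  set.seed(33)
  x <- rnorm(12)
  base <- bcti(x, 0.95, 0.90)
  for (c0 in c(-3, 0.5, 10)) {
    sh <- bcti(x + c0, 0.95, 0.90)
    expect_equal(sh$lower, base$lower + c0, tolerance = 1e-10)
    expect_equal(sh$upper, base$upper + c0, tolerance = 1e-10)
    expect_equal(sh$k, base$k)
  }
})

test_that("accuracy profiles nest across content levels", {
  set.seed(34)
  for (i in 1:5) {
    a <- sample(0:3, 60, replace = TRUE)
    b <- pmin(pmax(a + sample(-1:1, 60, replace = TRUE), 0), 3)
    prof <- accuracy_profile(paired_two_ops(a, b),
                             betas = c(0.67, 0.95), gamma = 0.90)
    e <- prof$entries[!prof$entries$insufficient, ]
    for (g in unique(e$group)) {
      lo <- e[e$group == g & e$beta == 0.67, ]
      hi <- e[e$group == g & e$beta == 0.95, ]
      expect_lte(hi$lower, lo$lower)
      expect_gte(hi$upper, lo$upper)
    }
  }
})

test_that("profiles report categories without enough pairs as insufficient", {
  # category 1 observed once only: no dispersion estimate possible
  prof <- accuracy_profile(paired_two_ops(c(0, 0, 1), c(0, 1, 1)),
                           betas = 0.95)
  e <- prof$entries
  expect_true(all(e$insufficient[e$group == "1"]))
  expect_false(any(e$insufficient[e$group == "0"]))
  # identical raters: every interval is a degenerate spike at zero
  prof0 <- accuracy_profile(paired_two_ops(c(2, 2, 3, 3), c(2, 2, 3, 3)))
  e0 <- prof0$entries
  expect_true(all(e0$center == 0 & e0$lower == 0 & e0$upper == 0))
  expect_true(all(e0$degenerate))
  # nothing estimable at all -> error
  expect_error(accuracy_profile(paired_two_ops(c(0, 1), c(0, 1))),
               ">= 2 complete pairs")
})

test_that("bias detection flags centres beyond the threshold", {
  mk_prof <- function(a, b) accuracy_profile(paired_two_ops(a, b),
                                             betas = c(0.67, 0.95))
  # no disagreement -> no bias
  b0 <- detect_bias(mk_prof(c(2, 2, 3, 3), c(2, 2, 3, 3)), 0.25)
  expect_false(b0$any_bias)
  expect_length(b0$opposing, 0)

  # opposing pulls at the moderate/strong boundary
  a <- c(rep(2, 6), rep(3, 6))
  b <- c(rep(3, 4), 2, 2, rep(2, 4), 3, 3)  # A=2 pulled up, A=3 pulled down
  br <- detect_bias(mk_prof(a, b), 0.25)
  flagged <- br$by_group[br$by_group$biased, ]
  expect_setequal(flagged$group, c("2", "3"))
  expect_equal(sign(flagged$center[flagged$group == "2"]), 1)
  expect_equal(sign(flagged$center[flagged$group == "3"]), -1)
  expect_length(br$opposing, 1)

  # a dominating threshold silences every flag
  expect_false(detect_bias(mk_prof(a, b), 10)$any_bias)
})

test_that("ISR pass rate counts differences within the limit", {
  r <- isr_pass_rate(c(0, 40, -40, 0, 0, 0), limit = 30)
  expect_equal(r$rate, 4 / 6)
  expect_true(r$pass)  # 4/6 meets the 2/3 acceptance rule exactly

  # perfect repeats pass any limit; a zero limit fails any nonzero repeat
  expect_equal(isr_pass_rate(rep(0, 8))$rate, 1)
  expect_equal(isr_pass_rate(c(0, 0, 1e-9), limit = 0)$rate, 2 / 3)

  expect_error(isr_pass_rate(numeric(0)), "no differences")
  d_abs <- compute_differences(paired_two_ops(2, 3), "absolute")$all
  expect_error(isr_pass_rate(d_abs), "percent-scale")
})
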