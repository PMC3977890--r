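# Seeded two-operator study simulator.

fixed_design <- function(count, seed = 5L)
  study_design(n_patients = 1, spots_per_patient = 1,
               ctc_per_spot_law = list(dist = "fixed", count = count),
               seed = seed)

test_that("operator models enforce the probability invariants", {
  expect_error(operator_model(matrix(0.25, 3, 3)), "4x4")
  bad <- diag(4); bad[1, 1] <- 0.9
  expect_error(operator_model(bad), "sum to 1")
  neg <- diag(4); neg[1, 2] <- -0.1; neg[1, 1] <- 1.1
  expect_error(operator_model(neg), "non-negative")
  expect_error(operator_model(diag(4), detection_prob = 0), "0, 1")
  expect_error(preset_scenario("mystery"))
})

test_that("preset confusion matrices carry the stated masses", {
  post <- preset_scenario("post_training")
  for (op in post) {
    m <- op$confusion
    expect_lte(max(m[row(m) != col(m)]), 0.05)
    expect_equal(rowSums(m), rep(1, 4), ignore_attr = TRUE)
  }
  pre <- preset_scenario("pre_training")
  mA <- pre$op_A$confusion
  mB <- pre$op_B$confusion
  # operator A reads true strong (3) down to moderate (2)...
  expect_equal(mA["3", "2"], 0.40)
  expect_equal(mA["3", "3"], 0.60)
  expect_gt(mA["3", "3"], mA["3", "2"])  # bias does not dominate the truth
  # ...while operator B reads true moderate up to strong
  expect_equal(mB["2", "3"], 0.40)
  expect_equal(mB["2", "2"], 0.55)
  # rows without a configured bias are identical across the operators
  expect_equal(mA[c("0", "1"), ], mB[c("0", "1"), ])
  expect_equal(rowSums(mA), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rowSums(mB), rep(1, 4), ignore_attr = TRUE)
})

test_that("identical seeds give byte-identical studies and leave the RNG alone", {
  ops <- preset_scenario("pre_training")
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_study(study_design(seed = 17), ops$op_A, ops$op_B,
                       runs = c("R1", "R2"))
  expect_identical(.Random.seed, before)  # caller's stream untouched
  s2 <- simulate_study(study_design(seed = 17), ops$op_A, ops$op_B,
                       runs = c("R1", "R2"))
  expect_identical(s1$scores, s2$scores)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(study_design(seed = 18), ops$op_A, ops$op_B)
  expect_false(identical(s1$truth, s3$truth))
})

test_that("study structure follows the design", {
  ops <- preset_scenario("post_training")
  st <- simulate_study(study_design(seed = 4), ops$op_A, ops$op_B,
                       runs = c("R1", "R2"))
  expect_equal(length(unique(st$scores$patient_id)), 8L)
  expect_equal(length(unique(st$scores$spot_id)), 4L)
  expect_setequal(unique(st$scores$run_id), c("R1", "R2"))
  # every object is scored by both operators in both runs
  expect_equal(nrow(st$scores), 4L * nrow(st$truth))
  # per-spot counts within the 0..30 law
  per_spot <- table(paste(st$truth$patient_id, st$truth$spot_id))
  expect_true(all(per_spot <= 30))
  # runs share the same objects and truths: the skeleton is drawn once
  r1 <- st$scores[st$scores$run_id == "R1" & st$scores$operator_id == "OP1", ]
  r2 <- st$scores[st$scores$run_id == "R2" & st$scores$operator_id == "OP1", ]
  expect_identical(r1$object_id, r2$object_id)
})

test_that("noise-free identity operators agree perfectly", {
  id <- operator_model(diag(4))
  st <- simulate_study(study_design(seed = 3), id, id)
  p <- pair_scores(st$scores, "operator", "OP1", "OP2")
  expect_equal(p$n_complete, p$n_pairs)
  expect_identical(p$pairs$score_A, p$pairs$score_B)
  expect_equal(cohens_kappa(build_contingency(p, 0:3))$kappa, 1)
})

test_that("truth-independent scoring yields kappa near zero", {
  u <- operator_model(matrix(0.25, 4, 4))
  st <- simulate_study(fixed_design(5000, seed = 11), u, u)
  p <- pair_scores(st$scores, "operator", "OP1", "OP2")
  expect_lt(abs(cohens_kappa(build_contingency(p, 0:3))$kappa), 0.05)
})

test_that("the simulator's empirical confusion recovers the generator", {
  ops <- preset_scenario("pre_training")
  st <- simulate_study(fixed_design(5000, seed = 42L), ops$op_A, ops$op_B)
  expect_lt(max(abs(empirical_confusion(st, "OP1") - ops$op_A$confusion)),
            0.02)
  expect_lt(max(abs(empirical_confusion(st, "OP2") - ops$op_B$confusion)),
            0.02)
})

test_that("imperfect detection produces missing, pairable records", {
  ops <- preset_scenario("post_training", detection_prob = 0.8)
  st <- simulate_study(fixed_design(400, seed = 9), ops$op_A, ops$op_B)
  expect_gt(sum(is.na(st$scores$score)), 0)
  p <- pair_scores(st$scores, "operator", "OP1", "OP2")
  expect_equal(p$unmatched_A + p$unmatched_B,
               sum(xor(is.na(p$pairs$score_A), is.na(p$pairs$score_B))))
  expect_lt(p$n_complete, p$n_pairs)
})

test_that("training presets reproduce the bias-then-correction pattern", {
  ops_pre <- preset_scenario("pre_training")
  ops_post <- preset_scenario("post_training")
  d <- study_design(seed = 42L)
  st_pre <- simulate_study(d, ops_pre$op_A, ops_pre$op_B)
  st_post <- simulate_study(d, ops_post$op_A, ops_post$op_B)
  kap <- function(st) {
    p <- pair_scores(st$scores, "operator", "OP1", "OP2")
    cohens_kappa(build_contingency(p, 0:3))$kappa
  }
  expect_gt(kap(st_post), kap(st_pre))
})

test_that("a study writes its sheet, truth sidecar and scenario echo", {
  ops <- preset_scenario("post_training")
  st <- simulate_study(fixed_design(50, seed = 2), ops$op_A, ops$op_B)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  expect_identical(read_scores(paths[["scores"]]), st$scores)
  meta <- yaml::read_yaml(paths[["scenario"]])
  expect_equal(meta$design$seed, 2)
})
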