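# Seeded simulator of two-operator ordinal scoring studies.
#
# Each candidate cell carries a latent true intensity in {0,1,2,3}; an
# operator is a row-stochastic 4x4 confusion matrix (truth -> reported
# score) plus a detection probability.  Real studies have no ground truth;
# the latent category exists only so the simulator's statistical structure
# (agreement level, per-category bias) is known and recoverable.

#' Operator scoring model
#'
#' @param confusion 4x4 row-stochastic matrix; entry `(t, s)` is the
#'   probability that an object of true intensity `t` (rows, 0..3) is
#'   scored `s` (columns, 0..3).  Rows must sum to 1 within 1e-12.
#' @param detection_prob Probability in (0, 1] that the operator detects
#'   (and therefore scores) a given object at all; undetected objects get
#'   a missing score.
#' @return An object of class `operator_model`.
#' @export
operator_model <- function(confusion, detection_prob = 1) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4L, 4L)))
    stop("confusion matrix must be 4x4 (intensity scale 0..3)", call. = FALSE)
  if (any(confusion < 0))
    stop("confusion matrix entries must be non-negative", call. = FALSE)
  if (any(abs(rowSums(confusion) - 1) > 1e-12))
    stop("confusion matrix rows must each sum to 1 (within 1e-12)",
         call. = FALSE)
  if (length(detection_prob) != 1 || is.na(detection_prob) ||
      detection_prob <= 0 || detection_prob > 1)
    stop("detection_prob must lie in (0, 1]", call. = FALSE)
  dimnames(confusion) <- list(truth = as.character(0:3),
                              score = as.character(0:3))
  structure(list(confusion = confusion, detection_prob = detection_prob),
            class = "operator_model")
}

#' @export
print.operator_model <- function(x, digits = 3, ...) {
  cat("Operator model (detection probability ", x$detection_prob, ")\n",
      sep = "")
  print(round(x$confusion, digits))
  invisible(x)
}

#' Preset operator pairs: before and after reader training
#'
#' Returns the two operator models of the package's canonical scenarios.
#' Both carry small symmetric adjacent-category confusion (`noise` to each
#' neighbouring grade).  In `"pre_training"` the operators additionally
#' hold opposing systematic biases at the moderate/strong boundary:
#' operator A moves a probability mass `bias_mass` from true strong (3) to
#' reported moderate (2), operator B moves the same mass from true
#' moderate (2) to reported strong (3).  `"post_training"` removes both
#' biases, leaving only the residual noise — the pattern of a reader pair
#' after standardisation against a common training image gallery.
#'
#' @param name `"pre_training"` or `"post_training"`.
#' @param bias_mass Biased probability mass (default 0.35).
#' @param noise Adjacent-category confusion probability (default 0.05).
#' @param detection_prob Detection probability of both operators.
#' @return List with elements `op_A` and `op_B` (class `operator_model`).
#' @export
preset_scenario <- function(name = c("pre_training", "post_training"),
                            bias_mass = 0.35, noise = 0.05,
                            detection_prob = 1) {
  name <- match.arg(name)
  stopifnot(noise >= 0, noise <= 0.25, bias_mass >= 0)
  base <- diag(4)
  for (t in 1:4) {
    adj <- intersect(c(t - 1, t + 1), 1:4)
    base[t, adj] <- noise
    base[t, t] <- 1 - noise * length(adj)
  }
  conf_A <- base
  conf_B <- base
  if (name == "pre_training") {
    if (base[4, 4] < bias_mass || base[3, 3] < bias_mass)
      stop("bias_mass too large for the given noise level", call. = FALSE)
    conf_A[4, 3] <- conf_A[4, 3] + bias_mass  # strong read down as moderate
    conf_A[4, 4] <- conf_A[4, 4] - bias_mass
    conf_B[3, 4] <- conf_B[3, 4] + bias_mass  # moderate read up as strong
    conf_B[3, 3] <- conf_B[3, 3] - bias_mass
  }
  list(op_A = operator_model(conf_A, detection_prob),
       op_B = operator_model(conf_B, detection_prob))
}

#' Study design for a simulated scoring experiment
#'
#' Defaults mirror a typical CTC reproducibility experiment: 4 filter
#' spots from each of 8 patient blood samples, with per-spot candidate
#' cell counts uniform on 0..30 (the observed range of CTC yields per ml)
#' and a flat distribution over true intensities.
#'
#' @param n_patients Number of patients (default 8).
#' @param spots_per_patient Filter spots per patient (default 4).
#' @param ctc_per_spot_law Per-spot object count law: either
#'   `list(dist = "uniform", min = 0, max = 30)` or
#'   `list(dist = "fixed", count = n)`.
#' @param truth_dist Probability vector over true intensities 0..3
#'   (default flat).
#' @param seed Integer seed making the whole study reproducible.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_patients = 8, spots_per_patient = 4,
                         ctc_per_spot_law = list(dist = "uniform",
                                                 min = 0, max = 30),
                         truth_dist = rep(0.25, 4), seed = 1L) {
  stopifnot(n_patients >= 1, spots_per_patient >= 1)
  if (length(truth_dist) != 4 || any(truth_dist < 0) ||
      abs(sum(truth_dist) - 1) > 1e-9)
    stop("truth_dist must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  law <- ctc_per_spot_law
  if (is.null(law$dist) || !law$dist %in% c("uniform", "fixed"))
    stop("ctc_per_spot_law$dist must be 'uniform' or 'fixed'", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 spots_per_patient = as.integer(spots_per_patient),
                 ctc_per_spot_law = law,
                 truth_dist = truth_dist,
                 seed = as.integer(seed)),
            class = "study_design")
}

draw_counts <- function(law, n_spots) {
  switch(law$dist,
         uniform = sample(seq.int(law$min, law$max), n_spots, replace = TRUE),
         fixed = rep(as.integer(law$count), n_spots))
}

draw_scores <- function(truth, confusion) {
  scores <- integer(length(truth))
  for (t in 0:3) {
    idx <- which(truth == t)
    if (length(idx))
      scores[idx] <- sample(0:3, length(idx), replace = TRUE,
                            prob = confusion[t + 1, ])
  }
  scores
}

#' Simulate a two-operator scoring study
#'
#' Draws the study skeleton once — per-spot object counts from the design
#' law and a latent true intensity per object — then, for every requested
#' run, lets each operator score every object independently through its
#' confusion matrix.  Runs therefore share the identical physical samples
#' (the situation of a repeat validation experiment on the same filters)
#' while operator noise is fresh per run.  Objects an operator fails to
#' detect get a missing score.  The whole draw is a deterministic function
#' of the design seed; the caller's random number stream is left intact.
#'
#' @param design A [study_design()].
#' @param op_A,op_B [operator_model()]s for the two operators.
#' @param operators Labels of the two operators in the output records.
#' @param runs Character vector of run labels (default a single run
#'   `"R1"`).
#' @return An object of class `simulated_study`: list with `scores` (a
#'   score-record data frame with both operators and all runs), `truth`
#'   (object key plus `true_score` sidecar), and the generating `design`,
#'   `op_A`, `op_B`, `operators`, `runs`.
#' @export
simulate_study <- function(design, op_A, op_B,
                           operators = c("OP1", "OP2"), runs = "R1") {
  stopifnot(inherits(design, "study_design"),
            inherits(op_A, "operator_model"),
            inherits(op_B, "operator_model"),
            length(operators) == 2, length(runs) >= 1,
            !anyDuplicated(runs), operators[1] != operators[2])
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(design$seed)

  n_spots <- design$n_patients * design$spots_per_patient
  counts <- draw_counts(design$ctc_per_spot_law, n_spots)
  spot_idx <- rep(seq_len(n_spots), counts)
  n_obj <- sum(counts)
  if (n_obj == 0)
    stop("design produced no objects (all spot counts 0)", call. = FALSE)
  patient <- sprintf("P%02d", (spot_idx - 1L) %/% design$spots_per_patient + 1L)
  spot <- sprintf("S%d", (spot_idx - 1L) %% design$spots_per_patient + 1L)
  object <- sprintf("C%03d", sequence(counts))
  truth <- sample(0:3, n_obj, replace = TRUE, prob = design$truth_dist)

  ops <- list(op_A, op_B)
  rec <- vector("list", 2L * length(runs))
  i <- 0L
  for (run in runs) {
    for (j in 1:2) {
      op <- ops[[j]]
      score <- draw_scores(truth, op$confusion)
      detected <- stats::runif(n_obj) <= op$detection_prob
      score[!detected] <- NA_integer_
      i <- i + 1L
      rec[[i]] <- data.frame(
        patient_id = patient, spot_id = spot, object_id = object,
        operator_id = operators[j], run_id = run, score = score,
        stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rec)
  rownames(scores) <- NULL
  truth_df <- data.frame(patient_id = patient, spot_id = spot,
                         object_id = object, true_score = truth,
                         stringsAsFactors = FALSE)
  structure(list(scores = validate_scores(scores), truth = truth_df,
                 design = design, op_A = op_A, op_B = op_B,
                 operators = operators, runs = runs),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated scoring study: ", x$design$n_patients, " patients x ",
      x$design$spots_per_patient, " spots, ", nrow(x$truth),
      " objects, operators ", paste(x$operators, collapse = "/"),
      ", runs ", paste(x$runs, collapse = "/"),
      ", seed ", x$design$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits the scoring sheet (`scores.csv`, canonical dialect), the latent
#' truth sidecar (`truth.csv`) and the scenario parameters
#' (`scenario.yaml`) into a directory.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(scores = file.path(dir, "scores.csv"),
             truth = file.path(dir, "truth.csv"),
             scenario = file.path(dir, "scenario.yaml"))
  write_scores(study$scores, paths[["scores"]])
  utils::write.csv(study$truth, paths[["truth"]], row.names = FALSE,
                   fileEncoding = "UTF-8")
  meta <- list(
    design = list(n_patients = study$design$n_patients,
                  spots_per_patient = study$design$spots_per_patient,
                  ctc_per_spot_law = study$design$ctc_per_spot_law,
                  truth_dist = study$design$truth_dist,
                  seed = study$design$seed),
    operators = as.list(stats::setNames(study$operators, c("A", "B"))),
    runs = as.list(study$runs),
    op_A = list(confusion = apply(study$op_A$confusion, 1, as.list),
                detection_prob = study$op_A$detection_prob),
    op_B = list(confusion = apply(study$op_B$confusion, 1, as.list),
                detection_prob = study$op_B$detection_prob))
  writeLines(yaml::as.yaml(meta), paths[["scenario"]])
  invisible(paths)
}

#' Empirical confusion matrix of a simulated operator
#'
#' Cross-tabulates one operator's reported scores in one run against the
#' latent truth and row-normalises, estimating the generating confusion
#' matrix; used to check that the simulator has the statistical structure
#' it claims.
#'
#' @param study A [simulate_study()] result.
#' @param operator Operator label.
#' @param run Run label (default the first run).
#' @return 4x4 row-stochastic matrix (rows: truth 0..3; columns: score).
#' @export
empirical_confusion <- function(study, operator, run = study$runs[1]) {
  stopifnot(inherits(study, "simulated_study"))
  sc <- study$scores
  sc <- sc[sc$operator_id == operator & sc$run_id == run, , drop = FALSE]
  if (!nrow(sc)) stop("no records for that operator/run", call. = FALSE)
  m <- merge(sc, study$truth, by = c("patient_id", "spot_id", "object_id"))
  m <- m[!is.na(m$score), , drop = FALSE]
  tab <- table(factor(m$true_score, levels = 0:3),
               factor(m$score, levels = 0:3))
  out <- sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
  dimnames(out) <- list(truth = as.character(0:3), score = as.character(0:3))
  out
}
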