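# Orchestration of the full validation workflow: pairing, binary and
# intensity agreement, accuracy profiles, bias detection and the ISR
# benchmark, for every configured run and operator, with report tables.

#' Configuration of a validation analysis
#'
#' Exactly one input mode is active: `scores` (a scoring-sheet path or a
#' score-record data frame) or `simulate` (a scenario description, see
#' Details).  All statistical knobs carry the package defaults: content
#' levels 0.67 and 0.95, confidence 0.90, absolute difference scale,
#' quarter-category bias threshold, and the 2/3-within-30-percent ISR
#' rule.
#'
#' @details
#' `simulate` is a list with elements `scenario` (`"pre_training"` or
#' `"post_training"`, or a list with `op_A`/`op_B` operator models),
#' optionally `design` (a [study_design()]; default the 8-patient,
#' 4-spot design) and `runs` (default `c("R1", "R2")`).
#'
#' @param scores Scoring-sheet path or data frame, or `NULL`.
#' @param simulate Simulation scenario list, or `NULL`.
#' @param operators Length-2 operator labels; defaults to the two
#'   operators present (files) or `c("OP1", "OP2")` (simulation).
#' @param runs Run labels to analyse; default all runs present.
#' @param betas,gamma Tolerance-interval content and confidence levels.
#' @param scale Difference scale for the inter-operator profiles.
#' @param positive_threshold Minimum score counted positive in the binary
#'   evaluation.
#' @param bias_threshold Bias flag threshold, see [detect_bias()].
#' @param isr_limit,isr_min_fraction ISR acceptance rule, see
#'   [isr_pass_rate()].
#' @param seed Seed overriding the design seed in simulation mode.
#' @return An object of class `validation_config`.
#' @export
validation_config <- function(scores = NULL, simulate = NULL,
                              operators = NULL, runs = NULL,
                              betas = c(0.67, 0.95), gamma = 0.90,
                              scale = "absolute", positive_threshold = 1,
                              bias_threshold = 0.25, isr_limit = 30,
                              isr_min_fraction = 2 / 3, seed = NULL) {
  if (is.null(scores) == is.null(simulate))
    stop("exactly one input mode must be set: 'scores' or 'simulate'",
         call. = FALSE)
  stopifnot(all(betas > 0 & betas < 1), gamma > 0, gamma < 1,
            scale %in% c("absolute", "percent"))
  structure(list(scores = scores, simulate = simulate,
                 operators = operators, runs = runs,
                 betas = sort(betas), gamma = gamma, scale = scale,
                 positive_threshold = positive_threshold,
                 bias_threshold = bias_threshold, isr_limit = isr_limit,
                 isr_min_fraction = isr_min_fraction,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "validation_config")
}

resolve_records <- function(config) {
  if (!is.null(config$scores)) {
    rec <- if (is.character(config$scores)) read_scores(config$scores)
           else validate_scores(config$scores)
    return(list(records = rec, study = NULL))
  }
  sim <- config$simulate
  ops <- if (is.character(sim$scenario))
    preset_scenario(sim$scenario)
  else if (is.list(sim$scenario) && !is.null(sim$scenario$op_A))
    sim$scenario
  else stop("simulate$scenario must be a preset name or op_A/op_B models",
            call. = FALSE)
  design <- if (!is.null(sim$design)) sim$design else study_design()
  if (!is.null(config$seed)) design$seed <- config$seed
  runs <- if (!is.null(sim$runs)) sim$runs else c("R1", "R2")
  operators <- if (!is.null(config$operators)) config$operators
               else c("OP1", "OP2")
  study <- simulate_study(design, ops$op_A, ops$op_B,
                          operators = operators, runs = runs)
  list(records = study$scores, study = study)
}

#' Run the full scoring-validation workflow
#'
#' For every configured run, pairs the two operators' calls on the shared
#' objects and computes (i) the binary positive/negative agreement and
#' (ii) the full intensity-scale agreement, each as a contingency table
#' plus Cohen's kappa; then the per-category accuracy profile and its
#' bias report.  When at least two runs are present, each operator's
#' calls are additionally paired across the first two runs (conventional
#' incurred sample reanalysis): percent-scale differences are judged
#' against the ISR limit and summarised as a percent-scale profile.
#' Bias findings are results, not failures — only unusable inputs raise
#' errors.
#'
#' @param config A [validation_config()].
#' @return An object of class `validation_report`: `agreement` (long
#'   data frame: run, evaluation, n, pr_a, pr_e, kappa,
#'   percent_agreement, band), `tables` (the archived contingency
#'   tables), `profiles`, `bias`, `isr`, `isr_profiles`, `unmatched`
#'   (pairing bookkeeping per run), and a `provenance` block.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "validation_config"))
  inputs <- resolve_records(config)
  records <- inputs$records

  operators <- config$operators
  if (is.null(operators)) {
    operators <- if (!is.null(inputs$study)) inputs$study$operators
                 else sort(unique(records$operator_id))
    if (length(operators) != 2)
      stop("found ", length(operators), " operators; supply the pair to ",
           "compare via 'operators'", call. = FALSE)
  }
  runs <- config$runs
  if (is.null(runs)) runs <- sort(unique(records$run_id))

  agreement <- list()
  tables <- list()
  profiles <- list()
  bias <- list()
  unmatched <- list()

  for (run in runs) {
    rr <- records[records$run_id == run, , drop = FALSE]
    paired <- pair_scores(rr, "operator", operators[1], operators[2])
    unmatched[[run]] <- data.frame(
      run = run, n_pairs = paired$n_pairs, n_complete = paired$n_complete,
      unmatched_A = paired$unmatched_A, unmatched_B = paired$unmatched_B)

    bin <- collapse_to_binary(paired, config$positive_threshold)
    tab_bin <- build_contingency(bin, categories = 0:1)
    tab_int <- build_contingency(paired, categories = 0:3)
    k_bin <- cohens_kappa(tab_bin)
    k_int <- cohens_kappa(tab_int)
    tables[[run]] <- list(positive_vs_negative = tab_bin,
                          staining_intensity = tab_int)
    agreement[[run]] <- data.frame(
      run = run,
      evaluation = c("positive_vs_negative", "staining_intensity"),
      n = c(k_bin$n, k_int$n),
      pr_a = c(k_bin$pr_a, k_int$pr_a),
      pr_e = c(k_bin$pr_e, k_int$pr_e),
      kappa = c(k_bin$kappa, k_int$kappa),
      percent_agreement = c(k_bin$percent_agreement,
                            k_int$percent_agreement),
      band = c(k_bin$band, k_int$band))

    profiles[[run]] <- accuracy_profile(
      paired, betas = config$betas, gamma = config$gamma,
      scale = config$scale, comparison = "inter-operator")
    bias[[run]] <- detect_bias(profiles[[run]], config$bias_threshold)
  }

  isr <- list()
  isr_profiles <- list()
  if (length(runs) >= 2) {
    for (op in operators) {
      ro <- records[records$operator_id == op, , drop = FALSE]
      paired_runs <- pair_scores(ro, "run", runs[1], runs[2])
      d <- compute_differences(paired_runs, scale = "percent")
      isr[[op]] <- isr_pass_rate(d$all, limit = config$isr_limit,
                                 min_fraction = config$isr_min_fraction)
      isr_profiles[[op]] <- accuracy_profile(
        paired_runs, betas = config$betas, gamma = config$gamma,
        scale = "percent", comparison = "inter-run")
    }
  }

  provenance <- list(
    package = "ihcval",
    version = as.character(utils::packageVersion("ihcval")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    operators = operators, runs = runs,
    betas = config$betas, gamma = config$gamma, scale = config$scale,
    positive_threshold = config$positive_threshold,
    bias_threshold = config$bias_threshold,
    isr_limit = config$isr_limit,
    isr_min_fraction = config$isr_min_fraction,
    seed = if (!is.null(inputs$study)) inputs$study$design$seed
           else config$seed,
    input_mode = if (is.null(config$simulate)) "files" else "simulate",
    scenario = if (!is.null(config$simulate) &&
                   is.character(config$simulate$scenario))
      config$simulate$scenario,
    caveat = paste("normal-theory tolerance factors applied to discrete",
                   "score differences; interval contents are approximate"))

  structure(list(agreement = do.call(rbind, agreement),
                 tables = tables, profiles = profiles, bias = bias,
                 isr = isr, isr_profiles = isr_profiles,
                 unmatched = do.call(rbind, unmatched),
                 config = config, provenance = provenance,
                 study = inputs$study),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  cat("IHC scoring validation report\n")
  cat("=============================\n")
  ag <- x$agreement
  ag$kappa <- round(ag$kappa, digits)
  ag$pr_a <- round(ag$pr_a, digits)
  ag$pr_e <- round(ag$pr_e, digits)
  ag$percent_agreement <- round(ag$percent_agreement, 1)
  print(ag, row.names = FALSE)
  for (run in names(x$bias)) {
    b <- x$bias[[run]]
    cat("\nRun ", run, ": ", sep = "")
    if (b$any_bias) {
      flagged <- b$by_group[b$by_group$biased, , drop = FALSE]
      cat("bias flagged at category(ies) ",
          paste(flagged$group, collapse = ", "), "\n", sep = "")
      if (length(b$opposing))
        cat(paste0("  ", b$opposing, "\n"), sep = "")
    } else cat("no operator bias beyond ", b$threshold,
               " score units\n", sep = "")
  }
  if (length(x$isr)) {
    cat("\nConventional ISR between runs:\n")
    for (op in names(x$isr)) {
      r <- x$isr[[op]]
      cat(sprintf("  %s: %.1f%% within +/-%g%% (n = %d): %s\n", op,
                  100 * r$rate, r$limit, r$n,
                  if (r$pass) "PASS" else "FAIL"))
    }
  }
  invisible(x)
}

profile_frame <- function(profile, stratum) {
  e <- as.data.frame(profile)
  flags <- ifelse(e$insufficient, "insufficient_n",
                  ifelse(e$degenerate, "degenerate", ""))
  data.frame(comparison = e$comparison, stratum = stratum,
             group = e$group, beta = e$beta, gamma = e$gamma, n = e$n,
             center = e$center, sd = e$sd, k = e$k,
             lower = e$lower, upper = e$upper, scale = e$scale,
             flags = flags)
}

#' Render a validation report to CSV tables
#'
#' Writes the report as plain-text artifacts into a directory:
#' `agreement.csv` (rows: evaluation level; per-run kappa and percent
#' agreement columns), `agreement_long.csv`, `profiles.csv` (long format,
#' one row per stratum, category and content level, including explicit
#' insufficient-n rows), `bias.csv`, `isr.csv` (when two runs are
#' present), `unmatched.csv` and `provenance.yaml`.  Output is a pure
#' function of the report, so a rerun on the same configuration and seed
#' reproduces every file byte for byte.
#'
#' @param report A [run_validation()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
    paths[[name]] <<- p
  }

  ag <- report$agreement
  wide <- data.frame(evaluation = unique(ag$evaluation))
  for (run in unique(ag$run)) {
    sub <- ag[ag$run == run, , drop = FALSE]
    idx <- match(wide$evaluation, sub$evaluation)
    wide[[paste0("kappa_", run)]] <- sub$kappa[idx]
    wide[[paste0("pct_agreement_", run)]] <- sub$percent_agreement[idx]
  }
  wcsv(wide, "agreement.csv")
  wcsv(ag, "agreement_long.csv")

  prof <- do.call(rbind, c(
    lapply(names(report$profiles), function(run)
      profile_frame(report$profiles[[run]], run)),
    lapply(names(report$isr_profiles), function(op)
      profile_frame(report$isr_profiles[[op]], op))))
  wcsv(prof, "profiles.csv")

  bias <- do.call(rbind, lapply(names(report$bias), function(run) {
    b <- report$bias[[run]]
    data.frame(run = run, b$by_group, threshold = b$threshold,
               opposing_pattern = length(b$opposing) > 0)
  }))
  wcsv(bias, "bias.csv")

  if (length(report$isr)) {
    isr <- do.call(rbind, lapply(names(report$isr), function(op) {
      r <- report$isr[[op]]
      data.frame(operator = op, n = r$n, limit = r$limit,
                 min_fraction = r$min_fraction, rate = r$rate,
                 pass = r$pass)
    }))
    wcsv(isr, "isr.csv")
  }
  wcsv(report$unmatched, "unmatched.csv")

  p <- file.path(dir, "provenance.yaml")
  writeLines(yaml::as.yaml(report$provenance), p)
  paths[["provenance.yaml"]] <- p
  invisible(unlist(paths))
}
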