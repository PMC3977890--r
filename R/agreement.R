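# Categorical agreement statistics for paired ordinal calls.

#' Cross-tabulate paired categorical calls
#'
#' Builds the K x K contingency table of side-A categories (rows) against
#' side-B categories (columns) from matched pairs.
#'
#' @param paired A [pair_scores()] result.
#' @param categories Ordered vector of category labels covering every
#'   observed score (default the 0..3 intensity scale).
#' @param complete_only If `TRUE` (default) pairs with a missing side are
#'   excluded.  If `FALSE`, missing calls become an explicit extra `"ND"`
#'   (not detected) category, so a cell scored by only one side counts as
#'   a disagreement — the enumeration-level reading of the data.
#' @return An object of class `contingency_table`: list with `categories`,
#'   integer `counts` matrix, total `n`, and the side labels.
#' @export
build_contingency <- function(paired, categories = score_levels,
                              complete_only = TRUE) {
  stopifnot(inherits(paired, "paired_scores"))
  if (length(categories) < 2L)
    stop("need at least 2 categories", call. = FALSE)
  a <- paired$pairs$score_A
  b <- paired$pairs$score_B
  if (complete_only) {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    levs <- as.character(categories)
    fa <- factor(as.character(a), levels = levs)
    fb <- factor(as.character(b), levels = levs)
  } else {
    levs <- c(as.character(categories), "ND")
    fa <- factor(ifelse(is.na(a), "ND", as.character(a)), levels = levs)
    fb <- factor(ifelse(is.na(b), "ND", as.character(b)), levels = levs)
  }
  if (!length(fa))
    stop("no pairs to tabulate (empty contingency table)", call. = FALSE)
  if (anyNA(fa) || anyNA(fb))
    stop("observed score outside the supplied categories", call. = FALSE)
  counts <- table(A = fa, B = fb)
  counts <- matrix(as.integer(counts), nrow = length(levs),
                   dimnames = list(A = levs, B = levs))
  structure(list(categories = levs, counts = counts, n = sum(counts),
                 side_A = paired$side_A, side_B = paired$side_B),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table (rows: ", x$side_A, ", cols: ", x$side_B,
      "), n = ", x$n, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Cohen's kappa for a contingency table
#'
#' Chance-corrected agreement kappa = (Pr(a) - Pr(e)) / (1 - Pr(e)), where
#' Pr(a) is the observed agreement fraction (diagonal mass) and Pr(e) the
#' chance agreement obtained from the marginal probabilities of each rater
#' assigning each category: Pr(e) = sum_k (row_k/n)(col_k/n).
#'
#' @param table A [build_contingency()] result, or a square counts matrix.
#' @return An object of class `kappa_agreement`: `pr_a`, `pr_e`, `kappa`,
#'   `percent_agreement` (= 100 Pr(a)), the interpretive `band`
#'   (see [interpret_kappa()]), `n` and the table.
#' @examples
#' cohens_kappa(matrix(c(20, 10, 5, 15), 2))  # kappa = 0.40
#' @export
cohens_kappa <- function(table) {
  if (is.matrix(table))
    table <- structure(list(categories = as.character(seq_len(nrow(table))),
                            counts = table, n = sum(table),
                            side_A = "A", side_B = "B"),
                       class = "contingency_table")
  stopifnot(inherits(table, "contingency_table"))
  counts <- table$counts
  if (nrow(counts) != ncol(counts))
    stop("contingency table must be square", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("empty contingency table", call. = FALSE)
  pr_a <- sum(diag(counts)) / n
  pr_e <- sum((rowSums(counts) / n) * (colSums(counts) / n))
  if (pr_e >= 1 - .Machine$double.eps^0.5)
    stop("kappa undefined: both raters are degenerate on a single ",
         "category, so chance agreement Pr(e) = 1", call. = FALSE)
  kappa <- (pr_a - pr_e) / (1 - pr_e)
  structure(list(pr_a = pr_a, pr_e = pr_e, kappa = kappa,
                 percent_agreement = 100 * pr_a,
                 band = interpret_kappa(kappa), n = n, table = table),
            class = "kappa_agreement")
}

#' @export
print.kappa_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("Cohen's kappa = %.*f (%s agreement), %% agreement = %.1f, n = %d\n",
              digits, x$kappa, x$band, x$percent_agreement, x$n))
  cat(sprintf("  Pr(a) = %.*f, Pr(e) = %.*f\n", digits, x$pr_a,
              digits, x$pr_e))
  invisible(x)
}

#' Collapse intensity calls to a binary positive/negative evaluation
#'
#' Maps intensity scores at or above `positive_threshold` to 1 (positive)
#' and below it to 0 (negative), mirroring the overall
#' positive-versus-negative evaluation of a stained cell.  Missing calls
#' stay missing by default; `missing_as = "negative"` instead treats an
#' undetected object as a negative call, so that detection discrepancies
#' count as binary disagreements.
#'
#' @param paired A `paired_scores` object.
#' @param positive_threshold Minimum score counted as positive (default 1,
#'   i.e. any visible staining).
#' @param missing_as `"missing"` (default) or `"negative"`.
#' @return A `paired_scores` object on the 0/1 scale.
#' @export
collapse_to_binary <- function(paired, positive_threshold = 1,
                               missing_as = c("missing", "negative")) {
  stopifnot(inherits(paired, "paired_scores"))
  missing_as <- match.arg(missing_as)
  out <- paired
  map <- function(s) {
    v <- as.integer(!is.na(s) & s >= positive_threshold)
    if (missing_as == "missing") v[is.na(s)] <- NA_integer_
    v
  }
  out$pairs$score_A <- map(paired$pairs$score_A)
  out$pairs$score_B <- map(paired$pairs$score_B)
  out$unmatched_A <- sum(is.na(out$pairs$score_A))
  out$unmatched_B <- sum(is.na(out$pairs$score_B))
  out$n_complete <- sum(!is.na(out$pairs$score_A) & !is.na(out$pairs$score_B))
  out
}

#' Interpret a kappa value on the Landis-Koch scale
#'
#' Maps kappa to the conventional verbal agreement bands: below 0 poor,
#' 0-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial, 0.81-1.00 almost perfect.  Band boundaries are closed on
#' the upper end, so 0.80 is "substantial" and 0.81 "almost perfect".
#'
#' @param kappa Numeric vector of kappa values (each at most 1).
#' @return Character vector of band labels.
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(is.numeric(kappa), all(kappa <= 1 + 1e-12))
  cuts <- c(-Inf, 0, 0.20, 0.40, 0.60, 0.80, 1 + 1e-12)
  bands <- c("poor", "slight", "fair", "moderate", "substantial",
             "almost perfect")
  # kappa exactly 0 belongs to "slight" (the 0-0.20 band)
  idx <- findInterval(kappa, cuts, left.open = TRUE, rightmost.closed = TRUE)
  idx[kappa == 0] <- 2L
  bands[idx]
}
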