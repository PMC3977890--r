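# Scoring-sheet data model and I/O.
#
# A scoring sheet holds one row per candidate circulating tumour cell (CTC)
# per operator per run.  The staining-intensity call uses the ordinal IHC
# scale 0 (negative), 1 (weak), 2 (moderate), 3 (strong); an empty score
# means the operator did not detect / did not score that object, which is a
# distinct state from a real negative call of 0.

#' Required columns of a scoring sheet
#'
#' Column order and names of the canonical comma-separated scoring-sheet
#' interchange format: one row per candidate cell per operator per run,
#' header mandatory, empty score cell = missing (not detected / not scored).
#'
#' @format Character vector of column names.
#' @export
score_columns <- c("patient_id", "spot_id", "object_id",
                   "operator_id", "run_id", "score")

#' @keywords internal
score_levels <- 0:3

id_columns <- score_columns[1:5]

# Internal key for one physical object (candidate cell) on a filter spot.
object_key <- function(df) {
  paste(df$patient_id, df$spot_id, df$object_id, sep = "\x1f")
}

#' Validate a scoring-sheet data frame
#'
#' Checks the invariants of the score-record model: required columns
#' present, identifier fields non-empty, scores integer in 0..3 or `NA`,
#' and the (patient, spot, object, operator, run) key unique.  Identifier
#' columns are coerced to character and the score to integer.
#'
#' @param records Data frame with the columns in [score_columns].
#' @param rows Optional integer vector of source row numbers (e.g. file
#'   line numbers) used in diagnostics; defaults to `seq_len(nrow(records))`.
#' @return The validated, normalised data frame (invisibly usable as
#'   score records).
#' @export
validate_scores <- function(records, rows = NULL) {
  if (!is.data.frame(records))
    stop("score records must be a data frame", call. = FALSE)
  missing_cols <- setdiff(score_columns, names(records))
  if (length(missing_cols))
    stop("scoring sheet is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- records[score_columns]
  if (is.null(rows)) rows <- seq_len(nrow(records))

  for (col in id_columns) {
    v <- trimws(as.character(records[[col]]))
    bad <- is.na(v) | v == ""
    if (any(bad))
      stop("malformed (empty) ", col, " in row(s): ",
           paste(rows[bad], collapse = ", "), call. = FALSE)
    records[[col]] <- v
  }

  s <- records$score
  if (is.character(s)) {
    s <- trimws(s)
    s[s == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(s))
    bad <- !is.na(s) & is.na(parsed)
    if (any(bad))
      stop("non-numeric score in row(s): ",
           paste(rows[bad], collapse = ", "), call. = FALSE)
    s <- parsed
  }
  s <- as.numeric(s)
  bad <- !is.na(s) & (s %% 1 != 0 | s < min(score_levels) | s > max(score_levels))
  if (any(bad))
    stop("score outside {", paste(score_levels, collapse = ","),
         "} in row(s): ", paste(rows[bad], collapse = ", "), call. = FALSE)
  records$score <- as.integer(s)

  key <- paste(object_key(records), records$operator_id, records$run_id,
               sep = "\x1f")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (patient, spot, object, operator, run) record(s) at row(s): ",
         paste(rows[dup], collapse = ", "), call. = FALSE)
  rownames(records) <- NULL
  records
}

#' Read a scoring sheet
#'
#' Reads a comma-separated scoring sheet (UTF-8, mandatory header with the
#' columns in [score_columns], empty score cell = missing) and validates
#' every row.  Malformed rows are reported with their file line numbers
#' (the header is line 1).
#'
#' @param path Path to a CSV scoring sheet.
#' @return Validated data frame of score records.
#' @seealso [write_scores()], [pair_scores()]
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(), check.names = TRUE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(score_columns, names(raw))
  if (length(missing_cols))
    stop("scoring sheet ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  validate_scores(raw, rows = seq_len(nrow(raw)) + 1L)
}

#' Write a scoring sheet
#'
#' Writes score records as CSV in the canonical dialect; missing scores
#' become empty cells.  `read_scores(write_scores(x, f))` reproduces `x`.
#'
#' @param records Data frame of score records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(records, path) {
  records <- validate_scores(records)
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair scores for the same objects from two sides
#'
#' Matches the calls of two sides — two operators within one run (the
#' modified incurred-sample-reanalysis design, where a pair of operators
#' reading the same samples once stands in for one operator reading them
#' twice) or two runs of one operator (conventional ISR) — on the shared
#' object key (patient, spot, object).  Objects scored on only one side
#' appear as pairs with one missing score and are tallied in the unmatched
#' counts; objects with a missing score on both sides are dropped (and
#' counted), so every retained pair has at least one real call.
#'
#' @param records Data frame of score records.  When pairing operators the
#'   records must come from a single run (and vice versa); mixed strata
#'   violate the one-record-per-object precondition and raise an error.
#' @param side_key `"operator"` or `"run"`: which identifier distinguishes
#'   the two sides.
#' @param side_A,side_B Labels of the two sides (side A is the reference).
#' @return An object of class `paired_scores`: a list with `pairs` (data
#'   frame with `patient_id`, `spot_id`, `object_id`, `score_A`, `score_B`),
#'   side labels, and the unmatched tallies `unmatched_A` / `unmatched_B`
#'   (objects with no call from side A resp. side B).
#' @examples
#' rec <- expand.grid(patient_id = "P1", spot_id = "S1",
#'                    object_id = c("c1", "c2"),
#'                    operator_id = c("OP1", "OP2"), run_id = "R1",
#'                    stringsAsFactors = FALSE)
#' rec$score <- c(2L, 3L, 2L, 2L)
#' pair_scores(rec, "operator", "OP1", "OP2")
#' @export
pair_scores <- function(records, side_key = c("operator", "run"),
                        side_A, side_B) {
  side_key <- match.arg(side_key)
  records <- validate_scores(records)
  side_col <- paste0(side_key, "_id")
  other_col <- if (side_key == "operator") "run_id" else "operator_id"

  take_side <- function(label) {
    side <- records[records[[side_col]] == label, , drop = FALSE]
    if (!nrow(side))
      stop("no records for ", side_key, " '", label, "'", call. = FALSE)
    if (length(unique(side[[other_col]])) > 1L)
      stop("records for ", side_key, " '", label, "' span several ",
           other_col, " values; subset to one before pairing", call. = FALSE)
    key <- object_key(side)
    dup <- key[duplicated(key)]
    if (length(dup))
      stop("ambiguous pairing: duplicate records for ", side_key, " '",
           label, "' on object(s) ",
           paste(unique(gsub("\x1f", "/", dup)), collapse = ", "),
           call. = FALSE)
    side$`.key` <- key
    side
  }
  a <- take_side(side_A)
  b <- take_side(side_B)

  merged <- merge(a[c(".key", id_columns[1:3], "score")],
                  b[c(".key", "score")],
                  by = ".key", all = TRUE, suffixes = c("_A", "_B"))
  # fill object ids for objects seen on side B only
  only_b <- is.na(merged$patient_id)
  if (any(only_b)) {
    idx <- match(merged$`.key`[only_b], b$`.key`)
    for (col in id_columns[1:3]) merged[[col]][only_b] <- b[[col]][idx]
  }
  both_missing <- is.na(merged$score_A) & is.na(merged$score_B)
  merged <- merged[!both_missing, , drop = FALSE]
  if (!nrow(merged))
    stop("no pairable objects with at least one score", call. = FALSE)
  merged <- merged[order(merged$patient_id, merged$spot_id,
                         merged$object_id), , drop = FALSE]
  pairs <- merged[c(id_columns[1:3], "score_A", "score_B")]
  rownames(pairs) <- NULL

  structure(list(
    pairs = pairs,
    side_key = side_key,
    side_A = side_A,
    side_B = side_B,
    unmatched_A = sum(is.na(pairs$score_A)),
    unmatched_B = sum(is.na(pairs$score_B)),
    n_pairs = nrow(pairs),
    n_complete = sum(!is.na(pairs$score_A) & !is.na(pairs$score_B)),
    n_dropped_both_missing = sum(both_missing)
  ), class = "paired_scores")
}

#' @export
print.paired_scores <- function(x, ...) {
  cat("Paired scores (", x$side_key, "s): ", x$side_A, " (A) vs ",
      x$side_B, " (B)\n", sep = "")
  cat("  pairs:", x$n_pairs, " complete:", x$n_complete,
      " unmatched A/B:", x$unmatched_A, "/", x$unmatched_B, "\n")
  if (x$n_dropped_both_missing)
    cat("  dropped (missing on both sides):", x$n_dropped_both_missing, "\n")
  invisible(x)
}

#' @export
as.data.frame.paired_scores <- function(x, ...) x$pairs

#' Export paired scores
#'
#' Writes the pair table as CSV with columns `object_key`, `score_A`,
#' `score_B` (missing score = empty cell).
#'
#' @param paired A `paired_scores` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(paired, path) {
  stopifnot(inherits(paired, "paired_scores"))
  p <- paired$pairs
  out <- data.frame(
    object_key = paste(p$patient_id, p$spot_id, p$object_id, sep = "/"),
    score_A = p$score_A, score_B = p$score_B)
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
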