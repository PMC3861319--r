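#' Identifier-level evaluation counts
#'
#' Builds an evaluation result from raw true-positive / false-positive /
#' false-negative counts. Precision is `100 * tp / (tp + fp)`, recall
#' `100 * tp / (tp + fn)` (each defined as 0 when its denominator is 0),
#' and the F-score is the harmonic mean `2PR / (P + R)` of the unrounded
#' precision and recall (0 when both are 0). Unrounded percentages are the
#' API contract; the print method displays them rounded half-up to one
#' decimal.
#'
#' @param tp,fp,fn Nonnegative integer counts.
#' @return Object of class `gn_eval`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `fscore` (percentages in \[0, 100\]).
#' @export
#' @examples
#' eval_counts(723, 98, 62)  # precision 88.1, recall 92.1
eval_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), precision = precision,
                 recall = recall, fscore = fscore),
            class = "gn_eval")
}

#' Score predictions against a gold standard
#'
#' Identifier-level scoring: both sides are reduced to sets of
#' (document id, gene id) pairs; `tp` is the size of the intersection,
#' `fp` of predictions outside gold, `fn` of gold pairs missed. Mention
#' text plays no role.
#'
#' @param gold,pred Data frames with columns `doc_id` and `gene_id`
#'   (further columns ignored); duplicates are collapsed.
#' @return Object of class `gn_eval` (see [eval_counts()]).
#' @export
gn_score <- function(gold, pred) {
  gk <- unique(paste(as.character(gold$doc_id), as.character(gold$gene_id),
                     sep = "\t"))
  pk <- unique(paste(as.character(pred$doc_id), as.character(pred$gene_id),
                     sep = "\t"))
  if (!nrow(gold)) gk <- character(0)
  if (!nrow(pred)) pk <- character(0)
  tp <- length(intersect(pk, gk))
  eval_counts(tp, length(pk) - tp, length(gk) - tp)
}

#' Round half-up to a number of decimals
#'
#' Display rounding used for reported percentages (base `round()` rounds
#' half to even, which is not how published tables are rounded).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' @export
print.gn_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("Precision %.1f%%  Recall %.1f%%  F-score %.1f%%\n",
              round_half_up(x$precision), round_half_up(x$recall),
              round_half_up(x$fscore)))
  invisible(x)
}

#' Read a gold or prediction file
#'
#' Format: `doc_id<TAB>gene_id[<TAB>excerpt]`; the optional third column is
#' ignored for scoring. Duplicate pairs are collapsed; malformed lines
#' (fewer than two fields) are reported with their line numbers and
#' skipped.
#'
#' @param path Path to the TSV file.
#' @return Data frame with character columns `doc_id` and `gene_id`, one
#'   row per distinct pair.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(f) < 2L)
  if (length(bad)) {
    warning("annotation line(s) ",
            paste(which(keep)[bad], collapse = ", "), " malformed; skipped")
    f <- f[lengths(f) >= 2L]
  }
  df <- data.frame(doc_id = vapply(f, `[[`, "", 1L),
                   gene_id = vapply(f, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' @rdname read_gold
#' @export
read_pred <- read_gold

#' Write predictions in the normalization output format
#'
#' One decision per line: `doc_id<TAB>gene_id<TAB>mention_text`.
#'
#' @param predictions Data frame with columns `doc_id`, `gene_id` and
#'   optionally `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  text <- if ("text" %in% names(predictions)) predictions$text else ""
  lines <- paste(predictions$doc_id, predictions$gene_id, text, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
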