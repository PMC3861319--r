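#' Maximum-weight bipartite assignment (Munkres / Hungarian algorithm)
#'
#' Finds the one-to-one assignment of rows to columns of a rectangular
#' weight matrix that maximizes the total matched weight. The short side is
#' padded internally with zero-weight dummies to make the matrix square; the
#' returned matching has exactly `min(nrow, ncol)` pairs, all between real
#' rows and columns, and its total weight is the global optimum. Solved with
#' the O(n^3) Hungarian algorithm with row/column potentials.
#'
#' @param weights Numeric matrix of nonnegative weights (may be rectangular).
#'   A 0 x 0 matrix yields an empty assignment with total weight 0.
#' @param u_labels,v_labels Optional row / column labels carried through to
#'   the result (defaults to the matrix dimnames, if any).
#' @return Object of class `gn_assignment`: list with `pairs` (two-column
#'   integer matrix of matched row/column indices), `total_weight`,
#'   `u_labels`, `v_labels`.
#' @export
#' @examples
#' munkres_max_assignment(matrix(c(4, 2, 1, 3), 2, 2))  # total weight 7
munkres_max_assignment <- function(weights, u_labels = NULL, v_labels = NULL) {
  weights <- as.matrix(weights)
  nr <- nrow(weights)
  nc <- ncol(weights)
  if (is.null(u_labels)) u_labels <- rownames(weights)
  if (is.null(v_labels)) v_labels <- colnames(weights)
  if (nr == 0L || nc == 0L) {
    return(structure(
      list(pairs = matrix(integer(0), ncol = 2,
                          dimnames = list(NULL, c("u", "v"))),
           total_weight = 0, u_labels = u_labels, v_labels = v_labels),
      class = "gn_assignment"))
  }
  if (anyNA(weights)) stop("munkres_max_assignment(): weights contain NA")
  n <- max(nr, nc)
  padded <- matrix(0, n, n)
  padded[seq_len(nr), seq_len(nc)] <- weights
  # maximize weight == minimize (max - weight)
  cost <- max(padded) - padded
  col_of_row <- .hungarian_min(cost)
  keep <- which(seq_len(n) <= nr & col_of_row <= nc)
  pairs <- cbind(u = keep, v = col_of_row[keep])
  total <- if (nrow(pairs)) sum(weights[pairs]) else 0
  structure(list(pairs = pairs, total_weight = total,
                 u_labels = u_labels, v_labels = v_labels),
            class = "gn_assignment")
}

#' @export
print.gn_assignment <- function(x, ...) {
  cat("Bipartite assignment:", nrow(x$pairs), "pairs, total weight",
      format(x$total_weight, digits = 6), "\n")
  if (nrow(x$pairs)) {
    u <- if (!is.null(x$u_labels)) x$u_labels[x$pairs[, 1]] else x$pairs[, 1]
    v <- if (!is.null(x$v_labels)) x$v_labels[x$pairs[, 2]] else x$pairs[, 2]
    for (k in seq_len(nrow(x$pairs))) cat("  ", u[k], "<->", v[k], "\n")
  }
  invisible(x)
}

# O(n^3) Hungarian algorithm (minimization, square matrix), potentials +
# shortest augmenting paths. Returns, for each row, its assigned column.
.hungarian_min <- function(cost) {
  n <- nrow(cost)
  # index shift: position k holds row/column k-1; row/column 0 is virtual
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j+1]: row currently assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  col_of_row <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) col_of_row[p[j + 1L]] <- j
  col_of_row
}

#' Semantic similarity between a gene's metadata and an abstract's context
#'
#' Builds the weighted complete bipartite graph between a gene's extended
#' semantic information (set U: the non-empty of its four gene_info fields
#' Symbol, chromosome, map_location, description, each normalized and taken
#' as one vertex) and the entity context of the abstract (set V: one vertex
#' per context string), with Jaro-Winkler similarity as edge weight. In
#' `"munkres"` mode the score is the total weight of the maximum-weight
#' matching; in `"sum_all"` mode it is the sum of every edge weight,
#' including edges not in any matching.
#'
#' @param record A gene metadata record: list or one-row data frame with
#'   elements `symbol`, `chromosome`, `map_location`, `description`.
#' @param context Character vector of context entity strings (normalized
#'   with [normalize_term()]).
#' @param mode `"munkres"` (matching-based, default) or `"sum_all"`.
#' @param stop_words Stop words used when normalizing the record fields.
#' @return Nonnegative similarity score; 0 when the context is empty or all
#'   four fields are empty.
#' @export
semantic_similarity <- function(record, context,
                                mode = c("munkres", "sum_all"),
                                stop_words = gn_stop_words()) {
  mode <- match.arg(mode)
  u <- gene_fields(record, stop_words = stop_words)
  u <- u[nzchar(u)]
  v <- context[nzchar(context)]
  if (length(u) == 0L || length(v) == 0L) return(0)
  w <- matrix(0, length(u), length(v), dimnames = list(names(u), NULL))
  for (i in seq_along(u)) {
    for (j in seq_along(v)) w[i, j] <- jaro_winkler(u[[i]], v[[j]])
  }
  if (mode == "sum_all") sum(w) else munkres_max_assignment(w)$total_weight
}

#' Extract the four similarity fields of a gene metadata record
#'
#' Returns the fields in the fixed order symbol, chromosome, map_location,
#' description, normalized with [normalize_term()]; missing fields become
#' empty strings.
#'
#' @inheritParams semantic_similarity
#' @return Named character vector of length 4.
#' @export
gene_fields <- function(record, stop_words = gn_stop_words()) {
  nm <- c("symbol", "chromosome", "map_location", "description")
  out <- vapply(nm, function(f) {
    val <- record[[f]]
    if (is.null(val) || length(val) == 0L || is.na(val)) "" else as.character(val)
  }, character(1))
  stats::setNames(normalize_term(out, stop_words), nm)
}
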