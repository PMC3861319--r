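#' Jaro similarity between two strings
#'
#' Standard Jaro similarity: with `m` matching characters (equal characters
#' no further apart than `floor(max(|s1|,|s2|)/2) - 1` positions, each
#' character matched at most once) and `t` half the number of transpositions
#' among the matched characters, the similarity is
#' `(m/|s1| + m/|s2| + (m - t)/m) / 3`, or 0 when `m = 0`. Two empty strings
#' are identical and score 1. Symmetric and bounded in \[0, 1\].
#'
#' @param s1,s2 Single strings.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' jaro_similarity("MARTHA", "MARHTA")  # 0.9444...
jaro_similarity <- function(s1, s2) {
  a <- utf8ToInt(as.character(s1))
  b <- utf8ToInt(as.character(s2))
  la <- length(a)
  lb <- length(b)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  win <- max(floor(max(la, lb) / 2) - 1, 0)
  a_match <- logical(la)
  b_match <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1L, i - win)
    hi <- min(lb, i + win)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!b_match[j] && b[j] == a[i]) {
        a_match[i] <- TRUE
        b_match[j] <- TRUE
        break
      }
    }
  }
  m <- sum(a_match)
  if (m == 0L) return(0)
  t <- sum(a[a_match] != b[b_match]) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

#' Jaro-Winkler similarity between two strings
#'
#' Jaro similarity boosted by a shared-prefix bonus:
#' `J + l * p * (1 - J)` where `J` is [jaro_similarity()] and `l` is the
#' length of the common prefix, capped at `max_prefix`. Uses the canonical
#' parameterization `p = 0.1`, prefix cap 4. Always `>= J`, symmetric,
#' bounded in \[0, 1\], and 1 exactly when the strings are identical.
#'
#' @param s1,s2 Single strings.
#' @param p Prefix scaling factor in \[0, 0.25\].
#' @param max_prefix Maximum prefix length receiving the bonus.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")   # 0.9611...
#' jaro_winkler("DIXON", "DICKSONX")  # 0.8133...
jaro_winkler <- function(s1, s2, p = 0.1, max_prefix = 4L) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 0.25) {
    stop("jaro_winkler(): prefix scale `p` must be a single number in [0, 0.25]")
  }
  j <- jaro_similarity(s1, s2)
  a <- utf8ToInt(as.character(s1))
  b <- utf8ToInt(as.character(s2))
  n <- min(length(a), length(b), max_prefix)
  l <- 0L
  if (n > 0L) {
    for (i in seq_len(n)) {
      if (a[i] != b[i]) break
      l <- i
    }
  }
  j + l * p * (1 - j)
}
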