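# Shared internal helpers: sequence matrices, Hamming distances, seeded RNG,
# multivariate-hypergeometric draws.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run an expression under a local seed
#'
#' When `seed` is NULL the current RNG stream is used (and advanced);
#' otherwise the global RNG state is saved, the seed applied, and the state
#' restored afterwards, so seeded calls never perturb a caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::local_seed(as.integer(seed))
  expr
}

#' Split equal-length sequences into a character matrix (rows = sequences)
#' @noRd
seq_matrix <- function(seqs) {
  if (length(seqs) == 0L) abort("no sequences supplied")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    bad <- which(nchar(seqs) != nchar(seqs)[1])
    abort(paste0(
      "sequences are not all the same length; offending entries: ",
      paste(head(bad, 10L), collapse = ", ")
    ))
  }
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

collapse_rows <- function(m) {
  apply(m, 1L, paste0, collapse = "")
}

#' Pairwise Hamming distances between equal-length sequences
#'
#' The gap character `-` is an ordinary fifth state: a gap aligned against a
#' base counts as one difference.
#'
#' @param seqs Character vector of equal-length sequences, optionally named.
#' @return A symmetric integer matrix with zero diagonal; dimnames taken
#'   from `names(seqs)` when present.
#' @examples
#' hamming_distances(c(a = "ACGT", b = "ACGA", c = "TCGA"))
#' @export
hamming_distances <- function(seqs) {
  m <- seq_matrix(seqs)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  d
}

#' Multivariate hypergeometric draw: subsample `k` items without replacement
#' from categories with the given counts. Sequential rhyper construction.
#' @noRd
rmvhyper <- function(counts, k) {
  counts <- as.integer(counts)
  total <- sum(counts)
  stopifnot(k >= 0L, k <= total)
  out <- integer(length(counts))
  remaining <- total
  left <- k
  for (i in seq_along(counts)) {
    if (left == 0L) break
    rest <- remaining - counts[i]
    x <- rhyper(1L, counts[i], rest, left)
    out[i] <- x
    left <- left - x
    remaining <- rest
  }
  out
}

#' Coerce a count table to an integer matrix (oligotypes x sites)
#'
#' Accepts either a matrix with rownames, or a tibble/data frame whose first
#' column holds oligotype ids and remaining columns hold per-site counts.
#' @noRd
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
  } else if (is.data.frame(counts)) {
    ids <- as.character(counts[[1L]])
    m <- as.matrix(counts[, -1L, drop = FALSE])
    rownames(m) <- ids
  } else {
    abort("`counts` must be a matrix or a data frame of oligotype counts")
  }
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

#' Transpose a count table into a community matrix (samples x oligotypes)
#'
#' @param counts Count matrix or tibble as produced by
#'   [build_count_matrix()].
#' @return Numeric matrix with one row per sample/site.
#' @export
as_community_matrix <- function(counts) {
  t(as_count_matrix(counts))
}

round_num_cols <- function(df, digits = 4L) {
  df[] <- lapply(df, function(x) if (is.double(x)) round(x, digits) else x)
  df
}
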