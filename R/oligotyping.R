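# Minimum-entropy decomposition of aligned amplicon reads into oligotypes.
# Reads are recursively partitioned at their maximal Shannon-entropy
# column(s) until residual entropy falls below the threshold m; low-count
# terminal nodes are treated as noise and either discarded or reassigned to
# the closest surviving oligotype.

RESIDUES <- c("A", "C", "G", "T", "-")

validate_read_set <- function(reads) {
  if (!is.data.frame(reads) ||
      !all(c("sample", "seq") %in% names(reads))) {
    abort("a read set needs columns `sample` and `seq`")
  }
  if (nrow(reads) < 1L) abort("read set is empty")
  if (length(unique(nchar(reads$seq))) != 1L) {
    bad <- which(nchar(reads$seq) != nchar(reads$seq)[1])
    abort(paste0("reads are not positionally homologous (unequal lengths); ",
                 "offending rows: ", paste(head(bad, 10L), collapse = ", ")))
  }
  invisible(reads)
}

residue_counts <- function(sub) {
  # residues x positions counts over A/C/G/T/- (N excluded)
  cnt <- sapply(RESIDUES, function(b) colSums(sub == b))
  if (is.null(dim(cnt))) {
    cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL, RESIDUES))
  }
  t(cnt)
}

entropy_from_counts <- function(cnt) {
  # cnt: residues x positions count matrix over A/C/G/T/- (N excluded)
  tot <- colSums(cnt)
  f <- sweep(cnt, 2L, pmax(tot, 1L), "/")
  h <- -colSums(ifelse(f > 0, f * log2(f), 0))
  h[tot == 0L] <- 0
  h
}

#' Column-wise Shannon entropy of an aligned read set
#'
#' Entropy at position p is \eqn{H_p = -\sum_b f_b \log_2 f_b} over the five
#' residue states A, C, G, T and the gap `-`; `N` is missing data and is
#' excluded from the frequency denominator. A column consisting entirely of
#' `N` has entropy 0 (with a warning).
#'
#' @param reads Read-set tibble with columns `sample` and `seq` (equal
#'   lengths), e.g. from [read_labelled_fasta()] or [sample_reads()].
#' @return An `entropy_profile` tibble: position, entropy (bits), and the
#'   per-position residue counts.
#' @examples
#' reads <- tibble::tibble(sample = c("A", "A"), seq = c("AACC", "AGCC"))
#' column_entropy(reads)
#' @export
column_entropy <- function(reads) {
  validate_read_set(reads)
  m <- seq_matrix(reads$seq)
  cnt <- residue_counts(m)
  n_n <- colSums(m == "N")
  if (any(colSums(cnt) == 0L)) {
    warn("column(s) consisting entirely of N: entropy set to 0")
  }
  prof <- tibble(
    position = seq_len(ncol(m)),
    entropy = entropy_from_counts(cnt),
    a = cnt["A", ], c = cnt["C", ], g = cnt["G", ], t = cnt["T", ],
    gap = cnt["-", ], n = n_n
  )
  class(prof) <- c("entropy_profile", class(prof))
  prof
}

#' Minimum-entropy decomposition into oligotypes
#'
#' Recursive partition of a positionally homologous read set: a node whose
#' maximal column entropy exceeds `m` is split by the residues its reads
#' carry at the top-`d` highest-entropy positions (ties broken towards the
#' lowest position index); terminal nodes are oligotypes. Reads carrying `N`
#' at a split position follow the majority child. Oligotypes with fewer than
#' `min_abundance` reads are noise-filtered: their reads are either
#' reassigned to the surviving oligotype at minimal Hamming distance
#' (default) or discarded.
#'
#' @param reads Read-set tibble (`sample`, `seq`).
#' @param m Entropy threshold in bits below which a column is considered
#'   noise-free (default 0.0965, the conventional decomposition default).
#' @param min_abundance Minimum substantive abundance: a fraction of the
#'   input reads if `< 1` (default 0.01), otherwise an absolute count.
#' @param d Number of discriminant positions used per split (default 1).
#' @param policy `"reassign"` (default) or `"discard"` for noise reads.
#' @param max_oligotypes Guard: abort if the decomposition produces more
#'   terminal nodes than this (advising a larger `m`).
#' @return An `oligo_catalog`: tibble of oligotypes (id, representative
#'   seq, total count), a long per-site count tibble, the discriminant
#'   positions used, parameters, and read bookkeeping.
#' @export
med_decompose <- function(reads, m = 0.0965, min_abundance = 0.01, d = 1L,
                          policy = c("reassign", "discard"),
                          max_oligotypes = 10000L) {
  policy <- match.arg(policy)
  validate_read_set(reads)
  if (m < 0) abort("entropy threshold m must be >= 0")
  n_reads <- nrow(reads)
  min_count <- if (min_abundance < 1) min_abundance * n_reads
               else min_abundance
  if (min_count > n_reads) abort("min_abundance exceeds the read count")
  char <- seq_matrix(reads$seq)
  split_positions <- integer(0)
  leaves <- list()
  n_leaves <- 0L

  count_node <- function(idx) {
    residue_counts(char[idx, , drop = FALSE])
  }

  decompose <- function(idx) {
    cnt <- count_node(idx)
    h <- entropy_from_counts(cnt)
    if (max(h) <= m || length(idx) <= 1L) {
      n_leaves <<- n_leaves + 1L
      if (n_leaves > max_oligotypes) {
        abort(paste0("more than ", max_oligotypes, " oligotypes produced; ",
                     "the entropy threshold m is likely too low"))
      }
      leaves[[n_leaves]] <<- idx
      return(invisible(NULL))
    }
    ord <- order(-h, seq_along(h))
    pos <- ord[seq_len(min(d, sum(h > m)))]
    split_positions <<- union(split_positions, pos)
    key_chars <- char[idx, pos, drop = FALSE]
    has_n <- rowSums(key_chars == "N") > 0L
    key <- apply(key_chars, 1L, paste0, collapse = "")
    groups <- split(idx[!has_n], key[!has_n])
    if (any(has_n)) {
      if (length(groups) == 0L) {
        groups <- list(idx)               # all N at the split: stop here
      } else {
        sizes <- lengths(groups)
        major <- which.max(sizes)
        groups[[major]] <- c(groups[[major]], idx[has_n])
      }
    }
    if (length(groups) <= 1L) {           # cannot split further
      n_leaves <<- n_leaves + 1L
      leaves[[n_leaves]] <<- idx
      return(invisible(NULL))
    }
    for (g in groups) decompose(sort(g))
    invisible(NULL)
  }
  decompose(seq_len(n_reads))

  representative <- function(idx) {
    tab <- sort(table(reads$seq[idx]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    sort(top)[1L]                         # ties: lexicographically smallest
  }
  leaf_n <- lengths(leaves)
  keep <- leaf_n >= min_count
  if (!any(keep)) keep[which.max(leaf_n)] <- TRUE   # never drop everything
  surv <- leaves[keep]
  reps <- vapply(surv, representative, "")
  # order oligotypes by decreasing abundance, ties by representative
  ord <- order(-lengths(surv), reps)
  surv <- surv[ord]; reps <- reps[ord]
  assignment <- integer(n_reads)          # 0 = unassigned/noise
  for (k in seq_along(surv)) assignment[surv[[k]]] <- k
  noise_idx <- unlist(leaves[!keep], use.names = FALSE)
  n_discarded <- 0L
  if (length(noise_idx)) {
    if (policy == "reassign") {
      rep_mat <- seq_matrix(reps)
      for (i in noise_idx) {
        dist_to <- rowSums(sweep(rep_mat, 2L, char[i, ], "!=") > 0)
        assignment[i] <- which.min(dist_to)  # ties: first (most abundant)
      }
    } else {
      n_discarded <- length(noise_idx)
    }
  }
  retained <- assignment > 0L
  ids <- sprintf("OT%03d", seq_along(surv))
  counts <- tibble(
    oligo_id = ids[assignment[retained]],
    site = reads$sample[retained]
  ) %>% count(.data$oligo_id, .data$site, name = "n")
  oligos <- tibble(
    oligo_id = ids,
    seq = reps,
    n = as.integer(tabulate(assignment[retained], nbins = length(surv)))
  )
  structure(
    list(
      oligos = oligos,
      counts = counts,
      discriminant_positions = sort(split_positions),
      params = list(m = m, min_abundance = min_abundance, d = d,
                    policy = policy),
      n_input_reads = n_reads,
      n_retained = sum(retained),
      n_discarded = n_discarded
    ),
    class = "oligo_catalog"
  )
}

#' @export
print.oligo_catalog <- function(x, ...) {
  cat("<oligo_catalog> ", nrow(x$oligos), " oligotypes from ",
      x$n_input_reads, " reads (", x$n_retained, " retained)\n", sep = "")
  cat("  m = ", x$params$m, ", min_abundance = ", x$params$min_abundance,
      ", policy = ", x$params$policy, "\n", sep = "")
  invisible(x)
}

#' Oligotype representative sequences as a named vector
#'
#' @param catalog An [med_decompose()] catalog.
#' @return Named character vector (names = oligotype ids).
#' @export
catalog_seqs <- function(catalog) {
  stopifnot(inherits(catalog, "oligo_catalog"))
  setNames(catalog$oligos$seq, catalog$oligos$oligo_id)
}

#' Oligotype-by-site count matrix
#'
#' Materializes the catalog's per-site tallies as a wide table with a
#' stated column order.
#'
#' @param catalog An [med_decompose()] catalog.
#' @param site_order Optional character vector fixing column order; every
#'   named site must occur in the catalog.
#' @return Tibble: first column `oligo_id`, one integer column per site.
#'   Row sums equal the catalog's oligotype counts.
#' @export
build_count_matrix <- function(catalog, site_order = NULL) {
  stopifnot(inherits(catalog, "oligo_catalog"))
  if (nrow(catalog$oligos) == 0L) abort("catalog is empty")
  sites <- sort(unique(catalog$counts$site))
  if (!is.null(site_order)) {
    unknown <- setdiff(site_order, sites)
    if (length(unknown)) {
      abort(paste0("unknown site(s) in site_order: ",
                   paste(unknown, collapse = ", ")))
    }
    sites <- site_order
  }
  wide <- tidyr::pivot_wider(catalog$counts, names_from = "site",
                             values_from = "n", values_fill = 0L)
  wide <- wide[match(catalog$oligos$oligo_id, wide$oligo_id), ,
               drop = FALSE]
  out <- wide[, c("oligo_id", sites)]
  keep <- rowSums(out[, -1L, drop = FALSE]) > 0
  out[keep, ]
}

#' @export
tidy.oligo_catalog <- function(x, ...) {
  left_join(x$counts, x$oligos[, c("oligo_id", "seq")], by = "oligo_id")
}

#' @export
glance.oligo_catalog <- function(x, ...) {
  tibble(
    n_oligotypes = nrow(x$oligos),
    n_reads = x$n_input_reads,
    n_retained = x$n_retained,
    n_discarded = x$n_discarded,
    n_discriminant_positions = length(x$discriminant_positions),
    m = x$params$m
  )
}
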