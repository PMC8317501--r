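# Frequency-weighted population-genetic statistics over oligotype count
# tables: diversity indices with bootstrap rarefaction, two-level AMOVA
# Fst / Phi-st with permutation nulls, Hudson's Snn nearest-neighbour
# statistic, and a Wright island-model Nm surrogate. Everything works on
# counts directly; individual sequences are never materialized, so sample
# sizes of 1e5 reads cost the same as 10.

polymorphic_positions <- function(seqs) {
  if (length(seqs) < 2L) return(0L)
  m <- seq_matrix(seqs)
  sum(apply(m, 2L, function(col) length(unique(col[col != "N"])) > 1L))
}

#' Per-site genetic diversity indices
#'
#' For each site, computes the number of sequences N, the number of
#' oligotypes k, the number of discriminant (segregating) sites S among the
#' oligotypes present, the oligotype diversity
#' \eqn{H = \frac{n}{n-1}(1 - \sum p_i^2)} and the mean number of pairwise
#' differences \eqn{\Pi = \frac{n}{n-1}\sum_{i<j} 2 p_i p_j d_{ij}}, with
#' \eqn{d_{ij}} the Hamming distance between oligotype representatives.
#' All quantities are frequency-weighted; sites with fewer than two
#' sequences yield `NA` for H and Pi.
#'
#' @param counts Count matrix or tibble ([build_count_matrix()] output).
#' @param seqs Named character vector of oligotype representative
#'   sequences (names matching the count rows).
#' @return Tibble: site, n, k, s, h, pi.
#' @export
diversity_indices <- function(counts, seqs) {
  cm <- as_count_matrix(counts)
  seqs <- seqs[rownames(cm)]
  if (anyNA(seqs)) abort("every oligotype in `counts` needs a sequence")
  dists <- hamming_distances(seqs)
  purrr::map_dfr(colnames(cm), function(site) {
    cvec <- cm[, site]
    n <- sum(cvec)
    present <- cvec > 0
    k <- sum(present)
    s <- polymorphic_positions(seqs[present])
    if (n < 2) {
      return(tibble(site = site, n = n, k = k, s = s,
                    h = NA_real_, pi = NA_real_))
    }
    p <- cvec[present] / n
    h <- n / (n - 1) * (1 - sum(p^2))
    d <- dists[present, present, drop = FALSE]
    pi <- n / (n - 1) * sum((p %o% p) * d)  # ordered pairs = 2 * sum_{i<j}
    tibble(site = site, n = n, k = k, s = s, h = h, pi = pi)
  })
}

#' Rarefied diversity indices with bootstrap confidence intervals
#'
#' Every site is repeatedly subsampled without replacement (multivariate
#' hypergeometric) down to the smallest site's sequence count; the indices
#' are recomputed on each resample. Point estimates are resample means and
#' the 95% interval the 2.5/97.5 percentiles.
#'
#' @inheritParams diversity_indices
#' @param B Number of resamples (default 1000).
#' @param seed Optional seed.
#' @return Tibble with, per site and per index (k, s, h, pi), the mean and
#'   the 95% bootstrap bounds; `n_rarefied` records the common depth.
#' @export
rarefied_indices <- function(counts, seqs, B = 1000L, seed = NULL) {
  cm <- as_count_matrix(counts)
  if (ncol(cm) < 2L) abort("rarefaction needs at least two sites")
  if (B < 1L) abort("B must be >= 1")
  seqs <- seqs[rownames(cm)]
  dists <- hamming_distances(seqs)
  n_min <- min(colSums(cm))
  if (n_min < 2) abort("smallest site has fewer than 2 sequences")
  with_seed(seed, {
    purrr::map_dfr(colnames(cm), function(site) {
      cvec <- cm[, site]
      draws <- replicate(B, {
        sub <- rmvhyper(cvec, n_min)
        present <- sub > 0
        p <- sub[present] / n_min
        d <- dists[present, present, drop = FALSE]
        c(
          k = sum(present),
          s = polymorphic_positions(seqs[present]),
          h = n_min / (n_min - 1) * (1 - sum(p^2)),
          pi = n_min / (n_min - 1) * sum((p %o% p) * d)
        )
      })
      est <- unname(rowMeans(draws))
      lo <- apply(draws, 1L, quantile, 0.025, names = FALSE)
      hi <- apply(draws, 1L, quantile, 0.975, names = FALSE)
      tibble(
        site = site, n_rarefied = n_min,
        k = est[1], k_lo = lo[1], k_hi = hi[1],
        s = est[2], s_lo = lo[2], s_hi = hi[2],
        h = est[3], h_lo = lo[3], h_hi = hi[3],
        pi = est[4], pi_lo = lo[4], pi_hi = hi[4]
      )
    })
  })
}

#' Two-level AMOVA fixation index for one site pair (frequency-weighted)
#'
#' @param c1,c2 Count vectors over the same oligotypes.
#' @param d2 Squared distance matrix between oligotypes.
#' @return The fixation index, truncated below at 0.
#' @noRd
amova_pair <- function(c1, c2, d2) {
  n1 <- sum(c1); n2 <- sum(c2); N <- n1 + n2
  tot <- c1 + c2
  ssd_total <- sum((tot %o% tot) * d2) / (2 * N)
  ssd_within <- sum((c1 %o% c1) * d2) / (2 * n1) +
    sum((c2 %o% c2) * d2) / (2 * n2)
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - 2)
  n_prime <- (N - (n1^2 + n2^2) / N)          # / (P - 1) with P = 2
  msd_among <- ssd_among                       # / (P - 1)
  sigma_a <- (msd_among - sigma_w) / n_prime
  denom <- sigma_a + sigma_w
  if (denom <= 0) return(0)
  max(0, min(1, sigma_a / denom))
}

#' Pairwise AMOVA Fst / Phi-st between sites
#'
#' Analysis of molecular variance on squared inter-oligotype distances for
#' every site pair. `mode = "fst"` uses the 0/1 identity metric (allele
#' frequency differentiation); `mode = "phist"` uses squared Hamming
#' distances between oligotype representatives (nucleotide-level
#' differentiation). Negative variance components are truncated to zero.
#' All sums are frequency-weighted over counts.
#'
#' @param counts Count matrix or tibble.
#' @param seqs Named representative sequences (required for `"phist"`).
#' @param mode `"phist"` or `"fst"`.
#' @param dists Optional precomputed Hamming distance matrix (overrides
#'   `seqs`).
#' @return Tibble: site_a, site_b, statistic, mode. Pairs where a site has
#'   zero sequences are skipped with a warning.
#' @export
amova_structure <- function(counts, seqs = NULL,
                            mode = c("phist", "fst"), dists = NULL) {
  mode <- match.arg(mode)
  cm <- as_count_matrix(counts)
  if (ncol(cm) < 2L) abort("need at least two sites")
  d <- structure_distances(cm, seqs, mode, dists)
  d2 <- d^2
  sites <- colnames(cm)
  pairs <- combn(sites, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    c1 <- cm[, a]; c2 <- cm[, b]
    if (sum(c1) == 0 || sum(c2) == 0) {
      warn(paste0("pair ", a, "-", b, " skipped: empty site"))
      return(tibble(site_a = a, site_b = b, statistic = NA_real_,
                    mode = mode))
    }
    tibble(site_a = a, site_b = b,
           statistic = amova_pair(c1, c2, d2), mode = mode)
  })
}

structure_distances <- function(cm, seqs, mode, dists) {
  if (!is.null(dists)) {
    return(as.matrix(dists)[rownames(cm), rownames(cm)])
  }
  if (mode == "fst") {
    k <- nrow(cm)
    d <- matrix(1, k, k, dimnames = list(rownames(cm), rownames(cm)))
    diag(d) <- 0
    d
  } else {
    if (is.null(seqs)) abort("`seqs` (or `dists`) required for phist")
    hamming_distances(seqs[rownames(cm)])
  }
}

#' Permutation test for pairwise AMOVA statistics
#'
#' The null reshuffles sequence-to-site assignments for each pair while
#' preserving site sizes and oligotype totals (a multivariate
#' hypergeometric redraw of the 2 x k count table via the Patefield
#' algorithm); p-values use the add-one estimator
#' \eqn{p = (\#\{null \ge obs\} + 1)/(P + 1)}. A degenerate pair (a single
#' oligotype in total) gets p = 1 by convention.
#'
#' @inheritParams amova_structure
#' @param perms Number of permutations (default 999).
#' @param seed Optional seed.
#' @return Tibble: site_a, site_b, statistic, p_value, mode.
#' @export
amova_test <- function(counts, seqs = NULL, mode = c("phist", "fst"),
                       dists = NULL, perms = 999L, seed = NULL) {
  mode <- match.arg(mode)
  if (perms < 1L) abort("perms must be >= 1")
  cm <- as_count_matrix(counts)
  d2 <- structure_distances(cm, seqs, mode, dists)^2
  obs <- amova_structure(cm, seqs, mode, dists)
  with_seed(seed, {
    obs$p_value <- purrr::map2_dbl(obs$site_a, obs$site_b, function(a, b) {
      c1 <- cm[, a]; c2 <- cm[, b]
      if (sum(c1) == 0 || sum(c2) == 0) return(NA_real_)
      tot <- c1 + c2
      if (sum(tot > 0) < 2L) return(1)
      stat <- obs$statistic[obs$site_a == a & obs$site_b == b]
      null_tables <- r2dtable(perms, as.integer(c(sum(c1), sum(c2))),
                              as.integer(tot))
      hits <- sum(vapply(null_tables, function(tab) {
        amova_pair(tab[1L, ], tab[2L, ], d2) >= stat
      }, logical(1L)))
      (hits + 1) / (perms + 1)
    })
    obs[, c("site_a", "site_b", "statistic", "p_value", "mode")]
  })
}

#' Hudson's Snn nearest-neighbour statistic (frequency-weighted)
#'
#' For every sequence, its nearest neighbours are all other sequences at
#' minimal distance (identical copies included, self excluded); `x_i` is
#' the fraction of those neighbours drawn from the sequence's own site,
#' ties shared proportionally. Snn is the mean of `x_i` over all sequences,
#' computed from counts without expanding reads.
#'
#' @param counts Count matrix or tibble (all sites used).
#' @param seqs Named representative sequences.
#' @param dists Optional precomputed distance matrix (overrides `seqs`).
#' @return A single numeric value in `[0, 1]`.
#' @export
snn_statistic <- function(counts, seqs = NULL, dists = NULL) {
  cm <- as_count_matrix(counts)
  if (ncol(cm) < 2L) abort("Snn needs at least two sites")
  if (sum(cm) < 2) abort("Snn needs at least two sequences")
  d <- if (!is.null(dists)) as.matrix(dists)[rownames(cm), rownames(cm)]
       else hamming_distances(seqs[rownames(cm)])
  snn_from_counts(cm, d)
}

snn_from_counts <- function(cm, d) {
  tot <- rowSums(cm)
  present <- tot > 0
  cmp <- cm[present, , drop = FALSE]
  dp <- d[present, present, drop = FALSE]
  totp <- tot[present]
  N <- sum(totp)
  acc <- 0
  for (a in seq_len(nrow(cmp))) {
    if (totp[a] >= 2) {
      # nearest neighbours are the other identical copies (distance 0)
      for (s in which(cmp[a, ] > 0)) {
        x <- (cmp[a, s] - 1) / (totp[a] - 1)
        acc <- acc + cmp[a, s] * x
      }
    } else {
      others <- setdiff(seq_len(nrow(cmp)), a)
      dmin <- min(dp[a, others])
      nn <- others[dp[a, others] == dmin]
      denom <- sum(totp[nn])
      s <- which(cmp[a, ] > 0)             # the single copy's site
      x <- sum(cmp[nn, s, drop = FALSE]) / denom
      acc <- acc + x
    }
  }
  unname(acc / N)
}

#' Permutation test for Snn
#'
#' Site labels are permuted by redrawing the oligotype x site count table
#' with fixed margins (multivariate hypergeometric, Patefield algorithm);
#' p uses the add-one estimator.
#'
#' @inheritParams snn_statistic
#' @param perms Number of permutations.
#' @param seed Optional seed.
#' @return Tibble: snn, p_value, n_perm.
#' @export
snn_test <- function(counts, seqs = NULL, dists = NULL, perms = 999L,
                     seed = NULL) {
  cm <- as_count_matrix(counts)
  d <- if (!is.null(dists)) as.matrix(dists)[rownames(cm), rownames(cm)]
       else hamming_distances(seqs[rownames(cm)])
  obs <- snn_from_counts(cm, d)
  with_seed(seed, {
    null_tables <- r2dtable(perms, as.integer(rowSums(cm)),
                            as.integer(colSums(cm)))
    hits <- sum(vapply(null_tables, function(tab) {
      dimnames(tab) <- dimnames(cm)
      snn_from_counts(tab, d) >= obs
    }, logical(1L)))
    tibble(snn = obs, p_value = (hits + 1) / (perms + 1),
           n_perm = as.integer(perms))
  })
}

#' Island-model Nm surrogate from Fst
#'
#' Haploid island-model conversion \eqn{Nm = (1 - F_{st}) / (2 F_{st})}: a
#' deliberately simple, clearly labelled surrogate for coalescent
#' likelihood estimates of gene flow. `Fst = 0` maps to `Inf`, `Fst = 1`
#' to 0.
#'
#' @param fst Numeric vector of fixation indices in `[0, 1]`.
#' @return Numeric vector of effective migrants per generation.
#' @examples
#' nm_island(c(1/3, 0.2, 1))
#' @export
nm_island <- function(fst) {
  if (any(is.na(fst)) || any(fst < 0 | fst > 1)) {
    abort("fst values must lie in [0, 1]")
  }
  ifelse(fst == 0, Inf, (1 - fst) / (2 * fst))
}

#' Pairwise structure summary (Fst, Phi-st, Snn)
#'
#' Convenience wrapper bundling [amova_test()] in both modes with
#' [snn_test()] into one object with tidy/glance methods.
#'
#' @inheritParams amova_test
#' @return A `pairwise_structure` object.
#' @export
pairwise_structure <- function(counts, seqs, perms = 999L, seed = NULL) {
  fst <- amova_test(counts, seqs, mode = "fst", perms = perms,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
  phist <- amova_test(counts, seqs, mode = "phist", perms = perms,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 2L))
  snn <- snn_test(counts, seqs, perms = perms,
                  seed = if (is.null(seed)) NULL else derive_seed(seed, 3L))
  structure(list(fst = fst, phist = phist, snn = snn),
            class = "pairwise_structure")
}

#' @export
print.pairwise_structure <- function(x, ...) {
  cat("<pairwise_structure> Snn =", format(x$snn$snn, digits = 4),
      "(p =", format(x$snn$p_value, digits = 4), ")\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.pairwise_structure <- function(x, ...) {
  bind_rows(x$fst, x$phist)
}

#' @export
glance.pairwise_structure <- function(x, ...) {
  tibble(snn = x$snn$snn, snn_p_value = x$snn$p_value,
         mean_fst = mean(x$fst$statistic, na.rm = TRUE),
         mean_phist = mean(x$phist$statistic, na.rm = TRUE))
}
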