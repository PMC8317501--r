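# Ecological process partitioning of oligotype turnover: abundance-weighted
# beta mean-nearest-taxon distance against a tip-shuffle null (beta-NTI) and
# the abundance-weighted Bray-Curtis Raup-Crick index, classified into five
# assembly processes (homogeneous selection, variable selection,
# homogenizing dispersal, dispersal limitation + drift, ecological drift).

#' Neighbour-joining tree from a distance matrix
#'
#' Thin wrapper around [ape::nj()] for oligotype Hamming distances, with
#' negative branch lengths clamped to zero. With fewer than three tips a
#' trivial tree is returned with a warning.
#'
#' @param dists Symmetric non-negative distance matrix with dimnames.
#' @return A `phylo` tree.
#' @export
nj_tree <- function(dists) {
  d <- as.matrix(dists)
  if (any(d < 0)) abort("distances must be non-negative")
  n <- nrow(d)
  if (n < 2L) abort("need at least two tips")
  if (n == 2L) {
    warn("fewer than 3 tips: returning a trivial two-tip tree")
    phy <- structure(
      list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
           tip.label = rownames(d),
           edge.length = rep(d[1L, 2L] / 2, 2L), Nnode = 1L),
      class = "phylo", order = "cladewise")
    return(phy)
  }
  phy <- ape::nj(d)
  phy$edge.length <- pmax(phy$edge.length, 0)
  phy
}

#' Patristic (cophenetic) distances between tree tips
#'
#' @param tree A `phylo` tree.
#' @return Symmetric matrix of tip-to-tip path lengths.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

validate_community <- function(comm) {
  m <- if (is.data.frame(comm)) {
    x <- as.matrix(comm[, -1L, drop = FALSE])
    rownames(x) <- as.character(comm[[1L]])
    x
  } else as.matrix(comm)
  if (any(m < 0)) abort("community abundances must be non-negative")
  if (nrow(m) < 2L) abort("need at least two samples")
  if (any(rowSums(m) == 0)) abort("all-zero sample in community matrix")
  m
}

beta_mntd_pair <- function(f1, f2, D) {
  i <- which(f1 > 0); j <- which(f2 > 0)
  min_i <- apply(D[i, j, drop = FALSE], 1L, min)
  min_j <- apply(D[i, j, drop = FALSE], 2L, min)
  0.5 * (sum(f1[i] / sum(f1) * min_i) + sum(f2[j] / sum(f2) * min_j))
}

#' Abundance-weighted beta mean nearest-taxon distance
#'
#' \eqn{\beta MNTD = \frac12 [\sum_i f_i^{(k)} \min_{j \in m} D_{ij} +
#' \sum_j f_j^{(m)} \min_{i \in k} D_{ij}]} with `f` relative abundances
#' within each community and `D` patristic distances. Computed for one pair
#' or, with `pair = NULL`, for every pair of rows.
#'
#' @param comm Community matrix (samples x oligotypes) or tibble with a
#'   leading sample-id column.
#' @param tree `phylo` tree whose tips cover all oligotypes in `comm`.
#' @param pair Optional length-2 vector of sample names/indices.
#' @return A single value, or a tibble (sample_a, sample_b, bmntd).
#' @export
beta_mntd <- function(comm, tree, pair = NULL) {
  m <- validate_community(comm)
  D <- patristic_distances(tree)
  miss <- setdiff(colnames(m), rownames(D))
  if (length(miss)) {
    abort(paste0("tree is missing tips: ", paste(miss, collapse = ", ")))
  }
  D <- D[colnames(m), colnames(m)]
  if (!is.null(pair)) {
    return(beta_mntd_pair(m[pair[1L], ], m[pair[2L], ], D))
  }
  pairs <- combn(rownames(m), 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    tibble(sample_a = pairs[1L, k], sample_b = pairs[2L, k],
           bmntd = beta_mntd_pair(m[pairs[1L, k], ], m[pairs[2L, k], ], D))
  })
}

#' Beta nearest-taxon index against a tip-shuffle null
#'
#' The null shuffles oligotype labels across the tips of the (fixed) tree
#' and recomputes beta-MNTD; beta-NTI is the z-score
#' \eqn{(obs - \bar{null}) / sd(null)}. A degenerate null (sd = 0, e.g. a
#' star tree with equal tip distances) yields beta-NTI = 0 with a warning.
#'
#' @inheritParams beta_mntd
#' @param reps Number of tip shuffles (default 999).
#' @param seed Optional seed.
#' @return Tibble: sample_a, sample_b, bmntd, null_mean, null_sd, bnti.
#' @export
beta_nti <- function(comm, tree, reps = 999L, seed = NULL) {
  if (reps < 2L) abort("reps must be >= 2")
  m <- validate_community(comm)
  D <- patristic_distances(tree)[colnames(m), colnames(m)]
  obs <- beta_mntd(m, tree)
  with_seed(seed, {
    k <- ncol(m)
    nulls <- array(NA_real_, dim = c(nrow(obs), reps))
    for (r in seq_len(reps)) {
      perm <- sample.int(k)
      Dn <- D[perm, perm]
      dimnames(Dn) <- dimnames(D)
      for (p in seq_len(nrow(obs))) {
        nulls[p, r] <- beta_mntd_pair(m[obs$sample_a[p], ],
                                      m[obs$sample_b[p], ], Dn)
      }
    }
    mu <- rowMeans(nulls)
    sdv <- apply(nulls, 1L, sd)
    z <- (obs$bmntd - mu) / sdv
    if (any(sdv == 0)) {
      warn("degenerate null (sd = 0) for some pairs: beta-NTI set to 0")
      z[sdv == 0] <- 0
    }
    obs$null_mean <- mu
    obs$null_sd <- sdv
    obs$bnti <- z
    obs
  })
}

bray_curtis_pair <- function(x, y) {
  sum(abs(x - y)) / sum(x + y)
}

#' Abundance-weighted Raup-Crick index on Bray-Curtis dissimilarity
#'
#' For each pair the null assembles each community afresh from the
#' metacommunity (all samples): its observed richness of oligotypes is
#' drawn with probability proportional to occupancy across samples, each
#' drawn oligotype receives one individual, and the remaining abundance is
#' distributed multinomially proportional to metacommunity relative
#' abundances. \eqn{RC = 2[(\#null < obs) + \frac12 (\#null = obs)]/reps - 1},
#' bounded in `[-1, 1]`. A one-oligotype metacommunity returns 0 by
#' convention.
#'
#' @inheritParams beta_mntd
#' @param reps Number of null assemblies (default 999).
#' @param seed Optional seed.
#' @return Tibble: sample_a, sample_b, bray_curtis, rc_bray.
#' @export
rc_bray <- function(comm, reps = 999L, seed = NULL) {
  if (reps < 2L) abort("reps must be >= 2")
  m <- validate_community(comm)
  k <- ncol(m)
  occupancy <- colSums(m > 0)
  meta_ab <- colSums(m)
  pairs <- combn(rownames(m), 2L)
  with_seed(seed, {
    purrr::map_dfr(seq_len(ncol(pairs)), function(idx) {
      a <- pairs[1L, idx]; b <- pairs[2L, idx]
      obs <- bray_curtis_pair(m[a, ], m[b, ])
      if (sum(meta_ab > 0) < 2L) {
        return(tibble(sample_a = a, sample_b = b, bray_curtis = obs,
                      rc_bray = 0))
      }
      null_one <- function(total, rich) {
        picked <- sample.int(k, rich, prob = occupancy)
        v <- numeric(k)
        v[picked] <- 1
        if (total > rich) {
          extra <- rmultinom(1L, total - rich, meta_ab[picked])
          v[picked] <- v[picked] + extra
        }
        v
      }
      ra <- sum(m[a, ] > 0); rb <- sum(m[b, ] > 0)
      ta <- round(sum(m[a, ])); tb <- round(sum(m[b, ]))
      lt <- 0; eq <- 0
      for (r in seq_len(reps)) {
        bc <- bray_curtis_pair(null_one(ta, ra), null_one(tb, rb))
        if (bc < obs - 1e-12) lt <- lt + 1
        else if (abs(bc - obs) <= 1e-12) eq <- eq + 1
      }
      tibble(sample_a = a, sample_b = b, bray_curtis = obs,
             rc_bray = 2 * (lt + 0.5 * eq) / reps - 1)
    })
  })
}

#' Partition pairwise turnover into five assembly processes
#'
#' Classifies each sample pair: beta-NTI < -2 homogeneous selection;
#' beta-NTI > +2 variable selection; otherwise RC < -0.95 homogenizing
#' dispersal; RC > +0.95 dispersal limitation (+ drift); else ecological
#' drift. Fractions are reported over the classified pairs.
#'
#' @param bnti [beta_nti()] output (needs columns sample_a, sample_b,
#'   bnti).
#' @param rc [rc_bray()] output (sample_a, sample_b, rc_bray).
#' @return A `process_partition`: tibble of per-process fractions and
#'   counts; pairs present in only one input are excluded with a warning.
#' @export
partition_processes <- function(bnti, rc) {
  key <- function(df) paste(pmin(df$sample_a, df$sample_b),
                            pmax(df$sample_a, df$sample_b), sep = "|")
  bnti$.key <- key(bnti); rc$.key <- key(rc)
  joined <- dplyr::inner_join(
    bnti[, c(".key", "bnti")], rc[, c(".key", "rc_bray")], by = ".key")
  n_missing <- nrow(bnti) + nrow(rc) - 2L * nrow(joined)
  if (n_missing > 0L) {
    warn(paste0(n_missing, " unmatched pair(s) excluded from the ",
                "partition"))
  }
  cls <- dplyr::case_when(
    joined$bnti < -2 ~ "homogeneous_selection",
    joined$bnti > 2 ~ "variable_selection",
    joined$rc_bray < -0.95 ~ "homogenizing_dispersal",
    joined$rc_bray > 0.95 ~ "dispersal_limitation",
    TRUE ~ "ecological_drift"
  )
  levels <- c("homogeneous_selection", "homogenizing_dispersal",
              "ecological_drift", "dispersal_limitation",
              "variable_selection")
  counts <- table(factor(cls, levels = levels))
  out <- tibble(
    process = levels,
    n_pairs = as.integer(counts),
    fraction = as.numeric(counts) / nrow(joined)
  )
  structure(list(partition = out, n_pairs = nrow(joined),
                 n_excluded = as.integer(max(0L, n_missing))),
            class = "process_partition")
}

#' @export
print.process_partition <- function(x, ...) {
  cat("<process_partition> over", x$n_pairs, "pairs\n")
  print(x$partition)
  invisible(x)
}

#' @export
tidy.process_partition <- function(x, ...) x$partition

#' @export
glance.process_partition <- function(x, ...) {
  wide <- setNames(as.list(x$partition$fraction), x$partition$process)
  dplyr::bind_cols(as_tibble(wide), tibble(n_pairs = x$n_pairs))
}
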