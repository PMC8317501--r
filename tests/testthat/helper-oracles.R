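# Brute-force oracles: every statistic recomputed by expanding counts into
# individual sequences and looping, independent of the frequency-weighted
# implementations they check.

# expand a count matrix into one row per individual sequence
expand_individuals <- function(cm) {
  cm <- as.matrix(cm)
  out <- NULL
  for (s in colnames(cm)) {
    for (a in rownames(cm)) {
      k <- cm[a, s]
      if (k > 0) out <- rbind(out, data.frame(oligo = rep(a, k),
                                              site = rep(s, k)))
    }
  }
  out
}

# H equals the fraction of unordered individual pairs that differ
# (the n/(n-1) correction folds in exactly)
oracle_h <- function(cvec) {
  inds <- rep(seq_along(cvec), times = cvec)
  n <- length(inds)
  pairs <- combn(n, 2)
  mean(inds[pairs[1, ]] != inds[pairs[2, ]])
}

oracle_pi <- function(cvec, d) {
  inds <- rep(seq_along(cvec), times = cvec)
  n <- length(inds)
  pairs <- combn(n, 2)
  mean(d[cbind(inds[pairs[1, ]], inds[pairs[2, ]])])
}

# explicit-expansion two-level AMOVA for one site pair
oracle_amova <- function(c1, c2, d) {
  lab <- c(rep(1L, sum(c1)), rep(2L, sum(c2)))
  oligo <- c(rep(seq_along(c1), times = c1), rep(seq_along(c2), times = c2))
  N <- length(lab)
  d2 <- d[oligo, oligo]^2
  ssd_total <- sum(d2) / (2 * N)
  ssd_within <- 0
  for (p in 1:2) {
    idx <- which(lab == p)
    ssd_within <- ssd_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - 2)
  n_sizes <- c(sum(c1), sum(c2))
  n_prime <- (N - sum(n_sizes^2) / N) / 1
  sigma_a <- (ssd_among / 1 - sigma_w) / n_prime
  if (sigma_a + sigma_w <= 0) return(0)
  max(0, min(1, sigma_a / (sigma_a + sigma_w)))
}

# per-individual nearest-neighbour fractions
oracle_snn <- function(cm, d) {
  inds <- expand_individuals(cm)
  n <- nrow(inds)
  x <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[inds$oligo[i], inds$oligo[-i]]
    dmin <- min(di)
    nn <- which(di == dmin)
    sites <- inds$site[-i][nn]
    x[i] <- mean(sites == inds$site[i])
  }
  mean(x)
}

# exhaustive Steiner search: minimal MST cost over the terminals plus up to
# `max_extra` added sequences from the full alphabet^L space
oracle_steiner <- function(seqs, alphabet = c("A", "C"), max_extra = 1) {
  L <- nchar(seqs[1])
  all_seqs <- do.call(paste0, expand.grid(rep(list(alphabet), L),
                                          stringsAsFactors = FALSE))
  candidates <- setdiff(all_seqs, seqs)
  cost <- function(ss) {
    d <- hamming_distances(ss)
    # Prim
    n <- nrow(d); intree <- c(TRUE, rep(FALSE, n - 1)); best <- d[1, ]
    tot <- 0
    for (k in seq_len(n - 1)) {
      cand <- which(!intree)
      pick <- cand[which.min(best[cand])]
      tot <- tot + unname(best[pick]); intree[pick] <- TRUE
      best <- pmin(best, d[pick, ])
    }
    tot
  }
  best_cost <- cost(seqs)
  best_extra <- character(0)
  for (k in seq_len(max_extra)) {
    combs <- combn(candidates, k, simplify = FALSE)
    for (extra in combs) {
      cc <- cost(c(seqs, extra))
      if (cc < best_cost - 1e-9) {
        best_cost <- cc
        best_extra <- extra
      }
    }
  }
  list(cost = best_cost, extra = best_extra)
}

# random small count-matrix instance with sequences, for oracle equivalence
random_instance <- function(seed, max_n = 50) {
  withr::with_seed(seed, {
    k <- sample(2:6, 1)
    L <- 8
    repeat {
      seqs <- vapply(seq_len(k), function(i) {
        paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
      }, "")
      if (!anyDuplicated(seqs)) break
    }
    names(seqs) <- paste0("OT", seq_len(k))
    n_sites <- sample(2:4, 1)
    cm <- matrix(0L, k, n_sites,
                 dimnames = list(names(seqs),
                                 paste0("S", seq_len(n_sites))))
    total <- sample(8:max_n, 1)
    draws <- table(factor(sample(k, total, replace = TRUE), levels = 1:k),
                   factor(sample(n_sites, total, replace = TRUE),
                          levels = seq_len(n_sites)))
    cm[] <- as.integer(draws)
    # ensure every site has at least 2 individuals
    for (s in seq_len(n_sites)) {
      while (sum(cm[, s]) < 2) {
        idx <- sample(k, 1)
        cm[idx, s] <- cm[idx, s] + 1L
      }
    }
    cm <- cm[rowSums(cm) > 0, , drop = FALSE]
    list(cm = cm, seqs = seqs[rownames(cm)],
         dists = hamming_distances(seqs[rownames(cm)]))
  })
}

# small read set builder: named counts of sequences per site
make_reads <- function(..., sites = NULL) {
  specs <- list(...)
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    tibble::tibble(sample = sp$site, seq = rep(sp$seq, sp$n))
  })
  out <- dplyr::bind_rows(rows)
  out$read_id <- paste0(out$sample, "_", seq_len(nrow(out)))
  out
}

# Prim MST cost on a full distance matrix
oracle_mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1)); best <- d[1, ]; tot <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!intree)
    pick <- cand[which.min(best[cand])]
    tot <- tot + unname(best[pick]); intree[pick] <- TRUE
    best <- pmin(best, d[pick, ])
  }
  tot
}
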