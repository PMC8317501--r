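# Assembly-process machinery: NJ closed forms, beta-MNTD hand values and
# the independent picante cross-check, null-model guards, Raup-Crick
# regimes, and the threshold classification.

star_tree <- function(lengths) {
  # star: one internal node, tips t1..tn with the given branch lengths
  n <- length(lengths)
  structure(list(
    edge = cbind(rep(n + 1L, n), seq_len(n)),
    tip.label = paste0("t", seq_len(n)),
    edge.length = lengths, Nnode = 1L),
    class = "phylo", order = "cladewise")
}

test_that("NJ recovers the closed form for three equidistant tips", {
  d <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d) <- 0
  tr <- nj_tree(d)
  # b_i = (d_ij + d_ik - d_jk) / 2 = 1 for every tip
  expect_equal(sort(unname(tr$edge.length)), rep(1, 3))
})

test_that("NJ reproduces an additive four-taxon metric exactly", {
  # tree ((a:1, b:2):1.5, c:3, d:1): additive distances
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 1 + 1.5 + 3
  d["a", "d"] <- d["d", "a"] <- 1 + 1.5 + 1
  d["b", "c"] <- d["c", "b"] <- 2 + 1.5 + 3
  d["b", "d"] <- d["d", "b"] <- 2 + 1.5 + 1
  d["c", "d"] <- d["d", "c"] <- 4
  tr <- nj_tree(d)
  expect_equal(patristic_distances(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("NJ topology is invariant to input order", {
  inst <- random_instance(321)
  d <- inst$dists
  perm <- c(3, 1, 2)[seq_len(min(3, nrow(d)))]
  if (nrow(d) >= 4) perm <- sample(nrow(d))
  tr1 <- nj_tree(d)
  tr2 <- nj_tree(d[perm, perm])
  expect_equal(patristic_distances(tr1)[rownames(d), rownames(d)],
               patristic_distances(tr2)[rownames(d), rownames(d)],
               tolerance = 1e-10)
})

test_that("two-tip trees are returned trivially with a warning", {
  d <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_warning(tr <- nj_tree(d), "trivial")
  expect_equal(patristic_distances(tr)["a", "b"], 4)
})

test_that("beta-MNTD matches hand-evaluated cases", {
  # identical communities: 0
  tr <- star_tree(c(0.1, 0.5, 0.1))
  comm <- rbind(A = c(t1 = 1, t2 = 1, t3 = 0),
                B = c(t1 = 1, t2 = 1, t3 = 0))
  expect_equal(beta_mntd(comm, tr, pair = c("A", "B")), 0)
  # two single-taxon communities at patristic distance 0.4
  comm2 <- rbind(A = c(t1 = 1, t2 = 0, t3 = 0),
                 B = c(t1 = 0, t2 = 0, t3 = 1))
  expect_equal(beta_mntd(comm2, tr, pair = c("A", "B")), 0.2)
  # weights (0.5, 0.5) against one taxon at distances 0.2 / 0.6
  comm3 <- rbind(A = c(t1 = 1, t2 = 1, t3 = 0),
                 B = c(t1 = 0, t2 = 0, t3 = 1))
  # d(t1,t3) = 0.2, d(t2,t3) = 0.6
  expect_equal(beta_mntd(comm3, tr, pair = c("A", "B")),
               0.5 * (0.5 * 0.2 + 0.5 * 0.6) + 0.5 * 0.2)
  # symmetry and non-negativity on random data
  inst <- random_instance(11)
  tr2 <- nj_tree(inst$dists)
  cm <- t(inst$cm)
  expect_equal(beta_mntd(cm, tr2, pair = c(1, 2)),
               beta_mntd(cm, tr2, pair = c(2, 1)))
  expect_gte(beta_mntd(cm, tr2, pair = c(1, 2)), 0)
})

test_that("beta-MNTD agrees with picante::comdistnt", {
  skip_if_not_installed("picante")
  for (seed in c(5, 15)) {
    inst <- random_instance(seed)
    tr <- nj_tree(inst$dists)
    comm <- t(inst$cm)
    ours <- beta_mntd(comm, tr)
    ref <- as.matrix(picante::comdistnt(comm, stats::cophenetic(tr),
                                        abundance.weighted = TRUE))
    for (r in seq_len(nrow(ours))) {
      expect_equal(ours$bmntd[r],
                   ref[ours$sample_a[r], ours$sample_b[r]],
                   tolerance = 1e-10)
    }
  }
})

test_that("a fully symmetric star collapses the null: beta-NTI = 0", {
  tr <- star_tree(rep(0.3, 4))
  comm <- rbind(A = c(t1 = 3, t2 = 1, t3 = 0, t4 = 0),
                B = c(t1 = 0, t2 = 0, t3 = 2, t4 = 2))
  expect_warning(z <- beta_nti(comm, tr, reps = 25, seed = 1),
                 "degenerate null")
  expect_equal(z$bnti, 0)
})

test_that("beta-NTI is reproducible under a fixed seed", {
  inst <- random_instance(61)
  tr <- nj_tree(inst$dists)
  comm <- t(inst$cm)
  z1 <- beta_nti(comm, tr, reps = 49, seed = 8)
  z2 <- beta_nti(comm, tr, reps = 49, seed = 8)
  expect_identical(z1, z2)
})

test_that("Raup-Crick hits its three regimes", {
  # identical communities in a rich metacommunity: RC near -1
  comm <- rbind(A = c(5, 5, 5, 5, 5, 5),
                B = c(5, 5, 5, 5, 5, 5),
                C = c(2, 8, 1, 9, 3, 7),
                D = c(9, 1, 8, 2, 7, 3))
  colnames(comm) <- paste0("t", 1:6)
  rc <- rc_bray(comm, reps = 199, seed = 2)
  ab <- rc$rc_bray[rc$sample_a == "A" & rc$sample_b == "B"]
  expect_lt(ab, -0.9)
  # one-oligotype metacommunity: RC = 0 by convention
  comm1 <- rbind(A = c(t1 = 5), B = c(t1 = 8))
  expect_equal(rc_bray(comm1, reps = 49, seed = 3)$rc_bray, 0)
  # disjoint communities over a large even metacommunity: RC near +1
  k <- 40
  m <- matrix(5, 6, k, dimnames = list(paste0("S", 1:6),
                                       paste0("t", 1:k)))
  m["S1", ] <- c(rep(20, k / 2), rep(0, k / 2))
  m["S2", ] <- c(rep(0, k / 2), rep(20, k / 2))
  rc2 <- rc_bray(m, reps = 199, seed = 4)
  expect_gte(rc2$rc_bray[rc2$sample_a == "S1" & rc2$sample_b == "S2"],
             0.95)
  # bounds hold everywhere
  expect_true(all(rc2$rc_bray >= -1 & rc2$rc_bray <= 1))
})

test_that("threshold classification follows the two-index rule", {
  pairs <- tibble::tibble(
    sample_a = c("a", "a", "a", "b", "b"),
    sample_b = c("b", "c", "d", "c", "d"),
    bnti = c(-3, 1, 0, 2.5, 0),
    rc_bray = c(0.2, 0.99, 0, 0.5, -0.99))
  part <- partition_processes(pairs, pairs[, c("sample_a", "sample_b",
                                               "rc_bray")])
  tb <- part$partition
  get <- function(p) tb$n_pairs[tb$process == p]
  expect_equal(get("homogeneous_selection"), 1L)
  expect_equal(get("dispersal_limitation"), 1L)
  expect_equal(get("ecological_drift"), 1L)
  expect_equal(get("variable_selection"), 1L)
  expect_equal(get("homogenizing_dispersal"), 1L)
  expect_equal(sum(tb$fraction), 1, tolerance = 1e-12)
})

test_that("unmatched pairs are excluded with a warning", {
  bnti <- tibble::tibble(sample_a = c("a", "a"), sample_b = c("b", "c"),
                         bnti = c(0, 0))
  rc <- tibble::tibble(sample_a = "a", sample_b = "b", rc_bray = 0)
  expect_warning(part <- partition_processes(bnti, rc), "unmatched")
  expect_equal(part$n_pairs, 1L)
})
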