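# Frequency-weighted diversity, AMOVA, Snn and Nm: hand-computed examples,
# brute-force expansion oracles, permutation behaviour, rarefaction against
# the hypergeometric closed form.

two_site_cm <- function(c1, c2, ids = NULL) {
  k <- length(c1)
  ids <- ids %||% paste0("OT", seq_len(k))
  matrix(c(c1, c2), k, 2, dimnames = list(ids, c("S1", "S2")))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("diversity indices match hand-evaluated formulas", {
  seqs <- c(OT1 = "AAAA", OT2 = "AAAT")        # d = 1
  cm <- matrix(c(2, 2), 2, 1, dimnames = list(names(seqs), "S1"))
  div <- diversity_indices(cm, seqs)
  expect_equal(div$h, 4 / 3 * 0.5)             # 0.6667
  expect_equal(div$pi, 4 / 3 * 2 * 0.25 * 1)   # 0.6667
  expect_equal(div$k, 2L)
  expect_equal(div$s, 1L)
  cm2 <- matrix(c(3, 1), 2, 1, dimnames = list(names(seqs), "S1"))
  div2 <- diversity_indices(cm2, seqs)
  expect_equal(div2$h, 0.5)
  expect_equal(div2$pi, 0.5)
})

test_that("a single oligotype gives k=1, S=0, H=0, Pi=0", {
  div <- diversity_indices(
    matrix(5, 1, 1, dimnames = list("OT1", "S1")), c(OT1 = "ACGT"))
  expect_equal(div[, c("k", "s", "h", "pi")],
               tibble::tibble(k = 1L, s = 0L, h = 0, pi = 0))
})

test_that("H and Pi equal brute-force pairwise expansions", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    div <- diversity_indices(inst$cm, inst$seqs)
    for (j in seq_len(ncol(inst$cm))) {
      cvec <- inst$cm[, j]
      expect_equal(div$h[j], oracle_h(cvec), tolerance = 1e-12)
      expect_equal(div$pi[j], oracle_pi(cvec, inst$dists),
                   tolerance = 1e-12)
    }
  }
})

test_that("sites with fewer than two sequences yield explicit NA", {
  cm <- two_site_cm(c(1, 0), c(3, 2))
  div <- diversity_indices(cm, c(OT1 = "AA", OT2 = "AT"))
  expect_true(is.na(div$h[div$site == "S1"]))
  expect_true(is.na(div$pi[div$site == "S1"]))
  expect_false(is.na(div$h[div$site == "S2"]))
})

test_that("rarefied richness matches the hypergeometric expectation", {
  # site of 10+10 rarefied to n = 10: E[k] = 2 - 2 C(10,10)/C(20,10)
  seqs <- c(OT1 = "AAAA", OT2 = "AAAT")
  cm <- two_site_cm(c(10, 10), c(5, 5))
  rar <- rarefied_indices(cm, seqs, B = 1000, seed = 7)
  expect_equal(unique(rar$n_rarefied), 10)
  e_k <- 2 - 2 * choose(10, 10) / choose(20, 10)
  row <- rar[rar$site == "S1", ]
  se <- sqrt(e_k * 0.01)                     # crude bound; var(k) < 0.01
  expect_lt(abs(row$k - e_k), 0.01)
  # a site already at n_min has zero-width intervals
  row2 <- rar[rar$site == "S2", ]
  expect_equal(row2$k_lo, row2$k_hi)
  expect_equal(row2$h, 10 / 9 * 0.5)
})

test_that("rarefaction is reproducible under a fixed seed", {
  seqs <- c(OT1 = "AAAA", OT2 = "AAAT", OT3 = "TTAA")
  cm <- two_site_cm(c(10, 6, 3), c(4, 4, 0))
  r1 <- rarefied_indices(cm, seqs, B = 50, seed = 3)
  r2 <- rarefied_indices(cm, seqs, B = 50, seed = 3)
  expect_identical(r1, r2)
})

test_that("fixed differences give Fst = 1; identical frequencies give 0", {
  seqs <- c(OT1 = "AAAA", OT2 = "TTTT")
  cm <- two_site_cm(c(4, 0), c(0, 5))
  expect_equal(amova_structure(cm, seqs, mode = "fst")$statistic, 1)
  cm2 <- two_site_cm(c(6, 3), c(6, 3))
  expect_equal(amova_structure(cm2, seqs, mode = "fst")$statistic, 0)
  expect_equal(amova_structure(cm2, seqs, mode = "phist")$statistic, 0)
})

test_that("Phi-st matches the explicit-expansion AMOVA oracle", {
  # the spec-style toy: S1 = {h1:3, h2:1}, S2 = {h2:3, h3:1} with
  # d(h1,h2) = d(h2,h3) = 1, d(h1,h3) = 2
  seqs <- c(h1 = "AA", h2 = "AT", h3 = "TT")
  cm <- matrix(c(3, 1, 0, 0, 3, 1), 3, 2,
               dimnames = list(names(seqs), c("S1", "S2")))
  got <- amova_structure(cm, seqs, mode = "phist")$statistic
  d <- hamming_distances(seqs)
  expect_equal(got, oracle_amova(cm[, 1], cm[, 2], d), tolerance = 1e-12)
  # random instances, both metrics
  for (seed in 1:25) {
    inst <- random_instance(seed + 100)
    ident <- 1 - diag(nrow(inst$dists))
    dimnames(ident) <- dimnames(inst$dists)
    pairs <- combn(colnames(inst$cm), 2)
    fst <- amova_structure(inst$cm, inst$seqs, mode = "fst")
    phist <- amova_structure(inst$cm, inst$seqs, mode = "phist")
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      expect_equal(
        fst$statistic[fst$site_a == a & fst$site_b == b],
        oracle_amova(inst$cm[, a], inst$cm[, b], ident), tolerance = 1e-12)
      expect_equal(
        phist$statistic[phist$site_a == a & phist$site_b == b],
        oracle_amova(inst$cm[, a], inst$cm[, b], inst$dists),
        tolerance = 1e-12)
    }
  }
})

test_that("Fst and Phi-st stabilize under count duplication", {
  # the sample-size corrections (N - P, n') depend on absolute counts, so
  # exact duplication invariance cannot hold; the estimator must instead
  # converge as every count is scaled up
  inst <- random_instance(999)
  for (mode in c("fst", "phist")) {
    s64 <- amova_structure(inst$cm * 64, inst$seqs, mode = mode)$statistic
    s128 <- amova_structure(inst$cm * 128, inst$seqs,
                            mode = mode)$statistic
    s256 <- amova_structure(inst$cm * 256, inst$seqs,
                            mode = mode)$statistic
    expect_lt(max(abs(s128 - s256)), max(abs(s64 - s256)) + 1e-12)
    expect_lt(max(abs(s128 - s256)), 0.005)
  }
})

test_that("permutation p-values behave at the boundaries", {
  seqs <- c(OT1 = "AAAA", OT2 = "TTTT")
  cm <- two_site_cm(c(30, 0), c(0, 30))
  res <- amova_test(cm, seqs, mode = "fst", perms = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)        # no null table reaches Fst = 1
  # degenerate pair: a single oligotype in total
  cm_deg <- matrix(c(5, 4), 1, 2, dimnames = list("OT1", c("S1", "S2")))
  res_deg <- amova_test(cm_deg, c(OT1 = "AAAA"), mode = "fst",
                        perms = 99, seed = 1)
  expect_equal(res_deg$p_value, 1)
  # reproducibility
  r1 <- amova_test(cm, seqs, mode = "phist", perms = 99, seed = 42)
  r2 <- amova_test(cm, seqs, mode = "phist", perms = 99, seed = 42)
  expect_identical(r1, r2)
})

test_that("Snn matches hand values and the expansion oracle", {
  # one shared oligotype, sites of size 2 and 2: every sequence's
  # neighbours are its 3 identical copies, x = 1/3
  cm <- matrix(c(2, 2), 1, 2, dimnames = list("OT1", c("S1", "S2")))
  expect_equal(snn_statistic(cm, c(OT1 = "AAAA")), 1 / 3)
  # two sites sharing nothing, every oligotype in >= 2 copies: Snn = 1
  seqs <- c(OT1 = "AAAA", OT2 = "AATT", OT3 = "TTTT")
  cm2 <- matrix(c(3, 2, 0, 0, 0, 4), 3, 2,
                dimnames = list(names(seqs), c("S1", "S2")))
  expect_equal(snn_statistic(cm2, seqs), 1)
  for (seed in 1:25) {
    inst <- random_instance(seed + 500)
    expect_equal(snn_statistic(inst$cm, inst$seqs),
                 oracle_snn(inst$cm, inst$dists), tolerance = 1e-12)
  }
})

test_that("Snn permutation test is reproducible and bounded", {
  inst <- random_instance(77)
  r1 <- snn_test(inst$cm, inst$seqs, perms = 99, seed = 5)
  r2 <- snn_test(inst$cm, inst$seqs, perms = 99, seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$snn, 0); expect_lte(r1$snn, 1)
  expect_gt(r1$p_value, 0); expect_lte(r1$p_value, 1)
})

test_that("the island-model Nm surrogate evaluates its closed form", {
  expect_equal(nm_island(1 / 3), 1)
  expect_equal(nm_island(0.2), 2)
  expect_equal(nm_island(1), 0)
  expect_equal(nm_island(0), Inf)
  expect_error(nm_island(1.2), "\\[0, 1\\]")
})
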