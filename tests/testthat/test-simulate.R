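# Structured-coalescent simulator: event-rate scaling, mutation model,
# read sampling, determinism, and the island-model identity-probability
# cross-check.

one_deme <- function(n_lin, theta = 1) {
  scenario_config(deme_labels = "A", provinces = "p", sample_depths = 5L,
                  n_lineages_per_deme = n_lin, theta = theta,
                  migration = matrix(0, 1, 1), seq_length = 50L,
                  error_rate = 0)
}

test_that("a single lineage yields a trivial genealogy with no events", {
  g <- simulate_genealogy(one_deme(1L), seed = 1)
  expect_equal(g$n_tips, 1L)
  expect_equal(max(g$node_time), 0)
})

test_that("pairwise coalescent time matches the exponential expectation", {
  # 1 deme, 2 lineages, theta = 1: pair coalesces at rate 2/theta = 2,
  # so E[TMRCA] = theta / 2 = 0.5
  cfg <- one_deme(2L, theta = 1)
  tm <- vapply(seq_len(2000), function(i) {
    max(simulate_genealogy(cfg, seed = i)$node_time)
  }, numeric(1))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 0.5), 3 * se)
})

test_that("an empty-migration second deme leaves the single-deme law alone", {
  # 2 demes, zero migration, lineages only in deme A: same distribution
  cfg2 <- scenario_config(deme_labels = c("A", "B"), provinces = c("p", "p"),
                          sample_depths = c(5L, 5L),
                          n_lineages_per_deme = c(2L, 0L), theta = 1,
                          migration = matrix(0, 2, 2), seq_length = 50L,
                          error_rate = 0)
  tm <- vapply(seq_len(1000), function(i) {
    max(simulate_genealogy(cfg2, seed = i)$node_time)
  }, numeric(1))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 0.5), 3 * se)
})

test_that("unconnectable demes error without an isolation divergence", {
  cfg <- scenario_config(deme_labels = c("A", "B"), provinces = c("p", "q"),
                         sample_depths = c(5L, 5L),
                         n_lineages_per_deme = c(2L, 2L), theta = 1,
                         migration = matrix(0, 2, 2), seq_length = 50L,
                         error_rate = 0, isolation_divergence = NULL)
  expect_error(simulate_genealogy(cfg, seed = 1), "disconnected history")
})

test_that("isolated groups join at the configured vicariant divergence", {
  cfg <- scenario_config(deme_labels = c("A", "B"), provinces = c("p", "q"),
                         sample_depths = c(5L, 5L),
                         n_lineages_per_deme = c(2L, 2L), theta = 1,
                         migration = matrix(0, 2, 2), seq_length = 50L,
                         error_rate = 0, isolation_divergence = 7)
  g <- simulate_genealogy(cfg, seed = 3)
  inner <- sort(g$node_time[g$node_time > 0])
  expect_equal(max(g$node_time), max(inner[length(inner) - 1L]) + 7)
})

test_that("mutation counts on a fixed two-tip genealogy are Poisson(theta t)", {
  # two tips joined at depth t: two branches of length t, each
  # Poisson(theta/2 * t), so the total is Poisson(theta * t)
  t_depth <- 1.5; theta <- 2
  g <- structure(list(
    n_tips = 2L, tip_label = c("A_l1", "A_l2"), tip_deme = c("A", "A"),
    parent = c(3L, 3L, 0L), node_time = c(0, 0, t_depth),
    branch_length = c(t_depth, t_depth, 0), root = 3L),
    class = "genealogy")
  diffs <- vapply(seq_len(1000), function(i) {
    tr <- drop_mutations(g, theta = theta, seq_length = 370, seed = i)
    s <- tr$haplotypes$seq[match(tr$tip_hap, tr$haplotypes$hap_id)]
    sum(strsplit(s[1], "")[[1]] != strsplit(s[2], "")[[1]])
  }, numeric(1))
  lambda <- theta * t_depth
  # recurrent hits make observed differences <= mutation count; at
  # lambda/L = 3/370 the bias is under 1%, inside Monte-Carlo error
  expect_lt(abs(mean(diffs) - lambda), 4 * sd(diffs) / sqrt(length(diffs)))
  expect_lt(abs(stats::var(diffs) / mean(diffs) - 1), 0.15)
})

test_that("theta = 0 mutations leave all tips identical", {
  g <- simulate_genealogy(one_deme(6L), seed = 5)
  tr <- drop_mutations(g, theta = 0, seq_length = 40, seed = 6)
  expect_equal(nrow(tr$haplotypes), 1L)
})

test_that("panmictic mean pairwise difference matches the coalescent law", {
  # theta = 2: expected mean pairwise difference equals theta
  cfg <- one_deme(2L, theta = 2)
  pis <- vapply(seq_len(500), function(i) {
    g <- simulate_genealogy(cfg, seed = i)
    tr <- drop_mutations(g, theta = 2, seq_length = 370,
                         seed = derive_seed(i, 1))
    s <- tr$haplotypes$seq[match(tr$tip_hap, tr$haplotypes$hap_id)]
    sum(strsplit(s[1], "")[[1]] != strsplit(s[2], "")[[1]])
  }, numeric(1))
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 2), 3 * se)
})

test_that("read sampling conserves depths and honours error_rate = 0", {
  cfg <- scenario_barrier(seed = 2, error_rate = 0)
  g <- simulate_genealogy(cfg, seed = 2)
  tr <- drop_mutations(g, 2, 370, seed = 3)
  reads <- sample_reads(tr, cfg, seed = 4)
  depths <- table(reads$sample)
  expect_equal(as.integer(depths[names(cfg$sample_depths)]),
               unname(cfg$sample_depths))
  expect_true(all(unique(reads$seq) %in% tr$haplotypes$seq))
  rt <- attr(reads, "read_truth")
  sums <- tapply(rt$n, rt$deme, sum)
  expect_equal(as.integer(sums[names(cfg$sample_depths)]),
               unname(cfg$sample_depths))
})

test_that("per-read error fraction matches the binomial closed form", {
  cfg <- scenario_config(deme_labels = "A", provinces = "p",
                         sample_depths = 5000L, n_lineages_per_deme = 1L,
                         theta = 2, migration = matrix(0, 1, 1),
                         seq_length = 370L, error_rate = 0.001)
  g <- simulate_genealogy(cfg, seed = 1)
  tr <- drop_mutations(g, theta = 0, seq_length = 370, seed = 1)
  reads <- sample_reads(tr, cfg, seed = 9)
  truth_seq <- tr$haplotypes$seq[1]
  frac <- mean(reads$seq != truth_seq)
  p <- 1 - (1 - 0.001)^370
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / 5000))
})

test_that("error_rate outside [0, 1) is rejected", {
  expect_error(scenario_config(error_rate = 1), "error_rate")
  expect_error(scenario_config(error_rate = -0.1), "error_rate")
})

test_that("dataset generation is byte-identical for identical seeds", {
  cfg <- scenario_barrier(seed = 42, n_lineages_per_deme = 5L)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("island-model Fst agrees with the identity-probability oracle", {
  # symmetric 2-deme exchange: the AMOVA Fst computed from simulated counts
  # is compared, over replicates, with the same quantity estimated from
  # probabilities of identity (within-deme vs between-deme), an independent
  # formulation of the same expectation
  m <- 1
  cfg <- scenario_config(deme_labels = c("A", "B"), provinces = c("p", "q"),
                         sample_depths = c(30L, 30L),
                         n_lineages_per_deme = c(15L, 15L), theta = 2,
                         migration = matrix(c(0, m, m, 0), 2, 2),
                         seq_length = 200L, error_rate = 0)
  diffs <- vapply(seq_len(50), function(i) {
    g <- simulate_genealogy(cfg, seed = 100 + i)
    tr <- drop_mutations(g, 2, 200, seed = 200 + i)
    lc <- tr$lineage_counts
    cm <- matrix(0, nrow(tr$haplotypes), 2,
                 dimnames = list(tr$haplotypes$hap_id, c("A", "B")))
    cm[cbind(lc$hap_id, lc$deme)] <- lc$n
    fst <- amova_structure(cm, mode = "fst")$statistic
    # identity probabilities with unbiased within-deme estimator
    nA <- sum(cm[, 1]); nB <- sum(cm[, 2])
    fw <- mean(c(sum(cm[, 1] * (cm[, 1] - 1)) / (nA * (nA - 1)),
                 sum(cm[, 2] * (cm[, 2] - 1)) / (nB * (nB - 1))))
    fb <- sum(cm[, 1] * cm[, 2]) / (nA * nB)
    fst_ident <- (fw - fb) / (1 - fb)
    fst - fst_ident
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), max(3 * se, 0.02))
})
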