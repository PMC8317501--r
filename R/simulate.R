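# Structured-coalescent read simulator. Generates per-OTU aligned amplicon
# read sets with known population structure: a genealogy under the
# structured coalescent with migration, finite-sites mutations, multinomial
# read sampling per deme, and site-iid sequencing error. Time is scaled so a
# pair of lineages within deme i coalesces at rate 2/theta_i and mutations
# fall at rate theta/2 per lineage per unit time; with the default theta = 2
# the expected mean pairwise difference of a panmictic deme equals theta.

#' Simulation scenario configuration
#'
#' Bundles everything the simulator needs: deme layout, sampling depths,
#' coalescent parameters, the backward migration matrix, amplicon length and
#' sequencing error rate. Defaults emulate a four-site, three-province
#' Southern Ocean design: one maritime Antarctic site (KGI), two Patagonian
#' sites (PAT1, PAT2) and one Kerguelen site (KER), host sample sizes
#' 31/15/10/14, a 370 bp V4--V5 amplicon, and 0.1% per-base error.
#'
#' @param deme_labels Character vector of site ids.
#' @param provinces Character vector, one province per deme.
#' @param sample_depths Integer reads sampled per deme (>= 1 each).
#' @param n_lineages_per_deme Lineages per deme in the true genealogy.
#' @param theta Scaled mutation parameter; scalar or one value per deme.
#' @param migration Square backward migration matrix `M`; `M[i, j]` is the
#'   scaled rate at which a lineage currently in deme i traces its ancestry
#'   to deme j (each lineage migrates at `M[i, j] / 2`). Diagonal must be 0.
#' @param seq_length Amplicon length in aligned positions.
#' @param error_rate Per-base sequencing error probability in `[0, 1)`.
#' @param isolation_divergence Divergence time (coalescent units) at which
#'   the ancestries of deme groups with no migration path between them are
#'   joined (vicariance across a hard barrier). `NULL` forbids isolated
#'   groups: simulation then fails with a "disconnected history" error.
#' @param seed Optional integer seed recorded with the scenario.
#' @param site_table Optional tibble (site, province, lat, lon); defaults to
#'   the built-in four-site geography.
#' @return A `scenario_config` object (list).
#' @seealso [scenario_barrier()], [generate_dataset()]
#' @export
scenario_config <- function(deme_labels = c("KGI", "PAT1", "PAT2", "KER"),
                            provinces = c("Antarctica", "Patagonia",
                                          "Patagonia", "Kerguelen"),
                            sample_depths = c(31L, 15L, 10L, 14L),
                            n_lineages_per_deme = 20L,
                            theta = 2,
                            migration = NULL,
                            seq_length = 370L,
                            error_rate = 0.001,
                            isolation_divergence = 5,
                            seed = NULL,
                            site_table = NULL) {
  n <- length(deme_labels)
  if (n < 1L) abort("at least one deme is required")
  if (anyDuplicated(deme_labels)) abort("deme labels must be unique")
  if (length(provinces) != n) abort("one province per deme is required")
  sample_depths <- as.integer(rep_len(sample_depths, n))
  if (any(sample_depths < 1L)) abort("sample depths must be >= 1")
  n_lineages_per_deme <- as.integer(rep_len(n_lineages_per_deme, n))
  if (any(n_lineages_per_deme < 0L) || sum(n_lineages_per_deme) < 1L) {
    abort("at least one lineage must be sampled across demes")
  }
  theta <- rep_len(as.numeric(theta), n)
  if (any(theta <= 0)) abort("theta must be positive")
  if (!is.null(isolation_divergence) && isolation_divergence <= 0) {
    abort("isolation_divergence must be positive (or NULL)")
  }
  if (is.null(migration)) {
    migration <- matrix(1, n, n)
    diag(migration) <- 0
  }
  migration <- as.matrix(migration)
  if (!all(dim(migration) == c(n, n))) {
    abort("migration must be an n_demes x n_demes matrix")
  }
  if (any(migration < 0)) abort("migration rates must be >= 0")
  if (any(diag(migration) != 0)) abort("migration diagonal must be zero")
  seq_length <- as.integer(seq_length)
  if (seq_length < 1L) abort("seq_length must be >= 1")
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1)")
  dimnames(migration) <- list(deme_labels, deme_labels)
  if (is.null(site_table)) {
    site_table <- default_site_table()
    site_table <- site_table[match(deme_labels, site_table$site), ]
    if (anyNA(site_table$site)) {
      site_table <- tibble(site = deme_labels, province = provinces,
                           lat = NA_real_, lon = NA_real_)
    } else {
      site_table$province <- provinces
    }
  }
  structure(
    list(
      n_demes = n,
      deme_labels = deme_labels,
      provinces = setNames(provinces, deme_labels),
      sample_depths = setNames(sample_depths, deme_labels),
      n_lineages_per_deme = setNames(n_lineages_per_deme, deme_labels),
      theta = setNames(theta, deme_labels),
      migration = migration,
      seq_length = seq_length,
      error_rate = error_rate,
      isolation_divergence = isolation_divergence,
      seed = seed,
      site_table = as_tibble(site_table)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$n_demes, " demes: ",
      paste(x$deme_labels, collapse = ", "), "\n", sep = "")
  cat("  depths: ", paste(x$sample_depths, collapse = "/"),
      "  lineages: ", paste(x$n_lineages_per_deme, collapse = "/"), "\n",
      sep = "")
  cat("  theta: ", paste(format(x$theta), collapse = "/"),
      "  L = ", x$seq_length, "  error = ", x$error_rate, "\n", sep = "")
  invisible(x)
}

#' Built-in site geography
#'
#' Four Southern Ocean localities spanning three biogeographic provinces,
#' with decimal GPS coordinates.
#' @return Tibble with columns site, province, lat, lon.
#' @export
default_site_table <- function() {
  tibble(
    site     = c("KGI", "PAT1", "PAT2", "KER"),
    province = c("Antarctica", "Patagonia", "Patagonia", "Kerguelen"),
    lat      = c(-62.2154, -52.3314, -47.7519, -49.3537),
    lon      = c(-58.9455, -69.4862, -65.8678, 70.2191)
  )
}

#' Synthetic per-site environmental table
#'
#' Nine standard marine environmental variables (temperature, temperature
#' range, salinity, dissolved oxygen, pH, nitrate, phosphate, silicate,
#' chlorophyll) assigned province-level values with small site-level jitter.
#' Entirely synthetic: it stands in for a satellite/climatology extraction
#' and is labelled as such.
#'
#' @param site_table Tibble with columns site, province.
#' @param seed Seed for the site-level jitter.
#' @return Tibble, one row per site, nine numeric variables.
#' @export
synthetic_env_table <- function(site_table = default_site_table(),
                                seed = 1L) {
  base <- list(
    Antarctica = c(temperature = -0.5, temperature_range = 2.0,
                   salinity = 34.2, oxygen = 8.2, ph = 8.10,
                   nitrate = 28, phosphate = 1.9, silicate = 60,
                   chlorophyll = 0.6),
    Patagonia  = c(temperature = 8.5, temperature_range = 5.5,
                   salinity = 33.2, oxygen = 6.8, ph = 8.05,
                   nitrate = 12, phosphate = 1.1, silicate = 8,
                   chlorophyll = 1.8),
    Kerguelen  = c(temperature = 3.5, temperature_range = 3.0,
                   salinity = 33.8, oxygen = 7.6, ph = 8.08,
                   nitrate = 24, phosphate = 1.6, silicate = 20,
                   chlorophyll = 1.0)
  )
  with_seed(seed, {
    rows <- purrr::map2(site_table$site, site_table$province, function(s, p) {
      v <- base[[p]]
      if (is.null(v)) v <- colMeans(do.call(rbind, base))
      jit <- v * 0.01 * stats::rnorm(length(v))
      tibble::as_tibble_row(c(list(site = s), as.list(v + jit)))
    })
    bind_rows(rows)
  })
}

#' Dispersal-barrier scenario preset
#'
#' Two province groups separated by a hard dispersal barrier (zero
#' migration across, free migration within), emulating a polar-front-like
#' break between the Antarctic/Kerguelen group and the Patagonian pair.
#'
#' @param within Scaled migration rate within each group.
#' @param between Scaled migration rate across the barrier (default 0).
#' @param eastward_bias Multiplier applied to within-group migration in the
#'   "eastward" direction (first-listed deme towards later ones), emulating
#'   a circumpolar-current corridor; 1 = symmetric.
#' @inheritParams scenario_config
#' @inheritDotParams scenario_config
#' @return A `scenario_config`.
#' @export
scenario_barrier <- function(within = 4, between = 0, eastward_bias = 2,
                             seed = NULL, ...) {
  labels <- c("KGI", "PAT1", "PAT2", "KER")
  groups <- list(c("KGI", "KER"), c("PAT1", "PAT2"))
  M <- matrix(between, 4, 4, dimnames = list(labels, labels))
  for (g in groups) {
    idx <- match(g, labels)
    for (a in idx) for (b in idx) {
      if (a == b) next
      # backward rate: "eastward" forward flow a->b boosts backward b->a
      M[b, a] <- within * if (a < b) eastward_bias else 1
    }
  }
  diag(M) <- 0
  scenario_config(deme_labels = labels, migration = M, seed = seed, ...)
}

#' Simulate a structured-coalescent genealogy
#'
#' Backward-in-time simulation: within deme i, each pair of lineages
#' coalesces so that the total coalescence rate is `n_i (n_i - 1) / theta_i`;
#' each lineage in deme i migrates to deme j at rate `M[i, j] / 2`. Waiting
#' times are exponential and event participants are chosen uniformly.
#'
#' Deme groups with no migration path between them can never share a
#' coalescent event. Each such group coalesces internally, and the group
#' ancestors are then joined at `isolation_divergence` coalescent units
#' above the deepest group root (a fixed vicariant divergence across a
#' hard barrier). With `isolation_divergence = NULL` an unconnectable
#' history raises a "disconnected history" error instead.
#'
#' @param config A [scenario_config()].
#' @param seed Optional seed.
#' @return A `genealogy` object: tip labels/demes, parent pointers, node
#'   times (tips at 0) and per-node branch lengths to the parent.
#' @export
simulate_genealogy <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    n_per <- config$n_lineages_per_deme
    n_tips <- sum(n_per)
    if (n_tips < 1L) abort("all demes empty: nothing to simulate")
    tip_deme <- rep(config$deme_labels, times = n_per)
    tip_label <- unlist(lapply(config$deme_labels, function(d) {
      k <- n_per[[d]]
      if (k > 0L) paste0(d, "_l", seq_len(k)) else character(0)
    }))
    n_nodes <- 2L * n_tips - 1L
    parent <- integer(n_nodes)
    node_time <- numeric(n_nodes)
    active <- seq_len(n_tips)             # node ids of live lineages
    deme_of <- match(tip_deme, config$deme_labels)
    lin_deme <- deme_of                   # deme index per active lineage
    t_now <- 0
    next_node <- n_tips + 1L
    theta <- as.numeric(config$theta)
    M <- config$migration
    mig_out <- rowSums(M) / 2             # per-lineage migration rate by deme
    deme_comp <- migration_components(M)  # demes sharing a migration path
    while (length(active) > 1L &&
           max(tabulate(deme_comp[lin_deme])) > 1L) {
      n_i <- tabulate(lin_deme, nbins = config$n_demes)
      coal_rate <- n_i * (n_i - 1L) / theta
      coal_rate[n_i < 2L] <- 0
      mig_rate <- n_i * mig_out
      total <- sum(coal_rate) + sum(mig_rate)
      if (total <= 0) {
        abort(paste(
          "disconnected history: no coalescence or migration event has",
          "positive rate while multiple lineages remain (zero migration",
          "between occupied demes?)"))
      }
      t_now <- t_now + rexp(1L, total)
      ev <- sample.int(2L * config$n_demes, 1L,
                       prob = c(coal_rate, mig_rate))
      if (ev <= config$n_demes) {         # coalescence in deme ev
        d <- ev
        here <- which(lin_deme == d)
        pick <- sample(here, 2L)
        node <- next_node; next_node <- next_node + 1L
        node_time[node] <- t_now
        parent[active[pick]] <- node
        keep <- setdiff(seq_along(active), pick)
        active <- c(active[keep], node)
        lin_deme <- c(lin_deme[keep], d)
      } else {                            # migration out of deme ev - n
        d <- ev - config$n_demes
        here <- which(lin_deme == d)
        mover <- if (length(here) == 1L) here else sample(here, 1L)
        dest <- if (config$n_demes == 1L) d else {
          sample.int(config$n_demes, 1L, prob = M[d, ])
        }
        lin_deme[mover] <- dest
      }
    }
    if (length(active) > 1L) {           # isolated groups: vicariant joins
      div <- config$isolation_divergence
      if (is.null(div)) {
        abort(paste(
          "disconnected history: demes with no migration path between",
          "them cannot share ancestry (set isolation_divergence to allow",
          "a fixed vicariant divergence)"))
      }
      # deterministic order: by component index of each surviving lineage
      ord <- order(deme_comp[lin_deme])
      active <- active[ord]
      while (length(active) > 1L) {
        t_now <- max(t_now, max(node_time[active])) + div
        node <- next_node; next_node <- next_node + 1L
        node_time[node] <- t_now
        parent[active[1:2]] <- node
        active <- c(node, active[-(1:2)])
      }
    }
    branch <- numeric(n_nodes)
    has_parent <- parent > 0L
    branch[has_parent] <- node_time[parent[has_parent]] -
      node_time[has_parent]
    structure(
      list(
        n_tips = n_tips,
        tip_label = tip_label,
        tip_deme = tip_deme,
        parent = parent,
        node_time = node_time,
        branch_length = branch,
        root = if (n_tips == 1L) 1L else n_nodes
      ),
      class = "genealogy"
    )
  })
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy> ", x$n_tips, " tips, TMRCA = ",
      format(max(x$node_time), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Convert a genealogy to an ape phylo tree
#'
#' @param x A `genealogy`.
#' @return An object of class `phylo` (branch lengths in coalescent time).
#' @export
genealogy_to_phylo <- function(x) {
  stopifnot(inherits(x, "genealogy"))
  if (x$n_tips == 1L) {
    return(structure(
      list(edge = matrix(c(2L, 1L), 1, 2), tip.label = x$tip_label,
           edge.length = 0, Nnode = 1L),
      class = "phylo", order = "cladewise"))
  }
  n_nodes <- length(x$parent)
  # ape numbering: tips 1..n keep their ids; internals renumbered so the
  # root is n+1.
  internal <- seq(x$n_tips + 1L, n_nodes)
  new_id <- integer(n_nodes)
  new_id[seq_len(x$n_tips)] <- seq_len(x$n_tips)
  new_id[rev(internal)] <- x$n_tips + seq_along(internal)
  child <- which(x$parent > 0L)
  edge <- cbind(new_id[x$parent[child]], new_id[child])
  phy <- list(edge = edge, tip.label = x$tip_label,
              edge.length = x$branch_length[child],
              Nnode = length(internal))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Drop mutations on a genealogy (finite sites)
#'
#' The root sequence is uniform random over A/C/G/T; each branch receives
#' `Poisson(theta / 2 * branch length)` mutations, each hitting a uniformly
#' chosen site and substituting a uniformly chosen different base. Recurrent
#' hits are allowed, so the model is finite-sites and alignment length is
#' preserved by construction.
#'
#' @param genealogy A [simulate_genealogy()] result.
#' @param theta Scaled mutation parameter (>= 0).
#' @param seq_length Number of aligned sites.
#' @param seed Optional seed.
#' @return A `truth_table`: tibble of haplotypes (hap_id, seq), tibble of
#'   per-deme lineage counts (deme, hap_id, n), and the per-tip haplotype
#'   assignment.
#' @export
drop_mutations <- function(genealogy, theta, seq_length, seed = NULL) {
  stopifnot(inherits(genealogy, "genealogy"))
  if (theta < 0) abort("theta must be non-negative")
  seq_length <- as.integer(seq_length)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    n_nodes <- length(genealogy$parent)
    root <- genealogy$root
    root_seq <- sample(bases, seq_length, replace = TRUE)
    seqs <- vector("list", n_nodes)
    seqs[[root]] <- root_seq
    # children-of table, walk from root downwards
    kids <- split(seq_len(n_nodes)[genealogy$parent > 0L],
                  genealogy$parent[genealogy$parent > 0L])
    stack <- root
    while (length(stack)) {
      node <- stack[[1L]]; stack <- stack[-1L]
      for (ch in kids[[as.character(node)]] %||% integer(0)) {
        s <- seqs[[node]]
        k <- rpois(1L, theta / 2 * genealogy$branch_length[ch])
        if (k > 0L) {
          for (i in seq_len(k)) {
            pos <- sample.int(seq_length, 1L)
            s[pos] <- sample(setdiff(bases, s[pos]), 1L)
          }
        }
        seqs[[ch]] <- s
        stack <- c(stack, ch)
      }
    }
    tip_seq <- vapply(seq_len(genealogy$n_tips),
                      function(i) paste0(seqs[[i]], collapse = ""), "")
    uniq <- unique(tip_seq)
    hap_id <- paste0("H", seq_along(uniq))
    assign <- hap_id[match(tip_seq, uniq)]
    counts <- tibble(deme = genealogy$tip_deme, hap_id = assign) %>%
      count(.data$deme, .data$hap_id, name = "n")
    structure(
      list(
        haplotypes = tibble(hap_id = hap_id, seq = uniq),
        lineage_counts = counts,
        tip_hap = setNames(assign, genealogy$tip_label)
      ),
      class = "truth_table"
    )
  })
}

#' Sample sequencing reads from a haplotype truth table
#'
#' Per deme, `sample_depths[deme]` reads are drawn multinomially from the
#' deme's haplotype lineage frequencies; each read is then corrupted
#' site-wise: every position independently flips to a uniformly chosen
#' different base with probability `error_rate`. Read headers follow the
#' `SAMPLE_READN` labelling dialect.
#'
#' @param truth A [drop_mutations()] result.
#' @param config The [scenario_config()] (depths, error rate).
#' @param seed Optional seed.
#' @return A read-set tibble (read_id, sample, seq) with attribute
#'   `"read_truth"`: the pre-error haplotype draw per deme (deme, hap_id,
#'   n), whose per-deme totals equal the configured depths.
#' @export
sample_reads <- function(truth, config, seed = NULL) {
  stopifnot(inherits(truth, "truth_table"),
            inherits(config, "scenario_config"))
  e <- config$error_rate
  if (e < 0 || e >= 1) abort("error_rate must be in [0, 1)")
  demes_present <- unique(truth$lineage_counts$deme)
  if (!all(demes_present %in% config$deme_labels)) {
    abort("truth table contains demes absent from the configuration")
  }
  bases <- c("A", "C", "G", "T")
  hap_seqs <- setNames(truth$haplotypes$seq, truth$haplotypes$hap_id)
  L <- nchar(hap_seqs[[1L]])   # actual haplotype length governs errors
  with_seed(seed, {
    all_reads <- list()
    truth_rows <- list()
    for (d in config$deme_labels) {
      lc <- truth$lineage_counts[truth$lineage_counts$deme == d, ]
      if (nrow(lc) == 0L) next
      depth <- config$sample_depths[[d]]
      draw <- as.integer(rmultinom(1L, depth, lc$n / sum(lc$n)))
      truth_rows[[d]] <- tibble(deme = d, hap_id = lc$hap_id, n = draw)
      reads <- rep(hap_seqs[lc$hap_id], times = draw)
      if (e > 0 && length(reads)) {
        char <- seq_matrix(reads)
        for (r in seq_len(nrow(char))) {
          k <- rbinom(1L, L, e)
          if (k > 0L) {
            pos <- sample.int(L, k)
            for (p in pos) {
              char[r, p] <- sample(setdiff(bases, char[r, p]), 1L)
            }
          }
        }
        reads <- collapse_rows(char)
      }
      if (length(reads)) {
        all_reads[[d]] <- tibble(
          read_id = paste0(d, "_", seq_along(reads)),
          sample = d,
          seq = unname(reads)
        )
      }
    }
    out <- bind_rows(all_reads)
    attr(out, "read_truth") <- bind_rows(truth_rows)
    out
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs genealogy -> mutations -> reads for one scenario and writes the
#' FASTA read set, truth tables, site table, synthetic environment table and
#' the configuration used. Byte-identical for identical (config, seed).
#'
#' @param config A [scenario_config()]; its `seed` (or the `seed` argument)
#'   drives all randomness.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with the in-memory objects (genealogy, truth,
#'   reads) and the file paths written.
#' @export
generate_dataset <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) abort("a seed is required for reproducible datasets")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genealogy(config, seed = derive_seed(seed, 1L))
  truth <- drop_mutations(gen, theta = mean(config$theta),
                          seq_length = config$seq_length,
                          seed = derive_seed(seed, 2L))
  reads <- sample_reads(truth, config, seed = derive_seed(seed, 3L))
  paths <- list(
    reads = file.path(out_dir, "reads.fasta"),
    haplotypes = file.path(out_dir, "truth_haplotypes.tsv"),
    counts = file.path(out_dir, "truth_counts.tsv"),
    sites = file.path(out_dir, "sites.tsv"),
    env = file.path(out_dir, "environment.tsv"),
    config = file.path(out_dir, "config.yml")
  )
  write_labelled_fasta(reads, paths$reads)
  readr::write_tsv(truth$haplotypes, paths$haplotypes)
  readr::write_tsv(attr(reads, "read_truth"), paths$counts)
  readr::write_tsv(config$site_table, paths$sites)
  readr::write_tsv(round_num_cols(
    synthetic_env_table(config$site_table, seed = derive_seed(seed, 4L))),
    paths$env)
  cfg <- list(
    deme_labels = config$deme_labels,
    provinces = unname(config$provinces),
    sample_depths = unname(config$sample_depths),
    n_lineages_per_deme = unname(config$n_lineages_per_deme),
    theta = unname(config$theta),
    migration = apply(config$migration, 1L, as.list),
    seq_length = config$seq_length,
    error_rate = config$error_rate,
    seed = as.integer(seed)
  )
  writeLines(yaml::as.yaml(cfg), paths$config)
  invisible(list(genealogy = gen, truth = truth, reads = reads,
                 paths = paths))
}

#' Connected components of the deme migration graph (undirected on any
#' positive rate in either direction).
#' @noRd
migration_components <- function(M) {
  n <- nrow(M)
  comp <- seq_len(n)
  adj <- (M + t(M)) > 0
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          old <- max(comp[i], comp[j]); new <- min(comp[i], comp[j])
          comp[comp == old] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Counter-based seed fan-out
#'
#' Derives independent 31-bit stage seeds from one master seed so that
#' stages can be re-run in isolation yet the full pipeline stays
#' reproducible.
#'
#' @param seed Master integer seed.
#' @param counter Stage counter (>= 0).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, counter) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  c <- as.numeric(counter) %% 2147483647
  as.integer(((s * 48271) %% 2147483647 + c * 69621) %% 2147483647 + 1)
}
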