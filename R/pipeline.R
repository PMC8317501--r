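# End-to-end orchestration: simulate (optional) -> oligotype -> popgen ->
# network -> assembly -> matrix regression, with one master seed fanned out
# per stage, TSV/FASTA/Newick/GraphML outputs and a run manifest.

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stage derives its own seed from it via
#'   [derive_seed()].
#' @param scenario A [scenario_config()] to simulate from, or NULL when
#'   `reads_fasta` is given.
#' @param reads_fasta Optional path to an existing labelled FASTA.
#' @param site_table_path,env_table_path Optional TSV paths for the site
#'   and environment tables (required for the MMRR stage when no scenario
#'   is supplied).
#' @param m,min_abundance,d Oligotyping parameters ([med_decompose()]).
#' @param B Rarefaction resamples; `P` permutations for Fst/Phi-st/Snn;
#'   `reps` randomizations for beta-NTI / RC; `perms` MMRR permutations.
#' @param epsilon Median-joining relaxation.
#' @param pooled If TRUE (default) assembly communities are site pools;
#'   otherwise per-host subsamples (`n_hosts` per site).
#' @param n_hosts Hosts per site in per-host mode.
#' @param noise_policy Noise handling in [med_decompose()].
#' @param stages Character vector of stages to run.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       scenario = scenario_barrier(),
                       reads_fasta = NULL,
                       site_table_path = NULL,
                       env_table_path = NULL,
                       m = 0.0965, min_abundance = 0.01, d = 1L,
                       B = 200L, P = 199L, reps = 199L, perms = 999L,
                       epsilon = 0,
                       pooled = TRUE, n_hosts = 4L,
                       noise_policy = "reassign",
                       stages = c("simulate", "oligotype", "popgen",
                                  "network", "processes", "mmrr")) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), scenario = scenario,
         reads_fasta = reads_fasta, site_table_path = site_table_path,
         env_table_path = env_table_path,
         m = m, min_abundance = min_abundance, d = d,
         B = B, P = P, reps = reps, perms = perms, epsilon = epsilon,
         pooled = pooled, n_hosts = n_hosts, noise_policy = noise_policy,
         stages = stages),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [run_config()] can be set from a YAML file; the
#' scenario is rebuilt from a nested `scenario:` block when present.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- if (!is.null(y$scenario)) {
    do.call(scenario_config, c(
      y$scenario[setdiff(names(y$scenario), "migration")],
      if (!is.null(y$scenario$migration)) {
        list(migration = do.call(rbind, lapply(y$scenario$migration,
                                               unlist)))
      }))
  } else scenario_barrier()
  args <- y[setdiff(names(y), "scenario")]
  do.call(run_config, c(args, list(scenario = sc)))
}

preflight <- function(config) {
  if (is.null(config$scenario)) {
    if (is.null(config$reads_fasta) || !file.exists(config$reads_fasta)) {
      abort("pre-flight: no scenario and no existing reads_fasta")
    }
    if ("mmrr" %in% config$stages &&
        (is.null(config$site_table_path) ||
         !file.exists(config$site_table_path))) {
      abort("pre-flight: mmrr stage enabled but no site table supplied")
    }
  }
  for (p in c(config$site_table_path, config$env_table_path,
              config$reads_fasta)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("pre-flight: missing input file ", p))
    }
  }
  invisible(config)
}

stage_error <- function(stage, e) {
  abort(paste0("stage `", stage, "` failed: ", conditionMessage(e)))
}

write_tsv4 <- function(df, path) {
  readr::write_tsv(round_num_cols(as.data.frame(df)), path)
}

#' Run the full oligotype phylogeography pipeline
#'
#' Executes the configured stages in order, writing each stage's tables
#' next to a manifest recording package version, parameters, seed and
#' input digests. Identical (config, seed) runs produce byte-identical
#' outputs. Any stage failure aborts with a stage-named error.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  preflight(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  res <- list()
  log <- list()

  # --- simulate ------------------------------------------------------------
  if ("simulate" %in% config$stages && !is.null(config$scenario)) {
    tryCatch({
      sim_dir <- file.path(config$out_dir, "simulated")
      res$sim <- generate_dataset(config$scenario, sim_dir,
                                  seed = derive_seed(seed, 10L))
      config$reads_fasta <- res$sim$paths$reads
      config$site_table_path <- res$sim$paths$sites
      config$env_table_path <- res$sim$paths$env
      log$simulate <- derive_seed(seed, 10L)
    }, error = function(e) stage_error("simulate", e))
  }
  reads <- tryCatch(read_labelled_fasta(config$reads_fasta),
                    error = function(e) stage_error("input", e))

  # --- oligotype -----------------------------------------------------------
  catalog <- counts <- seqs <- NULL
  if ("oligotype" %in% config$stages) {
    tryCatch({
      catalog <- med_decompose(reads, m = config$m,
                               min_abundance = config$min_abundance,
                               d = config$d, policy = config$noise_policy)
      counts <- build_count_matrix(catalog)
      seqs <- catalog_seqs(catalog)
      write_catalog_fasta(catalog,
                          file.path(config$out_dir, "oligotypes.fasta"))
      write_tsv4(counts, file.path(config$out_dir, "oligotype_counts.tsv"))
      res$catalog <- catalog
      res$counts <- counts
    }, error = function(e) stage_error("oligotype", e))
  }

  # --- popgen --------------------------------------------------------------
  if ("popgen" %in% config$stages) {
    tryCatch({
      div <- diversity_indices(counts, seqs)
      rar <- rarefied_indices(counts, seqs, B = config$B,
                              seed = derive_seed(seed, 20L))
      log$rarefaction <- derive_seed(seed, 20L)
      struct <- pairwise_structure(counts, seqs, perms = config$P,
                                   seed = derive_seed(seed, 21L))
      log$structure <- derive_seed(seed, 21L)
      nm <- struct$fst %>%
        mutate(nm = nm_island(.data$statistic)) %>%
        select("site_a", "site_b", fst = "statistic", "nm")
      write_tsv4(div, file.path(config$out_dir, "diversity.tsv"))
      write_tsv4(rar, file.path(config$out_dir, "diversity_rarefied.tsv"))
      write_tsv4(struct$fst, file.path(config$out_dir, "structure_fst.tsv"))
      write_tsv4(struct$phist,
                 file.path(config$out_dir, "structure_phist.tsv"))
      write_tsv4(struct$snn, file.path(config$out_dir, "snn.tsv"))
      write_tsv4(nm, file.path(config$out_dir, "nm_island.tsv"))
      res$diversity <- div
      res$rarefied <- rar
      res$structure <- struct
      res$nm <- nm
    }, error = function(e) stage_error("popgen", e))
  }

  # --- network -------------------------------------------------------------
  if ("network" %in% config$stages) {
    tryCatch({
      w <- node_weights(counts)
      net <- median_joining(seqs[w$oligo_id], weights = w$weight,
                            epsilon = config$epsilon)
      write_network(net, file.path(config$out_dir, "network"))
      write_tsv4(w, file.path(config$out_dir, "node_weights.tsv"))
      res$network <- net
    }, error = function(e) stage_error("network", e))
  }

  # --- processes -----------------------------------------------------------
  if ("processes" %in% config$stages) {
    tryCatch({
      comm <- assembly_communities(reads, catalog, config,
                                   seed = derive_seed(seed, 30L))
      log$communities <- derive_seed(seed, 30L)
      tree <- nj_tree(hamming_distances(seqs))
      ape::write.tree(tree, file.path(config$out_dir, "oligotypes.nwk"))
      bnti <- beta_nti(comm, tree, reps = config$reps,
                       seed = derive_seed(seed, 31L))
      rc <- rc_bray(comm, reps = config$reps,
                    seed = derive_seed(seed, 32L))
      log$bnti <- derive_seed(seed, 31L)
      log$rc <- derive_seed(seed, 32L)
      part <- partition_processes(bnti, rc)
      write_tsv4(bnti, file.path(config$out_dir, "beta_nti.tsv"))
      write_tsv4(rc, file.path(config$out_dir, "rc_bray.tsv"))
      write_tsv4(mutate(tidy(part), percent = 100 * .data$fraction),
                 file.path(config$out_dir, "process_partition.tsv"))
      res$bnti <- bnti
      res$rc <- rc
      res$partition <- part
    }, error = function(e) stage_error("processes", e))
  }

  # --- mmrr ----------------------------------------------------------------
  if ("mmrr" %in% config$stages) {
    tryCatch({
      site_tbl <- readr::read_tsv(config$site_table_path,
                                  show_col_types = FALSE)
      env_tbl <- readr::read_tsv(config$env_table_path,
                                 show_col_types = FALSE)
      comm <- if (isTRUE(config$pooled)) as_community_matrix(counts)
              else assembly_communities(reads, catalog, config,
                                        seed = derive_seed(seed, 30L))
      fit <- mmrr_site_level(counts, site_tbl, env_tbl, comm = comm,
                             perms = config$perms,
                             seed = derive_seed(seed, 40L))
      log$mmrr <- derive_seed(seed, 40L)
      write_tsv4(mmrr_report(fit), file.path(config$out_dir, "mmrr.tsv"))
      res$mmrr <- fit
    }, error = function(e) stage_error("mmrr", e))
  }

  # --- manifest ------------------------------------------------------------
  inputs <- c(reads = config$reads_fasta, sites = config$site_table_path,
              env = config$env_table_path)
  inputs <- inputs[!vapply(inputs, is.null, logical(1L))]
  manifest <- list(
    package = "oligophylo",
    version = as.character(utils::packageVersion("oligophylo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    stage_seeds = log,
    parameters = list(m = config$m, min_abundance = config$min_abundance,
                      d = config$d, B = config$B, P = config$P,
                      reps = config$reps, perms = config$perms,
                      epsilon = config$epsilon, pooled = config$pooled,
                      n_hosts = config$n_hosts,
                      noise_policy = config$noise_policy),
    stages = config$stages,
    input_digests = as.list(setNames(
      unname(tools::md5sum(unlist(inputs))), names(inputs)))
  )
  writeLines(yaml::as.yaml(manifest),
             file.path(config$out_dir, "manifest.yml"))
  invisible(res)
}

#' Build assembly communities from reads (site pools or per-host)
#'
#' In pooled mode each site is one community (oligotype counts per site);
#' in per-host mode each site's reads are split uniformly at random into
#' `n_hosts` pseudo-host communities, mirroring per-individual sampling.
#'
#' @param reads Read-set tibble.
#' @param catalog The [med_decompose()] catalog fitted on `reads`.
#' @param config A [run_config()] (fields `pooled`, `n_hosts`).
#' @param seed Seed for the per-host split.
#' @return Community matrix (samples x oligotypes).
#' @export
assembly_communities <- function(reads, catalog, config, seed = NULL) {
  counts <- build_count_matrix(catalog)
  if (isTRUE(config$pooled)) {
    return(as_community_matrix(counts))
  }
  cm <- as_count_matrix(counts)
  with_seed(seed, {
    rows <- list()
    for (s in colnames(cm)) {
      expanded <- rep(rownames(cm), times = cm[, s])
      host <- sample(rep_len(seq_len(config$n_hosts), length(expanded)))
      for (h in seq_len(config$n_hosts)) {
        tab <- table(factor(expanded[host == h], levels = rownames(cm)))
        if (sum(tab) == 0L) next
        rows[[paste0(s, "_h", h)]] <- as.numeric(tab)
      }
    }
    out <- do.call(rbind, rows)
    colnames(out) <- rownames(cm)
    out
  })
}

#' Fit the IBD/IBE matrix regression for a count table
#'
#' Builds the geographic (haversine km, Hellinger-transformed and
#' re-symmetrized) and environmental (PC1 Euclidean) predictor matrices at
#' site level, expands them to the response's samples when the community
#' matrix is finer than sites, and fits [mmrr()] on the Bray-Curtis
#' response.
#'
#' @param counts Count matrix or tibble (defines the site set).
#' @param site_tbl Tibble (site, lat, lon, ...).
#' @param env_tbl Tibble (site, variables...).
#' @param comm Optional community matrix; defaults to site pools of
#'   `counts`. Row names of the form `site_hN` map samples to sites.
#' @param hellinger_geo Apply the Hellinger transform to the geographic
#'   matrix (default TRUE; set FALSE for raw kilometres).
#' @param perms,seed Passed to [mmrr()].
#' @return An `mmrr_fit` (with the PC1 variance explained attached as an
#'   attribute).
#' @export
mmrr_site_level <- function(counts, site_tbl, env_tbl, comm = NULL,
                            hellinger_geo = TRUE, perms = 999L,
                            seed = NULL) {
  cm <- as_count_matrix(counts)
  sites <- colnames(cm)
  site_tbl <- site_tbl[match(sites, site_tbl$site), ]
  if (anyNA(site_tbl$site)) abort("site table does not cover all sites")
  env_tbl <- env_tbl[match(sites, env_tbl[[1L]]), ]
  geo <- great_circle_km(site_tbl)
  if (hellinger_geo) {
    # literal convention: Hellinger transform of the geographic distance
    # matrix rows, re-symmetrized by averaging (see vignette)
    gh <- hellinger_rows(geo)
    geo <- (gh + t(gh)) / 2
    diag(geo) <- 0
  }
  envd <- env_pc1_distance(env_tbl)
  if (is.null(comm)) comm <- as_community_matrix(cm)
  bc <- bray_curtis(comm)
  sample_site <- setNames(sub("_h[0-9]+$", "", rownames(comm)),
                          rownames(comm))
  X <- list(IBD = expand_site_matrix(geo[sites, sites], sample_site),
            IBE = expand_site_matrix(envd[sites, sites], sample_site))
  fit <- mmrr(bc, X, perms = perms, seed = seed)
  attr(fit, "pc1_variance_explained") <-
    attr(envd, "variance_explained")
  fit
}

mmrr_report <- function(fit) {
  ct <- tidy(fit)
  gl <- glance(fit)
  ct$f_statistic <- c(gl$statistic, rep(NA_real_, nrow(ct) - 1L))
  ct$f_p_value <- c(gl$p.value, rep(NA_real_, nrow(ct) - 1L))
  ct$r_squared <- c(gl$r.squared, rep(NA_real_, nrow(ct) - 1L))
  ct
}
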