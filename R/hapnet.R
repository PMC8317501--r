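# Median-joining haplotype networks over oligotype sequences, with node
# weights from per-site relative frequencies summed across sites.

#' Per-oligotype node weights for network rendering
#'
#' Counts are first normalized to relative frequencies within each site;
#' an oligotype's weight is the sum of its frequencies across sites, so
#' that a low-coverage site contributes as much as a deep one. The per-site
#' frequency composition is retained for pie-style rendering.
#'
#' @param counts Count matrix or tibble.
#' @return Tibble: oligo_id, weight, then one `freq_<site>` column per
#'   site. Weights over all oligotypes sum to the number of sites.
#' @export
node_weights <- function(counts) {
  cm <- as_count_matrix(counts)
  cs <- colSums(cm)
  if (any(cs == 0)) {
    abort(paste0("site(s) with zero total count: ",
                 paste(colnames(cm)[cs == 0], collapse = ", ")))
  }
  freq <- sweep(cm, 2L, cs, "/")
  out <- tibble(oligo_id = rownames(cm), weight = unname(rowSums(freq)))
  for (s in colnames(freq)) out[[paste0("freq_", s)]] <- unname(freq[, s])
  out
}

# --- minimal-spanning machinery -------------------------------------------

# For every node pair, the distance level at which the two first become
# connected when edges are added in increasing weight order (ties level-wise).
connection_levels <- function(d) {
  n <- nrow(d)
  comp <- seq_len(n)
  lvl <- matrix(Inf, n, n)
  diag(lvl) <- 0
  for (w in sort(unique(d[upper.tri(d)]))) {
    merged <- comp
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (d[i, j] == w && merged[i] != merged[j]) {
          merged[merged == merged[j]] <- merged[i]
        }
      }
    }
    newly <- outer(merged, merged, "==") & !outer(comp, comp, "==")
    lvl[newly & !is.finite(lvl)] <- w
    comp <- merged
    if (length(unique(comp)) == 1L) break
  }
  lvl
}

# epsilon-relaxed minimum spanning network: admit every edge whose weight is
# within epsilon of the level at which its endpoints first connect. With
# epsilon = 0 this is exactly the union of all minimum spanning trees.
msn_edges <- function(d, epsilon = 0) {
  lvl <- connection_levels(d)
  n <- nrow(d)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (d[i, j] <= lvl[i, j] + epsilon) {
        out <- rbind(out, c(i, j, d[i, j]))
      }
    }
  }
  out
}

mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]
  cost <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    pick <- cand[which.min(best[cand])]
    cost <- cost + best[pick]
    in_tree[pick] <- TRUE
    best <- pmin(best, d[pick, ])
  }
  cost
}

triplet_median <- function(s1, s2, s3) {
  trip <- sort(c(s1, s2, s3))
  m <- seq_matrix(trip)
  med <- vapply(seq_len(ncol(m)), function(p) {
    col <- m[, p]
    tab <- table(col)
    if (max(tab) >= 2L) names(tab)[which.max(tab)]
    else col[1L]   # 3-way tie: state of the lexicographically first sequence
  }, "")
  paste0(med, collapse = "")
}

#' Median-joining haplotype network
#'
#' Iterates: (1) build the epsilon-relaxed minimum-spanning network over
#' the current node set; (2) for every connected triplet compute the
#' position-wise majority median sequence (three-way ties keep the state of
#' the lexicographically first sequence of the triplet); (3) add the novel
#' median that most reduces the total connection (MST) cost; repeat to a
#' fixed point; (4) prune inferred medians of degree <= 2. Deterministic
#' given the input (all ties broken lexicographically). The gap character
#' is a fifth state throughout.
#'
#' @param seqs Named character vector of distinct, equal-length sequences
#'   (duplicates are an error: deduplicate into oligotypes first).
#' @param weights Optional numeric weights (e.g. from [node_weights()]);
#'   nodes with weight 0 are treated as unsampled median vectors, which
#'   makes the algorithm idempotent on its own output.
#' @param epsilon Relaxation of the minimum-spanning criterion (default 0).
#' @return A `haplo_network`: node tibble (id, seq, sampled, weight) and
#'   edge tibble (from, to, distance = Hamming distance of the endpoints).
#' @export
median_joining <- function(seqs, weights = NULL, epsilon = 0) {
  if (length(seqs) < 2L) abort("need at least two sequences")
  if (anyDuplicated(seqs)) abort("duplicate sequences: deduplicate first")
  if (is.null(names(seqs))) names(seqs) <- paste0("OT", seq_along(seqs))
  weights <- weights %||% rep(1, length(seqs))
  nodes <- tibble(id = names(seqs), seq = unname(seqs),
                  sampled = weights > 0, weight = as.numeric(weights))
  n_median <- sum(!nodes$sampled)
  cost_prev <- Inf
  for (iter in seq_len(200L)) {
    d <- hamming_distances(setNames(nodes$seq, nodes$id))
    cost_now <- mst_cost(d)
    stopifnot(cost_now <= cost_prev)  # medians must never raise the cost
    cost_prev <- cost_now
    edges <- msn_edges(d, epsilon)
    adj <- vector("list", nrow(nodes))
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1L]; j <- edges[r, 2L]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    cand <- character(0)
    for (x in seq_len(nrow(nodes))) {
      nb <- adj[[x]]
      if (length(nb) < 2L) next
      for (a in seq_len(length(nb) - 1L)) {
        for (b in seq(a + 1L, length(nb))) {
          med <- triplet_median(nodes$seq[x], nodes$seq[nb[a]],
                                nodes$seq[nb[b]])
          if (!(med %in% nodes$seq)) cand <- c(cand, med)
        }
      }
    }
    cand <- sort(unique(cand))
    if (!length(cand)) break
    gains <- vapply(cand, function(s) {
      dd <- hamming_distances(c(setNames(nodes$seq, nodes$id), MV = s))
      mst_cost(dd)
    }, numeric(1L))
    best <- which(gains < cost_now - 1e-9)
    if (!length(best)) break
    pick <- best[order(gains[best], cand[best])][1L]
    n_median <- n_median + 1L
    nodes <- bind_rows(nodes, tibble(id = paste0("MV", n_median),
                                     seq = cand[pick], sampled = FALSE,
                                     weight = 0))
  }
  # prune unsampled medians of degree <= 2, re-deriving the network each time
  repeat {
    d <- hamming_distances(setNames(nodes$seq, nodes$id))
    edges <- msn_edges(d, epsilon)
    deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = nrow(nodes))
    drop <- which(!nodes$sampled & deg <= 2L)
    if (!length(drop)) break
    nodes <- nodes[-drop[1L], ]
  }
  d <- hamming_distances(setNames(nodes$seq, nodes$id))
  edges <- msn_edges(d, epsilon)
  edge_tbl <- tibble(
    from = nodes$id[edges[, 1L]],
    to = nodes$id[edges[, 2L]],
    distance = as.integer(edges[, 3L])
  )
  structure(list(nodes = nodes, edges = edge_tbl, epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network> ", nrow(x$nodes), " nodes (",
      sum(!x$nodes$sampled), " medians), ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.haplo_network <- function(x, ...) x$edges

#' @export
glance.haplo_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_medians = sum(!x$nodes$sampled),
         n_edges = nrow(x$edges),
         total_cost = sum(x$edges$distance[mst_edge_mask(x)]))
}

mst_edge_mask <- function(x) {
  # mark one MST inside the network's edge multiset (Kruskal on its edges)
  e <- x$edges[order(x$edges$distance), ]
  comp <- setNames(seq_len(nrow(x$nodes)), x$nodes$id)
  keep <- logical(nrow(e))
  for (r in seq_len(nrow(e))) {
    a <- comp[e$from[r]]; b <- comp[e$to[r]]
    if (a != b) {
      keep[r] <- TRUE
      comp[comp == b] <- a
    }
  }
  keep[order(order(x$edges$distance))]
}

#' Convert a haplotype network to an igraph graph
#'
#' @param x A `haplo_network`.
#' @return An igraph object with node weights and edge distances.
#' @export
haplo_network_igraph <- function(x) {
  stopifnot(inherits(x, "haplo_network"))
  igraph::graph_from_data_frame(
    x$edges, directed = FALSE,
    vertices = as.data.frame(x$nodes)
  )
}
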