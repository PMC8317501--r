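# ggplot2 presentation helpers for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_segment
#'   geom_hline labs theme_minimal scale_size_area coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot a column entropy profile
#'
#' @param object An [column_entropy()] profile.
#' @param ... Ignored.
#' @return A ggplot: entropy (bits) by alignment position.
#' @export
autoplot.entropy_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$entropy)) +
    geom_col(width = 1, fill = "grey25") +
    labs(x = "alignment position", y = "Shannon entropy (bits)") +
    theme_minimal()
}

#' Plot a median-joining haplotype network
#'
#' Nodes are placed with a seeded force-directed layout; circle area scales
#' with the frequency-sum node weight and edges are labelled by mutation
#' count through the edge legend.
#'
#' @param object A [median_joining()] network.
#' @param seed Layout seed (default 1).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.haplo_network <- function(object, seed = 1L, ...) {
  g <- haplo_network_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- xy[, 1L]; nodes$y <- xy[, 2L]
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, nodes$id)]
  edges$y <- nodes$y[match(edges$from, nodes$id)]
  edges$xend <- nodes$x[match(edges$to, nodes$id)]
  edges$yend <- nodes$y[match(edges$to, nodes$id)]
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, linewidth = .data$distance),
                 colour = "grey60", show.legend = TRUE) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, size = .data$weight,
                   shape = .data$sampled)) +
    scale_size_area(max_size = 10) +
    ggplot2::scale_linewidth(range = c(1, 0.2)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    labs(x = NULL, y = NULL, size = "frequency sum",
         shape = "sampled", linewidth = "mutations") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot an assembly-process partition
#'
#' @param object A [partition_processes()] result.
#' @param ... Ignored.
#' @return A ggplot bar chart of process fractions.
#' @export
autoplot.process_partition <- function(object, ...) {
  df <- object$partition
  df$process <- factor(df$process, levels = rev(df$process))
  ggplot(df, aes(x = .data$process, y = 100 * .data$fraction)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "% of pairwise comparisons") +
    theme_minimal()
}

#' Rarefaction curve of oligotype richness
#'
#' Expected oligotype count at increasing subsample depths per site
#' (hypergeometric expectation), a plain alternative to interpolated
#' accumulation curves.
#'
#' @param counts Count matrix or tibble.
#' @param steps Number of depth steps per site.
#' @return A ggplot of expected richness against depth.
#' @export
plot_rarefaction <- function(counts, steps = 25L) {
  cm <- as_count_matrix(counts)
  df <- purrr::map_dfr(colnames(cm), function(site) {
    cvec <- cm[, site]
    N <- sum(cvec)
    depths <- unique(round(seq(1, N, length.out = steps)))
    purrr::map_dfr(depths, function(nn) {
      # E[k] = sum_i 1 - C(N - c_i, n) / C(N, n), computed on log scale
      miss <- exp(lchoose(N - cvec, nn) - lchoose(N, nn))
      tibble(site = site, depth = nn, expected_k = sum(1 - miss))
    })
  })
  ggplot(df, aes(x = .data$depth, y = .data$expected_k,
                 colour = .data$site)) +
    ggplot2::geom_line() +
    labs(x = "reads subsampled", y = "expected oligotypes",
         colour = "site") +
    theme_minimal()
}
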