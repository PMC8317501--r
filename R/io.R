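# File formats: labelled FASTA (sample ids embedded in headers), TSV
# tables, and network export.

#' Read a sample-labelled FASTA file into a read set
#'
#' Headers follow the oligotyping dialect `SAMPLE_READID`: the sample id is
#' everything before the last underscore. All records must have equal
#' length (positionally homologous reads).
#'
#' @param path FASTA file path.
#' @return Read-set tibble: read_id (full header), sample, seq.
#' @export
read_labelled_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) abort("FASTA contains no records")
  headers <- sub("\\s.*$", "", names(set))
  if (any(!grepl("_", headers))) {
    bad <- headers[!grepl("_", headers)]
    abort(paste0("unlabelled header(s) (no SAMPLE_READID underscore): ",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1L) {
    bad <- headers[widths != widths[1L]]
    abort(paste0("ragged record lengths; offending records: ",
                 paste(head(bad, 10L), collapse = ", ")))
  }
  tibble(
    read_id = headers,
    sample = sub("_[^_]*$", "", headers),
    seq = as.character(set, use.names = FALSE)
  )
}

#' Write a read set as labelled FASTA
#'
#' @param reads Read-set tibble (read_id, sample, seq); `read_id` is used
#'   as the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labelled_fasta <- function(reads, path) {
  validate_read_set(reads)
  ids <- if ("read_id" %in% names(reads)) reads$read_id
         else paste0(reads$sample, "_", seq_len(nrow(reads)))
  lines <- character(2L * nrow(reads))
  lines[c(TRUE, FALSE)] <- paste0(">", ids)
  lines[c(FALSE, TRUE)] <- reads$seq
  writeLines(lines, path)
  invisible(path)
}

#' Write oligotype representatives as FASTA
#'
#' @param catalog An [med_decompose()] catalog.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  stopifnot(inherits(catalog, "oligo_catalog"))
  lines <- character(2L * nrow(catalog$oligos))
  lines[c(TRUE, FALSE)] <- paste0(">", catalog$oligos$oligo_id)
  lines[c(FALSE, TRUE)] <- catalog$oligos$seq
  writeLines(lines, path)
  invisible(path)
}

#' Export a haplotype network as edge/node TSVs and GraphML
#'
#' @param net A [median_joining()] network.
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv` and `<prefix>.graphml`.
#' @return Character vector of the paths written, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "haplo_network"))
  paths <- c(edges = paste0(prefix, "_edges.tsv"),
             nodes = paste0(prefix, "_nodes.tsv"),
             graphml = paste0(prefix, ".graphml"))
  readr::write_tsv(net$edges, paths["edges"])
  readr::write_tsv(round_num_cols(net$nodes), paths["nodes"])
  igraph::write_graph(haplo_network_igraph(net), paths["graphml"],
                      format = "graphml")
  invisible(paths)
}
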