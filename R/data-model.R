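#' Construct a gene set
#'
#' A named collection of unique gene identifiers, e.g. a benchmark pathology
#' set or a transcription-factor catalogue. Identifiers are opaque,
#' case-sensitive strings.
#'
#' @param name Label for the set.
#' @param members Character vector of gene identifiers; duplicates are
#'   collapsed, order of first occurrence is kept.
#' @return An object of class `gene_set` with elements `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  structure(list(name = as.character(name)[1], members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Genes of a network
#'
#' @param net An undirected [igraph::igraph] gene network (see
#'   [read_network()]).
#' @return Character vector of node identifiers.
#' @export
network_genes <- function(net) {
  stopifnot(inherits(net, "igraph"))
  if (igraph::vcount(net) == 0) return(character(0))
  igraph::V(net)$name
}

#' Build a gene network from an edge table
#'
#' Self-loops are dropped and duplicate (undirected) edges collapsed, so the
#' result satisfies the invariants of a simple undirected protein-protein
#' interaction graph. Nodes appearing only in removed records are dropped
#' entirely.
#'
#' @param edges Two-column character matrix or data frame of interacting gene
#'   pairs.
#' @param quiet Suppress the dropped-record log message.
#' @return An undirected, simple `igraph` object with vertex names.
#' @export
as_gene_network <- function(edges, quiet = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  stopifnot(ncol(edges) >= 2)
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  self <- a == b
  lo <- pmin(a[!self], b[!self]); hi <- pmax(a[!self], b[!self])
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (!quiet && (any(self) || any(dup))) {
    log_msg("as_gene_network: dropped %d self-interaction(s) and %d duplicate edge(s)",
            sum(self), sum(dup))
  }
  if (!any(!self)) return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup], stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Ranked gene list
#'
#' The shared output contract of every prioritization method: genes ordered by
#' non-increasing score. Ties are broken deterministically by higher network
#' degree first (when supplied), then lexicographic gene identifier.
#'
#' @param gene Character vector of gene identifiers (unique).
#' @param score Numeric scores, same length.
#' @param method Label of the producing algorithm.
#' @param degree Optional numeric vector of network degrees used for
#'   tie-breaking.
#' @return A data frame of class `ranked_gene_list` with columns `rank`,
#'   `gene`, `score`; attribute `method` records the algorithm.
#' @export
ranked_gene_list <- function(gene, score, method = "unknown", degree = NULL) {
  gene <- as.character(gene)
  stopifnot(!anyDuplicated(gene), length(gene) == length(score),
            all(is.finite(score)))
  if (is.null(degree)) degree <- numeric(length(gene))
  stopifnot(length(degree) == length(gene))
  ord <- order(-score, -degree, gene, method = "radix")
  out <- data.frame(rank = seq_along(gene), gene = gene[ord],
                    score = as.numeric(score)[ord],
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Top of a ranked list
#'
#' @param ranked A [ranked_gene_list()].
#' @param k Number of genes to take (capped at the list length).
#' @return Character vector of the `k` highest-ranked genes.
#' @export
top_genes <- function(ranked, k) {
  stopifnot(inherits(ranked, "ranked_gene_list"), k >= 1)
  ranked$gene[seq_len(min(k, nrow(ranked)))]
}
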