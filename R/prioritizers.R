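#' Differentially expressed genes at a linear fold-change cutoff
#'
#' A gene is differentially expressed when `|log2 FC| >= log2(cutoff)`, i.e.
#' linear-scale cutoffs such as 1.2, 1.5, 2, 3, 4 are applied on the log2
#' scale, counting up- and down-regulation alike.
#'
#' @param contrast Named numeric vector of log2 fold changes.
#' @param cutoff Linear fold-change cutoff, > 1.
#' @return Character vector of DEG identifiers with attribute `cutoff`.
#' @export
deg_set <- function(contrast, cutoff) {
  stopifnot(cutoff > 1)
  members <- names(contrast)[abs(contrast) >= log2(cutoff)]
  structure(members, cutoff = cutoff)
}

#' Rank genes by absolute fold change
#'
#' @param contrast Named numeric vector of log2 fold changes.
#' @param net Optional network supplying degrees for tie-breaking.
#' @return A [ranked_gene_list()] scored by `|log2 FC|`.
#' @export
fold_change_rank <- function(contrast, net = NULL) {
  deg <- if (!is.null(net)) {
    d <- igraph::degree(net)
    as.numeric(d[names(contrast)])
  } else NULL
  if (!is.null(deg)) deg[is.na(deg)] <- 0
  ranked_gene_list(names(contrast), abs(contrast), method = "fold_change",
                   degree = deg)
}

#' Rank genes by network degree
#'
#' @param net An `igraph` gene network.
#' @return A [ranked_gene_list()] scored by degree (hub genes first).
#' @export
degree_rank <- function(net) {
  d <- igraph::degree(net)
  ranked_gene_list(names(d), as.numeric(d), method = "degree",
                   degree = as.numeric(d))
}

#' Neighborhood scoring
#'
#' The absolute fold change of a gene and the average absolute fold change of
#' its direct neighbors contribute equally:
#' `score(i) = (|f_i| + mean_{j in N(i)} |f_j|) / 2`, with an empty
#' neighborhood contributing 0 to the average term. Genes that are neither
#' differentially expressed nor have any differentially expressed neighbor
#' are assigned score 0.
#'
#' @param net An `igraph` gene network.
#' @param contrast Named numeric vector of log2 fold changes; network genes
#'   without a value are treated as 0.
#' @param deg A [deg_set()] defining differential expression.
#' @return A [ranked_gene_list()].
#' @export
neighborhood_score <- function(net, contrast, deg) {
  genes <- network_genes(net)
  f <- setNames(numeric(length(genes)), genes)
  have <- intersect(genes, names(contrast))
  f[have] <- abs(contrast[have])
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A <- A[genes, genes]
  d <- Matrix::rowSums(A)
  nb_sum <- as.numeric(A %*% f)
  nb_mean <- ifelse(d > 0, nb_sum / d, 0)
  score <- 0.5 * (f + nb_mean)
  is_de <- genes %in% deg
  has_de_nb <- as.numeric(A %*% as.numeric(is_de)) > 0
  score[!is_de & !has_de_nb] <- 0
  ranked_gene_list(genes, score, method = "neighborhood",
                   degree = as.numeric(d))
}

#' Interconnectivity ranking
#'
#' The interconnectivity of genes i and d combines their direct interaction
#' and shared neighborhood, normalized by the geometric mean of their
#' degrees: `ICN(i,d) = (e(i,d) + |N(i) inter N(d)|) / sqrt(deg(i) deg(d))`.
#' Each gene's score is the sum of its interconnectivity to all
#' differentially expressed genes (excluding itself); degree-0 genes score 0.
#'
#' @inheritParams neighborhood_score
#' @return A [ranked_gene_list()].
#' @export
interconnectivity_rank <- function(net, deg) {
  genes <- network_genes(net)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A <- A[genes, genes] * 1.0
  d <- Matrix::rowSums(A)
  degs <- intersect(deg, genes)
  if (length(degs) == 0) {
    return(ranked_gene_list(genes, numeric(length(genes)),
                            method = "interconnectivity",
                            degree = as.numeric(d)))
  }
  di <- match(degs, genes)
  shared <- A %*% A[, di, drop = FALSE]      # |N(i) inter N(d)| for d in DEG
  raw <- A[, di, drop = FALSE] + shared      # e(i,d) + shared neighborhood
  denom <- outer(sqrt(d), sqrt(d[di]))
  denom[denom == 0] <- Inf
  icn <- as.matrix(raw) / denom
  # exclude the d = i term for DEG genes themselves
  icn[cbind(di, seq_along(di))] <- 0
  score <- rowSums(icn)
  ranked_gene_list(genes, score, method = "interconnectivity",
                   degree = as.numeric(d))
}

#' Network propagation of a differential-expression prior
#'
#' Differentially expressed genes start with flow 1 (others 0) and the flow
#' is diffused over the degree-normalized adjacency
#' `A_norm(i,j) = e(i,j) / sqrt(deg(i) deg(j))` by iterating
#' `F_t = alpha * A_norm %*% F_{t-1} + (1 - alpha) * F_0`
#' until the L1 change falls below `tol`. The normalization compensates for
#' high-degree genes picking up flow by chance.
#'
#' @param net An `igraph` gene network.
#' @param deg A [deg_set()] (the prior).
#' @param alpha Diffusion parameter in (0, 1); default 0.1 keeps the flow
#'   close to the prior.
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A [ranked_gene_list()] scored by the converged flow; attributes
#'   `iterations` and `converged` record the run.
#' @export
network_propagation <- function(net, deg, alpha = 0.1, tol = 1e-6,
                                max_iter = 10000) {
  stopifnot(alpha > 0, alpha < 1)
  genes <- network_genes(net)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A <- A[genes, genes] * 1.0
  d <- Matrix::rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  An <- Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
  F0 <- as.numeric(genes %in% deg)
  Ft <- F0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Fn <- as.numeric(alpha * (An %*% Ft) + (1 - alpha) * F0)
    delta <- sum(abs(Fn - Ft))
    Ft <- Fn
    if (delta < tol) break
    if (iter >= max_iter)
      stop("network_propagation: no convergence within ", max_iter, " iterations")
  }
  out <- ranked_gene_list(genes, Ft, method = "propagation",
                          degree = as.numeric(d))
  attr(out, "iterations") <- iter
  attr(out, "converged") <- TRUE
  out
}
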