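#' Parameters of the interaction-activity weighting function
#'
#' The weighting function is a sum of two bivariate logistic terms minus a
#' shift: with \eqn{s(x) = 1/(1+e^{-x})},
#' \deqn{A(f_i,f_j) = C\, s(K f_i)\, s(K f_j) + C\, s(-K f_i)\, s(-K f_j) - T.}
#' The first term captures co-activation (both fold changes up), the second
#' co-suppression (both down). With the defaults `C = 1`, `K = 5`, `T = 0.5`
#' the function is exactly zero at the origin: an edge between two
#' unresponsive genes carries no activity.
#'
#' @param C Amplitude of each logistic term (> 0). Default 1.
#' @param K Logistic steepness on the log2-fold-change axis (> 0). Default 5.
#'   (Unrelated to the top-K list size used downstream.)
#' @param T Shift subtracted from the sum, in `[0, 1]`. Default 0.5.
#' @return An object of class `weight_params`.
#' @export
weight_params <- function(C = 1, K = 5, T = 0.5) {
  stopifnot(C > 0, K > 0, T >= 0, T <= 1)
  structure(list(C = C, K = K, T = T), class = "weight_params")
}

#' Activity of a single interaction from its endpoint fold changes
#'
#' @param f_i,f_j Finite log2 fold changes of the two interacting genes.
#'   Vectorized.
#' @param params A [weight_params()].
#' @return Numeric activity value(s); symmetric in `f_i`, `f_j` and zero at
#'   `(0, 0)` under the default shift.
#' @export
edge_weight <- function(f_i, f_j, params = weight_params()) {
  if (!all(is.finite(f_i)) || !all(is.finite(f_j)))
    stop("edge_weight: fold changes must be finite")
  params$C * plogis(params$K * f_i) * plogis(params$K * f_j) +
    params$C * plogis(-params$K * f_i) * plogis(-params$K * f_j) -
    params$T
}

#' Interaction activity matrix of a network under a contrast
#'
#' Replaces every 1 in the adjacency matrix by the activity of that
#' interaction computed from the endpoint log2 fold changes. Genes present in
#' the network but absent from the contrast are treated as unresponsive
#' (fold change 0) and their count logged.
#'
#' @param net An `igraph` gene network (non-empty).
#' @param contrast Named numeric vector of log2 fold changes (see
#'   [log2_fold_change()]).
#' @param params A [weight_params()].
#' @return Symmetric sparse [Matrix::dgCMatrix-class] over the network genes;
#'   zero diagonal; nonzero pattern confined to network edges.
#' @export
build_activity_matrix <- function(net, contrast, params = weight_params()) {
  genes <- network_genes(net)
  if (length(genes) == 0) stop("empty network")
  f <- setNames(numeric(length(genes)), genes)
  have <- intersect(genes, names(contrast))
  f[have] <- contrast[have]
  n_missing <- length(genes) - length(have)
  if (n_missing > 0)
    log_msg("build_activity_matrix: %d network gene(s) without fold change set to 0",
            n_missing)
  el <- igraph::as_edgelist(net, names = TRUE)
  n <- length(genes)
  if (nrow(el) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n), dimnames = list(genes, genes)))
  }
  ii <- match(el[, 1], genes)
  jj <- match(el[, 2], genes)
  w <- edge_weight(f[ii], f[jj], params)
  Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(w, w),
                       dims = c(n, n), dimnames = list(genes, genes))
}

#' Rank genes by total received interaction activity
#'
#' The influence of gene i is the sum of the activities of all its
#' interactions (row sum of the activity matrix); genes are sorted by
#' descending influence, ties broken by higher degree then gene identifier.
#'
#' @param activity Activity matrix from [build_activity_matrix()].
#' @param net Optional network used for degree tie-breaking; when missing,
#'   degrees are taken from the sparsity pattern of `activity`.
#' @return A [ranked_gene_list()] with the influence as score.
#' @export
rank_genes <- function(activity, net = NULL) {
  genes <- rownames(activity)
  P <- Matrix::rowSums(activity)
  deg <- if (!is.null(net)) {
    as.numeric(igraph::degree(net)[genes])
  } else {
    Matrix::rowSums(activity != 0)
  }
  ranked_gene_list(genes, P, method = "activity", degree = deg)
}
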