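#' Run the full three-step signature and regulator pipeline
#'
#' Convenience wrapper: restrict the expression matrix to network genes,
#' compute log2 fold changes for one contrast, build the interaction
#' activity matrix and the activity ranking (step 1), tune the co-expression
#' signature on the top-K genes (step 2), and, when a TF catalogue is
#' supplied, infer CLR regulatory interactions and screen key regulators
#' (step 3).
#'
#' @param net `igraph` gene network.
#' @param expr Linear-scale expression matrix (genes x samples).
#' @param contrast List with character vectors `control` and `treated`.
#' @param tf_genes Optional TF catalogue ([gene_set()] or character); step 3
#'   is skipped when `NULL`.
#' @param benchmark Optional benchmark pathology set used for regulator
#'   screening (required for step 3).
#' @param top_k Number of top-ranked genes carried into steps 2 and 3
#'   (default 300).
#' @param target_size Target signature size for threshold tuning (default
#'   50).
#' @param weight [weight_params()] for step 1.
#' @param criteria [regulator_criteria()] for step 3.
#' @param grid Correlation threshold grid for [tune_threshold()].
#' @return List with `fold_change`, `ranking`, `top_genes`, `signature`,
#'   and (when step 3 runs) `interactions`, `regulator_report`,
#'   `regulators`.
#' @export
run_tsnba <- function(net, expr, contrast, tf_genes = NULL, benchmark = NULL,
                      top_k = 300, target_size = 50,
                      weight = weight_params(),
                      criteria = regulator_criteria(),
                      grid = seq(0.6, 0.945, by = 0.005)) {
  expr <- restrict_to_network(expr, net)
  fc <- log2_fold_change(expr, contrast$control, contrast$treated)
  A <- build_activity_matrix(net, fc, weight)
  ranking <- rank_genes(A, net)
  top <- top_genes(ranking, top_k)
  # Pearson profiles are taken on the log2 scale: linear-scale microarray
  # intensities are heavy-tailed and a single outlier sample dominates the
  # coefficient at small sample counts.
  corr <- pearson_matrix(log2(expr), top)
  signature <- tune_threshold(corr, target_size = target_size, grid = grid)
  out <- list(fold_change = fc, ranking = ranking, top_genes = top,
              signature = signature)
  if (!is.null(tf_genes)) {
    if (is.null(benchmark))
      stop("regulator screening needs a benchmark gene set")
    mi <- gaussian_mi(corr)
    out$interactions <- clr_z(mi, tf_genes)
    screened <- screen_regulators(out$interactions, benchmark, criteria)
    out$regulator_report <- screened$report
    out$regulators <- screened$regulators
  }
  out
}
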