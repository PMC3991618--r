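#' Pearson correlation matrix over a gene subset
#'
#' Each gene's profile is its expression across all samples of the dataset
#' (all conditions pooled). Constant (zero-variance) gene rows would yield
#' undefined coefficients and are dropped with a logged warning.
#'
#' @param expr Expression matrix (genes x samples), at least 3 samples.
#' @param genes Optional character vector restricting the computation (e.g.
#'   the top-K ranked genes); order follows `genes`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(expr, genes = NULL) {
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(expr))
    expr <- expr[genes, , drop = FALSE]
  }
  if (ncol(expr) < 3) stop("need at least 3 samples for co-expression")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    log_msg("pearson_matrix: dropped %d constant gene row(s)", sum(v == 0))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) == 0) stop("all gene rows are constant")
  cc <- cor(t(expr))
  diag(cc) <- 1
  cc
}

#' Co-expression signature at a fixed correlation threshold
#'
#' Retains every gene pair whose signed Pearson coefficient is at least
#' `tau` (coefficients below the threshold are filtered out); the genes
#' incident to at least one retained pair form the molecular signature.
#' Negative correlations are excluded unless `absolute = TRUE`.
#'
#' @param corr Correlation matrix from [pearson_matrix()].
#' @param tau Threshold in (0, 1).
#' @param absolute Threshold `|rho|` instead of the signed coefficient.
#' @return An object of class `signature_result`: `threshold`, `edges`
#'   (data frame gene1/gene2/rho), `signature` (character), `size`.
#' @export
signature_at_threshold <- function(corr, tau, absolute = FALSE) {
  stopifnot(tau > 0, tau < 1, nrow(corr) == ncol(corr))
  val <- if (absolute) abs(corr) else corr
  ut <- which(upper.tri(val) & val >= tau, arr.ind = TRUE)
  genes <- rownames(corr)
  edges <- data.frame(gene1 = genes[ut[, 1]], gene2 = genes[ut[, 2]],
                      rho = corr[ut], stringsAsFactors = FALSE)
  sig <- sort(unique(c(edges$gene1, edges$gene2)))
  structure(list(threshold = tau, edges = edges, signature = sig,
                 size = length(sig), met_target = NA),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result> threshold %.3f: %d genes, %d co-expression edges\n",
              x$threshold, x$size, nrow(x$edges)))
  invisible(x)
}

#' Tune the correlation threshold to a target signature size
#'
#' Scans the grid and returns the signature at the largest threshold whose
#' size still reaches `target_size` (signature size never increases with the
#' threshold, so this is the closest achievable size from above; it is the
#' "about 50, but no less than 50" policy with the default grid).
#' If no grid point reaches the target, the lowest-threshold result is
#' returned with `met_target = FALSE`.
#'
#' @param corr Correlation matrix from [pearson_matrix()].
#' @param target_size Minimum signature size (default 50).
#' @param grid Candidate thresholds; default 0.6 to 0.945 in steps of 0.005.
#' @param absolute Threshold on `|rho|` instead of the signed coefficient.
#' @return A `signature_result` whose `met_target` flag records whether the
#'   target size was achieved.
#' @export
tune_threshold <- function(corr, target_size = 50,
                           grid = seq(0.6, 0.945, by = 0.005),
                           absolute = FALSE) {
  stopifnot(target_size >= 1, length(grid) >= 1)
  if (nrow(corr) == 0) stop("empty correlation matrix")
  grid <- sort(grid)
  val <- if (absolute) abs(corr) else corr
  diag(val) <- -Inf
  row_max <- apply(val, 1, max)              # a gene enters iff its best
  sizes <- vapply(grid, function(tau) sum(row_max >= tau), integer(1)) # partner passes
  ok <- which(sizes >= target_size)
  if (length(ok)) {
    tau <- grid[max(ok)]
    res <- signature_at_threshold(corr, tau, absolute = absolute)
    res$met_target <- TRUE
  } else {
    log_msg("tune_threshold: no grid threshold reaches size %d; returning lowest threshold",
            target_size)
    res <- signature_at_threshold(corr, grid[1], absolute = absolute)
    res$met_target <- FALSE
  }
  res
}
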