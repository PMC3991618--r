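#' Gaussian mutual information from a correlation matrix
#'
#' Under a bivariate Gaussian model the mutual information of two profiles
#' with Pearson coefficient rho is \eqn{MI = -\frac{1}{2}\ln(1-\rho^2)}.
#' `|rho|` is clamped to `1 - 1e-12` so duplicated profiles stay finite; the
#' diagonal is set to 0 and excluded from all background statistics
#' downstream.
#'
#' @param corr Correlation matrix from [pearson_matrix()].
#' @return Symmetric nonnegative MI matrix, zero diagonal.
#' @export
gaussian_mi <- function(corr) {
  r2 <- pmin(corr^2, (1 - 1e-12)^2)
  mi <- -0.5 * log(1 - r2)
  diag(mi) <- 0
  dimnames(mi) <- dimnames(corr)
  mi
}

#' CLR background-corrected z-scores for TF-target pairs
#'
#' Context likelihood of relatedness: the MI of each TF-target pair is
#' compared with the background MI distribution of both the TF and the
#' target. For TF t and gene g, `z_t = max(0, (MI(t,g) - mu_t) / sd_t)` with
#' `mu_t`, `sd_t` the mean and standard deviation of t's MI to all non-self
#' partners (`z_g` analogously over g's row), and the combined score is the
#' Euclidean norm `sqrt(z_t^2 + z_g^2)`. Genes whose MI background has zero
#' spread contribute a zero component (logged).
#'
#' @param mi MI matrix from [gaussian_mi()] over the top-K gene universe.
#' @param tf_genes Transcription-factor catalogue ([gene_set()] or character
#'   vector); only TFs present in the universe are used.
#' @return Data frame of class `regulatory_interactions` with columns `tf`,
#'   `target`, `mi`, `z`, sorted by decreasing `z`.
#' @export
clr_z <- function(mi, tf_genes) {
  genes <- rownames(mi)
  K <- length(genes)
  if (K < 3) stop("need at least 3 genes for background statistics")
  tfs <- intersect(as_members(tf_genes), genes)
  if (length(tfs) == 0) stop("no transcription factors in the gene universe")
  mu <- vapply(seq_len(K), function(i) mean(mi[i, -i]), numeric(1))
  sdv <- vapply(seq_len(K), function(i) sd(mi[i, -i]), numeric(1))
  if (any(sdv == 0))
    log_msg("clr_z: %d gene(s) with zero MI spread contribute zero z-components",
            sum(sdv == 0))
  zmat <- (mi - mu) / ifelse(sdv == 0, Inf, sdv)   # row-standardized (by source)
  zmat[zmat < 0] <- 0
  ti <- match(tfs, genes)
  # component from the TF's background: zmat[ti, ], from the target's: t(zmat)[ti, ]
  z_tf <- zmat[ti, , drop = FALSE]
  z_tg <- t(zmat)[ti, , drop = FALSE]
  zz <- sqrt(z_tf^2 + z_tg^2)
  out <- data.frame(
    tf = rep(tfs, times = K),
    target = rep(genes, each = length(tfs)),
    mi = as.vector(mi[ti, , drop = FALSE]),
    z = as.vector(zz),
    stringsAsFactors = FALSE)
  out <- out[out$tf != out$target, ]
  out <- out[order(-out$z, out$tf, out$target, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("regulatory_interactions", "data.frame")
  out
}

#' Screening criteria for key regulators
#'
#' A TF is retained when, among its interactions surviving the z cutoff, the
#' number of benchmark targets is strictly greater than
#' `min_benchmark_targets` and the benchmark fraction of all its targets is
#' strictly greater than `min_benchmark_fraction`.
#'
#' @param z_min Minimum combined z-score (interactions with `z < z_min` are
#'   filtered out). Default 3.
#' @param min_benchmark_targets Benchmark-target count must exceed this.
#'   Default 3.
#' @param min_benchmark_fraction Benchmark fraction of all targets must
#'   exceed this. Default 0.6.
#' @return An object of class `regulator_criteria`.
#' @export
regulator_criteria <- function(z_min = 3, min_benchmark_targets = 3,
                               min_benchmark_fraction = 0.6) {
  stopifnot(z_min > 0, min_benchmark_targets > 0, min_benchmark_fraction > 0)
  structure(list(z_min = z_min,
                 min_benchmark_targets = min_benchmark_targets,
                 min_benchmark_fraction = min_benchmark_fraction),
            class = "regulator_criteria")
}

#' Screen TFs for key regulators
#'
#' @param interactions Output of [clr_z()].
#' @param benchmark Benchmark pathology gene set ([gene_set()] or character).
#' @param criteria A [regulator_criteria()].
#' @return List with `report` (one row per TF appearing among the surviving
#'   interactions: target counts, benchmark counts, fraction, retained flag)
#'   and `regulators` (sorted character vector of retained TFs).
#' @export
screen_regulators <- function(interactions, benchmark,
                              criteria = regulator_criteria()) {
  bench <- as_members(benchmark)
  keep <- interactions[interactions$z >= criteria$z_min, , drop = FALSE]
  if (nrow(keep) == 0) {
    report <- data.frame(tf = character(0), n_targets = integer(0),
                         n_benchmark = integer(0), benchmark_fraction = numeric(0),
                         retained = logical(0), stringsAsFactors = FALSE)
    return(list(report = report, regulators = character(0)))
  }
  tfs <- sort(unique(keep$tf))
  n_targets <- vapply(tfs, function(t) sum(keep$tf == t), integer(1))
  n_bench <- vapply(tfs, function(t)
    sum(keep$tf == t & keep$target %in% bench), integer(1))
  frac <- n_bench / n_targets
  retained <- n_bench > criteria$min_benchmark_targets &
    frac > criteria$min_benchmark_fraction
  report <- data.frame(tf = tfs, n_targets = n_targets, n_benchmark = n_bench,
                       benchmark_fraction = frac, retained = retained,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(report = report, regulators = tfs[retained])
}

#' Union of per-condition regulator sets with provenance
#'
#' @param per_condition Named list of character vectors (retained TFs per
#'   condition/contrast).
#' @return List with `members` (sorted union) and `provenance` (data frame
#'   mapping each TF to the conditions that nominated it).
#' @export
union_regulators <- function(per_condition) {
  stopifnot(length(per_condition) >= 1)
  if (is.null(names(per_condition)))
    names(per_condition) <- paste0("condition_", seq_along(per_condition))
  members <- sort(unique(unlist(per_condition, use.names = FALSE)))
  prov <- vapply(members, function(tf) {
    paste(names(per_condition)[vapply(per_condition, function(s) tf %in% s,
                                      logical(1))], collapse = ",")
  }, character(1))
  list(members = members,
       provenance = data.frame(tf = members, conditions = unname(prov),
                               stringsAsFactors = FALSE))
}
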