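#' Upper-tail hypergeometric p-value
#'
#' Exact probability of observing at least `hits` benchmark members when
#' `selected_size` genes are drawn without replacement from a population of
#' `population` genes containing `population_hits` benchmark members
#' (`P(X >= hits)`, the observed count included in the tail).
#'
#' @param hits Observed overlap count.
#' @param selected_size Size of the selection.
#' @param population_hits Benchmark members in the population.
#' @param population Population size.
#' @return Probability in (0, 1].
#' @export
hypergeom_pvalue <- function(hits, selected_size, population_hits, population) {
  stopifnot(hits >= 0, selected_size >= 0, population_hits >= 0,
            population >= 1, selected_size <= population,
            population_hits <= population,
            hits <= min(selected_size, population_hits))
  phyper(hits - 1, population_hits, population - population_hits,
         selected_size, lower.tail = FALSE)
}

#' Enrichment of a gene selection against a benchmark set
#'
#' The enrichment ratio is the fraction of the selection belonging to the
#' benchmark; the population for the hypergeometric test is the network gene
#' universe, with the benchmark pre-intersected against it.
#'
#' @param selection Selected genes ([gene_set()], character vector, or a
#'   [ranked_gene_list()] whose whole gene column is taken). Must be a
#'   non-empty subset of the population.
#' @param benchmark Benchmark pathology gene set.
#' @param population Gene universe: an `igraph` network or a character
#'   vector of gene identifiers.
#' @return An `enrichment_result` list: `selected_size`, `hits`, `ratio`,
#'   `percent` (one decimal, half-up), `population`, `population_hits`,
#'   `pvalue`.
#' @export
enrichment_ratio <- function(selection, benchmark, population) {
  pop <- if (inherits(population, "igraph")) network_genes(population)
         else unique(as.character(population))
  sel <- if (inherits(selection, "ranked_gene_list")) selection$gene
         else as_members(selection)
  if (length(sel) == 0) stop("empty selection")
  outside <- setdiff(sel, pop)
  if (length(outside))
    stop("selection contains genes outside the population: ",
         paste(head(outside, 5), collapse = ", "))
  bench <- intersect(as_members(benchmark), pop)
  hits <- length(intersect(sel, bench))
  ratio <- hits / length(sel)
  structure(list(
    selected_size = length(sel),
    hits = hits,
    ratio = ratio,
    percent = percent_round(ratio),
    population = length(pop),
    population_hits = length(bench),
    pvalue = hypergeom_pvalue(hits, length(sel), length(bench), length(pop))),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d/%d = %.1f%% (background %d/%d), p = %.3g\n",
              x$hits, x$selected_size, x$percent, x$population_hits,
              x$population, x$pvalue))
  invisible(x)
}

#' Enrichment curve over a top-K grid
#'
#' Evaluates [enrichment_ratio()] for the top K genes of a ranked list at
#' K = `k_start`, `k_start + k_step`, ... up to `k_max`.
#'
#' @param ranked A [ranked_gene_list()].
#' @param benchmark Benchmark gene set.
#' @param population Gene universe (network or character vector).
#' @param k_start,k_step K grid (defaults 50 and 50).
#' @param k_max Largest K; defaults to the list length (must not exceed it).
#' @return Data frame with one row per K: `k`, `hits`, `ratio`, `percent`,
#'   `pvalue`.
#' @export
enrichment_curve <- function(ranked, benchmark, population,
                             k_start = 50, k_step = 50, k_max = NULL) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  if (is.null(k_max)) k_max <- nrow(ranked)
  stopifnot(k_max <= nrow(ranked), k_start >= 1, k_step >= 1)
  ks <- seq(k_start, k_max, by = k_step)
  rows <- lapply(ks, function(k) {
    er <- enrichment_ratio(top_genes(ranked, k), benchmark, population)
    data.frame(k = k, hits = er$hits, ratio = er$ratio, percent = er$percent,
               pvalue = er$pvalue)
  })
  do.call(rbind, rows)
}

#' Paired comparison of per-dataset enrichment ratios
#'
#' Standard paired t-test on the differences of two equal-length vectors of
#' enrichment ratios (one value per dataset/condition). Zero-variance
#' differences are flagged degenerate and no p-value is emitted.
#'
#' @param ratios_a,ratios_b Paired numeric vectors, length >= 2.
#' @return List with `t`, `df`, `pvalue`, `mean_diff`, `degenerate`.
#' @export
paired_compare <- function(ratios_a, ratios_b) {
  stopifnot(length(ratios_a) == length(ratios_b), length(ratios_a) >= 2)
  d <- ratios_a - ratios_b
  if (sd(d) == 0) {
    return(list(t = NA_real_, df = NA_real_, pvalue = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(ratios_a, ratios_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       pvalue = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}
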