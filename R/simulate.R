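#' Simulation parameters for the planted-signature benchmark
#'
#' Defaults describe the standard signal condition: a 2000-gene scale-free
#' network at the density of curated human PPI networks (4 edges per node), a planted pathology
#' module of 200 genes (10 percent background rate) split into 4
#' co-expression modules of 50, one planted regulator TF per module plus
#' non-pathology decoy TFs, 4 control and 4 treated samples, a 2 log2-unit
#' treatment effect on pathology genes and unit log2 noise.
#'
#' @param n_genes Number of network genes.
#' @param edges_per_node Preferential-attachment edges added per new node.
#' @param n_pathology Number of planted pathology genes.
#' @param n_modules Number of co-expression modules the pathology genes are
#'   partitioned into.
#' @param n_tfs Total transcription factors (one regulator per module, the
#'   rest decoys sampled outside the pathology set).
#' @param n_samples_control,n_samples_treated Sample group sizes.
#' @param effect_size Treatment effect on pathology genes, log2 units.
#' @param within_module_correlation Target Pearson correlation between
#'   members of one module, in (0, 1).
#' @param tf_target_coupling Loading of a regulator's activity on its
#'   targets.
#' @param noise_sd Per-sample log2 noise standard deviation.
#' @param seed Base random seed.
#' @param preset One of `"signal"` (defaults), `"null"` (no treatment
#'   effect), `"full_scale"` (7633 genes, 1462 pathology genes,
#'   ~31000 edges). Explicit arguments override the preset.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 2000, edges_per_node = 4,
                              n_pathology = 200, n_modules = 4, n_tfs = 20,
                              n_samples_control = 4, n_samples_treated = 4,
                              effect_size = 2, within_module_correlation = 0.8,
                              tf_target_coupling = 0.8, noise_sd = 1,
                              seed = 1,
                              preset = c("signal", "null", "full_scale")) {
  preset <- match.arg(preset)
  if (preset == "null" && missing(effect_size)) effect_size <- 0
  if (preset == "full_scale") {
    if (missing(n_genes)) n_genes <- 7633
    if (missing(n_pathology)) n_pathology <- 1462
    if (missing(n_modules)) n_modules <- 29
    if (missing(n_tfs)) n_tfs <- 60
  }
  p <- list(n_genes = n_genes, edges_per_node = edges_per_node,
            n_pathology = n_pathology, n_modules = n_modules, n_tfs = n_tfs,
            n_samples_control = n_samples_control,
            n_samples_treated = n_samples_treated,
            effect_size = effect_size,
            within_module_correlation = within_module_correlation,
            tf_target_coupling = tf_target_coupling,
            noise_sd = noise_sd, seed = seed, preset = preset)
  stopifnot(p$n_genes > p$edges_per_node, p$edges_per_node >= 1,
            p$n_pathology >= 1, p$n_pathology <= p$n_genes,
            p$n_modules >= 1, p$n_tfs >= p$n_modules,
            p$n_samples_control >= 1, p$n_samples_treated >= 1,
            p$within_module_correlation > 0, p$within_module_correlation < 1,
            p$noise_sd > 0)
  structure(p, class = "simulation_params")
}

#' Generate a scale-free gene network
#'
#' Barabasi-Albert preferential attachment starting from a complete graph on
#' `edges_per_node` nodes; each subsequent node attaches `edges_per_node`
#' edges to existing nodes with probability proportional to current degree.
#' The edge count is therefore exactly
#' `(n_genes - m) * m + choose(m, 2)` with `m = edges_per_node`, and the
#' graph is connected with hub nodes, emulating PPI topology.
#'
#' @param n_genes Number of nodes (> `edges_per_node`).
#' @param edges_per_node Edges attached per new node.
#' @param seed Random seed (deterministic output per seed).
#' @return An undirected simple `igraph` network with gene names
#'   `g00001, ...`.
#' @export
generate_network <- function(n_genes, edges_per_node = 4, seed = 1) {
  stopifnot(n_genes > edges_per_node, edges_per_node >= 1)
  set.seed(seed)
  m <- as.integer(edges_per_node)
  n <- as.integer(n_genes)
  n_edges <- choose(m, 2) + (n - m) * m
  ei <- integer(n_edges); ej <- integer(n_edges)
  deg <- integer(n)
  k <- 0L
  if (m >= 2) {
    seed_pairs <- combn(m, 2)
    np <- ncol(seed_pairs)
    ei[seq_len(np)] <- seed_pairs[1, ]; ej[seq_len(np)] <- seed_pairs[2, ]
    deg[1:m] <- m - 1L
    k <- np
  }
  for (v in (m + 1L):n) {
    w <- deg[seq_len(v - 1L)]
    if (sum(w) == 0) w <- rep(1, v - 1L)
    tgt <- sample.int(v - 1L, m, replace = FALSE, prob = w)
    idx <- k + seq_len(m)
    ei[idx] <- v; ej[idx] <- tgt
    deg[v] <- deg[v] + m
    deg[tgt] <- deg[tgt] + 1L
    k <- k + m
  }
  width <- max(5L, nchar(n))
  nm <- sprintf(paste0("g%0", width, "d"), seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = nm[ei], to = nm[ej], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nm, stringsAsFactors = FALSE))
  g
}

#' Plant pathology genes, modules and TF regulators on a network
#'
#' Pathology genes are the first `n_pathology` nodes of a breadth-first
#' traversal from a random root, so the planted set forms a connected
#' neighborhood (the working hypothesis being that signature components
#' interact); `scattered = TRUE` plants them uniformly instead, for
#' ablation. The BFS order is split into `n_modules` contiguous modules.
#' Each module receives one regulator TF -- its highest-degree member,
#' since master regulators are typically hub proteins -- with planted
#' regulatory edges to every other member; the remaining TFs are decoys
#' sampled from non-pathology genes.
#'
#' @param net Network from [generate_network()].
#' @param params A [simulation_params()].
#' @param seed Random seed (defaults to `params$seed + 1`).
#' @param scattered Plant pathology genes uniformly at random instead of on
#'   a connected neighborhood.
#' @return An object of class `synthetic_truth`: `pathology_genes`,
#'   `tf_genes`, `regulators`, `regulatory_edges` (data frame tf/target),
#'   `module_assignments` (named integer), `params`, `seed`.
#' @export
plant_truth <- function(net, params, seed = params$seed + 1,
                        scattered = FALSE) {
  genes <- network_genes(net)
  stopifnot(params$n_pathology <= length(genes))
  set.seed(seed)
  if (scattered) {
    pathology <- sample(genes, params$n_pathology)
  } else {
    root <- sample(genes, 1)
    ord <- igraph::bfs(net, root = root, order = TRUE)$order
    pathology <- igraph::V(net)$name[as.integer(ord)][seq_len(params$n_pathology)]
  }
  module_size <- ceiling(params$n_pathology / params$n_modules)
  if (module_size < 2) stop("modules of fewer than 2 genes are infeasible")
  mod <- as.integer((seq_along(pathology) - 1L) %/% module_size) + 1L
  module_assignments <- setNames(mod, pathology)
  # master regulators are hub proteins: each module is driven by its
  # highest-degree member (ties broken lexicographically)
  dg <- igraph::degree(net)[pathology]
  regulators <- vapply(seq_len(max(mod)), function(m) {
    members <- pathology[mod == m]
    members[order(-dg[members], members)][1]
  }, character(1))
  n_decoys <- params$n_tfs - length(regulators)
  outside <- setdiff(genes, pathology)
  decoys <- if (n_decoys > 0) sample(outside, min(n_decoys, length(outside)))
            else character(0)
  reg_edges <- do.call(rbind, lapply(seq_along(regulators), function(m) {
    targets <- setdiff(pathology[mod == m], regulators[m])
    data.frame(tf = regulators[m], target = targets, stringsAsFactors = FALSE)
  }))
  structure(list(pathology_genes = pathology,
                 tf_genes = sort(c(regulators, decoys)),
                 regulators = regulators,
                 regulatory_edges = reg_edges,
                 module_assignments = module_assignments,
                 params = params, seed = seed),
            class = "synthetic_truth")
}

#' Simulate a linear-scale expression matrix from a planted truth
#'
#' Log2-scale generative model for gene g in sample s:
#' baseline + lambda * z(module(g), s) + u-term + delta (pathology genes,
#' treated samples) + residual noise. Every gene has the same marginal log2
#' standard deviation `noise_sd`: module members split that fixed variance
#' budget into a shared part (loading `lambda = noise_sd * sqrt(rho)` on the
#' module factor z) and a residual part (`noise_sd * sqrt(1 - rho)`), which
#' yields within-module correlation rho without inflating per-gene
#' variability -- co-expression redistributes variance, it does not add it.
#' Regulator TFs carry a private activity factor u (one residual-sd unit)
#' and their targets receive `beta` residual-sd units of u. Latent factors
#' are centered within each condition group so the planted effect size is
#' exactly the expected log2 fold change and a null (delta = 0) dataset is
#' free of condition-confounded module signal. The matrix is returned on
#' the linear scale (2^x), so the fold-change pipeline applies end to end.
#'
#' @param truth A [plant_truth()] result.
#' @param params A [simulation_params()].
#' @param seed Random seed (defaults to `params$seed + 2`).
#' @return List with `expression` (linear-scale matrix), `control` and
#'   `treated` sample identifier vectors.
#' @export
simulate_expression <- function(truth, params = truth$params,
                                seed = params$seed + 2) {
  set.seed(seed)
  nc <- params$n_samples_control; nt <- params$n_samples_treated
  samples <- c(paste0("ctrl_", seq_len(nc)), paste0("trt_", seq_len(nt)))
  is_treated <- c(rep(FALSE, nc), rep(TRUE, nt))
  genes <- names(truth$module_assignments)
  all_genes <- network_genes_of_truth(truth)
  n <- length(all_genes); ns <- nc + nt
  rho <- params$within_module_correlation
  lambda <- params$noise_sd * sqrt(rho)        # shared part of the unit budget
  resid_sd <- params$noise_sd * sqrt(1 - rho)  # residual part for module genes

  center_groups <- function(mat) {
    mat[, !is_treated] <- mat[, !is_treated, drop = FALSE] -
      rowMeans(mat[, !is_treated, drop = FALSE])
    mat[, is_treated] <- mat[, is_treated, drop = FALSE] -
      rowMeans(mat[, is_treated, drop = FALSE])
    mat
  }
  n_mod <- max(truth$module_assignments)
  z <- center_groups(matrix(rnorm(n_mod * ns), n_mod, ns))
  u <- center_groups(matrix(rnorm(length(truth$regulators) * ns),
                            length(truth$regulators), ns))
  rownames(u) <- truth$regulators

  gi <- match(genes, all_genes)
  gene_sd <- rep(params$noise_sd, n)
  gene_sd[gi] <- resid_sd
  x <- matrix(rnorm(n * ns), n, ns, dimnames = list(all_genes, samples)) * gene_sd
  x <- x + rnorm(n, mean = 8, sd = 1)          # per-gene baseline
  x[gi, ] <- x[gi, ] + lambda * z[truth$module_assignments, , drop = FALSE]
  x[match(truth$regulators, all_genes), ] <-
    x[match(truth$regulators, all_genes), ] + resid_sd * u
  if (nrow(truth$regulatory_edges) > 0) {
    ti <- match(truth$regulatory_edges$target, all_genes)
    x[ti, ] <- x[ti, ] + params$tf_target_coupling * resid_sd *
      u[truth$regulatory_edges$tf, , drop = FALSE]
  }
  if (params$effect_size != 0) {
    x[gi, is_treated] <- x[gi, is_treated] + params$effect_size
  }
  list(expression = 2^x,
       control = samples[!is_treated],
       treated = samples[is_treated])
}

# The gene universe a truth object was planted on (kept on the object to make
# simulate_expression self-contained once the network is attached).
network_genes_of_truth <- function(truth) {
  if (!is.null(truth$all_genes)) return(truth$all_genes)
  stop("truth object lacks the gene universe; use simulate_dataset() or attach $all_genes")
}

#' One-call synthetic dataset
#'
#' Generates the network, plants the truth, simulates expression, and wires
#' the pieces together.
#'
#' @param params A [simulation_params()].
#' @param seed Base seed; sub-steps use fixed small offsets from it.
#' @param scattered Passed to [plant_truth()].
#' @return List with `network`, `truth`, `expression`, `control`, `treated`.
#' @export
simulate_dataset <- function(params = simulation_params(), seed = params$seed,
                             scattered = FALSE) {
  net <- generate_network(params$n_genes, params$edges_per_node, seed = seed)
  truth <- plant_truth(net, params, seed = seed + 1, scattered = scattered)
  truth$all_genes <- network_genes(net)
  sim <- simulate_expression(truth, params, seed = seed + 2)
  list(network = net, truth = truth, expression = sim$expression,
       control = sim$control, treated = sim$treated)
}

#' Write a complete synthetic fixture to disk
#'
#' Produces files the whole pipeline (and its command-line interface)
#' consumes unmodified: `network.tsv` (edge list), `expression.tsv`,
#' `benchmark.gmt` (pathology genes), `tfs.txt`, `contrasts.yaml`, and
#' `truth.json` (the planted ground truth and all generator settings).
#'
#' @param params A [simulation_params()].
#' @param outdir Writable output directory (created if absent).
#' @param seed Base seed.
#' @return Invisibly, a named list of the written paths.
#' @export
make_fixture <- function(params = simulation_params(), outdir,
                         seed = params$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(params, seed = seed)
  paths <- list(
    network = file.path(outdir, "network.tsv"),
    expression = file.path(outdir, "expression.tsv"),
    benchmark = file.path(outdir, "benchmark.gmt"),
    tfs = file.path(outdir, "tfs.txt"),
    contrasts = file.path(outdir, "contrasts.yaml"),
    truth = file.path(outdir, "truth.json"))
  write_network(ds$network, paths$network)
  write_expression(ds$expression, paths$expression)
  write_gene_set(gene_set("pathology", ds$truth$pathology_genes),
                 paths$benchmark, description = "planted pathology genes")
  writeLines(ds$truth$tf_genes, paths$tfs)
  yaml::write_yaml(list(treatment = list(control = ds$control,
                                         treated = ds$treated)),
                   paths$contrasts)
  write_truth(ds$truth, paths$truth)
  invisible(paths)
}

#' Serialize / reload a planted truth as JSON
#'
#' @param truth A [plant_truth()] result.
#' @param path JSON path.
#' @return `write_truth` returns the path invisibly; `read_truth` the
#'   reloaded `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  obj <- list(pathology_genes = truth$pathology_genes,
              tf_genes = truth$tf_genes,
              regulators = truth$regulators,
              regulatory_edges = truth$regulatory_edges,
              module_assignments = as.list(truth$module_assignments),
              params = unclass(truth$params),
              seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ma <- unlist(obj$module_assignments)
  prm <- obj$params
  params <- simulation_params(
    n_genes = prm$n_genes, edges_per_node = prm$edges_per_node,
    n_pathology = prm$n_pathology, n_modules = prm$n_modules,
    n_tfs = prm$n_tfs, n_samples_control = prm$n_samples_control,
    n_samples_treated = prm$n_samples_treated, effect_size = prm$effect_size,
    within_module_correlation = prm$within_module_correlation,
    tf_target_coupling = prm$tf_target_coupling, noise_sd = prm$noise_sd,
    seed = prm$seed, preset = prm$preset)
  structure(list(pathology_genes = obj$pathology_genes,
                 tf_genes = obj$tf_genes,
                 regulators = obj$regulators,
                 regulatory_edges = as.data.frame(obj$regulatory_edges),
                 module_assignments = setNames(as.integer(ma), names(ma)),
                 params = params, seed = obj$seed),
            class = "synthetic_truth")
}
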