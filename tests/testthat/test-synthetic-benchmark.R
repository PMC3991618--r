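small_params <- function(...) {
  simulation_params(n_genes = 300, edges_per_node = 3, n_pathology = 40,
                    n_modules = 4, n_tfs = 6, n_samples_control = 3,
                    n_samples_treated = 3, ...)
}

test_that("preferential attachment yields the documented edge count and hubs", {
  net <- generate_network(100, 2, seed = 1)
  # complete start on m nodes + m edges per newcomer: (100-2)*2 + choose(2,2)
  expect_equal(igraph::ecount(net), 197)
  expect_equal(igraph::vcount(net), 100)
  expect_false(igraph::any_loop(net))
  expect_true(igraph::is_connected(net))

  big <- generate_network(2000, 4, seed = 3)
  expect_equal(igraph::ecount(big), (2000 - 4) * 4 + choose(4, 2))
  d <- igraph::degree(big)
  expect_gt(max(d), 10 * stats::median(d))   # hub existence
})

test_that("network generation is deterministic per seed", {
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(canon(generate_network(200, 3, seed = 9)),
                   canon(generate_network(200, 3, seed = 9)))
  expect_false(identical(canon(generate_network(200, 3, seed = 9)),
                         canon(generate_network(200, 3, seed = 10))))
})

test_that("planted truth respects the network and module structure", {
  p <- small_params()
  net <- generate_network(p$n_genes, p$edges_per_node, seed = 2)
  truth <- plant_truth(net, p, seed = 3)
  expect_length(truth$pathology_genes, 40)
  expect_true(all(truth$pathology_genes %in% network_genes(net)))
  expect_true(all(truth$regulatory_edges$target %in% network_genes(net)))
  expect_true(all(truth$regulators %in% truth$pathology_genes))
  expect_equal(sort(unique(truth$module_assignments)), 1:4)
  # the regulator of each module is its highest-degree member
  dg <- igraph::degree(net)
  for (m in 1:4) {
    members <- names(truth$module_assignments)[truth$module_assignments == m]
    expect_equal(max(dg[members]), unname(dg[truth$regulators[m]]))
  }
  # planting everything is allowed
  pall <- simulation_params(n_genes = 300, edges_per_node = 3,
                            n_pathology = 300, n_modules = 4, n_tfs = 6,
                            n_samples_control = 3, n_samples_treated = 3)
  expect_length(plant_truth(net, pall, seed = 1)$pathology_genes, 300)
})

test_that("the planted neighborhood is denser than degree-matched random sets", {
  internal_edges <- function(net, genes) {
    igraph::ecount(igraph::induced_subgraph(net, genes))
  }
  for (seed in 1:3) {
    p <- simulation_params(n_genes = 500, edges_per_node = 3,
                           n_pathology = 60, n_modules = 4, n_tfs = 6)
    net <- generate_network(p$n_genes, p$edges_per_node, seed = seed)
    truth <- plant_truth(net, p, seed = seed + 50)
    planted <- internal_edges(net, truth$pathology_genes)
    # degree-matched nulls: resample one gene per planted gene from its
    # degree decile
    d <- igraph::degree(net)
    decile <- cut(rank(d, ties.method = "first"), 10, labels = FALSE)
    names(decile) <- names(d)
    set.seed(seed)
    nulls <- replicate(20, {
      picked <- vapply(truth$pathology_genes, function(g)
        sample(names(decile)[decile == decile[g]], 1), character(1))
      internal_edges(net, unique(picked))
    })
    expect_gt(planted, stats::median(nulls))
  }
})

test_that("scattered planting spreads genes beyond one neighborhood", {
  p <- small_params()
  net <- generate_network(p$n_genes, p$edges_per_node, seed = 4)
  bfs <- plant_truth(net, p, seed = 5)
  sct <- plant_truth(net, p, seed = 5, scattered = TRUE)
  ie <- function(genes) igraph::ecount(igraph::induced_subgraph(net, genes))
  expect_gt(ie(bfs$pathology_genes), ie(sct$pathology_genes))
})

test_that("simulated expression recovers the planted effect size", {
  est <- vapply(1:10, function(s) {
    ds <- simulate_dataset(simulation_params(), seed = s * 101)
    fc <- log2_fold_change(ds$expression, ds$control, ds$treated)
    mean(fc[ds$truth$pathology_genes])
  }, numeric(1))
  expect_lt(abs(mean(est) - 2), 0.2)
})

test_that("a null dataset shows no excess fold change on pathology genes", {
  for (s in c(17, 34, 51)) {
    ds <- simulate_dataset(simulation_params(preset = "null"), seed = s)
    fc <- log2_fold_change(ds$expression, ds$control, ds$treated)
    path <- abs(fc[ds$truth$pathology_genes])
    bg <- abs(fc[setdiff(names(fc), ds$truth$pathology_genes)])
    expect_lte(mean(path), mean(bg) + 2 * sd(bg) / sqrt(length(path)))
  }
})

test_that("within-module correlation exceeds between-module correlation", {
  # delta = 0 isolates the rho_sig co-expression structure (with a planted
  # effect the shared treated/control contrast correlates all pathology
  # genes and compresses the within/between gap)
  gaps <- vapply(1:3, function(s) {
    ds <- simulate_dataset(simulation_params(preset = "null"), seed = s * 77)
    lx <- log2(ds$expression)
    ma <- ds$truth$module_assignments
    cc <- stats::cor(t(lx[names(ma), ]))
    same <- outer(ma, ma, "==") & upper.tri(cc)
    diff_mod <- outer(ma, ma, "!=") & upper.tri(cc)
    stats::median(cc[same]) - stats::median(cc[diff_mod])
  }, numeric(1))
  expect_true(all(gaps > 0.3))
})

test_that("expression simulation is deterministic per seed and strictly positive", {
  p <- small_params()
  a <- simulate_dataset(p, seed = 6)
  b <- simulate_dataset(p, seed = 6)
  expect_identical(a$expression, b$expression)
  expect_true(all(a$expression > 0))
  c2 <- simulate_dataset(p, seed = 7)
  expect_false(identical(a$expression, c2$expression))
  expect_identical(dimnames(a$expression), dimnames(c2$expression))
})

test_that("fixtures round-trip through the package readers", {
  outdir <- tempfile("fixture")
  paths <- suppressMessages(make_fixture(small_params(), outdir, seed = 8))
  expect_true(all(file.exists(unlist(paths))))

  net <- read_network(paths$network)
  expr <- read_expression(paths$expression)
  bench <- read_gene_set(paths$benchmark)
  tfs <- read_gene_set(paths$tfs)
  cts <- read_contrasts(paths$contrasts)
  truth <- read_truth(paths$truth)

  expect_equal(igraph::vcount(net), 300)
  expect_equal(nrow(expr), 300)
  expect_setequal(bench$members, truth$pathology_genes)
  expect_length(tfs$members, 6)
  expect_length(cts$treatment$control, 3)
  # serialization identity on the truth
  ds <- simulate_dataset(small_params(), seed = 8)
  expect_identical(truth$pathology_genes, ds$truth$pathology_genes)
  expect_identical(truth$regulatory_edges, ds$truth$regulatory_edges)
  expect_identical(truth$module_assignments, ds$truth$module_assignments)
  expect_equal(unclass(truth$params)[1:12],
               unclass(ds$truth$params)[1:12])
})
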