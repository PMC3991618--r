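test_that("DEG sets convert linear cutoffs to the log2 scale", {
  fc <- c(a = 2.1, b = 1.9, c = -2.4, d = 0.1)
  d4 <- deg_set(fc, 4)                 # log2(4) = 2
  expect_setequal(as.character(d4), c("a", "c"))
  expect_equal(attr(d4, "cutoff"), 4)
  # a cutoff just above 1 includes nearly everything responsive
  expect_setequal(as.character(deg_set(fc, 1.01)), c("a", "b", "c", "d"))
  expect_error(deg_set(fc, 1))
})

test_that("fold-change ranking sorts by |f| with deterministic ties", {
  fc <- c(g1 = 3, g2 = -4, g3 = 1)
  expect_equal(fold_change_rank(fc)$gene, c("g2", "g1", "g3"))

  net <- toy_star_network()
  tied <- setNames(rep(2, 5), network_genes(net))
  rl <- fold_change_rank(tied, net)
  expect_equal(rl$gene[1], "H")        # hub wins the tie

  set.seed(4)
  fc10 <- setNames(rnorm(10), sprintf("g%02d", 1:10))
  expect_equal(fold_change_rank(fc10)$gene,
               names(sort(abs(fc10), decreasing = TRUE)))
})

test_that("degree ranking puts hubs first and recounts adjacency sums", {
  rl <- degree_rank(toy_star_network())
  expect_equal(rl$gene[1], "H")
  expect_equal(rl$score[1], 4)

  ring <- as_gene_network(data.frame(from = c("a", "b", "c"),
                                     to = c("b", "c", "a")), quiet = TRUE)
  expect_equal(degree_rank(ring)$gene, c("a", "b", "c"))  # 2-regular: id order

  net <- generate_network(80, 2, seed = 5)
  rl2 <- degree_rank(net)
  A <- igraph::as_adjacency_matrix(net)
  expect_equal(setNames(rl2$score, rl2$gene)[rownames(A)],
               Matrix::rowSums(A))
})

test_that("neighborhood scores average the gene and its neighbors equally", {
  # B has |f| = 2 with neighbors |f| = 4 and 0 -> (2 + 2)/2 = 2
  net <- toy_path_network()
  fc <- c(A = 4, B = 2, C = 0)
  d <- deg_set(fc, 4)
  rl <- neighborhood_score(net, fc, d)
  s <- setNames(rl$score, rl$gene)
  expect_equal(unname(s["B"]), 2)
  # non-DE gene without DE neighbors scores 0
  net2 <- as_gene_network(data.frame(from = c("A", "C"), to = c("B", "D")),
                          quiet = TRUE)
  fc2 <- c(A = 4, B = 0.1, C = 0.2, D = 0.1)
  s2 <- with(neighborhood_score(net2, fc2, deg_set(fc2, 4)),
             setNames(score, gene))
  expect_equal(unname(s2["C"]), 0)
  expect_equal(unname(s2["D"]), 0)
  expect_equal(unname(s2["B"]), 0.5 * (0.1 + 4))
  # isolated DE gene: empty neighborhood contributes nothing
  net3 <- igraph::add_vertices(net, 1, name = "LONE")
  fc3 <- c(fc, LONE = 3)
  s3 <- with(neighborhood_score(net3, fc3, deg_set(fc3, 4)),
             setNames(score, gene))
  expect_equal(unname(s3["LONE"]), 1.5)
})

test_that("interconnectivity normalizes shared neighborhoods by degrees", {
  # i -- d direct edge, degrees 2 and 8, no shared neighbors -> 1/4
  edges <- data.frame(
    from = c("i", "i", rep("d", 7)),
    to = c("d", "x1", sprintf("y%d", 1:7)))
  net <- as_gene_network(edges, quiet = TRUE)
  fc <- setNames(rep(0, length(network_genes(net))), network_genes(net))
  fc["d"] <- 3
  rl <- interconnectivity_rank(net, deg_set(fc, 4))
  s <- setNames(rl$score, rl$gene)
  expect_equal(unname(s["i"]), (1 + 0) / sqrt(2 * 8))
  # unconnected gene with no shared neighborhood scores 0
  net2 <- igraph::add_vertices(net, 1, name = "far")
  expect_equal(with(interconnectivity_rank(net2, deg_set(fc, 4)),
                    score[gene == "far"]), 0)
})

test_that("interconnectivity matches brute-force enumeration on small graphs", {
  set.seed(31)
  net <- igraph::sample_gnp(12, 0.35)
  igraph::V(net)$name <- sprintf("g%02d", 1:12)
  degs <- c("g02", "g05", "g09")
  rl <- interconnectivity_rank(net, degs)
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  dg <- rowSums(A)
  for (g in network_genes(net)) {
    manual <- 0
    for (d in setdiff(degs, g)) {
      if (dg[g] == 0 || dg[d] == 0) next
      shared <- sum(A[g, ] * A[d, ])
      manual <- manual + (A[g, d] + shared) / sqrt(dg[g] * dg[d])
    }
    expect_equal(rl$score[rl$gene == g], unname(manual), info = g)
  }
  expect_true(all(rl$score >= 0))
})

test_that("propagation approaches the prior as alpha vanishes", {
  net <- toy_star_network()
  fc <- c(H = 0, A = 5, B = 0, C = 0, D = 0)
  d <- deg_set(fc, 4)
  rl <- network_propagation(net, d, alpha = 1e-9)
  s <- setNames(rl$score, rl$gene)
  expect_equal(unname(s["A"]), 1, tolerance = 1e-6)
  expect_equal(unname(s["C"]), 0, tolerance = 1e-6)
})

test_that("two-node propagation matches the hand-solved fixed point", {
  net <- as_gene_network(data.frame(from = "a", to = "b"), quiet = TRUE)
  d <- structure("a", cutoff = 4)
  rl <- network_propagation(net, d, alpha = 0.1)
  # closed form: F = 0.9 * solve(I - 0.1 * A_norm) %*% c(1, 0), A_norm = [[0,1],[1,0]]
  Fstar <- 0.9 * solve(diag(2) - 0.1 * matrix(c(0, 1, 1, 0), 2)) %*% c(1, 0)
  s <- setNames(rl$score, rl$gene)
  expect_equal(unname(s[c("a", "b")]), as.vector(Fstar), tolerance = 1e-6)
})

test_that("flow never reaches a disconnected unseeded component", {
  edges <- data.frame(from = c("a", "b", "x"), to = c("b", "c", "y"))
  net <- as_gene_network(edges, quiet = TRUE)
  rl <- network_propagation(net, structure("a", cutoff = 4), alpha = 0.3)
  s <- setNames(rl$score, rl$gene)
  expect_equal(unname(s[c("x", "y")]), c(0, 0))
})

test_that("iterative propagation agrees with the direct linear solve", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:120, 1)
    net <- igraph::sample_gnp(n, 3 / n)
    igraph::V(net)$name <- sprintf("g%03d", seq_len(n))
    degs <- sample(network_genes(net), max(2, n %/% 10))
    rl <- network_propagation(net, degs, alpha = 0.1)
    A <- as.matrix(igraph::as_adjacency_matrix(net))
    dg <- rowSums(A)
    dinv <- ifelse(dg > 0, 1 / sqrt(dg), 0)
    An <- diag(dinv) %*% A %*% diag(dinv)
    F0 <- as.numeric(network_genes(net) %in% degs)
    direct <- solve(diag(n) - 0.1 * An, 0.9 * F0)
    s <- setNames(rl$score, rl$gene)
    expect_lt(max(abs(s[network_genes(net)] - direct)), 1e-5)
  }
})

test_that("propagation converges for a range of diffusion parameters", {
  net <- generate_network(150, 3, seed = 2)
  degs <- network_genes(net)[1:15]
  for (alpha in c(0.1, 0.5, 0.9)) {
    rl <- network_propagation(net, degs, alpha = alpha)
    expect_true(attr(rl, "converged"))
  }
})
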