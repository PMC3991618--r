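# Shared toy fixtures, built in code.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A -- B -- C path plus isolated D (D enters via an edge to itself being
# invalid, so we attach it through a pendant edge when needed).
toy_path_network <- function() {
  as_gene_network(data.frame(from = c("A", "B"), to = c("B", "C")),
                  quiet = TRUE)
}

# 5-gene network: star around H plus one extra edge.
toy_star_network <- function() {
  as_gene_network(data.frame(from = c("H", "H", "H", "H", "A"),
                             to   = c("A", "B", "C", "D", "B")),
                  quiet = TRUE)
}

# Deterministic small expression matrix on the linear scale.
toy_expression <- function(genes = c("A", "B", "C"),
                           samples = c("c1", "c2", "t1", "t2")) {
  set.seed(42)
  m <- matrix(2^rnorm(length(genes) * length(samples), mean = 6),
              nrow = length(genes),
              dimnames = list(genes, samples))
  m
}

# Correlation matrix with a prescribed constant off-diagonal value.
constant_corr <- function(n, rho, genes = sprintf("g%03d", seq_len(n))) {
  m <- matrix(rho, n, n, dimnames = list(genes, genes))
  diag(m) <- 1
  m
}

# Null Gaussian expression (no structure), genes x samples.
null_gaussian_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}
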