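#' Read a PPI network from an edge-list file
#'
#' Accepts a whitespace/tab separated two-column edge list, or a three-column
#' SIF file whose middle (interaction type) column is ignored. Lines starting
#' with `#` are comments. Self-interactions are removed and duplicate edges
#' collapsed; counts of dropped records are logged to standard error.
#'
#' @param path Path to the edge-list file.
#' @return An undirected, simple `igraph` gene network.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("cannot read network file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  tab <- read.table(text = lines, header = FALSE, sep = "",
                    colClasses = "character", stringsAsFactors = FALSE,
                    fill = TRUE)
  if (ncol(tab) < 2 || any(!nzchar(tab[[2]]) & ncol(tab) == 2))
    stop("network file must have at least 2 columns on every line")
  # SIF: source, interaction type, target
  cols <- if (ncol(tab) >= 3 && all(nzchar(tab[[3]]))) c(1L, 3L) else c(1L, 2L)
  if (any(!nzchar(tab[[cols[1]]])) || any(!nzchar(tab[[cols[2]]])))
    stop("network file must have at least 2 columns on every line")
  as_gene_network(tab[, cols])
}

#' Write a network as a two-column TSV edge list
#'
#' @param net An `igraph` gene network.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-level expression matrix
#'
#' The first column holds gene identifiers and the header row sample
#' identifiers. Duplicate gene rows are collapsed by averaging (mirroring
#' probe-to-gene summarization by averaging all probes mapped to one gene).
#' Rows containing missing values are rejected at read time with a logged
#' count; imputation is deliberately not performed.
#'
#' @param path Path to a tab-separated table.
#' @return Numeric matrix, genes in rows (unique rownames), samples in
#'   columns.
#' @export
read_expression <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a gene column and >=1 sample")
  ids <- as.character(tab[[1]])
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample identifiers in header")
  body <- tab[, -1, drop = FALSE]
  numeric_ok <- vapply(body, is.numeric, logical(1))
  if (!all(numeric_ok))
    stop("non-numeric expression values in column(s): ",
         paste(samples[!numeric_ok], collapse = ", "))
  mat <- as.matrix(body)
  bad <- !stats::complete.cases(mat)
  if (any(bad)) {
    log_msg("read_expression: rejected %d row(s) with missing values", sum(bad))
    mat <- mat[!bad, , drop = FALSE]
    ids <- ids[!bad]
  }
  if (anyDuplicated(ids)) {
    log_msg("read_expression: averaged %d duplicate gene row(s)",
            sum(duplicated(ids)))
    keep_order <- unique(ids)
    mat <- rowsum(mat, group = ids, reorder = FALSE) /
      as.vector(table(factor(ids, levels = unique(ids))))
    mat <- mat[keep_order, , drop = FALSE]
    ids <- keep_order
  }
  rownames(mat) <- ids
  colnames(mat) <- samples
  mat
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param id_column Header of the gene-identifier column.
#' @export
write_expression <- function(expr, path, id_column = "gene") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set from a GMT or one-gene-per-line file
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; a file whose
#' lines carry no tabs is treated as a plain list.
#'
#' @param path Path to the file.
#' @param name For multi-set GMT files, the set to extract (default: first
#'   line). For list files, the label given to the returned set (default:
#'   file name).
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty gene-set file: ", path)
  if (any(grepl("\t", lines, fixed = TRUE))) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(fields, length, integer(1)) < 3
    if (any(bad)) stop("malformed GMT line (need name, description, >=1 gene)")
    set_names <- vapply(fields, `[[`, character(1), 1)
    pick <- if (is.null(name)) 1L else match(name, set_names)
    if (is.na(pick)) stop("gene set '", name, "' not found in ", path)
    members <- fields[[pick]][-(1:2)]
    gene_set(set_names[pick], members)
  } else {
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    gene_set(name, trimws(lines))
  }
}

#' Write a gene set as a single GMT line
#'
#' @param set A [gene_set()].
#' @param path Output path.
#' @param description Second GMT field.
#' @export
write_gene_set <- function(set, path, description = "na") {
  line <- paste(c(set$name, description, set$members), collapse = "\t")
  writeLines(line, path)
  invisible(path)
}

#' Read contrast definitions from a YAML config
#'
#' The config maps contrast names to `{control: [...], treated: [...]}` sample
#' identifier lists.
#'
#' @param path Path to a YAML file.
#' @return Named list of contrasts, each a list with character vectors
#'   `control` and `treated`.
#' @export
read_contrasts <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0) stop("no contrasts defined in ", path)
  for (nm in names(cfg)) {
    ct <- cfg[[nm]]
    if (is.null(ct$control) || is.null(ct$treated) ||
        length(ct$control) == 0 || length(ct$treated) == 0)
      stop("contrast '", nm, "' must define non-empty control and treated lists")
    cfg[[nm]]$control <- as.character(ct$control)
    cfg[[nm]]$treated <- as.character(ct$treated)
  }
  cfg
}

#' Per-gene log2 fold change of treated versus control group means
#'
#' Group means are taken on the linear intensity scale and the ratio is then
#' log2-transformed, matching fold-change computation on MAS5-style normalized
#' intensities.
#'
#' @param expr Linear-scale expression matrix (genes x samples), strictly
#'   positive.
#' @param control,treated Sample identifiers (or column indices) of the two
#'   groups; both non-empty.
#' @return Named numeric vector of log2 fold changes, one per gene.
#' @export
log2_fold_change <- function(expr, control, treated) {
  stopifnot(length(control) >= 1, length(treated) >= 1)
  if (is.character(control) || is.character(treated)) {
    missing <- setdiff(c(control, treated), colnames(expr))
    if (length(missing))
      stop("samples not in expression matrix: ", paste(missing, collapse = ", "))
  }
  mc <- rowMeans(expr[, control, drop = FALSE])
  mt <- rowMeans(expr[, treated, drop = FALSE])
  bad <- which(mc <= 0 | mt <= 0)
  if (length(bad))
    stop("non-positive mean intensity for gene(s): ",
         paste(head(rownames(expr)[bad], 5), collapse = ", "))
  f <- log2(mt / mc)
  names(f) <- rownames(expr)
  f
}

#' Restrict an expression matrix to genes present in the network
#'
#' @param expr Expression matrix with gene rownames.
#' @param net An `igraph` gene network.
#' @return The row subset of `expr` (original order preserved). Errors if the
#'   intersection is empty.
#' @export
restrict_to_network <- function(expr, net) {
  keep <- rownames(expr) %in% network_genes(net)
  if (!any(keep)) stop("no expression genes are present in the network")
  expr[keep, , drop = FALSE]
}
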