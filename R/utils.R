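#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd rnorm runif plogis phyper t.test setNames
#' @importFrom utils read.table read.delim write.table head combn
NULL

# Round a fraction to a percentage with `digits` decimals, half-up.
# round() half-to-even would print 0.1915 -> 19.1; the conventional
# half-up rule gives 19.2, matching how enrichment ratios are reported.
percent_round <- function(x, digits = 1) {
  stopifnot(is.numeric(x))
  floor(x * 100 * 10^digits + 0.5) / 10^digits
}

# Membership extraction: gene_set objects or bare character vectors.
as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

log_msg <- function(...) message(sprintf(...))
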