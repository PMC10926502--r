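# Shared helpers for the test suite. All fixtures are generated in code.

# Small named alignment from a character vector of equal-length strings.
mk_aln <- function(...) {
  s <- c(...)
  if (is.null(names(s))) names(s) <- paste0("s", seq_along(s))
  as_alignment(s)
}

# Minimal metadata table for an alignment; groups given per sample id.
mk_table <- function(ids, groups, species = "sp", subspecies = "",
                     locality = "loc") {
  as_sample_table(data.frame(
    sample_id = ids, species = species, subspecies = subspecies,
    group = groups, locality = locality, source = "test",
    stringsAsFactors = FALSE))
}

# Random unambiguous sequence string.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# Random rooted bifurcating tree with positive branch lengths, returned as
# an ape phylo; used to produce additive distance matrices.
rand_additive_tree <- function(ntips) {
  tr <- ape::rtree(ntips, br = function(n) stats::runif(n, 0.1, 2))
  tr$tip.label <- paste0("t", seq_len(ntips))
  tr
}

# Path-length (patristic) distance matrix of a phylo: the independent
# additive-distance oracle.
patristic <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}
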