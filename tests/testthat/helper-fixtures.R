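# shared fixtures and independent oracles, all built in code

# deterministic family-like protein: acylation N-terminus, kinase anchor
# triad, n_ef EF-hand loops; filler avoids D/E so motifs sit only where
# planted
make_kinase_protein <- function(nterm = "MGNACSGA", n_ef = 4,
                                gap1 = 40, gap2 = 30) {
  filler <- function(n) substr(strrep("QASTV", ceiling(n / 5)), 1, n)
  ef <- paste(rep(paste0("DKDGDGYISAAEL", filler(20)), n_ef), collapse = "")
  paste0(nterm, filler(50), "LAIK", filler(gap1), "HRD", filler(gap2),
         "DFG", filler(40), ef, filler(30))
}

write_tmp_fasta <- function(seqs) {
  p <- tempfile(fileext = ".fa")
  write_fasta(seqs, p)
  p
}

write_tmp_gff <- function(lines) {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), p)
  p
}

gff_line <- function(chr, type, start, end, strand, attrs) {
  paste(chr, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# distance matrix that is exactly additive on a random binary tree
random_additive_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- stats::cophenetic(tr)
    d <- d[order(rownames(d)), order(colnames(d))]
    list(tree = ape::unroot(tr), d = d)
  })
}

# exhaustive-alignment oracle: maximum global alignment score over every
# monotone path, affine gaps (open+extend charged on the first gap residue)
enumerate_align_score <- function(a, b, sub, gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(ca)) {
      pen <- if (last == "I") gap_extend else gap_open + gap_extend
      best <- max(best, -pen + rec(i + 1, j, "I"))
    }
    if (j <= length(cb)) {
      pen <- if (last == "D") gap_extend else gap_open + gap_extend
      best <- max(best, -pen + rec(i, j + 1, "D"))
    }
    best
  }
  rec(1, 1, "start")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# canonical bipartition keys of an unrooted tree, independent of cdpkfam's
# internals: via ape::prop.part on the same tree
tree_split_keys <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    s <- labs[idx]
    if (ref %in% s) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }, character(1))
  setdiff(unique(keys[vapply(pp, length, 1L) < length(labs)]), "")
}

same_topology <- function(t1, t2) {
  setequal(tree_split_keys(ape::unroot(t1)), tree_split_keys(ape::unroot(t2)))
}
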