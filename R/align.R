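AA_ALPHABET_X <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                   "S","T","V","W","Y","X")

.check_residues <- function(x, what = "sequence") {
  bad <- grepl(paste0("[^", paste(AA_ALPHABET_X, collapse = ""), "]"), x)
  if (any(bad)) stop("non-residue characters in ", what, ": ",
                     paste(names(x)[bad], collapse = ", "))
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, scored with
#' BLOSUM62 by default (gap open 10, gap extension 0.5) -- the conventional
#' desk-scale stand-in for a multiple-alignment program's pairwise stage.
#' Traceback is deterministic.
#'
#' @param a,b Protein sequences (non-empty, 20-letter alphabet plus X).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param substitution Name of the substitution matrix (passed to
#'   [Biostrings::pairwiseAlignment()]).
#' @return List with `a` and `b` (aligned strings of equal length, gaps as
#'   `-`) and `score`.
#' @export
global_align <- function(a, b, gap_open = 10, gap_extend = 0.5,
                         substitution = "BLOSUM62") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  seqs <- toupper(c(a = a, b = b))
  .check_residues(seqs)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqs[["a"]]), Biostrings::AAString(seqs[["b"]]),
    type = "global", substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Coverage and identity of a global alignment
#'
#' Coverage is the number of columns where both sequences hold a residue,
#' divided by the length of the longer unaligned sequence; identity is the
#' fraction of those residue-residue columns that match (gap-excluded
#' denominator).
#'
#' @param alignment List as returned by [global_align()].
#' @param len_longer Length of the longer of the two unaligned sequences.
#' @return List with `coverage`, `identity`, and `degenerate` (`TRUE` when no
#'   residue-residue column exists; both fractions are then reported as 0).
#' @export
pairwise_stats <- function(alignment, len_longer) {
  ca <- strsplit(alignment$a, "")[[1]]
  cb <- strsplit(alignment$b, "")[[1]]
  stopifnot(length(ca) == length(cb), len_longer >= 1)
  both <- ca != "-" & cb != "-"
  n_both <- sum(both)
  if (n_both == 0L)
    return(list(coverage = 0, identity = 0, degenerate = TRUE))
  list(coverage = n_both / len_longer,
       identity = sum(ca[both] == cb[both]) / n_both,
       degenerate = FALSE)
}

# Batch pairwise coverage/identity over all unordered pairs.
# Returns list(coverage=, identity=) of symmetric matrices (diagonal 1).
# Vectorised over Biostrings to keep 40x40 family scans fast.
.pairwise_stat_matrices <- function(seqs, gap_open = 10, gap_extend = 0.5,
                                    substitution = "BLOSUM62") {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs)))
    stop("duplicate labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  .check_residues(seqs)
  set <- Biostrings::AAStringSet(toupper(seqs))
  w <- Biostrings::width(set)
  cov <- id <- matrix(1, n, n, dimnames = list(names(seqs), names(seqs)))
  for (j in 2:n) {
    i <- seq_len(j - 1L)
    aln <- Biostrings::pairwiseAlignment(
      set[i], set[[j]], type = "global", substitutionMatrix = substitution,
      gapOpening = gap_open, gapExtension = gap_extend)
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    aligned <- nm + nmm
    cov[i, j] <- cov[j, i] <- aligned / pmax(w[i], w[j])
    id[i, j] <- id[j, i] <- ifelse(aligned > 0, nm / aligned, 0)
  }
  list(coverage = cov, identity = id)
}

#' Pairwise p-distance matrix from global alignments
#'
#' For every unordered pair of records the p-distance is `1 - identity` from
#' the pairwise global alignment (gap-excluded identity).
#'
#' @param seqs Named character vector of at least 3 protein sequences with
#'   unique labels.
#' @inheritParams global_align
#' @return Symmetric numeric matrix with zero diagonal, labelled by sequence
#'   names.
#' @export
p_distance_matrix <- function(seqs, gap_open = 10, gap_extend = 0.5,
                              substitution = "BLOSUM62") {
  if (length(seqs) < 3) stop("need at least 3 records")
  stats <- .pairwise_stat_matrices(seqs, gap_open, gap_extend, substitution)
  d <- 1 - stats$identity
  diag(d) <- 0
  d
}

# p-distance between aligned rows restricted to a column subset; gap-gap and
# gap-residue columns are excluded from the denominator per pair.
.msa_p_distance <- function(code_matrix, cols) {
  n <- nrow(code_matrix)
  labs <- rownames(code_matrix)
  sub <- code_matrix[, cols, drop = FALSE]
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- sub[i, ] > 0L & sub[j, ] > 0L
      nok <- sum(ok)
      d[i, j] <- d[j, i] <- if (nok == 0L) 1 else sum(sub[i, ok] != sub[j, ok]) / nok
    }
  }
  d
}

# residues -> integer codes (gap/- = 0) for fast column resampling
.encode_msa <- function(msa) {
  L <- unique(nchar(msa))
  if (length(L) != 1) stop("ragged alignment rows: all rows must share one length")
  m <- matrix(match(unlist(strsplit(toupper(msa), "")), AA_ALPHABET_X,
                    nomatch = 0L),
              nrow = length(msa), byrow = TRUE,
              dimnames = list(names(msa), NULL))
  m
}
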