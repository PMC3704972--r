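# Residue classes of the 13-residue EF-hand calcium-binding loop
# (PROSITE PS00018-style): D-x-[DNS]-{ILVFYW}-[DENSTG]-[DNQGHRK]-{GP}-
# [LIVMC]-[DENQSTAGC]-x(2)-[DE]-[LIVMFYW]
EF_HAND_REGEX <- "D.[DNS][^ILVFYW][DENSTG][DNQGHRK][^GP][LIVMC][DENQSTAGC]..[DE][LIVMFYW]"
EF_HAND_LOOP_LENGTH <- 13L

#' Predict N-terminal myristoylation and palmitoylation
#'
#' Myristoylation is called by a PROSITE PS00008-style rule anchored at the
#' initiator Met (position 1): Gly at position 2; position 3 not one of
#' E, D, R, K, H, P, F, Y, W; position 6 one of S, T, A, G, C, N; position 7
#' not P. Palmitoylation is called only among myristoylated proteins, when at
#' least one Cys occurs at positions 3-5 (1-based).
#'
#' @param sequence Protein sequence (at least 7 residues).
#' @return A list with logical `myristoylation` and `palmitoylation`, and
#'   `cys_positions`, the 1-based positions in 3..5 holding a Cys.
#' @export
predict_acylation <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 7L)
    stop("sequence shorter than 7 residues; cannot evaluate the N-terminal motif")
  aa <- strsplit(substr(sequence, 1, 7), "")[[1]]
  myr <- aa[2] == "G" &&
    !aa[3] %in% c("E", "D", "R", "K", "H", "P", "F", "Y", "W") &&
    aa[6] %in% c("S", "T", "A", "G", "C", "N") &&
    aa[7] != "P"
  cys <- which(aa[3:5] == "C") + 2L
  list(myristoylation = myr,
       palmitoylation = myr && length(cys) > 0L,
       cys_positions = cys)
}

#' Scan a protein for EF-hand calcium-binding loops
#'
#' Finds greedy, leftmost, non-overlapping matches of the 13-residue EF-hand
#' loop pattern (see `EF_HAND_REGEX`).
#'
#' @param sequence Protein sequence.
#' @return Data frame with one row per hit: `start` (1-based), `end`, and
#'   `loop_sequence`. Zero rows when no loop is found.
#' @export
scan_ef_hands <- function(sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  m <- gregexpr(EF_HAND_REGEX, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      loop_sequence = character(0), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  data.frame(start = starts, end = starts + EF_HAND_LOOP_LENGTH - 1L,
             loop_sequence = substring(sequence, starts,
                                       starts + EF_HAND_LOOP_LENGTH - 1L),
             stringsAsFactors = FALSE)
}

#' Locate a Ser/Thr kinase catalytic domain by its anchor triad
#'
#' The domain is called present when the sequence contains, in order, a
#' VAIK-like ATP-anchor motif (`[LIVMF]x[LIVMF]K`), the catalytic HRD motif,
#' and the Mg-binding DFG motif, with 10-120 residues between consecutive
#' anchors. The reported span runs from the first anchor's start to the last
#' anchor's end (1-based inclusive).
#'
#' @param sequence Protein sequence.
#' @param min_gap,max_gap Allowed number of residues between consecutive
#'   anchors.
#' @return `c(start, end)` or `NULL` when no compatible triad exists.
#' @export
scan_kinase_domain <- function(sequence, min_gap = 10L, max_gap = 120L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  hit_starts <- function(pattern) {
    m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  vaik <- hit_starts("(?=[LIVMF].[LIVMF]K)")   # lookahead: overlapping starts
  hrd <- hit_starts("HRD")
  dfg <- hit_starts("DFG")
  for (a in vaik) {
    a_end <- a + 3L
    for (h in hrd[hrd - a_end - 1L >= min_gap & hrd - a_end - 1L <= max_gap]) {
      h_end <- h + 2L
      ok <- dfg[dfg - h_end - 1L >= min_gap & dfg - h_end - 1L <= max_gap]
      if (length(ok)) return(c(start = a, end = ok[1] + 2L))
    }
  }
  NULL
}

#' Decide family membership from a domain annotation
#'
#' A protein belongs to the CDPK family when it carries a kinase domain
#' followed by a calmodulin-like domain with 1-4 EF hands, the kinase lying
#' N-terminal to every EF-hand loop. Kinase-only proteins with no EF hand
#' (CRK-like architecture) are excluded.
#'
#' @param annotation A list as returned by [annotate_protein()]:
#'   `kinase_span` (`NULL` or `c(start, end)`), `ef_hands` (data frame),
#'   `acylation`.
#' @return Logical.
#' @export
classify_family_member <- function(annotation) {
  ks <- annotation$kinase_span
  ef <- annotation$ef_hands
  !is.null(ks) && nrow(ef) >= 1L && nrow(ef) <= 4L && ks[["end"]] < min(ef$start)
}

#' Annotate one protein with kinase, EF-hand and acylation evidence
#'
#' @param id Protein identifier.
#' @param sequence Protein sequence.
#' @return A list (`domain_annotation`) with `protein_id`, `kinase_span`,
#'   `ef_hands`, `acylation` and `is_family_member`.
#' @export
annotate_protein <- function(id, sequence) {
  ann <- list(protein_id = id,
              kinase_span = scan_kinase_domain(sequence),
              ef_hands = scan_ef_hands(sequence),
              acylation = if (nchar(sequence) >= 7L) predict_acylation(sequence)
                          else list(myristoylation = FALSE, palmitoylation = FALSE,
                                    cys_positions = integer(0)))
  ann$is_family_member <- classify_family_member(ann)
  class(ann) <- "domain_annotation"
  ann
}

#' Annotate a set of proteins and tabulate the evidence
#'
#' @param seqs Named character vector of protein sequences.
#' @return Data frame with one row per protein: `protein_id`, `kinase_start`,
#'   `kinase_end`, `n_ef_hands`, `ef_positions` (comma-separated 1-based
#'   starts), `myristoylation`, `palmitoylation`, `is_family_member`.
#'   Deterministic and independent of input order (rows follow input order,
#'   each row depends only on its own sequence).
#' @export
annotate_proteins <- function(seqs) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  rows <- lapply(names(seqs), function(id) {
    a <- annotate_protein(id, seqs[[id]])
    data.frame(protein_id = id,
               kinase_start = if (is.null(a$kinase_span)) NA_integer_ else a$kinase_span[["start"]],
               kinase_end = if (is.null(a$kinase_span)) NA_integer_ else a$kinase_span[["end"]],
               n_ef_hands = nrow(a$ef_hands),
               ef_positions = paste(a$ef_hands$start, collapse = ","),
               myristoylation = a$acylation$myristoylation,
               palmitoylation = a$acylation$palmitoylation,
               is_family_member = a$is_family_member,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
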