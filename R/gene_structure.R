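#' Derive exon-intron architecture and intron phases from a gene model
#'
#' Intron phase after coding segment k is the cumulative CDS length through
#' segment k modulo 3, computed in transcript orientation (minus-strand
#' segments are walked from the genomically last segment backwards). Phase 0
#' means the intron falls between codons; phases 1 and 2 fall one or two
#' bases into a codon.
#'
#' @param model A [gene_model()] with at least one CDS segment.
#' @return List of class `gene_structure`: `gene_id`, `transcript_id`,
#'   `n_exons`, `intron_phases` (integer vector, one per CDS junction),
#'   `cds_length_nt`, `in_frame` (`FALSE`, with a warning, when the CDS total
#'   is not divisible by 3 -- tolerated as annotation reality).
#' @export
derive_structure <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (nrow(model$cds) < 1) stop("model has no CDS segment: ", model$transcript_id)
  lens <- model$cds[, 2] - model$cds[, 1]
  if (model$strand == "-") lens <- rev(lens)   # transcript orientation
  cds_len <- sum(lens)
  in_frame <- cds_len %% 3 == 0
  if (!in_frame)
    warning("CDS length of ", model$transcript_id, " (", cds_len,
            " nt) is not divisible by 3")
  phases <- if (length(lens) > 1) as.integer(cumsum(lens[-length(lens)]) %% 3)
            else integer(0)
  structure(list(gene_id = model$gene_id, transcript_id = model$transcript_id,
                 n_exons = nrow(model$exons), intron_phases = phases,
                 cds_length_nt = as.integer(cds_len), in_frame = in_frame),
            class = "gene_structure")
}

#' Protein length implied by a CDS length
#'
#' @param cds_length_nt CDS length in nucleotides (divisible by 3).
#' @param includes_stop Whether the CDS length includes the stop codon.
#' @return Amino-acid length: `cds/3 - 1` when the stop codon is included,
#'   `cds/3` otherwise.
#' @export
translate_cds_length <- function(cds_length_nt, includes_stop = TRUE) {
  if (any(cds_length_nt %% 3 != 0))
    stop("CDS length not divisible by 3: ",
         paste(cds_length_nt[cds_length_nt %% 3 != 0], collapse = ", "))
  cds_length_nt / 3 - if (includes_stop) 1 else 0
}

#' Per-group exon-count dispersion
#'
#' Summarises exon counts within phylogenetic groups: members of one group
#' are expected to share similar exon-intron architecture, so a wide
#' within-group exon-count range is flagged.
#'
#' @param groups Data frame with `member_id` and `group` (as returned by
#'   [assign_groups()]).
#' @param structures List of `gene_structure` objects covering every grouped
#'   gene.
#' @param flag_range_above Flag groups whose exon-count range (max - min)
#'   exceeds this width.
#' @return Data frame with `group`, `n`, `min_exons`, `max_exons`,
#'   `median_exons`, `flagged`.
#' @export
structure_similarity <- function(groups, structures, flag_range_above = 8L) {
  ids <- vapply(structures, `[[`, "", "gene_id")
  missing <- setdiff(groups$member_id, ids)
  if (length(missing))
    stop("no structure for grouped gene(s): ", paste(missing, collapse = ", "))
  nex <- vapply(structures, function(s) s$n_exons, 1L)[match(groups$member_id, ids)]
  out <- lapply(split(nex, groups$group), function(x) {
    data.frame(n = length(x), min_exons = min(x), max_exons = max(x),
               median_exons = stats::median(x),
               flagged = (max(x) - min(x)) > flag_range_above)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = rownames(res), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

#' Tabulate gene structures
#'
#' @param structures List of `gene_structure` objects.
#' @return Data frame with one row per structure (`gene_id`, `n_exons`,
#'   `intron_phases` comma-separated, `cds_length_nt`, `in_frame`).
#' @export
structure_table <- function(structures) {
  do.call(rbind, lapply(structures, function(s) {
    data.frame(gene_id = s$gene_id, transcript_id = s$transcript_id,
               n_exons = s$n_exons,
               intron_phases = paste(s$intron_phases, collapse = ","),
               cds_length_nt = s$cds_length_nt, in_frame = s$in_frame,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
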