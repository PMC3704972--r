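#' Read a protein or CDS FASTA file
#'
#' Sequences are uppercased and terminal stop symbols (`*`) are stripped from
#' the sequence ends (internal stops are left untouched so that annotation
#' problems stay visible).
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are the FASTA ids
#'   (the header word before the first whitespace), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("^\\*+", "", sub("\\*+$", "", seqs))
  if (any(!nzchar(seqs))) stop("empty sequence for id: ", ids[!nzchar(seqs)][1])
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(names(seqs)) == length(seqs), !anyDuplicated(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a gene model
#'
#' Genomic intervals use a 0-based half-open convention `[start, end)` on the
#' forward strand; minus-strand exons are stored ascending by genomic position
#' and transcript order is derived on demand.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Two-column matrices (`start`, `end`) of 0-based half-open
#'   intervals; `cds` segments must each fall inside an exon.
#' @param n_isoforms Number of annotated splice variants of the gene.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chromosome, strand, exons,
                       cds, n_isoforms = 1L) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.numeric(cds), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-")) stop("unknown strand symbol: ", strand)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("degenerate exon interval in ", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in ", transcript_id)
  for (k in seq_len(nrow(cds))) {
    inside <- any(cds[k, 1] >= exons[, 1] & cds[k, 2] <= exons[, 2])
    if (!inside) stop("CDS segment outside exon span in ", transcript_id)
  }
  if (n_isoforms < 1L) stop("n_isoforms must be >= 1")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chromosome = chromosome, strand = strand, exons = exons,
                 cds = cds, n_isoforms = as.integer(n_isoforms)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s  %d exon(s), %d CDS segment(s), %d isoform(s)\n",
              x$transcript_id, x$gene_id, x$chromosome, x$strand,
              nrow(x$exons), nrow(x$cds), x$n_isoforms))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Expects the usual gene/mRNA/exon/CDS hierarchy linked by `Parent`
#' attributes. GFF's 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention. One model is returned per mRNA;
#' `n_isoforms` is the number of mRNA children of the parent gene.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of [gene_model()] objects keyed by transcript id.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  strand <- as.character(BiocGenerics::strand(gr))
  id <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  start0 <- BiocGenerics::start(gr) - 1L   # 1-based incl -> 0-based half-open
  end0 <- BiocGenerics::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))

  is_mrna <- type %in% c("mRNA", "transcript")
  if (!any(is_mrna)) stop("no mRNA/transcript features in ", path)
  if (any(!strand[is_mrna] %in% c("+", "-")))
    stop("unknown strand symbol for transcript(s): ",
         paste(id[is_mrna & !strand %in% c("+", "-")], collapse = ", "))
  n_iso <- table(parent[is_mrna])

  models <- list()
  for (m in which(is_mrna)) {
    tx <- id[m]
    ex <- parent == tx & type == "exon"
    cd <- parent == tx & type == "CDS"
    models[[tx]] <- gene_model(
      gene_id = parent[m], transcript_id = tx, chromosome = chrom[m],
      strand = strand[m],
      exons = cbind(start0[ex], end0[ex]),
      cds = cbind(start0[cd], end0[cd]),
      n_isoforms = as.integer(n_iso[[parent[m]]]))
  }
  models
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff3()]: internal 0-based half-open intervals are written
#' as 1-based inclusive GFF coordinates.
#'
#' @param models List of [gene_model()] objects (possibly several isoforms per
#'   gene).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  genes <- split(models, vapply(models, `[[`, "", "gene_id"))
  for (gid in names(genes)) {
    ms <- genes[[gid]]
    g_start <- min(vapply(ms, function(m) m$exons[1, 1], 0)) + 1
    g_end <- max(vapply(ms, function(m) max(m$exons[, 2]), 0))
    m1 <- ms[[1]]
    lines <- c(lines, sprintf("%s\tcdpkfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              m1$chromosome, g_start, g_end, m1$strand, gid))
    for (m in ms) {
      lines <- c(lines, sprintf("%s\tcdpkfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                m$chromosome, m$exons[1, 1] + 1, max(m$exons[, 2]),
                                m$strand, m$transcript_id, gid))
      for (k in seq_len(nrow(m$exons)))
        lines <- c(lines, sprintf("%s\tcdpkfam\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                                  m$chromosome, m$exons[k, 1] + 1, m$exons[k, 2],
                                  m$strand, m$transcript_id, k, m$transcript_id))
      for (k in seq_len(nrow(m$cds)))
        lines <- c(lines, sprintf("%s\tcdpkfam\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                                  m$chromosome, m$cds[k, 1] + 1, m$cds[k, 2],
                                  m$strand, m$transcript_id, k, m$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialise a phylogenetic tree to a Newick string
#'
#' Bootstrap supports stored as `node.label` are carried as internal node
#' labels. The writer round-trips: parsing its output recovers topology,
#' branch lengths (to at least 6 decimals) and support labels.
#'
#' @param tree An [ape::phylo] tree.
#' @return Newick string, terminated by `;`.
#' @export
write_newick <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (anyDuplicated(tree$edge[, 2]))
    stop("cyclic structure: a node has more than one parent")
  nnode <- length(tree$tip.label) + tree$Nnode
  if (nrow(tree$edge) != nnode - 1L)
    stop("cyclic or disconnected structure: edge count != node count - 1")
  ape::write.tree(tree)
}

#' Parse a Newick string or file
#'
#' @param text Newick string (used if `path` is `NULL`).
#' @param path Optional path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}

#' Read a labelled TSV table as a matrix
#'
#' The first column holds row labels and the header row holds column labels.
#' `"-"` cells are replaced by `dash_value` (the family table marks
#' single-isoform genes with `-`, i.e. one isoform; Ct/expression tables use
#' it for missing values).
#'
#' @param path Path to a TSV file.
#' @param numeric If `TRUE` (default) parse cells as decimals and error on
#'   non-numeric cells; if `FALSE` return a character matrix.
#' @param dash_value Value substituted for `"-"` cells before parsing.
#' @return A matrix with row and column names.
#' @export
read_table <- function(path, numeric = TRUE, dash_value = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(fields)) > 1) {
    bad <- which(fields != fields[1])[1]
    stop("ragged row at line ", bad, " of ", path)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  m <- as.matrix(df)
  m[m == "-"] <- as.character(dash_value)
  if (!numeric) return(m)
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  bad <- which(is.na(num) & !is.na(m) & m != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric cell '", m[bad[1, 1], bad[1, 2]], "' at row '",
         rownames(m)[bad[1, 1]], "', column '", colnames(m)[bad[1, 2]], "'")
  }
  num
}

#' The packaged maize CDPK characteristics table
#'
#' The 40-member family table shipped with the package: gene names, N-terminal
#' octapeptides, myristoylation calls, EF-hand counts, splice-variant counts
#' and CDS/protein lengths. In the source table single-isoform genes are
#' marked `-` in the splicing column; these are loaded as `n_isoforms = 1`.
#' The reported-MW column is carried verbatim and never used in computation.
#'
#' @return A data frame with one row per family member and columns `name`,
#'   `previous_name`, `accession`, `n_isoforms`, `cds_length_nt`, `aa_length`,
#'   `mw_reported`, `octapeptide`, `myristoylation` (logical), `n_ef_hands`.
#' @export
family_table <- function() {
  path <- system.file("extdata", "zmcpk_characteristics.tsv", package = "cdpkfam",
                      mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  out <- data.frame(
    name = df$name,
    previous_name = ifelse(df$previous_name == "-", NA_character_, df$previous_name),
    accession = df$accession,
    n_isoforms = as.integer(ifelse(df$alt_splicing == "-", "1", df$alt_splicing)),
    cds_length_nt = as.integer(df$cds_nt),
    aa_length = as.integer(df$aa_length),
    mw_reported = df$mw_reported,
    octapeptide = df$octapeptide,
    myristoylation = df$myristoylation == "Yes",
    n_ef_hands = as.integer(df$n_ef_hands),
    stringsAsFactors = FALSE)
  stopifnot(all(nchar(out$octapeptide) == 8L), all(out$n_ef_hands %in% 0:4),
            all(out$n_isoforms >= 1L))
  out
}
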