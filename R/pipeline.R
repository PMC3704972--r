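.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.update_manifest <- function(out_dir, stage, params, inputs = character(0),
                             outputs = character(0)) {
  path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::read_json(path) else list()
  manifest[[stage]] <- list(
    params = params,
    input_md5 = as.list(setNames(unname(tools::md5sum(inputs[file.exists(inputs)])),
                                 basename(inputs[file.exists(inputs)]))),
    outputs = as.list(basename(outputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Identification stage: scan a proteome for family members
#'
#' Runs the domain-architecture scan over every protein and writes the
#' annotation report plus a FASTA of the called family members. With
#' `nterm_table`, only the N-terminal acylation predictor is run over a
#' table of octapeptides (column `octapeptide`), as when auditing a
#' published family table.
#'
#' @param proteins Path to a protein FASTA (ignored when `nterm_table` is
#'   given).
#' @param out_dir Output directory (created if needed).
#' @param nterm_table Optional path to a TSV with an `octapeptide` column.
#' @return The annotation report data frame, invisibly; writes
#'   `identify_report.tsv` (and `family.faa` in full mode).
#' @export
run_identify <- function(proteins = NULL, out_dir, nterm_table = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(nterm_table)) {
    tab <- utils::read.delim(nterm_table, sep = "\t", stringsAsFactors = FALSE)
    if (!"octapeptide" %in% names(tab))
      stop("nterm table needs an 'octapeptide' column")
    calls <- lapply(tab$octapeptide, predict_acylation)
    rep <- data.frame(
      name = if ("name" %in% names(tab)) tab$name else tab$octapeptide,
      octapeptide = tab$octapeptide,
      myristoylation = vapply(calls, `[[`, TRUE, "myristoylation"),
      palmitoylation = vapply(calls, `[[`, TRUE, "palmitoylation"),
      stringsAsFactors = FALSE)
    out <- file.path(out_dir, "identify_report.tsv")
    .write_tsv(rep, out)
    .update_manifest(out_dir, "identify", list(mode = "nterm_only"),
                     nterm_table, out)
    message(sprintf("identify: %d sequences, %d myristoylated, %d palmitoylated",
                    nrow(rep), sum(rep$myristoylation), sum(rep$palmitoylation)))
    return(invisible(rep))
  }
  seqs <- read_fasta(proteins)
  if (length(seqs) == 0) stop("empty proteome: ", proteins)
  rep <- annotate_proteins(seqs)
  out <- file.path(out_dir, "identify_report.tsv")
  .write_tsv(rep, out)
  fam <- file.path(out_dir, "family.faa")
  write_fasta(seqs[rep$protein_id[rep$is_family_member]], fam)
  .update_manifest(out_dir, "identify", list(mode = "full"), proteins,
                   c(out, fam))
  message(sprintf("identify: %d proteins scanned, %d family members",
                  nrow(rep), sum(rep$is_family_member)))
  invisible(rep)
}

#' Phylogeny stage: distances, NJ tree, bootstrap, group assignment
#'
#' @param family_fasta Path to the family-member FASTA (e.g. from
#'   [run_identify()]).
#' @param out_dir Output directory.
#' @param references Optional named character vector (leaf id -> group) of
#'   reference group memberships; when given, a group-assignment TSV is
#'   written.
#' @param bootstrap Number of bootstrap replicates; supports are computed
#'   only when all sequences share one length (a provided alignment), since
#'   column resampling needs aligned rows.
#' @param seed Seed for bootstrap resampling.
#' @return List with `tree` and (optionally) `groups`, invisibly; writes
#'   `tree.nwk` and `groups.tsv`.
#' @export
run_phylogeny <- function(family_fasta, out_dir, references = NULL,
                          bootstrap = 100L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_fasta(family_fasta)
  if (length(seqs) < 3) stop("phylogeny stage needs at least 3 sequences; ",
                             "run the identify stage first")
  aligned <- length(unique(nchar(seqs))) == 1
  if (aligned && bootstrap >= 1) {
    tree <- bootstrap_supports(seqs, n_replicates = bootstrap, seed = seed)
  } else {
    if (!aligned && bootstrap >= 1)
      message("sequences are not aligned rows; skipping bootstrap supports")
    tree <- neighbor_joining(p_distance_matrix(seqs))
  }
  tree_path <- file.path(out_dir, "tree.nwk")
  writeLines(write_newick(tree), tree_path)
  outputs <- tree_path
  groups <- NULL
  if (!is.null(references)) {
    groups <- assign_groups(tree, references)
    gp <- file.path(out_dir, "groups.tsv")
    .write_tsv(groups, gp)
    outputs <- c(outputs, gp)
  }
  .update_manifest(out_dir, "phylogeny",
                   list(bootstrap = bootstrap, seed = seed),
                   family_fasta, outputs)
  message(sprintf("phylogeny: %d leaves%s", length(seqs),
                  if (is.null(groups)) "" else
                    sprintf(", %d queries assigned", nrow(groups))))
  invisible(list(tree = tree, groups = groups))
}

#' Duplication stage: call and classify duplicated gene pairs
#'
#' @param family_fasta Path to family protein FASTA.
#' @param gff Path to the genome annotation (GFF3).
#' @param out_dir Output directory.
#' @param criteria A [duplication_criteria()] object.
#' @return Events data frame, invisibly; writes `duplications.tsv` and
#'   `chromosome_summary.tsv`.
#' @export
run_duplication <- function(family_fasta, gff, out_dir,
                            criteria = duplication_criteria()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_fasta(family_fasta)
  if (length(seqs) == 0) stop("no family sequences; run the identify stage first")
  models <- read_gff3(gff)
  gene_ids <- vapply(models, `[[`, "", "gene_id")
  fam_models <- models[match(names(seqs), gene_ids)]
  if (anyNA(names(fam_models)))
    stop("gene model missing for: ",
         paste(names(seqs)[is.na(match(names(seqs), gene_ids))], collapse = ", "))
  ev <- find_duplications(seqs, fam_models, criteria, genome_models = models)
  out <- file.path(out_dir, "duplications.tsv")
  .write_tsv(ev, out)
  cs <- chromosome_summary(fam_models)
  cs_path <- file.path(out_dir, "chromosome_summary.tsv")
  .write_tsv(cs, cs_path)
  .update_manifest(out_dir, "duplication",
                   list(min_coverage = criteria$min_coverage,
                        min_identity = criteria$min_identity,
                        tandem_max_intervening = criteria$tandem_max_intervening),
                   c(family_fasta, gff), c(out, cs_path))
  message(sprintf("duplication: %d events (%d tandem, %d segmental)",
                  nrow(ev), sum(ev$kind == "tandem"),
                  sum(ev$kind == "segmental")))
  invisible(ev)
}

#' Structure stage: exon-intron architecture and per-group dispersion
#'
#' @param gff Path to the genome annotation (GFF3).
#' @param out_dir Output directory.
#' @param groups Optional data frame (`member_id`, `group`), e.g. from
#'   [run_phylogeny()]; when given, a per-group exon-count summary is
#'   written.
#' @return List with `structures` table and optional `group_summary`,
#'   invisibly; writes `structures.tsv` (one representative transcript per
#'   gene) and `group_structure.tsv`.
#' @export
run_structure <- function(gff, out_dir, groups = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- read_gff3(gff)
  models <- models[!duplicated(vapply(models, `[[`, "", "gene_id"))]
  structs <- lapply(models, derive_structure)
  tab <- structure_table(structs)
  out <- file.path(out_dir, "structures.tsv")
  .write_tsv(tab, out)
  outputs <- out
  summ <- NULL
  if (!is.null(groups)) {
    summ <- structure_similarity(groups, structs)
    sp <- file.path(out_dir, "group_structure.tsv")
    .write_tsv(summ, sp)
    outputs <- c(outputs, sp)
  }
  .update_manifest(out_dir, "structure", list(), gff, outputs)
  message(sprintf("structure: %d genes", nrow(tab)))
  invisible(list(structures = tab, group_summary = summ))
}

#' Expression stage: delta-delta Ct folds and hierarchical clustering
#'
#' @param ct_path Optional path to a long-format Ct TSV; quantified with
#'   [ddct_table()].
#' @param expression_path Optional path to a wide expression TSV (genes x
#'   conditions); clustered by complete linkage on Euclidean distances.
#' @param reference_gene,calibrator Required with `ct_path` (the calibrator
#'   must be named explicitly; no default is assumed).
#' @param k Number of clusters to cut.
#' @param out_dir Output directory.
#' @return List with `folds`, `dendrogram`, `clusters`, invisibly; writes
#'   `folds.tsv`, `dendrogram_merges.tsv`, `clusters.tsv`.
#' @export
run_expression <- function(ct_path = NULL, expression_path = NULL,
                           reference_gene = NULL, calibrator = NULL,
                           k = 4L, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(ct_path) && is.null(expression_path))
    stop("need a Ct table and/or an expression matrix")
  folds <- NULL
  outputs <- character(0)
  if (!is.null(ct_path)) {
    if (is.null(reference_gene) || is.null(calibrator))
      stop("reference_gene and calibrator must be given with a Ct table")
    ct <- read_ct_table(ct_path)
    folds <- ddct_table(ct, reference_gene, calibrator)
    fp <- file.path(out_dir, "folds.tsv")
    utils::write.table(cbind(gene = rownames(folds), as.data.frame(folds)),
                       fp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, fp)
  }
  mat <- if (!is.null(expression_path)) read_table(expression_path) else folds
  h <- hierarchical_cluster(mat, axis = "rows")
  k <- min(k, nrow(mat))
  cl <- cut_dendrogram(h, k)
  merges <- data.frame(step = seq_len(nrow(h$merge)), left = h$merge[, 1],
                       right = h$merge[, 2], height = h$height)
  mp <- file.path(out_dir, "dendrogram_merges.tsv")
  cp <- file.path(out_dir, "clusters.tsv")
  .write_tsv(merges, mp)
  .write_tsv(data.frame(gene = names(cl), cluster = unname(cl)), cp)
  outputs <- c(outputs, mp, cp)
  .update_manifest(out_dir, "expression",
                   list(reference_gene = reference_gene,
                        calibrator = calibrator, k = k),
                   c(ct_path, expression_path), outputs)
  message(sprintf("expression: %d genes clustered into %d groups",
                  nrow(mat), k))
  invisible(list(folds = folds, dendrogram = h, clusters = cl))
}

#' Run the whole pipeline on a generated genome
#'
#' Generates a synthetic genome and expression data under `config`, then runs
#' identification, phylogeny (with the generator's group truth on a held-out
#' reference subset), duplication detection, structure derivation and
#' expression analysis, writing every stage's outputs and manifests under
#' `out_dir`.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory root.
#' @param bootstrap Bootstrap replicates for the phylogeny stage.
#' @return List with every stage's return value plus the generator truth,
#'   invisibly.
#' @export
run_pipeline <- function(config = generator_config(), out_dir,
                         bootstrap = 100L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen_dir <- file.path(out_dir, "generated")
  gen <- generate_family_genome(config, gen_dir)
  identify <- run_identify(file.path(gen_dir, "proteins.faa"), out_dir)

  # references: two members per true group anchor the group assignment
  truth_groups <- unlist(gen$truth$groups)
  fam <- gen$truth$family_member_ids
  refs <- unlist(lapply(split(fam, truth_groups[fam]), utils::head, 2L))
  references <- setNames(truth_groups[refs], refs)
  phylo <- run_phylogeny(file.path(out_dir, "family.faa"), out_dir,
                         references = references, bootstrap = bootstrap,
                         seed = config$seed)

  dupl <- run_duplication(file.path(out_dir, "family.faa"),
                          file.path(gen_dir, "genes.gff3"), out_dir)

  all_groups <- rbind(phylo$groups,
                      data.frame(member_id = refs,
                                 group = unname(references),
                                 stringsAsFactors = FALSE))
  fam_only <- all_groups[all_groups$member_id %in% fam, , drop = FALSE]
  struct <- run_structure(file.path(gen_dir, "genes.gff3"), out_dir,
                          groups = fam_only)

  expr <- generate_expression(config, fam)
  ct_path <- file.path(gen_dir, "ct.tsv")
  .write_tsv(expr$ct, ct_path)
  ex <- run_expression(ct_path = ct_path,
                       reference_gene = config$expression$reference_gene,
                       calibrator = config$expression$calibrator,
                       k = config$expression$n_blocks, out_dir = out_dir)
  invisible(list(generated = gen, identify = identify, phylogeny = phylo,
                 duplication = dupl, structure = struct, expression = ex,
                 expression_truth = expr$truth))
}
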