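# Filler alphabet excludes Asp/Glu so that EF-hand loops (which require D at
# loop position 1 and D/E at position 12) and the HRD/DFG kinase anchors can
# only arise where the generator plants them; ground truth stays exact.
FILLER_AA <- c("A","C","F","G","H","I","K","L","M","N","P","Q","R","S","T",
               "V","W","Y")

# one codon per amino acid for reverse translation of planted proteins
CODON_OF <- c(A="GCT", C="TGT", D="GAT", E="GAA", F="TTT", G="GGT", H="CAT",
              I="ATT", K="AAA", L="CTT", M="ATG", N="AAT", P="CCT", Q="CAA",
              R="CGT", S="TCT", T="ACT", V="GTT", W="TGG", Y="TAT")

EF_LOOP_SEQ <- "DKDGDGYISAAEL"

# octapeptide classes planted at member N-termini, with their true calls
OCTAPEPTIDE_CLASSES <- data.frame(
  octapeptide = c("MGNACSGA", "MQPDPSGN", "MGGRASRH", "MGNTCVGP", "MGQCCSKG"),
  myristoylation = c(TRUE, FALSE, TRUE, FALSE, TRUE),
  palmitoylation = c(TRUE, FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the structure of the maize CDPK survey: a 40-member
#' family in four groups of 17/11/9/3 on 10 chromosomes, with 10 segmental
#' and 4 tandem duplicate pairs at target identity 0.90 and a background of
#' unrelated genes. Within-group divergence 0.20 gives within-group pairwise
#' identities near 0.70 (typical of kinase subfamilies and well separated
#' from the 0.80 duplication threshold); between-group divergence 0.45 gives
#' between-group identities near 0.40.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_chromosomes Number of chromosomes (>= 2).
#' @param n_background_genes Unrelated background genes carrying neither the
#'   kinase triad nor EF hands.
#' @param group_sizes Named integer vector of final member counts per group.
#' @param duplication_spec Data frame with columns `kind`
#'   (`tandem`/`segmental`), `identity` (target alignment identity in
#'   (0.5, 1]), and `group` (group whose members are duplicated).
#' @param within_group_divergence Per-site substitution probability from a
#'   group ancestor to each member (free, non-motif sites only).
#' @param between_group_divergence Per-site substitution probability from the
#'   family ancestor to each group ancestor.
#' @param expression List: `conditions`, `n_blocks`, `block_means` (optional
#'   blocks x conditions matrix), `noise_sd`, `ct_noise_sd`, `replicates`,
#'   `reference_gene`, `calibrator`.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_chromosomes = 10L,
                             n_background_genes = 60L,
                             group_sizes = c(I = 17L, II = 11L, III = 9L, IV = 3L),
                             duplication_spec = data.frame(
                               kind = c(rep("segmental", 10), rep("tandem", 4)),
                               identity = 0.90,
                               group = c(rep("I", 2), rep("II", 3), rep("III", 4),
                                         "IV", rep("I", 3), "II"),
                               stringsAsFactors = FALSE),
                             within_group_divergence = 0.20,
                             between_group_divergence = 0.45,
                             expression = list()) {
  stopifnot(n_chromosomes >= 2, all(group_sizes >= 1),
            all(duplication_spec$identity > 0.5),
            all(duplication_spec$identity <= 1),
            all(duplication_spec$kind %in% c("tandem", "segmental")),
            all(duplication_spec$group %in% names(group_sizes)))
  ndup <- table(factor(duplication_spec$group, levels = names(group_sizes)))
  if (any(group_sizes < 2 * as.integer(ndup)))
    stop("infeasible config: group(s) too small for the requested duplications: ",
         paste(names(group_sizes)[group_sizes < 2 * as.integer(ndup)],
               collapse = ", "))
  expr <- utils::modifyList(list(
    conditions = c("root", "stem", "leaf", "anther", "seed", "endosperm"),
    n_blocks = 4L, block_means = NULL, noise_sd = 0.25, ct_noise_sd = 0.05,
    replicates = 3L, reference_gene = "ZmActin", calibrator = "root"),
    expression)
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 n_background_genes = as.integer(n_background_genes),
                 group_sizes = group_sizes, duplication_spec = duplication_spec,
                 within_group_divergence = within_group_divergence,
                 between_group_divergence = between_group_divergence,
                 expression = expr),
            class = "generator_config")
}

.sample_filler <- function(n) paste(sample(FILLER_AA, n, replace = TRUE),
                                    collapse = "")

# member protein = octapeptide + variable region + kinase triad + junction +
# up to 4 EF-hand loops + tail; returns chars + protected-position mask
.family_architecture <- function() {
  blocks <- list(
    list(seq = strrep("A", 8), protected = TRUE, slot = "octapeptide"),
    list(n = 60, protected = FALSE),
    list(seq = "LAIK", protected = TRUE),
    list(n = 60, protected = FALSE),
    list(seq = "HRD", protected = TRUE),
    list(n = 40, protected = FALSE),
    list(seq = "DFG", protected = TRUE),
    list(n = 40, protected = FALSE),
    list(seq = EF_LOOP_SEQ, protected = TRUE, slot = "ef1"),
    list(n = 17, protected = FALSE),
    list(seq = EF_LOOP_SEQ, protected = TRUE, slot = "ef2"),
    list(n = 17, protected = FALSE),
    list(seq = EF_LOOP_SEQ, protected = TRUE, slot = "ef3"),
    list(n = 17, protected = FALSE),
    list(seq = EF_LOOP_SEQ, protected = TRUE, slot = "ef4"),
    list(n = 40, protected = FALSE))
  chars <- character(0); prot <- logical(0); slots <- list()
  for (b in blocks) {
    piece <- if (!is.null(b$seq)) strsplit(b$seq, "")[[1]]
             else strsplit(.sample_filler(b$n), "")[[1]]
    if (!is.null(b$slot))
      slots[[b$slot]] <- seq(length(chars) + 1L, length(chars) + length(piece))
    chars <- c(chars, piece)
    prot <- c(prot, rep(b$protected, length(piece)))
  }
  list(chars = chars, protected = prot, slots = slots)
}

.mutate_free <- function(chars, protected, rate) {
  free <- which(!protected)
  hit <- free[stats::runif(length(free)) < rate]
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(old)
      sample(setdiff(FILLER_AA, old), 1L), "")
  }
  chars
}

.reverse_translate <- function(protein) {
  paste0(paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = ""), "TGA")
}

# split a CDS of cds_len nt into n_exons segments (each >= min_len) and lay
# them on the chromosome starting at `offset`, introns 80-200 nt
.make_gene_model <- function(gene_id, chromosome, strand, cds_len, n_exons,
                             offset, n_isoforms = 1L) {
  min_len <- max(3L, min(30L, cds_len %/% n_exons))
  if (n_exons == 1L) {
    lens <- cds_len
  } else {
    extra <- cds_len - n_exons * min_len
    bars <- sort(sample.int(extra + n_exons - 1L, n_exons - 1L))
    lens <- min_len + diff(c(0L, bars, extra + n_exons)) - 1L
  }
  stopifnot(sum(lens) == cds_len, all(lens >= 1))
  introns <- if (n_exons > 1) sample(80:200, n_exons - 1L, replace = TRUE) else integer(0)
  starts <- offset + cumsum(c(0L, lens[-n_exons] + introns))
  ends <- starts + lens
  models <- list()
  for (iso in seq_len(n_isoforms)) {
    tx <- sprintf("%s_T%02d", gene_id, iso)
    models[[tx]] <- gene_model(gene_id, tx, chromosome, strand,
                               exons = cbind(starts, ends),
                               cds = cbind(starts, ends),
                               n_isoforms = n_isoforms)
  }
  models
}

#' Generate a synthetic genome bearing a planted kinase family
#'
#' Emits a proteome, CDS set and gene annotation with exact ground truth:
#' family members carry the kinase anchor triad, 1-4 EF-hand loops and
#' class-assigned N-terminal octapeptides; group structure is created by
#' mutating a family ancestor into group ancestors and members at configured
#' per-site rates (motif positions protected); duplicate pairs are created by
#' substituting a fixed fraction of free sites of a member, so realized
#' alignment identity equals the target up to rounding; tandem copies are
#' placed on the source chromosome with at most 2 intervening genes,
#' segmental copies on a different chromosome. Background genes contain
#' neither motif set. Fixed seed implies byte-identical output files.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory; when given, writes `proteins.faa`,
#'   `cds.fna`, `genes.gff3` and `ground_truth.json` there.
#' @return List with `proteins`, `cds` (named character vectors), `models`
#'   (list of [gene_model()], one per mRNA) and `truth` (ground-truth list).
#' @export
generate_family_genome <- function(config = generator_config(), out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  res <- withr::with_seed(config$seed, .generate_genome_impl(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$proteins, file.path(out_dir, "proteins.faa"))
    write_fasta(res$cds, file.path(out_dir, "cds.fna"))
    write_gff3(res$models, file.path(out_dir, "genes.gff3"))
    jsonlite::write_json(res$truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

.generate_genome_impl <- function(config) {
  groups <- names(config$group_sizes)
  dup <- config$duplication_spec
  n_dup_g <- table(factor(dup$group, levels = groups))
  arch <- .family_architecture()
  ancestor <- arch$chars

  # group ancestors diverge from the family ancestor at free sites
  group_anc <- lapply(groups, function(g)
    .mutate_free(ancestor, arch$protected, config$between_group_divergence))
  names(group_anc) <- groups

  # seed members per group (duplicates are added afterwards)
  member_seqs <- list(); member_group <- character(0)
  member_protected <- list(); member_ef <- integer(0)
  for (g in groups) {
    n_seed <- config$group_sizes[[g]] - as.integer(n_dup_g[[g]])
    for (k in seq_len(n_seed)) {
      id <- sprintf("FAM%02d", length(member_seqs) + 1L)
      chars <- .mutate_free(group_anc[[g]], arch$protected,
                            config$within_group_divergence)
      prot <- arch$protected
      # EF-hand count: mostly 4, a few trimmed members (loops beyond the
      # count are overwritten with filler and freed)
      idx <- length(member_seqs) + 1L
      ef <- if (idx %in% c(7L)) 1L else if (idx %in% c(29L, 30L, 31L)) 3L else 4L
      if (ef < 4L) {
        for (slot in paste0("ef", seq(ef + 1L, 4L))) {
          pos <- arch$slots[[slot]]
          chars[pos] <- strsplit(.sample_filler(length(pos)), "")[[1]]
          prot[pos] <- FALSE
        }
      }
      member_seqs[[id]] <- chars
      member_protected[[id]] <- prot
      member_group[id] <- g
      member_ef[id] <- ef
    }
  }
  seed_ids <- names(member_seqs)

  # duplicates: one distinct source seed per event, substitutions at free
  # sites only, count fixed so realized identity hits the target
  dup_events <- data.frame(source = character(0), copy = character(0),
                           gene_a = character(0), gene_b = character(0),
                           kind = character(0), target_identity = numeric(0),
                           stringsAsFactors = FALSE)
  used <- character(0)
  for (k in seq_len(nrow(dup))) {
    pool <- setdiff(seed_ids[member_group[seed_ids] == dup$group[k]], used)
    if (length(pool) == 0) stop("infeasible config: no free source in group ",
                                dup$group[k])
    src <- pool[1]
    used <- c(used, src)
    id <- sprintf("FAM%02d", length(member_seqs) + 1L)
    chars <- member_seqs[[src]]
    prot <- member_protected[[src]]
    L <- length(chars)
    n_sub <- round((1 - dup$identity[k]) * L)
    free <- which(!prot)
    hit <- sample(free, min(n_sub, length(free)))
    chars[hit] <- vapply(chars[hit], function(old)
      sample(setdiff(FILLER_AA, old), 1L), "")
    member_seqs[[id]] <- chars
    member_protected[[id]] <- prot
    member_group[id] <- dup$group[k]
    member_ef[id] <- member_ef[[src]]
    pair <- sort(c(src, id))
    dup_events <- rbind(dup_events, data.frame(
      source = src, copy = id, gene_a = pair[1], gene_b = pair[2],
      kind = dup$kind[k], target_identity = dup$identity[k],
      stringsAsFactors = FALSE))
  }
  family_ids <- names(member_seqs)
  proteins <- setNames(vapply(member_seqs, paste, "", collapse = ""), family_ids)

  # octapeptide classes: assigned per seed, inherited by copies (protected)
  cls <- OCTAPEPTIDE_CLASSES[(seq_along(seed_ids) - 1L) %%
                               nrow(OCTAPEPTIDE_CLASSES) + 1L, ]
  octa <- setNames(cls$octapeptide, seed_ids)
  for (k in seq_len(nrow(dup_events)))
    octa[dup_events$copy[k]] <- octa[dup_events$source[k]]
  for (id in family_ids)
    proteins[id] <- paste0(octa[id], substr(proteins[id], 9, nchar(proteins[id])))
  acyl_truth <- OCTAPEPTIDE_CLASSES[match(octa, OCTAPEPTIDE_CLASSES$octapeptide), ]

  # background genes: full-alphabet random proteins, no planted motifs
  bg_ids <- sprintf("BG%03d", seq_len(config$n_background_genes))
  bg_prot <- setNames(vapply(bg_ids, function(i) {
    n <- sample(150:400, 1L)
    paste(sample(names(CODON_OF), n, replace = TRUE), collapse = "")
  }, ""), bg_ids)

  all_prot <- c(proteins, bg_prot)
  all_cds <- vapply(all_prot, .reverse_translate, "")

  # chromosome layout
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  placement <- setNames(vector("list", length(chroms)), chroms)
  non_tandem <- setdiff(family_ids, dup_events$copy[dup_events$kind == "tandem"])
  for (i in seq_along(non_tandem)) {
    ch <- chroms[(i - 1L) %% length(chroms) + 1L]
    placement[[ch]] <- c(placement[[ch]], non_tandem[i])
  }
  # segmental copies are re-homed onto a different chromosome than the source
  for (k in which(dup_events$kind == "segmental")) {
    src <- dup_events$source[k]; cp <- dup_events$copy[k]
    src_ch <- chroms[vapply(chroms, function(ch) src %in% placement[[ch]], TRUE)]
    cp_ch <- chroms[vapply(chroms, function(ch) cp %in% placement[[ch]], TRUE)]
    if (identical(src_ch, cp_ch)) {
      placement[[cp_ch]] <- setdiff(placement[[cp_ch]], cp)
      dest <- chroms[(match(cp_ch, chroms)) %% length(chroms) + 1L]
      placement[[dest]] <- c(placement[[dest]], cp)
    }
  }
  bg_pool <- bg_ids
  # tandem copies sit just after their source with 0-2 intervening genes
  for (k in which(dup_events$kind == "tandem")) {
    src <- dup_events$source[k]; cp <- dup_events$copy[k]
    ch <- chroms[vapply(chroms, function(chx) src %in% placement[[chx]], TRUE)]
    v <- placement[[ch]]
    at <- match(src, v)
    n_between <- sample(0:2, 1L)
    between <- if (n_between > 0 && length(bg_pool) >= n_between) {
      b <- bg_pool[seq_len(n_between)]; bg_pool <- setdiff(bg_pool, b); b
    } else character(0)
    placement[[ch]] <- append(v, c(between, cp), after = at)
  }
  for (i in seq_along(bg_pool)) {
    ch <- chroms[(i - 1L) %% length(chroms) + 1L]
    placement[[ch]] <- c(placement[[ch]], bg_pool[i])
  }

  # exon counts: groups I-III draw 2-9 exons, group IV 11-12; background 1-6
  exon_counts <- integer(0)
  for (id in family_ids) {
    exon_counts[id] <- if (member_group[id] == "IV") sample(11:12, 1L)
                       else sample(2:9, 1L)
  }
  for (id in bg_ids) exon_counts[id] <- sample(1:6, 1L)
  n_isoforms <- setNames(rep(1L, length(all_prot)), names(all_prot))
  n_isoforms[family_ids[seq_along(family_ids) %% 5L == 0L]] <- 2L

  models <- list()
  for (ch in chroms) {
    cursor <- 10000L
    for (id in placement[[ch]]) {
      cds_len <- nchar(all_cds[[id]])
      strand <- sample(c("+", "-"), 1L)
      ms <- .make_gene_model(id, ch, strand, cds_len, exon_counts[[id]],
                             cursor, n_isoforms[[id]])
      models <- c(models, ms)
      cursor <- max(vapply(ms, function(m) max(m$exons[, 2]), 0)) +
        sample(3000:8000, 1L)
    }
  }

  truth <- list(
    family_member_ids = family_ids,
    background_ids = bg_ids,
    groups = as.list(member_group),
    octapeptides = as.list(octa[family_ids]),
    myristoylation = as.list(setNames(acyl_truth$myristoylation, family_ids)),
    palmitoylation = as.list(setNames(acyl_truth$palmitoylation, family_ids)),
    n_ef_hands = as.list(member_ef[family_ids]),
    exon_counts = as.list(exon_counts[family_ids]),
    n_isoforms = as.list(n_isoforms[family_ids]),
    duplications = dup_events[, c("gene_a", "gene_b", "kind",
                                  "target_identity")])
  list(proteins = all_prot, cds = all_cds, models = models, truth = truth)
}

#' Generate expression matrices and Ct tables with planted structure
#'
#' Builds a block-structured expression matrix (per-block condition means
#' plus Gaussian noise, clamped at 0) and a long-format qPCR Ct table
#' constructed so that [ddct_fold_change()] recovers the configured true fold
#' changes exactly in expectation (reference gene at constant Ct, target Ct
#' offset by `-log2(fold)` plus measurement noise).
#'
#' @param config A [generator_config()] (its `expression` element is used;
#'   randomness flows from `config$seed`).
#' @param gene_ids Genes to simulate (non-empty).
#' @return List with `expression` (genes x conditions matrix), `ct`
#'   (long-format data frame), and `truth` (`blocks`: named block labels;
#'   `true_folds`: genes x conditions fold matrix vs the calibrator).
#' @export
generate_expression <- function(config = generator_config(), gene_ids) {
  stopifnot(length(gene_ids) > 0)
  e <- config$expression
  withr::with_seed(config$seed + 1L, {
    conds <- e$conditions
    nb <- e$n_blocks
    bm <- e$block_means
    if (is.null(bm)) {
      # separated default profiles: each block is high in a rotating subset
      bm <- matrix(1, nb, length(conds),
                   dimnames = list(paste0("block", seq_len(nb)), conds))
      for (b in seq_len(nb))
        bm[b, ((seq_along(conds) - 1L) %% nb) == (b - 1L)] <- 6
    } else {
      bm <- as.matrix(bm)
      stopifnot(ncol(bm) == length(conds))
      nb <- nrow(bm)
      if (is.null(rownames(bm))) rownames(bm) <- paste0("block", seq_len(nb))
    }
    blocks <- setNames(rownames(bm)[(seq_along(gene_ids) - 1L) %% nb + 1L],
                       gene_ids)
    expr <- t(vapply(gene_ids, function(g)
      pmax(0, bm[blocks[[g]], ] + stats::rnorm(length(conds), 0, e$noise_sd)),
      numeric(length(conds))))
    dimnames(expr) <- list(gene_ids, conds)

    stopifnot(e$calibrator %in% conds)
    true_folds <- t(vapply(gene_ids, function(g) {
      (bm[blocks[[g]], ] + 1) / (bm[blocks[[g]], e$calibrator] + 1)
    }, numeric(length(conds))))
    dimnames(true_folds) <- list(gene_ids, conds)

    base_dct <- setNames(stats::runif(length(gene_ids), 2, 8), gene_ids)
    rows <- list()
    for (g in c(e$reference_gene, gene_ids)) {
      for (cc in conds) {
        for (r in seq_len(e$replicates)) {
          ct <- if (g == e$reference_gene) 20
                else 20 + base_dct[[g]] - log2(true_folds[g, cc])
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, condition = cc, replicate = r,
            ct = ct + stats::rnorm(1, 0, e$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    ct_tab <- do.call(rbind, rows)
    list(expression = expr, ct = ct_tab,
         truth = list(blocks = blocks, true_folds = true_folds))
  })
}
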