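#' Duplication-calling criteria
#'
#' The three criteria used to call duplicated gene pairs: the alignment must
#' cover more than `min_coverage` of the longer gene, the aligned region must
#' exceed `min_identity` (both strict `>`), and tightly linked passing genes
#' are collapsed to a single duplication event.
#'
#' @param min_coverage Minimum fraction of the longer sequence covered by
#'   aligned residue-residue columns (strict `>`).
#' @param min_identity Minimum gap-excluded identity over the aligned region
#'   (strict `>`).
#' @param tandem_max_intervening Maximum number of annotated genes between
#'   two genes on the same chromosome for them to count as tandem / tightly
#'   linked.
#' @param collapse_linked Collapse clusters of tightly linked passing genes
#'   to one event between the two closest members.
#' @return List of class `duplication_criteria`.
#' @export
duplication_criteria <- function(min_coverage = 0.80, min_identity = 0.80,
                                 tandem_max_intervening = 5L,
                                 collapse_linked = TRUE) {
  stopifnot(min_coverage > 0, min_coverage < 1, min_identity > 0,
            min_identity < 1, tandem_max_intervening >= 0)
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 tandem_max_intervening = as.integer(tandem_max_intervening),
                 collapse_linked = isTRUE(collapse_linked)),
            class = "duplication_criteria")
}

.gene_midpoints <- function(models) {
  one_per_gene <- models[!duplicated(vapply(models, `[[`, "", "gene_id"))]
  data.frame(
    gene_id = vapply(one_per_gene, `[[`, "", "gene_id"),
    chromosome = vapply(one_per_gene, `[[`, "", "chromosome"),
    mid = vapply(one_per_gene,
                 function(m) (min(m$exons[, 1]) + max(m$exons[, 2])) / 2, 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

.n_intervening <- function(gene_a, gene_b, positions) {
  pa <- positions[positions$gene_id == gene_a, ]
  pb <- positions[positions$gene_id == gene_b, ]
  if (pa$chromosome != pb$chromosome) return(NA_integer_)
  lo <- min(pa$mid, pb$mid); hi <- max(pa$mid, pb$mid)
  sum(positions$chromosome == pa$chromosome & positions$mid > lo &
        positions$mid < hi & !positions$gene_id %in% c(gene_a, gene_b))
}

#' Classify a duplication event as tandem or segmental
#'
#' Tandem when both genes lie on the same chromosome with at most
#' `tandem_max_intervening` annotated genes between them; segmental
#' otherwise (including all inter-chromosomal pairs).
#'
#' @param model_a,model_b [gene_model()] objects for the two genes.
#' @param genome_models All annotated gene models (used to count intervening
#'   genes); must include the two genes themselves.
#' @param tandem_max_intervening See [duplication_criteria()].
#' @return `"tandem"` or `"segmental"`.
#' @export
classify_event <- function(model_a, model_b, genome_models,
                           tandem_max_intervening = 5L) {
  if (model_a$chromosome != model_b$chromosome) return("segmental")
  pos <- .gene_midpoints(genome_models)
  n <- .n_intervening(model_a$gene_id, model_b$gene_id, pos)
  if (!is.na(n) && n <= tandem_max_intervening) "tandem" else "segmental"
}

#' Detect duplicated gene pairs
#'
#' All unordered pairs of protein sequences are globally aligned; pairs whose
#' alignment coverage of the longer sequence and gap-excluded identity both
#' exceed the criteria thresholds are retained and classified tandem or
#' segmental. Clusters of tightly linked passing genes are collapsed to a
#' single event between the two closest members, so a tandem array of k
#' genes yields one event, not choose(k, 2).
#'
#' @param seqs Named character vector of protein sequences; names are gene
#'   ids.
#' @param models Named list of [gene_model()] objects covering every sequence
#'   (names/gene ids must match `names(seqs)`).
#' @param criteria A [duplication_criteria()] object.
#' @param genome_models All annotated gene models used for intervening-gene
#'   counts; defaults to `models`.
#' @return Data frame of events: `gene_a`, `gene_b` (canonical
#'   `gene_a < gene_b`), `chromosome_a`, `chromosome_b`, `coverage`,
#'   `identity`, `kind`.
#' @export
find_duplications <- function(seqs, models, criteria = duplication_criteria(),
                              genome_models = models) {
  stopifnot(inherits(criteria, "duplication_criteria"))
  model_genes <- vapply(models, `[[`, "", "gene_id")
  missing <- setdiff(names(seqs), model_genes)
  if (length(missing))
    stop("record(s) without gene model: ", paste(missing, collapse = ", "))
  by_gene <- models[match(names(seqs), model_genes)]
  names(by_gene) <- names(seqs)

  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      chromosome_a = character(0), chromosome_b = character(0),
                      coverage = numeric(0), identity = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE)
  if (length(seqs) < 2) return(empty)

  st <- .pairwise_stat_matrices(seqs)
  pos <- .gene_midpoints(genome_models)
  events <- list()
  ids <- names(seqs)
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      if (st$coverage[i, j] > criteria$min_coverage &&
          st$identity[i, j] > criteria$min_identity) {
        pair <- sort(c(ids[i], ids[j]))
        kind <- classify_event(by_gene[[pair[1]]], by_gene[[pair[2]]],
                               genome_models, criteria$tandem_max_intervening)
        events[[length(events) + 1L]] <- data.frame(
          gene_a = pair[1], gene_b = pair[2],
          chromosome_a = by_gene[[pair[1]]]$chromosome,
          chromosome_b = by_gene[[pair[2]]]$chromosome,
          coverage = st$coverage[i, j], identity = st$identity[i, j],
          kind = kind, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(events) == 0) return(empty)
  ev <- do.call(rbind, events)

  if (criteria$collapse_linked) {
    # union-find over tandem (tightly linked) pairs; one event per cluster,
    # kept between the two genomically closest members
    tandem <- ev[ev$kind == "tandem", , drop = FALSE]
    if (nrow(tandem) > 1) {
      parent <- setNames(unique(c(tandem$gene_a, tandem$gene_b)),
                         unique(c(tandem$gene_a, tandem$gene_b)))
      find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
      for (k in seq_len(nrow(tandem)))
        parent[[find(tandem$gene_a[k])]] <- find(tandem$gene_b[k])
      cluster <- vapply(tandem$gene_a, find, "")
      sep <- vapply(seq_len(nrow(tandem)), function(k) {
        abs(pos$mid[pos$gene_id == tandem$gene_a[k]] -
              pos$mid[pos$gene_id == tandem$gene_b[k]])
      }, 0)
      keep_rows <- unlist(lapply(split(seq_len(nrow(tandem)), cluster),
                                 function(rows) {
        rows[order(sep[rows], tandem$gene_a[rows], tandem$gene_b[rows])[1]]
      }))
      tandem <- tandem[sort(keep_rows), , drop = FALSE]
    }
    ev <- rbind(ev[ev$kind == "segmental", , drop = FALSE], tandem)
  }
  ev <- ev[order(ev$gene_a, ev$gene_b), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Per-chromosome family gene counts
#'
#' Counts family genes per chromosome and flags chromosomes carrying a local
#' cluster: `cluster_min` or more genes within a `cluster_window` span.
#'
#' @param models Named list of [gene_model()] objects (one entry per gene is
#'   sufficient; extra isoforms are collapsed by gene id).
#' @param cluster_window Window width in bp (default 5 Mb).
#' @param cluster_min Minimum genes within the window to flag a cluster.
#' @return Data frame with `chromosome`, `n_genes`, `clustered`; zero rows
#'   for empty input.
#' @export
chromosome_summary <- function(models, cluster_window = 5e6, cluster_min = 3L) {
  if (length(models) == 0)
    return(data.frame(chromosome = character(0), n_genes = integer(0),
                      clustered = logical(0), stringsAsFactors = FALSE))
  pos <- .gene_midpoints(models)
  out <- lapply(split(pos, pos$chromosome), function(p) {
    mids <- sort(p$mid)
    clustered <- FALSE
    if (length(mids) >= cluster_min) {
      span <- mids[seq(cluster_min, length(mids))] -
        mids[seq_len(length(mids) - cluster_min + 1L)]
      clustered <- any(span <= cluster_window)
    }
    data.frame(chromosome = p$chromosome[1], n_genes = nrow(p),
               clustered = clustered, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chromosome), , drop = FALSE]
}
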