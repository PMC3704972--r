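# two single-exon genes per chromosome position make positional fixtures terse
placed_gene <- function(id, chr, at, len = 900) {
  gene_model(id, paste0(id, ".t1"), chr, "+",
             exons = cbind(at, at + len), cds = cbind(at, at + len))
}

test_that("identical proteins on different chromosomes give one segmental event", {
  p <- make_kinase_protein()
  seqs <- c(gB = p, gA = p)
  models <- list(gA = placed_gene("gA", "chr1", 1000),
                 gB = placed_gene("gB", "chr2", 1000))
  ev <- find_duplications(seqs, models)
  expect_equal(nrow(ev), 1)
  expect_identical(ev$gene_a, "gA")   # canonical order despite input order
  expect_identical(ev$kind, "segmental")
  expect_equal(ev$coverage, 1)
  expect_equal(ev$identity, 1)
})

test_that("pairs below the identity threshold are not called", {
  base <- make_kinase_protein()
  chars <- strsplit(base, "")[[1]]
  idx <- seq(10, length(chars), by = 4)   # ~25% substitutions -> identity ~0.75
  chars[idx] <- ifelse(chars[idx] == "W", "M", "W")
  seqs <- c(gA = base, gB = paste(chars, collapse = ""))
  models <- list(gA = placed_gene("gA", "chr1", 1000),
                 gB = placed_gene("gB", "chr2", 1000))
  st <- pairwise_stats(global_align(seqs[["gA"]], seqs[["gB"]]), nchar(base))
  expect_lt(st$identity, 0.8)
  expect_equal(nrow(find_duplications(seqs, models)), 0)
})

test_that("event classification uses chromosome and intervening gene count", {
  genome <- c(list(a = placed_gene("a", "chr1", 1000),
                   b = placed_gene("b", "chr1", 3000)),
              setNames(lapply(1:40, function(i)
                placed_gene(paste0("bg", i), "chr1", 5000 + 2000 * i)), paste0("bg", 1:40)),
              list(far = placed_gene("far", "chr1", 100000 + 2000 * 41),
                   other = placed_gene("other", "chr2", 1000)))
  expect_identical(classify_event(genome$a, genome$b, genome), "tandem")
  expect_identical(classify_event(genome$a, genome$far, genome), "segmental")
  expect_identical(classify_event(genome$a, genome$other, genome), "segmental")
})

test_that("a tandem array collapses to a single event between closest members", {
  p <- make_kinase_protein()
  seqs <- c(g1 = p, g2 = p, g3 = p)
  models <- list(g1 = placed_gene("g1", "chr1", 1000),
                 g2 = placed_gene("g2", "chr1", 3000),
                 g3 = placed_gene("g3", "chr1", 8000))
  ev <- find_duplications(seqs, models)
  expect_equal(nrow(ev), 1)
  expect_identical(c(ev$gene_a, ev$gene_b), c("g1", "g2"))
  # without collapsing, all three pairs pass
  ev_all <- find_duplications(seqs, models,
                              duplication_criteria(collapse_linked = FALSE))
  expect_equal(nrow(ev_all), 3)
})

test_that("planted duplications are recovered exactly on a synthetic genome", {
  gen <- generate_family_genome(generator_config(seed = 42))
  fam <- gen$proteins[gen$truth$family_member_ids]
  gene_ids <- vapply(gen$models, `[[`, "", "gene_id")
  fam_models <- gen$models[match(names(fam), gene_ids)]
  ev <- find_duplications(fam, fam_models, genome_models = gen$models)
  expect_equal(sum(ev$kind == "segmental"), 10)
  expect_equal(sum(ev$kind == "tandem"), 4)
  truth <- gen$truth$duplications
  expect_setequal(paste(ev$gene_a, ev$gene_b), paste(truth$gene_a, truth$gene_b))
  expect_identical(
    setNames(ev$kind, paste(ev$gene_a, ev$gene_b)) [paste(truth$gene_a, truth$gene_b)],
    setNames(truth$kind, paste(truth$gene_a, truth$gene_b)))

  # self-consistency: stored stats re-verify against a fresh alignment
  for (k in seq_len(nrow(ev))) {
    aln <- global_align(fam[[ev$gene_a[k]]], fam[[ev$gene_b[k]]])
    st <- pairwise_stats(aln, max(nchar(fam[[ev$gene_a[k]]]),
                                  nchar(fam[[ev$gene_b[k]]])))
    expect_equal(st$coverage, ev$coverage[k], tolerance = 1e-12)
    expect_equal(st$identity, ev$identity[k], tolerance = 1e-12)
  }

  # pairs planted at identity 0.70 must be rejected
  cfg_low <- generator_config(seed = 42, duplication_spec = data.frame(
    kind = c("segmental", "tandem"), identity = 0.70, group = c("I", "II"),
    stringsAsFactors = FALSE))
  gen_low <- generate_family_genome(cfg_low)
  fam_low <- gen_low$proteins[gen_low$truth$family_member_ids]
  ids_low <- vapply(gen_low$models, `[[`, "", "gene_id")
  ev_low <- find_duplications(fam_low, gen_low$models[match(names(fam_low), ids_low)],
                              genome_models = gen_low$models)
  planted_low <- paste(gen_low$truth$duplications$gene_a,
                       gen_low$truth$duplications$gene_b)
  expect_false(any(paste(ev_low$gene_a, ev_low$gene_b) %in% planted_low))
})

test_that("raising the identity threshold never adds events", {
  gen <- generate_family_genome(generator_config(seed = 8))
  fam <- gen$proteins[gen$truth$family_member_ids]
  gene_ids <- vapply(gen$models, `[[`, "", "gene_id")
  fam_models <- gen$models[match(names(fam), gene_ids)]
  n_events <- vapply(c(0.6, 0.8, 0.9, 0.95), function(t)
    nrow(find_duplications(fam, fam_models,
                           duplication_criteria(min_identity = t),
                           genome_models = gen$models)), 1)
  expect_true(all(diff(n_events) <= 0))
})

test_that("records without a gene model are reported by name", {
  seqs <- c(gA = make_kinase_protein(), gB = make_kinase_protein())
  models <- list(gA = placed_gene("gA", "chr1", 1000))
  expect_error(find_duplications(seqs, models), "gB")
})

test_that("chromosome summary counts genes and flags local clusters", {
  models <- list(a = placed_gene("a", "chr1", 1e6),
                 b = placed_gene("b", "chr1", 2e6),
                 c = placed_gene("c", "chr1", 3e6),
                 d = placed_gene("d", "chr2", 1e6))
  cs <- chromosome_summary(models)
  expect_equal(cs$n_genes[cs$chromosome == "chr1"], 3)
  expect_equal(cs$n_genes[cs$chromosome == "chr2"], 1)
  expect_true(cs$clustered[cs$chromosome == "chr1"])
  expect_false(cs$clustered[cs$chromosome == "chr2"])

  spread <- list(a = placed_gene("a", "chr1", 1e6),
                 b = placed_gene("b", "chr1", 20e6),
                 c = placed_gene("c", "chr1", 40e6))
  expect_false(chromosome_summary(spread)$clustered)

  empty <- chromosome_summary(list())
  expect_equal(nrow(empty), 0)
})
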