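test_that("FASTA reading uppercases, strips terminal stops, keeps order", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">g1", "MGNA", "csga", ">g2 description here", "MKLV*"), p)
  seqs <- read_fasta(p)
  expect_identical(seqs, c(g1 = "MGNACSGA", g2 = "MKLV"))
})

test_that("duplicate FASTA ids raise an error naming the id", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">g1", "MGNA", ">g1", "CSGA"), p)
  expect_error(read_fasta(p), "g1")
})

test_that("empty FASTA gives an empty result with a warning", {
  p <- tempfile(fileext = ".fa")
  writeLines(character(0), p)
  expect_warning(seqs <- read_fasta(p), "empty")
  expect_length(seqs, 0)
})

test_that("FASTA writer round-trips through its own reader", {
  seqs <- c(a = "MGNACSGAQRST", b = strrep("ACDEFGHIKLMNPQRSTVWY", 8))
  p <- write_tmp_fasta(seqs)
  expect_identical(read_fasta(p), seqs)
})

test_that("GFF3 1-based inclusive coordinates become 0-based half-open", {
  p <- write_tmp_gff(c(
    gff_line("chr1", "gene", 1, 300, "+", "ID=g1"),
    gff_line("chr1", "mRNA", 1, 300, "+", "ID=g1.t1;Parent=g1"),
    gff_line("chr1", "exon", 1, 300, "+", "ID=e1;Parent=g1.t1"),
    gff_line("chr1", "CDS", 1, 300, "+", "ID=c1;Parent=g1.t1")))
  models <- read_gff3(p)
  expect_length(models, 1)
  m <- models[["g1.t1"]]
  expect_equal(unname(m$exons[1, ]), c(0, 300))
  expect_equal(unname(m$cds[1, ]), c(0, 300))
  expect_identical(m$n_isoforms, 1L)
})

test_that("isoform counting and invariant violations in GFF3", {
  three_iso <- unlist(lapply(1:3, function(i) c(
    gff_line("chr2", "mRNA", 100, 400, "-", sprintf("ID=g2.t%d;Parent=g2", i)),
    gff_line("chr2", "exon", 100, 400, "-", sprintf("ID=e%d;Parent=g2.t%d", i, i)),
    gff_line("chr2", "CDS", 100, 400, "-", sprintf("ID=c%d;Parent=g2.t%d", i, i)))))
  p <- write_tmp_gff(c(gff_line("chr2", "gene", 100, 400, "-", "ID=g2"), three_iso))
  models <- read_gff3(p)
  expect_length(models, 3)
  expect_true(all(vapply(models, `[[`, 1L, "n_isoforms") == 3L))

  # CDS extends past its exon
  p2 <- write_tmp_gff(c(
    gff_line("chr1", "gene", 1, 300, "+", "ID=g1"),
    gff_line("chr1", "mRNA", 1, 300, "+", "ID=g1.t1;Parent=g1"),
    gff_line("chr1", "exon", 1, 300, "+", "ID=e1;Parent=g1.t1"),
    gff_line("chr1", "CDS", 10, 500, "+", "ID=c1;Parent=g1.t1")))
  expect_error(read_gff3(p2), "outside exon")

  # strandless transcript
  p3 <- write_tmp_gff(c(
    gff_line("chr1", "gene", 1, 300, ".", "ID=g1"),
    gff_line("chr1", "mRNA", 1, 300, ".", "ID=g1.t1;Parent=g1"),
    gff_line("chr1", "exon", 1, 300, ".", "ID=e1;Parent=g1.t1")))
  expect_error(read_gff3(p3), "strand")
})

test_that("GFF3 writer output is parsed back to equal coordinates", {
  m <- gene_model("gA", "gA.t1", "chr3", "-",
                  exons = rbind(c(0, 120), c(220, 400)),
                  cds = rbind(c(10, 120), c(220, 390)))
  p <- tempfile(fileext = ".gff3")
  write_gff3(list(m), p)
  back <- read_gff3(p)[["gA.t1"]]
  expect_equal(back$exons, m$exons, ignore_attr = TRUE)
  expect_equal(back$cds, m$cds, ignore_attr = TRUE)
  expect_identical(back$strand, "-")
})

test_that("Newick writing round-trips topology, lengths and supports", {
  d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_identical(write_newick(neighbor_joining(d)), "(A:1,B:3,C:5);")

  withr::with_seed(42, {
    for (rep in 1:5) {
      tr <- ape::rtree(7)
      tr$node.label <- as.character(sample(0:100, tr$Nnode))
      s1 <- write_newick(tr)
      back <- read_newick(s1)
      expect_true(same_topology(tr, back))
      expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-6)
      expect_setequal(back$node.label, tr$node.label)
      expect_identical(write_newick(read_newick(s1)), s1)
    }
  })
})

test_that("a cyclic edge structure is rejected by the Newick writer", {
  tr <- ape::rtree(4)
  tr$edge[2, 2] <- tr$edge[1, 2]   # two parents for one node
  expect_error(write_newick(tr), "cyclic")
})

test_that("TSV tables parse shapes, dashes and bad cells as specified", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("id\tx\ty", "r1\t1\t2.5", "r2\t-3\t4"), p)
  m <- read_table(p)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["r2", "x"], -3)

  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tx\ty", "r1\t1\t2", "r2\t9"), p2)
  expect_error(read_table(p2), "line 3")

  p3 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tx", "r1\tabc"), p3)
  expect_error(read_table(p3), "abc")

  p4 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tx", "r1\t-"), p4)
  expect_equal(unname(read_table(p4, dash_value = 1)["r1", "x"]), 1)
})

test_that("the packaged family characteristics table has 40 consistent rows", {
  ft <- family_table()
  expect_equal(nrow(ft), 40)
  expect_true(all(nchar(ft$octapeptide) == 8))
  expect_true(all(ft$n_ef_hands %in% 0:4))
  expect_true(all(ft$n_isoforms >= 1))
  raw <- read_table(system.file("extdata", "zmcpk_characteristics.tsv",
                                package = "cdpkfam"), numeric = FALSE)
  expect_equal(nrow(raw), 40)
})
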