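test_that("global alignment matches an exhaustive-path oracle on short peptides", {
  withr::with_seed(7, {
    aa <- c("A", "C", "D", "E", "F", "G", "K", "L")
    for (rep in 1:15) {
      a <- paste(sample(aa, 5, replace = TRUE), collapse = "")
      b <- paste(sample(aa, sample(3:6, 1), replace = TRUE), collapse = "")
      aln <- global_align(a, b)
      expect_equal(aln$score, enumerate_align_score(a, b, blosum62),
                   tolerance = 1e-9, label = paste(a, b))
    }
  })
})

test_that("alignment handles identity, near-identity and bad input", {
  aln <- global_align("ACDEF", "ACDEF")
  st <- pairwise_stats(aln, 5)
  expect_equal(st$coverage, 1)
  expect_equal(st$identity, 1)

  aln2 <- global_align("ACDEF", "ACDFF")
  st2 <- pairwise_stats(aln2, 5)
  expect_equal(st2$identity, 4 / 5)

  expect_error(global_align("A", ""), "non-empty")
  expect_error(global_align("AC1DE", "ACDE"), "non-residue")
})

test_that("coverage uses the longer sequence as denominator", {
  long <- strrep("ACDEFGHIKL", 10)          # 100 residues
  short <- substr(long, 1, 80)
  st <- pairwise_stats(global_align(long, short), nchar(long))
  expect_equal(st$coverage, 0.8)
  expect_equal(st$identity, 1)
})

test_that("p-distance matrices are symmetric with structural zeros", {
  same <- c(x = "MGNACSGAKLV", y = "MGNACSGAKLV", z = "MGNACSGAKLV")
  d0 <- p_distance_matrix(same)
  expect_true(all(d0 == 0))

  seqs <- c(x = "MGNACSGAKLV", y = "MGNACSGAKLV", z = "MWYWPHWYWPH")
  d <- p_distance_matrix(seqs)
  expect_equal(d["x", "y"], 0)
  expect_gt(d["x", "z"], 0.5)
  expect_identical(d, t(d))

  expect_error(p_distance_matrix(c(a = "ACD", a = "ACD", b = "ACD")), "duplicate")
  expect_error(p_distance_matrix(c(a = "ACD", b = "ACD")), "at least 3")
})

test_that("three-taxon NJ reproduces the closed form and the input distances", {
  d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  pd <- stats::cophenetic(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, ignore_attr = TRUE)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 3, C = 5))
})

test_that("NJ recovers the generating topology and lengths on additive matrices", {
  for (s in 1:20) {
    for (n in 4:5) {
      fix <- random_additive_matrix(n, seed = 1000 * n + s)
      tr <- neighbor_joining(fix$d)
      expect_true(same_topology(tr, fix$tree),
                  label = sprintf("additive n=%d seed=%d", n, s))
      pd <- stats::cophenetic(tr)[rownames(fix$d), colnames(fix$d)]
      expect_equal(pd, fix$d, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("4-leaf NJ picks the quartet favoured by the four-point condition", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      fix <- random_additive_matrix(4, seed = 5000 + rep)
      d <- fix$d
      labs <- rownames(d)
      sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
      pairing <- list(c(1, 2), c(1, 3), c(1, 4))[[which.min(sums)]]
      side <- sort(labs[pairing])
      key <- tree_split_keys(neighbor_joining(d))
      want <- if (sort(labs)[1] %in% side)
        paste(sort(setdiff(labs, side)), collapse = "|")
      else paste(side, collapse = "|")
      expect_identical(key, want)
    }
  })
})

test_that("NJ agrees with an independent implementation on random matrices", {
  withr::with_seed(31, {
    for (rep in 1:100) {
      n <- sample(4:8, 1)
      m <- matrix(runif(n * n, 0.05, 1), n)
      d <- (m + t(m)) / 2
      diag(d) <- 0
      dimnames(d) <- list(letters[1:n], letters[1:n])
      mine <- neighbor_joining(d)
      ref <- ape::nj(as.dist(d))
      expect_true(same_topology(mine, ref), label = paste("rep", rep))
    }
  })
})

test_that("NJ rejects asymmetric input and ties break deterministically", {
  d <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(neighbor_joining(d), "asymmetric")

  eq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  t1 <- write_newick(neighbor_joining(eq))
  t2 <- write_newick(neighbor_joining(eq[c(3, 1, 4, 2), c(3, 1, 4, 2)]))
  expect_identical(t1, t2)
})

test_that("bootstrap supports are seeded, order-invariant, and certain for clean clades", {
  msa <- c(a1 = "AAAAAAAAAACCCC", a2 = "AAAAAAAAAACCCC",
           b1 = "GGGGGGGGGGTTTT", b2 = "GGGGGGGGGGTTTT",
           c1 = "CCCCCCCCCCAAAA")
  tr <- bootstrap_supports(msa, n_replicates = 50, seed = 5)
  sup <- as.numeric(tr$node.label[tr$node.label != ""])
  expect_true(all(sup == 100))   # zero-distance clades survive any resample

  tr2 <- bootstrap_supports(msa, n_replicates = 50, seed = 5)
  expect_identical(write_newick(tr), write_newick(tr2))

  perm <- msa[c(3, 5, 1, 4, 2)]
  tr3 <- bootstrap_supports(perm, n_replicates = 50, seed = 5)
  expect_setequal(tr3$node.label[tr3$node.label != ""],
                  tr$node.label[tr$node.label != ""])

  one <- bootstrap_supports(msa, n_replicates = 1, seed = 2)
  expect_true(all(as.numeric(one$node.label[one$node.label != ""]) %in% c(0, 100)))

  expect_error(bootstrap_supports(c(a = "AAA", b = "AA", c = "AAA"), 10, 1),
               "ragged")
})

test_that("group assignment follows reference-clade purity", {
  txt <- "(((q1:1,r1a:1):1,r1b:1):2,((q2:1,r2a:1):1,r2b:1):2,(qx:4,(r1c:1,r2c:1):2):1);"
  tr <- read_newick(txt)
  refs <- c(r1a = "I", r1b = "I", r1c = "I", r2a = "II", r2b = "II", r2c = "II")
  ga <- assign_groups(tr, refs)
  got <- setNames(ga$group, ga$member_id)
  expect_identical(got[["q1"]], "I")
  expect_identical(got[["q2"]], "II")
  expect_identical(got[["qx"]], "unassigned")  # nearest references are mixed

  expect_error(assign_groups(tr, c(r1a = "I", r1b = "I", r2a = "II")),
               "fewer than 2")
})

test_that("planted groups are recovered from generated families", {
  cfg <- generator_config(seed = 207, within_group_divergence = 0.11,
                          between_group_divergence = 0.45)
  gen <- generate_family_genome(cfg)
  fam <- gen$proteins[gen$truth$family_member_ids]
  truth <- unlist(gen$truth$groups)
  refs <- unlist(lapply(split(names(fam), truth[names(fam)]), head, 2))
  references <- setNames(truth[refs], refs)
  tree <- neighbor_joining(p_distance_matrix(fam))
  ga <- assign_groups(tree, references)
  acc <- mean(ga$group == truth[ga$member_id])
  expect_gte(acc, 0.95)
})
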