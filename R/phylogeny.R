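#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining: at every step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, branch
#' lengths follow the standard formulas, and the join distances are
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in Q are broken by the
#' lexicographically smallest sorted label pair (an internal node carries the
#' smallest leaf label beneath it), making the result independent of input
#' order. Negative branch-length estimates are clamped to 0 (the convention
#' used by common tree software).
#'
#' @param dm Symmetric distance matrix with unique row/column labels,
#'   at least 3 taxa.
#' @return Unrooted [ape::phylo] tree (root node of degree 3).
#' @export
neighbor_joining <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs) || anyDuplicated(labs)) stop("labels must be present and unique")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE)))
    stop("asymmetric distance matrix")

  # nodes are referenced by newick fragments built bottom-up
  frag <- labs                 # newick subtree per active node
  lab <- labs                  # tie-break label (smallest leaf beneath)
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  D <- d
  while (length(frag) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(p) {
      s <- sort(c(lab[p[1]], lab[p[2]]))
      paste(s, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    new_lab <- min(lab[c(i, j)])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    lab <- c(lab[keep], new_lab)
  }
  # final trifurcation: three-taxon closed form
  a <- D[1, 2]; b <- D[1, 3]; cc <- D[2, 3]
  l1 <- (a + b - cc) / 2
  l2 <- (a + cc - b) / 2
  l3 <- (b + cc - a) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1], fmt(l1), frag[2], fmt(l2), frag[3], fmt(l3))
  ape::read.tree(text = newick)
}

# Non-trivial bipartitions of an unrooted tree, one per internal node other
# than the (trifurcating) root. Keys are canonical: the split side NOT
# containing the alphabetically first leaf label, sorted and joined by "|".
# Returns a named character vector: names = internal node numbers.
.node_splits <- function(tree) {
  nt <- length(tree$tip.label)
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  po <- stats::reorder(tree, "postorder")
  desc <- vector("list", nt + tree$Nnode)
  for (t in seq_len(nt)) desc[[t]] <- labs[t]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- nt + 1L
  internal <- setdiff(seq_len(nt + tree$Nnode)[-seq_len(nt)], root)
  keys <- vapply(internal, function(v) {
    s <- desc[[v]]
    if (ref %in% s) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }, character(1))
  names(keys) <- internal
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' The point-estimate tree is built by [neighbor_joining()] on p-distances
#' computed from the full alignment. Each bootstrap replicate resamples
#' alignment columns with replacement, rebuilds the NJ tree, and every
#' internal bipartition of the point tree is scored by the percentage of
#' replicates containing it. Fully seeded and reproducible; supports do not
#' depend on leaf input order (bipartitions are compared by canonical label
#' sets).
#'
#' @param msa Named character vector of aligned sequences (equal lengths,
#'   gaps as `-`).
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed driving all resampling.
#' @return [ape::phylo] tree; `node.label` holds integer percent supports for
#'   internal nodes (empty label on the root).
#' @export
bootstrap_supports <- function(msa, n_replicates = 1000L, seed = 1L) {
  stopifnot(n_replicates >= 1L, length(msa) >= 3)
  code <- .encode_msa(msa)
  L <- ncol(code)
  tree <- neighbor_joining(.msa_p_distance(code, seq_len(L)))
  obs <- .node_splits(tree)
  counts <- setNames(numeric(length(obs)), obs)
  withr::with_seed(as.integer(seed), {
    for (rep in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_keys <- .node_splits(neighbor_joining(.msa_p_distance(code, cols)))
      hit <- obs %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- round(100 * counts / n_replicates)
  nt <- length(tree$tip.label)
  node_lab <- character(tree$Nnode)
  idx <- as.integer(names(obs)) - nt
  node_lab[idx] <- as.character(as.integer(support))
  tree$node.label <- node_lab
  tree
}

#' Assign query leaves to reference groups by clade membership
#'
#' Every leaf that is not itself a reference is labelled by the group of the
#' smallest bipartition side containing the query and at least one reference,
#' provided all references on that side belong to a single group; otherwise
#' the query is `unassigned`.
#'
#' @param tree [ape::phylo] tree containing every reference leaf.
#' @param reference_labels Named character vector: reference leaf id ->
#'   group label. Every group needs at least 2 references.
#' @return Data frame with `member_id` and `group` for each non-reference
#'   leaf.
#' @export
assign_groups <- function(tree, reference_labels) {
  stopifnot(inherits(tree, "phylo"), length(reference_labels) > 0,
            !is.null(names(reference_labels)))
  if (!all(names(reference_labels) %in% tree$tip.label))
    stop("tree is missing reference leaves: ",
         paste(setdiff(names(reference_labels), tree$tip.label), collapse = ", "))
  sizes <- table(reference_labels)
  if (any(sizes < 2))
    stop("reference group(s) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  labs <- tree$tip.label
  keys <- .node_splits(tree)
  sides <- list()
  for (k in keys) {
    s <- strsplit(k, "|", fixed = TRUE)[[1]]
    sides <- c(sides, list(s), list(setdiff(labs, s)))
  }
  # complements of terminal edges guarantee a fallback side for every query
  for (l in labs) sides <- c(sides, list(setdiff(labs, l)))
  sides <- unique(sides)

  queries <- setdiff(labs, names(reference_labels))
  out <- data.frame(member_id = queries, group = "unassigned",
                    stringsAsFactors = FALSE)
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    cand <- Filter(function(s) q %in% s && any(names(reference_labels) %in% s),
                   sides)
    if (length(cand) == 0) next
    ord <- order(vapply(cand, length, 1L),
                 vapply(cand, function(s) paste(sort(s), collapse = "|"), ""))
    best <- cand[[ord[1]]]
    gs <- unique(reference_labels[names(reference_labels) %in% best])
    if (length(gs) == 1) out$group[qi] <- gs
  }
  out
}
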