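test_that("single-linkage clustering separates diverged families", {
  set.seed(201)
  consA <- random_dna(300)
  consB <- apply_divergence(consA, 0.25, 0)
  seqs <- c(vapply(1:10, function(i) apply_divergence(consA, 0.05, 0),
                   character(1)),
            vapply(1:10, function(i) apply_divergence(consB, 0.05, 0),
                   character(1)))
  names(seqs) <- paste0("c", 1:20)
  cl <- cluster_copies(seqs, identity_cutoff = 0.85)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)

  # identical copies collapse to one cluster
  same <- stats::setNames(rep(consA, 4), paste0("s", 1:4))
  expect_equal(length(unique(cluster_copies(same))), 1L)

  # cutoff 1.0 on diverged copies: all singletons
  cl1 <- cluster_copies(seqs[c(1, 2, 11)], identity_cutoff = 1.0)
  expect_equal(length(unique(cl1)), 3L)
})

test_that("clustering is invariant under input permutation", {
  set.seed(202)
  consA <- random_dna(300)
  consB <- apply_divergence(consA, 0.3, 0)
  seqs <- c(vapply(1:6, function(i) apply_divergence(consA, 0.05, 0),
                   character(1)),
            vapply(1:6, function(i) apply_divergence(consB, 0.05, 0),
                   character(1)))
  names(seqs) <- paste0("c", 1:12)
  perm <- sample(12)
  cl1 <- cluster_copies(seqs)
  cl2 <- cluster_copies(seqs[perm])[names(seqs)]
  expect_equal(mclust::adjustedRandIndex(cl1, cl2), 1)
})

test_that("copies shorter than the overlap floor become flagged singletons", {
  seqs <- c(a = random_dna(300, 1), b = random_dna(50, 2))
  cl <- cluster_copies(seqs)
  expect_equal(length(unique(cl)), 2L)
  expect_identical(attr(cl, "flagged"), "b")
})

test_that("majority consensus follows the column rules", {
  expect_identical(majority_consensus(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_identical(majority_consensus(c("ACGT", "ACGA", "ACGT")), "ACGT")
  # all-gap and minority-coverage columns drop
  expect_identical(majority_consensus(c("A-C-", "A-C-", "AGC-")), "AC")
  # tie breaks alphabetically
  expect_identical(majority_consensus(c("AC", "AG", "TC", "TG")), "AC")
  # idempotence
  cons <- majority_consensus(c("ACGTAC", "ACGAAC", "ACGTAC"))
  expect_identical(majority_consensus(rep(cons, 5)), cons)
})

test_that("majority consensus recovers a known ancestor from diverged copies", {
  set.seed(203)
  anc <- random_dna(500)
  rows <- vapply(1:20, function(i) apply_divergence(anc, 0.10, 0),
                 character(1))
  cons <- majority_consensus(rows)
  h <- smith_waterman(cons, anc)
  expect_gte(h$identity, 0.99)
})

test_that("star alignment projects copies onto reference columns", {
  ref <- random_dna(200, seed = 204)
  aln <- star_align(c(a = ref, b = ref, c = ref), ref)
  expect_true(all(nchar(aln) == 200))
  expect_false(any(grepl("-", unclass(aln), fixed = TRUE)))

  # one copy with a 3-nt insertion opens a shared gap block
  ins <- paste0(substr(ref, 1, 100), "TTT", substr(ref, 101, 200))
  aln2 <- star_align(c(a = ref, b = ins), ref)
  expect_true(all(nchar(aln2) == 203))
  expect_equal(sum(strsplit(aln2[["a"]], "")[[1]] == "-"), 3L)
  # every row degaps to a subsequence of its copy
  expect_true(grepl(gsub("-", "", aln2[["b"]]), ins, fixed = TRUE))
})

test_that("neighbor joining inverts additive distances exactly", {
  true_tree <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  d <- cophenetic(true_tree)
  tr <- neighbor_joining(d)
  expect_equal(
    as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(true_tree))), 0)
  expect_equal(max(abs(cophenetic(tr)[rownames(d), colnames(d)] - d)), 0,
               tolerance = 1e-9)

  # three taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(d3)
  bl <- sort(tr3$edge.length)
  expect_equal(bl, sort(c((3 + 5 - 6) / 2, (3 + 6 - 5) / 2,
                          (5 + 6 - 3) / 2)), tolerance = 1e-9)
})

test_that("random additive trees are recovered topology-perfect", {
  set.seed(205)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    d <- cophenetic(tr0)
    tr <- neighbor_joining(d)
    expect_equal(
      as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr0))), 0)
  }
})

test_that("bootstrap strongly supports a clean two-family split", {
  set.seed(206)
  ancA <- random_dna(400)
  ancB <- apply_divergence(ancA, 0.35, 0)
  rows <- c(vapply(1:4, function(i) apply_divergence(ancA, 0.03, 0),
                   character(1)),
            vapply(1:4, function(i) apply_divergence(ancB, 0.03, 0),
                   character(1)))
  names(rows) <- c(paste0("A", 1:4), paste0("B", 1:4))
  aln <- structure(rows, class = "copy_alignment")
  bs <- bootstrap_support(aln, n_reps = 100, seed = 207)
  # the A|B bipartition is an internal split with near-total support
  expect_gte(max(bs$support, na.rm = TRUE), 95)
  expect_s3_class(bs$tree, "phylo")
})
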