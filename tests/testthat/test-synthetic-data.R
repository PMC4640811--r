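test_that("array layout arithmetic is exact", {
  model <- fix_model()
  arr <- build_target_arrays(model, n_arrays = 1, genes_per_array = 3,
                             spacer_len_range = c(200, 200),
                             flank_len = 0, minus_strand_prob = 0, seed = 1)
  expect_equal(sum(Biostrings::width(arr$genome)), 3 * 190 + 2 * 200)
  expect_equal(arr$gene_loci$start, c(1, 391, 781))
  expect_equal(arr$gene_loci$end, c(190, 580, 970))

  solo <- build_target_arrays(model, 1, 1, flank_len = 0,
                              minus_strand_prob = 0, seed = 2)
  expect_equal(c(solo$gene_loci$start, solo$gene_loci$end), c(1, 190))
})

test_that("every emitted gene locus re-extracts as the exact model sequence", {
  model <- fix_model()
  arr <- build_target_arrays(model, n_arrays = 2, genes_per_array = 5,
                             minus_strand_prob = 0.5, seed = 7)
  for (i in seq_len(nrow(arr$gene_loci))) {
    li <- arr$gene_loci[i, ]
    s <- as.character(Biostrings::subseq(arr$genome[[li$contig]],
                                         li$start, li$end))
    if (li$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(s, model$sequence)
  }
})

test_that("apply_divergence respects rates and determinism", {
  s <- random_dna(10000, seed = 3)
  expect_identical(apply_divergence(s, 0, 0), s)

  m <- apply_divergence(s, 0.10, 0, seed = 3)
  expect_equal(nchar(m), nchar(s))
  ham <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]]) / 10000
  expect_gte(ham, 0.08)   # binomial 99% interval around 0.10
  expect_lte(ham, 0.12)
  expect_identical(m, apply_divergence(s, 0.10, 0, seed = 3))

  # indel-only divergence introduces (almost) no substitutions: the
  # oracle alignment is gapped, and mismatch columns can only arise
  # where two indel events collide
  s2 <- random_dna(600, seed = 4)
  m2 <- apply_divergence(s2, 0, 0.01, seed = 5)
  h <- smith_waterman(s2, m2)
  a <- strsplit(h$aligned_a, "")[[1]]
  b <- strsplit(h$aligned_b, "")[[1]]
  both <- a != "-" & b != "-"
  expect_lte(sum(a[both] != b[both]), 2)
  expect_gt(sum(!both), 0)
})

test_that("TSD geometry duplicates the target block on both sides", {
  fam <- fix_family(geometry = geometry_tsd(20), n_copies = 1,
                    truncation_prob = 0, divergence = 0, indel_rate = 0)
  sim <- fix_sim(fam, n_arrays = 1, genes_per_array = 1, seed = 21)
  tr <- sim$truths
  g <- as.character(sim$genome[[tr$contig]])
  left <- substr(g, tr$start - 20, tr$start - 1)
  right <- substr(g, tr$end + 1, tr$end + 20)
  expect_identical(left, right)          # the 20-nt duplicated block
  expect_equal(tr$tsd_len, 20L)
  expect_equal(tr$deletion_len, 0L)
})

test_that("blunt geometry concatenates with zero duplicated or deleted bases", {
  model <- fix_model()
  fam <- fix_family(geometry = geometry_blunt(), n_copies = 1,
                    truncation_prob = 0, divergence = 0, indel_rate = 0)
  sim <- fix_sim(fam, n_arrays = 1, genes_per_array = 1, seed = 22)
  tr <- sim$truths
  g <- as.character(sim$genome[[tr$contig]])
  up38 <- substr(g, tr$start - 38, tr$start - 1)
  down <- substr(g, tr$end + 1, tr$end + (190 - 38))
  expect_identical(up38, substr(model$sequence, 1, 38))
  expect_identical(down, substr(model$sequence, 39, 190))
})

test_that("deletion geometry removes the 38 5'-terminal target bases", {
  model <- fix_model()
  fam <- fix_family(geometry = geometry_deletion(38), n_copies = 1,
                    truncation_prob = 0, divergence = 0, indel_rate = 0)
  sim <- fix_sim(fam, n_arrays = 1, genes_per_array = 1, seed = 23)
  tr <- sim$truths
  g <- as.character(sim$genome[[tr$contig]])
  down <- substr(g, tr$end + 1, tr$end + (190 - 38))
  expect_identical(down, substr(model$sequence, 39, 190))
  # the gene's first 38 nt are absent immediately upstream of the element
  up38 <- substr(g, tr$start - 38, tr$start - 1)
  expect_false(identical(up38, substr(model$sequence, 1, 38)))
  expect_equal(tr$deletion_len, 38L)
})

test_that("geometry deleting past the target 5' end is rejected", {
  fam <- fix_family(geometry = geometry_deletion(50), n_copies = 1)
  arr <- build_target_arrays(fix_model(), 1, 1, flank_len = 100,
                             minus_strand_prob = 0, seed = 1)
  expect_error(insert_elements(arr$genome, arr$gene_loci, fam, seed = 1),
               "spillover")
})

test_that("truth tables satisfy the generator invariants", {
  fams <- list(
    fix_family("f1", geometry_tsd(20), n_copies = 5, off_target_rate = 0),
    fix_family("f2", geometry_deletion(38), n_copies = 5,
               off_target_rate = 0))
  sim <- fix_sim(fams, n_arrays = 3, genes_per_array = 4, seed = 31)
  tr <- sim$truths
  expect_true(all(tr$tsd_len * tr$deletion_len == 0))
  expect_true(all(tr$on_target))
  expect_true(all(!is.na(tr$locus_id)))   # off_target_rate 0 => all in loci
  # fixed seed => byte-identical genome and truth list
  sim2 <- fix_sim(fams, n_arrays = 3, genes_per_array = 4, seed = 31)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))
  expect_identical(sim$truths, sim2$truths)
})

test_that("edit round-trip reconstructs the original locus", {
  model <- fix_model()
  set.seed(99)
  for (cfg in 1:100) {
    t_off <- sample(c(20L, 0L, -38L, 10L, -10L), 1)
    fam <- family_spec("f", random_dna(150), cleavage_geometry(38, t_off),
                       n_copies = 1, truncation_prob = 0, divergence = 0,
                       indel_rate = 0)
    sim <- simulate_genome(model, fam, n_arrays = 1, genes_per_array = 1,
                           flank_len = 50, minus_strand_prob = 0.5,
                           seed = sample.int(1e6, 1))
    tr <- sim$truths
    g <- as.character(sim$genome[[tr$contig]])
    li <- sim$gene_loci[1, ]
    # strip the element and undo the geometry edit
    without <- paste0(substr(g, 1, tr$start - 1),
                      substr(g, tr$end + 1, nchar(g)))
    locus_now <- substr(without, li$start,
                        li$start + 190 - 1 + max(t_off, 0) + min(t_off, 0))
    if (li$strand == "-")
      locus_now <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(locus_now)))
    if (t_off > 0) {
      # de-duplicate the TSD block
      rec <- paste0(substr(locus_now, 1, 38),
                    substr(locus_now, 38 + t_off + 1, nchar(locus_now)))
      expect_identical(rec, model$sequence)
    } else if (t_off == 0) {
      expect_identical(locus_now, model$sequence)
    } else {
      # deletion removes target bases (38+t_off+1)..38, 5' of the cut
      expect_identical(locus_now,
                       paste0(substr(model$sequence, 1, 38 + t_off),
                              substr(model$sequence, 39, 190)))
    }
  }
})

test_that("nesting places later copies 5' of the resident copy", {
  fam <- fix_family(geometry = geometry_blunt(), n_copies = 4,
                    truncation_prob = 0, divergence = 0, indel_rate = 0,
                    nesting_rate = 1)
  # 1 locus: first copy occupies it, the rest nest
  sim <- fix_sim(fam, n_arrays = 1, genes_per_array = 1, seed = 41)
  tr <- sim$truths
  expect_equal(sum(is.na(tr$nested_in)), 1L)
  expect_equal(sort(tr$nested_in[!is.na(tr$nested_in)]), c(1L, 2L, 3L))
  # each nested copy's 3' neighbour is its host
  tr <- tr[order(tr$start), ]
  expect_true(all(diff(tr$start) == 400))  # tandem, no gaps (blunt, exact)
})

test_that("off-target copies land outside gene loci", {
  fam <- fix_family(geometry = geometry_tsd(20), n_copies = 8,
                    truncation_prob = 0, divergence = 0, indel_rate = 0,
                    off_target_rate = 1)
  sim <- fix_sim(fam, n_arrays = 2, genes_per_array = 3, seed = 51,
                 flank_len = 3000)
  tr <- sim$truths
  expect_true(all(!tr$on_target))
  expect_true(all(is.na(tr$locus_id)))
  # TSD applied mechanically at the arbitrary site
  g <- as.character(sim$genome)
  for (i in seq_len(nrow(tr))) {
    gc <- g[[tr$contig[i]]]
    expect_identical(substr(gc, tr$start[i] - 20, tr$start[i] - 1),
                     substr(gc, tr$end[i] + 1, tr$end[i] + 20))
  }
})
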