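test_that("full-length undiverged copies are recovered exactly", {
  fam <- fix_family(geometry = geometry_blunt(), n_copies = 10,
                    truncation_prob = 0, divergence = 0, indel_rate = 0)
  sim <- fix_sim(fam, n_arrays = 2, genes_per_array = 5, seed = 61)
  hits <- detect_copies(list(fam), sim$genome)
  expect_equal(nrow(hits), 10L)
  expect_true(all(hits$has_intact_3prime))
  expect_true(all(hits$truncated_5prime_by == 0L))
  expect_true(all(hits$identity == 1))
  tr <- sim$truths[order(sim$truths$contig, sim$truths$start), ]
  expect_equal(hits$start, tr$start)
  expect_equal(hits$end, tr$end)
})

test_that("5' truncation is measured from consensus coverage", {
  fam <- fix_family(geometry = geometry_blunt(), n_copies = 1,
                    truncation_prob = 0, divergence = 0, indel_rate = 0)
  # insert a copy manually truncated by exactly 150 nt
  trunc_fam <- family_spec("famA", substr(fam$consensus, 151, 400),
                           geometry_blunt(), n_copies = 1,
                           truncation_prob = 0, divergence = 0,
                           indel_rate = 0)
  sim <- fix_sim(trunc_fam, n_arrays = 1, genes_per_array = 1, seed = 62)
  hits <- detect_copies(list(fam), sim$genome)   # detect with FULL consensus
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$truncated_5prime_by, 150L)
  expect_true(hits$has_intact_3prime)
})

test_that("copies are assigned to the correct of two diverged families", {
  consA <- random_dna(400, seed = 71)
  consB <- apply_divergence(consA, 0.25, 0, seed = 72)
  famA <- family_spec("famA", consA, geometry_blunt(), n_copies = 10,
                      truncation_prob = 0, divergence = 0.05)
  famB <- family_spec("famB", consB, geometry_blunt(), n_copies = 10,
                      truncation_prob = 0, divergence = 0.05)
  sim <- fix_sim(list(famA, famB), n_arrays = 4, genes_per_array = 5,
                 seed = 73)
  hits <- detect_copies(list(famA, famB), sim$genome)
  expect_equal(nrow(hits), 20L)
  tr <- sim$truths
  for (i in seq_len(nrow(hits))) {
    m <- which(tr$contig == hits$contig[i] &
                 pmin(tr$end, hits$end[i]) - pmax(tr$start, hits$start[i]) >
                   0.5 * (hits$end[i] - hits$start[i]))
    expect_length(m, 1L)
    expect_identical(hits$family[i], tr$family[m])
  }
})

test_that("anchor scan finds 3' termini of heavily truncated copies", {
  cons <- random_dna(600, seed = 81)
  fam <- element_family("famA", cons)
  # 2 full copies + 3 copies truncated beyond half the element
  specs <- list(
    family_spec("famA", cons, geometry_blunt(), n_copies = 2,
                truncation_prob = 0, divergence = 0.02),
    family_spec("famA", substr(cons, 451, 600), geometry_blunt(),
                n_copies = 3, truncation_prob = 0, divergence = 0.02))
  sim <- fix_sim(specs, n_arrays = 1, genes_per_array = 5, seed = 82)
  hits <- anchor_3prime_scan(fam, sim$genome)
  expect_equal(nrow(hits), 5L)
  expect_true(all(hits$has_intact_3prime))
  # anchor hits report query coordinates on the full consensus
  expect_true(all(hits$q_end == 600L))
})

test_that("a missing consensus 3' terminus clears the intact-3' flag", {
  cons <- random_dna(500, seed = 91)
  fam <- element_family("famA", cons)
  # copy lacking the final 10 consensus bases
  cut <- family_spec("famA", substr(cons, 1, 490), geometry_blunt(),
                     n_copies = 1, truncation_prob = 0, divergence = 0)
  sim <- fix_sim(cut, n_arrays = 1, genes_per_array = 1, seed = 92)
  hits <- anchor_3prime_scan(fam, sim$genome)
  expect_equal(nrow(hits), 1L)
  expect_false(hits$has_intact_3prime)
})

test_that("minus-strand copies report element-sense coordinates", {
  fam <- fix_family(geometry = geometry_blunt(), n_copies = 3,
                    truncation_prob = 0, divergence = 0.02, indel_rate = 0)
  sim <- simulate_genome(fix_model(), fam, n_arrays = 1,
                         genes_per_array = 3, flank_len = 300,
                         minus_strand_prob = 1, seed = 93)
  hits <- detect_copies(list(fam), sim$genome)
  expect_equal(nrow(hits), 3L)
  expect_true(all(hits$strand == "-"))
  anch <- anchor_3prime_scan(as.element_family(fam), sim$genome)
  expect_true(all(anch$strand == "-"))
  # 3' terminus of a minus-strand copy is at the genome start side
  expect_true(all(anch$start >= hits$start - 5))
})

test_that("anchor-scan sensitivity holds at 10% divergence", {
  fam <- fix_family(geometry = geometry_blunt(), length = 500,
                    n_copies = 60, truncation_prob = 0.5,
                    divergence = 0.10, indel_rate = 0.001)
  sim <- fix_sim(fam, n_arrays = 12, genes_per_array = 5, seed = 94)
  hits <- anchor_3prime_scan(as.element_family(fam), sim$genome)
  # every truth has an intact 3' terminus at least anchor-length long
  found <- vapply(seq_len(nrow(sim$truths)), function(i) {
    tr <- sim$truths[i, ]
    any(hits$contig == tr$contig & hits$start <= tr$end + 10 &
          hits$end >= tr$start - 10 &
          pmin(hits$end, tr$end) - pmax(hits$start, tr$start) > 30)
  }, logical(1))
  expect_gte(mean(found), 0.95)
})
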