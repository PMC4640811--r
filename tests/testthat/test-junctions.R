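test_that("flank extraction matches literal genome substrings", {
  g <- c(chr = paste0(random_dna(100, 1), strrep("G", 50),
                      random_dna(100, 2)))
  fl <- extract_flanks(g, "chr", 101, 150, "+", flank_len = 60)
  expect_identical(fl$flank_5p, substr(g[["chr"]], 41, 100))
  expect_identical(fl$flank_3p, substr(g[["chr"]], 151, 210))

  # minus strand: element-sense flanks are reverse complements
  flm <- extract_flanks(g, "chr", 101, 150, "-", flank_len = 60)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_identical(flm$flank_5p, rc(substr(g[["chr"]], 151, 210)))
  expect_identical(flm$flank_3p, rc(substr(g[["chr"]], 41, 100)))
})

test_that("flanks clamp at contig ends and N-runs flag unsequenced", {
  g <- c(chr = paste0(random_dna(50, 3), strrep("C", 20), random_dna(10, 4)))
  fl <- extract_flanks(g, "chr", 51, 70, "+", flank_len = 60)
  expect_equal(nchar(fl$flank_3p), 10L)   # clamped at contig end
  expect_equal(nchar(fl$flank_5p), 50L)

  gn <- c(chr = paste0(random_dna(30, 5), "NNNNNNN", random_dna(23, 6),
                       strrep("C", 20), random_dna(60, 7)))
  fln <- extract_flanks(gn, "chr", 61, 80, "+", flank_len = 60)
  expect_true(fln$unseq_5p)
  expect_false(fln$unseq_3p)
})

test_that("the diagnostic target fragment classifies at position 39", {
  model <- fix_model()
  cl <- classify_flank("TCTGTTCTAATCAGTGTGAAA", model)
  expect_identical(cl$class, "target_gene")
  expect_equal(cl$target_start, 39L)
  expect_equal(cl$target_end, 59L)
  expect_equal(cl$identity, 1)
})

test_that("random flanks classify as other; element flanks by family", {
  model <- fix_model()
  set.seed(404)
  other_n <- 0
  for (i in 1:10) {
    cl <- classify_flank(random_dna(60), model)
    other_n <- other_n + (cl$class == "other")
  }
  expect_gte(other_n, 8)   # chance 12-nt matches are rare but possible

  fam <- element_family("famX", random_dna(300, seed = 11))
  cl <- classify_flank(substr(fam$consensus, 1, 60), model, list(fam))
  expect_identical(cl$class, "element:famX")

  cl_un <- classify_flank("ACGT", model, unsequenced = TRUE)
  expect_identical(cl_un$class, "unsequenced")
})

test_that("TSD and deletion inference follows the evidence rules", {
  blk <- random_dna(20, seed = 21)
  f5 <- paste0(random_dna(40, 22), blk)
  f3 <- paste0(blk, random_dna(40, 23))
  # sequence-evidence TSD of 20
  inf <- infer_tsd_and_deletion(
    "other", "other",
    list(target_end = NA_integer_, flank_end = NA_integer_, flank_len = 60L),
    list(target_start = NA_integer_, flank_start = NA_integer_), f5, f3)
  expect_equal(inf$tsd_len, 20L)
  expect_equal(inf$top_offset, 20L)

  # coordinate evidence: both flanks abut the junction, gap 0 => blunt
  inf0 <- infer_tsd_and_deletion(
    "target_gene", "target_gene",
    list(target_end = 38L, flank_end = 60L, flank_len = 60L),
    list(target_start = 39L, flank_start = 1L),
    random_dna(60, 24), random_dna(60, 25))
  expect_equal(inf0$tsd_len, 0L)
  expect_equal(inf0$deletion_len, 0L)
  expect_equal(inf0$top_offset, 0L)

  # 3' flank starts at 39 with no 5' target signal => 38-bp deletion
  infd <- infer_tsd_and_deletion(
    "other", "target_gene",
    list(target_end = NA_integer_, flank_end = NA_integer_, flank_len = 60L),
    list(target_start = 39L, flank_start = 1L),
    random_dna(60, 26), random_dna(60, 27))
  expect_equal(infd$deletion_len, 38L)
  expect_equal(infd$top_offset, -38L)

  # coincidental 1-3 nt suffix/prefix agreement is never called a TSD
  f5c <- paste0(random_dna(57, 28), "ACG")
  f3c <- paste0("ACG", random_dna(57, 29))
  infc <- infer_tsd_and_deletion(
    "other", "other",
    list(target_end = NA_integer_, flank_end = NA_integer_, flank_len = 60L),
    list(target_start = NA_integer_, flank_start = NA_integer_), f5c, f3c)
  expect_equal(infc$tsd_len, 0L)
})

test_that("TSD length never exceeds tsd_max", {
  blk <- random_dna(40, seed = 31)
  inf <- infer_tsd_and_deletion(
    "other", "other",
    list(target_end = NA_integer_, flank_end = NA_integer_, flank_len = 100L),
    list(target_start = NA_integer_, flank_start = NA_integer_),
    paste0(random_dna(60, 32), blk), paste0(blk, random_dna(60, 33)),
    tsd_max = 30L)
  expect_lte(inf$tsd_len, 30L)
})

test_that("geometry calls are identical on a reverse-complemented locus", {
  model <- fix_model()
  fam <- fix_family(geometry = geometry_tsd(20), n_copies = 3,
                    truncation_prob = 0, divergence = 0.03, indel_rate = 0)
  sim <- fix_sim(fam, n_arrays = 1, genes_per_array = 3, seed = 44)
  copies <- detect_copies(list(fam), sim$genome)
  calls <- call_insertions(copies, sim$genome, model, list(fam))

  grc <- Biostrings::reverseComplement(sim$genome)
  names(grc) <- names(sim$genome)
  copies2 <- detect_copies(list(fam), grc)
  calls2 <- call_insertions(copies2, grc, model, list(fam))
  expect_equal(sort(calls$tsd_len), sort(calls2$tsd_len))
  expect_equal(sort(calls$top_offset), sort(calls2$top_offset))
})

test_that("simulated geometries round-trip through junction calls", {
  model <- fix_model()
  cases <- list(list(geom = geometry_tsd(20), want = 20L),
                list(geom = geometry_blunt(), want = 0L),
                list(geom = geometry_deletion(38), want = -38L))
  for (cs in cases) {
    fam <- fix_family(geometry = cs$geom, length = 500, n_copies = 8,
                      truncation_prob = 0, divergence = 0.05,
                      indel_rate = 0.001)
    sim <- fix_sim(fam, n_arrays = 2, genes_per_array = 5, seed = 45)
    copies <- detect_copies(list(fam), sim$genome)
    calls <- call_insertions(copies, sim$genome, model, list(fam))
    expect_equal(modal_value(calls$top_offset), cs$want)
  }
})
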