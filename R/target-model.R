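#' Target-gene model
#'
#' Describes the multicopy target gene of a site-specific retrotransposon:
#' its reference sequence, the length of the 5' region required for
#' function, and the fixed insertion site. For U2 snRNA genes all
#' nucleotides needed for splicing lie in the first 50 nt, and the
#' element-targeted bottom-strand cut falls after nucleotide 38, so the
#' gene fragment downstream of an insertion starts at nucleotide 39.
#'
#' @param name Model name.
#' @param sequence DNA string (ACGTN) of the full gene.
#' @param functional_5prime_len Length (nt) of the functionally required
#'   5' region. Default 50.
#' @param insertion_site 1-based position of the last target base 5' of
#'   the bottom-strand cut. Default 38.
#' @return An object of class `target_gene_model`.
#' @export
target_gene_model <- function(name, sequence, functional_5prime_len = 50L,
                              insertion_site = 38L) {
  sequence <- .assert_dna(sequence, "target model sequence")
  L <- nchar(sequence)
  insertion_site <- as.integer(insertion_site)
  functional_5prime_len <- as.integer(functional_5prime_len)
  if (insertion_site < 1L || insertion_site >= L)
    stop("insertion_site must satisfy 1 <= insertion_site < length(sequence)")
  if (functional_5prime_len > L)
    stop("functional_5prime_len exceeds target length")
  structure(list(name = name, sequence = sequence,
                 functional_5prime_len = functional_5prime_len,
                 insertion_site = insertion_site, length = L),
            class = "target_gene_model")
}

#' @export
print.target_gene_model <- function(x, ...) {
  cat("<target_gene_model>", x$name, "\n",
      " length:", x$length, "nt;",
      "functional 5':", x$functional_5prime_len, "nt;",
      "insertion site after nt", x$insertion_site, "\n")
  invisible(x)
}

#' Built-in synthetic U2-like target-gene model
#'
#' A fixed 190-nt synthetic stand-in for a U2 snRNA gene. It is not a
#' natural U2 sequence; it carries the diagnostic post-insertion-site
#' fragment TCTGTTCTAATCAGTGTGAAA at positions 39-59 so that flanks of
#' simulated insertions classify and map exactly as real junction
#' fragments would (the gene region downstream of the cut starts at
#' nucleotide 39). Functional 5' region 50 nt, insertion site 38.
#'
#' @return A `target_gene_model`.
#' @export
example_u2_model <- function() {
  seq5 <- "ATCGCTTCTCGGCCTTTTGGCTAAGATCAAGTGTAGTA"          # nt 1-38
  diag21 <- "TCTGTTCTAATCAGTGTGAAA"                          # nt 39-59
  rest <- paste0("CTCGGATACAGGCTAATACCTGGAGAAGTTCCTATTGGC",   # nt 60-190,
                 "ATAAGGCCTGGTACGCAGTACCTCCAGGAACGGTGCACC",   # synthetic
                 "TGGATTGCTCCAGTCAAGGCCGAATGCAGGTCTTAGCCAT",
                 "TTTGGCTTAGATC")
  target_gene_model("U2_synth", paste0(seq5, diag21, rest))
}

#' Cleavage geometry of an element family
#'
#' The endonuclease cuts the target bottom strand after `bottom_cut`
#' (the insertion site). `top_offset` is the signed distance of the
#' top-strand cut from the bottom-strand cut: positive values duplicate
#' `top_offset` target bases (a TSD), zero gives a blunt joint, negative
#' values delete `|top_offset|` target bases 5' of the bottom cut.
#'
#' @param bottom_cut 1-based target coordinate of the bottom-strand cut.
#' @param top_offset Signed nt offset of the top-strand cut.
#' @return An object of class `cleavage_geometry`.
#' @export
cleavage_geometry <- function(bottom_cut = 38L, top_offset = 0L) {
  bottom_cut <- as.integer(bottom_cut)
  top_offset <- as.integer(top_offset)
  if (bottom_cut < 1L) stop("bottom_cut must be >= 1")
  structure(list(bottom_cut = bottom_cut, top_offset = top_offset),
            class = "cleavage_geometry")
}

#' Preset cleavage geometries
#'
#' The three junction signatures observed across element families:
#' `geometry_tsd(20)` duplicates 20 target bases (reptile-type families),
#' `geometry_blunt()` makes a blunt joint (arthropod-type families), and
#' `geometry_deletion(38)` deletes the 38 5'-terminal target bases
#' (oomycete-type families, whose disrupted genes start at nucleotide 39).
#'
#' @param len TSD or deletion length in nt.
#' @param bottom_cut Bottom-strand cut position (default 38).
#' @return A `cleavage_geometry`.
#' @export
geometry_tsd <- function(len = 20L, bottom_cut = 38L)
  cleavage_geometry(bottom_cut, as.integer(len))

#' @rdname geometry_tsd
#' @export
geometry_blunt <- function(bottom_cut = 38L) cleavage_geometry(bottom_cut, 0L)

#' @rdname geometry_tsd
#' @export
geometry_deletion <- function(len = 38L, bottom_cut = 38L)
  cleavage_geometry(bottom_cut, -as.integer(len))

#' Element family simulation spec
#'
#' Parameters controlling how copies of one element family are placed in
#' a synthetic genome: number of copies, cleavage geometry, 5'-truncation
#' model, per-copy divergence, off-target rate, and tandem-nesting rate.
#'
#' Defaults reflect a recently active family: half of the copies are
#' 5'-truncated (the non-LTR hallmark of incomplete reverse
#' transcription), truncation length uniform on `[0, 0.8 * length]`,
#' 5% substitutions and 0.1% indels per site, no off-target copies and
#' no tandem nesting.
#'
#' @param name Family name.
#' @param consensus Consensus DNA string.
#' @param geometry A [cleavage_geometry()].
#' @param n_copies Number of copies to insert.
#' @param truncation_prob Probability a copy is 5'-truncated.
#' @param truncation_max_frac Maximum truncated fraction of the consensus.
#' @param divergence Substitutions per site applied to each copy.
#' @param indel_rate Single-nt indel events per site.
#' @param off_target_rate Fraction of copies inserted at uniform random
#'   genome positions instead of target-gene loci.
#' @param nesting_rate Fraction of on-target copies inserted in tandem at
#'   an already-occupied locus (5' of the resident copy).
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(name, consensus, geometry = geometry_blunt(),
                        n_copies = 10L, truncation_prob = 0.5,
                        truncation_max_frac = 0.8, divergence = 0.05,
                        indel_rate = 0.001, off_target_rate = 0,
                        nesting_rate = 0) {
  consensus <- .assert_dna(consensus, "consensus")
  stopifnot(inherits(geometry, "cleavage_geometry"), n_copies >= 0)
  rates <- c(truncation_prob, truncation_max_frac, divergence, indel_rate,
             off_target_rate, nesting_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  structure(list(name = name, consensus = consensus, geometry = geometry,
                 n_copies = as.integer(n_copies),
                 truncation_prob = truncation_prob,
                 truncation_max_frac = truncation_max_frac,
                 divergence = divergence, indel_rate = indel_rate,
                 off_target_rate = off_target_rate,
                 nesting_rate = nesting_rate),
            class = "family_spec")
}

#' Element family used for detection
#'
#' A named consensus plus the length of the 3'-terminal anchor used by
#' the junction-harvest scan (default 70 nt, the anchor length that
#' recovers 3' termini of 5'-truncated copies).
#'
#' @param name Family name.
#' @param consensus Consensus DNA string.
#' @param anchor_3prime_len 3' anchor length in nt (default 70).
#' @return An object of class `element_family`.
#' @export
element_family <- function(name, consensus, anchor_3prime_len = 70L) {
  consensus <- .assert_dna(consensus, "consensus")
  anchor_3prime_len <- as.integer(anchor_3prime_len)
  if (anchor_3prime_len > nchar(consensus))
    stop("anchor length exceeds consensus length")
  structure(list(name = name, consensus = consensus,
                 anchor_3prime_len = anchor_3prime_len),
            class = "element_family")
}

#' @export
as.element_family <- function(x) UseMethod("as.element_family")

#' @export
as.element_family.element_family <- function(x) x

#' @export
as.element_family.family_spec <- function(x)
  element_family(x$name, x$consensus)

#' Synthetic element consensus
#'
#' A random consensus for simulation; real site-specific non-LTR elements
#' run to several kb, the default 1200 nt keeps desk-scale simulations
#' fast while leaving the 3' anchor and internal regions realistic in
#' length.
#'
#' @param name Family name.
#' @param length Consensus length in nt.
#' @param seed Optional integer seed.
#' @param ... Passed to [family_spec()].
#' @return A `family_spec`.
#' @export
synthetic_family <- function(name, length = 1200L, seed = NULL, ...) {
  family_spec(name, random_dna(length, seed = seed), ...)
}
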