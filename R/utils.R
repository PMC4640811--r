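# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards. With `seed = NULL` the code runs on the current RNG
#' stream (so nested calls inside an already-seeded run stay deterministic).
#'
#' @param seed Integer seed or `NULL`.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

.assert_dna <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty DNA string", call. = FALSE)
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside ACGTN", call. = FALSE)
  x
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases; used for spacers, off-array background and
#' synthetic element consensus sequences.
#'
#' @param n Sequence length in nt.
#' @param seed Optional integer seed.
#' @return A character string of length-`n` DNA.
#' @export
random_dna <- function(n, seed = NULL) {
  stopifnot(n >= 0)
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Coerce a genome given as character vector / DNAStringSet to a named
# DNAStringSet. Unnamed contigs are named contig_1, contig_2, ...
.as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or character vector", call. = FALSE)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    names(genome) <- paste0("contig_", seq_along(genome))
  genome
}

.subseq_chr <- function(genome, contig, start, end) {
  if (end < start) return("")
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

# Longest run of N in a string (0 if none); used to flag unsequenced flanks.
.max_n_run <- function(x) {
  if (!nzchar(x)) return(0L)
  r <- rle(strsplit(x, "")[[1]] == "N")
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Statistical mode of an integer vector
#'
#' Most frequent value; ties broken by the smallest value. `NA`s dropped.
#'
#' @param x Integer vector.
#' @return The modal value (or `NA` if `x` is empty after `NA` removal).
#' @export
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}
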