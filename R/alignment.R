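# Local alignment: an exact Smith-Waterman oracle (Biostrings dynamic
# programming under a custom ACGTN scheme) and a k-mer seed-and-extend
# scanner that restricts the exact alignment to seeded windows.

#' Local alignment scoring scheme
#'
#' Affine scheme: a gap of length L scores
#' `gap_open + (L - 1) * gap_extend`. N never matches anything
#' (including N) and scores as a mismatch.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Score of the first gapped position (<= mismatch).
#' @param gap_extend Score of each additional gapped position.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L, gap_open = -2L,
                           gap_extend = -1L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= mismatch,
            gap_extend <= mismatch)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

.sub_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch   # N never matches, not even N
  m
}

#' Optimal local alignment (Smith-Waterman)
#'
#' Exact best local alignment of two sequences under a
#' [scoring_scheme()]. This is the reference oracle used to validate
#' every hit the fast scanner reports.
#'
#' @param a,b DNA strings (ACGTN), each non-empty and at most 20 kb.
#' @param scoring A [scoring_scheme()].
#' @return A `local_hit` list: `q_start`, `q_end`, `s_start`, `s_end`
#'   (1-based closed, in `a` and `b` respectively), `strand` ("+"),
#'   `score`, `identity` (matches / alignment columns, gaps counted),
#'   `n_match`, `width` (alignment columns), and the gapped alignment
#'   strings `aligned_a`, `aligned_b`. A hit with `score = 0` and empty
#'   intervals means no positive-scoring local alignment exists.
#' @export
smith_waterman <- function(a, b, scoring = scoring_scheme()) {
  a <- .assert_dna(a, "a"); b <- .assert_dna(b, "b")
  if (nchar(a) > 20000 || nchar(b) > 20000)
    stop("smith_waterman is the exact oracle; sequences must be <= 20 kb")
  pwa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = .sub_matrix(scoring),
    gapOpening = -(scoring$gap_open - scoring$gap_extend),
    gapExtension = -scoring$gap_extend)
  sc <- Biostrings::score(pwa)
  pa <- as.character(Biostrings::pattern(pwa))
  if (sc <= 0 || !nzchar(pa)) {
    return(structure(list(q_start = NA_integer_, q_end = NA_integer_,
                          s_start = NA_integer_, s_end = NA_integer_,
                          strand = "+", score = 0, identity = NA_real_,
                          n_match = 0L, width = 0L,
                          aligned_a = "", aligned_b = ""),
                     class = "local_hit"))
  }
  sb <- as.character(Biostrings::subject(pwa))
  width <- nchar(pa)
  nm <- Biostrings::nmatch(pwa)
  structure(list(
    q_start = Biostrings::start(Biostrings::pattern(pwa)),
    q_end = Biostrings::end(Biostrings::pattern(pwa)),
    s_start = Biostrings::start(Biostrings::subject(pwa)),
    s_end = Biostrings::end(Biostrings::subject(pwa)),
    strand = "+", score = sc, identity = nm / width,
    n_match = nm, width = width, aligned_a = pa, aligned_b = sb),
    class = "local_hit")
}

#' @export
print.local_hit <- function(x, ...) {
  cat(sprintf("<local_hit> score %.0f, id %.3f, q %d-%d, s %d-%d (%s)\n",
              x$score, x$identity %||% NA, x$q_start, x$q_end,
              x$s_start, x$s_end, x$strand))
  invisible(x)
}

# Precompiled k-mer dictionary of a query (PDict is expensive; build it
# once per query, not per contig/strand).
.query_pdict <- function(query, k) {
  n <- nchar(query)
  offs <- seq_len(n - k + 1L)
  kmers <- substring(query, offs, offs + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  offs <- offs[keep]; kmers <- kmers[keep]
  if (!length(offs)) return(NULL)
  list(pd = Biostrings::PDict(Biostrings::DNAStringSet(kmers)),
       offs = offs)
}

# k-mer seed positions of a precompiled query dictionary in a subject.
# Returns data.frame(q_off, s_pos) of exact matches, 1-based.
.seed_positions <- function(qpd, subject) {
  if (is.null(qpd)) return(data.frame(q_off = integer(), s_pos = integer()))
  m <- Biostrings::matchPDict(qpd$pd, subject)
  st <- Biostrings::startIndex(m)
  ql <- rep.int(qpd$offs, lengths(st))
  data.frame(q_off = ql, s_pos = unlist(st, use.names = FALSE))
}

# Cluster seeds into candidate windows by diagonal bands.
.seed_windows <- function(seeds, k, qlen, slen, band, cluster_gap) {
  if (!nrow(seeds)) return(NULL)
  seeds$diag <- seeds$s_pos - seeds$q_off
  seeds <- seeds[order(seeds$diag, seeds$s_pos), ]
  grp <- cumsum(c(TRUE, diff(seeds$diag) > band |
                    abs(diff(seeds$s_pos)) > cluster_gap + qlen))
  win <- lapply(split(seeds, grp), function(s) {
    ws <- max(1L, min(s$s_pos - s$q_off + 1L) - band)
    we <- min(slen, max(s$s_pos + k - 1L + (qlen - (s$q_off + k - 1L))) + band)
    c(ws, we)
  })
  # one window per cluster; windows may overlap (a window always spans
  # the full query around its seeds, so duplicate alignments from
  # overlapping windows collapse at the hit-merging stage)
  unique(win)
}

#' Seed-and-extend genome scan
#'
#' Finds local alignments of `query` across all contigs of `genome` on
#' both strands: exact k-mer seeds are clustered into diagonal bands and
#' each candidate window is resolved with the exact Smith-Waterman
#' oracle, so no reported hit can score below `min_score` under the
#' scheme. Reverse-strand hits are reported with query coordinates in
#' query sense and subject coordinates on the forward genome strand.
#'
#' @param query DNA string.
#' @param genome DNAStringSet or character vector of contigs.
#' @param k Seed length (8-32; default 11).
#' @param band Diagonal band width for clustering seeds (default 32).
#' @param min_score Minimum alignment score to report (default 30).
#' @param both_strands Scan the minus strand too (default TRUE).
#' @param scoring A [scoring_scheme()].
#' @param cluster_gap Maximum seed spacing within one cluster beyond the
#'   query length (default 250).
#' @return A data.frame of hits sorted by contig and position: contig,
#'   start, end (1-based closed, forward strand), strand, q_start, q_end
#'   (query sense), score, identity, n_match, width.
#' @export
seed_extend_scan <- function(query, genome, k = 11L, band = 32L,
                             min_score = 30L, both_strands = TRUE,
                             scoring = scoring_scheme(),
                             cluster_gap = 250L) {
  query <- .assert_dna(query, "query")
  genome <- .as_genome(genome)
  if (k < 8L || k > 32L) stop("k must lie in [8, 32]")
  if (k > nchar(query)) stop("k exceeds query length")
  qlen <- nchar(query)
  qpd <- .query_pdict(query, k)
  hits <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (ctg in names(genome)) {
    L <- length(genome[[ctg]])
    for (strand in strands) {
      subj_x <- if (strand == "+") genome[[ctg]] else
        Biostrings::reverseComplement(genome[[ctg]])
      subj <- as.character(subj_x)
      seeds <- .seed_positions(qpd, subj_x)
      wins <- .seed_windows(seeds, k, qlen, L, band, cluster_gap)
      for (w in wins %||% list()) {
        h <- smith_waterman(query, substr(subj, w[1], w[2]), scoring)
        if (h$score < min_score || is.na(h$s_start)) next
        s1 <- w[1] + h$s_start - 1L
        s2 <- w[1] + h$s_end - 1L
        if (strand == "-") { tmp <- L - s2 + 1L; s2 <- L - s1 + 1L; s1 <- tmp }
        hits[[length(hits) + 1L]] <- data.frame(
          contig = ctg, start = s1, end = s2, strand = strand,
          q_start = h$q_start, q_end = h$q_end, score = h$score,
          identity = h$identity, n_match = h$n_match, width = h$width)
      }
    }
  }
  if (!length(hits)) return(.empty_hits())
  hits <- do.call(rbind, hits)
  hits <- .merge_overlapping_hits(hits)
  hits <- hits[order(hits$contig, hits$start, hits$end), ]
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), q_start = integer(), q_end = integer(),
             score = numeric(), identity = numeric(), n_match = integer(),
             width = integer())
}

# Keep the best-scoring hit among hits whose subject intervals overlap by
# more than half of the shorter interval (same contig and strand).
.merge_overlapping_hits <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score)
  for (i in ord) {
    if (!keep[i]) next
    for (j in ord) {
      if (j == i || !keep[j]) next
      if (hits$contig[j] != hits$contig[i] ||
          hits$strand[j] != hits$strand[i]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      if (ov <= 0) next
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j]) + 1L
      if (ov > shorter / 2) keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}
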