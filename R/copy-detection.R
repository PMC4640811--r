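# Genome-wide element copy detection: full-consensus scan with fragment
# chaining and family resolution, plus the 3'-terminal-anchor scan that
# harvests junctions of 5'-truncated copies.

.normalize_families <- function(families) {
  if (inherits(families, "element_family") ||
      inherits(families, "family_spec")) families <- list(families)
  lapply(families, as.element_family)
}

# Chain collinear fragments of one copy (same family/contig/strand) when
# the genomic gap and the query gap are both small. Spacer-free junction
# precision matters more than chaining distant fragments, so the default
# tolerance is tight (50 nt).
.chain_hits <- function(hits, chain_gap = 50L) {
  if (nrow(hits) < 2L) return(hits)
  out <- list()
  for (key in unique(paste(hits$contig, hits$strand))) {
    h <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start), ]
    cur <- h[1, ]
    for (i in seq_len(nrow(h))[-1]) {
      nxt <- h[i, ]
      g_gap <- nxt$start - cur$end - 1L
      q_gap <- if (cur$strand == "+") nxt$q_start - cur$q_end - 1L
               else cur$q_start - nxt$q_end - 1L
      if (g_gap >= -10L && g_gap <= chain_gap &&
          q_gap >= -10L && q_gap <= chain_gap) {
        cur$end <- nxt$end
        cur$q_start <- min(cur$q_start, nxt$q_start)
        cur$q_end <- max(cur$q_end, nxt$q_end)
        cur$score <- cur$score + nxt$score
        cur$n_match <- cur$n_match + nxt$n_match
        cur$width <- cur$width + nxt$width
        cur$identity <- cur$n_match / cur$width
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

#' Detect element copies genome-wide
#'
#' Scans the genome with each family's full consensus, chains collinear
#' fragments, resolves loci hit by several families to the best-identity
#' family, and annotates 5' truncation (consensus bases absent from the
#' alignment 5' end) and 3'-terminus intactness (alignment covers the
#' final consensus base). Copies immediately adjacent to another
#' detected copy are annotated with the neighbour's id (`nested_in`),
#' the tandem-nesting signature.
#'
#' @param families A list of [element_family()] (or `family_spec`) objects.
#' @param genome DNAStringSet or character vector.
#' @param k,band,min_score,cluster_gap Passed to [seed_extend_scan()].
#' @param chain_gap Maximum genomic/query gap chained (default 50 nt).
#' @param scoring A [scoring_scheme()].
#' @return A data.frame of copy hits: copy, family, contig, start, end,
#'   strand, identity, score, q_start, q_end, truncated_5prime_by,
#'   has_intact_3prime, nested_in.
#' @export
detect_copies <- function(families, genome, k = 11L, band = 32L,
                          min_score = 30L, chain_gap = 50L,
                          scoring = scoring_scheme(), cluster_gap = 250L) {
  families <- .normalize_families(families)
  if (!length(families)) stop("at least one family required")
  genome <- .as_genome(genome)
  all_hits <- list()
  for (fam in families) {
    h <- seed_extend_scan(fam$consensus, genome, k = k, band = band,
                          min_score = min_score, scoring = scoring,
                          cluster_gap = cluster_gap)
    if (!nrow(h)) next
    h <- .chain_hits(h, chain_gap)
    h$family <- fam$name
    h$consensus_len <- nchar(fam$consensus)
    all_hits[[length(all_hits) + 1L]] <- h
  }
  if (!length(all_hits)) return(.empty_copies())
  hits <- do.call(rbind, all_hits)
  # resolve multi-family overlaps: best identity wins, score breaks ties
  hits <- hits[order(-hits$identity, -hits$score), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (i == j || !keep[j]) next
      if (hits$contig[i] != hits$contig[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      shorter <- min(hits$end[i] - hits$start[i],
                     hits$end[j] - hits$start[j]) + 1L
      if (ov > shorter / 2 && hits$family[i] != hits$family[j]) keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$truncated_5prime_by <- hits$q_start - 1L
  hits$has_intact_3prime <- hits$q_end == hits$consensus_len
  hits <- hits[order(hits$contig, hits$start), ]
  hits$copy <- seq_len(nrow(hits))
  # tandem-nesting annotation: neighbour starting right at our 3' end
  hits$nested_in <- NA_integer_
  for (i in seq_len(nrow(hits))) {
    same <- which(hits$contig == hits$contig[i] & seq_len(nrow(hits)) != i)
    for (j in same) {
      gap3 <- if (hits$strand[i] == "+") hits$start[j] - hits$end[i]
              else hits$start[i] - hits$end[j]
      if (!is.na(gap3) && gap3 >= 0L && gap3 <= 3L &&
          hits$strand[j] == hits$strand[i]) hits$nested_in[i] <- hits$copy[j]
    }
  }
  rownames(hits) <- NULL
  hits[, c("copy", "family", "contig", "start", "end", "strand", "identity",
           "score", "q_start", "q_end", "truncated_5prime_by",
           "has_intact_3prime", "nested_in")]
}

.empty_copies <- function() {
  data.frame(copy = integer(), family = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             identity = numeric(), score = numeric(), q_start = integer(),
             q_end = integer(), truncated_5prime_by = integer(),
             has_intact_3prime = logical(), nested_in = integer())
}

#' Locate element 3' termini with a terminal anchor
#'
#' Scans the genome with only the 3'-terminal anchor of the consensus
#' (default 70 nt), the junction-harvest mode: it finds the 3' ends of
#' heavily 5'-truncated copies that a full-length scan may miss, and
#' marks whether the consensus 3'-terminal base is present
#' (`has_intact_3prime`). Truncation cannot be measured from an anchor
#' hit and is reported as `NA`.
#'
#' @param family An [element_family()] (or `family_spec`).
#' @param genome DNAStringSet or character vector.
#' @param k,band,cluster_gap Passed to [seed_extend_scan()].
#' @param min_score Minimum anchor alignment score (default 30).
#' @param scoring A [scoring_scheme()].
#' @return A data.frame with the same columns as [detect_copies()].
#' @export
anchor_3prime_scan <- function(family, genome, k = 11L, band = 32L,
                               min_score = 30L,
                               scoring = scoring_scheme(),
                               cluster_gap = 100L) {
  family <- as.element_family(family)
  clen <- nchar(family$consensus)
  anchor <- substr(family$consensus, clen - family$anchor_3prime_len + 1L,
                   clen)
  h <- seed_extend_scan(anchor, genome, k = k, band = band,
                        min_score = min_score, scoring = scoring,
                        cluster_gap = cluster_gap)
  if (!nrow(h)) return(.empty_copies())
  h$family <- family$name
  h$has_intact_3prime <- h$q_end == family$anchor_3prime_len
  h$truncated_5prime_by <- NA_integer_
  # report query coordinates on the full consensus
  off <- clen - family$anchor_3prime_len
  h$q_start <- h$q_start + off
  h$q_end <- h$q_end + off
  h <- h[order(h$contig, h$start), ]
  h$copy <- seq_len(nrow(h))
  h$nested_in <- NA_integer_
  rownames(h) <- NULL
  h[, c("copy", "family", "contig", "start", "end", "strand", "identity",
        "score", "q_start", "q_end", "truncated_5prime_by",
        "has_intact_3prime", "nested_in")]
}

#' Write copy hits as BED6+
#'
#' BED6 (0-based half-open, score column = alignment score) with extra
#' columns family, identity, truncation, intact-3' flag.
#'
#' @param hits Copy-hit data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$contig, chromStart = hits$start - 1L,
                    chromEnd = hits$end, name = hits$family,
                    score = round(hits$score), strand = hits$strand,
                    identity = round(hits$identity, 4),
                    truncated_5prime_by = hits$truncated_5prime_by,
                    has_intact_3prime = hits$has_intact_3prime)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
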