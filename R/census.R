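# Target-gene census: find every target-gene locus in a genome and
# classify it intact (full functional 5' region present), disrupted
# (locus begins at/after the insertion site with an element 3' terminus
# immediately adjacent) or fragment.

#' Census target-gene loci
#'
#' Scans the genome with the target-gene model, merges overlapping hits
#' into loci, and classifies each locus. A locus is `intact` when model
#' coverage starts at base 1 and extends through the functional 5'
#' region; `disrupted` when it begins past the insertion site (the
#' post-integration signature: the gene fragment starts at nucleotide
#' `insertion_site + 1`) and an element 3' terminus lies within
#' `adjacency_gap` nt on its 5' side; anything else is a `fragment`.
#' Adjacency of an element 5' terminus is recorded but never counts as
#' disruption (the disruption signature is 3'-end adjacency).
#'
#' @param genome DNAStringSet or character vector.
#' @param target_model A [target_gene_model()].
#' @param element_calls Copy-hit data.frame from [detect_copies()] (or
#'   calls from [call_insertions()]); may be `NULL` / empty.
#' @param id_threshold Minimum locus identity (default 0.85).
#' @param adjacency_gap Maximum gap (nt) between an element terminus and
#'   a disrupted locus (default 5).
#' @param min_score Minimum scan score; the default 25 keeps short
#'   5'-side gene fragments (down to ~30 nt) visible.
#' @param k,band Passed to [seed_extend_scan()].
#' @param array_gap Loci closer than this on one contig share an
#'   `array_id` (default 1000 nt).
#' @param scoring A [scoring_scheme()].
#' @return A data.frame: locus, contig, start, end, strand, model_start,
#'   model_end, missing_5prime, identity, status, adjacent_family,
#'   adjacent_side, array_id.
#' @export
census_target_genes <- function(genome, target_model, element_calls = NULL,
                                id_threshold = 0.85, adjacency_gap = 5L,
                                min_score = 25L, k = 11L, band = 32L,
                                array_gap = 1000L,
                                scoring = scoring_scheme()) {
  genome <- .as_genome(genome)
  hits <- seed_extend_scan(target_model$sequence, genome, k = k,
                           band = band, min_score = min_score,
                           scoring = scoring, cluster_gap = 60L)
  if (!nrow(hits)) return(.empty_census())
  hits <- .clip_to_elements(hits, element_calls, genome, target_model,
                            scoring)
  if (nrow(hits)) hits <- hits[hits$identity >= id_threshold, , drop = FALSE]
  if (!nrow(hits)) return(.empty_census())
  hits <- .merge_census_hits(hits)
  hits <- hits[order(hits$contig, hits$start), ]
  n <- nrow(hits)
  status <- character(n)
  adj_fam <- rep(NA_character_, n)
  adj_side <- rep(NA_character_, n)
  s <- target_model$insertion_site
  f_len <- target_model$functional_5prime_len
  for (i in seq_len(n)) {
    missing5 <- hits$q_start[i] - 1L
    adj <- .adjacent_element(hits[i, ], element_calls, adjacency_gap)
    adj_fam[i] <- adj$family
    adj_side[i] <- adj$side
    if (missing5 == 0L && hits$q_end[i] >= f_len) {
      status[i] <- "intact"
    } else if (hits$q_start[i] > s && identical(adj$side, "3p")) {
      status[i] <- "disrupted"
    } else {
      status[i] <- "fragment"
    }
  }
  out <- data.frame(locus = seq_len(n), contig = hits$contig,
                    start = hits$start, end = hits$end,
                    strand = hits$strand, model_start = hits$q_start,
                    model_end = hits$q_end,
                    missing_5prime = hits$q_start - 1L,
                    identity = hits$identity, status = status,
                    adjacent_family = adj_fam, adjacent_side = adj_side)
  # array grouping of co-located loci
  out$array_id <- NA_integer_
  aid <- 0L
  for (ctg in unique(out$contig)) {
    idx <- which(out$contig == ctg)
    brk <- c(TRUE, diff(out$start[idx]) > array_gap)
    aid_local <- cumsum(brk)
    out$array_id[idx] <- aid + aid_local
    aid <- aid + max(aid_local)
  }
  rownames(out) <- NULL
  out
}

.empty_census <- function() {
  data.frame(locus = integer(), contig = character(), start = integer(),
             end = integer(), strand = character(), model_start = integer(),
             model_end = integer(), missing_5prime = integer(),
             identity = numeric(), status = character(),
             adjacent_family = character(), adjacent_side = character(),
             array_id = integer())
}

# Merge genomically overlapping census hits (one locus can attract a
# duplicate hit from the opposite strand when the scan window is noisy);
# the best-scoring hit represents the locus.
.merge_census_hits <- function(hits) {
  hits <- hits[order(-hits$score), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (i == j || !keep[j]) next
      if (hits$contig[i] != hits$contig[j]) next
      ov <- min(hits$end[i], hits$end[j]) -
        max(hits$start[i], hits$start[j]) + 1L
      if (ov > 0) keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

# Clip census hits so they never overlap a detected element copy:
# terminal element bases that coincidentally (or noisily) match the
# model otherwise drag the apparent locus boundary, and hence
# missing_5prime, into the element. Clipped hits are re-aligned against
# the model over the element-free genome segment, so their model
# coordinates and identity are exact.
.clip_to_elements <- function(hits, calls, genome, target_model, scoring) {
  if (is.null(calls) || !nrow(calls)) return(hits)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    el <- calls[calls$contig == hits$contig[i], , drop = FALSE]
    clipped <- FALSE
    for (j in seq_len(nrow(el))) {
      if (el$start[j] > hits$end[i] || el$end[j] < hits$start[i]) next
      if (el$start[j] <= hits$start[i] && el$end[j] >= hits$end[i]) {
        keep[i] <- FALSE
        break
      }
      if (el$end[j] >= hits$start[i] && el$start[j] <= hits$start[i]) {
        hits$start[i] <- el$end[j] + 1L               # genome-left overhang
        clipped <- TRUE
      }
      if (el$start[j] <= hits$end[i] && el$end[j] >= hits$end[i]) {
        hits$end[i] <- el$start[j] - 1L               # genome-right overhang
        clipped <- TRUE
      }
      if (hits$end[i] < hits$start[i]) {
        keep[i] <- FALSE
        break
      }
    }
    if (keep[i] && clipped) {
      subj <- .subseq_chr(genome, hits$contig[i], hits$start[i], hits$end[i])
      if (hits$strand[i] == "-") subj <- .revcomp(subj)
      h <- smith_waterman(target_model$sequence, subj, scoring)
      if (h$score <= 0 || is.na(h$s_start)) { keep[i] <- FALSE; next }
      if (hits$strand[i] == "+") {
        hits$end[i] <- hits$start[i] + h$s_end - 1L
        hits$start[i] <- hits$start[i] + h$s_start - 1L
      } else {
        L <- hits$end[i] - hits$start[i] + 1L
        g1 <- hits$start[i] + (L - h$s_end)
        g2 <- hits$start[i] + (L - h$s_start)
        hits$start[i] <- g1
        hits$end[i] <- g2
      }
      hits$q_start[i] <- h$q_start
      hits$q_end[i] <- h$q_end
      hits$identity[i] <- h$identity
      hits$score[i] <- h$score
    }
  }
  hits[keep, , drop = FALSE]
}

# Element terminus adjacent to the locus 5' edge (gene sense).
# Returns list(family, side) where side is "3p" when the adjacent
# terminus is the element's 3' end, "5p" for its 5' end.
.adjacent_element <- function(locus, calls, gap) {
  none <- list(family = NA_character_, side = NA_character_)
  if (is.null(calls) || !nrow(calls)) return(none)
  same <- calls[calls$contig == locus$contig, , drop = FALSE]
  if (!nrow(same)) return(none)
  for (j in seq_len(nrow(same))) {
    if (locus$strand == "+") {
      # gene-sense upstream is genome-left of locus start
      d_end <- locus$start - same$end[j] - 1L      # element genome end
      d_start <- locus$start - same$start[j] - 1L  # element genome start
      if (d_end >= -2L && d_end <= gap) {
        side <- if (same$strand[j] == "+") "3p" else "5p"
        return(list(family = same$family[j], side = side))
      }
      if (d_start >= -2L && d_start <= gap && same$strand[j] == "-")
        next  # minus-strand element's genome start is its 3' end but it
              # faces away; handled by the d_end branch of that element
    } else {
      # gene-sense upstream is genome-right of locus end
      d_start <- same$start[j] - locus$end - 1L
      if (d_start >= -2L && d_start <= gap) {
        side <- if (same$strand[j] == "-") "3p" else "5p"
        return(list(family = same$family[j], side = side))
      }
    }
  }
  none
}

#' Summarise a census as intact/disrupted/fragment counts
#'
#' @param census Data.frame from [census_target_genes()].
#' @return A one-row data.frame: intact, disrupted, fragment, total.
#' @export
census_summary <- function(census) {
  data.frame(intact = sum(census$status == "intact"),
             disrupted = sum(census$status == "disrupted"),
             fragment = sum(census$status == "fragment"),
             total = nrow(census))
}

#' Bootstrap a target-gene model from a genome
#'
#' Avoids cross-species reference bias by rebuilding the target model
#' from the surveyed genome itself: loci found intact with a seed model
#' are extracted (strand-corrected), star-aligned to the seed, and their
#' majority-rule consensus becomes the new model sequence (coordinates
#' inherited from the seed model).
#'
#' @param genome DNAStringSet or character vector.
#' @param seed_model A [target_gene_model()] used for the initial scan.
#' @param min_copies Minimum intact loci required (default 3).
#' @param ... Passed to [census_target_genes()].
#' @return A `target_gene_model`.
#' @export
bootstrap_target_model <- function(genome, seed_model, min_copies = 3L,
                                   ...) {
  genome <- .as_genome(genome)
  cen <- census_target_genes(genome, seed_model, ...)
  cen <- cen[cen$status == "intact", , drop = FALSE]
  if (nrow(cen) < min_copies)
    stop("fewer than ", min_copies, " intact loci; cannot bootstrap")
  seqs <- vapply(seq_len(nrow(cen)), function(i) {
    x <- .subseq_chr(genome, cen$contig[i], cen$start[i], cen$end[i])
    if (cen$strand[i] == "-") .revcomp(x) else x
  }, character(1))
  aln <- star_align(seqs, seed_model$sequence)
  target_gene_model(paste0(seed_model$name, "_boot"),
                    majority_consensus(aln),
                    seed_model$functional_5prime_len,
                    seed_model$insertion_site)
}

#' Write a census as TSV
#'
#' @param census Data.frame from [census_target_genes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_census_tsv <- function(census, path) {
  utils::write.table(census, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
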