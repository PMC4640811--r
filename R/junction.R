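# Junction analysis: flank extraction in element sense, flank
# classification (target gene / element / other / unsequenced), and
# TSD / target-deletion / cleavage-geometry inference.

#' Extract element-sense flanks of a copy
#'
#' Returns the sequences flanking a copy on its 5' and 3' sides in
#' element-sense orientation (minus-strand copies have their genomic
#' neighbourhood reverse-complemented). Flanks are truncated at contig
#' ends; flanks containing a run of >= `n_run` Ns are flagged
#' unsequenced (assembly-gap proxy).
#'
#' @param genome DNAStringSet or character vector.
#' @param contig,start,end,strand Copy location (1-based closed).
#' @param flank_len Flank length in nt (default 60).
#' @param n_run N-run length that flags a flank unsequenced (default 5).
#' @return A list: `flank_5p`, `flank_3p`, `unseq_5p`, `unseq_3p`.
#' @export
extract_flanks <- function(genome, contig, start, end, strand = "+",
                           flank_len = 60L, n_run = 5L) {
  genome <- .as_genome(genome)
  L <- length(genome[[contig]])
  up <- .subseq_chr(genome, contig, max(1L, start - flank_len), start - 1L)
  down <- .subseq_chr(genome, contig, end + 1L, min(L, end + flank_len))
  if (strand == "-") {
    f5 <- .revcomp(down); f3 <- .revcomp(up)
  } else {
    f5 <- up; f3 <- down
  }
  list(flank_5p = f5, flank_3p = f3,
       unseq_5p = !nzchar(f5) || .max_n_run(f5) >= n_run,
       unseq_3p = !nzchar(f3) || .max_n_run(f3) >= n_run)
}

#' Classify a junction flank
#'
#' Aligns the flank against the target-gene model and against each
#' family consensus (both orientations for elements) and classifies it
#' as `target_gene`, `element:<family>`, or `other`. A candidate match
#' must reach `id_threshold` identity over at least `min_match` aligned
#' nt; on ties the precedence is target gene over element over other.
#' The default 0.75/12 profile scores the short degenerate target
#' fragments seen at weakly specific junctions as target-like; use
#' 0.85/15 for a strict profile.
#'
#' @param flank Flank DNA string (element sense).
#' @param target_model A [target_gene_model()].
#' @param families List of [element_family()] objects (may be empty).
#' @param id_threshold Minimum alignment identity (default 0.75).
#' @param min_match Minimum aligned length in nt (default 12).
#' @param unsequenced Flag from [extract_flanks()]; propagated untouched.
#' @param scoring A [scoring_scheme()].
#' @return A list: `class` ("target_gene", "element:<name>", "other" or
#'   "unsequenced"), `target_start`, `target_end` (1-based model
#'   coordinates of the matched block, NA unless target_gene),
#'   `identity`, `score`.
#' @export
classify_flank <- function(flank, target_model, families = list(),
                           id_threshold = 0.75, min_match = 12L,
                           unsequenced = FALSE,
                           scoring = scoring_scheme()) {
  if (unsequenced || !nzchar(flank))
    return(list(class = "unsequenced", target_start = NA_integer_,
                target_end = NA_integer_, flank_start = NA_integer_,
                flank_end = NA_integer_, identity = NA_real_, score = 0))
  families <- .normalize_families(families)
  tg <- smith_waterman(flank, target_model$sequence, scoring)
  tg_ok <- tg$score > 0 && !is.na(tg$identity) &&
    tg$identity >= id_threshold && tg$width >= min_match
  best_el <- NULL
  for (fam in families) {
    for (seqv in c(fam$consensus, .revcomp(fam$consensus))) {
      e <- smith_waterman(flank, seqv, scoring)
      if (e$score > 0 && !is.na(e$identity) && e$identity >= id_threshold &&
          e$width >= min_match &&
          (is.null(best_el) || e$score > best_el$hit$score))
        best_el <- list(name = fam$name, hit = e)
    }
  }
  if (tg_ok && (is.null(best_el) || tg$score >= best_el$hit$score)) {
    return(list(class = "target_gene", target_start = tg$s_start,
                target_end = tg$s_end, flank_start = tg$q_start,
                flank_end = tg$q_end, identity = tg$identity,
                score = tg$score))
  }
  if (!is.null(best_el)) {
    return(list(class = paste0("element:", best_el$name),
                target_start = NA_integer_, target_end = NA_integer_,
                flank_start = NA_integer_, flank_end = NA_integer_,
                identity = best_el$hit$identity, score = best_el$hit$score))
  }
  list(class = "other", target_start = NA_integer_,
       target_end = NA_integer_, flank_start = NA_integer_,
       flank_end = NA_integer_, identity = tg$identity, score = tg$score)
}

# Marginal element-alignment score of the first k element-sense bases
# of a detected copy (k = 1..K): E(0) - E(k), where E(k) is the best
# local score of the consensus against the element head segment with
# its first k bases ceded to the flank. Re-aligning for every k lets
# the element re-anchor, so a base the element only annexed through a
# homopolymer shift or a diverged terminal base carries (correctly) a
# near-zero marginal claim.
.element_marginal_scores <- function(genome, contig, start, end, strand,
                                     consensus, K, scoring,
                                     cons_hint = 1L) {
  K <- min(K, end - start + 1L)
  seg_len <- min(end - start + 1L, K + 80L)
  # only the consensus region around the copy's aligned 5' end can pair
  # with the head segment; a window keeps the re-alignments cheap
  consensus <- substr(consensus, max(1L, cons_hint - 80L),
                      min(nchar(consensus), cons_hint + seg_len + 160L))
  S <- if (strand == "+")
    .subseq_chr(genome, contig, start, start + seg_len - 1L)
  else
    .revcomp(.subseq_chr(genome, contig, end - seg_len + 1L, end))
  e0 <- smith_waterman(consensus, S, scoring)$score
  vapply(seq_len(K), function(k)
    e0 - smith_waterman(consensus, substr(S, k + 1L, seg_len),
                        scoring)$score, numeric(1))
}

# Junction-anchored 5'-side target match for one copy.
#
# A 5'-truncated copy offers the aligner consensus bases 5' of its true
# truncation point; when those resemble the target bases just 5' of the
# junction, the element alignment annexes target bases and the apparent
# junction shifts into the element. This probes a window spanning the
# flank plus `K` bases of the detected element with the target model;
# if the model match reaches the detected junction, the bases beyond it
# are settled by score competition: reassigning the first k
# element-claimed bases to the target pays off only when the target
# match gains more than the element alignment loses (ties keep the
# detected boundary). Returns list(found, target_end, shift): `shift`
# is the number of element-sense bases the junction moves 3'.
.junction_target_5p <- function(genome, contig, start, end, strand,
                                target_model, consensus = NULL,
                                flank_len = 60L, K = 40L,
                                id_threshold = 0.75, min_match = 12L,
                                end_slack = 3L, probe_min_score = 12L,
                                cons_hint = 1L, resid = 0L,
                                scoring = scoring_scheme()) {
  genome <- .as_genome(genome)
  L <- length(genome[[contig]])
  K <- min(K, end - start + 1L)
  if (strand == "+") {
    w_from <- max(1L, start - flank_len)
    w_to <- min(L, start + K - 1L)
    W <- .subseq_chr(genome, contig, w_from, w_to)
    junction <- start - w_from            # bases of W 5' of the element
  } else {
    w_from <- max(1L, end - K + 1L)
    w_to <- min(L, end + flank_len)
    W <- .revcomp(.subseq_chr(genome, contig, w_from, w_to))
    junction <- w_to - end
  }
  # a few unaligned terminal consensus bases (resid) are almost always
  # the element's diverged terminus sitting just outside the detected
  # interval: the effective junction moves into the flank by that many
  # bases so the target cannot claim them as coincidental matches.
  # Large resid means 5' truncation (the bases are genuinely absent)
  # and must not move the junction.
  resid <- as.integer(resid)
  j_adj <- if (resid >= 1L && resid <= 6L) resid else 0L
  junction <- junction - j_adj
  none <- list(found = FALSE, target_end = NA_integer_, shift = 0L)
  if (junction < 1L) return(none)
  h <- smith_waterman(W, target_model$sequence, scoring)
  if (h$score < probe_min_score || is.na(h$identity) ||
      h$identity < id_threshold || h$width < min_match) return(none)
  if (h$q_end < junction - end_slack) return(none)   # match ends mid-flank
  k_cand <- min(h$q_end - junction, K)
  if (k_cand <= 0L)
    return(list(found = TRUE, target_end = h$s_end, shift = -j_adj))
  # map window positions to model coordinates and per-base target gains
  pa <- strsplit(h$aligned_a, "")[[1]]
  sa <- strsplit(h$aligned_b, "")[[1]]
  wp <- h$q_start - 1L
  mp <- h$s_start - 1L
  run <- 0
  gain <- rep(NA_real_, k_cand)          # cumulative target score past junction
  mpos <- rep(NA_integer_, k_cand)
  base_run <- NA_real_
  m_at_junction <- NA_integer_
  for (col in seq_along(pa)) {
    colsc <- if (sa[col] == "-" || pa[col] == "-") scoring$gap_extend
             else if (pa[col] == sa[col]) scoring$match
             else scoring$mismatch
    run <- run + colsc
    if (sa[col] != "-") mp <- mp + 1L
    if (pa[col] != "-") {
      wp <- wp + 1L
      if (wp == junction) { base_run <- run; m_at_junction <- mp }
      if (wp > junction && wp - junction <= k_cand) {
        if (is.na(base_run)) { base_run <- 0; m_at_junction <- mp - 1L }
        gain[wp - junction] <- run - base_run
        mpos[wp - junction] <- mp
      }
    }
  }
  if (is.na(m_at_junction)) m_at_junction <- h$s_end - k_cand
  ok <- !is.na(gain)
  if (!any(ok))
    return(list(found = TRUE, target_end = m_at_junction, shift = -j_adj))
  pscore <- if (is.null(consensus)) numeric(k_cand)
            else .element_marginal_scores(genome, contig, start, end, strand,
                                          consensus, k_cand, scoring,
                                          cons_hint = cons_hint)
  # moving the junction must beat the element's claim by a margin: the
  # target side scores exact model matches while the element side scores
  # a diverged copy against its consensus, so raw score ties are biased
  # toward the target. Half a match unit per reassigned base restores
  # the balance.
  obj <- c(0, ifelse(ok, gain, -Inf) - pscore[seq_len(k_cand)] -
               0.5 * seq_len(k_cand))
  k_star <- which.max(obj) - 1L          # first max: ties keep boundary
  te <- if (k_star == 0L) m_at_junction else mpos[k_star]
  # shift is relative to the detected boundary: positive = junction
  # moves into the detected element, negative = residue bases returned
  # to the element
  list(found = TRUE, target_end = min(te, target_model$length),
       shift = k_star - j_adj)
}

# Longest L <= tsd_max with suffix(f5, L) == prefix(f3, L), allowing up
# to max_mismatch mismatches.
.sequence_tsd <- function(f5, f3, tsd_max = 30L, max_mismatch = 0L) {
  lim <- min(tsd_max, nchar(f5), nchar(f3))
  if (lim < 1L) return(0L)
  a <- strsplit(f5, "")[[1]]
  b <- strsplit(f3, "")[[1]]
  for (L in seq(lim, 1L)) {
    sfx <- a[(length(a) - L + 1L):length(a)]
    pfx <- b[1:L]
    if (sum(sfx != pfx) <= max_mismatch) return(L)
  }
  0L
}

#' Infer TSD, target deletion and cleavage geometry for one insertion
#'
#' Combines three lines of evidence, in order:
#' 1. If both flanks map to the target model *at the junction* (the 5'
#'    flank's match reaches the flank's 3' terminus and the 3' flank's
#'    match starts at its 5' terminus, within `end_slack` nt), the
#'    coordinate gap decides:
#'    `deletion = (target_start_3p - 1) - target_end_5p`; negative gaps
#'    are re-reported as TSDs (the duplicated block maps twice).
#'    Gaps outside `[-tsd_max, del_max]` are geometrically impossible
#'    and fall through to the remaining rules (flagged inconsistent).
#' 2. Otherwise a sequence-evidence TSD (longest common block ending the
#'    5' flank and starting the 3' flank) of at least `min_seq_tsd` nt is
#'    called; shorter blocks are indistinguishable from coincidence.
#' 3. Otherwise, a 3' flank mapping at target position > 1 with no
#'    junction-abutting target signal on the 5' side implies the
#'    5'-terminal `target_start_3p - 1` target bases were deleted on
#'    integration (the flank upstream is intact-gene or spacer
#'    sequence, not the missing gene 5' fragment).
#'
#' The inferred top-strand cut offset is `tsd_len` (> 0), `0` (blunt) or
#' `-deletion_len`; it is `NA` when no evidence line applies.
#'
#' @param class_5p,class_3p Flank classes from [classify_flank()].
#' @param map_5p List for the 5' flank: `target_end`, `flank_end`
#'   (flank coordinate where the target match ends), `flank_len`.
#' @param map_3p List for the 3' flank: `target_start`, `flank_start`.
#' @param flank_5p,flank_3p Flank sequences (element sense).
#' @param tsd_max Longest credible TSD (default 30).
#' @param del_max Longest coordinate-evidence deletion (default 60).
#' @param min_seq_tsd Shortest sequence-only TSD called (default 5).
#' @param max_mismatch Mismatches tolerated inside a TSD block (default
#'   0; old, diverged elements may warrant up to 2).
#' @param end_slack Max distance (nt) between a flank match and the
#'   element junction for coordinate evidence (default 3).
#' @return A list: `tsd_len`, `deletion_len`, `top_offset`, `consistent`.
#' @export
infer_tsd_and_deletion <- function(class_5p, class_3p, map_5p, map_3p,
                                   flank_5p, flank_3p, tsd_max = 30L,
                                   del_max = 60L, min_seq_tsd = 5L,
                                   max_mismatch = 0L, end_slack = 3L) {
  seq_tsd <- .sequence_tsd(flank_5p, flank_3p, tsd_max, max_mismatch)
  t5 <- identical(class_5p, "target_gene")
  t3 <- identical(class_3p, "target_gene")
  abut5 <- t5 && !is.na(map_5p$flank_end) &&
    nchar(flank_5p) - map_5p$flank_end <= end_slack
  abut3 <- t3 && !is.na(map_3p$flank_start) &&
    map_3p$flank_start - 1L <= end_slack
  consistent <- TRUE
  if (abut5 && abut3 && !is.na(map_5p$target_end) &&
      !is.na(map_3p$target_start)) {
    d <- (map_3p$target_start - 1L) - map_5p$target_end
    if (d >= -tsd_max && d < 0L)
      return(list(tsd_len = -d, deletion_len = 0L, top_offset = -d,
                  consistent = TRUE))
    if (d >= 0L && d <= del_max)
      return(list(tsd_len = 0L, deletion_len = d, top_offset = -d,
                  consistent = TRUE))
    consistent <- FALSE   # junction-abutting matches with impossible gap
  }
  if (seq_tsd >= min_seq_tsd)
    return(list(tsd_len = seq_tsd, deletion_len = 0L, top_offset = seq_tsd,
                consistent = consistent))
  if (abut3 && (!abut5 || !consistent) && !is.na(map_3p$target_start) &&
      map_3p$target_start > 1L)
    return(list(tsd_len = 0L, deletion_len = map_3p$target_start - 1L,
                top_offset = -(map_3p$target_start - 1L),
                consistent = consistent))
  list(tsd_len = 0L, deletion_len = 0L, top_offset = NA_integer_,
       consistent = consistent)
}

#' Build insertion calls for detected copies
#'
#' For each copy hit: extract element-sense flanks, classify both
#' junctions, and infer TSD / deletion / cleavage geometry. This is the
#' per-insertion record the specificity tables and the census consume.
#'
#' @param copies Copy-hit data.frame from [detect_copies()] or
#'   [anchor_3prime_scan()].
#' @param genome DNAStringSet or character vector.
#' @param target_model A [target_gene_model()].
#' @param families List of families (for element-flank classification).
#' @param flank_len Flank length (default 60).
#' @param id_threshold,min_match Passed to [classify_flank()].
#' @param tsd_max,min_seq_tsd,max_mismatch Passed to
#'   [infer_tsd_and_deletion()].
#' @param scoring A [scoring_scheme()].
#' @return The `copies` data.frame with junction columns appended:
#'   class_5p, class_3p, target_start_5p, target_end_5p, target_start_3p,
#'   target_end_3p, flank_5p, flank_3p, tsd_len, deletion_len,
#'   top_offset, consistent.
#' @export
call_insertions <- function(copies, genome, target_model,
                            families = list(), flank_len = 60L,
                            id_threshold = 0.75, min_match = 12L,
                            tsd_max = 30L, min_seq_tsd = 5L,
                            max_mismatch = 0L,
                            scoring = scoring_scheme()) {
  genome <- .as_genome(genome)
  n <- nrow(copies)
  cols <- data.frame(class_5p = character(n), class_3p = character(n),
                     target_start_5p = rep(NA_integer_, n),
                     target_end_5p = rep(NA_integer_, n),
                     target_start_3p = rep(NA_integer_, n),
                     target_end_3p = rep(NA_integer_, n),
                     flank_5p = character(n), flank_3p = character(n),
                     tsd_len = rep(NA_integer_, n),
                     deletion_len = rep(NA_integer_, n),
                     top_offset = rep(NA_integer_, n),
                     consistent = rep(NA, n))
  fams_n <- .normalize_families(families)
  fam_seq <- stats::setNames(lapply(fams_n, `[[`, "consensus"),
                             vapply(fams_n, `[[`, "", "name"))
  rc_model <- target_gene_model(target_model$name,
                                .revcomp(target_model$sequence),
                                target_model$functional_5prime_len,
                                target_model$insertion_site)
  flip <- c(`+` = "-", `-` = "+")
  for (i in seq_len(n)) {
    fl <- extract_flanks(genome, copies$contig[i], copies$start[i],
                         copies$end[i], copies$strand[i], flank_len)
    c5 <- classify_flank(fl$flank_5p, target_model, families,
                         id_threshold, min_match, fl$unseq_5p, scoring)
    c3 <- classify_flank(fl$flank_3p, target_model, families,
                         id_threshold, min_match, fl$unseq_3p, scoring)
    cons <- fam_seq[[copies$family[i]]] %||% NULL
    # junction-anchored target evidence on both sides (robust to element
    # boundary slop at diverged or 5'-truncated copies)
    j5 <- list(found = FALSE, target_end = NA_integer_, shift = 0L)
    f5 <- fl$flank_5p
    if (!fl$unseq_5p) {
      j5 <- .junction_target_5p(
        genome, copies$contig[i], copies$start[i], copies$end[i],
        copies$strand[i], target_model, consensus = cons,
        flank_len = flank_len, id_threshold = id_threshold,
        min_match = min_match,
        cons_hint = if (is.na(copies$q_start[i])) 1L else copies$q_start[i],
        resid = if (is.na(copies$q_start[i])) 0L else copies$q_start[i] - 1L,
        scoring = scoring)
      if (j5$shift > 0L) {
        ext <- if (copies$strand[i] == "+")
          .subseq_chr(genome, copies$contig[i], copies$start[i],
                      copies$start[i] + j5$shift - 1L)
        else
          .revcomp(.subseq_chr(genome, copies$contig[i],
                               copies$end[i] - j5$shift + 1L,
                               copies$end[i]))
        f5 <- paste0(f5, ext)
      } else if (j5$shift < 0L) {
        f5 <- substr(f5, 1L, nchar(f5) + j5$shift)   # tail is element
      }
    }
    # 3' junction: the element's 3' boundary in reverse-complement space
    # is a 5' boundary, so the same probe applies to the mirrored locus
    j3 <- list(found = FALSE, target_end = NA_integer_, shift = 0L)
    f3 <- fl$flank_3p
    start3 <- NA_integer_
    if (!fl$unseq_3p) {
      j3 <- .junction_target_5p(
        genome, copies$contig[i], copies$start[i], copies$end[i],
        flip[[copies$strand[i]]], rc_model,
        consensus = if (is.null(cons)) NULL else .revcomp(cons),
        flank_len = flank_len, id_threshold = id_threshold,
        min_match = min_match,
        cons_hint = if (is.null(cons) || is.na(copies$q_end[i])) 1L else
          nchar(cons) - copies$q_end[i] + 1L,
        resid = if (is.null(cons) || is.na(copies$q_end[i])) 0L else
          nchar(cons) - copies$q_end[i],
        scoring = scoring)
      if (j3$found)
        start3 <- target_model$length - j3$target_end + 1L
      if (j3$shift > 0L) {
        ext <- if (copies$strand[i] == "+")
          .subseq_chr(genome, copies$contig[i],
                      copies$end[i] - j3$shift + 1L, copies$end[i])
        else
          .revcomp(.subseq_chr(genome, copies$contig[i], copies$start[i],
                               copies$start[i] + j3$shift - 1L))
        f3 <- paste0(ext, f3)
      } else if (j3$shift < 0L) {
        f3 <- substr(f3, 1L - j3$shift, nchar(f3))   # head is element
      }
    }
    inf <- infer_tsd_and_deletion(
      if (j5$found) "target_gene" else c5$class,
      if (j3$found) "target_gene" else c3$class,
      list(target_end = if (j5$found) j5$target_end else NA_integer_,
           flank_end = if (j5$found) nchar(f5) else NA_integer_,
           flank_len = nchar(f5)),
      list(target_start = start3,
           flank_start = if (j3$found) 1L else NA_integer_),
      f5, f3, tsd_max = tsd_max,
      min_seq_tsd = min_seq_tsd, max_mismatch = max_mismatch)
    # refined element boundaries (element-sense 5' shift, 3' shrink)
    if (copies$strand[i] == "+") {
      copies$start[i] <- copies$start[i] + j5$shift
      copies$end[i] <- copies$end[i] - j3$shift
    } else {
      copies$end[i] <- copies$end[i] - j5$shift
      copies$start[i] <- copies$start[i] + j3$shift
    }
    cols$class_5p[i] <- c5$class
    cols$class_3p[i] <- c3$class
    cols$target_start_5p[i] <- c5$target_start
    cols$target_end_5p[i] <- if (j5$found) j5$target_end else c5$target_end
    cols$target_start_3p[i] <- if (j3$found) start3 else c3$target_start
    cols$target_end_3p[i] <- c3$target_end
    cols$flank_5p[i] <- fl$flank_5p
    cols$flank_3p[i] <- fl$flank_3p
    cols$tsd_len[i] <- inf$tsd_len
    cols$deletion_len[i] <- inf$deletion_len
    cols$top_offset[i] <- inf$top_offset
    cols$consistent[i] <- inf$consistent
  }
  cbind(copies, cols)
}

#' Write insertion calls as TSV
#'
#' Per-insertion table (family, locus, junction classes, target
#' coordinates, tsd_len, deletion_len, top_offset).
#'
#' @param calls Data.frame from [call_insertions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_insertions_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
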