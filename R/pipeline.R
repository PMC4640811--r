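# Pipeline orchestration: scan -> junction calls -> specificity tables
# -> census -> family clustering/consensus/tree, plus recovery scoring
# against simulation ground truth.

#' Specificity table of junction flanks
#'
#' Per family, counts of flanks classified target gene / element /
#' other / unsequenced, and the specificity fraction
#' `target / (target + element + other)`. For the 3' side, copies that
#' are 3'-truncated (no intact 3' terminus) or whose 3' flank is
#' unsequenced are excluded from the denominator, the standard exclusion
#' rule for junction tables; excluded copies are tallied separately.
#'
#' @param calls Data.frame from [call_insertions()].
#' @param side `"3p"` (default) or `"5p"`.
#' @return A data.frame: family, n_target, n_element, n_other,
#'   n_unsequenced, n_excluded, specificity.
#' @export
specificity_table <- function(calls, side = c("3p", "5p")) {
  side <- match.arg(side)
  empty <- data.frame(family = character(), n_target = integer(),
                      n_element = integer(), n_other = integer(),
                      n_unsequenced = integer(), n_excluded = integer(),
                      specificity = numeric())
  if (!nrow(calls)) return(empty)
  cls <- if (side == "3p") calls$class_3p else calls$class_5p
  fams <- sort(unique(calls$family))
  rows <- lapply(fams, function(f) {
    sel <- calls$family == f
    excl <- rep(FALSE, sum(sel))
    if (side == "3p") {
      intact <- calls$has_intact_3prime[sel]
      intact[is.na(intact)] <- FALSE
      excl <- !intact | cls[sel] == "unsequenced"
    }
    cc <- cls[sel][!excl]
    n_t <- sum(cc == "target_gene")
    n_e <- sum(startsWith(cc, "element:"))
    n_o <- sum(cc == "other")
    n_u <- sum(cc == "unsequenced")
    denom <- n_t + n_e + n_o
    data.frame(family = f, n_target = n_t, n_element = n_e, n_other = n_o,
               n_unsequenced = n_u, n_excluded = sum(excl),
               specificity = if (denom > 0) n_t / denom else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full target-specificity pipeline
#'
#' Detects element copies (full-consensus scan, supplemented by the
#' 3'-anchor scan so that termini of heavily 5'-truncated copies are
#' not lost), calls junctions and cleavage geometry, builds 3' and 5'
#' specificity tables, censuses the target gene, and (when enough
#' copies exist) clusters copies, builds a majority-rule consensus per
#' cluster and an NJ tree over cluster consensi. Deterministic given
#' identical inputs and `seed`.
#'
#' @param genome DNAStringSet or character vector.
#' @param families List of [element_family()] / `family_spec` objects.
#' @param target_model A [target_gene_model()].
#' @param flank_len,id_threshold,min_match,tsd_max,min_seq_tsd
#'   Junction parameters, see [call_insertions()].
#' @param k,band,min_score Scan parameters, see [seed_extend_scan()].
#' @param census_min_score,adjacency_gap Census parameters, see
#'   [census_target_genes()].
#' @param cluster_cutoff Identity cutoff for copy clustering (default
#'   0.85); set to `NA` to skip the family-tools stage.
#' @param seed Optional integer seed (used by stochastic stages, e.g.
#'   bootstrap when requested downstream).
#' @param out_dir Optional directory; when given, all outputs are
#'   written there (see [write_pipeline_outputs()]).
#' @return A list of class `pipeline_result`: copies, calls,
#'   specificity_3p, specificity_5p, census, census_counts, clusters,
#'   consensi, tree, params.
#' @export
run_pipeline <- function(genome, families, target_model,
                         flank_len = 60L, id_threshold = 0.75,
                         min_match = 12L, tsd_max = 30L, min_seq_tsd = 5L,
                         k = 11L, band = 32L, min_score = 30L,
                         census_min_score = 25L, adjacency_gap = 5L,
                         cluster_cutoff = 0.85, seed = NULL,
                         out_dir = NULL) {
  genome <- .as_genome(genome)
  families <- .normalize_families(families)
  if (!length(genome) || !length(families))
    stop("genome and families must be non-empty")
  with_seed(seed, {
    copies <- detect_copies(families, genome, k = k, band = band,
                            min_score = min_score)
    # supplement with anchor-only termini missed by the full scan
    for (fam in families) {
      anch <- anchor_3prime_scan(fam, genome, k = k, band = band,
                                 min_score = min_score)
      if (!nrow(anch)) next
      for (i in seq_len(nrow(anch))) {
        covered <- any(copies$contig == anch$contig[i] &
                         pmin(copies$end, anch$end[i]) -
                           pmax(copies$start, anch$start[i]) >= 0)
        if (!covered) copies <- rbind(copies, anch[i, ])
      }
    }
    if (nrow(copies)) {
      copies <- copies[order(copies$contig, copies$start), ]
      copies$copy <- seq_len(nrow(copies))
      rownames(copies) <- NULL
    }
    calls <- call_insertions(copies, genome, target_model, families,
                             flank_len = flank_len,
                             id_threshold = id_threshold,
                             min_match = min_match, tsd_max = tsd_max,
                             min_seq_tsd = min_seq_tsd)
    spec3 <- specificity_table(calls, "3p")
    spec5 <- specificity_table(calls, "5p")
    census <- census_target_genes(genome, target_model,
                                  element_calls = copies,
                                  adjacency_gap = adjacency_gap,
                                  min_score = census_min_score)
    clusters <- NULL; consensi <- NULL; tree <- NULL
    if (!is.na(cluster_cutoff) && nrow(copies) >= 2L) {
      seqs <- vapply(seq_len(nrow(copies)), function(i) {
        x <- .subseq_chr(genome, copies$contig[i], copies$start[i],
                         copies$end[i])
        if (copies$strand[i] == "-") .revcomp(x) else x
      }, character(1))
      names(seqs) <- paste0("copy_", copies$copy)
      clusters <- cluster_copies(seqs, identity_cutoff = cluster_cutoff)
      consensi <- character(0)
      for (cl in sort(unique(clusters))) {
        members <- seqs[clusters == cl]
        if (length(members) >= 2L) {
          ref <- members[[which.max(nchar(members))]]
          cons <- majority_consensus(star_align(members, ref))
        } else cons <- members[[1L]]
        consensi[paste0("cluster_", cl)] <- cons
      }
      if (length(consensi) >= 3L) {
        ref <- consensi[[which.max(nchar(consensi))]]
        aln <- star_align(consensi, ref)
        d <- p_distance(aln)
        if (!any(is.na(d))) tree <- neighbor_joining(d)
      }
    }
    res <- structure(list(
      copies = copies, calls = calls, specificity_3p = spec3,
      specificity_5p = spec5, census = census,
      census_counts = census_summary(census), clusters = clusters,
      consensi = consensi, tree = tree,
      params = list(flank_len = flank_len, id_threshold = id_threshold,
                    min_match = min_match, tsd_max = tsd_max,
                    min_seq_tsd = min_seq_tsd, k = k, band = band,
                    min_score = min_score,
                    census_min_score = census_min_score,
                    adjacency_gap = adjacency_gap,
                    cluster_cutoff = cluster_cutoff, seed = seed)),
      class = "pipeline_result")
    if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
    res
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(" copies detected:", nrow(x$copies), "\n")
  cat(" census:", x$census_counts$intact, "intact,",
      x$census_counts$disrupted, "disrupted,",
      x$census_counts$fragment, "fragment\n")
  cat(" 3' specificity:\n")
  print(x$specificity_3p)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes copies.bed, insertions.tsv, specificity_3p.tsv,
#' specificity_5p.tsv, census.tsv, census_counts.tsv, consensus.fa,
#' tree.nwk and params.yaml (files only when the stage produced output).
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(res$copies)) write_hits_bed(res$copies, file.path(dir, "copies.bed"))
  write_insertions_tsv(res$calls, file.path(dir, "insertions.tsv"))
  utils::write.table(res$specificity_3p, file.path(dir, "specificity_3p.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$specificity_5p, file.path(dir, "specificity_5p.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_census_tsv(res$census, file.path(dir, "census.tsv"))
  utils::write.table(res$census_counts, file.path(dir, "census_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(res$consensi)) {
    cons <- Biostrings::DNAStringSet(res$consensi)
    Biostrings::writeXStringSet(cons, file.path(dir, "consensus.fa"))
  }
  if (!is.null(res$tree)) write_tree_newick(res$tree, file.path(dir, "tree.nwk"))
  yaml::write_yaml(res$params, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Score pipeline outputs against simulation ground truth
#'
#' Matches detected copies to truth intervals (reciprocal overlap of at
#' least half the shorter interval on the same contig) and reports:
#' `sensitivity` (matched truths / truths), `geometry_accuracy`
#' (matched on-target, non-nested calls whose inferred top-strand
#' offset equals the generator's), `census_accuracy`
#' (`1 - (|intact error| + |disrupted error|) / expected total`, given
#' `gene_loci`), and `clustering_ari` (adjusted Rand index between
#' detected family assignment and truth families over matched copies).
#'
#' @param result A `pipeline_result`.
#' @param truths Truth table from [insert_elements()] /
#'   [simulate_genome()].
#' @param gene_loci Optional locus table (enables census accuracy).
#' @param target_model Required with `gene_loci`: the model used.
#' @return A list of metrics (JSON-serialisable).
#' @export
score_against_truth <- function(result, truths, gene_loci = NULL,
                                target_model = NULL) {
  copies <- result$copies
  calls <- result$calls
  match_of <- rep(NA_integer_, nrow(truths))
  for (i in seq_len(nrow(truths))) {
    cand <- which(copies$contig == truths$contig[i])
    for (j in cand) {
      ov <- min(copies$end[j], truths$end[i]) -
        max(copies$start[j], truths$start[i]) + 1L
      shorter <- min(copies$end[j] - copies$start[j],
                     truths$end[i] - truths$start[i]) + 1L
      if (ov > shorter / 2) { match_of[i] <- j; break }
    }
  }
  sensitivity <- mean(!is.na(match_of))
  sel <- which(!is.na(match_of) & truths$on_target & is.na(truths$nested_in))
  geometry_accuracy <- if (length(sel)) {
    inferred <- calls$top_offset[match_of[sel]]
    mean(!is.na(inferred) & inferred == truths$top_offset[sel])
  } else NA_real_
  census_accuracy <- NA_real_
  if (!is.null(gene_loci) && !is.null(target_model)) {
    exp_cnt <- expected_census(truths, gene_loci, target_model)
    got <- result$census_counts
    denom <- exp_cnt$intact + exp_cnt$disrupted
    census_accuracy <- max(0, 1 - (abs(got$intact - exp_cnt$intact) +
                                     abs(got$disrupted - exp_cnt$disrupted)) /
                             max(1L, denom))
  }
  clustering_ari <- NA_real_
  ok <- which(!is.na(match_of))
  if (length(ok) >= 2L) {
    clustering_ari <- mclust::adjustedRandIndex(
      copies$family[match_of[ok]], truths$family[ok])
  }
  list(sensitivity = sensitivity, geometry_accuracy = geometry_accuracy,
       census_accuracy = census_accuracy, clustering_ari = clustering_ari,
       n_truths = nrow(truths), n_detected = nrow(copies))
}

#' Expected census counts from generator truth
#'
#' A locus never hit on-target stays intact; a hit locus contributes one
#' disrupted record (its post-insertion-site 3' fragment abuts an
#' element 3' end) and remains countable as intact only when the
#' surviving 5' piece still spans the functional region, i.e. when
#' `insertion_site + max(top_offset, 0) >= functional_5prime_len`.
#'
#' @param truths Truth table.
#' @param gene_loci Locus table.
#' @param target_model The [target_gene_model()] used in simulation.
#' @return A list: intact, disrupted.
#' @export
expected_census <- function(truths, gene_loci, target_model) {
  s <- target_model$insertion_site
  f <- target_model$functional_5prime_len
  hit <- truths[truths$on_target & !is.na(truths$locus_id), , drop = FALSE]
  per_locus <- split(hit, hit$locus_id)
  n_hit <- length(per_locus)
  intact <- nrow(gene_loci) - n_hit
  for (pl in per_locus) {
    t0 <- pl$top_offset[is.na(pl$nested_in)][1]
    if (s + max(t0, 0L) >= f) intact <- intact + 1L
  }
  list(intact = intact, disrupted = n_hit)
}
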