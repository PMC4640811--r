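# Family tools: single-linkage identity clustering of copies,
# star alignment to a reference, majority-rule consensus, p-distances,
# and a neighbor-joining tree with bootstrap support as a lightweight
# distance-based stand-in for a full phylogenetic analysis.

#' Single-linkage identity clustering of copies
#'
#' Pairwise local-alignment identity is computed for every pair of
#' copies; two copies link when their identity over an aligned overlap
#' of at least `min_overlap` nt reaches `identity_cutoff`. Clusters are
#' the connected components of the link graph (single linkage), so the
#' partition does not depend on input order. Copies shorter than
#' `min_overlap` cannot link and are returned as flagged singletons.
#'
#' @param seqs Character vector of copy sequences (names kept).
#' @param identity_cutoff Linking identity (default 0.85).
#' @param min_overlap Minimum aligned overlap in nt (default 100).
#' @param scoring A [scoring_scheme()].
#' @return An integer cluster vector (named as `seqs`); attribute
#'   `flagged` marks copies too short to cluster.
#' @export
cluster_copies <- function(seqs, identity_cutoff = 0.85,
                           min_overlap = 100L,
                           scoring = scoring_scheme()) {
  n <- length(seqs)
  if (n < 1L) stop("at least one copy required")
  if (is.null(names(seqs))) names(seqs) <- paste0("copy_", seq_len(n))
  short <- nchar(seqs) < min_overlap
  if (n == 1L) {
    cl <- stats::setNames(1L, names(seqs))
    attr(cl, "flagged") <- names(seqs)[short]
    return(cl)
  }
  d <- matrix(1, n, n, dimnames = list(names(seqs), names(seqs)))
  diag(d) <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (short[i] || short[j]) next
      h <- smith_waterman(seqs[[i]], seqs[[j]], scoring)
      if (h$width >= min_overlap && !is.na(h$identity))
        d[i, j] <- d[j, i] <- 1 - h$identity
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  cl <- stats::cutree(hc, h = 1 - identity_cutoff + 1e-9)
  attr(cl, "flagged") <- names(seqs)[short]
  cl
}

#' Star alignment of copies to a reference
#'
#' Aligns each copy to the reference with the exact local aligner and
#' projects all copies into common columns: one column per reference
#' base plus shared insertion columns where any copy carries extra
#' sequence. Each row degaps to the aligned subsequence of its copy.
#' Copies with no positive-scoring alignment to the reference are
#' excluded (recorded in attribute `excluded`).
#'
#' @param seqs Character vector of copy sequences.
#' @param reference Reference DNA string (typically the longest copy or
#'   a prior consensus).
#' @param scoring A [scoring_scheme()].
#' @return Character vector of equal-length gapped rows (class
#'   `copy_alignment`), named as `seqs`; attributes `reference_columns`
#'   (logical: which columns are reference positions) and `excluded`.
#' @export
star_align <- function(seqs, reference, scoring = scoring_scheme()) {
  reference <- .assert_dna(reference, "reference")
  if (is.null(names(seqs))) names(seqs) <- paste0("copy_", seq_along(seqs))
  L <- nchar(reference)
  rows <- list()
  excluded <- character(0)
  # per copy: base aligned to each ref position ("-" outside/deleted) and
  # insertion strings attached after each ref position (0 = before ref 1)
  per <- list()
  ins_len <- integer(L + 1L)
  for (nm in names(seqs)) {
    h <- smith_waterman(seqs[[nm]], reference, scoring)
    if (h$score <= 0 || is.na(h$s_start)) { excluded <- c(excluded, nm); next }
    pa <- strsplit(h$aligned_a, "")[[1]]
    sa <- strsplit(h$aligned_b, "")[[1]]
    base <- rep("-", L)
    ins <- rep("", L + 1L)
    rp <- h$s_start - 1L
    for (col in seq_along(pa)) {
      if (sa[col] == "-") {
        ins[rp + 1L] <- paste0(ins[rp + 1L], pa[col])
      } else {
        rp <- rp + 1L
        base[rp] <- pa[col]
      }
    }
    per[[nm]] <- list(base = base, ins = ins)
    ins_len <- pmax(ins_len, nchar(ins))
  }
  if (!length(per)) stop("no copy aligned to the reference")
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
  ref_cols <- logical(0)
  for (nm in names(per)) {
    p <- per[[nm]]
    parts <- character(0)
    for (i in 0:L) {
      if (ins_len[i + 1L] > 0)
        parts <- c(parts, pad(p$ins[i + 1L], ins_len[i + 1L]))
      if (i < L) parts <- c(parts, p$base[i + 1L])
    }
    rows[[nm]] <- paste(parts, collapse = "")
  }
  for (i in 0:L) {
    if (ins_len[i + 1L] > 0) ref_cols <- c(ref_cols, rep(FALSE, ins_len[i + 1L]))
    if (i < L) ref_cols <- c(ref_cols, TRUE)
  }
  out <- unlist(rows)
  structure(out, class = "copy_alignment", reference_columns = ref_cols,
            excluded = excluded)
}

.alignment_matrix <- function(alignment) {
  rows <- unclass(alignment)
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  m
}

#' Majority-rule consensus of aligned copies
#'
#' Per column, the most frequent non-gap base is emitted; a column
#' enters the consensus only when non-gap characters make up at least
#' half of the rows (all-gap columns are dropped). Base ties break
#' alphabetically (A < C < G < T), a fixed, documented rule.
#'
#' @param alignment A `copy_alignment` (or character vector of
#'   equal-length gapped rows) with at least 2 rows.
#' @return The consensus DNA string.
#' @export
majority_consensus <- function(alignment) {
  m <- .alignment_matrix(alignment)
  if (nrow(m) < 2L) stop("majority consensus needs >= 2 rows")
  if (length(unique(nchar(unclass(alignment)))) != 1L)
    stop("alignment rows differ in length")
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    nongap <- col[col != "-"]
    if (length(nongap) / length(col) < 0.5) next
    votes <- nongap[nongap %in% c("A", "C", "G", "T")]
    if (!length(votes)) next
    tab <- table(factor(votes, levels = c("A", "C", "G", "T")))
    out <- c(out, names(tab)[which.max(tab)])   # first max = alphabetical
  }
  paste(out, collapse = "")
}

#' Pairwise p-distances on aligned rows
#'
#' Proportion of mismatching sites over columns where both rows are
#' ungapped (gap-excluded pairwise deletion). Pairs with no overlapping
#' ungapped column get distance `NA`. p-distances need not satisfy the
#' triangle inequality; they feed the clustering stand-in tree, not a
#' publishable phylogeny.
#'
#' @param alignment A `copy_alignment` or character vector of
#'   equal-length gapped rows.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(alignment) {
  m <- .alignment_matrix(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      d[i, j] <- d[j, i] <-
        if (!any(ok)) NA_real_ else mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper over the canonical NJ algorithm; negative branch
#' lengths (an NJ artefact on non-additive input) are clamped to zero
#' and flagged via attribute `clamped`.
#'
#' @param d Symmetric distance matrix with labels.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (is.null(rownames(d))) stop("distance matrix must carry labels")
  if (nrow(d) < 3L) stop("NJ needs >= 3 labels")
  if (any(is.na(d))) stop("distance matrix contains NA")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(d)
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree from p-distances each time, and reports the percentage of
#' replicates containing each internal split of the original tree.
#'
#' @param alignment A `copy_alignment` (>= 4 rows for informative
#'   splits).
#' @param n_reps Number of replicates (default 100).
#' @param seed Optional integer seed.
#' @return A list: `tree` (the NJ tree of the full alignment) and
#'   `support` (per-internal-node percentages, in `ape::prop.clades`
#'   node order).
#' @export
bootstrap_support <- function(alignment, n_reps = 100L, seed = NULL) {
  m <- .alignment_matrix(alignment)
  build <- function(mat) {
    rows <- apply(mat, 1L, paste, collapse = "")
    neighbor_joining(p_distance(rows))
  }
  tree <- build(m)
  with_seed(seed, {
    counts <- ape::boot.phylo(tree, m, function(x) build(x), B = n_reps,
                              quiet = TRUE, trees = FALSE)
    list(tree = tree, support = 100 * counts / n_reps)
  })
}

#' Write a tree with support values as newick
#'
#' Support percentages become internal node labels.
#'
#' @param tree An `ape::phylo`.
#' @param path Output file.
#' @param support Optional per-internal-node support values.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path, support = NULL) {
  if (!is.null(support)) tree$node.label <- round(support)
  ape::write.tree(tree, file = path)
  invisible(path)
}
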