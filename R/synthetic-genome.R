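# Synthetic-genome generator: tandem target-gene arrays plus element
# insertions with known ground truth. All genome coordinates in truth
# tables and locus tables are 1-based closed; file writers emit BED-like
# 0-based half-open intervals.

#' Build a genome of tandem target-gene arrays
#'
#' Emits one contig per array. Each array carries `genes_per_array`
#' copies of the target gene separated by spacers drawn from a common
#' ancestral spacer and then heavily diverged (real intergenic sequence
#' between tandem U2 genes is essentially unalignable between loci),
#' with random background sequence padding the array on both sides.
#' Each array is placed on the plus or minus genome strand (probability
#' `minus_strand_prob`); locus coordinates and strands always describe
#' the emitted contig.
#'
#' @param model A [target_gene_model()].
#' @param n_arrays Number of arrays (contigs).
#' @param genes_per_array Gene copies per array.
#' @param spacer_len_range Integer range for spacer lengths.
#' @param spacer_divergence Substitutions per site applied per spacer
#'   instance (default 0.3: spacers mutually diverged).
#' @param gene_divergence Substitutions per site applied per gene copy
#'   (default 0: genes exact).
#' @param flank_len Background padding on each side of the array.
#' @param minus_strand_prob Probability an array lies on the minus strand.
#' @param seed Optional integer seed.
#' @return A list with `genome` (DNAStringSet) and `gene_loci`
#'   (data.frame: contig, start, end, strand, locus_id).
#' @export
build_target_arrays <- function(model, n_arrays = 1L, genes_per_array = 5L,
                                spacer_len_range = c(150L, 400L),
                                spacer_divergence = 0.3,
                                gene_divergence = 0,
                                flank_len = 500L,
                                minus_strand_prob = 0.5,
                                seed = NULL) {
  stopifnot(inherits(model, "target_gene_model"),
            n_arrays >= 1, genes_per_array >= 1)
  with_seed(seed, {
    spacer_anc <- random_dna(max(spacer_len_range))
    contigs <- character(n_arrays)
    loci <- vector("list", n_arrays)
    locus_id <- 0L
    for (a in seq_len(n_arrays)) {
      parts <- character(0)
      pos <- flank_len
      starts <- ends <- integer(genes_per_array)
      parts <- c(parts, random_dna(flank_len))
      for (g in seq_len(genes_per_array)) {
        gene <- model$sequence
        if (gene_divergence > 0)
          gene <- apply_divergence(gene, gene_divergence, 0)
        starts[g] <- pos + 1L
        ends[g] <- pos + nchar(gene)
        parts <- c(parts, gene)
        pos <- pos + nchar(gene)
        if (g < genes_per_array) {
          sp_len <- spacer_len_range[1] +
            sample.int(spacer_len_range[2] - spacer_len_range[1] + 1L, 1L) - 1L
          spacer <- substr(apply_divergence(spacer_anc, spacer_divergence, 0),
                           1L, sp_len)
          parts <- c(parts, spacer)
          pos <- pos + nchar(spacer)
        }
      }
      parts <- c(parts, random_dna(flank_len))
      ctg <- paste(parts, collapse = "")
      strand <- if (runif(1) < minus_strand_prob) "-" else "+"
      if (strand == "-") {
        L <- nchar(ctg)
        ctg <- .revcomp(ctg)
        new_starts <- L - ends + 1L
        ends <- L - starts + 1L
        starts <- new_starts
      }
      contigs[a] <- ctg
      loci[[a]] <- data.frame(
        contig = paste0("array_", a), start = starts, end = ends,
        strand = strand, locus_id = locus_id + seq_len(genes_per_array))
      locus_id <- locus_id + genes_per_array
    }
    genome <- Biostrings::DNAStringSet(contigs)
    names(genome) <- paste0("array_", seq_len(n_arrays))
    gene_loci <- do.call(rbind, loci)
    gene_loci <- gene_loci[order(gene_loci$contig, gene_loci$start), ]
    rownames(gene_loci) <- NULL
    list(genome = genome, gene_loci = gene_loci)
  })
}

#' Mutate a sequence with substitutions and single-nt indels
#'
#' Each site is substituted with probability `substitution_rate`
#' (always to a different base) and independently hit by an indel event
#' with probability `indel_rate` (equal odds of a 1-nt deletion or a
#' 1-nt random insertion after the site).
#'
#' @param sequence DNA string.
#' @param substitution_rate Substitutions per site, in `[0, 1)`.
#' @param indel_rate Indel events per site, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return The mutated DNA string.
#' @export
apply_divergence <- function(sequence, substitution_rate = 0,
                             indel_rate = 0, seed = NULL) {
  sequence <- .assert_dna(sequence)
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  if (substitution_rate == 0 && indel_rate == 0) return(sequence)
  with_seed(seed, {
    bases <- strsplit(sequence, "")[[1]]
    n <- length(bases)
    if (substitution_rate > 0) {
      hit <- which(runif(n) < substitution_rate & bases != "N")
      if (length(hit)) {
        alt <- c("A", "C", "G", "T")
        bases[hit] <- vapply(bases[hit], function(b)
          sample(setdiff(alt, b), 1L), character(1))
      }
    }
    if (indel_rate > 0) {
      ev <- which(runif(n) < indel_rate)
      if (length(ev)) {
        del <- runif(length(ev)) < 0.5
        ins <- ev[!del]
        add <- character(n)
        if (length(ins))
          add[ins] <- sample(c("A", "C", "G", "T"), length(ins),
                             replace = TRUE)
        keep <- rep(TRUE, n)
        keep[ev[del]] <- FALSE
        bases <- paste0(ifelse(keep, bases, ""), add)
      }
    }
    paste(bases, collapse = "")
  })
}

# Build the post-insertion locus string in target sense.
# locus_seq: target-sense locus; s: bottom cut; t: top offset;
# elements: character vector, first = innermost (3'-most) copy.
# Returns list(seq, elem_start, elem_end): target-sense 1-based intervals
# of each element (same order as `elements`).
.compose_locus <- function(locus_seq, s, t, elements) {
  L <- nchar(locus_seq)
  if (t < 0 && -t > s)
    stop("deletion extends past the target 5' end (|top_offset| > bottom_cut)")
  left <- substr(locus_seq, 1L, s + t)          # includes dup block if t > 0
  right <- substr(locus_seq, s + 1L, L)
  mid <- paste(rev(elements), collapse = "")    # outermost copy first
  lens <- nchar(elements)
  # elements appear reversed in mid; compute each start
  offs <- cumsum(c(0L, rev(lens)))[seq_along(lens)]
  starts_in_mid <- rev(offs) + 1L               # back to input order
  elem_start <- nchar(left) + starts_in_mid
  elem_end <- elem_start + lens - 1L
  list(seq = paste0(left, mid, right), elem_start = elem_start,
       elem_end = elem_end)
}

#' Insert element copies into a genome with known ground truth
#'
#' Places copies of each family according to its [family_spec()]:
#' on-target copies at unoccupied target-gene loci using the family's
#' cleavage geometry (TSD, blunt, or 5' target deletion), tandem-nested
#' copies 5' of a resident copy at an occupied locus, and off-target
#' copies at uniform random background positions (geometry applied
#' mechanically at the arbitrary site). On-target copies inherit the
#' locus strand; off-target copies get a random strand. Copies may be
#' 5'-truncated and are diverged per their family parameters before
#' insertion.
#'
#' @param genome DNAStringSet (or character vector) of contigs.
#' @param gene_loci Locus table from [build_target_arrays()].
#' @param specs A `family_spec` or list of them.
#' @param seed Optional integer seed.
#' @param allow_spillover Permit deletions past the target 5' end.
#' @return A list with `genome` (mutated DNAStringSet) and `truths`
#'   (data.frame: copy_id, family, contig, start, end, strand, tsd_len,
#'   deletion_len, truncated_5prime_by, on_target, nested_in, locus_id,
#'   top_offset). Coordinates are 1-based closed intervals of the
#'   inserted element in the mutated genome.
#' @export
insert_elements <- function(genome, gene_loci, specs, seed = NULL,
                            allow_spillover = FALSE) {
  genome <- .as_genome(genome)
  if (inherits(specs, "family_spec")) specs <- list(specs)
  with_seed(seed, {
    # --- plan all copies -------------------------------------------------
    plan <- list()
    free <- gene_loci$locus_id
    occupied <- integer(0)
    copy_id <- 0L
    for (sp in specs) {
      t <- sp$geometry$top_offset
      s <- sp$geometry$bottom_cut
      if (t < 0 && -t > s && !allow_spillover)
        stop("geometry deletes beyond the target 5' end; ",
             "set allow_spillover = TRUE to permit")
      for (i in seq_len(sp$n_copies)) {
        copy_id <- copy_id + 1L
        elem <- sp$consensus
        trunc <- 0L
        if (runif(1) < sp$truncation_prob) {
          trunc <- sample.int(
            max(1L, floor(sp$truncation_max_frac * nchar(elem))), 1L)
          elem <- substr(elem, trunc + 1L, nchar(elem))
        }
        elem <- apply_divergence(elem, sp$divergence, sp$indel_rate)
        off <- runif(1) < sp$off_target_rate
        nested <- !off && runif(1) < sp$nesting_rate && length(occupied) > 0
        if (!off && !nested) {
          if (!length(free)) {
            if (sp$nesting_rate > 0 && length(occupied)) nested <- TRUE
            else stop("no unoccupied target-gene locus left for family ",
                      sp$name)
          }
        }
        locus <- NA_integer_
        if (!off) {
          if (nested) {
            locus <- occupied[sample.int(length(occupied), 1L)]
          } else {
            locus <- free[sample.int(length(free), 1L)]
            free <- setdiff(free, locus)
            occupied <- c(occupied, locus)
          }
        }
        plan[[copy_id]] <- list(copy_id = copy_id, family = sp$name,
                                elem = elem, trunc = trunc, t = t, s = s,
                                off = off, locus = as.integer(locus))
      }
    }
    if (!length(plan)) {
      return(list(genome = genome,
                  truths = .empty_truths()))
    }
    # --- per-locus edits -------------------------------------------------
    edits <- list()   # each: contig, start, end (replaced interval), repl,
                      # per-element target-sense offsets + metadata
    on_plan <- plan[!vapply(plan, `[[`, TRUE, "off")]
    by_locus <- split(on_plan, vapply(on_plan, function(p)
      as.integer(p$locus), integer(1)))
    for (lname in names(by_locus)) {
      copies <- by_locus[[lname]]
      li <- gene_loci[gene_loci$locus_id == as.integer(lname), ]
      locus_seq <- .subseq_chr(genome, li$contig, li$start, li$end)
      if (li$strand == "-") locus_seq <- .revcomp(locus_seq)
      # first (primary) copy defines geometry; later ones nest 5' of it
      prim <- copies[[1L]]
      elems <- vapply(copies, `[[`, "", "elem")
      comp <- .compose_locus(locus_seq, prim$s, prim$t, elems)
      new_seq <- comp$seq
      es <- comp$elem_start; ee <- comp$elem_end
      if (li$strand == "-") {
        Lp <- nchar(new_seq)
        new_seq <- .revcomp(new_seq)
        tmp <- Lp - ee + 1L
        ee <- Lp - es + 1L
        es <- tmp
      }
      edits[[length(edits) + 1L]] <- list(
        contig = li$contig, start = li$start, end = li$end, repl = new_seq,
        copies = copies, es = es, ee = ee, strand = li$strand,
        locus = as.integer(lname))
    }
    # --- off-target edits ------------------------------------------------
    offs <- plan[vapply(plan, `[[`, TRUE, "off")]
    used <- lapply(edits, function(e) c(e$contig, e$start, e$end))
    clen <- Biostrings::width(genome)
    names(clen) <- names(genome)
    for (p in offs) {
      for (try in 1:200) {
        ctg <- sample(names(genome), 1L,
                      prob = as.numeric(clen) / sum(as.numeric(clen)))
        c_pos <- sample.int(clen[[ctg]] - 1L, 1L)   # cut after c_pos
        win <- c(c_pos - abs(p$t) - 5L, c_pos + abs(p$t) + 5L)
        clash <- any(vapply(edits, function(e)
          e$contig == ctg && win[2] >= e$start - 60L && win[1] <= e$end + 60L,
          TRUE))
        clash <- clash || any(gene_loci$contig == ctg &
                                win[2] >= gene_loci$start - 60L &
                                win[1] <= gene_loci$end + 60L)
        if (!clash) break
        if (try == 200) stop("could not place off-target copy")
      }
      strand <- if (runif(1) < 0.5) "-" else "+"
      eseq <- if (strand == "-") .revcomp(p$elem) else p$elem
      t <- p$t
      a <- c_pos + min(t, 0L) + 1L           # replaced interval [a..c_pos]
      dup <- if (t > 0) .subseq_chr(genome, ctg, c_pos + 1L, c_pos + t) else ""
      repl <- paste0(dup, eseq)
      es <- nchar(dup) + 1L
      edits[[length(edits) + 1L]] <- list(
        contig = ctg, start = a, end = c_pos, repl = repl,
        copies = list(p), es = es, ee = es + nchar(eseq) - 1L,
        strand = strand, locus = NA_integer_)
    }
    # --- apply edits right-to-left per contig ----------------------------
    out <- as.character(genome)
    names(out) <- names(genome)
    truths <- list()
    for (ctg in names(out)) {
      idx <- which(vapply(edits, `[[`, "", "contig") == ctg)
      if (!length(idx)) next
      starts <- vapply(edits[idx], `[[`, 0, "start")
      idx <- idx[order(starts, decreasing = TRUE)]
      seqc <- out[[ctg]]
      # final-coordinate offset for each edit = sum of deltas to its left
      ord_asc <- rev(idx)
      deltas <- vapply(edits[ord_asc], function(e)
        nchar(e$repl) - (e$end - e$start + 1L), 0)
      shifts <- cumsum(c(0, deltas))[seq_along(ord_asc)]
      names(shifts) <- as.character(ord_asc)
      for (ei in idx) {
        e <- edits[[ei]]
        pre <- if (e$start > 1L) substr(seqc, 1L, e$start - 1L) else ""
        post <- substr(seqc, e$end + 1L, nchar(seqc))
        seqc <- paste0(pre, e$repl, post)
        shift <- shifts[[as.character(ei)]]
        base <- e$start - 1L + shift
        for (k in seq_along(e$copies)) {
          p <- e$copies[[k]]
          nested_in <- if (k > 1L) e$copies[[k - 1L]]$copy_id else NA_integer_
          tsd <- if (k == 1L && p$t > 0) p$t else 0L
          del <- if (k == 1L && p$t < 0) -p$t else 0L
          truths[[length(truths) + 1L]] <- data.frame(
            copy_id = p$copy_id, family = p$family, contig = ctg,
            start = base + e$es[k], end = base + e$ee[k],
            strand = e$strand, tsd_len = tsd, deletion_len = del,
            truncated_5prime_by = p$trunc, on_target = !p$off,
            nested_in = nested_in, locus_id = e$locus,
            top_offset = p$t)
        }
      }
      out[[ctg]] <- seqc
    }
    truths <- do.call(rbind, truths)
    truths <- truths[order(truths$copy_id), ]
    rownames(truths) <- NULL
    genome2 <- Biostrings::DNAStringSet(out)
    list(genome = genome2, truths = truths)
  })
}

.empty_truths <- function() {
  data.frame(copy_id = integer(), family = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             tsd_len = integer(), deletion_len = integer(),
             truncated_5prime_by = integer(), on_target = logical(),
             nested_in = integer(), locus_id = integer(),
             top_offset = integer())
}

#' One-call genome simulation
#'
#' Convenience wrapper: build target-gene arrays, insert elements, and
#' return genome, locus table, truth table and the echoed configuration.
#'
#' @param model A [target_gene_model()].
#' @param specs A `family_spec` or list of them.
#' @param n_arrays,genes_per_array,flank_len,minus_strand_prob,
#'   spacer_len_range,spacer_divergence Passed to [build_target_arrays()].
#' @param seed Integer seed governing the whole simulation.
#' @return A list: genome, gene_loci, truths, config.
#' @export
simulate_genome <- function(model, specs, n_arrays = 4L,
                            genes_per_array = 5L, flank_len = 500L,
                            minus_strand_prob = 0.5,
                            spacer_len_range = c(150L, 400L),
                            spacer_divergence = 0.3, seed = NULL) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  with_seed(seed, {
    arr <- build_target_arrays(model, n_arrays = n_arrays,
                               genes_per_array = genes_per_array,
                               spacer_len_range = spacer_len_range,
                               spacer_divergence = spacer_divergence,
                               flank_len = flank_len,
                               minus_strand_prob = minus_strand_prob)
    ins <- insert_elements(arr$genome, arr$gene_loci, specs)
    config <- list(
      model = list(name = model$name, length = model$length,
                   functional_5prime_len = model$functional_5prime_len,
                   insertion_site = model$insertion_site),
      n_arrays = n_arrays, genes_per_array = genes_per_array,
      flank_len = flank_len, minus_strand_prob = minus_strand_prob,
      spacer_len_range = as.integer(spacer_len_range),
      spacer_divergence = spacer_divergence, seed = seed,
      families = lapply(specs, function(sp)
        list(name = sp$name, n_copies = sp$n_copies,
             bottom_cut = sp$geometry$bottom_cut,
             top_offset = sp$geometry$top_offset,
             truncation_prob = sp$truncation_prob,
             divergence = sp$divergence, indel_rate = sp$indel_rate,
             off_target_rate = sp$off_target_rate,
             nesting_rate = sp$nesting_rate)))
    list(genome = ins$genome, gene_loci = arr$gene_loci,
         truths = ins$truths, config = config)
  })
}

#' Write simulation outputs to a directory
#'
#' Writes `genome.fa`, a BED-like `truths.tsv` (0-based half-open
#' start/end), `gene_loci.tsv`, and a `config.yaml` echo.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  tr <- sim$truths
  tr$start <- tr$start - 1L   # 0-based half-open on disk
  utils::write.table(tr, file.path(dir, "truths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gl <- sim$gene_loci
  gl$start <- gl$start - 1L
  utils::write.table(gl, file.path(dir, "gene_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
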