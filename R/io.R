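# FASTA readers for the pipeline's external inputs.

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return A named DNAStringSet.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read element families from FASTA
#'
#' One [element_family()] per record; record names become family names.
#'
#' @param path FASTA file of consensus sequences.
#' @param anchor_3prime_len 3' anchor length (default 70).
#' @return A list of `element_family` objects.
#' @export
read_families_fasta <- function(path, anchor_3prime_len = 70L) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  lapply(seq_along(x), function(i)
    element_family(names(x)[i], as.character(x[[i]]),
                   min(anchor_3prime_len, length(x[[i]]))))
}

#' Read a target-gene model from FASTA
#'
#' The first record becomes the model sequence.
#'
#' @param path FASTA file.
#' @param functional_5prime_len,insertion_site See [target_gene_model()].
#' @return A `target_gene_model`.
#' @export
read_target_model_fasta <- function(path, functional_5prime_len = 50L,
                                    insertion_site = 38L) {
  x <- Biostrings::readDNAStringSet(path)
  target_gene_model(sub("\\s.*$", "", names(x)[1]),
                    as.character(x[[1]]),
                    functional_5prime_len, insertion_site)
}
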