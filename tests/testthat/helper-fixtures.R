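# Small fixtures shared across test files; everything is generated in
# code under fixed seeds.

fix_model <- function() example_u2_model()

# A compact family for fast tests.
fix_family <- function(name = "famA", geometry = geometry_blunt(),
                       length = 400L, seed = 101L, ...) {
  synthetic_family(name, length = length, seed = seed,
                   geometry = geometry, ...)
}

# Genome with a single plus-strand array, no background strand flips:
# coordinates are easy to reason about.
fix_sim <- function(specs, n_arrays = 2L, genes_per_array = 5L,
                    seed = 5L, flank_len = 300L, minus_strand_prob = 0) {
  simulate_genome(fix_model(), specs, n_arrays = n_arrays,
                  genes_per_array = genes_per_array, flank_len = flank_len,
                  minus_strand_prob = minus_strand_prob, seed = seed)
}
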