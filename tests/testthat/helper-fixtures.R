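# Shared fixtures: tiny fragment maps and interaction tables built in code.

# Uniform fragment map: `n` fragments of `width` bp per chromosome.
toy_fragments <- function(n = 10, width = 1000, chroms = "chr1") {
  out <- dplyr::bind_rows(lapply(chroms, function(ch) {
    tibble::tibble(chrom = ch, start = (seq_len(n) - 1) * width,
                   end = seq_len(n) * width)
  }))
  out$frag_id <- seq_len(nrow(out))
  dplyr::select(out, frag_id, chrom, start, end)
}

toy_interactions <- function(bait, prey, cell = "MCF7", capture = "PC",
                             score = 6, mppc = NA_real_, fragments) {
  x <- tibble::tibble(
    bait_frag = bait, prey_frag = prey, cell_line = cell, capture = capture,
    chicago_score = score, mppc = mppc
  )
  add_interaction_distance(x, fragments)
}

# Small simulation configs used across tests: a single-chromosome genome
# with two cell lines (one per latent group).
two_line_panel <- function() {
  tibble::tibble(cell_line = c("A", "B"), group = c("ERpos", "ERneg"))
}

small_config <- function(seed, ...) {
  sim_config(
    seed = seed, n_chrom = 1, chrom_length = 1.5e6, n_regions = 2,
    signals_per_region = 1, ccvs_per_signal = 4, n_genes = 12,
    cell_lines = two_line_panel(), ...
  )
}

# Random DNA of length n (fixed composition draw from the current RNG).
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

located_variants <- function(ds) {
  v <- ds$variants
  v$frag <- locate_fragment(ds$fragments, v$chrom, v$pos)
  v
}
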