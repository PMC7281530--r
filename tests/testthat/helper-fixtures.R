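# Shared fixtures: everything is built in code, no files on disk.

# A small hand-made library with known sequences.
manual_library <- function(seqs, genes = NULL) {
  n <- length(seqs)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(n))
  lib <- data.frame(hairpin_id = sprintf("sh%03d", seq_len(n)),
                    gene_symbol = genes,
                    hairpin_seq = seqs,
                    stringsAsFactors = FALSE)
  class(lib) <- c("shrna_library", "data.frame")
  lib
}

# A compact amplicon model (short segments keep read simulation fast).
tiny_amplicon <- function(sample_ids = c("ctrl", "drug"), seed = 42) {
  amplicon_model(generate_barcodes(sample_ids, barcode_len = 6,
                                   min_dist = 4, seed = seed),
                 fwd_len = 8, insert_len = 40, rev_len = 16,
                 adaptor_len = 6, barcode_len = 6, hairpin_offset = 5,
                 seed = seed)
}

# Build a screen_counts object from a raw matrix with minimal ceremony.
manual_counts <- function(counts, condition, library) {
  sample_id <- colnames(counts)
  replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  screen_counts(counts,
                data.frame(sample_id = sample_id, condition = condition,
                           replicate = replicate, stringsAsFactors = FALSE),
                library)
}

# Independent most-synergistic-area oracle: scan every window explicitly.
brute_force_msa <- function(delta, window = 3) {
  best <- -Inf
  for (i in seq_len(nrow(delta) - window + 1)) {
    for (j in seq_len(ncol(delta) - window + 1)) {
      tot <- 0
      for (a in 0:(window - 1)) {
        for (b in 0:(window - 1)) {
          tot <- tot + delta[i + a, j + b]
        }
      }
      best <- max(best, tot / window^2)
    }
  }
  best
}

# Mutate one position of a read sequence to a different base.
mutate_base <- function(seq, pos) {
  bases <- c("A", "C", "G", "T")
  old <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- setdiff(bases, old)[1]
  seq
}
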