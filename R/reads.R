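#' Simulate barcoded amplicon reads for one sample
#'
#' Draws `depth` hairpins from the abundance profile by multinomial
#' sampling and emits one full-length single-end FASTQ read per draw.
#' Each read is `fwd segment + insert (hairpin spliced in at the model's
#' fixed offset) + rev segment (spacer + adaptor + sample barcode)`;
#' the exact per-hairpin tally used is returned so downstream recovery
#' tests never have to re-infer the truth. Optional sequencing noise is
#' limited to uniform base substitutions; quality strings are constant.
#'
#' @param library A `shrna_library`.
#' @param profile Abundance profile keyed to `library` (see
#'   [generate_abundance()]).
#' @param amplicon An [amplicon_model()] whose barcode map contains
#'   `sample_id`.
#' @param sample_id Sample to emit (selects the barcode).
#' @param depth Number of reads (>= 0).
#' @param path Output FASTQ path; `.gz` suffix writes gzip.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param append Append to an existing plain-text FASTQ (not supported
#'   for `.gz` output); used to pool several samples into one file.
#' @return Invisibly, a list with `tally` (named integer vector over all
#'   library hairpins, summing to `depth`), `sample_id`, `depth`, `path`.
#' @examples
#' lib <- generate_library(20, 2, seed = 1)
#' p <- generate_abundance(lib, 0.5, seed = 2)
#' amp <- amplicon_model(generate_barcodes("s1", seed = 3))
#' fq <- tempfile(fileext = ".fastq")
#' sim <- generate_reads(lib, p, amp, "s1", depth = 100, path = fq, seed = 4)
#' sum(sim$tally)
#' @export
generate_reads <- function(library, profile, amplicon, sample_id, depth,
                           path, error_rate = 0, seed = NULL,
                           append = FALSE) {
  validate_library(library)
  validate_profile(profile, library)
  stopifnot(inherits(amplicon, "amplicon_model"))
  if (!sample_id %in% names(amplicon$barcodes)) {
    stop("unknown sample_id `", sample_id, "`: not in the barcode map",
         call. = FALSE)
  }
  assert_scalar_count(depth, "depth", min = 0)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1) {
    stop("`error_rate` must be in [0, 1)", call. = FALSE)
  }
  gz <- grepl("\\.gz$", path)
  if (append && gz) {
    stop("append = TRUE is not supported for gzip output", call. = FALSE)
  }
  hairpin_len <- nchar(library$hairpin_seq[1])
  hairpin_window(amplicon, hairpin_len)  # errors if the hairpin cannot fit
  total_len <- amplicon_total_length(amplicon)

  with_rng_seed(seed, {
    tally <- as.integer(stats::rmultinom(1L, depth, profile))
    idx <- rep.int(seq_len(nrow(library)), tally)
    if (depth > 1L) idx <- sample(idx)

    head_seq <- paste0(amplicon$fwd_seq,
                       substr(amplicon$insert_ctx, 1L,
                              amplicon$hairpin_offset))
    tail_seq <- paste0(
      substr(amplicon$insert_ctx,
             amplicon$hairpin_offset + hairpin_len + 1L,
             amplicon$insert_len),
      amplicon$rev_spacer, amplicon$adaptor_seq,
      amplicon$barcodes[[sample_id]])
    seqs <- paste0(head_seq, library$hairpin_seq[idx], tail_seq)

    if (error_rate > 0 && depth > 0) {
      n_err <- stats::rbinom(depth, total_len, error_rate)
      for (r in which(n_err > 0L)) {
        chars <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
        pos <- sample.int(total_len, n_err[r])
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, "")
        seqs[r] <- paste(chars, collapse = "")
      }
    }

    con <- if (gz) gzfile(path, "wb") else file(path, if (append) "a" else "w")
    on.exit(close(con), add = TRUE)
    if (depth > 0) {
      ids <- sprintf("@%s:%07d", sample_id, seq_len(depth))
      qual <- strrep("I", total_len)
      writeLines(as.vector(rbind(ids, seqs, "+", qual)), con)
    }
    invisible(list(tally = stats::setNames(tally, library$hairpin_id),
                   sample_id = sample_id, depth = as.integer(depth),
                   path = path))
  })
}
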