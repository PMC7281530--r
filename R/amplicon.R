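#' Describe the sequenced shRNA amplicon
#'
#' Amplicon reads span a PCR product with a fixed segment structure:
#' a forward primer segment, a vector-derived insert carrying the
#' hairpin at a fixed offset, and a reverse primer segment whose tail
#' contains a sequencing adaptor followed by the per-sample barcode.
#' The defaults describe a ~634 bp product: 53 nt forward + 513 nt
#' insert + 68 nt reverse (of which 30 nt adaptor and 9 nt barcode).
#'
#' Fixed context sequences (forward segment, insert backbone, spacer and
#' adaptor) are drawn deterministically from `seed`, so a model built
#' with the same arguments always emits and parses identical reads. The
#' barcode occupies the last `barcode_len` nt of the read; the hairpin
#' occupies `hairpin_offset + 1 .. hairpin_offset + hairpin length`
#' within the insert.
#'
#' @param barcodes Named character vector: `sample_id -> barcode`.
#'   Barcodes must be unique, of length `barcode_len`, over A/C/G/T.
#' @param fwd_len,insert_len,rev_len Segment lengths in nt.
#' @param adaptor_len,barcode_len Lengths of the adaptor and barcode
#'   within the reverse segment (`rev_len >= adaptor_len + barcode_len`).
#' @param hairpin_offset 0-based offset of the hairpin within the insert.
#' @param seed Seed for the fixed context sequences.
#' @return An object of class `amplicon_model`.
#' @examples
#' bc <- generate_barcodes(c("ctrl_1", "dox_1"), seed = 1)
#' amp <- amplicon_model(bc)
#' amplicon_total_length(amp)
#' @export
amplicon_model <- function(barcodes, fwd_len = 53, insert_len = 513,
                           rev_len = 68, adaptor_len = 30, barcode_len = 9,
                           hairpin_offset = 100, seed = 1) {
  for (nm in c("fwd_len", "insert_len", "rev_len", "adaptor_len",
               "barcode_len", "hairpin_offset")) {
    assert_scalar_count(get(nm), nm, min = 0)
  }
  if (rev_len < adaptor_len + barcode_len) {
    stop("rev_len must be >= adaptor_len + barcode_len", call. = FALSE)
  }
  if (hairpin_offset >= insert_len && insert_len > 0) {
    stop("hairpin_offset must lie within the insert", call. = FALSE)
  }
  if (is.null(names(barcodes)) || any(names(barcodes) == "")) {
    stop("`barcodes` must be a named character vector (sample_id -> barcode)",
         call. = FALSE)
  }
  if (anyDuplicated(names(barcodes)) || anyDuplicated(barcodes)) {
    stop("sample ids and barcodes must be unique", call. = FALSE)
  }
  if (any(nchar(barcodes) != barcode_len)) {
    stop("all barcodes must have length barcode_len = ", barcode_len,
         call. = FALSE)
  }
  if (any(grepl("[^ACGT]", barcodes))) {
    stop("barcodes must use the alphabet A/C/G/T", call. = FALSE)
  }
  ctx <- with_rng_seed(seed, list(
    fwd_seq = random_dna(1L, fwd_len),
    insert_ctx = random_dna(1L, insert_len),
    rev_spacer = random_dna(1L, rev_len - adaptor_len - barcode_len),
    adaptor_seq = random_dna(1L, adaptor_len)
  ))
  structure(
    c(list(barcodes = barcodes, fwd_len = as.integer(fwd_len),
           insert_len = as.integer(insert_len), rev_len = as.integer(rev_len),
           adaptor_len = as.integer(adaptor_len),
           barcode_len = as.integer(barcode_len),
           hairpin_offset = as.integer(hairpin_offset)),
      ctx),
    class = "amplicon_model"
  )
}

#' Total amplicon length
#'
#' Sum of the forward, insert and reverse segment lengths. With the
#' default segment model, 53 + 513 + 68 = 634 nt.
#'
#' @param fwd_len An `amplicon_model`, or the forward segment length.
#' @param insert_len,rev_len Insert and reverse lengths when the first
#'   argument is numeric.
#' @return Total length in nt.
#' @examples
#' amplicon_total_length(53, 513, 68)
#' @export
amplicon_total_length <- function(fwd_len, insert_len = NULL, rev_len = NULL) {
  if (inherits(fwd_len, "amplicon_model")) {
    return(fwd_len$fwd_len + fwd_len$insert_len + fwd_len$rev_len)
  }
  stopifnot(is.numeric(fwd_len), is.numeric(insert_len), is.numeric(rev_len),
            fwd_len >= 0, insert_len >= 0, rev_len >= 0)
  fwd_len + insert_len + rev_len
}

#' @export
print.amplicon_model <- function(x, ...) {
  cat(sprintf(
    "amplicon model: %d nt total (fwd %d + insert %d + rev %d; adaptor %d, barcode %d)\n",
    amplicon_total_length(x), x$fwd_len, x$insert_len, x$rev_len,
    x$adaptor_len, x$barcode_len))
  cat(sprintf("samples: %s\n", paste(names(x$barcodes), collapse = ", ")))
  invisible(x)
}

#' 1-based position of the barcode window within a read
#' @noRd
barcode_window <- function(amplicon) {
  total <- amplicon_total_length(amplicon)
  c(start = total - amplicon$barcode_len + 1L, end = total)
}

#' 1-based position of the hairpin window within a read
#' @noRd
hairpin_window <- function(amplicon, hairpin_len) {
  if (amplicon$hairpin_offset + hairpin_len > amplicon$insert_len) {
    stop("hairpin of length ", hairpin_len,
         " does not fit in the insert at offset ", amplicon$hairpin_offset,
         call. = FALSE)
  }
  start <- amplicon$fwd_len + amplicon$hairpin_offset + 1L
  c(start = start, end = start + hairpin_len - 1L)
}

#' Minimum pairwise Hamming distance among barcodes
#' @noRd
barcode_min_distance <- function(barcodes) {
  k <- length(barcodes)
  if (k < 2L) return(Inf)
  d <- Inf
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      d <- min(d, hamming(barcodes[i], barcodes[j]))
    }
  }
  d
}

#' Generate well-separated sample barcodes
#'
#' Draws random barcodes whose pairwise Hamming distance is at least
#' `min_dist`, so that demultiplexing with up to
#' `floor((min_dist - 1) / 2)` mismatches is unambiguous.
#'
#' @param sample_ids Character vector of sample names.
#' @param barcode_len Barcode length in nt (default 9).
#' @param min_dist Minimum pairwise Hamming distance (default 3,
#'   supporting 1-mismatch demultiplexing).
#' @param seed Optional integer seed.
#' @param max_tries Draw attempts before giving up.
#' @return Named character vector `sample_id -> barcode`.
#' @export
generate_barcodes <- function(sample_ids, barcode_len = 9, min_dist = 3,
                              seed = NULL, max_tries = 1000) {
  stopifnot(length(sample_ids) >= 1, !anyDuplicated(sample_ids))
  assert_scalar_count(barcode_len, "barcode_len", min = 1)
  with_rng_seed(seed, {
    picked <- character(0)
    tries <- 0L
    while (length(picked) < length(sample_ids)) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not find ", length(sample_ids), " barcodes of length ",
             barcode_len, " with pairwise distance >= ", min_dist,
             call. = FALSE)
      }
      cand <- random_dna(1L, barcode_len)
      if (all(vapply(picked, hamming, 0L, b = cand) >= min_dist)) {
        picked <- c(picked, cand)
      }
    }
    stats::setNames(picked, sample_ids)
  })
}
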