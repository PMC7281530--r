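#' Hairpin-by-sample count container
#'
#' The central screen object, in the spirit of edgeR's `DGEList`: an
#' integer count matrix with one row per library hairpin (zero rows are
#' retained so "lost" calls stay well defined), a sample sheet, and the
#' hairpin library the rows are keyed on.
#'
#' @param counts Non-negative integer matrix, rownames = hairpin IDs,
#'   colnames = sample IDs.
#' @param samples Data frame with columns `sample_id`, `condition`,
#'   `replicate` (one row per count column, same order).
#' @param library The `shrna_library` the rows are keyed on.
#' @return An object of class `screen_counts`.
#' @export
screen_counts <- function(counts, samples, library) {
  validate_library(library)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs hairpin rownames and sample colnames", call. = FALSE)
  }
  if (!setequal(rownames(counts), library$hairpin_id) ||
      anyDuplicated(rownames(counts))) {
    missing <- setdiff(library$hairpin_id, rownames(counts))
    extra <- setdiff(rownames(counts), library$hairpin_id)
    stop("count rows must match the library hairpins exactly",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5),
                                           collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(utils::head(extra, 5),
                                         collapse = ", ")),
         call. = FALSE)
  }
  counts <- counts[library$hairpin_id, , drop = FALSE]
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  need <- c("sample_id", "condition", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop("`samples` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!identical(as.character(samples$sample_id), colnames(counts))) {
    stop("samples$sample_id must match the count columns in order",
         call. = FALSE)
  }
  structure(list(counts = counts, samples = samples, library = library),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d hairpins x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.screen_counts <- function(x) dim(x$counts)

#' Count hairpins in amplicon reads
#'
#' Demultiplexes FASTQ reads by the sample barcode at the amplicon
#' model's fixed offset, identifies the hairpin by extracting the
#' fixed-offset hairpin window and matching it against the library
#' (exact, then Hamming within `max_hairpin_mismatch`), and tabulates a
#' hairpin-by-sample count matrix. Ties at the same best distance are
#' counted as ambiguous, never assigned; reads shorter than the model
#' or matching no barcode within tolerance are counted as unassigned.
#' No read is silently dropped: the report categories partition the
#' reads seen.
#'
#' @param fastq Character vector of FASTQ paths (plain or gzip); all
#'   files are pooled before demultiplexing.
#' @param library A `shrna_library`.
#' @param amplicon An [amplicon_model()]. Barcodes must be separable:
#'   pairwise Hamming distance strictly greater than
#'   `2 * max_barcode_mismatch`.
#' @param samples Optional sample sheet (`sample_id`, `condition`,
#'   `replicate`); defaults to one condition per barcode, replicate 1.
#' @param max_barcode_mismatch,max_hairpin_mismatch Mismatch tolerances
#'   (defaults 1 and 2).
#' @return List with `counts` (a [screen_counts()]) and `report` (a
#'   `quant_report`: per-sample and overall read-category totals).
#' @export
count_hairpins <- function(fastq, library, amplicon, samples = NULL,
                           max_barcode_mismatch = 1,
                           max_hairpin_mismatch = 2) {
  validate_library(library)
  stopifnot(inherits(amplicon, "amplicon_model"))
  assert_scalar_count(max_barcode_mismatch, "max_barcode_mismatch", 0)
  assert_scalar_count(max_hairpin_mismatch, "max_hairpin_mismatch", 0)
  barcodes <- amplicon$barcodes
  if (barcode_min_distance(barcodes) <= 2 * max_barcode_mismatch) {
    stop("barcode map is not separable at max_barcode_mismatch = ",
         max_barcode_mismatch,
         ": pairwise Hamming distance must exceed ",
         2 * max_barcode_mismatch, call. = FALSE)
  }
  hairpin_len <- nchar(library$hairpin_seq[1])
  hw <- hairpin_window(amplicon, hairpin_len)
  bw <- barcode_window(amplicon)
  total_len <- amplicon_total_length(amplicon)

  reads <- lapply(fastq, function(f) {
    tryCatch(Biostrings::readDNAStringSet(f, format = "fastq"),
             error = function(e) {
               stop("malformed FASTQ `", f, "`: ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  chars <- unlist(lapply(reads, function(r) unname(as.character(r))),
                  use.names = FALSE)
  n_seen <- length(chars)
  long_enough <- nchar(chars) >= total_len

  k <- length(barcodes)
  nlib <- nrow(library)
  sample_idx <- rep(NA_integer_, n_seen)
  bc_amb <- rep(FALSE, n_seen)
  if (any(long_enough)) {
    bc <- substr(chars[long_enough], bw["start"], bw["end"])
    m <- match_with_mismatch(bc, unname(barcodes), max_barcode_mismatch)
    sample_idx[long_enough] <- m$index
    bc_amb[long_enough] <- m$ambiguous
  }

  hp_idx <- rep(NA_integer_, n_seen)
  hp_amb <- rep(FALSE, n_seen)
  has_sample <- !is.na(sample_idx)
  if (any(has_sample)) {
    hp <- substr(chars[has_sample], hw["start"], hw["end"])
    m <- match_with_mismatch(hp, library$hairpin_seq, max_hairpin_mismatch)
    hp_idx[has_sample] <- m$index
    hp_amb[has_sample] <- m$ambiguous
  }

  assigned <- has_sample & !is.na(hp_idx)
  counts <- matrix(0L, nrow = nlib, ncol = k,
                   dimnames = list(library$hairpin_id, names(barcodes)))
  if (any(assigned)) {
    tab <- table(factor(hp_idx[assigned], levels = seq_len(nlib)),
                 factor(sample_idx[assigned], levels = seq_len(k)))
    counts <- counts + as.integer(tab)
  }

  per_sample <- data.frame(
    sample_id = names(barcodes),
    barcode_assigned = as.integer(tabulate(sample_idx, k)),
    hairpin_assigned = as.integer(colSums(counts)),
    unassigned_hairpin = as.integer(
      tabulate(sample_idx[has_sample & is.na(hp_idx) & !hp_amb], k)),
    ambiguous_hairpin = as.integer(tabulate(sample_idx[hp_amb], k)),
    stringsAsFactors = FALSE
  )
  overall <- c(
    reads_seen = n_seen,
    too_short = sum(!long_enough),
    unassigned_barcode = sum(!has_sample & !bc_amb),
    ambiguous_barcode = sum(bc_amb),
    unassigned_hairpin = sum(has_sample & is.na(hp_idx) & !hp_amb),
    ambiguous_hairpin = sum(hp_amb),
    assigned = sum(assigned)
  )
  report <- structure(list(overall = overall, per_sample = per_sample),
                      class = "quant_report")

  if (is.null(samples)) {
    samples <- data.frame(sample_id = names(barcodes),
                          condition = names(barcodes),
                          replicate = 1L, stringsAsFactors = FALSE)
  }
  list(counts = screen_counts(counts, samples, library), report = report)
}

#' @export
print.quant_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "reads seen %d | assigned %d | unassigned barcode %d (of which too short %d) | ambiguous barcode %d | unassigned hairpin %d | ambiguous hairpin %d\n",
    o["reads_seen"], o["assigned"], o["unassigned_barcode"], o["too_short"],
    o["ambiguous_barcode"], o["unassigned_hairpin"], o["ambiguous_hairpin"]))
  print.data.frame(x$per_sample)
  invisible(x)
}

#' Write / read a hairpin count matrix as tab-separated text
#'
#' `write_counts` emits hairpins as rows and samples as columns with a
#' leading `hairpin_id` column; the round trip through `read_counts` is
#' lossless. `read_counts` validates the row set against the library:
#' a missing or unknown hairpin, a negative or non-integer value all
#' fail with the offending ID.
#'
#' @param x A [screen_counts()].
#' @param path File path.
#' @param library A `shrna_library` to validate against.
#' @param samples Optional sample sheet; defaults to condition =
#'   sample_id, replicate 1.
#' @return `write_counts` returns `path` invisibly; `read_counts` a
#'   [screen_counts()].
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "screen_counts"))
  df <- data.frame(hairpin_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, library, samples = NULL) {
  validate_library(library)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "hairpin_id") {
    stop("counts file must start with a `hairpin_id` column", call. = FALSE)
  }
  unknown <- setdiff(df$hairpin_id, library$hairpin_id)
  if (length(unknown)) {
    stop("counts file contains hairpins not in the library: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(library$hairpin_id, df$hairpin_id)
  if (length(missing)) {
    stop("counts file is missing library hairpins: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$hairpin_id
  bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid count for hairpin ", rownames(counts)[bad[1, 1]],
         " in sample ", colnames(counts)[bad[1, 2]],
         ": counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(counts),
                          condition = colnames(counts),
                          replicate = 1L, stringsAsFactors = FALSE)
  }
  screen_counts(counts, samples, library)
}

#' Write / read the sample sheet
#' @param samples Data frame (`sample_id`, `condition`, `replicate`).
#' @param path File path.
#' @return `write_samples` returns `path` invisibly; `read_samples` the
#'   sample sheet data frame.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
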