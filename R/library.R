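#' Generate a synthetic shRNA hairpin library
#'
#' Builds a hairpin catalogue of the kind used by pooled drop-out screens:
#' unique hairpin identifiers, target gene symbols (several hairpins may
#' target one gene) and unique fixed-length hairpin sequences over
#' \{A,C,G,T\}. The default dimensions can be chosen to mirror a boutique
#' polarity/EMP library of 4020 hairpins over 1677 genes (about 2.4
#' hairpins per gene).
#'
#' @param n_genes Number of distinct target genes (>= 1).
#' @param hairpins_per_gene Either a single integer (every gene gets that
#'   many hairpins) or an integer vector of length `n_genes` giving the
#'   per-gene hairpin count. Ignored when `n_hairpins` is supplied.
#' @param n_hairpins Optional total hairpin count. Every gene receives at
#'   least one hairpin and the remaining `n_hairpins - n_genes` hairpins
#'   are distributed over genes uniformly at random, producing a mixture
#'   of per-gene multiplicities with the requested mean.
#' @param seq_len Hairpin sequence length in nucleotides. At least 12 nt
#'   is recommended so that sequences stay well separated.
#' @param seed Optional integer seed; a fixed seed makes the library
#'   reproducible.
#' @param max_tries Maximum rounds of re-drawing duplicated sequences
#'   before giving up (guards against a sequence space that is too small).
#'
#' @return A data frame of class `shrna_library` with columns
#'   `hairpin_id`, `gene_symbol` and `hairpin_seq`.
#'
#' @examples
#' lib <- generate_library(n_genes = 10, hairpins_per_gene = 3, seed = 7)
#' nrow(lib)
#' @export
generate_library <- function(n_genes, hairpins_per_gene = 2, n_hairpins = NULL,
                             seq_len = 21, seed = NULL, max_tries = 50) {
  assert_scalar_count(n_genes, "n_genes", min = 1)
  assert_scalar_count(seq_len, "seq_len", min = 1)
  with_rng_seed(seed, {
    if (!is.null(n_hairpins)) {
      assert_scalar_count(n_hairpins, "n_hairpins", min = n_genes)
      extra <- n_hairpins - n_genes
      per_gene <- rep(1L, n_genes)
      if (extra > 0) {
        per_gene <- per_gene +
          tabulate(sample.int(n_genes, extra, replace = TRUE), n_genes)
      }
    } else if (length(hairpins_per_gene) == n_genes && n_genes > 1L) {
      per_gene <- vapply(hairpins_per_gene, assert_scalar_count, integer(1),
                         name = "hairpins_per_gene", min = 1)
    } else {
      assert_scalar_count(hairpins_per_gene, "hairpins_per_gene", min = 1)
      per_gene <- rep(as.integer(hairpins_per_gene), n_genes)
    }
    n <- sum(per_gene)
    if (4^seq_len < 4 * n) {
      stop("sequence space 4^seq_len is too small to hold ", n,
           " unique hairpins; increase `seq_len`", call. = FALSE)
    }
    genes <- sprintf("G%04d", seq_len(n_genes))
    gene_symbol <- rep(genes, per_gene)
    seqs <- random_dna(n, seq_len)
    tries <- 0L
    while (anyDuplicated(seqs)) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not draw ", n, " unique hairpin sequences of length ",
             seq_len, " after ", max_tries, " retries", call. = FALSE)
      }
      dup <- which(duplicated(seqs))
      seqs[dup] <- random_dna(length(dup), seq_len)
    }
    lib <- data.frame(
      hairpin_id = sprintf("sh%05d", seq_len(n)),
      gene_symbol = gene_symbol,
      hairpin_seq = seqs,
      stringsAsFactors = FALSE
    )
    class(lib) <- c("shrna_library", "data.frame")
    validate_library(lib)
    lib
  })
}

#' Validate a hairpin library
#'
#' Checks the invariants required for unambiguous counting: unique
#' hairpin IDs, unique sequences, a single sequence length, and the
#' \{A,C,G,T\} alphabet.
#' @param lib A `shrna_library` data frame (or any data frame with
#'   columns `hairpin_id`, `gene_symbol`, `hairpin_seq`).
#' @return `lib`, invisibly, or an error.
#' @export
validate_library <- function(lib) {
  need <- c("hairpin_id", "gene_symbol", "hairpin_seq")
  if (!all(need %in% names(lib))) {
    stop("library must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(lib) == 0L) stop("library is empty", call. = FALSE)
  if (anyDuplicated(lib$hairpin_id)) {
    stop("hairpin_id values must be unique", call. = FALSE)
  }
  if (anyDuplicated(lib$hairpin_seq)) {
    stop("hairpin_seq values must be unique", call. = FALSE)
  }
  len <- unique(nchar(lib$hairpin_seq))
  if (length(len) != 1L) {
    stop("all hairpin sequences must have the same length", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", lib$hairpin_seq))) {
    stop("hairpin sequences must use the alphabet A/C/G/T", call. = FALSE)
  }
  invisible(lib)
}

#' @export
print.shrna_library <- function(x, ...) {
  cat(sprintf("shRNA library: %d hairpins targeting %d genes (%d nt)\n",
              nrow(x), length(unique(x$gene_symbol)),
              nchar(x$hairpin_seq[1])))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Write / read a hairpin library as tab-separated text
#'
#' Three columns (`hairpin_id`, `gene_symbol`, `hairpin_seq`) with a
#' header row, UTF-8.
#' @param lib A `shrna_library`.
#' @param path File path.
#' @return `write_library` returns `path` invisibly; `read_library`
#'   returns a validated `shrna_library`.
#' @export
write_library <- function(lib, path) {
  validate_library(lib)
  utils::write.table(as.data.frame(lib)[c("hairpin_id", "gene_symbol",
                                          "hairpin_seq")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  class(lib) <- c("shrna_library", "data.frame")
  validate_library(lib)
  lib
}
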