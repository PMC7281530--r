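# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream.
#' @noRd
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Random DNA strings
#' @noRd
random_dna <- function(n, len) {
  if (n == 0L || len == 0L) {
    return(rep("", n))
  }
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Split equal-length strings into a character matrix (one row per string)
#' @noRd
string_matrix <- function(x, len) {
  if (length(x) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = len))
  }
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = len, byrow = TRUE)
}

#' Match query strings against a set of targets allowing substitutions
#'
#' Exact matches are resolved by hashing; the remainder by explicit Hamming
#' distance in chunks. Queries whose best distance exceeds `max_mm` are
#' unassigned (NA, ambiguous = FALSE); queries with two or more targets at
#' the same best distance within tolerance are ambiguous (NA, TRUE).
#'
#' @return list(index = integer (NA if unassigned/ambiguous),
#'              ambiguous = logical)
#' @noRd
match_with_mismatch <- function(query, targets, max_mm, chunk = 2000L) {
  nq <- length(query)
  idx <- match(query, targets)
  amb <- rep(FALSE, nq)
  if (max_mm <= 0L || all(!is.na(idx))) {
    return(list(index = idx, ambiguous = amb))
  }
  len <- nchar(targets[1])
  t_mat <- string_matrix(targets, len)
  todo <- which(is.na(idx) & nchar(query) == len)
  if (length(todo) == 0L) {
    return(list(index = idx, ambiguous = amb))
  }
  for (start in seq(1L, length(todo), by = chunk)) {
    rows <- todo[start:min(start + chunk - 1L, length(todo))]
    q_mat <- string_matrix(query[rows], len)
    d <- matrix(0L, nrow = length(rows), ncol = length(targets))
    for (pos in seq_len(len)) {
      d <- d + outer(q_mat[, pos], t_mat[, pos], "!=")
    }
    best_at <- max.col(-d, ties.method = "first")
    best <- d[cbind(seq_along(rows), best_at)]
    n_best <- rowSums(d == best)
    hit <- best <= max_mm
    idx[rows[hit & n_best == 1L]] <- best_at[hit & n_best == 1L]
    amb[rows[hit & n_best > 1L]] <- TRUE
  }
  list(index = idx, ambiguous = amb)
}

#' Stop unless a scalar numeric condition holds
#' @noRd
assert_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
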