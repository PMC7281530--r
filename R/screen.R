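#' Simulate a replicated treated-vs-untreated count matrix
#'
#' Draws multinomial counts per replicate directly from the abundance
#' profile (untreated arms) or from the profile with planted effects
#' applied (treated arms), bypassing read-level simulation when only
#' counts are needed. Optional between-replicate biological noise
#' perturbs each replicate's expected abundance log-normally so that
#' counts carry a chosen extra coefficient of variation on top of the
#' multinomial sampling noise.
#'
#' @param library A `shrna_library`.
#' @param profile Untreated abundance profile keyed to `library`.
#' @param effects A single [effect_spec()] or a list of them (one
#'   treated arm per spec; arm condition labels come from each spec).
#'   `NULL` simulates controls only.
#' @param depth Reads per sample (default 1e6, a typical per-sample
#'   sequencing depth for a ~4000-hairpin pool).
#' @param n_control,n_treated Replicates per arm (default 3, the
#'   triplicate design of a drop-out screen).
#' @param rep_cv Extra per-replicate abundance CV (0 = multinomial
#'   noise only).
#' @param control_condition Label for the untreated arm.
#' @param seed Optional integer seed.
#' @return A [screen_counts()] containing the untreated replicates
#'   followed by each treated arm.
#' @export
simulate_screen_counts <- function(library, profile, effects = NULL,
                                   depth = 1e6, n_control = 3, n_treated = 3,
                                   rep_cv = 0,
                                   control_condition = "untreated",
                                   seed = NULL) {
  validate_library(library)
  validate_profile(profile, library)
  assert_scalar_count(depth, "depth", min = 1)
  assert_scalar_count(n_control, "n_control", min = 1)
  assert_scalar_count(n_treated, "n_treated", min = 1)
  stopifnot(is.numeric(rep_cv), rep_cv >= 0)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  if (!is.null(effects)) {
    cond <- vapply(effects, function(e) as.character(attr(e, "condition")),
                   "")
    if (anyDuplicated(cond) || control_condition %in% cond) {
      stop("treatment arm conditions must be unique and differ from the ",
           "control condition", call. = FALSE)
    }
    names(effects) <- cond
  }
  sdlog <- if (rep_cv > 0) sqrt(log(1 + rep_cv^2)) else 0

  with_rng_seed(seed, {
    draw_arm <- function(p, n_rep) {
      vapply(seq_len(n_rep), function(i) {
        pr <- if (sdlog > 0) {
          w <- p * exp(stats::rnorm(length(p), 0, sdlog))
          w / sum(w)
        } else p
        as.integer(stats::rmultinom(1L, depth, pr))
      }, integer(nrow(library)))
    }
    arms <- list()
    arms[[control_condition]] <- draw_arm(profile, n_control)
    for (cond in names(effects)) {
      arms[[cond]] <- draw_arm(apply_effects(profile, effects[[cond]]),
                               n_treated)
    }
    counts <- do.call(cbind, arms)
    reps <- unlist(lapply(arms, function(a) seq_len(ncol(a))),
                   use.names = FALSE)
    condition <- rep(names(arms), vapply(arms, ncol, 0L))
    sample_id <- paste(condition, reps, sep = "_")
    dimnames(counts) <- list(library$hairpin_id, sample_id)
    screen_counts(counts,
                  data.frame(sample_id = sample_id, condition = condition,
                             replicate = reps, stringsAsFactors = FALSE),
                  library)
  })
}

#' Resolve a condition label or sample IDs to count columns
#' @noRd
resolve_samples <- function(x, which, arg = "which") {
  stopifnot(inherits(x, "screen_counts"))
  if (all(which %in% x$samples$condition)) {
    cols <- x$samples$sample_id[x$samples$condition %in% which]
  } else if (all(which %in% x$samples$sample_id)) {
    cols <- which
  } else {
    stop("`", arg, "` must name a condition or sample ids present in the ",
         "sample sheet", call. = FALSE)
  }
  as.character(cols)
}

#' Normalise hairpin counts
#'
#' Default is reads per million: each sample's counts are scaled so the
#' column sums to 10^6, preserving within-sample ratios. A
#' median-of-ratios option (DESeq-style size factors) is available for
#' screens where a few dominant hairpins distort library size.
#'
#' @param x A [screen_counts()] or a counts matrix.
#' @param method `"cpm"` (default) or `"median_ratio"`.
#' @return Numeric matrix of normalised counts (same dimnames).
#' @examples
#' m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("h", 1:3), "s1"))
#' lib <- data.frame(hairpin_id = paste0("h", 1:3), gene_symbol = "G",
#'                   hairpin_seq = c("AAAA", "CCCC", "GGGG"))
#' sc <- screen_counts(m, data.frame(sample_id = "s1", condition = "c",
#'                                   replicate = 1), lib)
#' normalize_counts(sc)
#' @export
normalize_counts <- function(x, method = c("cpm", "median_ratio")) {
  method <- match.arg(method)
  counts <- if (inherits(x, "screen_counts")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  if (method == "cpm") {
    return(sweep(counts, 2, totals, "/") * 1e6)
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("median-of-ratios normalisation needs hairpins detected in every ",
         "sample", call. = FALSE)
  }
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  sf <- apply(sweep(counts[pos, , drop = FALSE], 1, ref, "/"), 2,
              stats::median)
  sweep(counts, 2, sf, "/")
}

#' Partition hairpins by control abundance
#'
#' Hairpins whose mean raw count across the untreated control replicates
#' exceeds `min_raw` are kept for testing; the rest are carried forward
#' with class `filtered`. The default threshold of 100 raw reads
#' reflects the practice of only trusting hairpins with solid
#' pre-treatment representation.
#'
#' @param x A [screen_counts()].
#' @param control Condition label or sample IDs of the untreated arm.
#' @param min_raw Strict threshold on the mean raw control count.
#' @return List with character vectors `kept` and `filtered`, plus
#'   `keep`, a named logical over all hairpins.
#' @export
filter_low_abundance <- function(x, control, min_raw = 100) {
  cols <- resolve_samples(x, control, "control")
  keep <- rowMeans(x$counts[, cols, drop = FALSE]) > min_raw
  list(kept = rownames(x$counts)[keep],
       filtered = rownames(x$counts)[!keep],
       keep = keep)
}

#' Row-wise two-sample t-tests on matrices
#' @noRd
row_t_test <- function(xt, xc, var_equal = TRUE) {
  k1 <- ncol(xt); k2 <- ncol(xc)
  m1 <- rowMeans(xt); m2 <- rowMeans(xc)
  v1 <- rowSums((xt - m1)^2) / (k1 - 1)
  v2 <- rowSums((xc - m2)^2) / (k2 - 1)
  if (var_equal) {
    sp2 <- ((k1 - 1) * v1 + (k2 - 1) * v2) / (k1 + k2 - 2)
    se <- sqrt(sp2 * (1 / k1 + 1 / k2))
    df <- rep(k1 + k2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / k1 + v2 / k2)
    df <- (v1 / k1 + v2 / k2)^2 /
      ((v1 / k1)^2 / (k1 - 1) + (v2 / k2)^2 / (k2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  t[degenerate & m1 == m2] <- 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- .Machine$double.xmin
  t[degenerate & m1 != m2] <- sign(m1 - m2)[degenerate & m1 != m2] * Inf
  list(t = t, df = df, p = p)
}

#' Call depleted, enriched and lost hairpins for one drug contrast
#'
#' The core drop-out statistic: per kept hairpin, a two-sided Student's
#' t-test (classical equal-variance by default; Welch optional) on
#' normalised counts of treated vs control replicates, together with
#' `log2((mean treated + pseudocount) / (mean control + pseudocount))`.
#' Classes are assigned as a partition of the library:
#' \describe{
#'   \item{filtered}{failed the control-abundance filter; never tested.}
#'   \item{lost}{kept, but every raw treated count is zero — detected
#'     before the ratio rule, the count-matrix analogue of hairpins
#'     plotted on the axis of a drop-out scatterplot.}
#'   \item{depleted}{`log2 ratio <= -log2(fold)` and `p < alpha`.}
#'   \item{enriched}{`log2 ratio >= +log2(fold)` and `p < alpha`.}
#'   \item{unchanged}{everything else.}
#' }
#' Benjamini-Hochberg adjusted p-values are reported for context but
#' calling uses the raw `p < alpha` rule with the two-fold change.
#'
#' @param x A [screen_counts()].
#' @param treated,control Condition labels (or sample-ID vectors) for
#'   the two arms; each needs >= 2 replicates.
#' @param alpha Significance level on the raw p-value (default 0.01).
#' @param fold Fold-change threshold (> 1; default 2).
#' @param min_raw Control-abundance filter threshold (see
#'   [filter_low_abundance()]).
#' @param pseudocount Added to both normalised means inside the log2
#'   ratio (default 0.5 normalised units) so depleted-but-nonzero
#'   hairpins remain finite.
#' @param normalize Normalisation method (see [normalize_counts()]).
#' @param var_equal `TRUE` for classical Student's t (default), `FALSE`
#'   for Welch.
#' @return A `hit_table`: data frame with one row per library hairpin
#'   (`hairpin_id`, `gene_symbol`, `mean_control`, `mean_treated`,
#'   `log2_ratio`, `t`, `p_value`, `adjusted_p`, `class`), with
#'   attributes `contrast`, `control`, `alpha`, `fold`.
#' @export
call_hits <- function(x, treated, control, alpha = 0.01, fold = 2,
                      min_raw = 100, pseudocount = 0.5,
                      normalize = c("cpm", "median_ratio"),
                      var_equal = TRUE) {
  stopifnot(inherits(x, "screen_counts"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(fold) || fold <= 1) {
    stop("`fold` must be > 1", call. = FALSE)
  }
  t_cols <- resolve_samples(x, treated, "treated")
  c_cols <- resolve_samples(x, control, "control")
  if (length(t_cols) < 2 || length(c_cols) < 2) {
    stop("need >= 2 replicates per arm for the t-test", call. = FALSE)
  }
  if (length(intersect(t_cols, c_cols))) {
    stop("treated and control samples overlap", call. = FALSE)
  }
  norm <- normalize_counts(x, match.arg(normalize))
  flt <- filter_low_abundance(x, control, min_raw)
  keep <- flt$keep

  nt <- norm[, t_cols, drop = FALSE]
  nc <- norm[, c_cols, drop = FALSE]
  mean_treated <- rowMeans(nt)
  mean_control <- rowMeans(nc)
  log2_ratio <- log2((mean_treated + pseudocount) /
                       (mean_control + pseudocount))

  tt <- row_t_test(nt[keep, , drop = FALSE], nc[keep, , drop = FALSE],
                   var_equal = var_equal)
  t_stat <- p_value <- adjusted_p <- rep(NA_real_, nrow(norm))
  t_stat[keep] <- tt$t
  p_value[keep] <- tt$p
  adjusted_p[keep] <- stats::p.adjust(tt$p, method = "BH")

  lost <- keep & rowSums(x$counts[, t_cols, drop = FALSE]) == 0
  lfc_cut <- log2(fold)
  cls <- rep("unchanged", nrow(norm))
  cls[!keep] <- "filtered"
  sig <- keep & !lost & !is.na(p_value) & p_value < alpha
  cls[sig & log2_ratio <= -lfc_cut] <- "depleted"
  cls[sig & log2_ratio >= lfc_cut] <- "enriched"
  cls[lost] <- "lost"

  out <- data.frame(
    hairpin_id = x$library$hairpin_id,
    gene_symbol = x$library$gene_symbol,
    mean_control = mean_control,
    mean_treated = mean_treated,
    log2_ratio = log2_ratio,
    t = t_stat,
    p_value = p_value,
    adjusted_p = adjusted_p,
    class = factor(cls, levels = c("depleted", "enriched", "lost",
                                   "unchanged", "filtered")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "contrast") <- if (length(treated) == 1) treated else "treated"
  attr(out, "control") <- if (length(control) == 1) control else "control"
  attr(out, "alpha") <- alpha
  attr(out, "fold") <- fold
  class(out) <- c("hit_table", "data.frame")
  out
}

#' @export
summary.hit_table <- function(object, ...) {
  tab <- table(object$class)
  cat(sprintf("contrast %s vs %s (alpha = %g, fold = %g)\n",
              attr(object, "contrast"), attr(object, "control"),
              attr(object, "alpha"), attr(object, "fold")))
  print(tab)
  invisible(tab)
}

#' Write a hit table as TSV
#' @param ht A `hit_table`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(ht, path) {
  stopifnot(inherits(ht, "hit_table"))
  utils::write.table(as.data.frame(ht), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Intersect hit sets across drug contrasts
#'
#' Hairpin-level set intersection of one class (e.g. `"depleted"`)
#' across several hit tables keyed to the same library, with the gene
#' set obtained by mapping the intersected hairpins through the
#' library. Useful for questions like "which genes deplete under all
#' three drugs?".
#'
#' @param tables List of `hit_table`s over the same library.
#' @param class Hit class to intersect (default `"depleted"`;
#'   `"lost"` hits can be included via `include_lost`).
#' @param include_lost Treat `lost` hairpins as members of the depleted
#'   set (default `TRUE` when `class = "depleted"`: a hairpin wiped out
#'   entirely is the extreme of depletion).
#' @return An `overlap_result`: list with `class`, `contrasts`,
#'   `hairpin_id` (the intersection) and `gene_symbol` (its image in
#'   the library).
#' @export
intersect_hits <- function(tables, class = "depleted",
                           include_lost = identical(class, "depleted")) {
  stopifnot(is.list(tables), length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "hit_table")))
  keys <- lapply(tables, function(t) paste(t$hairpin_id, t$gene_symbol))
  if (!all(vapply(keys, identical, TRUE, keys[[1]]))) {
    stop("hit tables are keyed to different libraries", call. = FALSE)
  }
  sets <- lapply(tables, function(t) {
    sel <- t$class == class
    if (include_lost) sel <- sel | t$class == "lost"
    t$hairpin_id[sel]
  })
  hp <- Reduce(intersect, sets)
  genes <- unique(tables[[1]]$gene_symbol[match(hp, tables[[1]]$hairpin_id)])
  structure(list(class = class,
                 contrasts = vapply(tables, attr, "", "contrast"),
                 hairpin_id = hp, gene_symbol = genes),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap of %s hits across %s:\n", x$class,
              paste(x$contrasts, collapse = " & ")))
  cat(sprintf("  %d hairpins -> %d genes\n", length(x$hairpin_id),
              length(x$gene_symbol)))
  if (length(x$gene_symbol)) {
    cat("  genes:", paste(x$gene_symbol, collapse = ", "), "\n")
  }
  invisible(x)
}
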