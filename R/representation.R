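#' Monte-Carlo simulation of library sampling error
#'
#' Models drawing `n_draws` hairpin-carrying cells from a large pool
#' (multinomial sampling with replacement from the abundance profile)
#' and summarises, per hairpin, how the sampled count varies across
#' replicates. This quantifies the sampling error incurred when a
#' screen passages a bottleneck of ~10^6 cells: for a hairpin with
#' probability p the relative error (CV of counts) follows the binomial
#' closed form `sqrt((1 - p) / (n_draws * p))`, so rare hairpins are
#' measured proportionally less precisely.
#'
#' @param profile Abundance profile (named, non-negative, sums to 1).
#' @param n_draws Cells (hairpins) sampled per replicate (>= 0).
#' @param n_replicates Independent replicate draws (>= 1).
#' @param seed Optional integer seed.
#' @return An object of class `sampling_sim`: list with `summary` (data
#'   frame: `hairpin_id`, `prob`, `mean`, `sd`, `cv`, `min_count`),
#'   `n_draws`, `n_replicates`, and `frac_detected` (fraction of
#'   hairpins with >= 1 copy in every replicate). `cv` is `NA` where the
#'   mean count is 0.
#' @examples
#' lib <- generate_library(100, 1, seed = 1)
#' p <- generate_abundance(lib, 0, seed = 1)
#' sim <- simulate_sampling(p, n_draws = 1e4, n_replicates = 20, seed = 2)
#' head(sim$summary)
#' @export
simulate_sampling <- function(profile, n_draws, n_replicates, seed = NULL) {
  validate_profile(profile)
  assert_scalar_count(n_draws, "n_draws", min = 0)
  assert_scalar_count(n_replicates, "n_replicates", min = 1)
  with_rng_seed(seed, {
    counts <- stats::rmultinom(n_replicates, n_draws, profile)
    mu <- rowMeans(counts)
    sdev <- apply(counts, 1, stats::sd)
    if (n_replicates == 1L) sdev <- rep(NA_real_, length(mu))
    cv <- ifelse(mu > 0, sdev / mu, NA_real_)
    min_count <- apply(counts, 1, min)
    summary <- data.frame(hairpin_id = names(profile),
                          prob = as.numeric(profile),
                          mean = mu, sd = sdev, cv = cv,
                          min_count = as.integer(min_count),
                          stringsAsFactors = FALSE)
    structure(list(summary = summary,
                   n_draws = as.integer(n_draws),
                   n_replicates = as.integer(n_replicates),
                   frac_detected = mean(min_count >= 1)),
              class = "sampling_sim")
  })
}

#' @export
print.sampling_sim <- function(x, ...) {
  cat(sprintf(
    "sampling simulation: %d hairpins, %d draws x %d replicates\n",
    nrow(x$summary), x$n_draws, x$n_replicates))
  cat(sprintf("median CV %.4g | fraction with >=1 copy in all replicates %.4g\n",
              stats::median(x$summary$cv, na.rm = TRUE), x$frac_detected))
  invisible(x)
}

#' Fraction of hairpins at or above a copy threshold in all replicates
#'
#' Answers the representation question behind bottleneck sizing: does a
#' sample of `n_draws` cells preserve at least `min_copies` of every
#' hairpin? Monotone non-increasing in `min_copies`.
#'
#' @param result A [simulate_sampling()] result.
#' @param min_copies Copy threshold (>= 1).
#' @return Fraction in `[0, 1]`.
#' @export
representation_check <- function(result, min_copies = 1) {
  stopifnot(inherits(result, "sampling_sim"))
  assert_scalar_count(min_copies, "min_copies", min = 1)
  mean(result$summary$min_count >= min_copies)
}

#' Export the per-hairpin sampling-error table as TSV
#' @param result A [simulate_sampling()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sampling_sim <- function(result, path) {
  stopifnot(inherits(result, "sampling_sim"))
  utils::write.table(result$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Log-log scatter of sampling error against hairpin abundance
#'
#' Plots the observed per-hairpin CV against sampling probability with
#' the binomial closed form `sqrt((1 - p) / (n p))` overlaid.
#'
#' @param result A [simulate_sampling()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `result`, invisibly.
#' @export
plot_sampling_error <- function(result, ...) {
  stopifnot(inherits(result, "sampling_sim"))
  s <- result$summary
  ok <- !is.na(s$cv) & s$cv > 0 & s$prob > 0
  graphics::plot(s$prob[ok], s$cv[ok], log = "xy",
                 xlab = "hairpin sampling probability",
                 ylab = "relative sampling error (CV of counts)",
                 pch = 16, cex = 0.4, col = "grey40", ...)
  p_grid <- exp(seq(log(min(s$prob[ok])), log(max(s$prob[ok])),
                    length.out = 200))
  graphics::lines(p_grid, sqrt((1 - p_grid) / (result$n_draws * p_grid)),
                  col = "firebrick", lwd = 2)
  invisible(result)
}
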