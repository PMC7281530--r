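#' Zero-interaction expectation for two inhibition fractions
#'
#' The ZIP (zero interaction potency) null: two non-interacting drugs
#' combine like independent events, `yA + yB - yA * yB`. Symmetric,
#' bounded in `[0, 1]`, and monotone in each argument.
#'
#' @param ya,yb Inhibition fractions in `[0, 1]` (vectorised,
#'   recycled).
#' @return Expected combination inhibition fraction.
#' @examples
#' zip_expected(0.5, 0.4)
#' @export
zip_expected <- function(ya, yb) {
  if (any(ya < 0 | ya > 1 | yb < 0 | yb > 1)) {
    stop("inhibition fractions must lie in [0, 1]", call. = FALSE)
  }
  ya + yb - ya * yb
}

#' Overall and most-synergistic-area scores of a delta surface
#'
#' `overall` is the mean delta over all cells of the surface (the
#' combination cells of a dose matrix); `msa` is the maximum mean over
#' any contiguous `window x window` block, the "most synergistic area"
#' convention (default 3 x 3). Surfaces smaller than the window return
#' `msa = NA`.
#'
#' @param delta Numeric matrix of per-cell synergy deltas (percentage
#'   points).
#' @param window MSA window edge (default 3).
#' @return List with `overall` and `msa`.
#' @export
synergy_scores <- function(delta, window = 3) {
  stopifnot(is.matrix(delta), is.numeric(delta))
  assert_scalar_count(window, "window", min = 1)
  overall <- mean(delta)
  nr <- nrow(delta); nc <- ncol(delta)
  msa <- NA_real_
  if (nr >= window && nc >= window) {
    msa <- -Inf
    for (i in seq_len(nr - window + 1L)) {
      for (j in seq_len(nc - window + 1L)) {
        msa <- max(msa, mean(delta[i:(i + window - 1L),
                                   j:(j + window - 1L)]))
      }
    }
  }
  list(overall = overall, msa = msa)
}

#' Fit a conditional Hill curve along one line of the combination block
#' Returns fitted values, or the observed values if the fit fails or
#' there are too few doses.
#' @noRd
conditional_fit <- function(dose, observed) {
  if (length(unique(dose)) < 4) {
    return(list(fitted = observed, ok = FALSE))
  }
  fit <- tryCatch(
    suppressWarnings(fit_hill(dose, pmin(pmax(observed, 0), 1))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(fitted = observed, ok = FALSE))
  }
  list(fitted = predict(fit, dose), ok = TRUE)
}

#' ZIP synergy scoring of a dose-combination matrix
#'
#' Implements the zero-interaction-potency workflow: monotherapy Hill
#' curves are fitted to the dose-0 margins; for each combination cell
#' the observed response is smoothed by potency-shifted conditional
#' Hill fits - the response to drug A refitted along its row at fixed
#' drug B dose, and vice versa, averaged - and the synergy delta is
#' `100 * (fitted observed - zip_expected(yA, yB))` in percentage
#' points, with `yA`, `yB` the monotherapy predictions. A failed
#' conditional fit for a line falls back to the raw observed values and
#' is logged in the result. Summary scores come from
#' [synergy_scores()]: the overall mean delta over combination cells
#' and the most-synergistic-area (3 x 3 window) mean.
#'
#' @param x A `dose_matrix` with monotherapy margins (dose 0 first in
#'   each grid).
#' @param window MSA window edge (default 3).
#' @return A `synergy_result`: list with `delta` (combination-cell
#'   matrix, percentage points), `overall`, `msa`, the monotherapy
#'   `fit_a` and `fit_b`, and `fallback` (character log of lines where
#'   the conditional fit fell back to raw values).
#' @examples
#' hillA <- list(emin = 0, emax = 0.6, ec50 = 1, hill = 1.2)
#' hillB <- list(emin = 0, emax = 0.6, ec50 = 5, hill = 1)
#' dm <- generate_dose_matrix(hillA, hillB, 10^seq(-1, 1, length.out = 5),
#'                            10^seq(-0.5, 1.5, length.out = 5))
#' res <- zip_delta(dm)
#' res$overall
#' @export
zip_delta <- function(x, window = 3) {
  stopifnot(inherits(x, "dose_matrix"))
  if (x$d1[1] != 0 || x$d2[1] != 0) {
    stop("dose matrix must include dose-0 monotherapy margins",
         call. = FALSE)
  }
  da <- x$d1[-1]
  db <- x$d2[-1]
  if (length(da) < 3 || length(db) < 3) {
    warning("fewer than 3x3 combination cells; msa will be NA")
  }
  fit_a <- fit_hill(x$d1, x$response[, 1])
  fit_b <- fit_hill(x$d2, x$response[1, ])
  ya <- predict(fit_a, da)
  yb <- predict(fit_b, db)
  expected <- outer(ya, yb, zip_expected)

  obs <- x$response[-1, -1, drop = FALSE]
  fallback <- character(0)
  fit_rows <- obs  # drug A response along each column (fixed B dose)
  for (j in seq_along(db)) {
    cf <- conditional_fit(da, obs[, j])
    fit_rows[, j] <- cf$fitted
    if (!cf$ok) {
      fallback <- c(fallback,
                    sprintf("%s = %g", x$drug_b, db[j]))
    }
  }
  fit_cols <- obs  # drug B response along each row (fixed A dose)
  for (i in seq_along(da)) {
    cf <- conditional_fit(db, obs[i, ])
    fit_cols[i, ] <- cf$fitted
    if (!cf$ok) {
      fallback <- c(fallback,
                    sprintf("%s = %g", x$drug_a, da[i]))
    }
  }
  fitted <- (fit_rows + fit_cols) / 2
  delta <- 100 * (fitted - expected)
  dimnames(delta) <- list(format(da, trim = TRUE), format(db, trim = TRUE))
  scores <- synergy_scores(delta, window = window)
  structure(list(delta = delta, overall = scores$overall, msa = scores$msa,
                 fit_a = fit_a, fit_b = fit_b, fallback = fallback,
                 window = window),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf(
    "ZIP synergy: overall score %.2f, most synergistic area (%dx%d) %.2f\n",
    x$overall, x$window, x$window, x$msa))
  if (length(x$fallback)) {
    cat("conditional fit fell back to raw values at:",
        paste(x$fallback, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write a ZIP delta surface and summary to disk
#'
#' The surface goes to `<path>` as CSV (doses as row/column names); the
#' summary (`overall`, `msa`, monotherapy Hill parameters) to
#' `<path>.summary.csv`.
#' @param x A `synergy_result`.
#' @param path CSV path for the delta surface.
#' @return `path`, invisibly.
#' @export
write_synergy <- function(x, path) {
  stopifnot(inherits(x, "synergy_result"))
  utils::write.csv(x$delta, path)
  summary_path <- paste0(path, ".summary.csv")
  s <- data.frame(
    metric = c("overall", "msa",
               "drug_a_emin", "drug_a_emax", "drug_a_ec50", "drug_a_hill",
               "drug_b_emin", "drug_b_emax", "drug_b_ec50", "drug_b_hill"),
    value = c(x$overall, x$msa,
              x$fit_a$emin, x$fit_a$emax, x$fit_a$ec50, x$fit_a$hill,
              x$fit_b$emin, x$fit_b$emax, x$fit_b$ec50, x$fit_b$hill)
  )
  utils::write.csv(s, summary_path, row.names = FALSE)
  invisible(path)
}
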