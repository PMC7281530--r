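#' Four-parameter Hill (log-logistic) dose-response model
#'
#' `hill_response(d) = emin + (emax - emin) * d^h / (ec50^h + d^h)`,
#' with inhibition fractions in `[0, 1]`, `ec50 > 0` and slope `h > 0`;
#' at dose 0 the response is `emin`.
#'
#' @param dose Dose vector (same units as `ec50`; 0 allowed).
#' @param emin,emax Lower/upper inhibition asymptotes.
#' @param ec50 Dose of half-maximal effect.
#' @param hill Hill slope.
#' @return Predicted inhibition fractions.
#' @export
hill_response <- function(dose, emin, emax, ec50, hill) {
  stopifnot(all(dose >= 0), ec50 > 0, hill > 0)
  r <- (dose / ec50)^hill
  emin + (emax - emin) * r / (1 + r)
}

#' Fit a four-parameter Hill curve to monotherapy viability data
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) of the
#' four-parameter Hill function to observed inhibition fractions, with
#' box constraints keeping `emin`, `emax` in `[0, 1]`, `ec50 > 0` and
#' the slope in `[0.05, 20]`. Doses of 0 (vehicle wells) are allowed
#' and pin down `emin`.
#'
#' @param dose Dose vector (>= 4 distinct values required).
#' @param inhibition Observed inhibition fractions in `[0, 1]`.
#' @param weights Optional non-negative fit weights.
#' @param flat_tol Fitted span `emax - emin` below which the response
#'   is flagged flat.
#' @return An object of class `hill_fit`: list with `emin`, `emax`,
#'   `ec50`, `hill`, `rss` (residual sum of squares), `fitted`, `data`,
#'   `flat` and `converged`.
#' @examples
#' d <- 10^seq(-3, 2, length.out = 8)
#' y <- hill_response(d, 0, 1, 1, 1)
#' fit <- fit_hill(d, y)
#' estimate_ecx(fit, 50)
#' @export
fit_hill <- function(dose, inhibition, weights = NULL, flat_tol = 0.01) {
  stopifnot(is.numeric(dose), is.numeric(inhibition),
            length(dose) == length(inhibition))
  if (length(unique(dose)) < 4) {
    stop("need >= 4 distinct doses to fit a 4-parameter Hill curve",
         call. = FALSE)
  }
  if (any(dose < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(inhibition < -1e-6 | inhibition > 1 + 1e-6)) {
    stop("inhibition must be a fraction in [0, 1]", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(dose))

  emin0 <- max(0, min(inhibition))
  emax0 <- min(1, max(inhibition))
  if (emax0 <= emin0) emax0 <- min(1, emin0 + 0.1)
  pos <- dose > 0
  half <- (emin0 + emax0) / 2
  ec50_0 <- if (any(pos)) {
    above <- pos & inhibition >= half
    if (any(above)) min(dose[above]) else stats::median(dose[pos])
  } else 1
  start <- list(emin = emin0, emax = emax0, ec50 = max(ec50_0, 1e-9),
                hill = 1)
  lower <- c(emin = 0, emax = 0, ec50 = 1e-12, hill = 0.05)
  upper <- c(emin = 1, emax = 1, ec50 = Inf, hill = 20)

  resid_fn <- function(par) {
    sqrt(weights) *
      (inhibition - hill_response(dose, par[["emin"]], par[["emax"]],
                                  par[["ec50"]], par[["hill"]]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(start), lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) {
      stop("Hill fit did not converge: ", conditionMessage(e),
           "\n  doses: ", paste(signif(dose, 3), collapse = ", "),
           call. = FALSE)
    }
  )
  if (fit$info == 0 || fit$info == 9) {
    stop("Hill fit did not converge: ", fit$message,
         "\n  doses: ", paste(signif(dose, 3), collapse = ", "),
         call. = FALSE)
  }
  cf <- fit$par
  flat <- (cf[["emax"]] - cf[["emin"]]) < flat_tol
  if (flat) {
    warning("flat response: fitted emax - emin = ",
            signif(cf[["emax"]] - cf[["emin"]], 3), call. = FALSE)
  }
  fitted_vals <- hill_response(dose, cf[["emin"]], cf[["emax"]],
                               cf[["ec50"]], cf[["hill"]])
  structure(list(emin = cf[["emin"]], emax = cf[["emax"]],
                 ec50 = cf[["ec50"]], hill = cf[["hill"]],
                 rss = sum(weights * (inhibition - fitted_vals)^2),
                 fitted = fitted_vals,
                 data = data.frame(dose = dose, inhibition = inhibition),
                 flat = flat, converged = TRUE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: emin %.4g, emax %.4g, ec50 %.4g, slope %.4g (rss %.3g%s)\n",
    x$emin, x$emax, x$ec50, x$hill, x$rss,
    if (x$flat) "; FLAT response" else ""))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, dose, ...) {
  hill_response(dose, object$emin, object$emax, object$ec50, object$hill)
}

#' Invert a Hill curve for the dose giving x% inhibition
#'
#' Closed form: with `f = (x/100 - emin) / (emax - emin)`,
#' `EC_x = ec50 * (f / (1 - f))^(1 / hill)`. Used to derive screening
#' doses such as the EC10 (10% growth inhibition) from a monotherapy
#' fit.
#'
#' @param curve A [fit_hill()] result, or any list with `emin`, `emax`,
#'   `ec50`, `hill`.
#' @param x Target percent inhibition; must satisfy
#'   `emin < x/100 < emax`.
#' @return The dose, in the units of the fitted `ec50`.
#' @examples
#' estimate_ecx(list(emin = 0, emax = 1, ec50 = 1, hill = 1), 10)
#' @export
estimate_ecx <- function(curve, x) {
  stopifnot(is.numeric(x), length(x) == 1L)
  f <- (x / 100 - curve$emin) / (curve$emax - curve$emin)
  if (!is.finite(f) || f <= 0 || f >= 1) {
    stop("EC", x, " is outside the achievable response range (emin = ",
         signif(curve$emin, 3), ", emax = ", signif(curve$emax, 3), ")",
         call. = FALSE)
  }
  curve$ec50 * (f / (1 - f))^(1 / curve$hill)
}

#' Simulate a dose-combination inhibition matrix with known interaction
#'
#' Ground truth for synergy scoring: each drug follows its own Hill
#' curve; the combination surface is the probabilistic-independence
#' expectation `y1 + y2 - y1*y2`, plus a constant interaction offset
#' `delta` (inhibition fraction, applied to interior cells only) and
#' Gaussian replicate noise, clipped to `[0, 1]`. `delta = 0` with no
#' noise yields an exact zero-interaction surface. Monotherapy margins
#' (other drug at dose 0) are always included.
#'
#' @param drug_a,drug_b Lists with `emin`, `emax`, `ec50`, `hill` (and
#'   optionally `name`).
#' @param doses_a,doses_b Strictly positive, sorted dose grids for the
#'   combination cells (the 0 margin is added automatically).
#' @param delta Interaction offset in inhibition-fraction units
#'   (positive = synergy).
#' @param noise_sd Gaussian noise sd on each cell.
#' @param seed Optional integer seed.
#' @return A `dose_matrix`: list with `d1`, `d2` (dose vectors
#'   including 0), `response` (inhibition matrix, rows = drug A doses,
#'   columns = drug B doses) and drug names.
#' @export
generate_dose_matrix <- function(drug_a, drug_b, doses_a, doses_b,
                                 delta = 0, noise_sd = 0, seed = NULL) {
  stopifnot(length(doses_a) >= 1, length(doses_b) >= 1,
            all(doses_a > 0), all(doses_b > 0),
            !is.unsorted(doses_a, strictly = TRUE),
            !is.unsorted(doses_b, strictly = TRUE))
  d1 <- c(0, doses_a)
  d2 <- c(0, doses_b)
  y1 <- hill_response(d1, drug_a$emin, drug_a$emax, drug_a$ec50, drug_a$hill)
  y2 <- hill_response(d2, drug_b$emin, drug_b$emax, drug_b$ec50, drug_b$hill)
  surf <- outer(y1, y2, function(a, b) a + b - a * b)
  interior <- outer(d1 > 0, d2 > 0, "&")
  surf[interior] <- surf[interior] + delta
  surf[1, 1] <- 0
  with_rng_seed(seed, {
    if (noise_sd > 0) {
      surf <- surf + matrix(stats::rnorm(length(surf), 0, noise_sd),
                            nrow = nrow(surf))
    }
    surf <- pmin(pmax(surf, 0), 1)
    dimnames(surf) <- list(format(d1, trim = TRUE, scientific = FALSE),
                           format(d2, trim = TRUE, scientific = FALSE))
    structure(list(d1 = d1, d2 = d2, response = surf,
                   drug_a = if (is.null(drug_a$name)) "drug_a" else drug_a$name,
                   drug_b = if (is.null(drug_b$name)) "drug_b" else drug_b$name),
              class = "dose_matrix")
  })
}

#' Assemble a dose matrix from raw components
#' @noRd
new_dose_matrix <- function(d1, d2, response, drug_a = "drug_a",
                            drug_b = "drug_b") {
  stopifnot(length(d1) == nrow(response), length(d2) == ncol(response),
            !is.unsorted(d1), !is.unsorted(d2))
  if (d1[1] != 0 || d2[1] != 0) {
    stop("dose matrix must include the dose-0 monotherapy margins",
         call. = FALSE)
  }
  structure(list(d1 = d1, d2 = d2, response = response,
                 drug_a = drug_a, drug_b = drug_b),
            class = "dose_matrix")
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("dose matrix: %s (%d doses) x %s (%d doses)\n",
              x$drug_a, length(x$d1), x$drug_b, length(x$d2)))
  print(round(x$response, 3))
  invisible(x)
}

#' Write / read a dose-combination matrix as CSV
#'
#' Layout: first row and first column hold the dose grids (cell `[1,1]`
#' empty), remaining cells the readout. `readout = "inhibition"` takes
#' cells as inhibition fractions; `"viability"` converts via
#' `1 - viability`; `"fluorescence"` converts raw readings via
#' `1 - (value - blank) / (vehicle - blank)` with the vehicle taken
#' from the (0, 0) cell. Negative inhibition values are clipped to 0
#' with a message.
#'
#' @param x A `dose_matrix`.
#' @param path File path.
#' @param readout Interpretation of the cells on read.
#' @param blank Blank reading subtracted in fluorescence mode.
#' @param drug_a,drug_b Drug names for the returned object.
#' @return `write_dose_matrix` returns `path` invisibly;
#'   `read_dose_matrix` a `dose_matrix`.
#' @export
write_dose_matrix <- function(x, path) {
  stopifnot(inherits(x, "dose_matrix"))
  m <- rbind(c(NA, x$d2), cbind(x$d1, unname(x$response)))
  utils::write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dose_matrix
#' @export
read_dose_matrix <- function(path,
                             readout = c("inhibition", "viability",
                                         "fluorescence"),
                             blank = 0, drug_a = "drug_a",
                             drug_b = "drug_b") {
  readout <- match.arg(readout)
  raw <- as.matrix(utils::read.csv(path, header = FALSE))
  d2 <- as.numeric(raw[1, -1])
  d1 <- as.numeric(raw[-1, 1])
  vals <- matrix(as.numeric(raw[-1, -1]), nrow = length(d1))
  inh <- switch(readout,
    inhibition = vals,
    viability = 1 - vals,
    fluorescence = {
      vehicle <- vals[1, 1]
      if (!is.finite(vehicle) || vehicle == blank) {
        stop("fluorescence mode needs a vehicle (0,0) cell distinct from ",
             "the blank", call. = FALSE)
      }
      1 - (vals - blank) / (vehicle - blank)
    })
  n_clip <- sum(inh < 0, na.rm = TRUE)
  if (n_clip > 0) {
    message(n_clip, " negative inhibition value(s) clipped to 0")
    inh <- pmax(inh, 0)
  }
  inh <- pmin(inh, 1)
  dimnames(inh) <- list(format(d1, trim = TRUE), format(d2, trim = TRUE))
  new_dose_matrix(d1, d2, inh, drug_a, drug_b)
}
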