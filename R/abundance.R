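#' Generate a skewed hairpin abundance profile
#'
#' Pooled libraries are never uniformly represented: transduction and
#' expansion leave a heavy-tailed distribution of hairpin abundances.
#' This is modelled as a log-normal profile: per-hairpin weights
#' `exp(N(0, dispersion^2))` normalised to sum to one. `dispersion = 0`
#' gives the uniform profile. For large libraries the coefficient of
#' variation of the probabilities approaches the log-normal closed form
#' `sqrt(exp(dispersion^2) - 1)`.
#'
#' @param library A `shrna_library`.
#' @param dispersion Log-scale standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return Named numeric vector of sampling probabilities (names =
#'   `hairpin_id`), non-negative, summing to 1.
#' @examples
#' lib <- generate_library(5, 2, seed = 1)
#' p <- generate_abundance(lib, dispersion = 1, seed = 1)
#' sum(p)
#' @export
generate_abundance <- function(library, dispersion = 1, seed = NULL) {
  validate_library(library)
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion < 0) {
    stop("`dispersion` must be a single number >= 0", call. = FALSE)
  }
  n <- nrow(library)
  with_rng_seed(seed, {
    w <- if (dispersion == 0) rep(1, n) else exp(stats::rnorm(n, 0, dispersion))
    stats::setNames(w / sum(w), library$hairpin_id)
  })
}

#' Check that a numeric vector is a valid abundance profile
#' @noRd
validate_profile <- function(profile, library = NULL) {
  if (!is.numeric(profile) || is.null(names(profile))) {
    stop("abundance profile must be a named numeric vector", call. = FALSE)
  }
  if (any(profile < 0)) stop("abundance profile has negative entries",
                             call. = FALSE)
  if (abs(sum(profile) - 1) > 1e-8) {
    stop("abundance profile must sum to 1", call. = FALSE)
  }
  if (!is.null(library) && !identical(names(profile), library$hairpin_id)) {
    stop("abundance profile is not keyed to this library", call. = FALSE)
  }
  invisible(profile)
}

#' Declare planted treatment effects for a simulated screen
#'
#' The ground truth for a simulated drug arm: each listed hairpin's
#' sampling probability is multiplied by `multiplier` (relative to the
#' untreated profile) and renormalised; `lost = TRUE` forces the hairpin
#' to probability zero, emulating clones eliminated outright by the
#' drug. Hairpins not listed keep multiplier 1.
#'
#' @param hairpin_id Character vector of affected hairpins (may be empty
#'   for a null arm).
#' @param multiplier Positive finite abundance multipliers (recycled).
#'   Values < 1 plant depletion ("rescuer"-type hits), values > 1
#'   enrichment.
#' @param lost Logical, recycled; `TRUE` overrides the multiplier and
#'   zeroes the hairpin.
#' @param condition Label for the treatment arm.
#' @return Data frame of class `effect_spec` with attribute `condition`.
#' @export
effect_spec <- function(hairpin_id = character(0), multiplier = 1,
                        lost = FALSE, condition = "treated") {
  n <- length(hairpin_id)
  multiplier <- rep_len(as.numeric(multiplier), n)
  lost <- rep_len(as.logical(lost), n)
  if (any(!lost & (!is.finite(multiplier) | multiplier <= 0))) {
    stop("effect multipliers must be finite and > 0 unless lost",
         call. = FALSE)
  }
  if (anyDuplicated(hairpin_id)) {
    stop("duplicate hairpin_id in effect_spec", call. = FALSE)
  }
  out <- data.frame(hairpin_id = as.character(hairpin_id),
                    multiplier = multiplier, lost = lost,
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  class(out) <- c("effect_spec", "data.frame")
  out
}

#' Apply planted effects to an abundance profile
#'
#' @param profile Named abundance profile (see [generate_abundance()]).
#' @param effects An [effect_spec()].
#' @return The treated profile: `p_i * multiplier_i`, renormalised; lost
#'   hairpins get probability exactly 0.
#' @export
apply_effects <- function(profile, effects) {
  validate_profile(profile)
  if (!inherits(effects, "effect_spec")) {
    stop("`effects` must be an effect_spec", call. = FALSE)
  }
  m <- rep(1, length(profile))
  i <- match(effects$hairpin_id, names(profile))
  if (anyNA(i)) {
    stop("effect_spec names hairpins absent from the profile: ",
         paste(effects$hairpin_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  m[i] <- effects$multiplier
  m[i[effects$lost]] <- 0
  p <- profile * m
  s <- sum(p)
  if (s == 0) stop("all hairpins lost: treated profile is empty",
                   call. = FALSE)
  p / s
}

#' Write / read an effect specification as a YAML config
#'
#' The file records the condition label, an explicit seed field for the
#' simulation that will consume it, and one entry per affected hairpin.
#' @param effects An [effect_spec()].
#' @param path File path.
#' @param seed Seed recorded in the file (may be NULL).
#' @return `write_effects` returns `path` invisibly; `read_effects`
#'   returns the `effect_spec` with attribute `seed`.
#' @export
write_effects <- function(effects, path, seed = NULL) {
  stopifnot(inherits(effects, "effect_spec"))
  doc <- list(
    condition = attr(effects, "condition"),
    seed = seed,
    effects = lapply(seq_len(nrow(effects)), function(i) {
      list(hairpin_id = effects$hairpin_id[i],
           multiplier = effects$multiplier[i],
           lost = effects$lost[i])
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  doc <- yaml::read_yaml(path)
  rows <- doc$effects
  out <- effect_spec(
    hairpin_id = vapply(rows, `[[`, "", "hairpin_id"),
    multiplier = vapply(rows, function(r) as.numeric(r$multiplier), 0),
    lost = vapply(rows, function(r) isTRUE(r$lost), FALSE),
    condition = doc$condition
  )
  attr(out, "seed") <- doc$seed
  out
}
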