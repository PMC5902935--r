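#' @title COBRA quantification of AluS methylation
#' @name cobra
#' @description Combined bisulfite restriction analysis of the two CpG
#'   loci in the AluS internal promoter. Bisulfite-converted amplicons
#'   (133 bp) are digested with TaqI, which cuts only where the CpG was
#'   methylated (the TCGA site is retained); the digest resolves into six
#'   fragments of 133, 90, 75, 58, 43 and 32 bp whose band intensities
#'   encode the four two-CpG methylation states: uCuC (133), mCuC
#'   (90 + 43), uCmC (75 + 58), mCmC (58 + 43 + 32). Band intensity
#'   percentages are divided by fragment length to recover molar
#'   quantities, from which the methylation level and the four pattern
#'   percentages are computed.
NULL

#' Fragment lengths (bp) of the six diagnostic bands
#' @export
BAND_LENGTHS <- c(b133 = 133, b90 = 90, b75 = 75, b58 = 58, b43 = 43,
                  b32 = 32)

#' Construct a band-intensity profile
#'
#' @param x Named non-negative numeric vector with entries `b133`, `b90`,
#'   `b75`, `b58`, `b43`, `b32` (raw intensities or percentages; the lane
#'   is normalized so shares sum to 100).
#' @return Named numeric vector of intensity shares (percent of lane
#'   total) in canonical band order.
#' @export
band_profile <- function(x) {
  x <- unlist(x)
  if (!all(names(BAND_LENGTHS) %in% names(x))) {
    stop("profile must have entries ", paste(names(BAND_LENGTHS),
                                             collapse = ", "))
  }
  x <- as.numeric(x[names(BAND_LENGTHS)])
  names(x) <- names(BAND_LENGTHS)
  if (any(!is.finite(x))) stop("band intensities must be finite")
  if (any(x < 0)) stop("negative band intensity")
  tot <- sum(x)
  if (tot <= 0) stop("blank lane: total intensity is zero")
  100 * x / tot
}

#' Construct a four-state methylation mixture
#'
#' Molecule fractions of amplicons in the four joint methylation states of
#' the two interrogated CpGs.
#'
#' @param p_uu,p_mu,p_um,p_mm Fractions in `[0, 1]` summing to 1 (uCuC,
#'   mCuC, uCmC, mCmC).
#' @return Named numeric vector of class `state_mixture`.
#' @export
state_mixture <- function(p_uu, p_mu, p_um, p_mm) {
  p <- c(p_uu = p_uu, p_mu = p_mu, p_um = p_um, p_mm = p_mm)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("state fractions must be in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-8) stop("state fractions must sum to 1")
  structure(p / sum(p), class = "state_mixture")
}

#' Molar band quantities from intensity shares
#'
#' Divides each band's intensity percentage by its fragment length, exactly
#' as the estimator prescribes: `%133/133 = A`, `%58/58 = B`, `%75/75 = C`,
#' `%90/90 = D`, `%43/43 = E`, `%32/32 = F`. No further rescaling.
#'
#' @param profile A [band_profile()] (or coercible named vector).
#' @return Named numeric vector `c(A, B, C, D, E, F)`.
#' @export
normalize_bands <- function(profile) {
  s <- band_profile(profile)
  c(A = s[["b133"]] / 133, B = s[["b58"]] / 58, C = s[["b75"]] / 75,
    D = s[["b90"]] / 90, E = s[["b43"]] / 43, F = s[["b32"]] / 32)
}

compute_methylation_one <- function(profile) {
  q <- normalize_bands(profile)
  den_pat <- q[["A"]] + q[["C"]] + q[["D"]] + q[["F"]]
  den_mc <- 2 * q[["A"]] + q[["E"]] + q[["B"]] + q[["C"]] + q[["D"]]
  if (den_pat <= 0 || den_mc <= 0) {
    warning("degenerate lane: methylation summary undefined")
    vals <- rep(NA_real_, 5L)
  } else {
    vals <- c(100 * (q[["E"]] + q[["B"]]) / den_mc,
              100 * q[["F"]] / den_pat,
              100 * q[["C"]] / den_pat,
              100 * q[["D"]] / den_pat,
              100 * q[["A"]] / den_pat)
  }
  names(vals) <- c("pct_mC", "pct_mCmC", "pct_uCmC", "pct_mCuC", "pct_uCuC")
  c(vals, q)
}

#' Methylation level and patterns from band intensities
#'
#' Evaluates the five estimator formulas verbatim:
#' \deqn{\%mC = 100 (E + B) / (2A + E + B + C + D)}
#' \deqn{\%mCmC = 100 F / (A+C+D+F), \quad \%uCmC = 100 C / (A+C+D+F)}
#' \deqn{\%mCuC = 100 D / (A+C+D+F), \quad \%uCuC = 100 A / (A+C+D+F)}
#' The four pattern percentages share a denominator and sum to 100. The
#' result is invariant to the lane's total intensity.
#'
#' @param profiles Either a single profile (named vector with `b133` ...
#'   `b32`) or a data frame with a `sample_id` column plus those six band
#'   columns (one row per lane).
#' @return For a single profile, a named numeric vector with `pct_mC`, the
#'   four pattern percentages, and the molar quantities `A`-`F`. For a data
#'   frame, a `methylation_summary` data frame with one row per sample.
#' @export
compute_methylation <- function(profiles) {
  if (is.data.frame(profiles)) {
    stopifnot("sample_id" %in% names(profiles))
    rows <- lapply(seq_len(nrow(profiles)), function(i) {
      as.list(compute_methylation_one(profiles[i, names(BAND_LENGTHS)]))
    })
    out <- cbind(data.frame(sample_id = as.character(profiles$sample_id),
                            stringsAsFactors = FALSE),
                 do.call(rbind, lapply(rows, as.data.frame)))
    extra <- setdiff(names(profiles),
                     c("sample_id", names(BAND_LENGTHS), names(out)))
    for (cl in extra) out[[cl]] <- profiles[[cl]]
    rownames(out) <- NULL
    class(out) <- c("methylation_summary", "data.frame")
    out
  } else {
    compute_methylation_one(profiles)
  }
}

#' Forward digestion/gel model: band profile of a state mixture
#'
#' One molecule contributes fragments according to its state: uCuC keeps
#' the intact 133-mer; mCuC is cut once into 43 + 90; uCmC is cut once into
#' 75 + 58; mCmC is cut twice into 43 + 32 + 58 (TaqI cuts only
#' bisulfite-retained, i.e. methylated, sites). Band intensity is the molar
#' count times fragment length under the default mass-proportional
#' (intercalating) stain; a molar-proportional mode (e.g. end-labelled
#' chemistry) is available. Shares are normalized to 100.
#'
#' @param mix A [state_mixture()].
#' @param intensity_mode `"mass"` (default) or `"molar"`.
#' @param digestion_efficiency Probability that any given methylated site
#'   is actually cut; 1 (complete digestion) by default. Values below 1
#'   exist in the simulator only, to probe estimator bias under partial
#'   digestion: an uncut methylated site leaves the molecule's fragments
#'   joined as if that site were unmethylated.
#' @return A [band_profile()] (shares summing to 100).
#' @export
forward_profile <- function(mix, intensity_mode = c("mass", "molar"),
                            digestion_efficiency = 1) {
  if (!inherits(mix, "state_mixture")) mix <- state_mixture(mix[1], mix[2], mix[3], mix[4])
  intensity_mode <- match.arg(intensity_mode)
  e <- digestion_efficiency
  if (!(e >= 0 && e <= 1)) stop("digestion_efficiency must be in [0, 1]")
  p <- unclass(mix)
  # effective state fractions after incomplete digestion: an uncut
  # methylated site behaves like an unmethylated one
  p_eff <- c(
    p_uu = p[["p_uu"]] + (1 - e) * (p[["p_mu"]] + p[["p_um"]]) +
      (1 - e)^2 * p[["p_mm"]],
    p_mu = e * p[["p_mu"]] + e * (1 - e) * p[["p_mm"]],
    p_um = e * p[["p_um"]] + e * (1 - e) * p[["p_mm"]],
    p_mm = e^2 * p[["p_mm"]]
  )
  counts <- c(
    b133 = p_eff[["p_uu"]],
    b90 = p_eff[["p_mu"]],
    b75 = p_eff[["p_um"]],
    b58 = p_eff[["p_um"]] + p_eff[["p_mm"]],
    b43 = p_eff[["p_mu"]] + p_eff[["p_mm"]],
    b32 = p_eff[["p_mm"]]
  )
  intensity <- if (intensity_mode == "mass") counts * BAND_LENGTHS else counts
  band_profile(intensity)
}

#' Add multiplicative gel quantification noise to a profile
#'
#' Lognormal multiplicative noise per band (mean 1, coefficient of
#' variation `cv`), then renormalization to 100. Intensities stay positive
#' with roughly constant CV, matching densitometry error. Seed-reproducible.
#'
#' @param profile A [band_profile()].
#' @param cv Coefficient of variation, `>= 0`. `cv = 0` is the identity.
#' @param seed Optional integer seed for reproducibility.
#' @return A noisy [band_profile()].
#' @export
add_gel_noise <- function(profile, cv, seed = NULL) {
  s <- band_profile(profile)
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(s)
  draw <- function() {
    sdlog <- sqrt(log(1 + cv^2))
    s * stats::rlnorm(length(s), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  noisy <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  band_profile(noisy)
}

#' Read band-intensity profiles from CSV
#'
#' Expected columns: `sample_id`, then `b133`, `b90`, `b75`, `b58`, `b43`,
#' `b32` (raw intensities; normalized internally). Extra columns (e.g.
#' `group`, `subgroup`) are carried through.
#'
#' @param path CSV path.
#' @return Data frame of profiles.
#' @export
read_band_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", names(BAND_LENGTHS))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("band CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Write band-intensity profiles to CSV
#'
#' @param profiles Data frame as returned by the cohort generator.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_band_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
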