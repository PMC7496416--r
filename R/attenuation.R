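# Readthrough quantification for single-round transcription attenuation
# assays: two band species per lane, terminated (T) and run-off (RO).

#' Fraction readthrough from gel band intensities
#'
#' Raw mode computes \eqn{f = I_{RO} / (I_{RO} + I_T)} per lane. With
#' \code{normalizeByU = TRUE} intensities are first converted to molar
#' signals \eqn{I / u} using each species' uridine count, appropriate when
#' the label is alpha-32P-UTP so band signal scales with U content.
#'
#' @param lanes data.frame with columns \code{intensity_T},
#'   \code{intensity_RO}, optionally \code{lane}, \code{condition},
#'   \code{u_count_T}, \code{u_count_RO}. Intensities must be
#'   non-negative and not both zero in a lane.
#' @param normalizeByU divide intensities by uridine counts first
#'   (requires the u_count columns).
#' @return data.frame: lane, condition, fraction_ro, normalized
#' @examples
#' readthroughFraction(data.frame(intensity_T = 48, intensity_RO = 52))
#' @export
readthroughFraction <- function(lanes, normalizeByU = FALSE) {
  stopifnot(all(c("intensity_T", "intensity_RO") %in% names(lanes)))
  if (any(lanes$intensity_T < 0 | lanes$intensity_RO < 0))
    stop("negative band intensity")
  if (any(lanes$intensity_T + lanes$intensity_RO == 0))
    stop("lane with zero total signal")
  iT <- lanes$intensity_T
  iRO <- lanes$intensity_RO
  if (normalizeByU) {
    if (!all(c("u_count_T", "u_count_RO") %in% names(lanes)) ||
        any(is.na(lanes$u_count_T) | is.na(lanes$u_count_RO)))
      stop("normalizeByU = TRUE requires u_count_T and u_count_RO")
    iT <- iT / lanes$u_count_T
    iRO <- iRO / lanes$u_count_RO
  }
  data.frame(
    lane = if ("lane" %in% names(lanes)) lanes$lane
           else seq_len(nrow(lanes)),
    condition = if ("condition" %in% names(lanes)) lanes$condition
                else NA_character_,
    fraction_ro = iRO / (iRO + iT),
    normalized = normalizeByU,
    stringsAsFactors = FALSE)
}

#' Simulate gel lanes at a known readthrough fraction
#'
#' Molecules are split binomially between run-off and terminated species;
#' each band's intensity is molecules times the species' uridine count
#' times a mean-one lognormal noise factor with coefficient of variation
#' \code{noiseCv}. Seeded and reproducible.
#'
#' @param trueFraction true fraction readthrough per lane (recycled over
#'   \code{nLanes}).
#' @param totalMolecules transcripts per lane.
#' @param noiseCv lognormal noise CV on each band intensity.
#' @param uCountT,uCountRO uridine counts of the terminated and run-off
#'   species (equal by default so the raw intensity ratio estimates the
#'   molecular fraction directly).
#' @param nLanes number of replicate lanes.
#' @param condition label(s) recycled over lanes.
#' @param seed integer RNG seed.
#' @return data.frame of lanes suitable for
#'   \code{\link{readthroughFraction}}
#' @export
simulateLanes <- function(trueFraction, totalMolecules = 10000,
                          noiseCv = 0.05, uCountT = 25, uCountRO = 25,
                          nLanes = 1, condition = NA_character_,
                          seed = 1) {
  stopifnot(all(trueFraction >= 0 & trueFraction <= 1))
  rng <- .seededRNG(seed)
  f <- rep_len(trueFraction, nLanes)
  nRO <- stats::rbinom(nLanes, totalMolecules, f)
  nT <- totalMolecules - nRO
  noise <- function(n) {
    if (noiseCv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + noiseCv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out <- data.frame(
    lane = seq_len(nLanes),
    condition = rep_len(condition, nLanes),
    intensity_T = nT * uCountT * noise(nLanes),
    intensity_RO = nRO * uCountRO * noise(nLanes),
    u_count_T = uCountT, u_count_RO = uCountRO,
    true_fraction = f,
    stringsAsFactors = FALSE)
  rng$restore()
  out
}
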