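# Joint-angle templates for the 16-channel dataglove emulation.
#
# Channel layout mirrors the glove: 3 flexion angles per finger
# (thumb, index, middle, ring, little) plus 1 wrist angle, in degrees.
# Four canonical postures:
#   NEUTRAL - relaxed rest pose at movement onset,
#   FIST    - closed fist held throughout no-shape stimuli,
#   POW     - wide whole-hand opening preparing a power grasp,
#   PRE     - thumb-index opposition preparing a precision grip
#             (remaining fingers extended out of the way).
# POW and PRE are placed near-equidistant from FIST so that an unchanging
# fist is (by construction) about equally surprising under either grip
# hypothesis; values are package constants, not measurements.

ag_channel_names <- c(
  t(outer(c("thumb", "index", "middle", "ring", "little"),
          c("mcp", "pip", "dip"), paste, sep = "_")),
  "wrist"
)

# The grip templates are built so that |POW - NEUTRAL| = |PRE - NEUTRAL| and
# |POW - FIST| = |PRE - FIST| exactly: both grips progress the same distance
# along the open/close axis (u, the NEUTRAL->FIST flexion direction) and the
# same distance along a grip-specific posture direction orthogonal to it.
# An unchanging fist is then, by construction, equally (im)plausible under
# either grip hypothesis, and preshape discrimination rests on the posture
# direction, not on gross opening.
ag_templates <- local({
  neutral <- c(rep(c(30, 35, 32), 5), 5)
  fist    <- c(rep(c(70, 80, 75), 5), 10)
  u <- (fist - neutral) / sqrt(sum((fist - neutral)^2))
  orth_unit <- function(v) {
    w <- v - sum(v * u) * u
    w / sqrt(sum(w^2))
  }
  # power grasp: whole-hand opening, proximal joints leading
  p_pow <- orth_unit(c(rep(c(-1.5, -0.7, -1.0), 5), -1))
  # precision grip: thumb-index closing onto the pad, other fingers extending
  p_pre <- orth_unit(c(rep(c(1.0, 1.1, 1.0), 2), rep(c(-1.0, -1.1, -1.0), 3), 0.5))
  beta <- 14     # shared posture excursion (degrees)
  tpl <- list(NEUTRAL = neutral, FIST = fist,
              POW = neutral + beta * p_pow,
              PRE = neutral + beta * p_pre)
  lapply(tpl, function(v) { names(v) <- ag_channel_names; v })
})

#' Joint-angle template for a hand posture
#'
#' @param which One of `"NEUTRAL"`, `"FIST"`, `"POW"`, `"PRE"`.
#' @return Named numeric vector of 16 joint angles (degrees).
#' @export
#' @examples
#' length(grip_template("POW"))  # 16 channels
grip_template <- function(which = c("NEUTRAL", "FIST", "POW", "PRE")) {
  which <- match.arg(which)
  ag_templates[[which]]
}

#' Thumb-index grip aperture implied by a joint-angle vector
#'
#' A scalar openness proxy: 90 degrees minus the mean flexion of the thumb
#' and index channels. Larger values mean a wider thumb-index opening.
#'
#' @param angles Numeric vector of 16 joint angles (degrees).
#' @return Aperture in degrees of extension.
#' @export
grip_aperture <- function(angles) {
  stopifnot(length(angles) == 16L)
  90 - mean(angles[1:6])
}

# Soft classification of an angle vector into the three visible hand
# patterns. Returns probabilities over c(POW, PRE, FIST) via a Gaussian
# kernel in angle space; near-neutral hands split evenly between the two
# grip patterns by construction.
#' @keywords internal
classify_hand_pattern <- function(angles, kappa = 20) {
  d2 <- vapply(c("POW", "PRE", "FIST"),
               function(k) sum((angles - ag_templates[[k]])^2), numeric(1))
  w <- exp(-(d2 - min(d2)) / (2 * kappa^2))
  w / sum(w)
}
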