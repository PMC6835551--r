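#' Probability that the probe wins the exponential encoding race
#'
#' Shared arrival-time core of all three TOJ models. Both targets are
#' encoded by independent exponential processes; a stimulus with rate `v`
#' (events/ms) has been encoded by time `t` after its onset with
#' probability `1 - exp(-v * t)`. The probe leads at negative SOAs
#' (negative SOA = probe presented first), so for `soa < 0`
#'
#' \deqn{P = 1 - e^{-v_p|SOA|} + e^{-v_p|SOA|} \frac{v_p}{v_p+v_r},}
#'
#' i.e. either the probe finishes before the reference even appears, or
#' both are racing and the probe wins with the Luce choice probability
#' `vp/(vp+vr)`. For `soa >= 0` the reference has the head start and
#' `P = exp(-vr * soa) * vp/(vp+vr)`. The function is continuous at 0,
#' strictly decreasing in `soa`, and tends to 1 (resp. 0) as `soa` goes to
#' minus (plus) infinity.
#'
#' @param vp,vr Encoding rates of probe and reference in events/ms
#'   (strictly positive). Multiply by 1000 for the conventional Hz scale.
#' @param soa Stimulus onset asynchrony in ms (numeric vector, finite).
#'   Negative values mean the probe was presented first.
#' @return Numeric vector of probabilities, one per `soa`.
#' @seealso [toj_prob()] for the full psychometric models.
#' @examples
#' race_prob(0.06, 0.04, 0)    # Luce ratio 0.6
#' race_prob(0.06, 0.04, 50)   # 0.6 * exp(-2)
#' @export
race_prob <- function(vp, vr, soa) {
  check_rate(vp, "vp")
  check_rate(vr, "vr")
  check_soa(soa)
  luce <- vp / (vp + vr)
  p <- numeric(length(soa))
  neg <- soa < 0
  # 1 - e^{-vp|soa|}(1 - luce); exp(vp * soa) == exp(-vp * |soa|) for soa < 0
  p[neg] <- 1 - exp(vp * soa[neg]) * (1 - luce)
  p[!neg] <- exp(-vr * soa[!neg]) * luce
  p
}

check_rate <- function(v, name) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop("invalid parameter: `", name,
         "` must be a single finite rate > 0 (events/ms)", call. = FALSE)
  invisible(v)
}

check_soa <- function(soa) {
  if (!is.numeric(soa) || length(soa) < 1L || anyNA(soa) ||
      any(!is.finite(soa)))
    stop("invalid input: `soa` must be finite numeric (ms)", call. = FALSE)
  invisible(soa)
}
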