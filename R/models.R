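#' @rdname toj_prob
#' @export
toj_models <- function() c("simple", "indecision", "reset")

model_par_names <- function(model) {
  switch(model,
    simple     = c("vp", "vr", "tau"),
    indecision = c("vp", "vr", "delta", "xi", "tau"),
    reset      = c("vp", "vr", "t0", "s0", "tau"),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# Validate and normalize a parameter vector/list for `model`.
# `tau` may be omitted and defaults to 0 (no net processing delay).
as_params <- function(model, params) {
  model <- match.arg(model, toj_models())
  p <- unlist(params)
  if (!is.numeric(p) || is.null(names(p)))
    stop("invalid parameter: `params` must be a named numeric vector or list",
         call. = FALSE)
  if (!"tau" %in% names(p)) p <- c(p, tau = 0)
  need <- model_par_names(model)
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("invalid parameter: missing ", paste(miss, collapse = ", "),
         " for model '", model, "'", call. = FALSE)
  p <- p[need]
  if (anyNA(p) || any(!is.finite(p)))
    stop("invalid parameter: all parameters must be finite", call. = FALSE)
  check_rate(p[["vp"]], "vp")
  check_rate(p[["vr"]], "vr")
  if (model == "indecision") {
    if (p[["delta"]] < 0)
      stop("invalid parameter: `delta` must be >= 0 (ms)", call. = FALSE)
    if (p[["xi"]] < 0 || p[["xi"]] > 1)
      stop("invalid parameter: `xi` must lie in [0, 1]", call. = FALSE)
  }
  if (model == "reset" && p[["s0"]] < 0)
    stop("invalid parameter: `s0` must be >= 0 (ms)", call. = FALSE)
  p
}

#' Psychometric model probabilities for "probe first" judgments
#'
#' Evaluates the probability of a "probe first" response at the given SOAs
#' under one of the three models. All parameter vectors carry encoding
#' rates `vp`, `vr` in events/ms and an optional net delay `tau` in ms
#' (default 0), which shifts the curve along the SOA axis.
#'
#' * `"simple"`: the bare race, `race_prob(vp, vr, soa + tau)`.
#' * `"indecision"`: adds `delta` (half-width of the range of indecision,
#'   ms) and `xi` (bias with which simultaneity percepts are resolved
#'   *against* the probe; a simultaneity percept is reported "probe first"
#'   with probability `1 - xi`). The response probability is
#'   `xi * race_prob(soa + tau + delta) + (1 - xi) * race_prob(soa + tau - delta)`,
#'   equivalently P(probe-first percept) + (1 - xi) P(simultaneous).
#' * `"reset"`: adds `t0` (mean ineffective-exposure threshold, ms) and
#'   `s0` (its across-trial SD, ms). With probability
#'   `w = P(|soa + tau| < t0_trial)`, `t0_trial ~ N(t0, s0)`, the second
#'   onset falls inside the reset window, both races restart together and
#'   the probe wins with the Luce ratio; otherwise the plain race decides:
#'   `w * vp/(vp+vr) + (1-w) * race_prob(soa + tau)`.
#'
#' @param model One of `"simple"`, `"indecision"`, `"reset"`.
#' @param params Named numeric vector or list of model parameters (see
#'   Details above for the names each model requires).
#' @param soa Stimulus onset asynchrony in ms; vectorized. Negative SOA =
#'   probe presented first.
#' @return Numeric vector of response probabilities in \[0, 1\].
#' @examples
#' toj_prob("simple", c(vp = 0.06, vr = 0.04), soa = c(-50, 0, 50))
#' toj_prob("indecision",
#'          c(vp = 0.05, vr = 0.05, delta = 20, xi = 0.5), soa = 0)
#' @export
toj_prob <- function(model, params, soa) {
  model <- match.arg(model, toj_models())
  p <- as_params(model, params)
  switch(model,
    simple     = toj_prob_simple(p, soa),
    indecision = toj_prob_indecision(p, soa),
    reset      = toj_prob_reset(p, soa)
  )
}

#' @rdname toj_prob
#' @export
toj_prob_simple <- function(params, soa) {
  p <- as_params("simple", params)
  race_prob(p[["vp"]], p[["vr"]], soa + p[["tau"]])
}

#' @rdname toj_prob
#' @export
toj_prob_indecision <- function(params, soa) {
  p <- as_params("indecision", params)
  s <- soa + p[["tau"]]
  p[["xi"]] * race_prob(p[["vp"]], p[["vr"]], s + p[["delta"]]) +
    (1 - p[["xi"]]) * race_prob(p[["vp"]], p[["vr"]], s - p[["delta"]])
}

#' @rdname toj_prob
#' @export
toj_prob_reset <- function(params, soa) {
  p <- as_params("reset", params)
  w <- reset_prob(p, soa)
  luce <- p[["vp"]] / (p[["vp"]] + p[["vr"]])
  w * luce + (1 - w) * race_prob(p[["vp"]], p[["vr"]], soa + p[["tau"]])
}

#' Percept probabilities under the indecision-range model
#'
#' Splits each trial of the indecision-range model into its three percept
#' classes: "probe first" (the probe's arrival leads by more than `delta`
#' ms), "reference first" (the reference leads by more than `delta`), and
#' "simultaneous" (arrival difference inside the +/- `delta` range of
#' indecision). The response bias `xi` plays no role at the percept level.
#'
#' @inheritParams toj_prob
#' @param params Named vector with `vp`, `vr`, `delta` and optionally
#'   `tau`; `xi` is accepted but ignored.
#' @return A data.frame with columns `soa`, `probe_first`, `simultaneous`,
#'   `reference_first`; the three probabilities sum to 1 in every row.
#' @export
percept_probs <- function(params, soa) {
  p <- unlist(params)
  if (!"xi" %in% names(p)) p <- c(p, xi = 0.5)  # inert placeholder
  p <- as_params("indecision", p)
  s <- soa + p[["tau"]]
  pf <- race_prob(p[["vp"]], p[["vr"]], s + p[["delta"]])
  rf <- 1 - race_prob(p[["vp"]], p[["vr"]], s - p[["delta"]])
  data.frame(soa = soa, probe_first = pf, simultaneous = 1 - pf - rf,
             reference_first = rf)
}

#' Probability that a trial falls in the encoding-reset window
#'
#' Mixing weight of the reset model: the probability that the second
#' stimulus onset arrives within the trial's ineffective-exposure window
#' `t0_trial ~ Normal(t0, s0)` of the first, i.e.
#' `P(|soa + tau| < t0_trial)`. With `s = soa + tau` this equals
#' `pnorm((s + t0)/s0)` for `s <= 0` and `1 - pnorm((s - t0)/s0)` for
#' `s > 0`; both branches agree at `s = 0` where the weight is
#' `pnorm(t0/s0)`. The normal is not truncated: a negative `t0_trial` draw
#' simply means the window never triggers. `s0 = 0` is handled as the
#' degenerate step limit, the indicator of `|soa + tau| <= t0`.
#'
#' @inheritParams toj_prob
#' @param params Named vector with `vp`, `vr`, `t0`, `s0` and optionally
#'   `tau`.
#' @return Numeric vector of reset probabilities in \[0, 1\].
#' @export
reset_prob <- function(params, soa) {
  p <- as_params("reset", params)
  s <- soa + p[["tau"]]
  check_soa(s)
  if (p[["s0"]] == 0) return(as.numeric(abs(s) <= p[["t0"]]))
  ifelse(s <= 0,
         pnorm((s + p[["t0"]]) / p[["s0"]]),
         1 - pnorm((s - p[["t0"]]) / p[["s0"]]))
}
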