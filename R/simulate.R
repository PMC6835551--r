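# Run `expr` with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Per-SOA judgment counts
#'
#' Container for observed or simulated "probe first" counts: a data.frame
#' with columns `soa_ms`, `n_trials`, `n_probe_first` and class
#' `"toj_data"`. [fit_toj()] accepts any data.frame with these columns.
#'
#' @param soa_ms SOA values in ms.
#' @param n_trials Trials presented at each SOA (positive integers).
#' @param n_probe_first "Probe first" responses at each SOA
#'   (`0 <= n_probe_first <= n_trials`).
#' @param label Optional condition label, stored as an attribute.
#' @return A `"toj_data"` data.frame.
#' @export
toj_data <- function(soa_ms, n_trials, n_probe_first, label = NULL) {
  if (length(soa_ms) != length(n_trials) ||
      length(soa_ms) != length(n_probe_first))
    stop("`soa_ms`, `n_trials` and `n_probe_first` must have equal length",
         call. = FALSE)
  check_soa(soa_ms)
  n <- as.integer(n_trials)
  k <- as.integer(n_probe_first)
  if (anyNA(n) || any(n < 1L))
    stop("`n_trials` must all be >= 1", call. = FALSE)
  if (anyNA(k) || any(k < 0L) || any(k > n))
    stop("`n_probe_first` must satisfy 0 <= count <= n_trials at every SOA",
         call. = FALSE)
  out <- data.frame(soa_ms = as.numeric(soa_ms), n_trials = n,
                    n_probe_first = k)
  class(out) <- c("toj_data", "data.frame")
  if (!is.null(label)) attr(out, "label") <- label
  out
}

#' Sample binomial judgment data from a model
#'
#' Draws, at every SOA of the design, a binomial count of "probe first"
#' responses with success probability given by the model curve. Identical
#' seeds give identical counts; the caller's RNG stream is left untouched.
#'
#' @inheritParams toj_prob
#' @param design A [toj_design()] object.
#' @param seed Integer seed (required: simulated data should always be
#'   reproducible).
#' @return A [toj_data()] data.frame with attributes `model`, `params`,
#'   `seed` and `label` recording the generating configuration.
#' @examples
#' d <- simulate_judgments("reset",
#'        c(vp = 0.06, vr = 0.04, t0 = 15, s0 = 18),
#'        toj_design("exp1"), seed = 1)
#' head(d)
#' @export
simulate_judgments <- function(model, params, design, seed) {
  stopifnot(inherits(design, "toj_design"))
  if (missing(seed) || is.null(seed))
    stop("`seed` is required for simulate_judgments()", call. = FALSE)
  p <- toj_prob(model, params, design$soas)
  k <- with_seed(seed, rbinom(length(p), design$repetitions, p))
  out <- toj_data(design$soas, design$repetitions, k, label = design$label)
  attr(out, "model") <- model
  attr(out, "params") <- as_params(model, params)
  attr(out, "seed") <- seed
  out
}

#' Per-trial Monte Carlo simulators
#'
#' Trial-level simulators of the three models, used as independent oracles
#' for the closed-form curves in [toj_prob()]. They draw actual exponential
#' encoding latencies (and, for the reset model, per-trial normal `t0`
#' draws) rather than evaluating any model formula, and consume the current
#' RNG stream (seed them with [set.seed()] for reproducibility).
#'
#' * `simulate_race_trials()` offsets the two onsets by the SOA, draws an
#'   exponential encoding latency for each target, and labels the winner
#'   (`"probe"`/`"reference"`; exact ties, a probability-zero event, go to
#'   the probe).
#' * `simulate_indecision_trials()` computes the arrival difference at
#'   separation `soa + tau`; the percept is `"probe_first"` if the probe
#'   leads by more than `delta`, `"reference_first"` if the reference does,
#'   otherwise `"simultaneous"`, which is reported as "probe first" with
#'   probability `1 - xi`.
#' * `simulate_reset_trials()` draws `t0_trial ~ Normal(t0, s0)` (no
#'   truncation); if `|soa + tau| < t0_trial` both stimuli race from a
#'   common start via fresh exponential draws, else the plain race runs at
#'   `soa + tau`.
#'
#' @inheritParams toj_prob
#' @param vp,vr Encoding rates in events/ms.
#' @param soa A single SOA in ms.
#' @param n Number of trials to simulate.
#' @return `simulate_race_trials()`: character vector of winners.
#'   `simulate_indecision_trials()`: data.frame with columns `percept` and
#'   `response`. `simulate_reset_trials()`: data.frame with columns
#'   `reset` (logical) and `response`.
#' @export
simulate_race_trials <- function(vp, vr, soa, n) {
  check_rate(vp, "vp"); check_rate(vr, "vr"); check_soa(soa)
  stopifnot(length(soa) == 1L, n >= 1)
  arr_p <- max(soa, 0) + rexp(n, vp)
  arr_r <- max(-soa, 0) + rexp(n, vr)
  ifelse(arr_p <= arr_r, "probe", "reference")
}

#' @rdname simulate_race_trials
#' @export
simulate_indecision_trials <- function(params, soa, n) {
  p <- as_params("indecision", params)
  stopifnot(length(soa) == 1L, n >= 1)
  s <- soa + p[["tau"]]
  arr_p <- max(s, 0) + rexp(n, p[["vp"]])
  arr_r <- max(-s, 0) + rexp(n, p[["vr"]])
  lead <- arr_r - arr_p  # > 0: probe leads
  percept <- ifelse(lead > p[["delta"]], "probe_first",
                    ifelse(lead < -p[["delta"]], "reference_first",
                           "simultaneous"))
  guess_pf <- runif(n) < (1 - p[["xi"]])
  response <- ifelse(percept == "probe_first", "probe_first",
                     ifelse(percept == "reference_first", "reference_first",
                            ifelse(guess_pf, "probe_first",
                                   "reference_first")))
  data.frame(percept = percept, response = response)
}

#' @rdname simulate_race_trials
#' @export
simulate_reset_trials <- function(params, soa, n) {
  p <- as_params("reset", params)
  stopifnot(length(soa) == 1L, n >= 1)
  s <- soa + p[["tau"]]
  t0_trial <- rnorm(n, p[["t0"]], p[["s0"]])
  reset <- abs(s) < t0_trial
  # common start after a reset: fresh exponential draws from one origin
  arr_p <- ifelse(reset, 0, max(s, 0)) + rexp(n, p[["vp"]])
  arr_r <- ifelse(reset, 0, max(-s, 0)) + rexp(n, p[["vr"]])
  data.frame(reset = reset,
             response = ifelse(arr_p <= arr_r, "probe_first",
                               "reference_first"))
}

#' Empirical psychometric curve from per-trial simulation
#'
#' Runs the matching per-trial simulator at each SOA and returns the
#' empirical "probe first" frequency with its binomial standard error.
#' This is the package's independent oracle harness: the simulators share
#' no code with the closed forms they are checked against.
#'
#' @inheritParams toj_prob
#' @param soas Numeric vector of SOAs (ms).
#' @param n_per_soa Trials per SOA (>= 1).
#' @param seed Integer seed.
#' @return data.frame with columns `soa`, `freq`, `se`, `n`.
#' @examples
#' mc <- monte_carlo_curve("simple", c(vp = 0.06, vr = 0.04),
#'                         soas = c(-50, 0, 50), n_per_soa = 2000, seed = 1)
#' @export
monte_carlo_curve <- function(model, params, soas, n_per_soa, seed = NULL) {
  model <- match.arg(model, toj_models())
  p <- as_params(model, params)
  stopifnot(n_per_soa >= 1)
  with_seed(seed, {
    freq <- vapply(soas, function(s) {
      pf <- switch(model,
        simple = simulate_race_trials(p[["vp"]], p[["vr"]],
                                      s + p[["tau"]], n_per_soa) == "probe",
        indecision = simulate_indecision_trials(p, s, n_per_soa)$response ==
          "probe_first",
        reset = simulate_reset_trials(p, s, n_per_soa)$response ==
          "probe_first")
      mean(pf)
    }, numeric(1))
    data.frame(soa = soas, freq = freq,
               se = sqrt(freq * (1 - freq) / n_per_soa), n = n_per_soa)
  })
}
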