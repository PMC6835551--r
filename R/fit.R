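#' Binomial log-likelihood of a model on judgment data
#'
#' Sum over SOAs of `k * log(p) + (n - k) * log(1 - p)` with `p` the model
#' probability at that SOA. Probabilities are clipped to
#' `[1e-9, 1 - 1e-9]` so that a saturated cell never produces `-Inf`; the
#' binomial coefficient is omitted (it is constant across models, so BIC
#' differences are unaffected).
#'
#' @inheritParams toj_prob
#' @param data A [toj_data()] object or data.frame with columns `soa_ms`,
#'   `n_trials`, `n_probe_first`.
#' @return The log-likelihood (a single number).
#' @export
binomial_loglik <- function(model, params, data) {
  d <- as_judgment_df(data)
  p <- toj_prob(model, params, d$soa_ms)
  loglik_from_probs(p, d$n_probe_first, d$n_trials)
}

loglik_from_probs <- function(p, k, n) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  sum(k * log(p) + (n - k) * log1p(-p))
}

as_judgment_df <- function(data) {
  if (inherits(data, "toj_design"))
    stop("`data` is a design; simulate or supply counts first", call. = FALSE)
  d <- as.data.frame(data)
  need <- c("soa_ms", "n_trials", "n_probe_first")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("`data` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(d$n_probe_first < 0) || any(d$n_probe_first > d$n_trials) ||
      any(d$n_trials < 1))
    stop("`data` counts must satisfy 0 <= n_probe_first <= n_trials",
         call. = FALSE)
  check_soa(d$soa_ms)
  d[need]
}

#' Bayesian information criterion
#'
#' `k * log(n) - 2 * loglik`, with `n` the total trial count (the binomial
#' likelihood's unit of observation is the trial, not the SOA level).
#' Smaller is better; see [compare_toj()] for the evidence convention.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_free_parameters Number of free parameters.
#' @param n_trials Total number of trials.
#' @export
bic <- function(loglik, n_free_parameters, n_trials) {
  stopifnot(n_trials >= 1)
  n_free_parameters * log(n_trials) - 2 * loglik
}

#' Default parameter bounds used in fitting
#'
#' Rates are bounded to \[1e-4, 1\] events/ms (0.1 to 1000 Hz), `delta`
#' and `t0` to \[0, 200\] ms, `s0` to \[0, 100\] ms, `xi` to \[0, 1\] and
#' `tau` to \[-200, 200\] ms — wide enough to cover every plausible
#' psychophysical estimate (rates of tens of Hz, plateau widths of tens of
#' ms) with margin.
#'
#' @inheritParams toj_prob
#' @return Named list of `c(lower, upper)` pairs for the model's
#'   parameters.
#' @export
default_bounds <- function(model) {
  model <- match.arg(model, toj_models())
  all_b <- list(vp = c(1e-4, 1), vr = c(1e-4, 1), delta = c(0, 200),
                xi = c(0, 1), t0 = c(0, 200), s0 = c(0, 100),
                tau = c(-200, 200))
  all_b[model_par_names(model)]
}

# Logit rescaling between a box and the unconstrained optimizer space.
to_unit <- function(theta, lo, hi) (theta - lo) / (hi - lo)
from_z <- function(z, lo, hi) lo + (hi - lo) * plogis(z)
to_z <- function(theta, lo, hi) {
  u <- pmin(pmax(to_unit(theta, lo, hi), 1e-4), 1 - 1e-4)
  qlogis(u)
}

#' Fit a TOJ model by binomial maximum likelihood
#'
#' Maximizes the binomial log-likelihood of the chosen model with a
#' bounded derivative-free search: `n_starts` Latin-hypercube starting
#' points are drawn over the (logit-rescaled) parameter box, each is
#' polished by Nelder-Mead, and the best solution gets one simplex
#' restart. Parameters named in `fixed` are frozen; the default
#' `fixed = c(tau = 0)` reproduces the equal-complexity configuration of a
#' basic (uncued) TOJ: 2 free parameters for the simple model and 4 for
#' either plateau model. Pass `fixed = NULL` to free `tau` (cued designs).
#'
#' @param data A [toj_data()] object or data.frame with columns `soa_ms`,
#'   `n_trials`, `n_probe_first`. Duplicate SOA rows are allowed (their
#'   likelihood contributions add).
#' @param model `"simple"`, `"indecision"` or `"reset"`.
#' @param fixed Named numeric vector of parameters to freeze (values must
#'   lie inside the bounds), or `NULL` to free everything.
#' @param bounds Named list of `c(lower, upper)` pairs overriding entries
#'   of [default_bounds()].
#' @param n_starts Number of Latin-hypercube starting points (>= 1).
#' @param seed Seed for the starting-point draw (fits are deterministic
#'   given data and seed).
#' @param control Passed to [stats::optim()]'s Nelder-Mead (defaults:
#'   `maxit = 2000`, `reltol = 1e-10`).
#' @return An object of class `"toj_fit"`; see
#'   [coef.toj_fit()], [logLik.toj_fit()], [predict.toj_fit()],
#'   [plot.toj_fit()], [residuals.toj_fit()], [simulate.toj_fit()].
#' @examples
#' dat <- simulate_judgments("indecision",
#'          c(vp = 0.05, vr = 0.05, delta = 20, xi = 0.5),
#'          toj_design("exp1"), seed = 7)
#' fit <- fit_toj(dat, "indecision", n_starts = 4)
#' coef(fit)
#' @export
fit_toj <- function(data, model = c("simple", "indecision", "reset"),
                    fixed = c(tau = 0), bounds = NULL, n_starts = 10,
                    seed = 1L, control = list()) {
  model <- match.arg(model)
  d <- as_judgment_df(data)
  for (a in c("participant", "condition", "label"))
    attr(d, a) <- attr(data, a, exact = TRUE)
  if (all(d$n_probe_first == 0L) || all(d$n_probe_first == d$n_trials))
    stop("degenerate data: all counts are 0 or all equal n_trials; ",
         "the likelihood has no interior optimum", call. = FALSE)
  stopifnot(n_starts >= 1)
  control <- modifyList(list(maxit = 2000, reltol = 1e-10), control)

  pars <- model_par_names(model)
  b <- default_bounds(model)
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), pars)
    if (length(bad))
      stop("bounds given for unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    b <- modifyList(b, bounds)
  }
  lo <- vapply(b, `[`, numeric(1), 1L)
  hi <- vapply(b, `[`, numeric(1), 2L)

  fixed <- unlist(fixed)
  fixed <- fixed[names(fixed) %in% pars]  # e.g. tau=0 is inert extras-free
  if (length(fixed)) {
    out_of <- fixed < lo[names(fixed)] | fixed > hi[names(fixed)]
    if (any(out_of))
      stop("fixed value(s) outside bounds: ",
           paste(names(fixed)[out_of], collapse = ", "), call. = FALSE)
  }
  free <- setdiff(pars, names(fixed))
  nf <- length(free)
  n_trials <- sum(d$n_trials)

  build_full <- function(theta) {
    full <- setNames(numeric(length(pars)), pars)
    full[names(fixed)] <- fixed
    full[free] <- theta
    full
  }
  negll <- function(z) {
    full <- build_full(from_z(z, lo[free], hi[free]))
    p <- toj_prob(model, full, d$soa_ms)
    -loglik_from_probs(p, d$n_probe_first, d$n_trials)
  }

  if (nf == 0L) {
    full <- build_full(numeric(0))
    ll <- binomial_loglik(model, full, d)
    res <- list(coefficients = full, loglik = ll, converged = TRUE,
                best_start = NA_integer_, start_values = numeric(0))
  } else {
    starts <- with_seed(seed, lhs::randomLHS(n_starts, nf))
    runs <- vector("list", n_starts)
    for (i in seq_len(n_starts)) {
      z0 <- qlogis(pmin(pmax(starts[i, ], 1e-3), 1 - 1e-3))
      runs[[i]] <- tryCatch(
        if (nf == 1L)
          optim(z0, negll, method = "Brent", lower = -25, upper = 25,
                control = list(maxit = control$maxit))
        else
          optim(z0, negll, method = "Nelder-Mead", control = control),
        error = function(e) NULL)
    }
    ok <- !vapply(runs, is.null, logical(1))
    if (!any(ok))
      stop("fit failure: all ", n_starts, " starts failed for model '",
           model, "'", call. = FALSE)
    vals <- vapply(runs, function(r) if (is.null(r)) Inf else r$value,
                   numeric(1))
    best_i <- which.min(vals)
    # one simplex restart from the incumbent guards against collapse
    polish <- if (nf == 1L) runs[[best_i]] else
      optim(runs[[best_i]]$par, negll, method = "Nelder-Mead",
            control = control)
    full <- build_full(from_z(polish$par, lo[free], hi[free]))
    res <- list(coefficients = full, loglik = -polish$value,
                converged = polish$convergence == 0L,
                best_start = best_i, start_values = vals)
  }

  structure(list(
    model = model,
    coefficients = res$coefficients,
    free = free,
    fixed = fixed,
    loglik = res$loglik,
    n_free = nf,
    n_trials = n_trials,
    bic = bic(res$loglik, nf, n_trials),
    converged = res$converged,
    best_start = res$best_start,
    start_values = res$start_values,
    n_starts = n_starts,
    bounds = b,
    seed = seed,
    data = d,
    call = match.call()
  ), class = "toj_fit")
}
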