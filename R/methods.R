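# S3 methods for "toj_fit" objects.

# Rates are stored in events/ms; display in Hz (x1000) alongside.
display_params <- function(coefs) {
  out <- coefs
  hz <- names(out) %in% c("vp", "vr")
  out[hz] <- out[hz] * 1000
  units <- ifelse(names(out) %in% c("vp", "vr"), "Hz",
                  ifelse(names(out) == "xi", "", "ms"))
  data.frame(parameter = names(out), estimate = unname(coefs),
             display = unname(out), unit = units)
}

#' @export
print.toj_fit <- function(x, digits = 4, ...) {
  cat("TOJ model fit: '", x$model, "' (binomial maximum likelihood)\n",
      sep = "")
  tab <- display_params(x$coefficients)
  tab$role <- ifelse(tab$parameter %in% x$free, "free", "fixed")
  tab$display <- signif(tab$display, digits)
  print(tab, row.names = FALSE)
  cat("logLik ", format(x$loglik, digits = digits + 2),
      "  BIC ", format(x$bic, digits = digits + 2),
      "  (", x$n_free, " free parameters, ", x$n_trials, " trials)\n",
      sep = "")
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
summary.toj_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.toj_fit")
}

#' @export
print.summary.toj_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  luce <- f$coefficients[["vp"]] /
    (f$coefficients[["vp"]] + f$coefficients[["vr"]])
  cat("Luce ratio vp/(vp+vr): ", signif(luce, digits),
      "; capacity C = vp+vr: ",
      signif(1000 * (f$coefficients[["vp"]] + f$coefficients[["vr"]]),
             digits), " Hz\n", sep = "")
  near <- vapply(f$free, function(nm) {
    b <- f$bounds[[nm]]
    th <- f$coefficients[[nm]]
    w <- b[2] - b[1]
    min(th - b[1], b[2] - th) < 1e-3 * w
  }, logical(1))
  if (any(near))
    cat("note: estimate(s) near a bound: ",
        paste(f$free[near], collapse = ", "), "\n", sep = "")
  cat("best start: ", f$best_start, " of ", f$n_starts,
      "; converged: ", f$converged, "\n", sep = "")
  invisible(x)
}

#' Extract quantities from a fitted TOJ model
#'
#' `coef()` returns the full parameter vector in internal units (rates in
#' events/ms, times in ms); `logLik()` carries `df` (free parameters) and
#' `nobs` (total trials) so that [stats::BIC()] agrees with the stored
#' `$bic`; `nobs()` is the total trial count.
#'
#' @param object A `"toj_fit"` object.
#' @param ... Unused.
#' @name toj_fit-extractors
#' @export
coef.toj_fit <- function(object, ...) object$coefficients

#' @rdname toj_fit-extractors
#' @export
logLik.toj_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = object$n_trials,
            class = "logLik")
}

#' @rdname toj_fit-extractors
#' @export
nobs.toj_fit <- function(object, ...) object$n_trials

#' Predicted "probe first" probabilities from a fitted model
#'
#' @param object A `"toj_fit"`.
#' @param newdata Optional data.frame with a `soa_ms` column; defaults to
#'   the fitted data's SOAs.
#' @param soa Optional numeric vector of SOAs (ms), overriding `newdata`.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.toj_fit <- function(object, newdata = NULL, soa = NULL, ...) {
  if (is.null(soa))
    soa <- if (is.null(newdata)) object$data$soa_ms else newdata$soa_ms
  toj_prob(object$model, object$coefficients, soa)
}

#' Residuals of a fitted TOJ model
#'
#' Per-SOA residuals of the binomial fit. `"response"` residuals are
#' observed minus fitted frequency, `"pearson"` residuals divide by the
#' binomial standard error `sqrt(p (1-p) / n)`.
#'
#' @param object A `"toj_fit"`.
#' @param type `"pearson"` (default) or `"response"`.
#' @param ... Unused.
#' @export
residuals.toj_fit <- function(object, type = c("pearson", "response"),
                              ...) {
  type <- match.arg(type)
  d <- object$data
  p <- predict(object)
  obs <- d$n_probe_first / d$n_trials
  r <- obs - p
  if (type == "pearson") {
    pc <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    r <- r / sqrt(pc * (1 - pc) / d$n_trials)
  }
  r
}

#' Simulate judgment data from a fitted model
#'
#' Parametric-bootstrap style simulation: draws new binomial counts at the
#' fitted data's SOAs and trial numbers, using the fitted parameters.
#'
#' @param object A `"toj_fit"`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed (required for reproducibility).
#' @param ... Unused.
#' @return A list of `nsim` [toj_data()] objects.
#' @export
simulate.toj_fit <- function(object, nsim = 1, seed = 1L, ...) {
  d <- object$data
  des <- toj_design(soas = d$soa_ms, repetitions = d$n_trials,
                    label = paste0("sim_", object$model))
  lapply(seq_len(nsim), function(i)
    simulate_judgments(object$model, object$coefficients, des,
                       seed = seed + i - 1L))
}

#' Plot data and fitted psychometric curve
#'
#' Observed "probe first" frequencies with the fitted model curve overlaid
#' on a fine SOA grid.
#'
#' @param x A `"toj_fit"`.
#' @param n_grid Number of grid points for the curve.
#' @param ... Passed to [plot()].
#' @export
plot.toj_fit <- function(x, n_grid = 401, ...) {
  d <- x$data
  grid <- seq(min(d$soa_ms), max(d$soa_ms), length.out = n_grid)
  plot(d$soa_ms, d$n_probe_first / d$n_trials, ylim = c(0, 1),
       xlab = "SOA (ms)  [negative = probe first]",
       ylab = "P(\"probe first\")",
       main = paste0("TOJ fit: ", x$model), ...)
  lines(grid, toj_prob(x$model, x$coefficients, grid))
  invisible(x)
}

#' @export
print.toj_data <- function(x, ...) {
  lab <- attr(x, "label")
  mod <- attr(x, "model")
  cat("TOJ judgment data: ", nrow(x), " SOAs, ", sum(x$n_trials),
      " trials", if (!is.null(lab)) paste0(" ('", lab, "')"),
      if (!is.null(mod)) paste0(", simulated from '", mod, "'"),
      "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
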