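#' Evidence label for a BIC difference
#'
#' Differences of 10 and larger are read as strong evidence for the model
#' with the smaller score; below that the standard Kass-Raftery-style
#' convention is used: `< 2` inconclusive, `2` to `< 10` positive.
#'
#' @param delta_bic Nonnegative BIC difference(s).
#' @return Character vector: `"inconclusive"`, `"positive"` or `"strong"`.
#' @export
bic_evidence <- function(delta_bic) {
  if (any(delta_bic < 0)) stop("`delta_bic` must be >= 0", call. = FALSE)
  ifelse(delta_bic >= 10, "strong",
         ifelse(delta_bic >= 2, "positive", "inconclusive"))
}

#' Compare fitted TOJ models by BIC
#'
#' Ranks fits of the same data by BIC and labels pairwise differences
#' with the evidence convention of [bic_evidence()]. All fits must be on
#' the same data (equal total trial counts).
#'
#' @param ... `"toj_fit"` objects (or a single list of them). Plain lists
#'   carrying `model`, `loglik`, `n_free`, `n_trials` and `bic` fields —
#'   e.g. fit results re-read from JSON — are accepted too.
#' @return An object of class `"toj_comparison"`: list with a `table`
#'   (one row per model, sorted by BIC, with `delta_bic` relative to the
#'   best), the `preferred` model id, and a pairwise `evidence` table.
#' @examples
#' dat <- simulate_judgments("indecision",
#'          c(vp = 0.05, vr = 0.05, delta = 20, xi = 0.5),
#'          toj_design("exp1"), seed = 3)
#' cmp <- compare_toj(fit_toj(dat, "simple", n_starts = 3),
#'                    fit_toj(dat, "indecision", n_starts = 3))
#' cmp$preferred
#' @export
compare_toj <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "toj_fit") &&
      is.null(fits[[1]]$bic))
    fits <- fits[[1]]
  if (length(fits) < 2L)
    stop("need at least two fits to compare", call. = FALSE)
  fields <- c("model", "loglik", "n_free", "n_trials", "bic")
  for (f in fits) {
    miss <- fields[vapply(fields, function(nm) is.null(f[[nm]]),
                          logical(1))]
    if (length(miss))
      stop("fit object lacks field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  n_trials <- vapply(fits, function(f) as.numeric(f$n_trials), numeric(1))
  if (length(unique(n_trials)) != 1L)
    stop("inconsistent comparison: fits are not on the same data ",
         "(total trial counts differ)", call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, function(f) as.character(f$model), character(1)),
    n_free = vapply(fits, function(f) as.numeric(f$n_free), numeric(1)),
    loglik = vapply(fits, function(f) as.numeric(f$loglik), numeric(1)),
    bic = vapply(fits, function(f) as.numeric(f$bic), numeric(1))
  )
  tab <- tab[order(tab$bic), ]
  tab$delta_bic <- tab$bic - tab$bic[1]
  tab$evidence_vs_best <- bic_evidence(tab$delta_bic)
  rownames(tab) <- NULL
  pairs <- t(combn(nrow(tab), 2))
  evidence <- data.frame(
    preferred = tab$model[pairs[, 1]],
    over = tab$model[pairs[, 2]],
    delta_bic = tab$bic[pairs[, 2]] - tab$bic[pairs[, 1]]
  )
  evidence$label <- bic_evidence(evidence$delta_bic)
  structure(list(table = tab, preferred = tab$model[1],
                 evidence = evidence, n_trials = n_trials[1]),
            class = "toj_comparison")
}

#' @export
print.toj_comparison <- function(x, digits = 4, ...) {
  cat("TOJ model comparison (", x$n_trials, " trials; smaller BIC wins)\n",
      sep = "")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 2)
  tab$bic <- round(tab$bic, 2)
  tab$delta_bic <- round(tab$delta_bic, 2)
  print(tab, row.names = FALSE)
  cat("preferred: '", x$preferred, "'\n", sep = "")
  invisible(x)
}

#' Seeded parameter-recovery study
#'
#' Repeatedly samples binomial judgment data from a generating model,
#' refits both the generating model and the simple race to each replicate,
#' and summarizes estimation error and BIC model selection. This is the
#' package's main self-validation harness: with a full-scale design the
#' generating plateau model should recover its parameters closely and be
#' preferred over the simple race in nearly every replicate.
#'
#' @inheritParams toj_prob
#' @param true_params Generating parameter vector.
#' @param design A [toj_design()].
#' @param n_replicates Number of replicates (>= 1).
#' @param fixed Passed to [fit_toj()] for both models (default freezes
#'   `tau` at 0, the basic-TOJ configuration).
#' @param n_starts,seed Multi-start count and master seed; all replicate
#'   and fit seeds derive from `seed`.
#' @return Object of class `"toj_recovery"`: list with `true` (the free
#'   generating parameters), `estimates` (replicate x parameter matrix),
#'   `abs_error`, `median_abs_error`, `prefers_generating` (logical per
#'   replicate: BIC of generating-model fit below the simple fit's),
#'   `frac_preferred`, `delta_bic_vs_simple`, and `failures`.
#' @export
parameter_recovery <- function(model, true_params, design,
                               n_replicates = 20, fixed = c(tau = 0),
                               n_starts = 10, seed = 1L) {
  model <- match.arg(model, toj_models())
  stopifnot(inherits(design, "toj_design"), n_replicates >= 1)
  true <- as_params(model, true_params)
  seeds <- with_seed(seed,
                     matrix(sample.int(.Machine$integer.max - 1L,
                                       3L * n_replicates),
                            ncol = 3L))
  free <- setdiff(model_par_names(model), names(unlist(fixed)))
  est <- matrix(NA_real_, n_replicates, length(free),
                dimnames = list(NULL, free))
  prefers <- rep(NA, n_replicates)
  dbic <- rep(NA_real_, n_replicates)
  failures <- character(0)
  for (i in seq_len(n_replicates)) {
    res <- tryCatch({
      dat <- simulate_judgments(model, true, design, seed = seeds[i, 1])
      fg <- fit_toj(dat, model, fixed = fixed, n_starts = n_starts,
                    seed = seeds[i, 2])
      fs <- fit_toj(dat, "simple", fixed = fixed, n_starts = n_starts,
                    seed = seeds[i, 3])
      list(fg = fg, fs = fs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("replicate ", i, ": ",
                                     conditionMessage(res)))
      next
    }
    est[i, ] <- res$fg$coefficients[free]
    prefers[i] <- res$fg$bic < res$fs$bic
    dbic[i] <- res$fs$bic - res$fg$bic
  }
  abs_err <- abs(sweep(est, 2, true[free]))
  structure(list(
    model = model,
    true = true[free],
    fixed = fixed,
    design = design,
    n_replicates = n_replicates,
    seed = seed,
    estimates = est,
    abs_error = abs_err,
    median_abs_error = apply(abs_err, 2, median, na.rm = TRUE),
    prefers_generating = prefers,
    frac_preferred = mean(prefers, na.rm = TRUE),
    delta_bic_vs_simple = dbic,
    failures = failures
  ), class = "toj_recovery")
}

#' @export
print.toj_recovery <- function(x, digits = 4, ...) {
  cat("Parameter recovery: model '", x$model, "', ", x$n_replicates,
      " replicates of design '", x$design$label, "'\n", sep = "")
  tab <- data.frame(parameter = names(x$true), true = unname(x$true),
                    median_estimate = apply(x$estimates, 2, median,
                                            na.rm = TRUE),
                    median_abs_error = unname(x$median_abs_error))
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  cat("BIC prefers generating class over simple race in ",
      round(100 * x$frac_preferred, 1), "% of replicates\n", sep = "")
  if (length(x$failures))
    cat(length(x$failures), "replicate(s) failed\n")
  invisible(x)
}
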