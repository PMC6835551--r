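test_that("binomial log-likelihood matches the closed form and is additive", {
  d1 <- toj_data(0, 10, 5)
  expect_equal(binomial_loglik("simple", c(vp = 0.05, vr = 0.05), d1),
               10 * log(0.5), tolerance = 1e-9)
  des <- toj_design("exp1")
  dat <- simulate_judgments("reset", pars_reset, des, seed = 2)
  total <- binomial_loglik("reset", pars_reset, dat)
  per_row <- vapply(seq_len(nrow(dat)), function(i)
    binomial_loglik("reset", pars_reset, dat[i, , drop = FALSE]),
    numeric(1))
  expect_equal(total, sum(per_row), tolerance = 1e-9)
})

test_that("clipping keeps saturated cells finite", {
  # true probability ~ 0 at soa 2000; a 0 count contributes ~ n*log(1-1e-9)
  d <- toj_data(2000, 100, 0)
  ll <- binomial_loglik("simple", pars_simple, d)
  expect_true(is.finite(ll))
  expect_equal(ll, 0, tolerance = 1e-6)
})

test_that("BIC arithmetic is n_free * log(n_trials) - 2 * loglik", {
  expect_equal(bic(-1000, 4, 5040), 2000 + 4 * log(5040),
               tolerance = 1e-9)
  expect_equal(bic(-500, 0, 100), 1000)
  expect_equal(bic(-1000, 4, 5040) - bic(-1000, 2, 5040), 2 * log(5040),
               tolerance = 1e-9)
})

test_that("noise-free simple-model data is recovered within 2%", {
  des <- toj_design("exp1")
  p <- toj_prob("simple", pars_simple, des$soas)
  dat <- toj_data(des$soas, des$repetitions, round(des$repetitions * p))
  fit <- fit_toj(dat, "simple")
  expect_lt(abs(coef(fit)[["vp"]] - 0.06) / 0.06, 0.02)
  expect_lt(abs(coef(fit)[["vr"]] - 0.04) / 0.04, 0.02)
  expect_true(fit$converged)
  expect_equal(fit$n_free, 2)
  expect_equal(fit$n_trials, 5040)
})

test_that("degenerate data raises an error rather than a fit", {
  des <- small_design()
  all_probe <- toj_data(des$soas, des$repetitions, des$repetitions)
  expect_error(fit_toj(all_probe, "simple"), "degenerate")
  none <- toj_data(des$soas, des$repetitions, 0 * des$repetitions)
  expect_error(fit_toj(none, "simple"), "degenerate")
})

test_that("plateau models have 4 free parameters under the tau = 0 config", {
  dat <- simulate_judgments("indecision", pars_ind, small_design(),
                            seed = 4)
  fi <- fit_toj(dat, "indecision", n_starts = 4)
  fr <- fit_toj(dat, "reset", n_starts = 4)
  expect_equal(fi$n_free, 4)
  expect_equal(fr$n_free, 4)
  expect_equal(coef(fi)[["tau"]], 0)
  # freeing tau gives the 5-parameter cued configuration
  f5 <- fit_toj(dat, "indecision", fixed = NULL, n_starts = 4)
  expect_equal(f5$n_free, 5)
})

test_that("generating plateau model dominates the nested simple race", {
  for (model in c("indecision", "reset")) {
    p <- if (model == "indecision") pars_ind else pars_reset
    dat <- simulate_judgments(model, p, toj_design("exp1"), seed = 11)
    fg <- fit_toj(dat, model, n_starts = 6)
    fs <- fit_toj(dat, "simple", n_starts = 6)
    expect_gte(fg$loglik, fs$loglik - 1e-6)
  }
})

test_that("fits are invariant to row order and to splitting a row", {
  dat <- simulate_judgments("indecision", pars_ind, small_design(),
                            seed = 12)
  f1 <- fit_toj(dat, "indecision", n_starts = 6)
  shuffled <- dat[sample(nrow(dat)), ]
  f2 <- fit_toj(shuffled, "indecision", n_starts = 6)
  expect_equal(f1$bic, f2$bic, tolerance = 1e-6)
  # split the middle row's trials into two rows at the same SOA
  mid <- which(dat$soa_ms == 0)
  k <- dat$n_probe_first[mid]
  n <- dat$n_trials[mid]
  split_rows <- data.frame(
    soa_ms = c(dat$soa_ms[-mid], 0, 0),
    n_trials = c(dat$n_trials[-mid], n %/% 2, n - n %/% 2),
    n_probe_first = c(dat$n_probe_first[-mid], min(k, n %/% 2),
                      k - min(k, n %/% 2)))
  f3 <- fit_toj(split_rows, "indecision", n_starts = 6)
  expect_equal(f1$bic, f3$bic, tolerance = 1e-4)
})

test_that("multi-start optimization is stable across seeds", {
  dat <- simulate_judgments("reset", pars_reset, toj_design("exp1"),
                            seed = 13)
  f1 <- fit_toj(dat, "reset", n_starts = 10, seed = 1)
  f2 <- fit_toj(dat, "reset", n_starts = 10, seed = 2)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-4)
})

test_that("estimates respect bounds, including user overrides", {
  dat <- simulate_judgments("reset", pars_reset, small_design(),
                            seed = 14)
  fit <- fit_toj(dat, "reset", n_starts = 4)
  for (nm in fit$free) {
    b <- fit$bounds[[nm]]
    expect_gte(coef(fit)[[nm]], b[1])
    expect_lte(coef(fit)[[nm]], b[2])
  }
  narrow <- fit_toj(dat, "reset", bounds = list(t0 = c(0, 10)),
                    n_starts = 4)
  expect_lte(coef(narrow)[["t0"]], 10)
  expect_error(fit_toj(dat, "reset", fixed = c(t0 = 500)),
               "outside bounds")
  expect_error(fit_toj(dat, "reset", bounds = list(zeta = c(0, 1))),
               "unknown parameter")
})
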