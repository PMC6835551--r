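# SOA grids and repetition schedules of the two study designs.
#
# exp1: 21 SOAs from -100 to 100 ms in 10 ms steps, 240 repetitions each
#   (5040 trials in total).
# exp2_neutral: the same grid with an uneven schedule concentrating
#   repetitions at the central SOAs; the printed 19-entry schedule is laid
#   over the central 19 SOAs and the two extremes get the minimum count.
# exp2_cued: SOAs from -40 to 160 ms with the same schedule; the cue leads
#   the probe by a fixed 140 ms interval (carried as metadata only — the
#   cue's effect enters the models solely through tau and rate changes).
exp2_schedule <- function() {
  inner <- c(8, 10, 12, 14, 16, 18, 20, 22, 24, 26, 28,
             26, 24, 22, 18, 16, 14, 12, 8)
  c(min(inner), inner, min(inner))
}

#' Experiment designs for temporal-order judgments
#'
#' Builds an SOA grid with per-SOA repetition counts, either from one of
#' the study presets (`"exp1"`, `"exp2_neutral"`, `"exp2_cued"`) or from an
#' explicit grid.
#'
#' @param preset Preset name, or `NULL` when `soas`/`repetitions` are
#'   given explicitly.
#' @param soas Strictly increasing numeric vector of SOAs (ms).
#' @param repetitions Positive integer vector of per-SOA trial counts;
#'   either length 1 (recycled) or the same length as `soas`.
#' @param label Condition label stored with the design.
#' @return An object of class `"toj_design"`: a list with `label`, `soas`,
#'   `repetitions` and optional metadata (`cue_interval_ms` for the cued
#'   preset).
#' @examples
#' d <- toj_design("exp1")
#' sum(d$repetitions)  # 5040 trials
#' @export
toj_design <- function(preset = NULL, soas = NULL, repetitions = NULL,
                       label = NULL) {
  if (!is.null(preset)) {
    if (!is.null(soas) || !is.null(repetitions))
      stop("configuration error: give either `preset` or an explicit grid, not both",
           call. = FALSE)
    des <- switch(preset,
      exp1 = list(soas = seq(-100, 100, by = 10), repetitions = 240L,
                  label = "exp1"),
      exp2_neutral = list(soas = seq(-100, 100, by = 10),
                          repetitions = exp2_schedule(),
                          label = "exp2_neutral"),
      exp2_cued = list(soas = seq(-40, 160, by = 10),
                       repetitions = exp2_schedule(),
                       label = "exp2_cued", cue_interval_ms = 140),
      stop("configuration error: unknown design preset '", preset, "'",
           call. = FALSE)
    )
    if (!is.null(label)) des$label <- label
    soas <- des$soas
    repetitions <- des$repetitions
  } else {
    des <- list(label = if (is.null(label)) "custom" else label)
  }
  if (is.null(soas) || is.null(repetitions))
    stop("configuration error: `soas` and `repetitions` are required",
         call. = FALSE)
  if (!is.numeric(soas) || anyNA(soas) || any(!is.finite(soas)) ||
      is.unsorted(soas, strictly = TRUE))
    stop("configuration error: `soas` must be strictly increasing and finite",
         call. = FALSE)
  if (length(repetitions) == 1L)
    repetitions <- rep(repetitions, length(soas))
  if (length(repetitions) != length(soas))
    stop("configuration error: `repetitions` length (", length(repetitions),
         ") does not match `soas` length (", length(soas), ")",
         call. = FALSE)
  repetitions <- as.integer(repetitions)
  if (anyNA(repetitions) || any(repetitions < 1L))
    stop("configuration error: `repetitions` must all be >= 1",
         call. = FALSE)
  out <- list(label = des$label, soas = as.numeric(soas),
              repetitions = repetitions)
  if (!is.null(des$cue_interval_ms)) out$cue_interval_ms <- des$cue_interval_ms
  class(out) <- "toj_design"
  out
}

#' @export
print.toj_design <- function(x, ...) {
  cat("TOJ design '", x$label, "': ", length(x$soas), " SOAs from ",
      min(x$soas), " to ", max(x$soas), " ms, ",
      sum(x$repetitions), " trials total\n", sep = "")
  if (!is.null(x$cue_interval_ms))
    cat("  cue leads probe by ", x$cue_interval_ms, " ms\n", sep = "")
  invisible(x)
}

#' @rdname toj_design
#' @param x A `"toj_design"` object (for `design_to_list`) or a plain list
#'   with fields `label`, `soas`, `repetitions` or a `preset` name (for
#'   `design_from_list`) — the round-trippable plain form used in
#'   YAML/JSON configs.
#' @export
design_to_list <- function(x) {
  stopifnot(inherits(x, "toj_design"))
  unclass(x)
}

#' @rdname toj_design
#' @export
design_from_list <- function(x) {
  if (is.character(x) && length(x) == 1L) return(toj_design(preset = x))
  if (!is.null(x$preset)) return(toj_design(preset = x$preset, label = x$label))
  toj_design(soas = x$soas, repetitions = x$repetitions, label = x$label)
}
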