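# Plain-text I/O: the judgment CSV schema, fit/comparison/recovery JSON,
# and YAML/JSON configs. The CSV is wide (one row per SOA with counts),
# since all three likelihoods are binomial at the SOA level. Lines
# starting with '#' are provenance comments and are ignored on read.

judgment_cols <- c("participant", "condition", "soa_ms", "n_trials",
                   "n_probe_first")

#' Read and write judgment-count CSV files
#'
#' The schema has one row per (participant, condition, SOA):
#' `participant` (string), `condition` (string), `soa_ms` (number,
#' negative = probe presented first), `n_trials` (integer),
#' `n_probe_first` (integer). SOAs must be unique within each
#' (participant, condition) cell and counts must satisfy
#' `0 <= n_probe_first <= n_trials`; violations raise an error naming the
#' offending row. Comment lines beginning with `#` (provenance written by
#' the CLI) are skipped.
#'
#' @param path File path.
#' @return `read_judgment_csv()`: a named list of [toj_data()] objects,
#'   one per participant/condition cell, named `"participant:condition"`
#'   and carrying `participant` and `condition` attributes. Row order in
#'   the file is irrelevant.
#' @export
read_judgment_csv <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(judgment_cols, names(df))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(df$n_probe_first < 0 | df$n_probe_first > df$n_trials |
                 df$n_trials < 1)
  if (length(bad))
    stop("schema error in ", path, ": n_probe_first > n_trials (or ",
         "n_trials < 1) at row ", bad[1], call. = FALSE)
  key <- paste(df$participant, df$condition, sep = ":")
  out <- lapply(split(df, key), function(g) {
    if (anyDuplicated(g$soa_ms)) {
      dup <- g$soa_ms[duplicated(g$soa_ms)][1]
      stop("schema error in ", path, ": duplicate soa_ms ", dup,
           " for participant '", g$participant[1], "', condition '",
           g$condition[1], "'", call. = FALSE)
    }
    g <- g[order(g$soa_ms), ]
    d <- toj_data(g$soa_ms, g$n_trials, g$n_probe_first,
                  label = g$condition[1])
    attr(d, "participant") <- g$participant[1]
    attr(d, "condition") <- g$condition[1]
    d
  })
  out[order(names(out))]
}

#' @rdname read_judgment_csv
#' @param x A [toj_data()] object, or a list of them.
#' @param participant,condition Labels for the CSV columns; for lists,
#'   per-element attributes win over these defaults.
#' @param provenance Optional named list written as `# key: value` header
#'   comments (e.g. the resolved configuration and seed).
#' @export
write_judgment_csv <- function(x, path, participant = "p1",
                               condition = NULL, provenance = NULL) {
  items <- if (inherits(x, "toj_data")) list(x) else x
  rows <- lapply(items, function(d) {
    stopifnot(inherits(d, "toj_data"))
    data.frame(
      participant = attr(d, "participant") %||% participant,
      condition = attr(d, "condition") %||% condition %||%
        attr(d, "label") %||% "default",
      soa_ms = d$soa_ms, n_trials = d$n_trials,
      n_probe_first = d$n_probe_first)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), ": ",
                      vapply(provenance, function(v)
                        paste(format(unlist(v)), collapse = " "),
                        character(1))), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- fit serialization ------------------------------------------------

fit_to_list <- function(fit) {
  co <- as.list(fit$coefficients)
  hz <- intersect(names(co), c("vp", "vr"))
  list(
    model = fit$model,
    estimates = co,
    estimates_hz = setNames(lapply(co[hz], function(v) 1000 * v),
                            paste0(hz, "_hz")),
    free = as.list(fit$free),
    fixed = as.list(fit$fixed),
    loglik = fit$loglik,
    n_free = fit$n_free,
    n_trials = fit$n_trials,
    bic = fit$bic,
    converged = fit$converged,
    participant = attr(fit$data, "participant"),
    condition = attr(fit$data, "condition")
  )
}

#' Write fit results to JSON
#'
#' Serializes one or more `"toj_fit"` objects (estimates in both internal
#' events/ms and display Hz units, log-likelihood, BIC, convergence) plus
#' a provenance block to a JSON file that [compare_toj()] and the CLI can
#' consume again.
#'
#' @param fits A `"toj_fit"` or list of them.
#' @param path Output file.
#' @param provenance Named list stored under `"provenance"` (the CLI puts
#'   the resolved configuration, seed and package version here).
#' @export
write_fit_json <- function(fits, path, provenance = NULL) {
  if (inherits(fits, "toj_fit")) fits <- list(fits)
  payload <- list(provenance = provenance,
                  fits = lapply(fits, fit_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @return `read_fit_json()`: the parsed list; each element of `$fits` has
#'   the fields [compare_toj()] needs.
#' @export
read_fit_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# --- configs ----------------------------------------------------------

#' Read a YAML or JSON configuration file
#'
#' Dispatches on the file extension: `.yaml`/`.yml` via the yaml package,
#' `.json` via jsonlite.
#'
#' @param path Config file path.
#' @return The parsed list.
#' @export
read_toj_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config must be .yaml, .yml or .json: ", path, call. = FALSE)
}
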