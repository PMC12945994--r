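# All on-disk artifacts are plain delimited text (or JSON for the model
# checkpoint) with a one-line schema-version header of the form
#   #crossrbm <kind> <major>.<minor>
# Readers reject files whose major version is newer than they understand.

SCHEMA_VERSIONS <- c(spiketable = "1.0", features = "1.0", report = "1.0")

write_schema_header <- function(path, kind) {
  writeLines(sprintf("#crossrbm %s %s", kind, SCHEMA_VERSIONS[[kind]]), path)
}

check_schema_header <- function(path, kind) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#crossrbm (\\S+) (\\d+)\\.(\\d+)$", first))[[1]]
  if (length(m) != 4L)
    stop(sprintf("'%s' has no schema header; expected '#crossrbm %s %s'",
                 path, kind, SCHEMA_VERSIONS[[kind]]))
  if (m[2] != kind)
    stop(sprintf("'%s' is a '%s' file, expected '%s'", path, m[2], kind))
  have_major <- as.integer(strsplit(SCHEMA_VERSIONS[[kind]], ".", fixed = TRUE)[[1]][1])
  if (as.integer(m[3]) > have_major)
    stop(sprintf("'%s' uses schema major version %s, newer than supported %d",
                 path, m[3], have_major))
  invisible(TRUE)
}

#' Write / read a spike-timing table
#'
#' Tab-separated text with a schema-version header and columns `subject_id`,
#' `trial_id`, `label`, `muscle_id`, `spike_time_ms` (one row per spike).
#' Missing muscles are declared in an optional sidecar roster file with
#' columns `subject_id`, `muscle_id`.
#'
#' @param spikes a spike table data frame (see [synth_spikes()]); its
#'   `missing` attribute is written to `missing_path` when given.
#' @param path file path for the spike rows.
#' @param missing_path optional sidecar path for the missing-muscle table.
#' @return `write_spike_table()` returns `path` invisibly;
#'   `read_spike_table()` returns the spike table data frame with its
#'   `missing` attribute attached.
#' @export
write_spike_table <- function(spikes, path, missing_path = NULL) {
  write_schema_header(path, "spiketable")
  cols <- c("subject_id", "trial_id", "label", "muscle_id", "spike_time_ms")
  suppressWarnings(utils::write.table(spikes[cols], path, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  if (!is.null(missing_path)) {
    miss <- attr(spikes, "missing") %||%
      data.frame(subject_id = character(), muscle_id = character())
    write_schema_header(missing_path, "spiketable")
    suppressWarnings(utils::write.table(miss, missing_path, sep = "\t",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
  }
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path, missing_path = NULL) {
  check_schema_header(path, "spiketable")
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           colClasses = "character")
  expected <- c("subject_id", "trial_id", "label", "muscle_id",
                "spike_time_ms")
  if (!all(expected %in% names(tab)))
    stop(sprintf("'%s': expected columns %s, found %s", path,
                 paste(expected, collapse = ", "),
                 paste(names(tab), collapse = ", ")))
  extra <- setdiff(names(tab), expected)
  if (length(extra))
    warning(sprintf("'%s': ignoring unknown column(s): %s", path,
                    paste(extra, collapse = ", ")))
  tab <- tab[expected]
  tab$spike_time_ms <- suppressWarnings(as.numeric(tab$spike_time_ms))
  bad <- which(!tab$muscle_id %in% muscle_roster())
  if (length(bad))
    stop(sprintf("'%s': out-of-roster muscle '%s' at data row %d", path,
                 tab$muscle_id[bad[1]], bad[1]))
  bad_t <- which(!is.finite(tab$spike_time_ms) | tab$spike_time_ms < 0)
  if (length(bad_t))
    stop(sprintf("'%s': invalid spike time at data row %d", path, bad_t[1]))
  miss <- data.frame(subject_id = character(), muscle_id = character())
  if (!is.null(missing_path)) {
    check_schema_header(missing_path, "spiketable")
    miss <- utils::read.table(missing_path, header = TRUE, sep = "\t",
                              skip = 1L, colClasses = "character")
  }
  attr(tab, "missing") <- miss
  tab
}

#' Write / read a per-subject feature matrix
#'
#' Tab-separated text with a schema header; columns are `trial_id`, `label`
#' and the `P` feature columns `f1..fP`.
#'
#' @param dataset a per-subject feature dataset (list with `X`, `y` and
#'   optionally `trial_id`).
#' @param path file path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns a list with `X` (matrix), `y` and `trial_id`.
#' @export
write_features <- function(dataset, path) {
  X <- as.matrix(dataset$X)
  df <- data.frame(trial_id = dataset$trial_id %||%
                     sprintf("t%05d", seq_len(nrow(X))),
                   label = as.character(dataset$y))
  feat <- as.data.frame(X)
  names(feat) <- paste0("f", seq_len(ncol(X)))
  write_schema_header(path, "features")
  suppressWarnings(utils::write.table(cbind(df, feat), path, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  check_schema_header(path, "features")
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  fcols <- grep("^f\\d+$", names(tab), value = TRUE)
  if (!length(fcols)) stop(sprintf("'%s': no feature columns f1..fP", path))
  X <- as.matrix(tab[fcols])
  n_bad <- sum(!is.finite(X))
  if (n_bad > 0)
    stop(sprintf("'%s': %d non-finite feature cell(s)", path, n_bad))
  list(X = X, y = as.character(tab$label), trial_id = as.character(tab$trial_id))
}

#' Save / load a fitted RBM checkpoint
#'
#' The checkpoint is a single versioned JSON container holding every
#' parameter array (`W`, `b`, `c`, `lam`), the subject layout and the
#' training configuration, so a mapping run can be reproduced from the file
#' alone.
#'
#' @param fit a fitted [gbrbm] model.
#' @param path file path (conventionally `.json`).
#' @return `write_gbrbm()` returns `path` invisibly; `read_gbrbm()` returns
#'   a `gbrbm` object (without the training trace).
#' @export
write_gbrbm <- function(fit, path) {
  stopifnot(inherits(fit, "gbrbm"))
  payload <- list(
    format = "crossrbm-checkpoint", version = "1.0",
    config = fit$config,
    layout = if (!is.null(fit$layout))
      list(subjects = fit$layout$subjects, dims = fit$layout$dims),
    params = list(W = fit$params$W, b = fit$params$b, c = fit$params$c,
                  lam = fit$params$lam))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_gbrbm
#' @export
read_gbrbm <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "crossrbm-checkpoint"))
    stop(sprintf("'%s' is not a crossrbm checkpoint", path))
  if (as.integer(strsplit(payload$version, ".", fixed = TRUE)[[1]][1]) > 1L)
    stop(sprintf("'%s': checkpoint major version %s is newer than supported",
                 path, payload$version))
  params <- rbm_params(W = payload$params$W, b = payload$params$b,
                       c = payload$params$c, lam = payload$params$lam)
  layout <- if (!is.null(payload$layout))
    subject_layout(payload$layout$subjects, payload$layout$dims)
  cfg <- payload$config
  structure(list(params = params, config = cfg,
                 trace = data.frame(epoch = integer(), objective = numeric(),
                                    seconds = numeric()),
                 init = NULL, layout = layout,
                 data_dim = c(n = NA_integer_, D = params$D)),
            class = "gbrbm")
}

#' Write / read an evaluation report
#'
#' @param report an `eval_report` data frame from [run_scenario()].
#' @param path file path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the report data frame.
#' @export
write_report <- function(report, path) {
  write_schema_header(path, "report")
  suppressWarnings(utils::write.table(report, path, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  check_schema_header(path, "report")
  out <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           colClasses = c(scenario = "character",
                                          method = "character",
                                          source = "character",
                                          target = "character"))
  class(out) <- c("eval_report", class(out))
  out
}
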