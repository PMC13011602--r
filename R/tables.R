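# Tabular IO: delimited read/write with full-precision round-trips and
# parse errors that name the offending row.

#' Write a data.frame as CSV or TSV
#'
#' Values are written at full double precision (17 significant digits) so a
#' write/read round-trip reproduces them exactly.
#'
#' @param rows A data.frame.
#' @param path Output file path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a delimited table written by [write_table()]
#'
#' The delimiter is inferred from the extension (`.tsv`/`.txt` tab,
#' otherwise comma) unless given. Columns whose names are known numeric
#' fields, or that parse fully as numbers, are converted; a non-numeric
#' cell inside an otherwise numeric column is a parse error naming the row.
#'
#' @param path File path.
#' @param numeric_cols Character vector of column names that must parse as
#'   numeric; defaults to every column except known identifier columns
#'   (`id`, `sample_id`, `cell_id`, `condition_id`, `origin_id`, `phase`,
#'   `condition`).
#' @return A data.frame.
#' @export
read_table <- function(path, numeric_cols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  id_like <- c("id", "sample_id", "cell_id", "condition_id", "origin_id",
               "phase", "condition", "regime", "model", "preferred")
  if (is.null(numeric_cols))
    numeric_cols <- setdiff(names(df), id_like)
  for (col in intersect(numeric_cols, names(df))) {
    x <- df[[col]]
    logi <- toupper(x) %in% c("TRUE", "FALSE")
    if (all(logi) && length(x) > 0) {
      df[[col]] <- as.logical(toupper(x))
      next
    }
    suppressWarnings(num <- as.numeric(x))
    bad <- which(is.na(num) & !(x %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("parse error in '%s': non-numeric value '%s' in column '%s' at data row %d",
                   basename(path), x[bad[1]], col, bad[1]), call. = FALSE)
    df[[col]] <- num
  }
  df
}

#' Per-cell table of a population result
#'
#' @param result A [sample_population()] result.
#' @return The `cells` data.frame (cell_id, A, D, C, phi, score, response,
#'   fired).
#' @export
population_table <- function(result) {
  stopifnot(inherits(result, "population_result"))
  result$cells
}

#' Time-series table of a cycle trajectory
#'
#' @param trajectory A [simulate_cycle()] result.
#' @return A data.frame with columns `t, A, D, C, phi, score, R,
#'   cumulative_firings`.
#' @export
trajectory_table <- function(trajectory) {
  stopifnot(inherits(trajectory, "cycle_trajectory"))
  cum <- vapply(trajectory$times, function(t)
    sum(trajectory$firings$time <= t), integer(1))
  data.frame(t = trajectory$times, A = trajectory$A, D = trajectory$D,
             C = trajectory$C, phi = trajectory$phi,
             score = trajectory$score, R = trajectory$R,
             cumulative_firings = cum)
}

#' Read an origin table from CSV/TSV
#'
#' Expects columns `id, A, D, C, threshold` (extra columns ignored).
#'
#' @param path File path.
#' @return An [origin_frame()].
#' @export
read_origins <- function(path) {
  df <- read_table(path)
  need <- c("id", "A", "D", "C", "threshold")
  if (!all(need %in% names(df)))
    stop("origin table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  origin_frame(A = df$A, D = df$D, C = df$C, threshold = df$threshold,
               id = df$id)
}
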