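#' @useDynLib histowall3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dist optimize quantile rnorm runif sd
#' @importFrom utils head tail write.table read.table
NULL

# internal: leveled logging, controlled by options(histowall3d.log_level)
.log_levels <- c(debug = 1L, info = 2L, warning = 3L, quiet = 4L)

hw_log <- function(msg, level = "info") {
  thr <- getOption("histowall3d.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[thr]]) {
    message(sprintf("[histowall3d %s] %s", level, msg))
  }
  invisible(NULL)
}

# internal: validation helper naming the offending field
check_that <- function(ok, field, what) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, what), call. = FALSE)
  }
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Write a flat key/value configuration file
#'
#' Serializes a named list (optionally one level of named sub-lists, written
#' as `[section]` blocks) to a plain-text `key = value` file. Numeric values
#' are written at full precision (17 significant digits) so a write/read
#' round trip is exact.
#'
#' @param config named list of scalar values and/or named sub-lists.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_flat_config()]
#' @export
write_flat_config <- function(config, path) {
  fmt1 <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  lines <- character(0)
  scalars <- config[!vapply(config, is.list, logical(1))]
  for (k in names(scalars)) {
    lines <- c(lines, sprintf("%s = %s", k, fmt1(scalars[[k]])))
  }
  sections <- config[vapply(config, is.list, logical(1))]
  for (s in names(sections)) {
    lines <- c(lines, sprintf("[%s]", s))
    for (k in names(sections[[s]])) {
      lines <- c(lines, sprintf("%s = %s", k, fmt1(sections[[s]][[k]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key/value configuration file
#'
#' Parses files written by [write_flat_config()]. Values that parse as
#' numbers are returned numeric; comma-separated values become vectors.
#'
#' @param path file path.
#' @return named list (with named sub-lists for `[section]` blocks).
#' @export
read_flat_config <- function(path) {
  check_that(file.exists(path), "path", sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  section <- NULL
  parse_val <- function(s) {
    parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- parse_val(sub("^[^=]*=", "", ln))
      if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
    }
  }
  out
}

# internal: squared euclidean distances between rows of a and b (na x nb)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * (a %*% t(b))
}
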