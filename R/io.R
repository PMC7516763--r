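## Plain-text table I/O and small OLS utilities used by the selection tools.

#' Load a numeric delimiter-separated table
#'
#' Reads a rectangular numeric table with a header row. Comma or tab
#' delimiters are auto-detected from the header line; the decimal separator
#' is the point. Any missing or non-numeric cell is an error naming the
#' offending column.
#'
#' @param path Path to the file.
#' @param response Optional name of the response column; if given it must be
#'   present.
#'
#' @return A data frame; if `response` was given, the response column name is
#'   kept in `attr(, "response")`.
#' @export
load_table <- function(path, response = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("table must have a header and at least two columns", call. = FALSE)
  }
  for (cn in names(df)) {
    v <- df[[cn]]
    bad <- which(is.na(v) | v == "" | is.na(suppressWarnings(as.numeric(v))))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing value in column '%s', row %d",
                   cn, bad[1]), call. = FALSE)
    }
    df[[cn]] <- as.numeric(v)
  }
  if (!is.null(response)) {
    if (!response %in% names(df)) {
      stop(sprintf("response column '%s' not found", response), call. = FALSE)
    }
    attr(df, "response") <- response
  }
  df
}

#' Write a numeric table as tab-separated text
#'
#' Full-precision round trip companion of [load_table()].
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- formatC(out[[cn]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adjusted R-squared of a regression submodel
#'
#' OLS fit with intercept of the submodel, returning
#' \eqn{1 - (1 - R^2)(n-1)/(n-p-1)}.
#'
#' @inheritParams aic_score
#' @return A scalar.
#' @examples
#' data <- hald()
#' adjusted_r2(data$Y, as.matrix(data[, c("X1", "X2", "X4")]))
#' @export
adjusted_r2 <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) stop("insufficient data: need n > p + 1", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, X), y)
  if (fit$rank < p + 1L) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  1 - (rss / tss) * (n - 1) / (n - p - 1)
}
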