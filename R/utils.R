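#' Percentile cutoff by linear interpolation between order statistics
#'
#' Computes the `p`-th percentile of `x` as the linearly interpolated order
#' statistic: with the sorted non-missing values \eqn{x_{(1)} \le \dots \le
#' x_{(n)}} and \eqn{h = (n - 1)p + 1}, the cutoff is
#' \deqn{x_{(\lfloor h \rfloor)} + (h - \lfloor h \rfloor)\,
#'       (x_{(\lfloor h \rfloor + 1)} - x_{(\lfloor h \rfloor)}).}
#' This is the common default continuous-quantile convention. Missing values
#' are dropped.
#'
#' @param x Numeric vector.
#' @param p Probability in `[0, 1]`.
#' @return The interpolated cutoff, or `NA` if `x` has no non-missing values.
#' @examples
#' percentile_cutoff(seq(0.01, 0.10, by = 0.01), 0.70)  # 0.073
#' @export
percentile_cutoff <- function(x, p) {
  stopifnot(is.numeric(x), length(p) == 1L, p >= 0, p <= 1)
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# normalize name keys: case-fold and collapse internal whitespace
normalize_key <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\s+", " ", x)
  x[x == ""] <- NA_character_
  x
}

stop_config <- function(msg, field = NULL) {
  abort(msg, class = "nutrisupply_config_error", field = field)
}

stop_data <- function(msg, ...) {
  abort(msg, class = "nutrisupply_data_error", ...)
}

assert_fraction <- function(x, name, allow_na = FALSE) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad) || (!allow_na && anyNA(x))) {
    stop_config(sprintf("`%s` must be a fraction in [0, 1]", name), field = name)
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_data(sprintf("%s is missing column(s): %s", what,
                      paste(missing, collapse = ", ")))
  }
  invisible(df)
}
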