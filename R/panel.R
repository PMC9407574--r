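#' Multivariate time-series panels
#'
#' A `ts_panel` is a tibble with one column per univariate series, carrying two
#' attributes: `rates`, the per-series number of observations per common time
#' unit, and `starts`, the per-series start offset in sub-unit ticks.  For
#' equally sampled series all rates are 1 and all starts are 0, and rows line
#' up in time.  With different sampling rates a series of rate `N_p` has one
#' observation every `L / N_p` ticks, where `L` is the least common multiple of
#' all rates; shorter columns are padded with trailing `NA`.
#'
#' @param data a data frame (or anything coercible) with one numeric column per
#'   series; a column named `time` (or the name given in `time_col`) is
#'   dropped.
#' @param rates integer vector of observations per common time unit, recycled
#'   or named by series; default 1 for every series.
#' @param starts integer vector of start offsets in sub-unit ticks; default 0.
#' @param time_col optional name of a time column to drop.
#' @return a `ts_panel` tibble.
#' @examples
#' pan <- ts_panel(data.frame(x = rnorm(50), y = rnorm(50)))
#' n_obs(pan)
#' @export
ts_panel <- function(data, rates = NULL, starts = NULL, time_col = "time") {
  data <- tibble::as_tibble(data)
  if (!is.null(time_col) && time_col %in% names(data)) {
    data <- data[setdiff(names(data), time_col)]
  }
  if (ncol(data) < 1L) abort("a panel needs at least one series")
  if (!all(vapply(data, is.numeric, logical(1)))) {
    abort("all series must be numeric")
  }
  nm <- names(data)
  if (!is.null(rates) && any(rates != round(rates))) {
    abort("rates must be positive integers")
  }
  rates <- expand_per_series(rates %||% 1L, nm, "rates")
  starts <- expand_per_series(starts %||% 0L, nm, "starts")
  if (any(rates < 1L) || any(rates != round(rates))) {
    abort("rates must be positive integers")
  }
  lens <- vapply(data, series_length, integer(1))
  if (any(lens < 2L)) abort("every series needs at least 2 observations")
  structure(data,
    rates = rates, starts = starts,
    class = c("ts_panel", class(tibble::tibble())))
}

expand_per_series <- function(x, nm, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(nm, names(x))
    full <- stats::setNames(rep(if (what == "rates") 1L else 0L, length(nm)), nm)
    full[names(x)] <- x
    x <- full[nm]
  } else if (length(x) == 1L) {
    x <- stats::setNames(rep(x, length(nm)), nm)
  } else if (length(x) == length(nm)) {
    x <- stats::setNames(x, nm)
  } else {
    abort(paste0(what, " must have length 1 or one entry per series"))
  }
  stats::setNames(as.integer(x), nm)
}

#' @rdname ts_panel
#' @param x object to coerce or test.
#' @export
as_ts_panel <- function(x, rates = NULL, starts = NULL) {
  if (is_ts_panel(x) && is.null(rates) && is.null(starts)) return(x)
  ts_panel(x, rates = rates, starts = starts)
}

#' @rdname ts_panel
#' @export
is_ts_panel <- function(x) inherits(x, "ts_panel")

#' @rdname ts_panel
#' @export
panel_rates <- function(x) attr(x, "rates") %||%
  stats::setNames(rep(1L, ncol(x)), names(x))

#' @rdname ts_panel
#' @export
panel_starts <- function(x) attr(x, "starts") %||%
  stats::setNames(rep(0L, ncol(x)), names(x))

#' @rdname ts_panel
#' @export
series_names <- function(x) names(x)

# observations of one series, trailing NA padding removed
panel_series <- function(panel, name) {
  if (!name %in% names(panel)) {
    abort(paste0("unknown series: ", name), class = "ctmi_lookup_error")
  }
  v <- panel[[name]]
  n <- series_length(v)
  v[seq_len(n)]
}

series_length <- function(v) {
  ok <- which(!is.na(v))
  if (length(ok) == 0L) 0L else max(ok)
}

#' @rdname ts_panel
#' @export
n_obs <- function(x) {
  vapply(as.list(x), series_length, integer(1))
}

#' Read a time-series panel from a delimited file
#'
#' Expects a header row of series names and one column per series; an optional
#' leading time column is dropped.  Columns of different lengths (trailing
#' empty cells) are kept as `NA`-padded series, with their sampling rates
#' supplied through `rates`.
#'
#' @param path file path; delimiter is guessed from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `delim` is given.
#' @param delim field delimiter override.
#' @inheritParams ts_panel
#' @return a [ts_panel].
#' @export
read_panel <- function(path, rates = NULL, starts = NULL, delim = NULL,
                       time_col = "time") {
  delim <- delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  ts_panel(df, rates = rates, starts = starts, time_col = time_col)
}

#' Decimate a panel to emulate different sampling rates
#'
#' Keeps every `keep_every`-th observation of each series and rewrites the
#' rate metadata relative to the new common time unit (the least common
#' multiple of the per-series sampling intervals).
#'
#' @param panel a [ts_panel].
#' @param keep_every positive integer, recycled or named by series.
#' @return a decimated [ts_panel].
#' @examples
#' pan <- ts_panel(data.frame(a = rnorm(10), b = rnorm(10)))
#' panel_rates(decimate(pan, c(1, 2)))
#' @export
decimate <- function(panel, keep_every) {
  panel <- as_ts_panel(panel)
  nm <- names(panel)
  keep_every <- expand_per_series(keep_every, nm, "keep_every")
  if (any(keep_every < 1L)) abort("keep_every must be positive integers")
  lens <- n_obs(panel)
  if (any(keep_every >= lens)) {
    abort("keep_every must be smaller than the series length")
  }
  rates <- panel_rates(panel)
  L <- Reduce(lcm_int, rates)
  # sampling interval of each decimated series, in old ticks
  interval <- keep_every * (L %/% rates)
  unit <- Reduce(lcm_int, interval) # new common time unit, in old ticks
  new_rates <- unit %/% interval
  cols <- purrr::imap(as.list(panel), function(v, s) {
    v[seq.int(1L, lens[[s]], by = keep_every[[s]])]
  })
  nmax <- max(lengths(cols))
  cols <- purrr::map(cols, function(v) c(v, rep(NA_real_, nmax - length(v))))
  ts_panel(tibble::as_tibble(cols), rates = new_rates,
           starts = panel_starts(panel))
}

lcm_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  as.integer(a %/% gcd_int(a, b) * b)
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  abs(a)
}

# Standardize every series to zero mean / unit variance and add a seeded
# uniform jitter of tiny amplitude to break ties between identical values
# (the sup-distance counts of the estimator assume distinct points).
prepare_panel <- function(panel, seed, jitter = 1e-10) {
  panel <- as_ts_panel(panel)
  if (isTRUE(attr(panel, "prepared"))) return(panel)
  cols <- as.list(panel)
  withr::with_seed(as.integer(seed %% 2147483647), {
    cols <- purrr::map(cols, function(v) {
      n <- series_length(v)
      obs <- v[seq_len(n)]
      s <- stats::sd(obs, na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      obs <- (obs - mean(obs, na.rm = TRUE)) / s
      v[seq_len(n)] <- obs + stats::runif(n, -jitter, jitter)
      v
    })
  })
  out <- ts_panel(tibble::as_tibble(cols), rates = panel_rates(panel),
                  starts = panel_starts(panel))
  attr(out, "prepared") <- TRUE
  out
}

#' @export
print.ts_panel <- function(x, ...) {
  rates <- panel_rates(x)
  cat(sprintf("# A ts_panel: %d series, %s observations\n",
              ncol(x), paste(unique(n_obs(x)), collapse = "/")))
  if (length(unique(rates)) > 1L) {
    cat("# rates:", paste(sprintf("%s=%d", names(rates), rates),
                          collapse = ", "), "\n")
  }
  NextMethod()
}
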