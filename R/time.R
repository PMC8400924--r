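#' Parse a clock time given as "HH:MM" into minutes since midnight
#'
#' The engine works on a minute-resolution clock: every time of day is an
#' integer number of minutes since midnight in `[0, 1440)`. `parse_hm()` and
#' [fmt_hm()] convert between that representation and the usual "HH:MM"
#' notation. "24:00" is accepted and maps to 1440 so that range endpoints at
#' midnight can be written naturally.
#'
#' @param x Character vector of "HH:MM" strings.
#' @return Integer vector of minutes since midnight.
#' @examples
#' parse_hm(c("00:00", "13:56", "24:00"))
#' @export
parse_hm <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("not a valid HH:MM time: ", paste(x[bad], collapse = ", "))
  h <- as.integer(vapply(m, `[`, character(1), 2L))
  mi <- as.integer(vapply(m, `[`, character(1), 3L))
  out <- h * 60L + mi
  if (any(mi >= 60L) || any(out > 1440L)) {
    stop("clock time out of range: ", paste(x[mi >= 60L | out > 1440L], collapse = ", "))
  }
  out
}

#' Format minutes since midnight as "HH:MM"
#'
#' @param m Integer vector of minutes in `[0, 1440]`.
#' @return Character vector of "HH:MM" strings.
#' @examples
#' fmt_hm(c(0L, 836L, 1440L))
#' @export
fmt_hm <- function(m) {
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

#' Construct a validated half-open time range
#'
#' Time ranges are half-open minute intervals `[start, end)` within a single
#' day; they never wrap midnight (an overnight schedule such as 23:00--07:00
#' is represented as the two ranges `[1380, 1440)` and `[0, 420)`). The range
#' "23:00--00:00" is therefore `make_time_range(1380, 1440)`.
#'
#' @param start_min Integer start minute, `0 <= start_min < end_min`.
#' @param end_min Integer exclusive end minute, `start_min < end_min <= 1440`.
#' @return A `time_range`: an integer vector `c(start, end)` of class
#'   `"time_range"`.
#' @examples
#' make_time_range(0, 480)        # 00:00-08:00
#' make_time_range(1380, 1440)    # 23:00-24:00
#' @export
make_time_range <- function(start_min, end_min) {
  start_min <- as.integer(start_min)
  end_min <- as.integer(end_min)
  if (length(start_min) != 1L || length(end_min) != 1L ||
      is.na(start_min) || is.na(end_min)) {
    stop("time range endpoints must be single integers")
  }
  if (start_min < 0L || end_min > 1440L || start_min >= end_min) {
    stop(sprintf("invalid time range [%d, %d): need 0 <= start < end <= 1440",
                 start_min, end_min))
  }
  structure(c(start_min, end_min), class = "time_range")
}

#' @export
format.time_range <- function(x, ...) {
  sprintf("[%s, %s)", fmt_hm(x[[1L]]), fmt_hm(x[[2L]]))
}

#' @export
print.time_range <- function(x, ...) {
  cat("<time_range> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Test whether a time of day falls inside a time range
#'
#' Half-open semantics: the start minute is inside, the end minute is not.
#'
#' @param t Integer vector of minutes since midnight.
#' @param r A [make_time_range()] range (or plain `c(start, end)` pair).
#' @return Logical vector, `TRUE` where `start <= t < end`.
#' @examples
#' in_range(480, make_time_range(0, 480))   # FALSE: 08:00 is outside [00:00, 08:00)
#' in_range(0,   make_time_range(0, 480))   # TRUE
#' @export
in_range <- function(t, r) {
  t >= r[[1L]] & t < r[[2L]]
}

#' Test whether a time of day falls inside any of a list of ranges
#'
#' @param t Integer vector of minutes since midnight.
#' @param ranges List of time ranges.
#' @return Logical vector.
#' @export
in_any_range <- function(t, ranges) {
  if (length(ranges) == 0L) return(rep(FALSE, length(t)))
  Reduce(`|`, lapply(ranges, function(r) in_range(t, r)))
}

#' Sort and merge a list of time ranges
#'
#' Overlapping or adjacent ranges are merged; the result is sorted and
#' pairwise disjoint with gaps of at least one minute. The union of covered
#' minutes is preserved exactly, and the operation is idempotent.
#'
#' @param rs List of time ranges.
#' @return List of disjoint, sorted time ranges.
#' @examples
#' normalize_ranges(list(make_time_range(0, 480), make_time_range(420, 540)))
#' @export
normalize_ranges <- function(rs) {
  if (length(rs) == 0L) return(list())
  starts <- vapply(rs, `[[`, integer(1), 1L)
  ends <- vapply(rs, `[[`, integer(1), 2L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1L]; out_e <- ends[1L]
  res <- list()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= out_e) {           # overlap or adjacency: merge
      out_e <- max(out_e, ends[i])
    } else {
      res[[length(res) + 1L]] <- make_time_range(out_s, out_e)
      out_s <- starts[i]; out_e <- ends[i]
    }
  }
  res[[length(res) + 1L]] <- make_time_range(out_s, out_e)
  res
}

#' Minutes of the day covered by a list of ranges
#'
#' @param ranges List of time ranges.
#' @return Integer vector of covered minutes (0-based, sorted, unique).
#' @export
range_minutes <- function(ranges) {
  if (length(ranges) == 0L) return(integer(0))
  sort(unique(unlist(lapply(ranges, function(r) seq.int(r[[1L]], r[[2L]] - 1L)))))
}

# 1440-length logical membership mask for fast per-minute lookup.
range_mask <- function(ranges) {
  mask <- rep(FALSE, 1440L)
  mask[range_minutes(ranges) + 1L] <- TRUE
  mask
}
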