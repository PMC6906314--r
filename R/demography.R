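#' Parse an MSMC2-format output table
#'
#' Reads the tab-separated table with columns time_index,
#' left_time_boundary, right_time_boundary, lambda (scaled coalescence
#' rates). Segments must be contiguous (each right boundary equals the next
#' left boundary); the final right boundary may be infinite.
#'
#' @param path path to the file.
#' @return data.frame of segments in order.
#' @export
parse_msmc <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = "numeric")
  need <- c("time_index", "left_time_boundary", "right_time_boundary", "lambda")
  if (!all(need %in% names(x)))
    stop("expected MSMC2 columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(x$left_time_boundary) | is.na(x$lambda))
  if (length(bad))
    stop("malformed MSMC2 row at line ", bad[1] + 1L)
  n <- nrow(x)
  if (n > 1) {
    gap <- which(abs(x$right_time_boundary[-n] - x$left_time_boundary[-1]) >
                 1e-12 * pmax(1, abs(x$left_time_boundary[-1])))
    if (length(gap))  # +2: header line, and the gap precedes row gap+1
      stop("non-contiguous segment boundaries at line ", gap[1] + 2L)
  }
  if (any(diff(x$left_time_boundary) <= 0))
    stop("segment boundaries must strictly increase")
  x
}

#' Convert MSMC2 scaled units to biological units
#'
#' Times: \code{time_years = (scaled_time / mu_gen) * gen_time_years};
#' effective size: \code{Ne = 1 / (2 * mu_gen * lambda)}.
#'
#' @param segments data.frame from [parse_msmc()].
#' @param mu_gen per-generation mutation rate (default 0.8e-8).
#' @param gen_time_years years per generation (default 4).
#' @return Ne trajectory data.frame: left_years, right_years, Ne.
#' @examples
#' seg <- data.frame(time_index = 0, left_time_boundary = 0,
#'                   right_time_boundary = 1e-5, lambda = 625)
#' convert_units(seg)  # Ne = 100,000
#' @export
convert_units <- function(segments, mu_gen = 0.8e-8, gen_time_years = 4) {
  if (mu_gen <= 0) stop("mu_gen must be > 0")
  if (any(segments$lambda <= 0)) stop("lambda must be > 0")
  data.frame(left_years = segments$left_time_boundary / mu_gen * gen_time_years,
             right_years = segments$right_time_boundary / mu_gen * gen_time_years,
             Ne = 1 / (2 * mu_gen * segments$lambda))
}

#' Harmonic mean Ne over retained time segments
#'
#' n / sum(1/Ne_i) over the segments remaining after dropping the first
#' \code{drop_first} and last \code{drop_last} (the extremes of SMC-type
#' inference are unreliable). Unweighted by default; duration weighting over
#' finite segments is available.
#'
#' @param trajectory data.frame from [convert_units()].
#' @param drop_first,drop_last numbers of leading/trailing segments excluded
#'   (defaults 5 and 5).
#' @param weight_by_duration weight each segment by its length in years
#'   (infinite final segments are excluded under weighting).
#' @return harmonic mean Ne (scalar).
#' @examples
#' tr <- data.frame(left_years = 0:1, right_years = 1:2, Ne = c(100, 200))
#' harmonic_mean_ne(tr, drop_first = 0, drop_last = 0)  # 133.33
#' @export
harmonic_mean_ne <- function(trajectory, drop_first = 5, drop_last = 5,
                             weight_by_duration = FALSE) {
  n <- nrow(trajectory)
  keep <- seq_len(n)
  if (drop_first > 0) keep <- keep[keep > drop_first]
  if (drop_last > 0) keep <- keep[keep <= n - drop_last]
  if (!length(keep)) stop("no segments retained after drops")
  ne <- trajectory$Ne[keep]
  if (!weight_by_duration) return(length(ne) / sum(1 / ne))
  w <- trajectory$right_years[keep] - trajectory$left_years[keep]
  ok <- is.finite(w) & w > 0
  if (!any(ok)) stop("no finite-duration segments to weight")
  sum(w[ok]) / sum(w[ok] / ne[ok])
}
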