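#' Genomic regions in 0-based half-open coordinates
#'
#' A region set is a data frame with columns \code{scaffold}, \code{start},
#' \code{end} where \code{start < end} and coordinates are 0-based half-open
#' (BED convention). [merge_regions()] canonicalizes a set: sorted, with
#' overlapping or touching regions unioned.
#'
#' @param scaffold character vector of scaffold names.
#' @param start,end integer-like vectors, 0-based half-open.
#' @return A \code{data.frame} with columns scaffold, start, end.
#' @examples
#' regions(c("s1", "s1"), c(0, 10000), c(40000, 50000))
#' @export
regions <- function(scaffold = character(), start = integer(), end = integer()) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("region start must be < end")
  if (any(start < 0)) stop("region start must be >= 0")
  data.frame(scaffold = as.character(scaffold), start = start, end = end,
             stringsAsFactors = FALSE)
}

.check_regions <- function(x) {
  if (!all(c("scaffold", "start", "end") %in% names(x)))
    stop("expected a region data.frame with columns scaffold, start, end")
  if (nrow(x) && any(x$start >= x$end)) stop("region start must be < end")
  x
}

# 0-based half-open -> IRanges (1-based closed) per scaffold
.as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = as.integer(x$end))
}

#' Merge overlapping or touching regions
#'
#' Returns the canonical sorted union of the input intervals. Touching
#' intervals (end of one equals start of the next) are merged, so the result
#' contains no two regions that overlap or abut. Idempotent.
#'
#' @param x region data frame (see [regions()]).
#' @return Canonical merged region data frame.
#' @examples
#' merge_regions(regions(c("s1", "s1"), c(0, 10000), c(40000, 50000)))
#' @export
merge_regions <- function(x) {
  x <- .check_regions(x)
  if (!nrow(x)) return(regions())
  out <- lapply(split(x, x$scaffold), function(xs) {
    r <- IRanges::reduce(.as_iranges(xs))  # reduce() merges touching ranges
    data.frame(scaffold = xs$scaffold[1],
               start = IRanges::start(r) - 1, end = as.numeric(IRanges::end(r)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

#' Intersect two merged region sets
#'
#' Computes the pairwise intersection sections of two region sets, the number
#' of regions of \code{a} that overlap at least 1 bp of \code{b}, and the
#' number of discrete intersection sections.
#'
#' @param a,b region data frames; merged internally.
#' @return list with \code{sections} (region data frame), \code{n_a_hit},
#'   \code{n_sections}.
#' @examples
#' a <- regions(c("s1", "s1"), c(0, 200), c(100, 300))
#' b <- regions(c("s1", "s1"), c(50, 90), c(60, 210))
#' intersect_regions(a, b)
#' @export
intersect_regions <- function(a, b) {
  a <- merge_regions(a); b <- merge_regions(b)
  scafs <- union(a$scaffold, b$scaffold)
  secs <- list(); n_hit <- 0L
  for (s in scafs) {
    ra <- .as_iranges(a[a$scaffold == s, , drop = FALSE])
    rb <- .as_iranges(b[b$scaffold == s, , drop = FALSE])
    if (!length(ra) || !length(rb)) next
    n_hit <- n_hit + sum(IRanges::countOverlaps(ra, rb) > 0)
    ri <- IRanges::intersect(ra, rb)
    if (length(ri))
      secs[[s]] <- data.frame(scaffold = s, start = IRanges::start(ri) - 1,
                              end = as.numeric(IRanges::end(ri)),
                              stringsAsFactors = FALSE)
  }
  sections <- if (length(secs)) {
    out <- do.call(rbind, secs[order(names(secs))]); rownames(out) <- NULL; out
  } else regions()
  list(sections = sections, n_a_hit = as.integer(n_hit),
       n_sections = nrow(sections))
}

#' Clip regions to scaffold ends
#'
#' Windows built by coordinate arithmetic can overrun the end of a scaffold;
#' this truncates each region's end to the scaffold length. Regions starting
#' at or beyond the scaffold end are dropped with a warning.
#'
#' @param x region data frame.
#' @param scaffold_lengths named numeric vector of scaffold lengths (bp).
#' @return Clipped region data frame.
#' @examples
#' clip_to_scaffold(regions("s1", 990000, 1030000), c(s1 = 1e6))
#' @export
clip_to_scaffold <- function(x, scaffold_lengths) {
  x <- .check_regions(x)
  if (!nrow(x)) return(x)
  if (is.null(names(scaffold_lengths)))
    stop("scaffold_lengths must be a named vector")
  len <- scaffold_lengths[x$scaffold]
  if (anyNA(len)) stop("unknown scaffold(s): ",
                       paste(unique(x$scaffold[is.na(len)]), collapse = ", "))
  bad <- x$start >= len
  if (any(bad)) {
    warning(sum(bad), " region(s) start at or beyond the scaffold end; dropped")
    x <- x[!bad, , drop = FALSE]; len <- len[!bad]
  }
  x$end <- pmin(x$end, as.numeric(len))
  rownames(x) <- NULL
  x
}

#' Total length of a region set in bp
#' @param x region data frame (merged internally).
#' @return numeric total base pairs covered.
#' @export
region_span <- function(x) {
  x <- merge_regions(x)
  if (!nrow(x)) return(0)
  sum(x$end - x$start)
}
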