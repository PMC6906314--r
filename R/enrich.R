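#' Flag genes overlapping candidate regions
#'
#' A gene is flagged if it overlaps any region by at least 1 bp under
#' half-open semantics (touching intervals do not overlap).
#'
#' @param genes data.frame with columns \code{gene}, \code{scaffold},
#'   \code{start}, \code{end} and logical \code{in_set} (member of the focal
#'   gene set).
#' @param region_set region data frame (e.g. candidate introgression
#'   regions).
#' @return the gene table with a logical \code{overlaps} column added.
#' @export
genes_in_regions <- function(genes, region_set) {
  if (anyDuplicated(genes$gene)) stop("gene ids must be unique")
  reg <- merge_regions(region_set)
  ov <- logical(nrow(genes))
  for (s in unique(genes$scaffold)) {
    gi <- which(genes$scaffold == s)
    rs <- reg[reg$scaffold == s, , drop = FALSE]
    if (!nrow(rs)) next
    rg <- .as_iranges(genes[gi, , drop = FALSE])
    rr <- .as_iranges(rs)
    ov[gi] <- IRanges::countOverlaps(rg, rr) > 0
  }
  genes$overlaps <- ov
  genes
}

#' 2x2 contingency table: gene-set membership vs region overlap
#'
#' @param genes gene table from [genes_in_regions()] with \code{in_set} and
#'   \code{overlaps} columns.
#' @return 2x2 integer matrix; rows = in focal set / not, columns =
#'   overlapping / not.
#' @export
build_contingency <- function(genes) {
  if (!nrow(genes)) stop("zero genes")
  if (anyNA(genes$in_set) || anyNA(genes$overlaps))
    stop("every gene needs both flags")
  m <- matrix(c(sum(genes$in_set & genes$overlaps),
                sum(genes$in_set & !genes$overlaps),
                sum(!genes$in_set & genes$overlaps),
                sum(!genes$in_set & !genes$overlaps)),
              nrow = 2, byrow = TRUE,
              dimnames = list(set = c("in_set", "not_in_set"),
                              overlap = c("overlapping", "not_overlapping")))
  m
}

#' Chi-square test of independence for a 2x2 table
#'
#' chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with df = 1; with the Yates
#' continuity correction |ad - bc| is reduced by N/2 (floored at 0) before
#' squaring. The p-value is the upper tail of the chi-square distribution.
#' The direction of association (excess or deficit of overlap in the focal
#' set) is reported alongside.
#'
#' @param tab 2x2 matrix as from [build_contingency()].
#' @param continuity_correction apply Yates' correction (default FALSE).
#' @return list with \code{chi2}, \code{p}, \code{df} (= 1),
#'   \code{odds_ratio}, \code{direction} ("excess"/"deficit"/"none").
#' @examples
#' chi_square_2x2(matrix(c(20, 80, 10, 90), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(tab, continuity_correction = FALSE) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  if (N <= 0) stop("empty table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("a zero margin makes the test undefined")
  delta <- abs(a * d - b * c)
  if (continuity_correction) delta <- max(0, delta - N / 2)
  chi2 <- N * delta^2 / prod(marg)
  or <- if (b * c > 0) (a * d) / (b * c) else Inf
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), df = 1L,
       odds_ratio = or,
       direction = if (or > 1) "excess" else if (or < 1) "deficit" else "none")
}
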