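#' Read biallelic SNPs from a multi-sample VCF
#'
#' Reads a VCF, keeps biallelic SNP records on scaffolds strictly longer than
#' \code{min_scaffold_len} (contig lengths are taken from the header), and
#' decodes genotypes to alt-allele counts (0, 1, 2; \code{NA} for missing).
#' Indels and multiallelic records are dropped.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param samples optional character vector of sample names to retain, in
#'   order. An absent sample is an error.
#' @param min_scaffold_len scaffolds must be strictly longer than this (bp) to
#'   be retained; default 100 kb.
#' @return A genotype table: \code{data.frame} with columns \code{scaffold},
#'   \code{pos} (0-based), \code{ref}, \code{alt}, then one integer column per
#'   sample. Positions are strictly increasing within scaffold.
#' @export
read_vcf_biallelic <- function(path, samples = NULL, min_scaffold_len = 100000) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  ids <- sub('.*[<,]ID=([^,>]+).*', "\\1", contig)
  lens <- suppressWarnings(as.numeric(sub(".*[<,]length=([0-9]+).*", "\\1", contig)))
  if (!length(contig) || anyNA(lens))
    stop("VCF header lacks contig lines with lengths")
  contig_len <- stats::setNames(lens, ids)

  fix <- v@fix
  gt <- v@gt
  have <- colnames(gt)[-1]
  if (is.null(samples)) samples <- have
  missing_s <- setdiff(samples, have)
  if (length(missing_s))
    stop("sample(s) absent from VCF header: ", paste(missing_s, collapse = ", "))

  chrom <- fix[, "CHROM"]
  keep_scaf <- contig_len[chrom] > min_scaffold_len
  keep_scaf[is.na(keep_scaf)] <- FALSE
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- keep_scaf & snp & !is.na(alt)
  if (!any(keep)) {
    out <- data.frame(scaffold = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    for (s in samples) out[[s]] <- integer()
    attr(out, "scaffold_lengths") <- contig_len
    return(out)
  }
  fix <- fix[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]

  out <- data.frame(scaffold = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]) - 1,  # to 0-based
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  for (s in samples) {
    g <- sub(":.*", "", gt[, s])
    a1 <- substr(g, 1, 1); a2 <- substr(g, 3, 3)
    cnt <- (a1 == "1") + (a2 == "1")
    cnt[a1 == "." | a2 == "." | a1 == "" | a2 == ""] <- NA_integer_
    out[[s]] <- as.integer(cnt)
  }
  ord <- order(out$scaffold, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scaffold_lengths") <- contig_len
  out
}

#' Polarize genotypes by the outgroup
#'
#' Defines the ancestral allele at each site as the outgroup's homozygous
#' allele and converts each ingroup diploid genotype to a derived-allele
#' frequency in \{0, 0.5, 1\}. Sites where the outgroup is heterozygous or
#' missing, or where any ingroup genotype is missing, are excluded.
#'
#' @param gt genotype table from [read_vcf_biallelic()] or
#'   [simulate_dataset()].
#' @param outgroup name of the outgroup sample column.
#' @return data.frame with \code{scaffold}, \code{pos} and one derived-allele
#'   frequency column per ingroup sample.
#' @export
polarize <- function(gt, outgroup) {
  samp <- setdiff(names(gt), c("scaffold", "pos", "ref", "alt", "n_alleles"))
  if (!outgroup %in% samp) stop("outgroup sample not present: ", outgroup)
  ing <- setdiff(samp, outgroup)
  og <- gt[[outgroup]]
  keep <- !is.na(og) & og != 1L
  if (!is.null(gt$n_alleles)) keep <- keep & gt$n_alleles == 2L
  for (s in ing) keep <- keep & !is.na(gt[[s]])
  idx <- which(keep)
  og0 <- as.numeric(og[idx] == 0L)
  out <- data.frame(scaffold = gt$scaffold[idx], pos = gt$pos[idx],
                    stringsAsFactors = FALSE)
  # og == 0: ancestral is ref, derived freq = g/2; og == 2: ancestral is alt
  for (s in ing) {
    g <- gt[[s]][idx]
    out[[s]] <- (og0 * g + (1 - og0) * (2 - g)) / 2
  }
  attr(out, "scaffold_lengths") <- attr(gt, "scaffold_lengths")
  rownames(out) <- NULL
  out
}

#' Coverage-based site mask
#'
#' Computes the cross-sample mean depth at each site, then the per-scaffold
#' mean of those site means, and fails a site whose mean depth is strictly
#' greater than \code{high_factor} times, or strictly less than
#' \code{low_factor} times, its scaffold mean. Sites exactly at a threshold
#' pass.
#'
#' @param coverage long-format data.frame with columns \code{scaffold},
#'   \code{pos} (0-based), \code{sample}, \code{depth}, or a site x sample
#'   depth matrix accompanied by \code{scaffold}/\code{pos} columns.
#' @param low_factor,high_factor multiples of the scaffold mean bounding the
#'   pass band; defaults 0.5 and 2.
#' @return data.frame with \code{scaffold}, \code{pos}, \code{mean_depth},
#'   \code{fail}; the per-scaffold means are attached as attribute
#'   \code{"scaffold_mean"}.
#' @export
coverage_mask <- function(coverage, low_factor = 0.5, high_factor = 2.0) {
  if (!nrow(coverage)) stop("empty coverage table")
  if (all(c("sample", "depth") %in% names(coverage))) {
    key <- paste(coverage$scaffold, coverage$pos)
    site_mean <- tapply(coverage$depth, key, mean)
    first <- !duplicated(key)
    sites <- data.frame(scaffold = coverage$scaffold[first],
                        pos = coverage$pos[first], stringsAsFactors = FALSE)
    sites$mean_depth <- as.numeric(site_mean[paste(sites$scaffold, sites$pos)])
  } else {
    depth_cols <- setdiff(names(coverage), c("scaffold", "pos"))
    sites <- data.frame(scaffold = coverage$scaffold, pos = coverage$pos,
                        stringsAsFactors = FALSE)
    sites$mean_depth <- rowMeans(as.matrix(coverage[, depth_cols, drop = FALSE]))
  }
  scaf_mean <- tapply(sites$mean_depth, sites$scaffold, mean)
  m <- as.numeric(scaf_mean[sites$scaffold])
  sites$fail <- sites$mean_depth > high_factor * m |
                sites$mean_depth < low_factor * m
  sites <- sites[order(sites$scaffold, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "scaffold_mean") <- scaf_mean
  sites
}
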