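#' Site-level genotype container
#'
#' A `site_set` holds the per-position genotype records that the sweep scan
#' consumes: one row per *explicit* site (polymorphic, divergent, or
#' artifact-bearing positions, or every position when read from an all-sites
#' VCF), with parallel genotype, depth and genotype-quality matrices, plus an
#' optional set of *callable background* intervals. Positions inside the
#' callable intervals that carry no explicit record are treated as clean
#' homozygous-reference sites with the stated default depth and genotype
#' quality: they contribute to the callable length L of a window but nothing
#' to diversity or divergence. All-sites VCF input uses `callable = NULL`
#' (absent positions are simply not callable); the sparse synthetic generator
#' and the variant-VCF + callable-mask route use explicit intervals.
#'
#' Genotypes are encoded as the number of non-reference alleles carried by the
#' diploid (0, 1, 2) with `NA` for a missing call. Coordinates follow the VCF
#' convention (`pos` is 1-based); interval fields (`callable`, windows) are
#' 0-based half-open.
#'
#' @param chrom character vector of sequence names, one per explicit site.
#' @param pos 1-based integer positions, sorted within each chromosome.
#' @param ref,alt reference and alternate allele strings (`"."` when
#'   monomorphic; comma-separated when multi-allelic).
#' @param qual numeric site quality (VCF QUAL); `NA` for monomorphic records.
#' @param n_alt integer count of distinct alternate alleles at the record.
#' @param is_variant logical, `TRUE` for records with at least one alternate
#'   allele (the QUAL filter only applies to these).
#' @param gt,dp,gq integer matrices (sites x samples) of genotype codes,
#'   read depths and Phred-scaled genotype qualities.
#' @param samples sample names (column order of the matrices).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param callable optional data frame (`chrom`, `start`, `end`; 0-based
#'   half-open) of intervals whose non-explicit positions are default-callable.
#' @param default_dp,default_gq depth and genotype quality attributed to
#'   default-callable background positions. `default_dp = NA` means the
#'   background asserts callability without contributing to the depth
#'   distribution (the callable-mask route).
#'
#' @return An object of class `site_set`.
#' @export
site_set <- function(chrom, pos, ref, alt, qual, n_alt, is_variant,
                     gt, dp, gq, samples, chrom_lengths,
                     callable = NULL, default_dp = NA_integer_,
                     default_gq = NA_integer_) {
  m <- length(pos)
  stopifnot(
    length(chrom) == m, length(ref) == m, length(alt) == m,
    length(qual) == m, length(n_alt) == m, length(is_variant) == m,
    is.matrix(gt), nrow(gt) == m, is.matrix(dp), is.matrix(gq),
    all(dim(dp) == dim(gt)), all(dim(gq) == dim(gt)),
    ncol(gt) == length(samples)
  )
  if (m > 0 && any(pos < 1)) stop("positions must be >= 1 (VCF convention)")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  colnames(gt) <- colnames(dp) <- colnames(gq) <- samples
  if (!is.null(callable)) {
    stopifnot(is.data.frame(callable),
              all(c("chrom", "start", "end") %in% names(callable)),
              all(callable$start < callable$end))
  }
  structure(list(
    sites = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                       ref = ref, alt = alt, qual = qual,
                       n_alt = as.integer(n_alt), is_variant = is_variant,
                       stringsAsFactors = FALSE),
    gt = gt, dp = dp, gq = gq,
    samples = samples,
    chrom_lengths = chrom_lengths,
    callable = callable,
    default_dp = default_dp,
    default_gq = default_gq
  ), class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set: %d explicit sites, %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(x$samples, collapse = ", ")))
  cat(sprintf("  chromosomes: %s\n",
              paste(sprintf("%s (%g bp)", names(x$chrom_lengths),
                            x$chrom_lengths), collapse = ", ")))
  if (!is.null(x$callable)) {
    cat(sprintf("  callable background: %g bp in %d interval(s)\n",
                sum(x$callable$end - x$callable$start), nrow(x$callable)))
  } else {
    cat("  callable background: none (explicit sites only)\n")
  }
  invisible(x)
}

# number of default-callable background positions (callable span minus
# explicit records lying inside the callable intervals)
n_default_positions <- function(ss) {
  if (is.null(ss$callable)) return(0)
  total <- sum(ss$callable$end - ss$callable$start)
  total - sum(sites_in_callable(ss))
}

# logical: does each explicit site fall inside a callable interval?
sites_in_callable <- function(ss) {
  if (is.null(ss$callable)) {
    return(rep(FALSE, nrow(ss$sites)))
  }
  out <- logical(nrow(ss$sites))
  for (ch in unique(ss$sites$chrom)) {
    i <- ss$sites$chrom == ch
    cal <- ss$callable[ss$callable$chrom == ch, , drop = FALSE]
    if (!nrow(cal)) next
    ir <- IRanges::reduce(IRanges::IRanges(cal$start + 1L, cal$end))
    out[i] <- IRanges::countOverlaps(
      IRanges::IRanges(ss$sites$pos[i], width = 1L), ir) > 0
  }
  out
}
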