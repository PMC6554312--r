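#' Site filter configuration
#'
#' Bundles the thresholds of the site filter stack applied before any position
#' contributes to a window. The defaults implement a conventional all-sites
#' scan: depth below 3 reads fails, per-sample depth above the nearest-rank
#' 95th percentile of that sample's genome-wide depth distribution fails,
#' variant records with QUAL below 50 fail, genotype quality below 20 fails,
#' any missing genotype among the relevant samples fails, non-biallelic
#' records fail, windows need at least 10 kb of callable sequence, and windows
#' whose reference GC fraction exceeds the 95th percentile of all windows are
#' dropped.
#'
#' @param min_depth minimum per-sample read depth (inclusive; depth 3 passes
#'   under the default, depth 2 fails).
#' @param max_depth_quantile quantile of the per-sample depth distribution
#'   used as the depth ceiling (nearest-rank; inclusive).
#' @param min_site_qual minimum VCF QUAL for variant records (inclusive;
#'   QUAL 50 passes, 49 fails). Monomorphic records are exempt: all-sites
#'   callers give them low or absent QUAL by construction.
#' @param min_genotype_quality minimum Phred-scaled genotype quality
#'   (inclusive).
#' @param require_biallelic drop records with more than one alternate allele
#'   entirely (no decomposition).
#' @param max_gc_quantile window-level GC ceiling quantile; windows with
#'   reference GC strictly above the nearest-rank quantile of all window GC
#'   values are dropped. Only applied when a reference sequence is supplied.
#' @param min_callable_bp minimum callable sites per retained window.
#' @param hom_divergence_weight contribution of a homozygous-alternate
#'   genotype to the divergence sum: 1 counts divergent *sites* (the default,
#'   keeping D a per-site probability on the same scale as theta), 2 counts
#'   derived *alleles*.
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 3, max_depth_quantile = 0.95,
                          min_site_qual = 50, min_genotype_quality = 20,
                          require_biallelic = TRUE, max_gc_quantile = 0.95,
                          min_callable_bp = 10000,
                          hom_divergence_weight = 1) {
  stopifnot(min_depth >= 0,
            max_depth_quantile > 0, max_depth_quantile < 1,
            max_gc_quantile > 0, max_gc_quantile < 1,
            min_site_qual >= 0, min_genotype_quality >= 0,
            min_callable_bp > 0,
            isTRUE(require_biallelic) || isFALSE(require_biallelic),
            hom_divergence_weight %in% c(1, 2))
  structure(list(min_depth = min_depth,
                 max_depth_quantile = max_depth_quantile,
                 min_site_qual = min_site_qual,
                 min_genotype_quality = min_genotype_quality,
                 require_biallelic = require_biallelic,
                 max_gc_quantile = max_gc_quantile,
                 min_callable_bp = min_callable_bp,
                 hom_divergence_weight = hom_divergence_weight),
            class = "filter_config")
}

#' Per-site unbiased heterozygosity
#'
#' Contribution of one biallelic site to nucleotide diversity:
#' `2 p (1 - p) * n / (n - 1)` with `p = k / n`, equivalently
#' `2 k (n - k) / (n (n - 1))` — the mean pairwise difference among the `n`
#' sampled chromosomes at that site. Symmetric in `k <-> n - k` and bounded by
#' `n / (2 (n - 1))`.
#'
#' @param k derived (alternate) allele count, `0 <= k <= n`. Vectorised.
#' @param n number of sampled chromosomes (8 for four diploids), `n >= 2`.
#' @return Numeric vector of per-site diversity values.
#' @export
site_pi <- function(k, n) {
  if (any(is.na(k)) || any(is.na(n))) stop("k and n must be non-missing")
  if (any(n < 2)) stop("n must be at least 2")
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]")
  2 * k * (n - k) / (n * (n - 1))
}

#' Per-site divergence contribution of one genotype
#'
#' The divergence sum counts homozygous-alternate genotypes of the divergence
#' sample with weight `hom_weight` (1 by default: divergent sites) and
#' heterozygous genotypes with weight 0.5.
#'
#' @param gt integer genotype code(s): number of non-reference alleles
#'   (0, 1, 2). Missing genotypes are an error — the filter stack must have
#'   excluded them already.
#' @param hom_weight weight of a homozygous-alternate genotype (1 or 2); see
#'   [filter_config()].
#' @return Numeric vector with values in `{0, 0.5, hom_weight}`.
#' @export
site_divergence_contrib <- function(gt, hom_weight = 1) {
  if (any(is.na(gt))) {
    stop("missing genotype passed to site_divergence_contrib(); ",
         "sites must be filtered first")
  }
  if (any(!gt %in% 0:2)) stop("genotype codes must be 0, 1 or 2")
  c(0, 0.5, hom_weight)[gt + 1L]
}

#' Derived allele count among the focal cohort
#'
#' @param gt integer vector of per-individual genotype codes (0/1/2 alternate
#'   alleles) for the focal samples at one site; no missing values allowed.
#' @return List with `k` (alternate allele count) and `n` (2 x number of
#'   focal diploids).
#' @export
allele_frequency <- function(gt) {
  if (!length(gt)) stop("no focal genotypes supplied")
  if (any(is.na(gt))) {
    stop("missing focal genotype: site should have been excluded by the ",
         "missing-genotype filter")
  }
  if (any(!gt %in% 0:2)) stop("genotype codes must be 0, 1 or 2")
  list(k = as.integer(sum(gt)), n = 2L * length(gt))
}

#' Nearest-rank depth quantile
#'
#' The depth ceiling is the nearest-rank percentile of a sample's depth
#' distribution: the `ceiling(q * N)`-th order statistic. Deterministic for a
#' fixed input; always an observed value.
#'
#' @param depths integer/numeric depths (NA dropped).
#' @param quantile fraction in (0, 1].
#' @return The nearest-rank quantile of `depths`.
#' @export
compute_depth_threshold <- function(depths, quantile = 0.95) {
  depths <- depths[!is.na(depths)]
  if (!length(depths)) stop("empty depth stream")
  stopifnot(quantile > 0, quantile <= 1)
  sort(depths)[ceiling(quantile * length(depths))]
}

# nearest-rank quantile of the mixture {explicit depths} U {default_dp
# repeated n_default times}, without materialising the defaults
depth_threshold_mixture <- function(explicit, n_default, default_dp, q) {
  explicit <- explicit[!is.na(explicit)]
  n_tot <- length(explicit) + n_default
  if (n_tot == 0) stop("empty depth stream")
  if (n_default == 0 || is.na(default_dp)) {
    return(compute_depth_threshold(explicit, q))
  }
  r <- ceiling(q * n_tot)
  srt <- sort(explicit)
  n_below <- sum(srt < default_dp)
  n_eq <- sum(srt == default_dp)
  if (r <= n_below) return(srt[r])
  if (r <= n_below + n_default + n_eq) return(default_dp)
  srt[r - n_default]
}

#' Per-sample depth ceilings for a site set
#'
#' Computes the nearest-rank `quantile` depth ceiling for each requested
#' sample over the full depth distribution implied by the site set: explicit
#' record depths plus, when the set carries a default-callable background with
#' a stated default depth, that constant depth for every background position.
#'
#' @param ss a [site_set()].
#' @param samples sample names; default all.
#' @param quantile ceiling quantile, see [filter_config()].
#' @return Named numeric vector of ceilings.
#' @export
depth_ceilings <- function(ss, samples = ss$samples, quantile = 0.95) {
  stopifnot(inherits(ss, "site_set"))
  nd <- if (is.na(ss$default_dp)) 0 else n_default_positions(ss)
  vapply(samples, function(s) {
    as.numeric(depth_threshold_mixture(ss$dp[, s], nd, ss$default_dp,
                                       quantile))
  }, numeric(1))
}

#' Apply the site filter stack
#'
#' Pure predicate over the explicit sites of a site set. A site passes iff,
#' in order: every relevant sample has a non-missing genotype; every relevant
#' depth lies in `[min_depth, ceiling]`; variant records have
#' `QUAL >= min_site_qual`; the record is biallelic (when required); and every
#' relevant genotype quality is `>= min_genotype_quality`. `reason` names the
#' first violated rule. A failing site contributes to neither L nor the
#' diversity nor the divergence sum of any window.
#'
#' @param ss a [site_set()].
#' @param config a [filter_config()].
#' @param samples the relevant samples (focal cohort plus divergence sample).
#' @param ceilings named per-sample depth ceilings; computed from `ss` via
#'   [depth_ceilings()] when omitted.
#' @return Data frame with logical `pass` and character `reason`
#'   (`NA` for passing sites).
#' @export
site_passes_filters <- function(ss, config = filter_config(),
                                samples = ss$samples, ceilings = NULL) {
  stopifnot(inherits(ss, "site_set"), inherits(config, "filter_config"))
  if (!all(samples %in% ss$samples)) {
    stop("unknown samples: ",
         paste(setdiff(samples, ss$samples), collapse = ", "))
  }
  if (is.null(ceilings)) {
    ceilings <- depth_ceilings(ss, samples, config$max_depth_quantile)
  }
  m <- nrow(ss$sites)
  gt <- ss$gt[, samples, drop = FALSE]
  dp <- ss$dp[, samples, drop = FALSE]
  gq <- ss$gq[, samples, drop = FALSE]
  reason <- rep(NA_character_, m)
  flag <- function(cond, what) {
    idx <- is.na(reason) & cond
    reason[idx] <<- what
  }
  flag(rowSums(is.na(gt)) > 0, "missing_genotype")
  ceil_m <- matrix(ceilings[samples], m, length(samples), byrow = TRUE)
  bad_dp <- is.na(dp) | dp < config$min_depth | dp > ceil_m
  flag(rowSums(bad_dp) > 0, "depth")
  flag(ss$sites$is_variant &
         (is.na(ss$sites$qual) | ss$sites$qual < config$min_site_qual),
       "site_quality")
  if (config$require_biallelic) flag(ss$sites$n_alt > 1, "biallelic")
  flag(rowSums(is.na(gq) | gq < config$min_genotype_quality) > 0,
       "genotype_quality")
  data.frame(pass = is.na(reason), reason = reason, stringsAsFactors = FALSE)
}

#' GC fraction of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; N (and other ambiguity) bases are excluded
#' from the denominator. Returns `NA` for a sequence with no unambiguous
#' bases.
#'
#' @param seq a character string or `Biostrings::DNAString` over
#'   `{A, C, G, T, N}` (case-insensitive).
#' @return GC fraction in `[0, 1]`, or `NA_real_`.
#' @export
gc_fraction <- function(seq) {
  if (!methods::is(seq, "DNAString")) {
    stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
    seq <- Biostrings::DNAString(toupper(seq))
  }
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) return(NA_real_)
  unname((f[["G"]] + f[["C"]]) / denom)
}
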