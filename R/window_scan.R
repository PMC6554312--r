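#' Build genomic windows
#'
#' Emits fixed-length windows `[s, s + window_bp)` for
#' `s = 0, step_bp, 2 step_bp, ...` with `s + window_bp <= chromosome length`.
#' Partial trailing windows are not emitted, so the callable-length rule and L
#' remain comparable across windows. The default `step_bp = window_bp` gives
#' non-overlapping windows; a smaller step gives a sliding scan.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window_bp window length in bp (default 100 kb).
#' @param step_bp distance between window starts; `0 < step_bp <= window_bp`.
#' @return Data frame with `chrom`, `start` (0-based inclusive), `end`
#'   (exclusive), in chromosome input order.
#' @export
make_windows <- function(chrom_lengths, window_bp = 100000L,
                         step_bp = window_bp) {
  if (window_bp <= 0 || step_bp <= 0) {
    stop("window_bp and step_bp must be positive")
  }
  if (step_bp > window_bp) stop("step_bp must not exceed window_bp")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- as.numeric(chrom_lengths[[ch]])
    if (len < window_bp) return(NULL)
    starts <- seq.int(0, len - window_bp, by = step_bp)
    data.frame(chrom = ch, start = starts, end = starts + window_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Diversity/divergence summary of one window
#'
#' Evaluates the windowed ratio for a single window from already-filtered
#' sites: `theta = sum(site_pi) / L`, `D = sum(divergence contrib) / L`,
#' `ratio = theta / D` (missing when `D == 0`). Sites absent from `gt` but
#' counted in `L` are clean monomorphic positions contributing zero to both
#' sums.
#'
#' @param gt integer genotype-code matrix (filtered sites x samples) with
#'   sample column names; may have zero rows. No missing values allowed.
#' @param focal_samples names of the focal cohort columns (>= 1 diploid).
#' @param divergence_sample name of the divergence column.
#' @param L callable-site count of the window, `>= nrow(gt)`.
#' @param hom_divergence_weight see [filter_config()].
#' @return List with `L`, `theta`, `D`, `ratio`.
#' @export
scan_window <- function(gt, focal_samples, divergence_sample, L = nrow(gt),
                        hom_divergence_weight = 1) {
  stopifnot(is.matrix(gt), !is.null(colnames(gt)),
            all(c(focal_samples, divergence_sample) %in% colnames(gt)))
  if (L <= 0) stop("window has no callable sites")
  if (L < nrow(gt)) stop("L cannot be smaller than the number of sites")
  if (nrow(gt) && any(is.na(gt))) {
    stop("missing genotypes: sites must pass the filter stack first")
  }
  n <- 2L * length(focal_samples)
  theta <- if (nrow(gt)) {
    k <- rowSums(gt[, focal_samples, drop = FALSE])
    sum(site_pi(k, n)) / L
  } else 0
  D <- if (nrow(gt)) {
    sum(site_divergence_contrib(gt[, divergence_sample],
                                hom_divergence_weight)) / L
  } else 0
  list(L = L, theta = theta, D = D,
       ratio = if (D > 0) theta / D else NA_real_)
}

#' Empirical p-values for the low-ratio tail
#'
#' Rank-based tail probability against the genome-wide distribution itself:
#' `p_i = #\{j : ratio_j <= ratio_i\} / N`. Ties share the same p, lower
#' ratios get smaller p, and the minimum attainable p is `1/N`. The
#' denominator is N (the number of windows with a defined ratio), not N + 1,
#' so a `p < alpha` cut can select at most `ceiling(alpha * N)` windows;
#' this makes thresholds like `p < 0.01` exactly reproducible.
#'
#' @param ratios finite numeric vector of theta/D ratios (windows with
#'   missing ratio must be excluded beforehand).
#' @return Numeric vector of empirical p-values in `(0, 1]`.
#' @export
empirical_p <- function(ratios) {
  if (!length(ratios)) stop("no ratios supplied")
  if (any(!is.finite(ratios))) stop("ratios must be finite and non-missing")
  rank(ratios, ties.method = "max") / length(ratios)
}

#' Information-content diagnostic
#'
#' Checks that window information content does not drive the statistic: the
#' Spearman rank correlation between the theta/D ratio and the number of
#' called bases L per window should be near zero on neutral data. Also
#' returns the (L, ratio) table for plotting.
#'
#' @param windows a window table from [scan_windows()] (or any data frame
#'   with `L` and `ratio` columns); windows with missing ratio are dropped.
#' @return List with `rho` (Spearman correlation, 0 with a warning when
#'   either variable is constant) and `table` (data frame of `L`, `ratio`).
#' @export
info_diagnostic <- function(windows) {
  stopifnot(all(c("L", "ratio") %in% names(windows)))
  ok <- !is.na(windows$ratio)
  if (sum(ok) < 3) stop("need at least 3 windows with a defined ratio")
  L <- windows$L[ok]
  r <- windows$ratio[ok]
  if (stats::sd(r) == 0 || stats::sd(L) == 0) {
    warning("degenerate input: ratio or L constant across windows; ",
            "reporting rho = 0")
    rho <- 0
  } else {
    rho <- stats::cor(L, r, method = "spearman")
  }
  list(rho = rho, table = data.frame(L = L, ratio = r))
}

# reference GC fraction per window; reference is a DNAStringSet (or FASTA
# path). Returns numeric vector aligned with `windows` rows, NA where the
# window's chromosome is absent from the reference or fully ambiguous.
window_gc <- function(reference, windows) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  names(reference) <- sub("\\s.*$", "", names(reference))
  gc <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    i <- which(windows$chrom == ch)
    if (!ch %in% names(reference)) next
    v <- Biostrings::Views(reference[[ch]], start = windows$start[i] + 1L,
                           end = windows$end[i])
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(f)
    gc[i] <- ifelse(denom > 0, (f[, "G"] + f[, "C"]) / denom, NA_real_)
  }
  gc
}

# sum `x` by window index `wi` into a length-nw vector
sum_by_window <- function(x, wi, nw) {
  out <- numeric(nw)
  if (length(x)) {
    agg <- rowsum(x, wi)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Windowed diversity/divergence scan
#'
#' The main driver: builds windows, computes per-sample depth ceilings,
#' applies the site filter stack, evaluates windowed theta, D and their ratio,
#' applies the window-level callable-length and GC filters, and assigns
#' empirical p-values over the windows with a defined ratio.
#'
#' Windows below `min_callable_bp` callable sites are flagged
#' `"low_callable"`, windows removed by the GC filter `"high_gc"`; both are
#' excluded from the retained set and the ranking. Windows with `D == 0`
#' (flag `"zero_divergence"`) are retained but excluded from the ranking:
#' the candidate set is the low-ratio tail, and a zero-divergence window is
#' the anti-sweep extreme with an undefined ratio.
#'
#' @param ss a [site_set()].
#' @param focal_samples names of >= 2 focal diploid samples (the polymorphism
#'   cohort; `n = 2 x` their number).
#' @param divergence_sample name of the genome contrasted against the
#'   reference for D (may itself be one of the focal samples).
#' @param config a [filter_config()].
#' @param window_bp,step_bp window geometry, see [make_windows()].
#' @param reference optional reference sequence (`DNAStringSet` or FASTA
#'   path) enabling the window-level GC filter.
#' @return Data frame of class `window_stats` with columns `chrom`, `start`,
#'   `end`, `L`, `theta`, `D`, `ratio`, `empirical_p`, `flags` (`"."` when
#'   clean, else comma-joined). Attributes: `filter_tally` (site counts per
#'   failure reason), `depth_ceilings`, `gc_cutoff`, `config`.
#' @export
scan_windows <- function(ss, focal_samples, divergence_sample,
                         config = filter_config(), window_bp = 100000L,
                         step_bp = window_bp, reference = NULL) {
  stopifnot(inherits(ss, "site_set"), inherits(config, "filter_config"))
  if (length(focal_samples) < 2) {
    stop("at least two focal samples are required")
  }
  if (length(divergence_sample) != 1) {
    stop("exactly one divergence sample is required")
  }
  missing_s <- setdiff(c(focal_samples, divergence_sample), ss$samples)
  if (length(missing_s)) {
    stop("samples not in site set: ", paste(missing_s, collapse = ", "))
  }
  relevant <- unique(c(focal_samples, divergence_sample))

  wins <- make_windows(ss$chrom_lengths, window_bp, step_bp)
  ceilings <- depth_ceilings(ss, relevant, config$max_depth_quantile)
  status <- site_passes_filters(ss, config, relevant, ceilings)
  reason_levels <- c("missing_genotype", "depth", "site_quality",
                     "biallelic", "genotype_quality")
  tally <- table(factor(ifelse(status$pass, "pass", status$reason),
                        levels = c("pass", reason_levels)))

  n_chrom <- 2L * length(focal_samples)
  in_cal <- sites_in_callable(ss)

  L <- theta_sum <- d_sum <- numeric(nrow(wins))
  for (ch in unique(wins$chrom)) {
    wsel <- which(wins$chrom == ch)
    nw <- length(wsel)
    ir_w <- IRanges::IRanges(wins$start[wsel] + 1L, wins$end[wsel])
    sidx <- which(ss$sites$chrom == ch)
    L_pass <- th <- dv <- n_expl_cal <- numeric(nw)
    if (length(sidx)) {
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(ss$sites$pos[sidx], width = 1L), ir_w)
      gi <- sidx[S4Vectors::queryHits(hits)]   # global site index per hit
      wi <- S4Vectors::subjectHits(hits)       # local window index per hit
      p <- status$pass[gi]
      n_expl_cal <- tabulate(wi[in_cal[gi]], nw)
      gi_p <- gi[p]
      wi_p <- wi[p]
      L_pass <- tabulate(wi_p, nw)
      if (length(gi_p)) {
        k <- rowSums(ss$gt[gi_p, focal_samples, drop = FALSE])
        th <- sum_by_window(site_pi(k, n_chrom), wi_p, nw)
        dc <- site_divergence_contrib(ss$gt[gi_p, divergence_sample],
                                      config$hom_divergence_weight)
        dv <- sum_by_window(dc, wi_p, nw)
      }
    }
    def_cnt <- numeric(nw)
    if (!is.null(ss$callable)) {
      cal <- ss$callable[ss$callable$chrom == ch, , drop = FALSE]
      if (nrow(cal)) {
        ir_c <- IRanges::reduce(IRanges::IRanges(cal$start + 1L, cal$end))
        ov <- IRanges::findOverlaps(ir_w, ir_c)
        if (length(ov)) {
          pw <- IRanges::width(IRanges::pintersect(
            ir_w[S4Vectors::queryHits(ov)], ir_c[S4Vectors::subjectHits(ov)]))
          def_cnt <- sum_by_window(pw, S4Vectors::queryHits(ov), nw)
        }
        def_cnt <- pmax(def_cnt - n_expl_cal, 0)
      }
    }
    L[wsel] <- L_pass + def_cnt
    theta_sum[wsel] <- th
    d_sum[wsel] <- dv
  }

  theta <- ifelse(L > 0, theta_sum / L, NA_real_)
  D <- ifelse(L > 0, d_sum / L, NA_real_)
  ratio <- ifelse(!is.na(D) & D > 0, theta / D, NA_real_)

  gc_cutoff <- NA_real_
  high_gc <- rep(FALSE, nrow(wins))
  if (!is.null(reference) && nrow(wins)) {
    gcv <- window_gc(reference, wins)
    ok <- !is.na(gcv)
    if (any(ok)) {
      gc_cutoff <- sort(gcv[ok])[ceiling(config$max_gc_quantile * sum(ok))]
      high_gc <- ok & gcv > gc_cutoff
    }
  }
  low_cal <- L < config$min_callable_bp
  retained <- !low_cal & !high_gc
  zero_div <- retained & !is.na(D) & D == 0

  flags <- character(nrow(wins))
  add_flag <- function(flags, cond, name) {
    ifelse(cond, ifelse(nzchar(flags), paste(flags, name, sep = ","), name),
           flags)
  }
  flags <- add_flag(flags, low_cal, "low_callable")
  flags <- add_flag(flags, high_gc, "high_gc")
  flags <- add_flag(flags, zero_div, "zero_divergence")
  flags[!nzchar(flags)] <- "."

  emp <- rep(NA_real_, nrow(wins))
  rankable <- retained & !is.na(ratio)
  if (any(rankable)) emp[rankable] <- empirical_p(ratio[rankable])

  out <- data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
                    L = L, theta = theta, D = D, ratio = ratio,
                    empirical_p = emp, flags = flags,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_stats", "data.frame")
  attr(out, "filter_tally") <- tally
  attr(out, "depth_ceilings") <- ceilings
  attr(out, "gc_cutoff") <- gc_cutoff
  attr(out, "config") <- config
  out
}

#' Retained windows of a scan
#'
#' Windows that passed the callable-length and GC window filters (including
#' zero-divergence windows, which carry a flag but no empirical p).
#'
#' @param windows a `window_stats` table from [scan_windows()].
#' @return The retained subset, same columns.
#' @export
retained_windows <- function(windows) {
  drop <- grepl("low_callable|high_gc", windows$flags)
  windows[!drop, , drop = FALSE]
}
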