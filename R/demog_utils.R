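#' Mutation-rate and generation-time calibration
#'
#' Constants used to convert mutation-scaled coalescent parameters to natural
#' units. Defaults: a per-site per-generation mutation rate of
#' `mu = 4.0e-9` and an average generation time of three years.
#'
#' @param mu mutation rate per site per generation (> 0).
#' @param gen_time_years average generation time in years (> 0).
#' @return Object of class `calibration_params`.
#' @export
calibration_params <- function(mu = 4.0e-9, gen_time_years = 3) {
  stopifnot(mu > 0, gen_time_years > 0)
  structure(list(mu = mu, gen_time_years = gen_time_years),
            class = "calibration_params")
}

#' Filter neutral loci by genotype missingness
#'
#' A locus is removed when *more than* `max_missing_fraction` of its
#' genotype cells are missing (strictly greater: a locus at exactly the
#' threshold is retained). Missingness is typically pre-encoded upstream as
#' depth below four reads or above the per-sample 95th coverage percentile
#' (see [compute_depth_threshold()]).
#'
#' @param loci data frame with one row per locus and columns `locus_id`,
#'   `n_sites`, `n_samples`, `n_missing` (missing genotype cells out of
#'   `n_sites * n_samples`); build it from per-locus alignments with
#'   [read_locus_alignments()].
#' @param max_missing_fraction removal threshold (default 0.10).
#' @return List with `retained` and `removed` subsets of `loci` and a
#'   `report` list (`n_input`, `n_removed`, `n_retained`,
#'   `max_missing_fraction`).
#' @export
neutral_locus_filter <- function(loci, max_missing_fraction = 0.10) {
  stopifnot(is.data.frame(loci),
            all(c("locus_id", "n_sites", "n_samples", "n_missing") %in%
                  names(loci)),
            max_missing_fraction >= 0, max_missing_fraction < 1)
  if (!nrow(loci)) stop("empty locus list")
  cells <- loci$n_sites * loci$n_samples
  stopifnot(all(loci$n_sites > 0), all(loci$n_samples > 0),
            all(loci$n_missing >= 0), all(loci$n_missing <= cells))
  frac <- loci$n_missing / cells
  keep <- frac <= max_missing_fraction
  list(retained = loci[keep, , drop = FALSE],
       removed = loci[!keep, , drop = FALSE],
       report = list(n_input = nrow(loci),
                     n_removed = sum(!keep),
                     n_retained = sum(keep),
                     max_missing_fraction = max_missing_fraction))
}

#' Per-locus missingness from alignment files
#'
#' Reads one sequence-alignment FASTA per locus (one row per sample) and
#' counts missing characters (`?`, `N`, `n`, `-` by default).
#'
#' @param paths FASTA file paths, one per locus.
#' @param missing_chars characters counted as missing.
#' @return Data frame suitable for [neutral_locus_filter()].
#' @export
read_locus_alignments <- function(paths,
                                  missing_chars = c("?", "N", "n", "-")) {
  stopifnot(length(paths) > 0)
  rows <- lapply(paths, function(p) {
    x <- Biostrings::readBStringSet(p)
    if (!length(x)) stop("no sequences in ", p)
    w <- Biostrings::width(x)
    if (length(unique(w)) != 1) {
      stop("unequal sequence lengths in ", p, ": not an alignment")
    }
    n_missing <- sum(vapply(missing_chars, function(ch) {
      sum(Biostrings::vcountPattern(ch, x))
    }, numeric(1)))
    data.frame(locus_id = sub("\\.[^.]*$", "", basename(p)),
               n_sites = w[1], n_samples = length(x),
               n_missing = as.integer(n_missing), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Missing-site percentage of a concatenated matrix
#'
#' `100 * missing / total`, rounded half-up to one decimal place (the
#' conventional reporting style for alignment missingness).
#'
#' @param total_sites total sites in the matrix (> 0).
#' @param missing_sites missing sites, `0 <= missing <= total`.
#' @return Percentage with one decimal.
#' @export
missingness_summary <- function(total_sites, missing_sites) {
  if (total_sites <= 0) stop("total_sites must be positive")
  if (missing_sites < 0 || missing_sites > total_sites) {
    stop("missing_sites must lie in [0, total_sites]")
  }
  pct <- 100 * missing_sites / total_sites
  floor(pct * 10 + 0.5) / 10
}

#' Convert mutation-scaled population size to Ne
#'
#' `Ne = theta / (4 mu)` for a diploid population.
#'
#' @param theta mutation-scaled population size (>= 0); vectorised.
#' @param cal a [calibration_params()].
#' @return Effective population size in individuals.
#' @export
scale_theta_to_Ne <- function(theta, cal = calibration_params()) {
  stopifnot(inherits(cal, "calibration_params"), all(theta >= 0))
  theta / (4 * cal$mu)
}

#' Convert mutation-scaled divergence time to years
#'
#' `years = (tau / mu) * gen_time_years`.
#'
#' @param tau mutation-scaled divergence time (>= 0); vectorised.
#' @param cal a [calibration_params()].
#' @return Divergence time in years.
#' @export
scale_tau_to_years <- function(tau, cal = calibration_params()) {
  stopifnot(inherits(cal, "calibration_params"), all(tau >= 0))
  (tau / cal$mu) * cal$gen_time_years
}

#' Total migration rate of a migration band
#'
#' Scales an instantaneous migration rate by the duration of its band,
#' `total = m * tau_span`, approximating the probability that a lineage
#' experienced migration through the band. Bands with total rate strictly
#' above `threshold` (default 0.05) are flagged as major bands; a total of
#' exactly 0.05 is not flagged.
#'
#' @param m mutation-scaled migration rate(s) (>= 0).
#' @param tau_span duration(s) of the band in mutation-scaled time (>= 0).
#' @param threshold major-band flag threshold (strict `>`).
#' @return Data frame with `total` and logical `major_band`.
#' @export
total_migration_rate <- function(m, tau_span, threshold = 0.05) {
  stopifnot(all(m >= 0), all(tau_span >= 0), threshold >= 0)
  total <- m * tau_span
  data.frame(total = total, major_band = total > threshold)
}

#' Summarise a posterior parameter trace
#'
#' Operates on parameter samples supplied as a plain numeric table (one row
#' per MCMC sample, one column per parameter); the sampler itself is out of
#' scope. Reports the posterior mean and equal-tailed 95% interval of each
#' column, in both mutation-scaled and natural units. Intervals are
#' equal-tailed (2.5% / 97.5% quantiles), not highest-posterior-density.
#'
#' @param trace data frame or matrix of numeric samples with column names.
#' @param kinds named character vector mapping each column to `"theta"`,
#'   `"tau"` or `"migration"`.
#' @param cal a [calibration_params()].
#' @param tau_spans optional named numeric vector of band durations for
#'   migration columns; when present, their natural value is the total
#'   migration rate `m * tau_span`, otherwise the raw rate is echoed.
#' @return Data frame with one row per parameter: `param`, `kind`,
#'   `raw_mean`, `raw_lo`, `raw_hi`, `natural_mean`, `natural_lo`,
#'   `natural_hi`.
#' @export
summarize_trace <- function(trace, kinds, cal = calibration_params(),
                            tau_spans = NULL) {
  trace <- as.data.frame(trace)
  stopifnot(nrow(trace) > 0, all(names(kinds) %in% names(trace)),
            all(kinds %in% c("theta", "tau", "migration")))
  rows <- lapply(names(kinds), function(p) {
    x <- trace[[p]]
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    raw <- c(mean(x), q)
    nat <- switch(kinds[[p]],
      theta = scale_theta_to_Ne(raw, cal),
      tau = scale_tau_to_years(raw, cal),
      migration = if (!is.null(tau_spans) && p %in% names(tau_spans)) {
        raw * tau_spans[[p]]
      } else raw)
    data.frame(param = p, kind = kinds[[p]],
               raw_mean = raw[1], raw_lo = raw[2], raw_hi = raw[3],
               natural_mean = nat[1], natural_lo = nat[2],
               natural_hi = nat[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
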