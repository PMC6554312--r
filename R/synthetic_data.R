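#' Parameters of the synthetic cohort generator
#'
#' Describes a reference-mapped cohort of diploid focal genomes plus a
#' divergence contrast on one chromosome. Sites are independent: neutral
#' background polymorphism appears at per-site density
#' `pi_background * H_{n-1}` with derived-allele counts drawn from the
#' standard neutral `1/k` frequency spectrum (so the expected per-site
#' unbiased heterozygosity is exactly `pi_background`); divergence sites make
#' the divergence sample homozygous-alternate (or heterozygous with
#' probability `het_fraction_of_divergence`); sweep intervals multiply the
#' polymorphic density by their `diversity_factor`; artifact classes inject
#' sites that the filter stack must remove. Linkage is deliberately absent —
#' the windowed statistics are per-site sums, and independence gives
#' closed-form oracles for testing.
#'
#' The divergence contrast is carried by a dedicated sample (`div1`) rather
#' than by one of the focal genomes, so that the analytic expectations of
#' theta and D stay exactly separable; the scan itself accepts any sample,
#' including a focal one, as the divergence sample.
#'
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param n_focal_diploids number of focal diploid genomes (default 4, i.e.
#'   n = 8 sampled chromosomes).
#' @param pi_background expected per-site heterozygosity outside sweeps.
#' @param divergence_rate expected per-site divergence-event rate of the
#'   divergence sample.
#' @param het_fraction_of_divergence fraction of divergence sites that are
#'   heterozygous (weight 0.5 in D) rather than homozygous-alternate.
#' @param sweep_intervals optional data frame (`start`, `end`,
#'   `diversity_factor` in `[0, 1]`; 0-based half-open) of non-overlapping
#'   low-diversity intervals within the chromosome.
#' @param artifact_rates optional named list of per-site injection
#'   probabilities for `low_depth`, `low_gq`, `low_qual`, `missing`,
#'   `multi_allelic`; missing entries default to 0.
#' @param gc_tract optional list/vector with `start`, `end`, `gc_level`
#'   describing a high-GC tract of the simulated reference.
#' @param gc_background GC fraction of the reference outside the tract.
#' @param seed integer seed; fixes all outputs byte-for-byte.
#' @return Object of class `sweep_sim_params`.
#' @export
sweep_sim_params <- function(chrom_length, chrom = "chr1",
                             n_focal_diploids = 4, pi_background = 1e-3,
                             divergence_rate = 2e-3,
                             het_fraction_of_divergence = 0.2,
                             sweep_intervals = NULL, artifact_rates = NULL,
                             gc_tract = NULL, gc_background = 0.4,
                             seed = 1L) {
  stopifnot(chrom_length >= 1, n_focal_diploids >= 1,
            pi_background >= 0, pi_background < 1,
            divergence_rate >= 0, divergence_rate < 1,
            het_fraction_of_divergence >= 0,
            het_fraction_of_divergence <= 1,
            gc_background > 0, gc_background < 1,
            is.numeric(seed), length(seed) == 1)
  classes <- c("low_depth", "low_gq", "low_qual", "missing", "multi_allelic")
  rates <- stats::setNames(rep(0, length(classes)), classes)
  if (!is.null(artifact_rates)) {
    bad <- setdiff(names(artifact_rates), classes)
    if (length(bad)) stop("unknown artifact classes: ",
                          paste(bad, collapse = ", "))
    rates[names(artifact_rates)] <- unlist(artifact_rates)
  }
  stopifnot(all(rates >= 0), all(rates <= 1), sum(rates) <= 1)
  if (!is.null(sweep_intervals)) {
    stopifnot(is.data.frame(sweep_intervals),
              all(c("start", "end", "diversity_factor") %in%
                    names(sweep_intervals)))
    sw <- sweep_intervals[order(sweep_intervals$start), , drop = FALSE]
    if (any(sw$start < 0) || any(sw$end > chrom_length) ||
        any(sw$start >= sw$end)) {
      stop("sweep intervals must be non-empty and lie within [0, ",
           chrom_length, ")")
    }
    if (nrow(sw) > 1 && any(sw$start[-1] < sw$end[-nrow(sw)])) {
      stop("sweep intervals must not overlap")
    }
    if (any(sw$diversity_factor < 0) || any(sw$diversity_factor > 1)) {
      stop("diversity_factor must lie in [0, 1]")
    }
    sweep_intervals <- sw
  }
  if (!is.null(gc_tract)) {
    gc_tract <- as.list(gc_tract)
    stopifnot(all(c("start", "end", "gc_level") %in% names(gc_tract)),
              gc_tract$start >= 0, gc_tract$end <= chrom_length,
              gc_tract$start < gc_tract$end,
              gc_tract$gc_level > 0, gc_tract$gc_level < 1)
  }
  structure(list(chrom_length = chrom_length, chrom = chrom,
                 n_focal_diploids = as.integer(n_focal_diploids),
                 pi_background = pi_background,
                 divergence_rate = divergence_rate,
                 het_fraction_of_divergence = het_fraction_of_divergence,
                 sweep_intervals = sweep_intervals,
                 artifact_rates = as.list(rates),
                 gc_tract = gc_tract, gc_background = gc_background,
                 seed = as.integer(seed)),
            class = "sweep_sim_params")
}

#' Draw derived-allele counts from the neutral frequency spectrum
#'
#' `P(k) proportional to 1/k` for `k in {1, ..., n-1}` — the standard neutral
#' site frequency spectrum. Uses the global RNG stream.
#'
#' @param n number of draws.
#' @param n_chromosomes sampled chromosomes (>= 2).
#' @return Integer vector of counts.
#' @export
draw_sfs_count <- function(n, n_chromosomes) {
  stopifnot(n_chromosomes >= 2, n >= 0)
  if (n == 0) return(integer(0))
  kk <- seq_len(n_chromosomes - 1L)
  sample(kk, n, replace = TRUE, prob = 1 / kk)
}

#' Expected per-site diversity of the generator
#'
#' Outside sweeps the generator plants segregating sites at density
#' `s = pi_background * H_{n-1}` with `k ~ 1/k`. Since
#' `sum_k (1/k) * 2k(n-k)/(n(n-1)) = H_{n-1} * E[site_pi] = 1`, the expected
#' unbiased per-site heterozygosity is exactly `pi_background`; inside a
#' sweep it is `diversity_factor * pi_background`.
#'
#' @param params a [sweep_sim_params()].
#' @return Expected per-site theta outside sweeps.
#' @export
expected_pi <- function(params) {
  stopifnot(inherits(params, "sweep_sim_params"))
  params$pi_background
}

#' Expected per-site divergence of the generator
#'
#' `divergence_rate * (1 - 0.5 * het_fraction_of_divergence)`: homozygous
#' divergence sites contribute 1 and heterozygous ones 0.5.
#'
#' @param params a [sweep_sim_params()].
#' @return Expected per-site D.
#' @export
expected_divergence <- function(params) {
  stopifnot(inherits(params, "sweep_sim_params"))
  params$divergence_rate * (1 - 0.5 * params$het_fraction_of_divergence)
}

# [start, end) segments covering the chromosome with their diversity factor
diversity_segments <- function(params) {
  len <- params$chrom_length
  sw <- params$sweep_intervals
  if (is.null(sw) || !nrow(sw)) {
    return(data.frame(start = 0, end = len, factor = 1))
  }
  starts <- c(0, sw$end)
  ends <- c(sw$start, len)
  bg <- data.frame(start = starts, end = ends, factor = 1)
  bg <- bg[bg$start < bg$end, , drop = FALSE]
  seg <- rbind(bg, data.frame(start = sw$start, end = sw$end,
                              factor = sw$diversity_factor))
  seg <- seg[order(seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Simulate a cohort as a sparse site set
#'
#' The in-memory workhorse of the generator: draws every polymorphic,
#' divergent and artifact site explicitly and represents the remaining
#' positions as a clean homozygous-reference background (constant depth 20,
#' genotype quality 60) via the site set's callable interval, so
#' multi-megabase cohorts stay small and fast. Samples are
#' `focal1..focalN` plus the divergence contrast `div1`. Fully deterministic
#' for a fixed seed: same seed, identical output.
#'
#' Derived alleles at a polymorphic site are assigned to chromosomes
#' uniformly at random via a sequential hypergeometric split over the fixed
#' diploid pairing (chromosomes 2i-1, 2i belong to individual i).
#'
#' @param params a [sweep_sim_params()].
#' @return List with `sites` (a [site_set()]) and `truth` (sweep intervals,
#'   analytic expectations, parameter echo).
#' @export
simulate_sites <- function(params) {
  stopifnot(inherits(params, "sweep_sim_params"))
  set.seed(params$seed)
  nf <- params$n_focal_diploids
  nchr <- 2L * nf
  harm <- sum(1 / seq_len(nchr - 1L))
  s <- params$pi_background * harm
  if (s > 1) stop("pi_background too large for the 1/k spectrum density")
  len <- params$chrom_length

  seg <- diversity_segments(params)
  pos_poly <- integer(0)
  for (i in seq_len(nrow(seg))) {
    sl <- seg$end[i] - seg$start[i]
    pr <- min(1, s * seg$factor[i])
    ni <- stats::rbinom(1, sl, pr)
    if (ni > 0) pos_poly <- c(pos_poly, seg$start[i] + sample.int(sl, ni))
  }
  k <- draw_sfs_count(length(pos_poly), nchr)

  nd <- stats::rbinom(1, len, params$divergence_rate)
  pos_div <- if (nd > 0) sample.int(len, nd) else integer(0)
  het_div <- stats::runif(nd) < params$het_fraction_of_divergence

  art <- list()
  for (cls in names(params$artifact_rates)) {
    ra <- params$artifact_rates[[cls]]
    na <- if (ra > 0) stats::rbinom(1, len, ra) else 0L
    art[[cls]] <- if (na > 0) sample.int(len, na) else integer(0)
  }
  seen <- integer(0)  # one artifact class per position (first class wins)
  for (cls in names(art)) {
    art[[cls]] <- setdiff(art[[cls]], seen)
    seen <- c(seen, art[[cls]])
  }

  pos_all <- sort(unique(c(pos_poly, pos_div, seen)))
  m <- length(pos_all)
  samples <- c(paste0("focal", seq_len(nf)), "div1")
  ns <- length(samples)
  gt <- matrix(0L, m, ns, dimnames = list(NULL, samples))
  dp <- matrix(20L, m, ns, dimnames = list(NULL, samples))
  gq <- matrix(60L, m, ns, dimnames = list(NULL, samples))

  ip <- match(pos_poly, pos_all)
  if (length(ip)) {
    rem_k <- k
    rem_n <- nchr
    for (j in seq_len(nf)) {
      x <- as.integer(stats::rhyper(length(ip), 2L, rem_n - 2L, rem_k))
      gt[ip, j] <- x
      rem_k <- rem_k - x
      rem_n <- rem_n - 2L
    }
  }
  idv <- match(pos_div, pos_all)
  if (length(idv)) gt[idv, ns] <- ifelse(het_div, 1L, 2L)

  victim <- function(np) sample.int(ns, np, replace = TRUE)
  ia <- match(art$low_depth, pos_all)
  if (length(ia)) dp[cbind(ia, victim(length(ia)))] <-
      sample(0:2, length(ia), replace = TRUE)
  ia <- match(art$low_gq, pos_all)
  if (length(ia)) gq[cbind(ia, victim(length(ia)))] <- 5L
  ia <- match(art$missing, pos_all)
  if (length(ia)) gt[cbind(ia, victim(length(ia)))] <- NA_integer_
  ilq <- match(art$low_qual, pos_all)
  imu <- match(art$multi_allelic, pos_all)

  is_var <- rowSums(gt, na.rm = TRUE) > 0
  if (length(ilq)) {
    # QUAL only gates variant records: force these to carry a variant allele
    nonvar <- ilq[!is_var[ilq]]
    if (length(nonvar)) gt[nonvar, 1L] <- 1L
    is_var[ilq] <- TRUE
  }
  if (length(imu)) is_var[imu] <- TRUE
  n_alt <- as.integer(is_var)
  if (length(imu)) n_alt[imu] <- 2L
  qual <- ifelse(is_var, 200, NA_real_)
  if (length(ilq)) qual[ilq] <- 30

  bases <- c("A", "C", "G", "T")
  refb <- sample(bases, m, replace = TRUE)
  ri <- match(refb, bases)
  altb <- rep(".", m)
  altb[is_var] <- bases[(ri[is_var] %% 4L) + 1L]
  if (length(imu)) {
    altb[imu] <- paste(bases[(ri[imu] %% 4L) + 1L],
                       bases[((ri[imu] + 1L) %% 4L) + 1L], sep = ",")
  }

  ss <- site_set(chrom = rep(params$chrom, m), pos = pos_all,
                 ref = refb, alt = altb, qual = qual, n_alt = n_alt,
                 is_variant = is_var, gt = gt, dp = dp, gq = gq,
                 samples = samples,
                 chrom_lengths = stats::setNames(len, params$chrom),
                 callable = data.frame(chrom = params$chrom, start = 0,
                                       end = len, stringsAsFactors = FALSE),
                 default_dp = 20L, default_gq = 60L)
  truth <- list(
    sweep_bed = if (is.null(params$sweep_intervals)) {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 diversity_factor = numeric(0))
    } else {
      data.frame(chrom = params$chrom, params$sweep_intervals,
                 stringsAsFactors = FALSE)
    },
    expected = list(theta = expected_pi(params),
                    divergence = expected_divergence(params)),
    params = params)
  list(sites = ss, truth = truth)
}

#' Simulate the reference sequence
#'
#' Random sequence at `gc_background` GC, with the optional `gc_tract`
#' replaced by sequence at its `gc_level`. Seeded independently of the site
#' draws (from `seed + 1`) so sites and reference can be generated in either
#' order.
#'
#' @param params a [sweep_sim_params()].
#' @return A named `Biostrings::DNAStringSet` of length 1.
#' @export
simulate_reference <- function(params) {
  stopifnot(inherits(params, "sweep_sim_params"))
  set.seed(params$seed + 1L)
  bases <- c("A", "C", "G", "T")
  base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  x <- sample(bases, params$chrom_length, replace = TRUE,
              prob = base_probs(params$gc_background))
  if (!is.null(params$gc_tract)) {
    idx <- (params$gc_tract$start + 1L):params$gc_tract$end
    x[idx] <- sample(bases, length(idx), replace = TRUE,
                     prob = base_probs(params$gc_tract$gc_level))
  }
  out <- Biostrings::DNAStringSet(paste(x, collapse = ""))
  names(out) <- params$chrom
  out
}

#' Write a complete synthetic study to disk
#'
#' File-mode output: reference FASTA (indexed), an all-sites VCF 4.2 with one
#' record per position, the sweep truth intervals as BED, random gene
#' intervals as BED (for annotation tests), and a JSON echo of the
#' parameters. Because every position becomes a VCF record this mode is
#' capped at 5 Mb; larger studies use the sparse [simulate_sites()]
#' representation directly.
#'
#' @param params a [sweep_sim_params()] with `chrom_length <= 5e6`.
#' @param out_dir output directory (created if needed).
#' @return Named list of file paths (`reference`, `vcf`, `truth`, `genes`,
#'   `params`), invisibly also carrying the in-memory `sites` and `truth`.
#' @export
simulate_region <- function(params, out_dir) {
  stopifnot(inherits(params, "sweep_sim_params"))
  if (params$chrom_length > 5e6) {
    stop("simulate_region() writes one VCF record per position and is ",
         "capped at 5 Mb; use simulate_sites() for larger regions")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(params)
  sim <- simulate_sites(params)
  ss <- sim$sites
  len <- params$chrom_length
  ch <- params$chrom

  # re-anchor explicit records on the actual reference base
  refchars <- strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  pos <- ss$sites$pos
  ss$sites$ref <- refchars[pos]
  ri <- match(ss$sites$ref, bases)
  iv <- ss$sites$is_variant
  ss$sites$alt[iv] <- bases[(ri[iv] %% 4L) + 1L]
  multi <- ss$sites$n_alt > 1
  if (any(multi)) {
    ss$sites$alt[multi] <- paste(bases[(ri[multi] %% 4L) + 1L],
                                 bases[((ri[multi] + 1L) %% 4L) + 1L],
                                 sep = ",")
  }

  fa_path <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(ref, fa_path)
  Rsamtools::indexFa(fa_path)

  vcf_path <- file.path(out_dir, "cohort.vcf")
  ns <- length(ss$samples)
  gcode <- c("0/0", "0/1", "1/1")
  cell <- function(g, d, q) {
    gs <- ifelse(is.na(g), "./.", gcode[g + 1L])
    paste0(gs, ":", d, ":", q)
  }
  sample_cols <- matrix(sprintf("0/0:%d:%d", ss$default_dp, ss$default_gq),
                        len, ns)
  for (j in seq_len(ns)) {
    sample_cols[pos, j] <- cell(ss$gt[, j], ss$dp[, j], ss$gq[, j])
  }
  alt_col <- rep(".", len)
  alt_col[pos] <- ss$sites$alt
  qual_col <- rep(".", len)
  qual_col[pos] <- ifelse(is.na(ss$sites$qual), ".",
                          format(ss$sites$qual, trim = TRUE))
  body <- paste(ch, seq_len(len), ".", refchars, alt_col, qual_col, ".", ".",
                "GT:DP:GQ", sep = "\t")
  for (j in seq_len(ns)) body <- paste(body, sample_cols[, j], sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ch, len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
           "Description=\"Genotype quality\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ss$samples), collapse = "\t"))
  writeLines(c(header, body), vcf_path)

  truth_path <- file.path(out_dir, "truth.bed")
  tb <- sim$truth$sweep_bed
  writeLines(if (nrow(tb)) {
    paste(tb$chrom, format(tb$start, scientific = FALSE, trim = TRUE),
          format(tb$end, scientific = FALSE, trim = TRUE),
          tb$diversity_factor, sep = "\t")
  } else character(0), truth_path)

  genes_path <- file.path(out_dir, "genes.bed")
  set.seed(params$seed + 2L)
  n_genes <- max(3L, len %/% 50000L)
  gstart <- sort(sample.int(max(len - 20000L, 1L), n_genes))
  gend <- pmin(gstart + sample(2000:20000, n_genes, replace = TRUE), len)
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(gstart + 1L, gend),
                               name = sprintf("gene%04d", seq_len(n_genes)))
  rtracklayer::export(gr, genes_path, format = "BED")

  params_path <- file.path(out_dir, "params.json")
  jsonlite::write_json(unclass(params), params_path, auto_unbox = TRUE,
                       digits = NA, null = "null")

  out <- list(reference = fa_path, vcf = vcf_path, truth = truth_path,
              genes = genes_path, params = params_path)
  attr(out, "sites") <- ss
  attr(out, "truth") <- sim$truth
  out
}
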