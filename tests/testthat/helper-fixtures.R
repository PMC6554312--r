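# Shared fixtures and independent oracles for the suite.

# Build a small site_set from a genotype-code matrix (rows = sites).
toy_site_set <- function(pos, gt, dp = NULL, gq = NULL, qual = NULL,
                         n_alt = NULL, is_variant = NULL, chrom = "chr1",
                         chrom_length = max(pos, 1) + 10,
                         callable = NULL, default_dp = NA_integer_,
                         default_gq = NA_integer_) {
  m <- length(pos)
  stopifnot(nrow(gt) == m)
  if (is.null(colnames(gt))) {
    colnames(gt) <- paste0("s", seq_len(ncol(gt)))
  }
  if (is.null(dp)) dp <- matrix(20L, m, ncol(gt))
  if (is.null(gq)) gq <- matrix(60L, m, ncol(gt))
  iv <- if (is.null(is_variant)) rowSums(gt, na.rm = TRUE) > 0 else
    is_variant
  if (is.null(n_alt)) n_alt <- as.integer(iv)
  if (is.null(qual)) qual <- ifelse(iv, 200, NA_real_)
  site_set(rep(chrom, m), pos, rep("A", m), ifelse(iv, "C", "."), qual,
           n_alt, iv, gt, dp, gq, colnames(gt),
           stats::setNames(chrom_length, chrom), callable,
           default_dp, default_gq)
}

# Independent oracle: mean pairwise difference among n chromosomes carrying
# k derived alleles, by explicit double loop over chromosome pairs.
oracle_pairwise_pi <- function(k, n) {
  alleles <- c(rep(1, k), rep(0, n - k))
  tot <- 0
  npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + as.integer(alleles[i] != alleles[j])
      npairs <- npairs + 1
    }
  }
  tot / npairs
}

# Independent oracle: re-summation of the windowed ratio, site by site,
# without using the package's estimator functions.
oracle_scan_window <- function(gt, focal, div, L, hom_weight = 1) {
  n <- 2 * length(focal)
  theta_sum <- 0
  d_sum <- 0
  for (i in seq_len(nrow(gt))) {
    k <- sum(gt[i, focal])
    p <- k / n
    theta_sum <- theta_sum + 2 * p * (1 - p) * n / (n - 1)
    g <- gt[i, div]
    d_sum <- d_sum + if (g == 2) hom_weight else if (g == 1) 0.5 else 0
  }
  theta <- theta_sum / L
  D <- d_sum / L
  list(L = L, theta = theta, D = D,
       ratio = if (D > 0) theta / D else NA_real_)
}

# Brute-force half-open interval overlap between significant windows and
# genes, by checking all pairs.
oracle_candidate_genes <- function(windows, genes, alpha) {
  sig <- windows[!is.na(windows$empirical_p) & windows$empirical_p < alpha, ]
  hits <- character(0)
  for (g in seq_len(nrow(genes))) {
    for (w in seq_len(nrow(sig))) {
      if (genes$chrom[g] == sig$chrom[w] &&
          genes$start[g] < sig$end[w] && sig$start[w] < genes$end[g]) {
        hits <- c(hits, genes$gene_id[g])
        break
      }
    }
  }
  sort(unique(hits))
}
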