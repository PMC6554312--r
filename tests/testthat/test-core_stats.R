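test_that("site_pi evaluates the unbiased per-site heterozygosity", {
  expect_equal(site_pi(0, 8), 0)
  expect_equal(site_pi(4, 8), 2 * 0.25 * (8 / 7))
  expect_equal(site_pi(1, 8), 0.25)
  # vectorised
  expect_equal(site_pi(c(0, 1, 4), 8), c(0, 0.25, 4 / 7))
  expect_error(site_pi(1, 1), "at least 2")
  expect_error(site_pi(9, 8), "\\[0, n\\]")
  expect_error(site_pi(-1, 8), "\\[0, n\\]")
})

test_that("site_pi is frequency-fold symmetric and bounded", {
  for (n in 2:12) {
    k <- 0:n
    v <- site_pi(k, n)
    expect_equal(v, rev(v))
    expect_true(all(v >= 0 & v <= n / (2 * (n - 1)) + 1e-15))
  }
})

test_that("divergence contribution is 0 / 0.5 / 1 and sums like a count", {
  expect_equal(site_divergence_contrib(0L), 0)
  expect_equal(site_divergence_contrib(1L), 0.5)
  expect_equal(site_divergence_contrib(2L), 1)
  expect_equal(site_divergence_contrib(2L, hom_weight = 2), 2)
  expect_error(site_divergence_contrib(NA_integer_), "missing genotype")
  expect_error(site_divergence_contrib(3L), "0, 1 or 2")
  # summing a region equals hom-alt count + 0.5 * het count
  set.seed(7)
  g <- sample(0:2, 500, replace = TRUE)
  expect_equal(sum(site_divergence_contrib(g)),
               sum(g == 2) + 0.5 * sum(g == 1))
})

test_that("allele_frequency counts alternate alleles over 2N chromosomes", {
  expect_equal(allele_frequency(c(0L, 0L, 0L, 0L)), list(k = 0L, n = 8L))
  expect_equal(allele_frequency(c(1L, 1L, 2L, 0L)), list(k = 4L, n = 8L))
  expect_equal(allele_frequency(c(1L, 2L)), list(k = 3L, n = 4L))
  expect_error(allele_frequency(c(1L, NA)), "missing focal genotype")
  expect_error(allele_frequency(integer(0)), "no focal genotypes")
})

test_that("depth threshold is the nearest-rank percentile", {
  expect_equal(compute_depth_threshold(1:100, 0.95), 95)
  expect_equal(compute_depth_threshold(sample(1:100), 0.95), 95)
  expect_equal(compute_depth_threshold(rep(10, 37), 0.5), 10)
  expect_equal(compute_depth_threshold(5, 0.95), 5)
  expect_error(compute_depth_threshold(numeric(0)), "empty depth stream")
  expect_error(compute_depth_threshold(c(NA, NA)), "empty depth stream")
})

test_that("depth ceilings over an implicit background match the full set", {
  # explicit depths plus a constant default background: the mixture quantile
  # must equal the quantile of the materialised vector
  expl <- c(1, 4, 18, 20, 20, 25, 31, 40)
  for (nd in c(0, 5, 100, 10000)) {
    full <- c(expl, rep(20, nd))
    for (q in c(0.5, 0.9, 0.95, 0.99)) {
      expect_equal(
        hkascan:::depth_threshold_mixture(expl, nd, 20L, q),
        compute_depth_threshold(full, q),
        info = sprintf("nd=%d q=%g", nd, q))
    }
  }
})

test_that("gc_fraction excludes ambiguous bases from the denominator", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ANGC"), 2 / 3)
  expect_equal(gc_fraction("atgc"), 0.5)
  expect_true(is.na(gc_fraction("NNNN")))
  expect_equal(gc_fraction(Biostrings::DNAString("ACGTN")), 0.5)
})

test_that("filter stack enforces every rule at its exact boundary", {
  cfg <- filter_config()
  gt <- matrix(c(1L, 1L, 1L, 1L, 1L), 5, 1, dimnames = list(NULL, "s1"))
  mk <- function(...) toy_site_set(pos = 1:5, gt = gt, ...)

  # QUAL boundary on variant records
  ss <- mk(qual = c(49, 50, 200, 200, 200))
  st <- site_passes_filters(ss, cfg, ceilings = c(s1 = 100))
  expect_false(st$pass[1])
  expect_equal(st$reason[1], "site_quality")
  expect_true(st$pass[2])

  # monomorphic records are exempt from QUAL
  ss <- toy_site_set(pos = 1:2,
                     gt = matrix(0L, 2, 1, dimnames = list(NULL, "s1")),
                     qual = c(NA_real_, NA_real_))
  expect_true(all(site_passes_filters(ss, cfg,
                                      ceilings = c(s1 = 100))$pass))

  # depth floor: 2 fails, 3 passes; ceiling inclusive
  ss <- mk(dp = matrix(c(2L, 3L, 30L, 31L, 20L), 5, 1))
  st <- site_passes_filters(ss, cfg, ceilings = c(s1 = 30))
  expect_equal(st$pass, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(st$reason[c(1, 4)], c("depth", "depth"))

  # genotype quality boundary: 19 fails, 20 passes
  ss <- mk(gq = matrix(c(19L, 20L, 60L, 60L, 60L), 5, 1))
  st <- site_passes_filters(ss, cfg, ceilings = c(s1 = 100))
  expect_equal(st$pass[1:2], c(FALSE, TRUE))
  expect_equal(st$reason[1], "genotype_quality")

  # missing genotype is reported first
  gt2 <- gt
  gt2[3, 1] <- NA_integer_
  ss <- toy_site_set(pos = 1:5, gt = gt2,
                     dp = matrix(c(2L, 20L, 1L, 20L, 20L), 5, 1))
  st <- site_passes_filters(ss, cfg, ceilings = c(s1 = 100))
  expect_equal(st$reason[3], "missing_genotype")
  expect_equal(st$reason[1], "depth")

  # non-biallelic records are excluded entirely
  ss <- mk(n_alt = c(2L, 1L, 1L, 1L, 1L))
  st <- site_passes_filters(ss, cfg, ceilings = c(s1 = 100))
  expect_false(st$pass[1])
  expect_equal(st$reason[1], "biallelic")
  st <- site_passes_filters(ss, filter_config(require_biallelic = FALSE),
                            ceilings = c(s1 = 100))
  expect_true(st$pass[1])
})

test_that("a failing site contributes to neither L nor theta nor D", {
  gt <- matrix(c(1L, 1L, 0L, 0L,   # polymorphic, passes
                 1L, 1L, 0L, 2L,   # polymorphic + divergent, fails QUAL
                 0L, 0L, 0L, 2L),  # divergent, passes
               3, 4, byrow = TRUE,
               dimnames = list(NULL, c("f1", "f2", "f3", "div")))
  ss <- toy_site_set(pos = c(10L, 20L, 30L), gt = gt,
                     qual = c(200, 10, 200), chrom_length = 1000)
  ws <- scan_windows(ss, c("f1", "f2", "f3"), "div",
                     filter_config(min_callable_bp = 1), window_bp = 1000)
  expect_equal(ws$L, 2)
  expect_equal(ws$theta, site_pi(2, 6) / 2)
  expect_equal(ws$D, 1 / 2)
  tally <- attr(ws, "filter_tally")
  expect_equal(as.integer(tally["site_quality"]), 1L)
})
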