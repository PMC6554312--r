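test_that("window construction drops partial trailing windows", {
  w <- make_windows(c(chr1 = 1e6), 1e5, 1e5)
  expect_equal(nrow(w), 10)
  expect_equal(w$start, seq(0, 9e5, by = 1e5))
  expect_equal(w$end - w$start, rep(1e5, 10))

  # sliding windows: floor((250000 - 100000) / 10000) + 1
  w <- make_windows(c(chr1 = 250000), 1e5, 1e4)
  expect_equal(nrow(w), 16)
  expect_equal(w$start[16], 150000)

  expect_equal(nrow(make_windows(c(chr1 = 5e4), 1e5)), 0)
  expect_error(make_windows(c(chr1 = 1e6), 0), "positive")
  expect_error(make_windows(c(chr1 = 1e6), 1e5, 2e5), "not exceed")
  expect_error(make_windows(1e6), "named")
})

test_that("scan_window evaluates the windowed ratio", {
  # 5 callable sites: focal k = 4 and k = 2, one hom-alt and one het in the
  # divergence sample, one clean monomorphic site
  gt <- matrix(c(1L, 1L, 1L, 1L, 0L,
                 1L, 1L, 0L, 0L, 0L,
                 0L, 0L, 0L, 0L, 2L,
                 0L, 0L, 0L, 0L, 1L,
                 0L, 0L, 0L, 0L, 0L),
               5, 5, byrow = TRUE,
               dimnames = list(NULL, c("f1", "f2", "f3", "f4", "div")))
  st <- scan_window(gt, paste0("f", 1:4), "div", L = 5)
  expect_equal(st$theta, 0.2)
  expect_equal(st$D, 0.3)
  expect_equal(st$ratio, 2 / 3, tolerance = 1e-12)

  # all monomorphic: theta = D = 0, ratio undefined
  st <- scan_window(matrix(0L, 3, 5,
                           dimnames = list(NULL, colnames(gt))),
                    paste0("f", 1:4), "div", L = 10)
  expect_equal(st$theta, 0)
  expect_equal(st$D, 0)
  expect_true(is.na(st$ratio))

  expect_error(scan_window(gt, paste0("f", 1:4), "div", L = 0),
               "no callable sites")
  gt[1, 1] <- NA_integer_
  expect_error(scan_window(gt, paste0("f", 1:4), "div", L = 5),
               "missing genotypes")
})

test_that("empirical p-values are tie-sharing tail ranks over N", {
  p <- empirical_p(c(0.5, 0.1, 0.3, 0.3, 0.9))
  expect_equal(p, c(0.8, 0.2, 0.6, 0.6, 1.0))
  expect_equal(empirical_p(rep(2.5, 4)), rep(1, 4))
  expect_equal(empirical_p(c(1.0, 2.0)), c(0.5, 1.0))
  expect_error(empirical_p(numeric(0)), "no ratios")
  expect_error(empirical_p(c(1, NA)), "finite")
})

test_that("empirical p-values are monotone and control the tail count", {
  set.seed(42)
  for (rep in 1:20) {
    x <- round(stats::rexp(sample(5:200, 1)), sample(1:3, 1))
    p <- empirical_p(x)
    o <- order(x)
    expect_true(all(diff(p[o]) >= 0))
    for (alpha in c(0.01, 0.05, 0.1, 0.5)) {
      expect_lte(sum(p < alpha), ceiling(alpha * length(x)))
    }
    # smallest attainable p is 1/N, largest is exactly 1
    expect_gte(min(p), 1 / length(x))
    expect_equal(max(p), 1)
  }
})

test_that("information diagnostic reports Spearman rho and its table", {
  w <- data.frame(L = 1:10, ratio = (1:10) / 7)
  d <- info_diagnostic(w)
  expect_equal(d$rho, 1)
  expect_equal(nrow(d$table), 10)

  w$ratio <- rep(0.4, 10)
  expect_warning(d <- info_diagnostic(w), "degenerate")
  expect_equal(d$rho, 0)

  expect_error(info_diagnostic(data.frame(L = 1:2, ratio = c(1, 2))),
               "at least 3")

  # windows with undefined ratio are excluded
  w <- data.frame(L = 1:5, ratio = c(1, NA, 3, 2, NA))
  expect_equal(nrow(info_diagnostic(w)$table), 3)
})

test_that("scan bookkeeping: callable background, flags, discard rules", {
  # 2 windows of 1000 bp on a 2000 bp chromosome, full callable background
  gt <- matrix(c(1L, 1L, 0L, 0L, 0L,
                 0L, 0L, 0L, 0L, 2L,
                 1L, 0L, 0L, 0L, 0L,
                 NA, 0L, 0L, 0L, 0L),
               4, 5, byrow = TRUE,
               dimnames = list(NULL, c("f1", "f2", "f3", "f4", "div")))
  ss <- toy_site_set(pos = c(100L, 200L, 1100L, 1200L), gt = gt,
                     chrom_length = 2000,
                     callable = data.frame(chrom = "chr1", start = 0,
                                           end = 2000),
                     default_dp = 20L, default_gq = 60L)
  ws <- scan_windows(ss, paste0("f", 1:4), "div",
                     filter_config(min_callable_bp = 10), window_bp = 1000)
  # window 1: both explicit sites pass -> L = 1000
  # window 2: the missing-genotype site is dropped from L
  expect_equal(ws$L, c(1000, 999))
  expect_equal(ws$theta[1], site_pi(2, 8) / 1000)
  expect_equal(ws$D[1], 1 / 1000)
  expect_equal(ws$ratio[1], site_pi(2, 8), tolerance = 1e-12)
  # window 2 has no divergence: flagged, unranked, but retained
  expect_true(is.na(ws$ratio[2]))
  expect_match(ws$flags[2], "zero_divergence")
  expect_true(is.na(ws$empirical_p[2]))
  expect_equal(nrow(retained_windows(ws)), 2)

  # min_callable boundary: a window with L = 9999 out of 10000 is discarded
  gt1 <- matrix(c(NA, 0L, 0L, 0L, 0L), 1, 5,
                dimnames = list(NULL, c("f1", "f2", "f3", "f4", "div")))
  ss <- toy_site_set(pos = 5000L, gt = gt1, chrom_length = 10000,
                     callable = data.frame(chrom = "chr1", start = 0,
                                           end = 10000),
                     default_dp = 20L, default_gq = 60L)
  ws <- scan_windows(ss, paste0("f", 1:4), "div", filter_config(),
                     window_bp = 10000)
  expect_equal(ws$L, 9999)
  expect_match(ws$flags, "low_callable")
  expect_equal(nrow(retained_windows(ws)), 0)
})

test_that("retained window set is invariant to chromosome order", {
  mk <- function(order) {
    p1 <- sweep_sim_params(3e5, chrom = "chrA", seed = 11)
    p2 <- sweep_sim_params(4e5, chrom = "chrB", seed = 12)
    s1 <- simulate_sites(p1)$sites
    s2 <- simulate_sites(p2)$sites
    sets <- list(s1, s2)[order]
    merged <- site_set(
      chrom = c(sets[[1]]$sites$chrom, sets[[2]]$sites$chrom),
      pos = c(sets[[1]]$sites$pos, sets[[2]]$sites$pos),
      ref = c(sets[[1]]$sites$ref, sets[[2]]$sites$ref),
      alt = c(sets[[1]]$sites$alt, sets[[2]]$sites$alt),
      qual = c(sets[[1]]$sites$qual, sets[[2]]$sites$qual),
      n_alt = c(sets[[1]]$sites$n_alt, sets[[2]]$sites$n_alt),
      is_variant = c(sets[[1]]$sites$is_variant, sets[[2]]$sites$is_variant),
      gt = rbind(sets[[1]]$gt, sets[[2]]$gt),
      dp = rbind(sets[[1]]$dp, sets[[2]]$dp),
      gq = rbind(sets[[1]]$gq, sets[[2]]$gq),
      samples = sets[[1]]$samples,
      chrom_lengths = c(sets[[1]]$chrom_lengths, sets[[2]]$chrom_lengths),
      callable = rbind(sets[[1]]$callable, sets[[2]]$callable),
      default_dp = 20L, default_gq = 60L)
    scan_windows(merged, paste0("focal", 1:4), "div1", window_bp = 1e5)
  }
  a <- mk(1:2)
  b <- mk(2:1)
  key <- function(w) w[order(w$chrom, w$start), c("chrom", "start", "L",
                                                  "theta", "D", "ratio")]
  expect_equal(nrow(retained_windows(a)), nrow(retained_windows(b)))
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("window-level GC filter removes a high-GC tract", {
  params <- sweep_sim_params(2.2e6, gc_tract = list(start = 1e6, end = 1.1e6,
                                                    gc_level = 0.8),
                             gc_background = 0.4, seed = 31)
  sim <- simulate_sites(params)
  ref <- simulate_reference(params)
  ws <- scan_windows(sim$sites, paste0("focal", 1:4), "div1",
                     window_bp = 1e5, reference = ref)
  flagged <- ws[grepl("high_gc", ws$flags), ]
  expect_equal(flagged$start, 1e6)
  expect_true(is.na(flagged$empirical_p))
  expect_false(any(retained_windows(ws)$start == 1e6))
  expect_false(is.na(attr(ws, "gc_cutoff")))
})
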