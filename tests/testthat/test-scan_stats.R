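# Window tiling, F_ST, H_P, Z-transform and outlier calling.

test_that("window tiling follows the 100-kb/50-kb scheme with truncation", {
  w <- make_windows(c(`1` = 250000))
  expect_equal(nrow(w), 5)
  expect_equal(w$start, c(0, 50000, 100000, 150000, 200000))
  expect_equal(w$end, c(100000, 150000, 200000, 250000, 250000))

  w2 <- make_windows(c(`1` = 100000))
  expect_equal(w2$start, c(0, 50000))
  expect_equal(w2$end, c(100000, 100000))

  w3 <- make_windows(c(`1` = 40000))
  expect_equal(nrow(w3), 1)
  expect_equal(c(w3$start, w3$end), c(0, 40000))

  expect_error(make_windows(c(`1` = 0)), "positive")
  expect_error(make_windows(c(`1` = 1000), step = 0), "positive")
  expect_error(make_windows(c(`1` = 1000), window_size = 10, step = 20),
               "must not exceed")
  expect_error(make_windows(1000), "named")
})

test_that("per-SNP F_ST matches identities and hand-computed values", {
  expect_equal(per_snp_fst(0.5, 0.5)$fst, 0)
  expect_equal(per_snp_fst(1, 0)$fst, 1)          # fixed difference
  r <- per_snp_fst(0.8, 0.2)
  expect_equal(r$s2, 0.18)
  expect_equal(r$pbar, 0.5)
  expect_equal(r$fst, 0.18 / (0.25 + 0.09), tolerance = 1e-12)
  # monomorphic in both populations: denominator 0, unevaluable
  expect_true(is.na(per_snp_fst(0, 0)$fst))
  expect_true(is.na(per_snp_fst(1, 1)$fst))
  expect_error(per_snp_fst(1.2, 0.5), "\\[0, 1\\]")
  expect_error(per_snp_fst(c(0.1, 0.2), 0.5), "same length")
})

test_that("per-SNP F_ST agrees with a brute-force oracle on random pairs", {
  # independent evaluation of s^2/(pbar(1-pbar) + s^2/r), one pair at a time
  oracle <- function(p1, p2, r = 2) {
    ps <- c(p1, p2)
    pbar <- mean(ps)
    s2 <- sum((ps - pbar)^2) / (r - 1)
    den <- pbar * (1 - pbar) + s2 / r
    if (den == 0) NA_real_ else s2 / den
  }
  set.seed(7)
  p1 <- runif(1000)
  p2 <- runif(1000)
  got <- per_snp_fst(p1, p2)$fst
  want <- mapply(oracle, p1, p2)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("F_ST is symmetric, allele-label invariant and monotone in divergence", {
  set.seed(11)
  p1 <- runif(200)
  p2 <- runif(200)
  expect_equal(per_snp_fst(p1, p2)$fst, per_snp_fst(p2, p1)$fst)
  expect_equal(per_snp_fst(p1, p2)$fst, per_snp_fst(1 - p1, 1 - p2)$fst)
  # fixed pbar = 0.5, increasing |p1 - p2|
  d <- seq(0, 0.5, by = 0.01)
  f <- per_snp_fst(0.5 + d, 0.5 - d)$fst
  expect_true(all(diff(f) >= 0))
})

test_that("window F_ST averages evaluable SNPs and honours min_snps", {
  w <- make_windows(c(`1` = 150000))   # [0,100k), [50k,150k), [100k,150k)
  sites <- data.frame(chrom = "1", pos = c(10000, 20000), fst = c(0, 1))
  wf <- window_fst(sites, w, min_snps = 1)
  expect_equal(wf$fst_mean[1], 0.5)
  expect_true(is.na(wf$fst_mean[2]))      # no SNPs in [50k, 150k)
  expect_equal(wf$n_snps, c(2, 0, 0))

  # a SNP at 60 kb contributes to both [0,100k) and [50k,150k)
  s2 <- data.frame(chrom = "1", pos = 60000, fst = 0.3)
  wf2 <- window_fst(s2, w, min_snps = 1)
  expect_equal(wf2$fst_mean, c(0.3, 0.3, NA))

  # below min_snps the window is unevaluable
  wf3 <- window_fst(sites, w, min_snps = 10)
  expect_true(all(is.na(wf3$fst_mean)))

  # NA per-SNP values (monomorphic in both pops) are excluded from the mean
  s3 <- data.frame(chrom = "1", pos = c(1000, 2000, 3000), fst = c(0.2, NA, 0.4))
  wf4 <- window_fst(s3, w, min_snps = 2)
  expect_equal(wf4$fst_mean[1], 0.3)
  expect_equal(wf4$fst_n[1], 2)
  expect_equal(wf4$n_snps[1], 3)
})

test_that("window H_P matches the pooled-count closed form and its bounds", {
  w <- make_windows(c(`1` = 100000))[1, ]
  counts <- function(maj, min) {
    data.frame(chrom = "1", pos = seq_along(maj) * 100, nMaj = maj, nMin = min,
               typed = TRUE)
  }
  # sums 30 and 10 -> 2*300/1600
  expect_equal(window_hp(counts(c(20, 10), c(4, 6)), w, min_snps = 1)$hp, 0.375)
  # equal sums -> the maximum 0.5
  expect_equal(window_hp(counts(c(10, 10), c(10, 10)), w, min_snps = 1)$hp, 0.5)
  # fixation -> 0
  expect_equal(window_hp(counts(c(12, 8), c(0, 0)), w, min_snps = 1)$hp, 0)
  # zero typed sites -> unevaluable
  ct <- counts(10, 10)
  ct$typed <- FALSE
  expect_true(is.na(window_hp(ct, w, min_snps = 1)$hp))
  # mixed window including a tied site matches the closed form on the sums
  expect_equal(window_hp(counts(c(10, 7), c(10, 3)), w, min_snps = 1)$hp,
               2 * 17 * 13 / (17 + 13)^2)
})

test_that("H_P stays within [0, 0.5] on random windowed counts", {
  set.seed(3)
  w <- make_windows(c(`1` = 1000000))
  counts <- data.frame(chrom = "1", pos = sort(sample.int(1e6, 500)),
                       nMaj = sample(5:40, 500, replace = TRUE))
  counts$nMin <- vapply(counts$nMaj, function(m) sample.int(m, 1), 1L)
  counts$typed <- TRUE
  hp <- window_hp(counts, w, min_snps = 1)$hp
  hp <- hp[!is.na(hp)]
  expect_true(all(hp >= 0 & hp <= 0.5))
})

test_that("Z-transform centres, scales and rejects degenerate input", {
  z <- z_transform(c(0, 2))
  expect_equal(z, c(-1, 1) / sqrt(2), tolerance = 1e-12)   # sample sd
  set.seed(5)
  x <- rnorm(500, mean = 3, sd = 2)
  zz <- z_transform(x)
  expect_lt(abs(mean(zz)), 1e-12)
  expect_equal(sd(zz), 1, tolerance = 1e-9)
  # population convention
  zp <- z_transform(c(0, 2), sigma = "population")
  expect_equal(zp, c(-1, 1), tolerance = 1e-12)
  # NAs (unevaluable windows) are preserved and excluded from mu/sigma
  zna <- z_transform(c(0, NA, 2))
  expect_true(is.na(zna[2]))
  expect_equal(zna[c(1, 3)], z)
  expect_error(z_transform(rep(1, 5)), "degenerate")
  expect_error(z_transform(1), "at least 2")
})

make_ws <- function(z) {
  n <- length(z)
  data.frame(chrom = "1", start = (seq_len(n) - 1) * 50000,
             end = (seq_len(n) - 1) * 50000 + 100000, index = seq_len(n),
             n_snps = 50, fst_n = 50, fst_mean = z, zfst = z)
}

test_that("top-fraction ZF_ST outlier calling uses the ceiling rule", {
  set.seed(9)
  ws <- make_ws(rnorm(200))
  out <- call_fst_outliers(ws, fraction = 0.01)
  expect_equal(nrow(out$windows), 2)                      # ceil(2.0)
  expect_equal(sort(out$windows$z), sort(ws$zfst)[199:200])

  out50 <- call_fst_outliers(make_ws(rnorm(50)), fraction = 0.01)
  expect_equal(nrow(out50$windows), 1)                    # ceil(0.5)

  all_out <- call_fst_outliers(ws, fraction = 1)
  expect_equal(nrow(all_out$windows), 200)

  # deterministic positional tie-break: exactly k flagged, earliest first
  tied <- make_ws(c(5, 5, 5, rep(0, 197)))
  t1 <- call_fst_outliers(tied, fraction = 0.01)
  expect_equal(nrow(t1$windows), 2)
  expect_equal(t1$windows$start, c(0, 50000))
  expect_error(call_fst_outliers(make_ws(NA_real_)), "no evaluable")
})

test_that("ZH_P threshold calling respects the boundary convention", {
  ws <- make_ws(rep(0, 10))
  ws$hp_n_P1 <- 50
  ws$hp_P1 <- 0.3
  ws$zhp_P1 <- c(-4.0, -3.99, -5, 0, 1, -2, 0, 0, 0, -4.5)
  out <- call_hp_outliers(ws, "P1")
  expect_equal(sort(out$windows$z), c(-5, -4.5, -4))      # -4.0 included (<=)
  expect_false(-3.99 %in% out$windows$z)
  strict <- call_hp_outliers(ws, "P1", inclusive = FALSE)
  expect_equal(sort(strict$windows$z), c(-5, -4.5))
  none <- call_hp_outliers(ws, "P1", threshold = -10)
  expect_equal(nrow(none$windows), 0)                     # empty set is legal
  expect_error(call_hp_outliers(ws, "P9"), "unknown population")
})

test_that("window_stats assembles the full per-window record", {
  set.seed(21)
  n <- 40
  samples <- paste0("S", 1:8)
  sm_pops <- rep(c("P1", "P2"), each = 4)
  rows <- lapply(seq_len(n), function(i) {
    dos <- c(rbinom(4, 2, 0.5), rbinom(4, 2, 0.2))
    c("1", 5000 * i, "A", "T",
      paste0(c("0/0", "0/1", "1/1")[dos + 1], ":12"))
  })
  vt <- read_vcf(write_test_vcf(rows, samples, contigs = c(`1` = 200000)),
                 test_sample_map(samples, sm_pops))
  ws <- window_stats(vt, c("P1", "P2"), min_snps = 5)
  expect_equal(nrow(ws), 4)                 # 200 kb -> 4 windows
  expect_true(all(c("n_snps", "fst_mean", "zfst", "hp_P1", "zhp_P1",
                    "hp_P2", "zhp_P2") %in% names(ws)))
  ev <- !is.na(ws$zfst)
  expect_lt(abs(mean(ws$zfst[ev])), 1e-9)
  expect_equal(sd(ws$zfst[ev]), 1, tolerance = 1e-9)
  expect_true(all(ws$hp_P1[!is.na(ws$hp_P1)] <= 0.5))
  expect_error(window_stats(vt, c("P1", "P2", "P2")), "exactly 2")
  expect_error(window_stats(vt, c("P1", "P9")), "unknown")
})
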