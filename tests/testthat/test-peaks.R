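# Peak overlap, correlation, metaprofiles, stratified comparison,
# knockdown dependency and the fallback caller.

test_that("peak overlap uses shared-base semantics with half-open boundaries", {
  # BED [0,100) vs [50,150): one shared stretch
  a <- GRanges("chr1", IRanges(1, 100))
  b <- GRanges("chr1", IRanges(51, 150))
  expect_equal(overlap_peaks(a, b)$fraction_a, 1)
  # BED [0,100) vs [100,200): touching, no shared base
  b2 <- GRanges("chr1", IRanges(101, 200))
  expect_equal(overlap_peaks(a, b2)$fraction_a, 0)
  # min_overlap_bp raises the bar
  expect_equal(overlap_peaks(a, b, min_overlap_bp = 50)$fraction_a, 1)
  expect_equal(overlap_peaks(a, b, min_overlap_bp = 51)$fraction_a, 0)
})

test_that("overlap counts equal the all-pairs scan and conserve the Venn", {
  for (seed in 1:4) {
    set.seed(seed)
    a <- random_peaks(sample(100:500, 1), chroms = c("chr2L", "chr2R"),
                      named = FALSE)
    b <- random_peaks(sample(100:500, 1), chroms = c("chr2L", "chr2R"),
                      named = FALSE)
    mb <- sample(c(1, 25), 1)
    ov <- overlap_peaks(a, b, min_overlap_bp = mb)
    expect_equal(ov$a_overlapping, sum(brute_overlapping(a, b, mb)))
    expect_equal(ov$b_overlapping, sum(brute_overlapping(b, a, mb)))
    expect_equal(ov$a_only + ov$a_overlapping, length(a))
    expect_equal(ov$b_only + ov$b_overlapping, length(b))
  }
})

test_that("intensity correlation matches the covariance formula and is
           affine-invariant", {
  set.seed(5)
  x <- rlnorm(200, 3, 1); y <- x * exp(rnorm(200, 0, 0.5))
  r <- correlate_intensities(x, y)
  tx <- log2(1 + x); ty <- log2(1 + y)
  manual <- mean((tx - mean(tx)) * (ty - mean(ty))) /
    (sqrt(mean((tx - mean(tx))^2)) * sqrt(mean((ty - mean(ty))^2)))
  expect_equal(r$r, manual, tolerance = 1e-12)
  expect_equal(r$n, 200L)
  # identity and sign-flip limits under the identity transform
  id <- function(d) d
  expect_equal(correlate_intensities(x, x, id)$r, 1)
  expect_equal(correlate_intensities(x, -x + 10, id)$r, -1)
  # affine maps with positive slope leave r unchanged
  expect_equal(correlate_intensities(2.5 * x + 7, y, id)$r,
               correlate_intensities(x, y, id)$r)
  expect_error(correlate_intensities(rep(1, 10), 1:10), "variance")
  expect_error(correlate_intensities(1:2, 1:2), "at least 3")
})

test_that("metaprofile of a constant field is flat at the field value", {
  r <- GRanges("chrT", IRanges(rep(1, 50), 2e4),
               strand = rep("+", 50))  # uniform blanket coverage
  tr <- build_coverage(r, 2e4, 50, 1e6, c(chrT = 2e4), extend = FALSE)
  pk <- GRanges("chrT", IRanges(c(5001, 9001, 13001), width = 400))
  mp <- metaprofile(pk, tr, window = 2000)
  expect_equal(ncol(mp$matrix), 80L)
  expect_true(all(abs(mp$mean_profile - mp$mean_profile[1]) < 1e-9))
  # single peak: mean profile equals that row
  mp1 <- metaprofile(pk[1], tr, window = 2000)
  expect_equal(mp1$mean_profile, mp1$matrix[1, ])
})

test_that("metaprofile recovers a planted signal mound at offset zero", {
  set.seed(9)
  centers <- seq(20000, 180000, by = 20000)
  # Gaussian fragment-center placement around each anchor, sd 300 bp
  n_per <- 400
  mid <- rep(centers, each = n_per) + round(rnorm(n_per * length(centers),
                                                  0, 300))
  fr <- GRanges("chrT", IRanges(mid - 125, width = 250), strand = "+")
  tr <- build_coverage(fr, 250, 50, 1e7, c(chrT = 2e5), extend = FALSE)
  pk <- GRanges("chrT", IRanges(centers - 200, centers + 200))
  mp <- metaprofile(pk, tr, window = 2000)
  peak_bin <- which.max(mp$mean_profile)
  expect_true(abs(mp$offsets[peak_bin]) <= 100)
  # amplitude at the anchor within 10% of the analytic mound height:
  # coverage at the center = n_per * P(|fragment center| <= 125)
  lib <- length(fr)
  expected_max <- n_per * (pnorm(125, 0, 300) - pnorm(-125, 0, 300)) *
    1e7 / lib
  got <- max(mp$mean_profile)
  expect_lt(abs(got - expected_max) / expected_max, 0.1)
})

test_that("metaprofile excludes chromosome-truncated peaks from column means", {
  r <- GRanges("chrT", IRanges(rep(1, 20), 1e4), strand = rep("+", 20))
  tr <- build_coverage(r, 1e4, 50, 1e6, c(chrT = 1e4), extend = FALSE)
  pk <- GRanges("chrT", IRanges(c(101, 5001), width = 100))  # first truncated
  mp <- metaprofile(pk, tr, window = 2000)
  expect_true(anyNA(mp$matrix[1, ]))
  expect_false(anyNA(mp$mean_profile))
  expect_error(metaprofile(GRanges("chrZ", IRanges(1, 10)), tr, 2000),
               "chromosome")
})

test_that("cofactor stratification partitions peaks and balances strata", {
  # six distinct peaks: one per (stratum, group) cell
  resp <- c(1, 2, 3, 4, 5, 6)
  mrg <- c(10, 1, 12, 2, 14, 3)
  ash <- c(1, 2, 3, 4, 5, 6)
  s <- stratify_by_cofactor(resp, mrg, ash, n_ash1_strata = 3)
  expect_equal(sort(s$summary$n), rep(1L, 6))
  expect_equal(sum(s$summary$n), 6L)
  expect_error(stratify_by_cofactor(resp, rep(2, 6), ash), "degenerate")
  expect_error(stratify_by_cofactor(resp[1:4], mrg[1:4], ash[1:4],
                                    n_ash1_strata = 3), "at least")
})

test_that("stratified medians recover a multiplicative cofactor effect", {
  set.seed(13)
  n <- 600
  za <- rnorm(n); zm <- rnorm(n)
  ash <- 2^za; mrg <- 2^zm
  resp <- 2^(0.5 * za + 0.6 * zm + rnorm(n, 0, 0.2))
  s <- stratify_by_cofactor(resp, mrg, ash, n_ash1_strata = 3)
  sm <- s$summary
  for (k in 1:3) {
    expect_gt(sm$median[sm$stratum == k & sm$group == "high"],
              sm$median[sm$stratum == k & sm$group == "low"])
  }
})

test_that("dependency analysis is exact on proportional knockdowns", {
  set.seed(17)
  wt <- rlnorm(500, 5, 1)
  d <- dependency_analysis(wt, wt, n_strata = 5, eps = 0)
  expect_equal(d$retained$retained, rep(1, 5))
  d3 <- dependency_analysis(wt, 0.3 * wt, n_strata = 5, eps = 0)
  expect_equal(d3$retained$retained, rep(0.3, 5))
  # equivariance under joint rescaling of both tracks (default eps
  # scales with the wild-type median)
  da <- dependency_analysis(wt, 0.3 * wt, n_strata = 5)
  db <- dependency_analysis(10 * wt, 3 * wt, n_strata = 5)
  expect_equal(da$retained$retained, db$retained$retained,
               tolerance = 1e-9)
  expect_error(dependency_analysis(rep(0, 10), rep(0, 10)), "zero")
})

test_that("dependency analysis recovers a planted rising stratum profile", {
  planted <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  for (seed in 1:5) {
    set.seed(seed)
    wt <- rlnorm(500, 5, 1)
    stratum <- ceiling(rank(wt, ties.method = "first") / 100)
    kd <- wt * planted[stratum] * exp(rnorm(500, 0, 0.1))
    d <- dependency_analysis(wt, kd, n_strata = 5)
    expect_true(all(abs(d$retained$retained - planted) < 0.1))
    expect_true(d$monotone_increasing)
  }
})

test_that("fallback caller finds rectangular blocks and nothing on flat tracks", {
  flat <- structure(list(bins = list(chrT = rep(1, 200)), bin_size = 50L,
                         depth_scale = 1e6, library_size = 100L,
                         fragment_size = 250L,
                         chrom_lengths = c(chrT = 1e4)),
                    class = "CoverageTrack")
  expect_warning(pk <- call_peaks_simple(flat), "flat")
  expect_equal(length(pk), 0L)
  v <- rep(0, 400); v[101:110] <- 50   # one 500 bp block
  tr <- structure(list(bins = list(chrT = v), bin_size = 50L,
                       depth_scale = 1e6, library_size = 100L,
                       fragment_size = 250L, chrom_lengths = c(chrT = 2e4)),
                  class = "CoverageTrack")
  pk <- call_peaks_simple(tr, threshold_sd = 4, min_width = 200)
  expect_equal(length(pk), 1L)
  expect_equal(start(pk), 5001L)
  expect_equal(end(pk), 5500L)
  expect_equal(pk$score, 50)
})

test_that("fallback caller recovers high signal-to-noise truth peaks", {
  set.seed(23)
  chrom_len <- 5e5
  truth_centers <- seq(25000, 475000, by = 25000)
  sig <- unlist(lapply(truth_centers, function(cc)
    sample((cc - 300):(cc + 300), 300, replace = TRUE)))
  bg <- sample.int(chrom_len - 300, 3000, replace = TRUE)
  r <- GRanges("chrT", IRanges(c(sig, bg), width = 36),
               strand = sample(c("+", "-"), length(sig) + length(bg),
                               replace = TRUE))
  tr <- build_coverage(r, 250, 50, 1e6, c(chrT = chrom_len))
  pk <- call_peaks_simple(tr)
  truth <- GRanges("chrT", IRanges(truth_centers - 400,
                                   truth_centers + 400))
  recall <- mean(brute_overlapping(truth, pk))
  precision <- mean(brute_overlapping(pk, truth))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.9)
})

test_that("signal matrix cells equal per-peak quantification and sort stably", {
  set.seed(29)
  pk <- random_peaks(20, chrom_len = 5e4, chroms = "chrT")
  s1 <- random_reads(400, chrom_len = 5e4)
  s2 <- random_reads(300, chrom_len = 5e4)
  m <- signal_matrix(pk, list(WT = s1, KD = s2))
  expect_equal(dim(m), c(20L, 2L))
  expect_equal(unname(m[, "WT"]), quantify_regions(s1, pk)$density)
  expect_equal(unname(m[, "KD"]), quantify_regions(s2, pk)$density)
  # permuting peak order then sorting yields the same sorted matrix
  perm <- sample(20)
  m2 <- signal_matrix(pk[perm], list(WT = s1, KD = s2))
  expect_equal(sort_signal_matrix(m2, "WT")[, "WT"],
               sort_signal_matrix(m, "WT")[, "WT"])
  expect_error(signal_matrix(pk, list(WT = GRanges())), "empty|shared")
})
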