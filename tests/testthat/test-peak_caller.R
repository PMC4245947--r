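test_that("poisson_sf matches closed forms and brute-force summation", {
  expect_equal(poisson_sf(0, 5), 1.0)
  expect_equal(poisson_sf(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poisson_sf(20, 2), brute_poisson_sf(20, 2),
               tolerance = 1e-12)
  expect_error(poisson_sf(3, 0), "lam")
  for (lam in c(0.1, 1, 5, 20, 100)) {
    counts <- c(0:5, 10, 50, 120, 200)
    dev <- abs(poisson_sf(counts, lam) -
                 vapply(counts, brute_poisson_sf, 0, lam = lam))
    expect_lt(max(dev), 1e-10)
  }
})

test_that("shift_tags moves strands toward the midpoint and clamps", {
  g <- tiny_genome()
  ts <- make_tags(c(100, 100, 10), c(TRUE, FALSE, FALSE), g)
  sh <- shift_tags(ts, 75)
  expect_equal(sh$chr1, c(0, 25, 175))  # clamp; - moves up; + moves down
  expect_equal(attr(sh, "total"), 3)
  # count conserved and sorted under heavy clamping
  ts2 <- make_tags(c(0, 1, 99999), c(FALSE, FALSE, TRUE), g)
  sh2 <- shift_tags(ts2, 100)
  expect_equal(length(sh2$chr1), 3)
  expect_false(is.unsorted(sh2$chr1))
  expect_true(all(sh2$chr1 >= 0 & sh2$chr1 < 1e5))
})

test_that("candidate_regions matches a brute-force window scan", {
  set.seed(42)
  # two clusters 10 kb apart plus scattered noise
  pos <- sort(c(rnorm(50, 20000, 40), rnorm(30, 30000, 40),
                runif(100, 0, 1e5)))
  for (min_tags in c(3, 5, 10)) {
    got <- candidate_regions(pos, 1e5, 150, min_tags)
    want <- brute_candidates(pos, 1e5, 150, min_tags)
    expect_equal(got, want)
  }
  got <- candidate_regions(pos, 1e5, 150, 5)
  expect_gte(nrow(got), 2)  # both clusters found as disjoint regions
})

test_that("candidate_regions handles degenerate inputs", {
  expect_equal(nrow(candidate_regions(numeric(), 1e5, 150, 5)), 0)
  # 50 tags at one position -> one region containing it with count 50
  got <- candidate_regions(rep(1000, 50), 1e5, 150, 5)
  expect_equal(nrow(got), 1)
  expect_true(got$start <= 1000 && got$end > 1000)
  expect_equal(got$tag_count, 50)
  # sparse uniform tags below threshold -> nothing
  expect_equal(nrow(candidate_regions(seq(0, 1e5, by = 1e4), 1e5, 150, 5)),
               0)
})

test_that("lambda_local reproduces hand-computed window estimates", {
  g <- tiny_genome(len = 3e6)
  # background: 10000 tags spread uniformly -> lambda_BG for a 300 bp
  # region = 10000 * 300 / 3e6 = 1.0
  bg <- make_tags(seq(0, 3e6 - 1, length.out = 10000), genome = g)
  region <- list(chrom = "chr1", start = 1500000, end = 1500300)
  lam <- lambda_local(region, bg, levels = numeric(), depth_ratio = 1,
                      genome = g, shift = 0)
  expect_equal(lam, 1.0, tolerance = 1e-6)
  # 100 tags packed into the 1 kb window around a 200 bp region:
  # lambda_1k = 100 * 200 / 1000 = 20
  g2 <- tiny_genome(len = 1e6)
  bg2 <- make_tags(seq(49700, 50299, length.out = 100), genome = g2)
  region2 <- list(chrom = "chr1", start = 49900, end = 50100)
  lam2 <- lambda_local(region2, bg2, levels = 1000, depth_ratio = 1,
                       genome = g2, shift = 0)
  expect_equal(lam2, 20, tolerance = 1e-9)
  # doubling depth_ratio doubles lambda (linearity)
  expect_equal(lambda_local(region2, bg2, levels = 1000,
                            depth_ratio = 2, genome = g2, shift = 0),
               2 * lam2, tolerance = 1e-9)
})

test_that("lambda_local is monotone in background and floored at BG", {
  g <- tiny_genome(len = 1e6)
  region <- list(chrom = "chr1", start = 49900, end = 50100)
  base_pos <- seq(0, 1e6 - 1, length.out = 1000)
  lam0 <- lambda_local(region, make_tags(base_pos, genome = g),
                       levels = c(1000, 5000, 10000), depth_ratio = 1,
                       genome = g, shift = 0)
  for (extra in c(10, 50, 200)) {
    lam1 <- lambda_local(region,
                         make_tags(c(base_pos, rep(50000, extra)),
                                   genome = g),
                         levels = c(1000, 5000, 10000), depth_ratio = 1,
                         genome = g, shift = 0)
    expect_gte(lam1, lam0)
    # never below the genome-wide rate of its own library
    expect_gte(lam1, (1000 + extra) * 200 / 1e6 - 1e-12)
    lam0 <- lam1
  }
})

test_that("a single bimodal site yields one peak with an accurate summit", {
  g <- tiny_genome(len = 1e6)
  cl <- site_cluster(50000, n = 200, jitter_sd = 20, seed = 11)
  ts <- make_tags(cl$pos, cl$is_plus, g)
  pk <- call_peaks(ts, params = caller_params())
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$summit - 50000), 25)
  expect_equal(pk$norm_tag_count, pk$tag_count * 1e7 / ts$total_tags)
  expect_lt(pk$pvalue, 1e-4)
})

test_that("pure background produces false peaks at roughly the tested rate", {
  set.seed(99)
  g <- tiny_genome(len = 2e6)
  n <- 20000  # 0.01 tags/bp
  ts <- make_tags(floor(runif(n, 0, 2e6)), runif(n) < 0.5, g)
  pk <- call_peaks(ts, params = caller_params())
  # each ~10 bp step is a candidate test; 3-sigma binomial bound on
  # threshold * n_windows false discoveries
  n_windows <- 2e6 / 10
  bound <- 1e-4 * n_windows + 3 * sqrt(1e-4 * n_windows)
  expect_lte(nrow(pk), bound)
})

test_that("an identical control suppresses calls relative to no control", {
  # broad, moderate clusters: the 1 kb self-window sees most of the
  # cluster, so the with-control lambda rises above the call threshold
  # while the no-control 5/10 kb windows dilute it away
  g <- tiny_genome(len = 1e6)
  set.seed(7)
  pos <- floor(runif(3000, 0, 1e6))
  plus <- runif(3000) < 0.5
  for (s in seq(50000, 950000, by = 50000)) {
    cl <- site_cluster(s, 60, jitter_sd = 120, seed = s)
    pos <- c(pos, cl$pos)
    plus <- c(plus, cl$is_plus)
  }
  ts <- make_tags(pos, plus, g)
  no_ctrl <- call_peaks(ts)
  self_ctrl <- call_peaks(ts, control = ts)
  expect_gt(nrow(no_ctrl), 0)
  expect_lt(nrow(self_ctrl), nrow(no_ctrl))
  # the self-controlled call is a subset: every surviving interval is
  # also present in the no-control call
  if (nrow(self_ctrl))
    expect_true(all(self_ctrl$start %in% no_ctrl$start))
})

test_that("calling is deterministic and peaks never overlap", {
  sim <- simulate_pair(sim_config(genome = genome_spec("chrS", 5e5),
                                  n_true_peaks = 10,
                                  n_shared_artifacts = 10,
                                  n_hyper_loci = 2, seed = 3))
  p1 <- tempfile(); p2 <- tempfile()
  write_peaks(call_peaks(sim$wt, control = sim$ko), p1)
  write_peaks(call_peaks(sim$wt, control = sim$ko), p2)
  expect_identical(readLines(p1), readLines(p2))
  pk <- call_peaks(sim$wt, control = sim$ko)
  by_chrom <- split(pk, pk$chrom)
  for (b in by_chrom)
    if (nrow(b) > 1)
      expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
})

test_that("empty treatment errors; empty control falls back with warning", {
  g <- tiny_genome()
  empty <- make_tags(numeric(), logical(), g)
  cl <- site_cluster(50000, 100)
  ts <- make_tags(cl$pos, cl$is_plus, g)
  expect_error(call_peaks(empty), "empty")
  expect_warning(pk <- call_peaks(ts, control = empty), "empty")
  expect_gt(nrow(pk), 0)
})
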