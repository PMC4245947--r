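test_that("a fixed seed reproduces byte-identical BED output", {
  cfg <- sim_config(genome = genome_spec("chrS", 5e5), n_true_peaks = 10,
                    n_shared_artifacts = 10, n_hyper_loci = 2, seed = 13)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim(simulate_pair(cfg), d1)
  write_sim(simulate_pair(cfg), d2)
  for (f in c("wt.bed", "ko.bed", "truth.tsv", "sizes.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("simulate_pair does not disturb the caller's RNG stream", {
  set.seed(101)
  before <- runif(1)
  set.seed(101)
  invisible(simulate_pair(sim_config(genome = genome_spec("chrS", 1e5),
                                     n_true_peaks = 2,
                                     n_shared_artifacts = 0,
                                     n_hyper_loci = 0, seed = 5)))
  expect_identical(runif(1), before)
})

test_that("null config gives pure Poisson background at the set rate", {
  len <- 1e6; rate <- 0.01
  sim <- simulate_pair(sim_config(genome = genome_spec("chrS", len),
                                  n_true_peaks = 0,
                                  n_shared_artifacts = 0,
                                  n_hyper_loci = 0,
                                  background_rate = rate, seed = 2))
  expect_equal(nrow(sim$truth), 0)
  mu <- rate * len
  for (tot in c(sim$wt$total_tags, sim$ko$total_tags))
    expect_lt(abs(tot - mu), 4 * sqrt(mu))
})

test_that("per-class tag yields match configured means within 4 sigma", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_pair(cfg)
  tr <- sim$truth
  expect_equal(table(tr$class)[["true"]], 100)
  expect_equal(table(tr$class)[["shared_artifact"]], 100)
  expect_equal(table(tr$class)[["hyper"]], 5)
  for (cls in unique(tr$class)) {
    sel <- tr$class == cls
    mu <- sum(tr$mean_fragments[sel])
    expect_lt(abs(sum(tr$wt_fragments[sel]) - mu), 4 * sqrt(mu))
  }
  # clean knockout: no KO fragments at true sites; shared classes match
  expect_true(all(tr$ko_fragments[tr$class == "true"] == 0))
  mu_sh <- sum(tr$mean_fragments[tr$class != "true"])
  expect_lt(abs(sum(tr$ko_fragments[tr$class != "true"]) - mu_sh),
            4 * sqrt(mu_sh))
  # placement respects the minimum separation
  expect_true(all(diff(sort(tr$pos)) >= cfg$min_separation))
})

test_that("strand balance at sites is binomial", {
  sim <- simulate_pair(sim_config(genome = genome_spec("chrS", 1e6),
                                  n_true_peaks = 20,
                                  n_shared_artifacts = 0,
                                  n_hyper_loci = 0,
                                  background_rate = 0, seed = 19))
  n_plus <- sum(sim$wt$is_plus$chrS)
  n <- sim$wt$total_tags
  expect_lt(abs(n_plus - n / 2), 4 * sqrt(n / 4))
})

test_that("the bimodal strand offset is recoverable at lag ~ d", {
  d <- 150
  sim <- simulate_pair(sim_config(genome = genome_spec("chrS", 2e6),
                                  n_true_peaks = 50,
                                  n_shared_artifacts = 0,
                                  n_hyper_loci = 0, background_rate = 0,
                                  fragment_size = d,
                                  positional_noise_sd = 20, seed = 23))
  pos <- sim$wt$pos$chrS
  plus <- sim$wt$is_plus$chrS
  # mean nearest - tag downstream of each + tag should sit ~ d away
  lags <- seq(0, 300, by = 10)
  score <- vapply(lags, function(l) {
    shifted <- pos[plus] + l
    sum(findInterval(shifted + 5, pos[!plus]) -
          findInterval(shifted - 5, pos[!plus]))
  }, 0)
  best <- lags[which.max(score)]
  expect_lte(abs(best - d), 10)
})

test_that("leakage puts a controlled fraction of signal into KO", {
  cfg <- sim_config(genome = genome_spec("chrS", 2e6), n_true_peaks = 50,
                    n_shared_artifacts = 0, n_hyper_loci = 0,
                    leakage = 0.2, seed = 29)
  tr <- simulate_pair(cfg)$truth
  mu <- 0.2 * sum(tr$mean_fragments)
  expect_lt(abs(sum(tr$ko_fragments) - mu), 4 * sqrt(mu))
})

test_that("impossible site density raises a helpful error", {
  expect_error(
    simulate_pair(sim_config(genome = genome_spec("chrS", 5e4),
                             n_true_peaks = 50, n_shared_artifacts = 0,
                             n_hyper_loci = 0, seed = 1)),
    "genome")
})

test_that("a configured motif yields a genome with planted consensus", {
  p <- test_pwm()
  sim <- simulate_pair(sim_config(genome = genome_spec("chrS", 2e5),
                                  n_true_peaks = 5,
                                  n_shared_artifacts = 5,
                                  n_hyper_loci = 0, motif = p, seed = 3))
  expect_s4_class(sim$fasta, "DNAStringSet")
  cons <- pwm_consensus(p)
  seq_chr <- as.character(sim$fasta[["chrS"]])
  for (pos in sim$truth$pos[sim$truth$class == "true"]) {
    window <- substr(seq_chr, pos - 20, pos + 20)
    expect_true(grepl(cons, window), label = paste("site", pos))
  }
  # artifact sites carry no planted consensus (random background)
  n_art_hits <- sum(vapply(
    sim$truth$pos[sim$truth$class == "shared_artifact"],
    function(pos) grepl(cons, substr(seq_chr, pos - 20, pos + 20)),
    TRUE))
  expect_lte(n_art_hits, 1)
})

test_that("fixed hyper positions are honored across seeds", {
  hp <- c(50000, 150000, 250000)
  for (seed in c(1, 2)) {
    tr <- simulate_pair(sim_config(genome = genome_spec("chrS", 5e5),
                                   n_true_peaks = 10,
                                   n_shared_artifacts = 0,
                                   n_hyper_loci = 3,
                                   hyper_positions = hp,
                                   seed = seed))$truth
    expect_setequal(tr$pos[tr$class == "hyper"], hp)
  }
})
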