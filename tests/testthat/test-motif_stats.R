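revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("pwm validates its matrix and resolves the default threshold", {
  p <- test_pwm()
  # per-position score of the consensus base:
  # log2(((0.97 + 0.01) / 1.04) / 0.25), summed over 10 positions
  per_pos <- log2((0.98 / 1.04) / 0.25)
  expect_equal(p$max_score, 10 * per_pos, tolerance = 1e-12)
  expect_equal(p$score_threshold, 0.8 * 10 * per_pos, tolerance = 1e-12)
  expect_error(pwm(matrix(0.3, 4, 10)), "sum to 1")
  expect_error(pwm(matrix(0.25, 3, 10)), "4 rows")
})

test_that("consensus scores one maximal forward hit at offset 0", {
  p <- test_pwm()
  hits <- scan_pwm(pwm_consensus(p), p)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$offset, 0L)
  expect_equal(fwd$score, p$max_score, tolerance = 1e-12)
})

test_that("reverse complement of the consensus is found on the - strand", {
  p <- test_pwm()
  hits <- scan_pwm(revcomp(pwm_consensus(p)), p)
  expect_true(any(hits$strand == "-" & hits$offset == 0))
  expect_false(any(hits$strand == "+" & hits$score == p$max_score))
})

test_that("N bases poison their windows; all-N yields no hits", {
  p <- test_pwm()
  expect_equal(nrow(scan_pwm(strrep("N", 30), p)), 0)
  seq <- paste0("AAAA", pwm_consensus(p), "AAAA")
  with_n <- sub("CCAT", "CCNT", seq)
  expect_lt(nrow(scan_pwm(with_n, p)), nrow(scan_pwm(seq, p)) + 1)
})

test_that("scanning agrees with Biostrings::matchPWM on random sequence", {
  set.seed(17)
  p <- test_pwm(dom = 0.7)  # permissive threshold -> plenty of hits
  seq <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  ours <- scan_pwm(seq, p)
  fwd <- ours[ours$strand == "+", ]
  ref <- Biostrings::matchPWM(p$score_matrix, Biostrings::DNAString(seq),
                              min.score = p$score_threshold)
  expect_equal(sort(fwd$offset), sort(IRanges::start(ref@ranges) - 1L))
  # reverse-strand hits match scanning the reverse complement forward
  rc_ref <- Biostrings::matchPWM(
    p$score_matrix,
    Biostrings::reverseComplement(Biostrings::DNAString(seq)),
    min.score = p$score_threshold)
  expect_equal(length(rc_ref), sum(ours$strand == "-"))
})

test_that("scanning is strand-symmetric", {
  set.seed(23)
  p <- test_pwm(dom = 0.8)
  for (i in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    n_fwd <- nrow(scan_pwm(seq, p))
    n_rc <- nrow(scan_pwm(revcomp(seq), pwm_revcomp(p)))
    expect_equal(n_fwd, n_rc)
  }
})

test_that("JASPAR parsing normalizes counts and round-trips consensus", {
  path <- tempfile()
  writeLines(c(">MA0001 TESTTF",
               "A [  0 97  3  1 ]",
               "C [ 97  1  1  1 ]",
               "G [  2  1  1 96 ]",
               "T [  1  1 95  2 ]",
               ">PLAIN second",
               "A 1 0 0 25",
               "C 0 1 0 25",
               "G 0 0 1 25",
               "T 99 99 99 25"), path)
  pwms <- read_jaspar(path)
  expect_equal(names(pwms), c("MA0001", "PLAIN"))
  expect_equal(pwm_consensus(pwms$MA0001), "CATG")
  expect_equal(unname(colSums(pwms$PLAIN$matrix)), rep(1, 4))
  expect_equal(pwm_consensus(pwms$PLAIN), "TTTA")
})

test_that("extract_peak_sequences honors flanks and edge truncation", {
  fa <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 2500)))
  pk <- peaks_table(data.frame(chrom = "chr1", start = 100, end = 300,
                               summit = 150))
  sq <- extract_peak_sequences(pk, fa, flank = 100)
  expect_equal(nchar(sq[[1]]), 200)
  expect_false(attr(sq, "truncated"))
  pk_edge <- peaks_table(data.frame(chrom = "chr1", start = 0, end = 100,
                                    summit = 50))
  sq2 <- extract_peak_sequences(pk_edge, fa, flank = 100)
  expect_equal(nchar(sq2[[1]]), 150)
  expect_true(attr(sq2, "truncated"))
  pk_bad <- peaks_table(data.frame(chrom = "chrX", start = 0, end = 10))
  expect_error(extract_peak_sequences(pk_bad, fa), "chrX")
})

test_that("motif percentages count peaks with at least one hit", {
  p <- test_pwm()
  cons <- pwm_consensus(p)
  set.seed(5)
  rand <- function() paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                           collapse = "")
  # chromosome with the motif planted at 3 of 5 peak positions
  seqs <- vapply(1:5, function(i) rand(), "")
  planted <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  for (i in which(planted))
    substr(seqs[i], 195, 194 + nchar(cons)) <- cons
  fa <- Biostrings::DNAStringSet(
    stats::setNames(paste(seqs, collapse = ""), "chr1"))
  pk <- peaks_table(data.frame(chrom = "chr1",
                               start = 400 * (0:4) + 100,
                               end = 400 * (0:4) + 300,
                               summit = 400 * (0:4) + 200))
  rep_ <- motif_percentages(pk, p, fa)
  expect_equal(rep_$n_peaks_scanned, 5)
  expect_gte(rep_$n_peaks_with_hit, 3)
  expect_equal(rep_$percent_with_hit,
               100 * rep_$n_peaks_with_hit / 5)
  # determinism: identical report on a second scan
  expect_equal(motif_percentages(pk, p, fa), rep_)
  # empty peak set reports NA percent
  empty <- pk[integer(), ]
  class(empty) <- class(pk)
  rep0 <- motif_percentages(empty, p, fa)
  expect_true(is.na(rep0$percent_with_hit))
})

test_that("motif_ratio sign convention and antisymmetry", {
  expect_equal(motif_ratio(40, 10, 200, 100), 2.0)
  expect_equal(motif_ratio(10, 40, 100, 200), -2.0)
  expect_equal(motif_ratio(10, 10, 100, 100), 1.0)  # boundary -> positive
  # zero hits guarded by the 0.5 pseudocount
  expect_true(is.finite(motif_ratio(10, 0, 100, 100)))
  expect_equal(motif_ratio(0, 0, 100, 100), 1.0)
  expect_error(motif_ratio(1, 1, 0, 100), "> 0")
  # antisymmetry over random cases
  set.seed(41)
  for (i in 1:20) {
    h <- sample(0:50, 2); n <- sample(50:200, 2)
    if (h[1] * n[2] == h[2] * n[1]) next  # tie maps to +1 both ways
    r <- motif_ratio(h[1], h[2], n[1], n[2])
    r_swap <- motif_ratio(h[2], h[1], n[2], n[1])
    expect_equal(r, -r_swap, tolerance = 1e-12)
    expect_gte(abs(r), 1)
  }
})
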