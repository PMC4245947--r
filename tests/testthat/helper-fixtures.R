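# Shared fixtures, all built in code.

tiny_genome <- function(len = 1e5, eff = len, name = "chr1") {
  genome_spec(name, len, eff)
}

# tag_set from flat vectors (single chromosome unless chrom given)
make_tags <- function(pos, is_plus = rep(TRUE, length(pos)),
                      genome = tiny_genome(),
                      chrom = genome$chrom_names[1]) {
  tag_set(stats::setNames(list(pos), chrom),
          stats::setNames(list(is_plus), chrom), genome)
}

# a bimodal synthetic site: n/2 plus tags upstream, n/2 minus
# downstream, at fragment-size/2 from the site
site_cluster <- function(site, n = 200, d = 150, jitter_sd = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- if (jitter_sd > 0) round(rnorm(n, site, jitter_sd))
    else rep(site, n)
  plus <- rep(c(TRUE, FALSE), length.out = n)
  list(pos = ifelse(plus, centers - d / 2, centers + d / 2),
       is_plus = plus)
}

# strongly informative 10-bp PWM (0.97 on the consensus base)
test_pwm <- function(consensus = "CCATATTAGG", dom = 0.97,
                     name = "TESTTF", ...) {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- sapply(idx, function(i) {
    col <- rep((1 - dom) / 3, 4)
    col[i] <- dom
    col
  })
  pwm(m, name = name, ...)
}

# small gene model written to a temp TSV and read back
write_test_genes <- function(path = tempfile(fileext = ".tsv")) {
  df <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(NA, NA, 71000),
    gene_start = c(5000, 40000, 70000),
    gene_end = c(20000, 60000, 90000),
    introns = c("8000-15000", "45000-55000", ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_bed_lines <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

# brute-force sliding-window candidate scan (independent oracle)
brute_candidates <- function(pos, chrom_len, bw, min_tags, step = 10) {
  starts <- seq(0, max(0, chrom_len - bw), by = step)
  cnt <- vapply(starts, function(s)
    sum(pos >= s & pos < min(s + bw, chrom_len)), 0)
  sig <- starts[cnt >= min_tags]
  if (!length(sig))
    return(data.frame(start = numeric(), end = numeric(),
                      tag_count = numeric()))
  grp <- cumsum(c(TRUE, diff(sig) >= bw))
  st <- as.numeric(tapply(sig, grp, min))
  en <- pmin(as.numeric(tapply(sig, grp, max)) + bw, chrom_len)
  data.frame(start = st, end = en,
             tag_count = vapply(seq_along(st), function(i)
               sum(pos >= st[i] & pos < en[i]), 0),
             row.names = NULL)
}

# brute-force Poisson upper tail by term-wise pmf summation
brute_poisson_sf <- function(count, lam, horizon = 3000) {
  sum(stats::dpois(seq(count, count + horizon), lam))
}
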