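#' Simulation configuration for paired WT/KO ChIP-seq libraries
#'
#' The generator emulates the signal structure a knockout-control
#' correction is designed for: wild-type-specific true binding sites
#' with bimodal strand-shifted tag pileups, shared artifact sites with
#' equal-mean signal in both libraries, a few extreme-signal
#' hyper-ChIPable loci (an order of magnitude hotter than true sites,
#' present in both libraries), and uniform Poisson background.
#'
#' @param genome a [genome_spec()]; default one 5 Mb chromosome,
#'   effective size = length.
#' @param n_true_peaks WT-only true binding sites (default 100).
#' @param n_weak_true additional weak true sites (default 0), drawn
#'   with `fragments_per_weak` fragments; useful for probing the
#'   caller near its detection floor.
#' @param n_shared_artifacts sites with equal-mean signal in WT and KO
#'   (default 100).
#' @param n_hyper_loci hyper-ChIPable loci (default 5).
#' @param fragments_per_true,fragments_per_artifact,fragments_per_weak,fragments_per_hyper
#'   mean fragment counts per site class (defaults 200, 200, 20,
#'   2000; hyper is at least tenfold the true-site mean).
#' @param background_rate uniform background, tags per bp per library
#'   (default 0.01).
#' @param fragment_size bp (default 150).
#' @param positional_noise_sd SD (bp) of fragment centers around the
#'   site (default 30).
#' @param leakage fraction of `fragments_per_true` leaking into the KO
#'   library at true sites (default 0 = clean knockout).
#' @param min_separation minimum distance between placed sites, bp
#'   (default 5000).
#' @param hyper_positions optional fixed bp positions for the hyper
#'   loci (named by chromosome via `hyper_chrom`, default first
#'   chromosome); lets several simulations share the same hot loci.
#' @param motif optional [pwm()]; when set, [simulate_pair()] emits a
#'   genome sequence with the motif consensus planted at every true
#'   site (weak ones included) and random bases elsewhere.
#' @param read_length bp used when writing BED reads (default 36).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome = genome_spec("chrS", 5e6),
                       n_true_peaks = 100,
                       n_weak_true = 0,
                       n_shared_artifacts = 100,
                       n_hyper_loci = 5,
                       fragments_per_true = 200,
                       fragments_per_artifact = 200,
                       fragments_per_weak = 20,
                       fragments_per_hyper = 2000,
                       background_rate = 0.01,
                       fragment_size = 150,
                       positional_noise_sd = 30,
                       leakage = 0,
                       min_separation = 5000,
                       hyper_positions = NULL,
                       motif = NULL,
                       read_length = 36,
                       seed = 1) {
  stopifnot(n_true_peaks >= 0, n_weak_true >= 0,
            n_shared_artifacts >= 0, n_hyper_loci >= 0,
            fragments_per_true >= 0, fragments_per_artifact >= 0,
            fragments_per_weak >= 0, fragments_per_hyper >= 0,
            background_rate >= 0, fragment_size > 0,
            positional_noise_sd >= 0, leakage >= 0, leakage <= 1,
            min_separation > 0)
  if (!is.null(hyper_positions) &&
      length(hyper_positions) != n_hyper_loci)
    stop("hyper_positions must have length n_hyper_loci")
  structure(as.list(environment()), class = "sim_config")
}

# Random-sequential placement of n sites on one chromosome, each at
# least min_sep from every previously placed position (incl. fixed).
place_sites <- function(n, chrom_len, min_sep, margin, fixed = numeric()) {
  placed <- fixed
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:10000) {
      x <- floor(stats::runif(1, margin, chrom_len - margin))
      if (!length(placed) || min(abs(placed - x)) >= min_sep) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place ", n, " sites at min separation ", min_sep,
           " on a ", chrom_len, " bp chromosome; increase the genome ",
           "size to at least ~", format(3 * n * min_sep, scientific = FALSE),
           " bp")
    placed <- c(placed, x)
    out[i] <- x
  }
  out
}

# Tags for one binding event: fragment centers ~ N(site, sd); each
# fragment emits its + end (center - d/2) or - end (center + d/2).
site_tags <- function(n_frag, site, sd, d, chrom_len) {
  if (n_frag == 0)
    return(list(pos = numeric(), is_plus = logical()))
  centers <- round(stats::rnorm(n_frag, site, sd))
  plus <- stats::runif(n_frag) < 0.5
  pos <- ifelse(plus, centers - d / 2, centers + d / 2)
  list(pos = pmin(pmax(pos, 0), chrom_len - 1), is_plus = plus)
}

#' Simulate a paired WT/KO ChIP-seq experiment with ground truth
#'
#' Sites of three classes are placed at least `min_separation` apart.
#' True sites receive Poisson-mean `fragments_per_true` fragments in
#' WT and `leakage` times that in KO (zero by default — a clean
#' knockout). Shared artifacts and hyper loci receive independent
#' equal-mean fragment draws in both libraries. Every fragment center
#' is drawn Normal(site, `positional_noise_sd`) and emits a single
#' tag at one random fragment end, + strand upstream and - strand
#' downstream, producing the bimodal strand-split pileup a
#' midpoint-shifting caller expects. Uniform Poisson background tags
#' are added to both libraries.
#'
#' @param cfg a [sim_config()].
#' @return list with `wt` and `ko` ([tag_set()]s), `truth` (data
#'   frame: `chrom`, `pos`, `class` in true/shared_artifact/hyper,
#'   `mean_fragments`, `wt_fragments`, `ko_fragments`), `genome`, and
#'   `fasta` (a `DNAStringSet`, only when `cfg$motif` is set).
#' @export
simulate_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(cfg$seed)
  genome <- cfg$genome
  d <- cfg$fragment_size

  # site placement: distribute counts over chromosomes by length
  n_sites <- c(true = cfg$n_true_peaks, weak = cfg$n_weak_true,
               shared_artifact = cfg$n_shared_artifacts,
               hyper = cfg$n_hyper_loci)
  truth <- NULL
  wt_pos <- list(); wt_plus <- list(); ko_pos <- list(); ko_plus <- list()
  n_chrom <- length(genome$chrom_names)
  weights <- genome$chrom_lengths / sum(genome$chrom_lengths)
  for (ci in seq_len(n_chrom)) {
    chrom <- genome$chrom_names[ci]
    len <- genome$chrom_lengths[[ci]]
    # chromosome share of each class (all on chrom 1 when single)
    share <- function(n) {
      if (n_chrom == 1) return(n)
      lo <- floor(n * cumsum(c(0, weights))[ci])
      hi <- floor(n * cumsum(weights)[ci])
      hi - lo
    }
    fixed_hyper <- if (!is.null(cfg$hyper_positions) && ci == 1)
      as.numeric(cfg$hyper_positions) else NULL
    n_here <- vapply(n_sites, share, 1)
    if (!is.null(fixed_hyper)) n_here["hyper"] <- 0
    margin <- max(1000, 4 * cfg$positional_noise_sd + d)
    pos <- place_sites(sum(n_here), len, cfg$min_separation, margin,
                       fixed = fixed_hyper %||% numeric())
    cls <- rep(names(n_sites), n_here)
    if (!is.null(fixed_hyper)) {
      pos <- c(pos, fixed_hyper)
      cls <- c(cls, rep("hyper", length(fixed_hyper)))
    }
    # shuffle so class is independent of placement order
    o <- sample.int(length(pos))
    pos <- pos[o]; cls <- cls[o]
    means <- c(true = cfg$fragments_per_true,
               weak = cfg$fragments_per_weak,
               shared_artifact = cfg$fragments_per_artifact,
               hyper = cfg$fragments_per_hyper)[cls]
    wt_frag <- stats::rpois(length(pos), means)
    ko_mean <- ifelse(cls %in% c("true", "weak"),
                      means * cfg$leakage, means)
    ko_frag <- stats::rpois(length(pos), ko_mean)
    wp <- numeric(); ws <- logical(); kp <- numeric(); ks <- logical()
    for (i in seq_along(pos)) {
      tw <- site_tags(wt_frag[i], pos[i], cfg$positional_noise_sd, d, len)
      tk <- site_tags(ko_frag[i], pos[i], cfg$positional_noise_sd, d, len)
      wp <- c(wp, tw$pos); ws <- c(ws, tw$is_plus)
      kp <- c(kp, tk$pos); ks <- c(ks, tk$is_plus)
    }
    # uniform Poisson background per library
    for (lib in c("wt", "ko")) {
      nbg <- stats::rpois(1, cfg$background_rate * len)
      bp_ <- floor(stats::runif(nbg, 0, len))
      bs <- stats::runif(nbg) < 0.5
      if (lib == "wt") { wp <- c(wp, bp_); ws <- c(ws, bs) }
      else { kp <- c(kp, bp_); ks <- c(ks, bs) }
    }
    wt_pos[[chrom]] <- wp; wt_plus[[chrom]] <- ws
    ko_pos[[chrom]] <- kp; ko_plus[[chrom]] <- ks
    if (length(pos))
      truth <- rbind(truth, data.frame(
        chrom = chrom, pos = pos,
        class = ifelse(cls == "weak", "true", cls),
        weak = cls == "weak", mean_fragments = as.numeric(means),
        wt_fragments = wt_frag, ko_fragments = ko_frag,
        stringsAsFactors = FALSE))
  }
  if (is.null(truth))
    truth <- data.frame(chrom = character(), pos = numeric(),
                        class = character(), weak = logical(),
                        mean_fragments = numeric(),
                        wt_fragments = integer(),
                        ko_fragments = integer())
  truth <- truth[order(match(truth$chrom, genome$chrom_names),
                       truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  fasta <- if (!is.null(cfg$motif)) sim_genome_fasta(cfg, truth) else NULL
  list(wt = tag_set(wt_pos, wt_plus, genome),
       ko = tag_set(ko_pos, ko_plus, genome),
       truth = truth, genome = genome, fasta = fasta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random genome with the motif consensus planted at true sites.
sim_genome_fasta <- function(cfg, truth) {
  cons <- pwm_consensus(cfg$motif)
  w <- nchar(cons)
  seqs <- lapply(seq_along(cfg$genome$chrom_names), function(ci) {
    len <- cfg$genome$chrom_lengths[[ci]]
    s <- sample(BASES, len, replace = TRUE)
    chrom <- cfg$genome$chrom_names[ci]
    at <- truth$pos[truth$chrom == chrom & truth$class == "true"]
    for (p in at) {
      from <- max(1, floor(p - w / 2) + 1)
      if (from + w - 1 <= len)
        s[from:(from + w - 1)] <- strsplit(cons, "")[[1]]
    }
    paste(s, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- cfg$genome$chrom_names
  out
}

#' Write a simulated experiment to a directory
#'
#' Emits `wt.bed`, `ko.bed` (BED6 reads), `truth.tsv`, `sizes.tsv`
#' and, when a motif is configured, `genome.fa`.
#'
#' @param sim result of [simulate_pair()].
#' @param dir output directory.
#' @param read_length read length for the BED records (default 36).
#' @export
write_sim <- function(sim, dir, read_length = 36) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tag_bed(sim$wt, file.path(dir, "wt.bed"), read_length)
  write_tag_bed(sim$ko, file.path(dir, "ko.bed"), read_length)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_chrom_sizes(sim$genome, file.path(dir, "sizes.tsv"))
  if (!is.null(sim$fasta))
    Biostrings::writeXStringSet(sim$fasta, file.path(dir, "genome.fa"))
  invisible(dir)
}

#' Match corrected peaks against simulator truth
#'
#' A truth site is recovered when its position falls inside (or within
#' `slop` bp of) some peak interval.
#'
#' @param peaks a [peaks_table()].
#' @param truth truth table from [simulate_pair()].
#' @param slop bp of tolerance around peak intervals (default 100).
#' @return logical vector over truth rows: recovered or not.
#' @export
truth_recovered <- function(peaks, truth, slop = 100) {
  vapply(seq_len(nrow(truth)), function(i) {
    sel <- peaks$chrom == truth$chrom[i] &
      peaks$start - slop <= truth$pos[i] &
      peaks$end + slop > truth$pos[i]
    any(sel)
  }, TRUE)
}
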