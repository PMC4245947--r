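BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' @param matrix 4 x L numeric matrix of per-position base
#'   probabilities, rows A, C, G, T; every column must sum to 1
#'   (within 1e-6). Count matrices should be column-normalized before
#'   construction (see [read_jaspar()]).
#' @param name motif name.
#' @param background base frequencies used in the log-odds
#'   denominator (default uniform).
#' @param score_threshold absolute log2-odds threshold in bits; NULL
#'   (default) uses `threshold_frac` of the maximum achievable score.
#' @param threshold_frac fraction of the maximum score used when
#'   `score_threshold` is NULL (default 0.8).
#' @param pseudo probability added to each cell before log-odds
#'   (default 0.01), so legitimate bases never score -Inf.
#' @return object of class `pwm` with the log2-odds `score_matrix`,
#'   `max_score` and resolved `score_threshold`.
#' @export
pwm <- function(matrix, name = "motif", background = rep(0.25, 4),
                score_threshold = NULL, threshold_frac = 0.8,
                pseudo = 0.01) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM matrix must have 4 rows (A,C,G,T)")
  if (ncol(matrix) < 4) stop("PWM must be at least 4 positions long")
  if (any(matrix < 0)) stop("PWM probabilities must be >= 0")
  if (any(abs(colSums(matrix) - 1) > 1e-6))
    stop("every PWM column must sum to 1")
  rownames(matrix) <- BASES
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  smat <- log2(((matrix + pseudo) / (1 + 4 * pseudo)) / background)
  max_score <- sum(apply(smat, 2, max))
  if (is.null(score_threshold))
    score_threshold <- threshold_frac * max_score
  structure(list(name = name, matrix = matrix, background = background,
                 score_matrix = smat, max_score = max_score,
                 score_threshold = score_threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$name, "': ", ncol(x$matrix), " positions, consensus ",
      pwm_consensus(x), ", threshold ", sprintf("%.2f", x$score_threshold),
      "/", sprintf("%.2f", x$max_score), " bits\n", sep = "")
  invisible(x)
}

#' Consensus sequence (most probable base per position)
#' @param x a [pwm()].
#' @return character string of length ncol(matrix).
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Reverse-complement a PWM
#' @param x a [pwm()].
#' @return a [pwm()] scanning the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[4:1, rev(seq_len(ncol(x$matrix))), drop = FALSE]
  pwm(m, name = paste0(x$name, "_rc"), background = x$background,
      score_threshold = x$score_threshold)
}

#' Read motifs in JASPAR format
#'
#' Parses the JASPAR text layout: a `>name` header followed by four
#' lines `A [ counts... ]` (brackets optional), one per base. Counts
#' or probabilities are accepted; columns are normalized to sum to 1.
#'
#' @param path file path; may hold several motifs.
#' @param ... passed to [pwm()] (background, thresholds).
#' @return named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' motif header found in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    if (length(body) < 4)
      stop("motif '", name, "': expected 4 base rows")
    rows <- lapply(body[1:4], function(l) {
      base <- sub("^([ACGT]).*", "\\1", l)
      nums <- gsub("^[ACGT]\\s*\\[?|\\]\\s*$", "", l)
      list(base = base,
           counts = as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, BASES))
      stop("motif '", name, "': rows must be labeled A, C, G, T")
    m <- do.call(rbind, lapply(rows, `[[`, "counts"))[match(BASES, bases), ]
    if (any(is.na(m))) stop("motif '", name, "': non-numeric counts")
    m <- sweep(m, 2, colSums(m), "/")
    out[[name]] <- pwm(m, name = name, ...)
  }
  out
}

#' Extract peak-flanking sequence from a genome FASTA
#'
#' @param peaks a [peaks_table()] with summits.
#' @param genome_fasta path to a FASTA file, or a
#'   [Biostrings::DNAStringSet].
#' @param flank bp on each side of the summit (default 100, giving
#'   2*flank bp of sequence).
#' @return named uppercase character vector `[summit - flank,
#'   summit + flank)`, truncated at chromosome edges; attribute
#'   `truncated` flags shortened sequences.
#' @export
extract_peak_sequences <- function(peaks, genome_fasta, flank = 100) {
  seqs <- if (inherits(genome_fasta, "DNAStringSet")) genome_fasta
    else Biostrings::readDNAStringSet(genome_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(peaks$chrom), names(seqs))
  if (length(missing))
    stop("chromosome(s) missing from FASTA: ",
         paste(missing, collapse = ", "))
  n <- nrow(peaks)
  out <- character(n)
  trunc <- logical(n)
  anchor <- peak_anchor(peaks)
  for (i in seq_len(n)) {
    len <- length(seqs[[peaks$chrom[i]]])
    from <- max(0, anchor[i] - flank)
    to <- min(len, anchor[i] + flank)
    trunc[i] <- (from > anchor[i] - flank) || (to < anchor[i] + flank)
    out[i] <- toupper(as.character(
      Biostrings::subseq(seqs[[peaks$chrom[i]]], from + 1, to)))
  }
  names(out) <- sprintf("%s:%d-%d", peaks$chrom,
                        as.integer(anchor - flank),
                        as.integer(anchor + flank))
  attr(out, "truncated") <- trunc
  out
}

scan_one_strand <- function(idx, smat, L) {
  n <- length(idx)
  if (n < L) return(numeric())
  nwin <- n - L + 1
  scores <- numeric(nwin)
  for (j in seq_len(L)) {
    v <- smat[, j][idx[j:(j + nwin - 1)]]
    v[is.na(v)] <- -Inf
    scores <- scores + v
  }
  scores
}

#' Scan a sequence with a PWM on both strands
#'
#' Log2-odds scores against the PWM's background; windows containing
#' non-ACGT bases score -Inf. All windows at or above the score
#' threshold are returned (multiple hits per sequence are expected and
#' kept).
#'
#' @param seq character string (case-insensitive).
#' @param pwm_obj a [pwm()].
#' @return data frame with `offset` (0-based position of the window on
#'   the forward strand), `strand`, `score`, sorted by offset.
#' @export
scan_pwm <- function(seq, pwm_obj) {
  L <- ncol(pwm_obj$matrix)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < L)
    stop("sequence shorter than the PWM (", L, " bp)")
  idx <- match(chars, BASES)
  fwd <- scan_one_strand(idx, pwm_obj$score_matrix, L)
  # reverse strand: complement is 5 - idx, order reversed
  rev_idx <- rev(ifelse(is.na(idx), NA, 5L - idx))
  rev_sc <- scan_one_strand(rev_idx, pwm_obj$score_matrix, L)
  n <- length(chars)
  fi <- which(fwd >= pwm_obj$score_threshold)
  ri <- which(rev_sc >= pwm_obj$score_threshold)
  hits <- rbind(
    data.frame(offset = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi]),
    data.frame(offset = n - L + 1L - ri, strand = rep("-", length(ri)),
               score = rev_sc[ri]))
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Motif occurrence statistics over peak sequences
#'
#' For each PWM, the fraction of peak-flanking sequences containing at
#' least one hit. When a second peak set is given (e.g. corrected vs
#' uncorrected), both are reported side by side for comparison.
#'
#' @param peaks a [peaks_table()].
#' @param pwms a [pwm()] or list of them.
#' @param genome_fasta FASTA path or `DNAStringSet`.
#' @param flank bp around the summit (default 100).
#' @param peaks2 optional second [peaks_table()].
#' @param set_labels labels for the two sets in paired mode.
#' @return data frame with columns `pwm`, `set`, `n_peaks_scanned`,
#'   `n_peaks_with_hit`, `percent_with_hit` (NA when no peaks),
#'   `total_hits`.
#' @export
motif_percentages <- function(peaks, pwms, genome_fasta, flank = 100,
                              peaks2 = NULL,
                              set_labels = c("uncorrected", "corrected")) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(pwms)))
    names(pwms) <- vapply(pwms, `[[`, "", "name")
  seqs <- if (inherits(genome_fasta, "DNAStringSet")) genome_fasta
    else Biostrings::readDNAStringSet(genome_fasta)
  one_set <- function(pk, label) {
    sq <- if (nrow(pk)) extract_peak_sequences(pk, seqs, flank)
      else character()
    do.call(rbind, lapply(names(pwms), function(nm) {
      L <- ncol(pwms[[nm]]$matrix)
      nhits <- vapply(sq, function(s) {
        if (nchar(s) < L) return(0L)
        nrow(scan_pwm(s, pwms[[nm]]))
      }, 0L)
      data.frame(pwm = nm, set = label,
                 n_peaks_scanned = length(sq),
                 n_peaks_with_hit = sum(nhits > 0),
                 percent_with_hit = if (length(sq))
                   100 * sum(nhits > 0) / length(sq) else NA_real_,
                 total_hits = sum(nhits),
                 stringsAsFactors = FALSE)
    }))
  }
  rep1 <- one_set(peaks, set_labels[1])
  if (is.null(peaks2)) {
    rownames(rep1) <- NULL
    return(rep1)
  }
  out <- rbind(rep1, one_set(peaks2, set_labels[2]))
  rownames(out) <- NULL
  out
}

#' Signed WT/KO motif fold change
#'
#' Motif hit counts are normalized by the peak totals of their
#' dataset; the ratio of normalized abundances is reported with the
#' convention that WT excess is positive and KO excess negative:
#' `+r` when r >= 1, else `-1/r`. A pseudocount of 0.5 is added to
#' both hit counts whenever either is zero.
#'
#' @param wt_hits,ko_hits motif occurrence counts.
#' @param wt_peaks,ko_peaks total peak counts (> 0) of each dataset.
#' @return signed fold change; magnitude >= 1 always.
#' @export
motif_ratio <- function(wt_hits, ko_hits, wt_peaks, ko_peaks) {
  if (wt_peaks <= 0 || ko_peaks <= 0)
    stop("motif_ratio: peak totals must be > 0")
  if (wt_hits == 0 || ko_hits == 0) {
    wt_hits <- wt_hits + 0.5
    ko_hits <- ko_hits + 0.5
  }
  r <- (wt_hits / wt_peaks) / (ko_hits / ko_peaks)
  if (r >= 1) r else -1 / r
}
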