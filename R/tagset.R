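#' Strand-annotated sequencing tags
#'
#' A `tag_set` holds, per chromosome, the sorted 0-based 5' start
#' positions of aligned reads together with their strand, plus the
#' total tag count used for depth normalization. It is the in-memory
#' currency of the whole pipeline: peak calling, fold-change counting
#' and histograms all consume `tag_set`s.
#'
#' @param pos named list (by chromosome) of integer vectors of 0-based
#'   positions.
#' @param is_plus named list of logical vectors, parallel to `pos`,
#'   TRUE for the + strand.
#' @param genome a [genome_spec()].
#' @return An object of class `tag_set` with elements `pos`, `is_plus`,
#'   `total_tags` and `genome`. Positions are sorted within chromosome.
#' @export
tag_set <- function(pos, is_plus, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  pos <- pos[intersect(genome$chrom_names, names(pos))]
  is_plus <- is_plus[names(pos)]
  for (chrom in names(pos)) {
    p <- as.numeric(pos[[chrom]])
    s <- as.logical(is_plus[[chrom]])
    if (length(p) != length(s))
      stop("pos/is_plus length mismatch on ", chrom)
    if (length(p) && (min(p) < 0 || max(p) >= genome$chrom_lengths[[chrom]]))
      stop("tag position outside [0, chrom_length) on ", chrom)
    o <- order(p)
    pos[[chrom]] <- p[o]
    is_plus[[chrom]] <- s[o]
  }
  structure(list(pos = pos, is_plus = is_plus,
                 total_tags = sum(vapply(pos, length, 1L)),
                 genome = genome),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("tag_set:", format(x$total_tags, big.mark = ","), "tags on",
      length(x$pos), "chromosome(s)\n")
  invisible(x)
}

#' Read aligned reads from BED into a tag set
#'
#' Each BED record is reduced to a single strand-aware 5' tag: the
#' `start` coordinate for + reads and `end - 1` for - reads (0-based).
#' Records on chromosomes absent from `genome` are counted, reported
#' via a warning, and dropped. Lines starting with `#`, `track` or
#' `browser` are skipped.
#'
#' Aligned BAM files are converted on the way in rather than parsed
#' here: `bedtools bamtobed -i aligned.bam > reads.bed`.
#'
#' @param path BED file with at least 6 columns
#'   (chrom, start, end, name, score, strand).
#' @param genome a [genome_spec()].
#' @param max_dup optional cap on identical (chrom, position, strand)
#'   tags; `Inf` (default) keeps all duplicates.
#' @return A [tag_set()]. The numbers of parsed and dropped records are
#'   attached as attributes `n_parsed` and `n_dropped`.
#' @export
read_tag_bed <- function(path, genome, max_dup = Inf) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    ts <- tag_set(stats::setNames(list(), character()),
                  stats::setNames(list(), character()), genome)
    attr(ts, "n_parsed") <- 0L
    attr(ts, "n_dropped") <- 0L
    return(ts)
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed BED line ", line_no[which(nf < 6)[1]],
         ": expected >= 6 fields, got ", nf[which(nf < 6)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  strand <- vapply(fields, `[[`, "", 6L)
  bad <- which(!is.finite(start) | !is.finite(end) | end <= start)
  if (length(bad))
    stop("malformed BED line ", line_no[bad[1]],
         ": non-numeric or empty interval")
  bad_strand <- which(!strand %in% c("+", "-"))
  if (length(bad_strand))
    stop("malformed BED line ", line_no[bad_strand[1]],
         ": strand must be '+' or '-', got '", strand[bad_strand[1]], "'")
  known <- chrom %in% genome$chrom_names
  n_dropped <- sum(!known)
  if (n_dropped > 0)
    warning(n_dropped, " record(s) on chromosomes absent from the genome ",
            "spec were dropped (e.g. '", chrom[!known][1], "')")
  chrom <- chrom[known]; start <- start[known]; end <- end[known]
  is_plus <- strand[known] == "+"
  tagpos <- ifelse(is_plus, start, end - 1)
  pos <- split(tagpos, factor(chrom, levels = genome$chrom_names))
  strd <- split(is_plus, factor(chrom, levels = genome$chrom_names))
  pos <- pos[lengths(pos) > 0]
  strd <- strd[names(pos)]
  if (is.finite(max_dup)) {
    for (ch in names(pos)) {
      key <- paste0(pos[[ch]], ifelse(strd[[ch]], "+", "-"))
      o <- order(pos[[ch]], !strd[[ch]])
      key <- key[o]
      idx <- stats::ave(seq_along(key), key, FUN = seq_along) <= max_dup
      pos[[ch]] <- pos[[ch]][o][idx]
      strd[[ch]] <- strd[[ch]][o][idx]
    }
  }
  ts <- tag_set(pos, strd, genome)
  attr(ts, "n_parsed") <- length(lines)
  attr(ts, "n_dropped") <- n_dropped
  ts
}

#' Write a tag set as BED6 reads
#'
#' Inverse of [read_tag_bed()] up to read length: each tag becomes a
#' read of `read_length` bp whose 5' end sits at the tag position
#' (clipped at chromosome edges, preserving the 5' coordinate).
#'
#' @param tags a [tag_set()].
#' @param path output path.
#' @param read_length bp, default 36.
#' @export
write_tag_bed <- function(tags, path, read_length = 36) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(tags$pos)) {
    p <- tags$pos[[chrom]]
    if (!length(p)) next
    plus <- tags$is_plus[[chrom]]
    len <- tags$genome$chrom_lengths[[chrom]]
    start <- ifelse(plus, p, pmax(0, p - read_length + 1))
    end <- ifelse(plus, pmin(len, p + read_length), p + 1)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, as.integer(start),
                       as.integer(end),
                       paste0("t", seq_along(p)),
                       ifelse(plus, "+", "-")), con)
  }
  invisible(path)
}

#' Shift tags toward the fragment midpoint
#'
#' Sense tags move downstream and anti-sense tags upstream by `shift`
#' bp, so that the bimodal strand-separated pileup flanking a binding
#' site collapses onto the site itself. Positions are clamped to
#' `[0, chrom_length)`; the tag count is conserved.
#'
#' @param tags a [tag_set()].
#' @param shift non-negative bp, typically fragment_size / 2.
#' @return Named list (by chromosome) of sorted numeric position
#'   vectors, with attribute `total` = total tag count.
#' @export
shift_tags <- function(tags, shift) {
  stopifnot(inherits(tags, "tag_set"), shift >= 0)
  out <- lapply(names(tags$pos), function(chrom) {
    p <- tags$pos[[chrom]]
    plus <- tags$is_plus[[chrom]]
    len <- tags$genome$chrom_lengths[[chrom]]
    sort(pmin(pmax(ifelse(plus, p + shift, p - shift), 0), len - 1))
  })
  names(out) <- names(tags$pos)
  attr(out, "total") <- tags$total_tags
  out
}

# Count of sorted positions falling in [start, end), vectorized over
# parallel start/end vectors.
count_in_windows <- function(sorted_pos, start, end) {
  if (!length(sorted_pos)) return(numeric(length(start)))
  findInterval(end - 0.5, sorted_pos) - findInterval(start - 0.5, sorted_pos)
}
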