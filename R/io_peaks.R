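#' Construct a peak table
#'
#' Peaks are plain data frames (class `koin_peaks`) with 0-based
#' half-open coordinates and one row per called peak. Columns:
#' `chrom`, `start`, `end`, `summit` (bp, inside the peak),
#' `tag_count` (shifted treatment tags in the interval),
#' `lambda_local` (expected background tags), `pvalue` (Poisson upper
#' tail), `norm_tag_count` (tag_count scaled to a 1e7-tag library) and
#' `label` (one of `"WT"`, `"KO-negative"`, `"corrected"`).
#'
#' @param df data frame with the columns above (missing statistic
#'   columns are filled with NA).
#' @param chrom_order chromosome ordering used for sorting; defaults to
#'   order of appearance.
#' @return The validated, sorted `koin_peaks` data frame.
#' @export
peaks_table <- function(df, chrom_order = unique(df$chrom)) {
  needed <- c("chrom", "start", "end")
  if (!all(needed %in% names(df)))
    stop("peaks need at least columns: ", paste(needed, collapse = ", "))
  defaults <- list(summit = NA_real_, tag_count = NA_real_,
                   lambda_local = NA_real_, pvalue = NA_real_,
                   norm_tag_count = NA_real_, label = NA_character_)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  df <- df[c(needed, names(defaults))]
  if (nrow(df)) {
    if (any(df$start >= df$end)) stop("peak with start >= end")
    ok <- is.na(df$summit) | (df$summit >= df$start & df$summit < df$end)
    if (!all(ok)) stop("summit outside [start, end)")
    o <- order(match(df$chrom, chrom_order), df$start)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("koin_peaks", "data.frame")
  df
}

peak_score <- function(pvalue, cap = 10000) {
  sc <- -10 * log10(pmax(pvalue, .Machine$double.xmin))
  as.integer(round(pmin(sc, cap)))
}

#' Write peaks to BED or narrowPeak
#'
#' The `bed` dialect emits chrom/start/end/name/score/strand with
#' score = -10 log10(p) capped at 10000 and strand ".". The
#' `narrowpeak` dialect appends the ENCODE 6+4 columns: signalValue
#' (normalized tag count), -log10 p-value, q-value (-1, not computed)
#' and the summit offset relative to `start`. An empty peak list yields
#' a file holding only the header comment.
#'
#' @param peaks a [peaks_table()] sorted by (chrom, start).
#' @param path output path.
#' @param dialect `"bed"` or `"narrowpeak"`.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowpeak", "bed")) {
  dialect <- match.arg(dialect)
  if (nrow(peaks)) {
    by_chrom <- split(seq_len(nrow(peaks)), peaks$chrom)
    for (idx in by_chrom) {
      if (is.unsorted(peaks$start[idx], strictly = FALSE))
        stop("peaks must be sorted by (chrom, start) before writing")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# koinr peaks (", dialect,
                    "); coordinates 0-based half-open"), con)
  if (!nrow(peaks)) return(invisible(path))
  name <- sprintf("%s_peak_%d",
                  ifelse(is.na(peaks$label), "peak", peaks$label),
                  seq_len(nrow(peaks)))
  score <- peak_score(ifelse(is.na(peaks$pvalue), 1, peaks$pvalue))
  if (dialect == "bed") {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.",
                       peaks$chrom, as.integer(peaks$start),
                       as.integer(peaks$end), name, score), con)
  } else {
    mlog10p <- ifelse(is.na(peaks$pvalue), -1,
                      -log10(pmax(peaks$pvalue, .Machine$double.xmin)))
    signal <- ifelse(is.na(peaks$norm_tag_count), 0, peaks$norm_tag_count)
    offset <- ifelse(is.na(peaks$summit), -1L,
                     as.integer(peaks$summit - peaks$start))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.6g\t%.6g\t-1\t%d",
                       peaks$chrom, as.integer(peaks$start),
                       as.integer(peaks$end), name, score,
                       signal, mlog10p, offset), con)
  }
  invisible(path)
}

#' Read peaks from BED or narrowPeak
#'
#' Dialect is detected from the column count (6 = BED, 10 =
#' narrowPeak). Coordinates round-trip exactly through
#' [write_peaks()]; statistics not representable in the dialect come
#' back as NA.
#'
#' @param path file path.
#' @param label optional label to assign to all peaks read.
#' @return A [peaks_table()].
#' @export
read_peaks <- function(path, label = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (!length(lines))
    return(peaks_table(data.frame(chrom = character(), start = numeric(),
                                  end = numeric())))
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 6)) stop("peak line with fewer than 6 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   label = label, stringsAsFactors = FALSE)
  if (all(nf >= 10)) {
    signal <- as.numeric(vapply(fields, `[[`, "", 7L))
    mlog10p <- as.numeric(vapply(fields, `[[`, "", 8L))
    offset <- as.numeric(vapply(fields, `[[`, "", 10L))
    df$norm_tag_count <- signal
    df$pvalue <- ifelse(mlog10p < 0, NA_real_, 10^(-mlog10p))
    df$summit <- ifelse(offset < 0, NA_real_, start + offset)
  }
  peaks_table(df)
}

#' Read a gene model table
#'
#' TSV with header columns `gene_id`, `chrom`, `strand`, `tss`,
#' `gene_start`, `gene_end` and optionally `introns`
#' (semicolon-separated `start-end` 0-based half-open blocks). A
#' missing/NA `tss` is derived strand-aware: `gene_start` for + genes,
#' `gene_end - 1` for - genes.
#'
#' @param path file path.
#' @return data frame of class `gene_model` with one row per gene and
#'   a list-column `introns` of 2-column matrices.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  needed <- c("gene_id", "chrom", "strand", "gene_start", "gene_end")
  if (!all(needed %in% names(df)))
    stop("gene model needs columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (is.null(df$tss)) df$tss <- NA_real_
  df$tss <- ifelse(is.na(df$tss),
                   ifelse(df$strand == "+", df$gene_start, df$gene_end - 1),
                   df$tss)
  bad <- df$tss < df$gene_start | df$tss >= df$gene_end
  if (any(bad))
    stop("tss outside [gene_start, gene_end) for gene ",
         df$gene_id[which(bad)[1]])
  intr <- if (is.null(df$introns)) rep("", nrow(df)) else
    ifelse(is.na(df$introns), "", df$introns)
  df$introns <- lapply(intr, function(s) {
    if (!nzchar(s)) return(matrix(numeric(), ncol = 2))
    blk <- do.call(rbind, lapply(strsplit(s, ";")[[1]], function(b)
      as.numeric(strsplit(b, "-")[[1]])))
    if (any(is.na(blk)) || any(blk[, 1] >= blk[, 2]))
      stop("malformed intron block: ", s)
    blk
  })
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Write a gene model table (inverse of [read_gene_model()])
#' @param genes a `gene_model` data frame.
#' @param path output path.
#' @export
write_gene_model <- function(genes, path) {
  out <- genes[c("gene_id", "chrom", "strand", "tss",
                 "gene_start", "gene_end")]
  out$introns <- vapply(genes$introns, function(m) {
    if (!nrow(m)) return("")
    paste(sprintf("%d-%d", as.integer(m[, 1]), as.integer(m[, 2])),
          collapse = ";")
  }, "")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
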