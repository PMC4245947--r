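#' Knockout-control correction parameters
#'
#' @param fc_threshold minimum WT/KO normalized tag-count ratio a peak
#'   must reach to survive the fold-change filter. A ratio of exactly
#'   `fc_threshold` is kept ("less than" the threshold is excluded).
#' @param fc_pseudocount raw tags (depth-scaled to a 1e7 library)
#'   added to both numerator and denominator; guards against division
#'   by a knockout count of zero, which is the expected outcome at
#'   genuine binding sites.
#' @param overlap_rule `"any"` (>= 1 shared bp removes a WT peak) or a
#'   positive integer n (>= n shared bp).
#' @param shift_count shift tags by the caller's tag_shift before
#'   counting in peak windows (consistent with calling); FALSE counts
#'   raw 5' positions.
#' @param caller a [caller_params()].
#' @return list of class `koin_params`.
#' @export
koin_params <- function(fc_threshold = 2, fc_pseudocount = 1,
                        overlap_rule = "any", shift_count = TRUE,
                        caller = caller_params()) {
  stopifnot(fc_threshold > 0, fc_pseudocount >= 0)
  if (!(identical(overlap_rule, "any") ||
        (is.numeric(overlap_rule) && overlap_rule >= 1)))
    stop("overlap_rule must be \"any\" or a minimum overlap in bp")
  structure(list(fc_threshold = fc_threshold,
                 fc_pseudocount = fc_pseudocount,
                 overlap_rule = overlap_rule,
                 shift_count = shift_count,
                 caller = caller),
            class = "koin_params")
}

#' Call negative peaks (knockout vs wild-type)
#'
#' The swapped second call of the correction: the knockout library is
#' the treatment and the wild-type the control, so that reproducible
#' non-specific signal (antibody cross-reactivity, hyper-ChIPable
#' loci) is called as peaks in the knockout.
#'
#' @param wt,ko non-empty [tag_set()]s.
#' @param params a [caller_params()].
#' @param genome a [genome_spec()].
#' @return A [peaks_table()] labeled `"KO-negative"`.
#' @export
call_negative_peaks <- function(wt, ko, params = caller_params(),
                                genome = wt$genome) {
  call_peaks(ko, control = wt, params = params, genome = genome,
             label = "KO-negative")
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = if (nrow(peaks)) peaks$chrom else character(),
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

check_sorted_disjoint <- function(peaks, what) {
  if (nrow(peaks) < 2) return(invisible())
  for (idx in split(seq_len(nrow(peaks)), peaks$chrom)) {
    if (is.unsorted(peaks$start[idx]))
      stop(what, " peaks are not sorted by start within chromosome")
    if (length(idx) > 1 &&
        any(peaks$start[idx][-1] < peaks$end[idx][-length(idx)]))
      stop(what, " peaks overlap within the list")
  }
  invisible()
}

#' Remove WT peaks shared with the knockout call
#'
#' A wild-type peak is removed iff it overlaps at least one
#' knockout-negative peak under the configured rule (default: any
#' shared bp). The two returned sets partition the input.
#'
#' @param wt_peaks,ko_peaks sorted, internally non-overlapping
#'   [peaks_table()]s.
#' @param rule `"any"` or minimum overlap in bp.
#' @return list with elements `kept` and `shared_removed`.
#' @export
subtract_shared <- function(wt_peaks, ko_peaks, rule = "any") {
  check_sorted_disjoint(wt_peaks, "WT")
  check_sorted_disjoint(ko_peaks, "KO")
  if (!nrow(wt_peaks) || !nrow(ko_peaks)) {
    return(list(kept = wt_peaks,
                shared_removed = wt_peaks[integer(), , drop = FALSE]))
  }
  minov <- if (identical(rule, "any")) 1L else as.integer(rule)
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(wt_peaks),
                                      peaks_to_granges(ko_peaks),
                                      minoverlap = minov)
  shared <- sort(unique(S4Vectors::queryHits(hits)))
  list(kept = wt_peaks[setdiff(seq_len(nrow(wt_peaks)), shared), ,
                       drop = FALSE],
       shared_removed = wt_peaks[shared, , drop = FALSE])
}

# Normalized (tags-per-1e7) counts of a library within peak windows.
count_tags_in_peaks <- function(peaks, tags, shift) {
  shifted <- shift_tags(tags, shift)
  cnt <- numeric(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == chrom)
    p <- shifted[[chrom]]
    if (is.null(p)) p <- numeric()
    cnt[idx] <- count_in_windows(p, peaks$start[idx], peaks$end[idx])
  }
  cnt
}

#' Fold-change filter on normalized WT/KO tag counts
#'
#' For each peak window (the peak's own coordinates) the WT and KO
#' tags are counted, each scaled to a 1e7-tag library, and the peak is
#' kept iff WT/KO >= `fc_threshold` after adding the depth-scaled
#' pseudocount to both sides. Peaks with less than a
#' `fc_threshold`-fold WT excess are excluded; exactly at the
#' threshold is kept.
#'
#' @param peaks sorted [peaks_table()].
#' @param wt,ko [tag_set()]s.
#' @param params a [koin_params()].
#' @return list with `kept`, `fc_removed` and `fc_table` (per-peak
#'   normalized counts and fold change, input order).
#' @export
fold_change_filter <- function(peaks, wt, ko, params = koin_params()) {
  shift <- if (params$shift_count) params$caller$tag_shift else 0
  wt_raw <- count_tags_in_peaks(peaks, wt, shift)
  ko_raw <- count_tags_in_peaks(peaks, ko, shift)
  wt_norm <- wt_raw * 1e7 / wt$total_tags
  ko_norm <- ko_raw * 1e7 / ko$total_tags
  pc_wt <- params$fc_pseudocount * 1e7 / wt$total_tags
  pc_ko <- params$fc_pseudocount * 1e7 / ko$total_tags
  fc <- (wt_norm + pc_wt) / (ko_norm + pc_ko)
  keep <- fc >= params$fc_threshold
  tab <- data.frame(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end, wt_norm = wt_norm, ko_norm = ko_norm,
                    fold_change = fc, kept = keep,
                    stringsAsFactors = FALSE)
  list(kept = peaks[keep, , drop = FALSE],
       fc_removed = peaks[!keep, , drop = FALSE],
       fc_table = tab)
}

#' Run the full knockout-implemented normalization
#'
#' The three-step correction: (1) call WT peaks with the KO library as
#' control; (2) swap treatment and control and call KO "negative"
#' peaks; (3) discard WT peaks overlapping any negative peak, then
#' discard surviving peaks with less than a 2-fold WT/KO normalized
#' tag-count excess. What remains is the corrected peak set; the
#' correction rate is the percentage of originally called WT peaks
#' that were removed.
#'
#' @param wt,ko non-empty [tag_set()]s.
#' @param params a [koin_params()].
#' @param genome a [genome_spec()].
#' @return An object of class `koin_result`: `wt_peaks`,
#'   `ko_negative_peaks`, `shared_removed`, `fc_removed`,
#'   `corrected_peaks`, `correction_rate` (percent) and `fc_table`.
#' @export
run_koin <- function(wt, ko, params = koin_params(), genome = wt$genome) {
  wt_peaks <- call_peaks(wt, control = ko, params = params$caller,
                         genome = genome, label = "WT")
  ko_neg <- call_negative_peaks(wt, ko, params = params$caller,
                                genome = genome)
  sub <- subtract_shared(wt_peaks, ko_neg, params$overlap_rule)
  fcf <- fold_change_filter(sub$kept, wt, ko, params)
  corrected <- fcf$kept
  if (nrow(corrected)) corrected$label <- "corrected"
  n_wt <- nrow(wt_peaks)
  rate <- if (n_wt == 0) {
    warning("no WT peaks called; correction_rate defined as 0")
    0
  } else 100 * (n_wt - nrow(corrected)) / n_wt
  structure(list(wt_peaks = wt_peaks, ko_negative_peaks = ko_neg,
                 shared_removed = sub$shared_removed,
                 fc_removed = fcf$fc_removed,
                 corrected_peaks = corrected,
                 correction_rate = rate,
                 fc_table = fcf$fc_table,
                 params = params),
            class = "koin_result")
}

#' @export
print.koin_result <- function(x, ...) {
  cat("KOIN correction\n",
      "  WT peaks:        ", nrow(x$wt_peaks), "\n",
      "  KO negative:     ", nrow(x$ko_negative_peaks), "\n",
      "  shared removed:  ", nrow(x$shared_removed), "\n",
      "  FC removed:      ", nrow(x$fc_removed), "\n",
      "  corrected peaks: ", nrow(x$corrected_peaks), "\n",
      "  correction rate: ", sprintf("%.1f%%", x$correction_rate), "\n",
      sep = "")
  invisible(x)
}

#' Write all outputs of a correction run to a directory
#'
#' Emits `corrected.narrowPeak`, `wt_raw.narrowPeak`,
#' `ko_negative.narrowPeak`, `shared_removed.bed`, `fc_removed.bed`,
#' `report.tsv` (per-peak fold-change table) and `summary.json`
#' (counts, correction rate, parameters).
#'
#' @param result a `koin_result`.
#' @param dir output directory (created if needed).
#' @export
write_koin_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peaks(result$corrected_peaks, file.path(dir, "corrected.narrowPeak"))
  write_peaks(result$wt_peaks, file.path(dir, "wt_raw.narrowPeak"))
  write_peaks(result$ko_negative_peaks,
              file.path(dir, "ko_negative.narrowPeak"))
  write_peaks(result$shared_removed, file.path(dir, "shared_removed.bed"),
              dialect = "bed")
  write_peaks(result$fc_removed, file.path(dir, "fc_removed.bed"),
              dialect = "bed")
  utils::write.table(result$fc_table, file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_wt_peaks = nrow(result$wt_peaks),
    n_ko_negative_peaks = nrow(result$ko_negative_peaks),
    n_shared_removed = nrow(result$shared_removed),
    n_fc_removed = nrow(result$fc_removed),
    n_corrected_peaks = nrow(result$corrected_peaks),
    correction_rate_percent = result$correction_rate,
    parameters = result$params[c("fc_threshold", "fc_pseudocount",
                                 "overlap_rule", "shift_count")])
  summary$parameters$caller <-
    result$params$caller[!vapply(result$params$caller, is.null, TRUE)]
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
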