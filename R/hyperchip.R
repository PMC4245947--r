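#' Hyper-ChIPable detection parameters
#'
#' Hyper-ChIPable regions are euchromatic loci yielding extreme ChIP
#' enrichment regardless of the antibody used; they recur across
#' independent experiments and are a recognized class of false
#' positives. Candidates are found by ranking peaks on normalized tag
#' count and requiring recurrence across datasets.
#'
#' @param top_n peaks per dataset entering the ranking (default 25).
#' @param min_datasets minimum distinct datasets supporting a locus
#'   (default 2).
#' @param locus_merge_window bp; peaks from different datasets whose
#'   summits lie within this window are treated as the same locus
#'   (default 1000).
#' @return list of class `hyper_params`.
#' @export
hyper_params <- function(top_n = 25, min_datasets = 2,
                         locus_merge_window = 1000) {
  stopifnot(top_n >= 1, min_datasets >= 2, locus_merge_window > 0)
  structure(list(top_n = top_n, min_datasets = min_datasets,
                 locus_merge_window = locus_merge_window),
            class = "hyper_params")
}

#' Top peaks by normalized tag count
#'
#' @param peaks a [peaks_table()] carrying `norm_tag_count`.
#' @param n number of peaks to return; a shorter list is returned
#'   whole. Ties are broken by smaller p-value, then leftmost
#'   coordinate, so the ranking is deterministic.
#' @return A [peaks_table()] of (at most) the n highest-signal peaks,
#'   in rank order.
#' @export
top_ranked <- function(peaks, n = 25) {
  if (!nrow(peaks)) return(peaks)
  if (all(is.na(peaks$norm_tag_count)))
    stop("peaks carry no norm_tag_count to rank on")
  o <- order(-peaks$norm_tag_count, peaks$pvalue, peaks$chrom,
             peaks$start)
  out <- peaks[o[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loci recurring across the top-ranked peaks of several datasets
#'
#' Top-ranked peaks from all datasets are pooled and clustered by
#' summit proximity (single linkage: a new cluster starts whenever the
#' summit gap to the previous peak exceeds `locus_merge_window`).
#' Clusters supported by at least `min_datasets` distinct datasets are
#' returned as candidate hyper-ChIPable loci.
#'
#' @param top_sets named list (dataset id -> [peaks_table()], already
#'   top-ranked) with at least two entries.
#' @param params a [hyper_params()].
#' @return data frame sorted by support then total normalized count,
#'   columns `chrom`, `start`, `end` (span of member peaks), `summit`
#'   (mean member summit), `support`, `datasets`
#'   (comma-separated ids), `total_norm_count`.
#' @export
recurrent_loci <- function(top_sets, params = hyper_params()) {
  if (length(top_sets) < 2)
    stop("recurrent_loci needs at least 2 datasets")
  if (is.null(names(top_sets)) || any(!nzchar(names(top_sets))))
    names(top_sets) <- paste0("dataset", seq_along(top_sets))
  pooled <- do.call(rbind, lapply(names(top_sets), function(id) {
    p <- top_sets[[id]]
    if (!nrow(p)) return(NULL)
    data.frame(dataset = id, chrom = p$chrom, start = p$start,
               end = p$end, summit = peak_anchor(p),
               norm = p$norm_tag_count, stringsAsFactors = FALSE)
  }))
  if (is.null(pooled)) return(empty_loci())
  pooled <- pooled[order(pooled$chrom, pooled$summit), , drop = FALSE]
  new_cluster <- c(TRUE, pooled$chrom[-1] != pooled$chrom[-nrow(pooled)] |
                     diff(pooled$summit) > params$locus_merge_window)
  grp <- cumsum(new_cluster)
  loci <- do.call(rbind, lapply(split(pooled, grp), function(cl) {
    ids <- sort(unique(cl$dataset))
    data.frame(chrom = cl$chrom[1], start = min(cl$start),
               end = max(cl$end), summit = floor(mean(cl$summit)),
               support = length(ids),
               datasets = paste(ids, collapse = ","),
               total_norm_count = sum(cl$norm),
               stringsAsFactors = FALSE)
  }))
  loci <- loci[loci$support >= params$min_datasets, , drop = FALSE]
  loci <- loci[order(-loci$support, -loci$total_norm_count,
                     loci$chrom, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

empty_loci <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             summit = numeric(), support = integer(),
             datasets = character(), total_norm_count = numeric(),
             stringsAsFactors = FALSE)
}

#' Read labeled evidence tracks (BED intervals)
#'
#' @param paths named character vector, label -> BED path. Only the
#'   first three columns are used.
#' @return named list of data frames (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @export
read_evidence_tracks <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("evidence tracks must be a named vector: label = path")
  lapply(paths, function(p) {
    lines <- readLines(p)
    lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) &
                     nzchar(lines)]
    if (!length(lines))
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    f <- strsplit(lines, "[ \t]+")
    if (any(lengths(f) < 3)) stop("evidence BED line with < 3 columns")
    data.frame(chrom = vapply(f, `[[`, "", 1L),
               start = as.numeric(vapply(f, `[[`, "", 2L)),
               end = as.numeric(vapply(f, `[[`, "", 3L)),
               stringsAsFactors = FALSE)
  })
}

#' Evidence-track overlap flags for a locus
#'
#' A programmatic surrogate for browser inspection of a candidate
#' locus against regulatory annotation (DNase hypersensitivity, PolII,
#' histone marks, unrelated TF binding): each track contributes a flag
#' that is TRUE iff the locus shares at least one bp with an interval
#' of the track (0-based half-open semantics).
#'
#' @param locus list/row with `chrom`, `start`, `end`.
#' @param tracks named list of interval data frames as returned by
#'   [read_evidence_tracks()]; NULL or empty yields an empty flag map.
#' @return list with `flags` (named logical) and `n_satisfied`.
#' @export
evidence_flags <- function(locus, tracks = NULL) {
  if (is.null(tracks) || !length(tracks))
    return(list(flags = stats::setNames(logical(), character()),
                n_satisfied = 0L))
  flags <- vapply(tracks, function(tr) {
    any(tr$chrom == locus$chrom & tr$start < locus$end &
          tr$end > locus$start)
  }, TRUE)
  list(flags = flags, n_satisfied = sum(flags))
}

#' Score recurrent loci against evidence tracks and write a TSV
#'
#' @param loci data frame from [recurrent_loci()].
#' @param tracks named list from [read_evidence_tracks()] (optional).
#' @param path optional output TSV path.
#' @return the loci table with one logical column per evidence label
#'   plus `n_criteria`.
#' @export
annotate_loci_evidence <- function(loci, tracks = NULL, path = NULL) {
  if (!is.null(tracks) && length(tracks)) {
    for (lab in names(tracks)) loci[[lab]] <- FALSE
    loci$n_criteria <- 0L
    for (i in seq_len(nrow(loci))) {
      ev <- evidence_flags(loci[i, ], tracks)
      for (lab in names(ev$flags)) loci[[lab]][i] <- ev$flags[[lab]]
      loci$n_criteria[i] <- ev$n_satisfied
    }
  }
  if (!is.null(path))
    utils::write.table(loci, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  loci
}
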