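#' Annotation parameters
#'
#' @param promoter_flank bp around a TSS within which a peak summit is
#'   classified as promoter (default 1000, i.e. +/- 1 kb).
#' @param histogram_flank bp up- and downstream of the peak summit
#'   covered by tag histograms (default 2000).
#' @param histogram_bin bin width, bp (default 10); must divide
#'   `histogram_flank`.
#' @param histogram_norm_total library size histograms are scaled to
#'   (default 1e7 tags).
#' @param promoter_precedence if TRUE (default) a TSS-proximal summit
#'   is promoter even when it also falls inside a gene body.
#' @return list of class `annotation_params`.
#' @export
annotation_params <- function(promoter_flank = 1000,
                              histogram_flank = 2000,
                              histogram_bin = 10,
                              histogram_norm_total = 1e7,
                              promoter_precedence = TRUE) {
  stopifnot(promoter_flank > 0, histogram_flank > 0, histogram_bin > 0,
            histogram_norm_total > 0,
            histogram_flank %% histogram_bin == 0)
  structure(list(promoter_flank = promoter_flank,
                 histogram_flank = histogram_flank,
                 histogram_bin = histogram_bin,
                 histogram_norm_total = histogram_norm_total,
                 promoter_precedence = promoter_precedence),
            class = "annotation_params")
}

# Position used for classification: the summit (signal mode), falling
# back to the interval midpoint when no summit is recorded.
peak_anchor <- function(peaks) {
  ifelse(is.na(peaks$summit), floor((peaks$start + peaks$end) / 2),
         peaks$summit)
}

#' Classify peaks by genomic context
#'
#' Each peak summit is assigned exactly one category: `promoter` when
#' within `promoter_flank` bp of any TSS (taking precedence by
#' default), else `intronic`/`exonic` when inside a gene span (intron
#' vs exon decided by the model's intron blocks; a gene without blocks
#' is treated as all-exonic), else `intergenic`. The nearest gene by
#' TSS distance and the signed, strand-oriented distance to its TSS
#' (positive = downstream of the TSS) are reported for every peak.
#'
#' @param peaks a [peaks_table()].
#' @param genes a `gene_model` from [read_gene_model()].
#' @param params an [annotation_params()].
#' @return data frame, one row per input peak (input order):
#'   `chrom`, `summit`, `category`, `nearest_gene`, `tss_distance`,
#'   `off_model` (TRUE when the chromosome is absent from the model).
#' @export
classify_peaks <- function(peaks, genes, params = annotation_params()) {
  n <- nrow(peaks)
  anchor <- peak_anchor(peaks)
  out <- data.frame(chrom = peaks$chrom, summit = anchor,
                    category = rep("intergenic", n),
                    nearest_gene = rep(NA_character_, n),
                    tss_distance = rep(NA_real_, n),
                    off_model = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) {
      out$off_model[i] <- TRUE
      next
    }
    s <- anchor[i]
    d <- abs(s - g$tss)
    # nearest TSS; ties broken by lexicographically smaller gene_id
    near <- order(d, g$gene_id)[1]
    out$nearest_gene[i] <- g$gene_id[near]
    out$tss_distance[i] <- (s - g$tss[near]) *
      ifelse(g$strand[near] == "+", 1, -1)
    is_promoter <- d[near] <= params$promoter_flank
    inside <- which(s >= g$gene_start & s < g$gene_end)
    in_body <- length(inside) > 0
    if (is_promoter && (params$promoter_precedence || !in_body)) {
      out$category[i] <- "promoter"
    } else if (in_body) {
      host <- inside[order(g$gene_id[inside])][1]
      intr <- g$introns[[host]]
      in_intron <- nrow(intr) > 0 &&
        any(s >= intr[, 1] & s < intr[, 2])
      out$category[i] <- if (in_intron) "intronic" else "exonic"
    } else if (is_promoter) {
      out$category[i] <- "promoter"
    }
  }
  out
}

#' Peak-centered tag histograms
#'
#' Counts shifted tags in fixed-width bins across +/-
#' `histogram_flank` bp of every peak summit and scales each count to
#' a `histogram_norm_total`-tag library, making profiles comparable
#' across libraries of different depth.
#'
#' @param peaks a [peaks_table()] with summits.
#' @param tags a [tag_set()].
#' @param params an [annotation_params()].
#' @param shift bp tags are shifted before counting (default 75).
#' @return list with `matrix` (rows = peaks in input order, columns =
#'   bins; column names are bin-start offsets relative to the summit)
#'   and `profile` (column means).
#' @export
tag_histogram <- function(peaks, tags, params = annotation_params(),
                          shift = 75) {
  flank <- params$histogram_flank
  bin <- params$histogram_bin
  offsets <- seq(-flank, flank - bin, by = bin)
  nb <- length(offsets)
  shifted <- shift_tags(tags, shift)
  scale <- params$histogram_norm_total / tags$total_tags
  m <- matrix(0, nrow = nrow(peaks), ncol = nb,
              dimnames = list(NULL, offsets))
  anchor <- peak_anchor(peaks)
  for (i in seq_len(nrow(peaks))) {
    p <- shifted[[peaks$chrom[i]]]
    if (is.null(p) || !length(p)) next
    edges <- anchor[i] + c(offsets, flank)
    m[i, ] <- count_in_windows(p, edges[-length(edges)], edges[-1]) * scale
  }
  list(matrix = m, profile = colMeans(m))
}

#' Write a tag histogram matrix as TSV with a bin-offset header
#' @param hist result of [tag_histogram()].
#' @param path output path.
#' @export
write_histogram <- function(hist, path) {
  df <- as.data.frame(hist$matrix)
  names(df) <- colnames(hist$matrix)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Category accounting before vs after correction
#'
#' @param before,after [peaks_table()]s (e.g. raw WT and corrected).
#' @param genes a `gene_model`.
#' @param params an [annotation_params()].
#' @return data frame with one row per category: `n_before`,
#'   `n_after`, `percent_remaining` (NA when `n_before` is 0).
#' @export
category_report <- function(before, after, genes,
                            params = annotation_params()) {
  cats <- c("promoter", "intronic", "exonic", "intergenic")
  cb <- factor(classify_peaks(before, genes, params)$category,
               levels = cats)
  ca <- factor(classify_peaks(after, genes, params)$category,
               levels = cats)
  nb <- as.integer(table(cb))
  na_ <- as.integer(table(ca))
  data.frame(category = cats, n_before = nb, n_after = na_,
             percent_remaining = ifelse(nb == 0, NA_real_,
                                        100 * na_ / nb),
             stringsAsFactors = FALSE)
}
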