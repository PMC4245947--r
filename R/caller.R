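#' Peak-caller parameters
#'
#' Defaults follow the classic single-end TF ChIP-seq setup: 150 bp
#' fragments, tags shifted by half a fragment, a 150 bp scanning
#' bandwidth and a raw Poisson p-value threshold of 1e-4. The local
#' background lambda is the maximum over a genome-wide rate and
#' window-local rates: 5 kb and 10 kb windows when the sample is its
#' own background, with an additional 1 kb window when an independent
#' control is supplied (a control can be trusted at short range where
#' the treatment's own signal would contaminate the estimate).
#'
#' @param fragment_size sonication fragment size d, bp.
#' @param tag_shift bp each tag is moved toward the fragment midpoint;
#'   default `fragment_size / 2`.
#' @param bandwidth scanning window width, bp.
#' @param pvalue_threshold raw Poisson p-value cutoff for reported
#'   peaks.
#' @param effective_genome_size optional override of the genome spec's
#'   effective size, bp.
#' @param lambda_levels_no_control local window widths (bp) used when
#'   calling without a control.
#' @param lambda_levels_with_control local window widths used when a
#'   control is supplied.
#' @param merge_gap peaks separated by at most this many bp are merged
#'   (0 merges book-ended peaks).
#' @return list of class `caller_params`.
#' @export
caller_params <- function(fragment_size = 150,
                          tag_shift = NULL,
                          bandwidth = 150,
                          pvalue_threshold = 1e-4,
                          effective_genome_size = NULL,
                          lambda_levels_no_control = c(5000, 10000),
                          lambda_levels_with_control = c(1000, 5000, 10000),
                          merge_gap = 0) {
  if (is.null(tag_shift)) tag_shift <- fragment_size / 2
  stopifnot(fragment_size > 0, tag_shift >= 0, bandwidth > 0,
            pvalue_threshold > 0, pvalue_threshold < 1,
            all(lambda_levels_no_control > 0),
            all(lambda_levels_with_control > 0), merge_gap >= 0)
  structure(list(fragment_size = fragment_size, tag_shift = tag_shift,
                 bandwidth = bandwidth,
                 pvalue_threshold = pvalue_threshold,
                 effective_genome_size = effective_genome_size,
                 lambda_levels_no_control = lambda_levels_no_control,
                 lambda_levels_with_control = lambda_levels_with_control,
                 merge_gap = merge_gap),
            class = "caller_params")
}

#' Poisson upper-tail probability P(X >= count)
#'
#' Thin, numerically stable wrapper around the regularized upper
#' incomplete gamma function (via [stats::ppois()]); vectorized over
#' both arguments.
#'
#' @param count non-negative integer observed tag count.
#' @param lam positive Poisson mean.
#' @return P(X >= count) for X ~ Poisson(lam).
#' @export
poisson_sf <- function(count, lam) {
  if (any(lam <= 0)) stop("poisson_sf: lam must be > 0")
  if (any(count < 0)) stop("poisson_sf: count must be >= 0")
  stats::ppois(count - 1, lam, lower.tail = FALSE)
}

# Smallest m with P(X >= m | lam) < p: the seed tag count a scanning
# window must reach before it is worth testing.
min_seed_tags <- function(lam, p) {
  m <- stats::qpois(p, lam, lower.tail = FALSE) + 1
  while (m > 1 && poisson_sf(m - 1, lam) < p) m <- m - 1
  while (poisson_sf(m, lam) >= p) m <- m + 1
  m
}

#' Candidate enriched regions from a sliding-window scan
#'
#' Slides windows of `bandwidth` bp in 10 bp steps across one
#' chromosome and merges overlapping windows holding at least
#' `min_tags` shifted tags into maximal candidate regions.
#'
#' @param shifted sorted numeric vector of shifted tag positions on one
#'   chromosome.
#' @param chrom_length chromosome length, bp.
#' @param bandwidth window width, bp.
#' @param min_tags seed threshold per window.
#' @param step window step, bp.
#' @return data frame with columns `start`, `end`, `tag_count` (exact
#'   shifted-tag count within the region).
#' @export
candidate_regions <- function(shifted, chrom_length, bandwidth, min_tags,
                              step = 10) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      tag_count = numeric())
  if (!length(shifted)) return(empty)
  win_start <- seq(0, max(0, chrom_length - bandwidth), by = step)
  cnt <- count_in_windows(shifted, win_start,
                          pmin(win_start + bandwidth, chrom_length))
  sig <- win_start[cnt >= min_tags]
  if (!length(sig)) return(empty)
  # windows overlap iff their starts differ by less than the width
  grp <- cumsum(c(TRUE, diff(sig) >= bandwidth))
  start <- tapply(sig, grp, min)
  end <- pmin(tapply(sig, grp, max) + bandwidth, chrom_length)
  data.frame(start = as.numeric(start), end = as.numeric(end),
             tag_count = count_in_windows(shifted, start, end),
             row.names = NULL)
}

# Vectorized local lambda over a set of regions on one chromosome.
# bg_shifted: sorted shifted background positions on the chromosome;
# bg_total: background library size; levels: local window widths.
lambda_local_vec <- function(start, end, bg_shifted, bg_total, levels,
                             depth_ratio, eff_size, floor_lambda = 1e-6) {
  width <- end - start
  lam_bg <- bg_total * depth_ratio * width / eff_size
  lam <- lam_bg
  mid <- (start + end) / 2
  for (w in levels) {
    cnt <- count_in_windows(bg_shifted, mid - w / 2, mid + w / 2)
    lam <- pmax(lam, cnt * depth_ratio * width / w)
  }
  pmax(lam, lam_bg, floor_lambda)
}

#' Local Poisson background rate for a candidate region
#'
#' The expected background tag count for a region is the maximum of a
#' genome-wide estimate (library size scaled by region width over the
#' effective genome size) and window-local estimates: background tags
#' in a window of each requested width centered on the region
#' midpoint, rescaled to the region width and to treatment depth. The
#' maximum guards against locally elevated background (open chromatin,
#' copy-number inflation) that a genome-wide rate would miss.
#'
#' @param region list or data frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param background_tags a [tag_set()] providing the background.
#' @param levels numeric vector of local window widths, bp.
#' @param depth_ratio treatment_total / background_total (1 when the
#'   background is the treatment itself).
#' @param genome a [genome_spec()]; supplies the effective genome
#'   size.
#' @param shift bp applied to background tags before counting.
#' @return The local lambda (expected background tags in the region),
#'   floored at the genome-wide rate and at 1e-6.
#' @export
lambda_local <- function(region, background_tags, levels, depth_ratio,
                         genome, shift = 75) {
  stopifnot(depth_ratio > 0)
  shifted <- shift_tags(background_tags, shift)
  bg <- shifted[[region$chrom]]
  if (is.null(bg)) bg <- numeric()
  lambda_local_vec(region$start, region$end, bg,
                   background_tags$total_tags, levels, depth_ratio,
                   genome$effective_genome_size)
}

# Summit: 10-bp-bin position of maximum shifted-tag density within
# [start, end); leftmost bin on ties; returns the bin midpoint.
region_summit <- function(shifted, start, end, bin = 10) {
  edges <- seq(start, end, by = bin)
  if (edges[length(edges)] < end) edges <- c(edges, end)
  cnt <- count_in_windows(shifted, edges[-length(edges)], edges[-1])
  i <- which.max(cnt)
  min(floor((edges[i] + edges[i + 1]) / 2), end - 1)
}

#' Call peaks with a local-Poisson background model
#'
#' Tags are shifted toward the fragment midpoint, candidate regions
#' are found by a sliding-window scan, each region's tag count is
#' tested against its local background lambda with a one-sided Poisson
#' test, and regions below the p-value threshold are reported as peaks
#' with a 10-bp-resolution summit. When `control` is supplied its tags
#' define the background (depth-scaled to the treatment library) and
#' the 1 kb local window joins the lambda computation; without a
#' control the treatment is its own background at 5/10 kb only.
#'
#' @param treatment a non-empty [tag_set()].
#' @param control optional [tag_set()] (e.g. a knockout library); NULL
#'   calls without a control.
#' @param params a [caller_params()].
#' @param genome a [genome_spec()].
#' @param label label stored on the returned peaks.
#' @return A [peaks_table()] of non-overlapping peaks sorted by
#'   (chrom, start).
#' @export
call_peaks <- function(treatment, control = NULL,
                       params = caller_params(), genome = treatment$genome,
                       label = "WT") {
  stopifnot(inherits(treatment, "tag_set"))
  if (treatment$total_tags == 0) stop("treatment tag set is empty")
  if (!is.null(control) && control$total_tags == 0) {
    warning("control tag set is empty; falling back to the treatment ",
            "as its own background")
    control <- NULL
  }
  eff_size <- params$effective_genome_size
  if (is.null(eff_size)) eff_size <- genome$effective_genome_size
  treat_shifted <- shift_tags(treatment, params$tag_shift)
  if (is.null(control)) {
    bg_shifted <- treat_shifted
    bg_total <- treatment$total_tags
    levels <- params$lambda_levels_no_control
  } else {
    bg_shifted <- shift_tags(control, params$tag_shift)
    bg_total <- control$total_tags
    levels <- params$lambda_levels_with_control
  }
  depth_ratio <- treatment$total_tags / bg_total
  lam_bg_win <- treatment$total_tags * params$bandwidth / eff_size
  min_tags <- min_seed_tags(max(lam_bg_win, 1e-6), params$pvalue_threshold)

  res <- lapply(genome$chrom_names, function(chrom) {
    ts <- treat_shifted[[chrom]]
    if (is.null(ts) || !length(ts)) return(NULL)
    reg <- candidate_regions(ts, genome$chrom_lengths[[chrom]],
                             params$bandwidth, min_tags)
    if (!nrow(reg)) return(NULL)
    bg <- bg_shifted[[chrom]]
    if (is.null(bg)) bg <- numeric()
    region_stats <- function(reg) {
      lam <- lambda_local_vec(reg$start, reg$end, bg, bg_total, levels,
                              depth_ratio, eff_size)
      list(lam = lam, pv = poisson_sf(reg$tag_count, lam))
    }
    st <- region_stats(reg)
    keep <- st$pv < params$pvalue_threshold
    if (!any(keep)) return(NULL)
    reg <- reg[keep, , drop = FALSE]
    merged <- merge_close_regions(reg, params$merge_gap, ts)
    if (nrow(merged) < nrow(reg)) {
      reg <- merged
      st <- region_stats(reg)
    } else {
      st <- list(lam = st$lam[keep], pv = st$pv[keep])
    }
    lam <- st$lam; pv <- st$pv
    summit <- mapply(region_summit, start = reg$start, end = reg$end,
                     MoreArgs = list(shifted = ts))
    data.frame(chrom = chrom, start = reg$start, end = reg$end,
               summit = summit, tag_count = reg$tag_count,
               lambda_local = lam, pvalue = pv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  else
    res$norm_tag_count <- res$tag_count * 1e7 / treatment$total_tags
  res$label <- rep(label, nrow(res))
  peaks_table(res, chrom_order = genome$chrom_names)
}

# Merge regions whose gap is <= merge_gap; counts recomputed exactly.
merge_close_regions <- function(reg, merge_gap, shifted) {
  if (nrow(reg) < 2) return(reg)
  gap_break <- c(TRUE, reg$start[-1] - reg$end[-nrow(reg)] > merge_gap)
  grp <- cumsum(gap_break)
  if (max(grp) == nrow(reg)) return(reg)
  start <- as.numeric(tapply(reg$start, grp, min))
  end <- as.numeric(tapply(reg$end, grp, max))
  data.frame(start = start, end = end,
             tag_count = count_in_windows(shifted, start, end),
             row.names = NULL)
}
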