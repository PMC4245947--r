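#' Genome specification
#'
#' A light container describing the reference genome a run operates on:
#' the ordered chromosome names, their lengths, and the effective genome
#' size used as the denominator of the genome-wide Poisson background
#' rate. The effective size is usually smaller than the assembly length
#' because repetitive sequence is not uniquely mappable; for the mouse
#' genome the conventional value is 1.87e9 bp.
#'
#' @param chrom_names character vector of chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths in bp,
#'   parallel to `chrom_names`.
#' @param effective_genome_size numeric scalar, bp. Defaults to the sum
#'   of `chrom_lengths` (appropriate for fully mappable synthetic
#'   genomes).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_names, chrom_lengths,
                        effective_genome_size = sum(chrom_lengths)) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("duplicate chromosome names: ",
         paste(unique(chrom_names[duplicated(chrom_names)]), collapse = ", "))
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  effective_genome_size <- as.numeric(effective_genome_size)
  if (length(effective_genome_size) != 1 || effective_genome_size <= 0)
    stop("effective_genome_size must be a single positive number")
  if (effective_genome_size > sum(chrom_lengths))
    stop("effective_genome_size exceeds total genome length")
  names(chrom_lengths) <- chrom_names
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = chrom_lengths,
                 effective_genome_size = effective_genome_size),
            class = "genome_spec")
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV (name, length), the format emitted by UCSC
#' `fetchChromSizes` and `samtools faidx` derived indices.
#'
#' @param path file path.
#' @param effective_genome_size optional override; defaults to the sum
#'   of the listed lengths.
#' @return A [genome_spec()].
#' @export
read_chrom_sizes <- function(path, effective_genome_size = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (is.null(effective_genome_size))
    effective_genome_size <- sum(df$length)
  genome_spec(df$chrom, df$length, effective_genome_size)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total,",
      "effective size", format(x$effective_genome_size, big.mark = ","),
      "bp\n")
  invisible(x)
}

write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(chrom = genome$chrom_names,
               length = format(genome$chrom_lengths, scientific = FALSE,
                               trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
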