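# Contact-matrix data model: construction, COO text I/O, rebinning,
# low-coverage bin filtering.
#
# Counts are held as a dense symmetric matrix; at the bin counts this package
# targets (a few thousand bins) this is both faster and simpler than sparse
# storage, and the on-disk format remains sparse upper-triangular COO.

#' Construct a contact matrix
#'
#' @param bins Bin table from [bin_table()].
#' @param counts Symmetric nonnegative numeric matrix, one row/column per bin.
#' @param valid Logical per-bin validity mask (default: bins with nonzero
#'   marginal count).
#' @return An object of class `contact_matrix` with fields `bins`, `counts`,
#'   `valid`, and (after balancing) `biases`, `normalized`, `norm_method`.
#' @export
contact_matrix <- function(bins, counts, valid = NULL) {
  n <- length(bins)
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == n, ncol(counts) == n)
  if (any(counts < 0)) stop("contact counts must be nonnegative")
  if (max(abs(counts - t(counts))) > 1e-8)
    stop("contact counts must be symmetric")
  if (is.null(valid)) valid <- rowSums(counts) > 0
  stopifnot(length(valid) == n)
  structure(list(bins = bins, counts = counts, valid = as.logical(valid),
                 biases = NULL, normalized = NULL, norm_method = NULL),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %d bins (%d valid), bin size %d bp, %s counts%s\n",
    length(x$bins), sum(x$valid), bin_size(x$bins),
    format(sum(x$counts[upper.tri(x$counts, diag = TRUE)]),
           big.mark = ","),
    if (!is.null(x$normalized)) paste0(", ", x$norm_method, "-normalized")
    else ""))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

# integer index vector of the bins on one chromosome
chrom_bin_index <- function(bins) {
  split(seq_along(bins), as.character(GenomicRanges::seqnames(bins)))
}

#' Write a contact matrix as COO text with sidecar bin table
#'
#' The COO file holds `bin1_id`, `bin2_id`, `count` for the nonzero upper
#' triangle, with 0-based bin ids (cooler convention). The bin table is BED3
#' and the chromosome sizes a two-column file.
#'
#' @param cm A `contact_matrix`.
#' @param coo,bins_bed,chrom_sizes Output paths; `chrom_sizes = NULL` skips it.
#' @return Invisibly, `coo`.
#' @export
write_contact_matrix <- function(cm, coo, bins_bed, chrom_sizes = NULL) {
  m <- cm$counts
  keep <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(bin1 = keep[, 1] - 1L, bin2 = keep[, 2] - 1L,
                   count = m[keep])
  df <- df[order(df$bin1, df$bin2), ]
  utils::write.table(df, coo, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_intervals(GenomicRanges::granges(cm$bins), bins_bed, format = "bed")
  if (!is.null(chrom_sizes))
    write_chrom_sizes(GenomeInfoDb::seqlengths(cm$bins), chrom_sizes)
  invisible(coo)
}

#' Read a contact matrix from COO text
#'
#' @param coo COO file (`bin1_id`, `bin2_id`, `count`, 0-based ids).
#' @param bins_bed BED file of bins, in bin-id order.
#' @param chrom_sizes Optional chrom.sizes path; when absent, chromosome
#'   lengths are taken from the last bin end of each chromosome.
#' @return A `contact_matrix` of raw counts.
#' @export
read_contact_matrix <- function(coo, bins_bed, chrom_sizes = NULL) {
  b <- rtracklayer::import(bins_bed, format = "BED")
  sizes <- if (!is.null(chrom_sizes)) read_chrom_sizes(chrom_sizes) else
    vapply(split(GenomicRanges::end(b),
                 as.character(GenomicRanges::seqnames(b))), max, 0)
  bs <- max(GenomicRanges::width(b))
  bins <- bin_table(sizes[unique(as.character(GenomicRanges::seqnames(b)))],
                    bs)
  if (length(bins) != length(b))
    stop("bin table does not tile the given chromosome sizes")
  df <- utils::read.table(coo, sep = "\t", header = FALSE,
                          col.names = c("bin1", "bin2", "count"))
  n <- length(bins)
  if (any(df$bin1 < 0 | df$bin1 >= n | df$bin2 < 0 | df$bin2 >= n))
    stop("COO bin id outside the bin table")
  m <- matrix(0, n, n)
  m[cbind(df$bin1 + 1L, df$bin2 + 1L)] <- df$count
  m[cbind(df$bin2 + 1L, df$bin1 + 1L)] <- df$count
  contact_matrix(bins, m)
}

#' Aggregate a contact matrix to a coarser bin size
#'
#' Counts are summed into the coarser bins (assignment by bin start
#' coordinate). Any previous balancing is dropped.
#'
#' @param cm A `contact_matrix`.
#' @param new_bin_size Target bin width in bp (need not be a multiple of the
#'   current width).
#' @return A raw-count `contact_matrix` at the coarser resolution.
#' @export
rebin <- function(cm, new_bin_size) {
  old_bs <- bin_size(cm$bins)
  if (new_bin_size < old_bs) stop("can only rebin to a coarser resolution")
  sizes <- GenomeInfoDb::seqlengths(cm$bins)
  bins <- bin_table(sizes, new_bin_size)
  mids <- (GenomicRanges::start(cm$bins) + GenomicRanges::end(cm$bins)) / 2
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(GenomicRanges::seqnames(cm$bins),
                           IRanges::IRanges(floor(mids), width = 1L)),
    bins, select = "first")
  if (anyNA(hit)) stop("bin could not be assigned to a coarser bin")
  g <- factor(hit, levels = seq_along(bins))
  m <- rowsum(cm$counts, g)
  m <- t(rowsum(t(m), g))
  dimnames(m) <- NULL
  contact_matrix(bins, m)
}

#' Mask low-coverage bins
#'
#' Bins whose marginal count is below `fraction` times the median marginal of
#' nonzero-coverage bins are masked. Idempotent; previously masked bins stay
#' masked.
#'
#' @param cm A `contact_matrix` with raw counts.
#' @param fraction Coverage threshold as a fraction of the median (default
#'   0.10).
#' @return The updated `contact_matrix`.
#' @export
filter_low_coverage <- function(cm, fraction = 0.10) {
  marg <- rowSums(cm$counts)
  nonzero <- marg > 0
  med <- stats::median(marg[nonzero])
  keep <- cm$valid & nonzero & (marg >= fraction * med)
  if (!any(keep)) stop("matrix empty after filtering")
  cm$valid <- keep
  cm
}
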