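# A/B compartments: pericentromeric-heterochromatin mask construction,
# compartment eigenvector with GC orientation, saddle-plot
# compartmentalization.

#' Pericentromeric heterochromatin mask from two enrichment tracks
#'
#' Bins enriched (score above `threshold`, log-ratio convention) in both
#' tracks are selected; runs separated by gaps smaller than `merge_gap` are
#' merged; regions smaller than `min_width` are removed; surviving regions
#' within `final_merge` of each other are merged; finally the largest
#' remaining region per chromosome is emitted.
#'
#' @param track_a,track_b `GRanges` with a `score` column on the same bins
#'   (typically 10-kb bins of log2 sample/input enrichment).
#' @param threshold Enrichment threshold (default 0).
#' @param merge_gap,min_width,final_merge Rule parameters in bp.
#' @return `GRanges`, one region per chromosome that had enriched bins;
#'   chromosomes without enriched bins are skipped with a warning.
#' @export
heterochromatin_mask <- function(track_a, track_b, threshold = 0,
                                 merge_gap = 25000, min_width = 20000,
                                 final_merge = 100000) {
  stopifnot(length(track_a) == length(track_b))
  enriched <- track_a[!is.na(track_a$score) & !is.na(track_b$score) &
                        track_a$score > threshold &
                        track_b$score > threshold]
  chroms <- unique(as.character(GenomicRanges::seqnames(track_a)))
  out <- list()
  for (ch in chroms) {
    e <- enriched[as.character(GenomicRanges::seqnames(enriched)) == ch]
    if (!length(e)) {
      warning("no enriched bins on chromosome ", ch)
      next
    }
    r <- merge_within(GenomicRanges::granges(e), merge_gap, strict = TRUE)
    r <- r[GenomicRanges::width(r) >= min_width]
    if (!length(r)) {
      warning("no region survives the size filter on chromosome ", ch)
      next
    }
    r <- merge_within(r, final_merge, strict = FALSE)
    out[[ch]] <- r[which.max(GenomicRanges::width(r))]
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(out)))
}

# Merge sorted same-chromosome intervals whose gap is < gap (strict) or
# <= gap (non-strict).
merge_within <- function(gr, gap, strict = TRUE) {
  gr <- sort(gr)
  if (length(gr) < 2) return(gr)
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  gaps <- s[-1] - cummax_end(e) - 1
  new_cluster <- if (strict) gaps >= gap else gaps > gap
  cl <- cumsum(c(1, new_cluster))
  starts <- tapply(s, cl, min)
  ends <- tapply(e, cl, max)
  GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr))[1],
                         IRanges::IRanges(as.vector(starts),
                                          as.vector(ends)))
}

cummax_end <- function(e) cummax(e)[-length(e)]

#' Compartment eigenvector
#'
#' Per chromosome: masked and invalid bins are removed, the observed/expected
#' matrix is correlated column-wise (Pearson), and the eigenvector of the
#' correlation matrix with the largest-magnitude eigenvalue is taken. The
#' sign is flipped so the eigenvector correlates positively with GC content
#' (A = active = high GC by convention). Masked or degenerate bins carry 0.
#'
#' @param cm A balanced `contact_matrix`.
#' @param gc_track Per-bin GC values (numeric vector aligned to the bins, or
#'   `GRanges` with a `score` column).
#' @param mask Optional `GRanges` of regions to exclude (e.g.
#'   [heterochromatin_mask()] output).
#' @param min_bins Chromosomes with fewer valid bins are skipped with a
#'   warning.
#' @return Bin `GRanges` with a signed `score` column (0 at masked bins).
#' @export
compartment_eigenvector <- function(cm, gc_track, mask = NULL,
                                    min_bins = 10L) {
  oe <- observed_expected(cm)
  gc <- track_values(gc_track, cm$bins)
  n <- length(cm$bins)
  masked <- if (!is.null(mask) && length(mask))
    seq_len(n) %in% bins_overlapping(cm$bins, mask) else rep(FALSE, n)
  values <- rep(0, n)
  idx <- chrom_bin_index(cm$bins)
  for (ch in names(idx)) {
    ix <- idx[[ch]]
    ok <- cm$valid[ix] & !masked[ix]
    use <- ix[ok]
    if (length(use) < min_bins) {
      warning("fewer than ", min_bins, " valid bins on chromosome ", ch,
              "; skipped")
      next
    }
    sub <- oe$values[use, use, drop = FALSE]
    sub[is.na(sub)] <- 0
    sds <- apply(sub, 2, stats::sd)
    nz <- sds > 0
    if (sum(nz) < min_bins) next
    cc <- suppressWarnings(stats::cor(sub[nz, nz, drop = FALSE]))
    cc[is.na(cc)] <- 0
    eg <- eigen(cc, symmetric = TRUE)
    lead <- which.max(abs(eg$values))
    ev <- eg$vectors[, lead]
    g <- gc[use][nz]
    if (sum(stats::complete.cases(ev, g)) > 2) {
      r <- suppressWarnings(stats::cor(ev, g, use = "complete.obs"))
      if (!is.na(r) && r < 0) ev <- -ev
    }
    values[use[nz]] <- ev
  }
  out <- GenomicRanges::granges(cm$bins)
  out$score <- values
  out
}

track_values <- function(track, bins) {
  if (is.numeric(track)) {
    stopifnot(length(track) == length(bins))
    return(track)
  }
  bin_track(track, bins, reducer = "mean")
}

#' Saddle plot and compartmentalization strength
#'
#' Bins with nonzero reference eigenvector values are ranked and cut into
#' `n_quantiles` equal-count groups (most negative first); entry (p, q) of
#' the saddle matrix is the mean cis observed/expected value over pixel
#' pairs in groups p and q. Zero-eigenvector bins are collapsed into one
#' extra trailing row/column. Strength is
#' (mean BB corner + mean AA corner) / (mean of the two AB corners).
#'
#' @param oe An `oe_matrix` from [observed_expected()].
#' @param reference Reference eigenvector (numeric per bin or `GRanges`
#'   with `score`).
#' @param n_quantiles Number of eigenvector quantile groups.
#' @param corner_size Corner block size used for the strength ratio.
#' @return List with `matrix` (the (n_quantiles+1)-square saddle, last
#'   row/column = collapsed zero bins) and `strength`.
#' @export
saddle <- function(oe, reference, n_quantiles = 50L, corner_size = 1L) {
  ev <- track_values(reference, oe$bins)
  ev[is.na(ev)] <- 0
  if (all(ev == 0)) stop("all reference eigenvector values are zero")
  nq <- as.integer(n_quantiles)
  group <- rep(NA_integer_, length(ev))
  nz <- which(ev != 0 & oe$valid)
  rk <- rank(ev[nz], ties.method = "first")
  group[nz] <- as.integer(cut(rk, breaks = nq, labels = FALSE))
  group[ev == 0 & oe$valid] <- nq + 1L  # collapsed zero row/column
  sums <- matrix(0, nq + 1, nq + 1)
  cnts <- matrix(0, nq + 1, nq + 1)
  idx <- chrom_bin_index(oe$bins)
  for (ch in names(idx)) {
    ix <- idx[[ch]]
    g <- group[ix]
    keep <- !is.na(g)
    ix <- ix[keep]; g <- g[keep]
    if (length(ix) < 2) next
    sub <- oe$values[ix, ix, drop = FALSE]
    fin <- is.finite(sub)
    sub[!fin] <- 0
    agg <- matrix(0, nq + 1, length(ix))
    agg[cbind(g, seq_along(ix))] <- 1
    sums <- sums + agg %*% sub %*% t(agg)
    cnts <- cnts + agg %*% (fin + 0) %*% t(agg)
  }
  sm <- ifelse(cnts > 0, sums / cnts, NA_real_)
  cs <- as.integer(corner_size)
  bb <- mean(sm[seq_len(cs), seq_len(cs)], na.rm = TRUE)
  aa <- mean(sm[nq - cs + seq_len(cs), nq - cs + seq_len(cs)], na.rm = TRUE)
  ab <- mean(sm[seq_len(cs), nq - cs + seq_len(cs)], na.rm = TRUE)
  ba <- mean(sm[nq - cs + seq_len(cs), seq_len(cs)], na.rm = TRUE)
  strength <- (bb + aa) / (ab + ba)
  list(matrix = sm, strength = strength)
}
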