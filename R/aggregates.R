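# Aggregate (meta-region) analysis: domain rescaling, loop APA,
# enhancer-promoter contact quantification and cross-condition comparison.

#' Area-weighted rescaling of a square matrix
#'
#' Maps a k x k matrix onto a p x p grid; each target pixel is the
#' overlap-area-weighted mean of the source pixels it covers (missing-aware).
#' A constant input yields a constant output.
#'
#' @param m Square numeric matrix (may contain NA).
#' @param p Target dimension.
#' @return p x p numeric matrix.
#' @export
rescale_matrix <- function(m, p) {
  k <- nrow(m)
  stopifnot(ncol(m) == k)
  w <- overlap_weights(k, p)
  fin <- is.finite(m)
  m0 <- ifelse(fin, m, 0)
  num <- w %*% m0 %*% t(w)
  den <- w %*% (fin + 0) %*% t(w)
  ifelse(den > 0, num / den, NA_real_)
}

# p x k matrix of overlap lengths between target cell a and source cell i
# on the unit interval.
overlap_weights <- function(k, p) {
  w <- matrix(0, p, k)
  for (a in seq_len(p)) {
    lo <- (a - 1) / p; hi <- a / p
    for (i in seq_len(k)) {
      ov <- min(hi, i / k) - max(lo, (i - 1) / k)
      if (ov > 0) w[a, i] <- ov
    }
  }
  w
}

#' Aggregate observed/expected signal over domains
#'
#' Each domain window (the domain extended by `flank_fraction` of its length
#' on both sides) is extracted from the O/E matrix, rescaled to
#' `n_pixels` x `n_pixels` by area-weighted interpolation, and averaged
#' elementwise across domains (missing-aware).
#'
#' @param oe An `oe_matrix`.
#' @param domains `GRanges` of domains (>= 3 bins at this resolution).
#' @param n_pixels Output grid dimension.
#' @param flank_fraction Flank size as a fraction of domain length.
#' @return List with `matrix` (the aggregate grid) and `n` (domains used).
#' @export
aggregate_domains <- function(oe, domains, n_pixels = 45L,
                              flank_fraction = 0.5) {
  if (!length(domains)) stop("empty domain list")
  bs <- bin_size(oe$bins)
  idx <- chrom_bin_index(oe$bins)
  acc <- matrix(0, n_pixels, n_pixels)
  cnt <- matrix(0, n_pixels, n_pixels)
  used <- 0L
  for (k in seq_along(domains)) {
    ch <- as.character(GenomicRanges::seqnames(domains))[k]
    if (!ch %in% names(idx)) next
    ix <- idx[[ch]]
    d_start <- GenomicRanges::start(domains)[k]
    d_end <- GenomicRanges::end(domains)[k]
    len <- d_end - d_start + 1
    if (len < 3 * bs) next
    w_start <- d_start - flank_fraction * len
    w_end <- d_end + flank_fraction * len
    b_lo <- floor((w_start - 1) / bs) + 1
    b_hi <- ceiling(w_end / bs)
    if (b_lo < 1 || b_hi > length(ix)) next
    sub <- oe$values[ix[b_lo:b_hi], ix[b_lo:b_hi], drop = FALSE]
    r <- rescale_matrix(sub, n_pixels)
    fin <- is.finite(r)
    acc[fin] <- acc[fin] + r[fin]
    cnt <- cnt + fin
    used <- used + 1L
  }
  if (!used) stop("no usable domains at this resolution")
  list(matrix = ifelse(cnt > 0, acc / cnt, NA_real_), n = used)
}

#' Aggregate peak analysis of loops
#'
#' A fixed (2 * window_bins + 1)^2 window is extracted around each
#' anchor-pair pixel and averaged across loops. `loop_strength` is the
#' center pixel over the mean of the 3 x 3 corner block on the
#' farther-from-diagonal side of the window (distal background).
#'
#' @param oe An `oe_matrix`.
#' @param loops `Pairs` of anchor `GRanges` or a BEDPE-style data.frame.
#' @param window_bins Half-window in bins.
#' @return List with `matrix`, `loop_strength`, `n` (loops used) and
#'   `n_skipped` (pairs too close to the diagonal or out of range).
#' @export
aggregate_loops <- function(oe, loops, window_bins = 10L) {
  loops <- as_anchor_pairs(loops)
  w <- as.integer(window_bins)
  a1 <- anchor_bin(oe$bins, S4Vectors::first(loops))
  a2 <- anchor_bin(oe$bins, S4Vectors::second(loops))
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  idx <- chrom_bin_index(oe$bins)
  chrom_of <- as.character(GenomicRanges::seqnames(oe$bins))
  size <- 2 * w + 1
  acc <- matrix(0, size, size)
  cnt <- matrix(0, size, size)
  centers <- numeric()
  backgrounds <- numeric()
  used <- 0L; skipped <- 0L
  for (k in seq_along(a1)) {
    i <- a1[k]; j <- a2[k]
    same_chrom <- chrom_of[i] == chrom_of[j]
    if (!same_chrom || (j - i) < w + 1) { skipped <- skipped + 1L; next }
    n_chr <- max(which(chrom_of == chrom_of[i]))
    lo_chr <- min(which(chrom_of == chrom_of[i]))
    if (i - w < lo_chr || j + w > n_chr) { skipped <- skipped + 1L; next }
    sub <- oe$values[(i - w):(i + w), (j - w):(j + w)]
    fin <- is.finite(sub)
    acc[fin] <- acc[fin] + sub[fin]
    cnt <- cnt + fin
    used <- used + 1L
  }
  if (!used) stop("all loop anchors too close to the diagonal or unusable")
  if (skipped) warning(skipped, " anchor pair(s) excluded")
  grid <- ifelse(cnt > 0, acc / cnt, NA_real_)
  center <- grid[w + 1, w + 1]
  bg <- mean(grid[1:3, (size - 2):size], na.rm = TRUE)
  list(matrix = grid, loop_strength = center / bg, n = used,
       n_skipped = skipped)
}

as_anchor_pairs <- function(x) {
  if (methods::is(x, "Pairs")) return(x)
  if (is.data.frame(x)) {
    return(S4Vectors::Pairs(
      GenomicRanges::GRanges(x$chrom1,
                             IRanges::IRanges(x$start1 + 1, x$end1)),
      GenomicRanges::GRanges(x$chrom2,
                             IRanges::IRanges(x$start2 + 1, x$end2))))
  }
  stop("loops must be a Pairs object or a BEDPE-style data.frame")
}

#' Per-pair enhancer-promoter contact values
#'
#' Pairs separated by less than `min_separation` are dropped; the center
#' value of each remaining pair is the O/E value at the
#' (enhancer-bin, promoter-bin) pixel, averaged over all spanned bins when a
#' feature covers more than one bin.
#'
#' @param oe An `oe_matrix`.
#' @param pairs `Pairs` of (enhancer, promoter) `GRanges`.
#' @param min_separation Minimum edge-to-edge separation in bp.
#' @return data.frame with the pair coordinates, `separation` and `value`.
#' @export
ep_contact_table <- function(oe, pairs, min_separation = 10000) {
  enh <- S4Vectors::first(pairs)
  prom <- S4Vectors::second(pairs)
  sep <- GenomicRanges::distance(enh, prom)
  keep <- which(!is.na(sep) & sep >= min_separation)
  value <- rep(NA_real_, length(keep))
  for (k in seq_along(keep)) {
    i <- bins_overlapping(oe$bins, enh[keep[k]])
    j <- bins_overlapping(oe$bins, prom[keep[k]])
    if (!length(i) || !length(j)) next
    value[k] <- mean(oe$values[i, j, drop = FALSE], na.rm = TRUE)
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(enh))[keep],
    enh_start = GenomicRanges::start(enh)[keep] - 1L,
    enh_end = GenomicRanges::end(enh)[keep],
    prom_start = GenomicRanges::start(prom)[keep] - 1L,
    prom_end = GenomicRanges::end(prom)[keep],
    separation = sep[keep],
    value = value)
}

#' Aggregate window around enhancer-promoter pairs
#'
#' @param oe An `oe_matrix`.
#' @param table Output of [ep_contact_table()].
#' @param window_bp Full window size in bp (e.g. 60000 at 2-kb bins gives a
#'   31 x 31 grid).
#' @return List with `matrix` and `n` (pairs used).
#' @export
ep_aggregate <- function(oe, table, window_bp = 60000) {
  if (!nrow(table)) stop("empty pair table")
  bs <- bin_size(oe$bins)
  w <- floor(window_bp / bs / 2)
  size <- 2 * w + 1
  chrom_of <- as.character(GenomicRanges::seqnames(oe$bins))
  acc <- matrix(0, size, size)
  cnt <- matrix(0, size, size)
  used <- 0L
  for (k in seq_len(nrow(table))) {
    e_mid <- floor((table$enh_start[k] + table$enh_end[k]) / 2)
    p_mid <- floor((table$prom_start[k] + table$prom_end[k]) / 2)
    pt <- function(pos) GenomicRanges::GRanges(
      table$chrom[k], IRanges::IRanges(pos + 1, width = 1L))
    i <- bins_overlapping(oe$bins, pt(e_mid))
    j <- bins_overlapping(oe$bins, pt(p_mid))
    if (!length(i) || !length(j)) next
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    lo_chr <- min(which(chrom_of == table$chrom[k]))
    hi_chr <- max(which(chrom_of == table$chrom[k]))
    if (i - w < lo_chr || j + w > hi_chr) next
    sub <- oe$values[(i - w):(i + w), (j - w):(j + w)]
    fin <- is.finite(sub)
    acc[fin] <- acc[fin] + sub[fin]
    cnt <- cnt + fin
    used <- used + 1L
  }
  if (!used) stop("no usable pairs for aggregation")
  list(matrix = ifelse(cnt > 0, acc / cnt, NA_real_), n = used)
}

#' Compare enhancer-promoter contact strength across conditions
#'
#' For each enhancer set, a two-sided Wilcoxon rank-sum test between each
#' non-control condition and the control.
#'
#' @param tables Named list (condition -> [ep_contact_table()] output); the
#'   tables must describe the same pairs.
#' @param control Name of the control condition.
#' @param sets Optional vector of enhancer-set labels, one per pair row; a
#'   single set is assumed when absent.
#' @return data.frame with columns `set`, `condition`, `n`, `p`.
#' @export
compare_pair_strength <- function(tables, control, sets = NULL) {
  stopifnot(control %in% names(tables))
  nr <- nrow(tables[[control]])
  if (is.null(sets)) sets <- rep("all", nr)
  stopifnot(length(sets) == nr)
  out <- list()
  for (cond in setdiff(names(tables), control)) {
    stopifnot(nrow(tables[[cond]]) == nr)
    for (s in unique(sets)) {
      i <- sets == s
      x <- tables[[cond]]$value[i]
      y <- tables[[control]]$value[i]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      p <- if (length(x) < 3 || length(y) < 3) {
        warning("fewer than 3 values in group '", s, "' for ", cond)
        NA_real_
      } else rank_sum_test(x, y)
      out[[length(out) + 1]] <- data.frame(set = s, condition = cond,
                                           n = sum(i), p = p)
    }
  }
  do.call(rbind, out)
}
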