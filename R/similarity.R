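# Windowed structural-similarity comparison of two contact maps, reference
# subtraction, Z-scored differential region calling, and association of
# differential windows with differentially expressed genes.
#
# Each on-diagonal window of the two observed/expected matrices is treated
# as an image and compared with the structural similarity index (ssim),
# computed globally per window pair on log2(O/E + eps) after light local
# smoothing (the role the sliding Gaussian sub-window plays in standard
# image ssim). The signal-to-noise ratio relates the absolute log-O/E signal
# of a window to the Poisson shot-noise scale implied by its raw counts, so
# that sparsely covered windows score low without penalizing windows whose
# two maps genuinely differ.

#' Structural similarity index of two matrix blocks
#'
#' ssim = ((2 mu_a mu_b + c1)(2 cov + c2)) /
#'        ((mu_a^2 + mu_b^2 + c1)(sigma_a^2 + sigma_b^2 + c2))
#' over the pixels finite in both blocks, with c1 = (k1 L)^2, c2 = (k2 L)^2
#' and L the joint dynamic range.
#'
#' @param a,b Equal-shaped numeric matrices (typically log2(O/E + eps)).
#' @param k1,k2 Stability constants (0.01, 0.03).
#' @param min_pixels Minimum shared finite pixels; below this, NA.
#' @return ssim value in \[-1, 1\], or NA.
#' @export
ssim <- function(a, b, k1 = 0.01, k2 = 0.03, min_pixels = 10L) {
  stopifnot(all(dim(a) == dim(b)))
  fin <- is.finite(a) & is.finite(b)
  if (sum(fin) < min_pixels) return(NA_real_)
  x <- a[fin]; y <- b[fin]
  L <- max(x, y) - min(x, y)
  if (L == 0) return(1)  # both blocks constant and equal
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cv <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + c1) * (2 * cv + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Windowed similarity scan of two contact maps
#'
#' Slides a window of `window_bp` along the diagonal in steps of `step_bp`;
#' for each window the on-diagonal O/E blocks of the two maps are smoothed
#' with a `smooth_bins`-wide mean filter, log-transformed and compared with
#' [ssim()], and a signal-to-noise ratio is computed. Z-scores are taken
#' genome-wide over finite windows.
#'
#' Two SNR definitions are available. `"shot_noise"` (default) divides the
#' mean absolute log-O/E signal of the two blocks by the Poisson noise scale
#' of the smoothed log values, `1 / (ln 2 * sqrt(n + 1))` with `n` the
#' pooled raw count under the smoothing kernel, so windows with sparse data
#' score low while windows with genuine structural differences do not.
#' `"difference"` divides the same signal by the standard deviation of the
#' pixelwise difference of the two blocks.
#'
#' @param cm_a,cm_b Balanced `contact_matrix` objects on identical bins.
#' @param window_bp,step_bp Window and step size in bp.
#' @param smooth_bins Width of the mean filter applied to O/E before log2
#'   (1 = no smoothing).
#' @param eps Pseudocount added to O/E before log2.
#' @param snr_method `"shot_noise"` or `"difference"`.
#' @return A `similarity_track` data.frame with columns `chrom`, `start`,
#'   `end`, `ssim`, `snr`, `ssim_z`, `snr_z`.
#' @export
scan_similarity <- function(cm_a, cm_b, window_bp = 500000, step_bp = 5000,
                            smooth_bins = 3L, eps = 1e-4,
                            snr_method = c("shot_noise", "difference")) {
  snr_method <- match.arg(snr_method)
  if (length(cm_a$bins) != length(cm_b$bins) ||
      any(GenomicRanges::start(cm_a$bins) != GenomicRanges::start(cm_b$bins)) ||
      any(as.character(GenomicRanges::seqnames(cm_a$bins)) !=
            as.character(GenomicRanges::seqnames(cm_b$bins))))
    stop("contact matrices must share one bin table")
  bs <- bin_size(cm_a$bins)
  w_bins <- max(2L, round(window_bp / bs))
  s_bins <- max(1L, round(step_bp / bs))
  la <- log2_oe(cm_a, eps, smooth_bins)
  lb <- log2_oe(cm_b, eps, smooth_bins)
  if (snr_method == "shot_noise") {
    noise_a <- 1 / (log(2) * sqrt(smooth_sum(cm_a$counts, smooth_bins) + 1))
    noise_b <- 1 / (log(2) * sqrt(smooth_sum(cm_b$counts, smooth_bins) + 1))
  }
  idx <- chrom_bin_index(cm_a$bins)
  rows <- list()
  for (ch in names(idx)) {
    ix <- idx[[ch]]
    n <- length(ix)
    if (n < w_bins) next
    starts <- seq(1L, n - w_bins + 1L, by = s_bins)
    svals <- snrs <- rep(NA_real_, length(starts))
    for (k in seq_along(starts)) {
      r <- ix[starts[k]:(starts[k] + w_bins - 1L)]
      a <- la[r, r]; b <- lb[r, r]
      svals[k] <- ssim(a, b)
      fin <- is.finite(a) & is.finite(b)
      if (sum(fin) >= 10) {
        sig <- (mean(abs(a[fin])) + mean(abs(b[fin]))) / 2
        if (snr_method == "shot_noise") {
          noi <- (mean(noise_a[r, r][fin]) + mean(noise_b[r, r][fin])) / 2
          snrs[k] <- sig / noi
        } else {
          dsd <- stats::sd(a[fin] - b[fin])
          snrs[k] <- if (dsd > 0) sig / dsd else NA_real_
        }
      }
    }
    gs <- GenomicRanges::start(cm_a$bins)[ix[starts]]
    rows[[ch]] <- data.frame(
      chrom = ch,
      start = gs - 1L,
      end = gs - 1L + w_bins * bs,
      ssim = svals, snr = snrs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$ssim_z <- zscore(out$ssim)
  out$snr_z <- zscore(out$snr)
  attr(out, "window_bp") <- window_bp
  attr(out, "step_bp") <- step_bp
  class(out) <- c("similarity_track", "data.frame")
  out
}

log2_oe <- function(cm, eps, smooth_bins = 1L) {
  oe <- observed_expected(cm)
  log2(smooth_mean(oe$values, smooth_bins) + eps)
}

# Separable boxcar sum with NA padding at the edges.
smooth_sum <- function(m, k) {
  if (k <= 1) return(m)
  f <- rep(1, k)
  num <- apply(m, 2, function(col) stats::filter(col, f, sides = 2))
  t(apply(t(num), 2, function(col) stats::filter(col, f, sides = 2)))
}

# NA-aware boxcar mean.
smooth_mean <- function(m, k) {
  if (k <= 1) return(m)
  fin <- is.finite(m)
  num <- smooth_sum(ifelse(fin, m, 0), k)
  den <- smooth_sum(fin + 0, k)
  ifelse(!is.na(den) & den > 0, num / den, NA_real_)
}

#' Subtract a reference similarity track
#'
#' delta_ssim = query ssim - reference ssim, so windows where the query pair
#' is less similar than the reference baseline are negative. A z-score of
#' delta (`delta_z`) is added; downstream calling uses it when present.
#'
#' @param query,reference `similarity_track`s over identical windows.
#' @return The query track with `delta_ssim` and `delta_z` columns.
#' @export
delta_similarity <- function(query, reference) {
  if (nrow(query) != nrow(reference) ||
      any(query$chrom != reference$chrom) ||
      any(query$start != reference$start))
    stop("query and reference tracks must share identical windows")
  query$delta_ssim <- query$ssim - reference$ssim
  query$delta_z <- zscore(query$delta_ssim)
  query
}

#' Call differential-conformation regions
#'
#' Windows with similarity z-score below `ssim_z_max` and signal-to-noise
#' z-score at least `snr_z_min` are selected; overlapping or adjacent
#' selected windows are merged. When the track carries a reference delta
#' (`delta_z`), the delta z-score is thresholded instead of `ssim_z`.
#'
#' @param track A `similarity_track`.
#' @param ssim_z_max,snr_z_min Calling thresholds.
#' @return `GRanges` of merged regions with `min_ssim_z` and `max_snr_z`.
#' @export
call_regions <- function(track, ssim_z_max = -2, snr_z_min = 1) {
  z <- if (!is.null(track$delta_z)) track$delta_z else track$ssim_z
  sel <- which(!is.na(z) & !is.na(track$snr_z) &
                 z < ssim_z_max & track$snr_z >= snr_z_min)
  if (!length(sel)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(track$chrom[sel],
                               IRanges::IRanges(track$start[sel] + 1,
                                                track$end[sel]))
  gr$z <- z[sel]
  gr$snr_z <- track$snr_z[sel]
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  mi <- S4Vectors::subjectHits(hits)
  merged$min_ssim_z <- as.vector(tapply(gr$z, mi, min))
  merged$max_snr_z <- as.vector(tapply(gr$snr_z, mi, max))
  merged
}

#' Similarity differences in windows with and without DE genes
#'
#' Every `subsample_every`-th window is kept (adjacent windows overlap), each
#' kept window is classified by whether it contains a differentially
#' expressed gene, and the two classes are compared with a two-sided rank-sum
#' test on `delta_ssim` (or `ssim` when no reference delta is attached).
#'
#' @param track A `similarity_track`.
#' @param de_genes `GRanges` of DE genes.
#' @param subsample_every Keep every n-th window.
#' @return List with `windows` (kept windows and their class), `p`, and the
#'   class sizes `n_de`, `n_non`.
#' @export
windows_vs_genes <- function(track, de_genes, subsample_every = 100L) {
  keep <- seq(1L, nrow(track), by = subsample_every)
  sub <- track[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(sub$chrom,
                               IRanges::IRanges(sub$start + 1, sub$end))
  de <- IRanges::overlapsAny(gr, de_genes)
  val <- if (!is.null(sub$delta_ssim)) sub$delta_ssim else sub$ssim
  sub$class <- ifelse(de, "DE", "non-DE")
  x <- val[de & is.finite(val)]
  y <- val[!de & is.finite(val)]
  p <- if (length(x) < 3 || length(y) < 3) {
    warning("a class has fewer than 3 windows; p-value not computed")
    NA_real_
  } else rank_sum_test(x, y)
  list(windows = sub, p = p, n_de = length(x), n_non = length(y))
}
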