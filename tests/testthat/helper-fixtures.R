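# Shared fixture builders. Everything is generated in code; no data files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

toy_bins <- function(n, bs = 1000, chrom = "chrT") {
  bin_table(stats::setNames(n * bs, chrom), bs)
}

# contact matrix with preset normalized values (for operations downstream of
# balancing)
cm_norm <- function(m, bs = 1000, chrom = "chrT", valid = NULL) {
  bins <- toy_bins(nrow(m), bs, chrom)
  if (is.null(valid)) valid <- rep(TRUE, nrow(m))
  cm <- contact_matrix(bins, ifelse(is.na(m), 0, m), valid = valid)
  norm <- m
  norm[!valid, ] <- NA
  norm[, !valid] <- NA
  cm$normalized <- norm
  cm$norm_method <- "preset"
  cm
}

toeplitz_cm <- function(n, f, bs = 1000) {
  cm_norm(outer(seq_len(n), seq_len(n), function(i, j) f(abs(i - j))), bs)
}

# symmetric positive random count matrix
random_sym_counts <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::rlnorm(n * n, 2, 0.5), n, n)
  round((a + t(a)) / 2 * 10)
}

# bare oe_matrix object for tests of operations that consume O/E
oe_obj <- function(values, bs = 1000, chrom = "chrT", valid = NULL) {
  bins <- toy_bins(nrow(values), bs, chrom)
  if (is.null(valid)) valid <- rep(TRUE, nrow(values))
  structure(list(bins = bins, values = values, valid = valid),
            class = "oe_matrix")
}

# tiling domains with random sizes drawn on a grid, covering [0, size]
mk_tiling_domains <- function(sizes, lo, hi, grid, seed) {
  set.seed(seed)
  out <- lapply(names(sizes), function(ch) {
    edges <- 0
    while (utils::tail(edges, 1) < sizes[[ch]] - hi)
      edges <- c(edges, utils::tail(edges, 1) +
                   sample(seq(lo, hi, by = grid), 1))
    edges <- c(edges, sizes[[ch]])
    d <- GRanges(ch, IRanges(utils::head(edges, -1) + 1,
                             utils::tail(edges, -1)))
    d$boost <- 1
    d
  })
  suppressWarnings(do.call(c, out))
}

# insulation-style track from a bare numeric vector
mk_track <- function(values, bs = 1000, chrom = "chrT",
                     window_size = 4L, resolution = bs) {
  gr <- granges(toy_bins(length(values), bs, chrom))
  gr$score <- values
  metadata(gr)$window_size <- window_size
  metadata(gr)$resolution <- resolution
  gr
}

# minimal hand-built similarity track
mk_sim_track <- function(n, chrom = "chrT", window_bp = 10000,
                         step_bp = 1000) {
  out <- data.frame(chrom = chrom,
                    start = (seq_len(n) - 1L) * step_bp,
                    end = (seq_len(n) - 1L) * step_bp + window_bp,
                    ssim = NA_real_, snr = NA_real_,
                    ssim_z = NA_real_, snr_z = NA_real_)
  class(out) <- c("similarity_track", "data.frame")
  out
}
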