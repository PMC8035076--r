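test_that("contact-map generation is reproducible and depth-scaled", {
  spec <- sim_spec(c(chrS = 2e5), 2000, depth = 2e5)
  a <- generate_contact_map(spec, seed = 5)
  b <- generate_contact_map(spec, seed = 5)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth$biases, b$truth$biases)
  # same seed family: identical biases, so the ratio is Poisson-only
  spec2 <- sim_spec(c(chrS = 2e5), 2000, depth = 4e5)
  c_ <- generate_contact_map(spec2, seed = 5)
  tot1 <- sum(a$matrix$counts[upper.tri(a$matrix$counts, diag = TRUE)])
  tot2 <- sum(c_$matrix$counts[upper.tri(c_$matrix$counts, diag = TRUE)])
  # Poisson mean scaling: ratio ~ 2 within 3 sd
  expect_lt(abs(tot2 - 2 * tot1), 3 * sqrt(tot2 + 4 * tot1))
})

test_that("decay exponent is recovered from plain simulated counts", {
  alpha <- 0.8
  spec <- sim_spec(c(chrS = 5e5), 1000, decay_exponent = alpha,
                   decay_offset = 1000, depth = 2e6)
  map <- generate_contact_map(spec, seed = 31)
  m <- map$matrix$counts
  d <- col(m) - row(m)
  keep <- d > 0
  mean_by_d <- tapply(m[keep], d[keep], mean)
  dist_bp <- as.numeric(names(mean_by_d)) * 1000 + 1000
  sel <- dist_bp > 5000 & dist_bp < 2e5 & mean_by_d > 0
  fit <- stats::lm(log(mean_by_d[sel]) ~ log(dist_bp[sel]))
  expect_lt(abs(-stats::coef(fit)[2] - alpha) / alpha, 0.05)
})

test_that("planted features raise contact intensity where expected", {
  dom <- GRanges("chrS", IRanges(100001, 200000))
  dom$boost <- 1
  spec <- sim_spec(c(chrS = 4e5), 2000, domains = dom, depth = 2e6)
  map <- generate_contact_map(spec, seed = 8)
  m <- map$matrix$counts
  inside <- 51:100
  outside <- 151:200
  d <- abs(row(m) - col(m))
  sel <- d >= 5 & d <= 40
  ratio <- mean(m[inside, inside][sel[inside, inside]]) /
    mean(m[outside, outside][sel[outside, outside]])
  expect_gt(ratio, 1.5)
  expect_equal(length(map$truth$boundaries), 2)
})

test_that("inversions produce the breakpoint-joining contact gain", {
  # f = 1 inversion of a 300-kb segment: the block joining the two
  # breakpoint-distal ends becomes short-range and gains contacts
  x1 <- 2e5; x2 <- 5e5
  spec0 <- sim_spec(c(chrS = 1e6), 5000, depth = 2e6, bias_sigma = 0)
  inv <- rearrangement("inversion", "chrS", start = x1, end = x2,
                       fraction = 1)
  spec1 <- sim_spec(c(chrS = 1e6), 5000, depth = 2e6, bias_sigma = 0,
                    rearrangements = list(inv))
  ref <- generate_contact_map(spec0, seed = 13)
  mut <- apply_rearrangement(spec1, ref, seed = 14)
  # bins just left of x1 vs bins just left of x2 (inside the segment):
  # after inversion those segment ends relocate next to x1
  left_out <- (x1 / 5000 - 19):(x1 / 5000)          # [x1-100kb, x1)
  seg_end <- (x2 / 5000 - 19):(x2 / 5000)           # [x2-100kb, x2)
  gain <- mean(mut$matrix$counts[left_out, seg_end]) /
    mean(ref$matrix$counts[left_out, seg_end])
  expect_gt(gain, 1.5)
  # breakpoint-adjacent pairs relocate to near-zero separation
  near <- mean(mut$matrix$counts[39:40, 99:100]) /
    mean(ref$matrix$counts[39:40, 99:100])
  expect_gt(near, 3)
  expect_equal(start(mut$truth$breakpoints), c(x1, x2))
})

test_that("carrier fraction 0 reproduces the reference distribution", {
  spec0 <- sim_spec(c(chrS = 2e5), 5000, depth = 1e5)
  mk <- function(s, e) sim_spec(c(chrS = 2e5), 5000, depth = 1e5,
                                rearrangements = list(
                                  rearrangement("inversion", "chrS",
                                                start = s, end = e,
                                                fraction = 0)))
  ref <- generate_contact_map(spec0, seed = 3)
  # with f = 0 the planted rearrangement is irrelevant: two different
  # inversions give bit-identical counts under the same sampling seed
  mut_a <- apply_rearrangement(mk(5e4, 1e5), ref, seed = 3)
  mut_b <- apply_rearrangement(mk(1e5, 1.5e5), ref, seed = 3)
  expect_identical(mut_a$matrix$counts, mut_b$matrix$counts)
  # and the expected depth matches the reference
  tot <- function(m) sum(m$matrix$counts[upper.tri(m$matrix$counts,
                                                   diag = TRUE)])
  expect_lt(abs(tot(mut_a) - tot(ref)), 4 * sqrt(tot(ref)))
})

test_that("translocations create trans contacts only for carriers", {
  sizes <- c(chrA = 2e5, chrB = 2e5)
  tr <- function(f) rearrangement("translocation", "chrA", pos = 1e5,
                                  chrom2 = "chrB", pos2 = 1e5, fraction = f)
  base <- sim_spec(sizes, 5000, depth = 5e5, trans_level = 0)
  ref <- generate_contact_map(base, seed = 2)
  trans_block <- function(map) {
    m <- map$matrix$counts
    sum(m[1:40, 41:80])
  }
  expect_equal(trans_block(ref), 0)
  spec1 <- sim_spec(sizes, 5000, depth = 5e5, trans_level = 0,
                    rearrangements = list(tr(1)))
  mut <- apply_rearrangement(spec1, ref, seed = 4)
  expect_gt(trans_block(mut), 0)
  spec0 <- sim_spec(sizes, 5000, depth = 5e5, trans_level = 0,
                    rearrangements = list(tr(0)))
  mut0 <- apply_rearrangement(spec0, ref, seed = 4)
  expect_equal(trans_block(mut0), 0)
})

test_that("rearrangement validation rejects bad input", {
  expect_error(rearrangement("inversion", "c", 0, 100, fraction = 1.2),
               "fraction")
  spec <- sim_spec(c(chrS = 1e5), 5000, depth = 1e4,
                   rearrangements = list(
                     rearrangement("inversion", "chrS", 2500, 5e4)))
  ref <- generate_contact_map(sim_spec(c(chrS = 1e5), 5000, depth = 1e4),
                              seed = 1)
  expect_error(apply_rearrangement(spec, ref, seed = 1), "bin edges")
})

test_that("regulatory annotations plant consistent truth", {
  spec <- sim_spec(c(chr1 = 1e6, chr2 = 1e6), 2000, depth = 1e5)
  ann <- generate_regulatory_annotation(spec, n_enhancers = 8, seed = 17)
  ann2 <- generate_regulatory_annotation(spec, n_enhancers = 8, seed = 17)
  expect_identical(ann$windows, ann2$windows)
  expect_identical(ann$expression, ann2$expression)
  # planted enhancer windows significant and up in both contrasts
  for (g in c("A", "B", "C")) {
    oth <- setdiff(c("A", "B", "C"), g)
    for (e in seq_along(ann$truth$enhancers[[g]])) {
      enh <- ann$truth$enhancers[[g]][e]
      for (h in oth) {
        t <- ann$windows[ann$windows$contrast == paste0(g, ">", h), ]
        w <- GRanges(t$chrom, IRanges(t$start + 1, t$end))
        hit <- IRanges::overlapsAny(w, enh)
        expect_true(any(hit))
        expect_true(all(t$FDR[hit] < 0.05))
        expect_true(all(t$logFC[hit] > 0))
      }
    }
  }
  # housekeeping genes expressed everywhere
  hk <- ann$genes$genes$housekeeping
  expect_true(all(ann$expression[hk, ] > 1))
  # planted targets are boosted in the matching genotype
  for (g in c("A", "B", "C")) {
    tg <- ann$truth$enhancers[[g]]$target_gene
    oth <- setdiff(colnames(ann$expression), g)
    expect_gt(median(ann$expression[tg, g] /
                       rowMeans(ann$expression[tg, oth])), 3)
  }
})
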