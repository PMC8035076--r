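test_that("matrix rescaling conserves constants and averages areas", {
  m <- matrix(3, 7, 7)
  expect_equal(rescale_matrix(m, 5), matrix(3, 5, 5), tolerance = 1e-12)
  # 2x2 -> 1x1 is the plain mean
  m2 <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(rescale_matrix(m2, 1)[1, 1], 2.5)
  # NA pixels are excluded, not zero-filled
  m3 <- matrix(1, 4, 4); m3[1, 1] <- NA
  expect_equal(rescale_matrix(m3, 2)[1, 1], 1)
})

test_that("domain aggregation shows planted enrichment", {
  # discrete domains on an otherwise unstructured background; unbiased
  # counts are used as normalized values directly so the aggregate reflects
  # the planted structure rather than balancing side effects
  set.seed(3)
  starts <- seq(1e5, 1.9e6, by = 2.5e5)
  doms <- GRanges("chrT", IRanges(starts + 1,
                                  width = sample(seq(6e4, 1e5, 2e4),
                                                 length(starts), TRUE)))
  doms$boost <- 1
  spec <- sim_spec(c(chrT = 2e6), 2000, domains = doms, depth = 4e6,
                   bias_sigma = 0)
  map <- generate_contact_map(spec, seed = 9)
  cm <- cm_norm(map$matrix$counts, bs = 2000)
  oe <- observed_expected(cm)
  agg <- aggregate_domains(oe, doms, n_pixels = 40, flank_fraction = 0.5)
  central <- agg$matrix[11:30, 11:30]
  # flank corners = off-diagonal corners (flank x flank across the domain);
  # the diagonal corners fall inside neighbouring domains in a tiling layout
  corners <- c(agg$matrix[1:8, 33:40], agg$matrix[33:40, 1:8])
  expect_gt(mean(central, na.rm = TRUE) / mean(corners, na.rm = TRUE), 1.3)
  # single domain input equals its rescaled window
  one <- aggregate_domains(oe, doms[3], n_pixels = 20)
  d <- doms[3]
  len <- width(d)
  b_lo <- floor((start(d) - 0.5 * len - 1) / 2000) + 1
  b_hi <- ceiling((end(d) + 0.5 * len) / 2000)
  manual <- rescale_matrix(oe$values[b_lo:b_hi, b_lo:b_hi], 20)
  expect_equal(one$matrix, manual, tolerance = 1e-12)
  expect_error(aggregate_domains(oe, GRanges()), "empty")
})

test_that("loop aggregation measures center over distal background", {
  # synthetic O/E with bumps planted at known anchor pixels
  n <- 200
  vals <- matrix(1, n, n)
  anchors1 <- c(50, 120)
  anchors2 <- anchors1 + 40
  for (k in 1:2) {
    i <- anchors1[k]; j <- anchors2[k]
    vals[i, j] <- vals[j, i] <- 3
  }
  oe <- oe_obj(vals, bs = 2000)
  loops <- Pairs(
    GRanges("chrT", IRanges((anchors1 - 1) * 2000 + 1, width = 2000)),
    GRanges("chrT", IRanges((anchors2 - 1) * 2000 + 1, width = 2000)))
  apa <- aggregate_loops(oe, loops, window_bins = 5)
  expect_equal(apa$n, 2)
  expect_equal(apa$matrix[6, 6], 3)
  expect_equal(apa$loop_strength, 3)
  # pairs closer to the diagonal than the window are excluded with warning
  near <- Pairs(GRanges("chrT", IRanges(100001, width = 2000)),
                GRanges("chrT", IRanges(104001, width = 2000)))
  expect_warning(apa2 <- aggregate_loops(oe, c(loops, near), window_bins = 5),
                 "excluded")
  expect_equal(apa2$n, 2)
  expect_error(aggregate_loops(oe, near, window_bins = 5), "too close")
})

test_that("pair contact tables filter separation and average spanned bins", {
  n <- 100
  oe <- oe_obj(matrix(1, n, n), bs = 2000)
  pairs <- Pairs(
    GRanges("chrT", IRanges(c(1, 1, 1), c(2000, 2000, 4000))),
    GRanges("chrT", IRanges(c(4001, 60001, 60001),
                            c(6000, 62000, 62000))))
  tab <- ep_contact_table(oe, pairs, min_separation = 10000)
  expect_equal(nrow(tab), 2)  # 2-kb separation dropped
  expect_equal(tab$value, c(1, 1))
  # planted signal at the pair pixel is picked up
  vals <- matrix(1, n, n)
  vals[1, 31] <- vals[31, 1] <- 4
  oe2 <- oe_obj(vals, bs = 2000)
  p2 <- Pairs(GRanges("chrT", IRanges(1, 2000)),
              GRanges("chrT", IRanges(60001, 62000)))
  expect_equal(ep_contact_table(oe2, p2)$value, 4)
})

test_that("ep aggregation windows have the documented geometry", {
  n <- 100
  oe <- oe_obj(matrix(1, n, n), bs = 2000)
  p <- Pairs(GRanges("chrT", IRanges(40001, 42000)),
             GRanges("chrT", IRanges(120001, 122000)))
  tab <- ep_contact_table(oe, p)
  agg <- ep_aggregate(oe, tab, window_bp = 60000)
  expect_equal(dim(agg$matrix), c(31, 31))  # 60 kb at 2-kb bins
  expect_equal(agg$matrix, matrix(1, 31, 31))
  # aggregate of a single pair equals its window
  set.seed(5)
  vals <- matrix(runif(n * n), n)
  oe2 <- oe_obj(vals, bs = 2000)
  agg2 <- ep_aggregate(oe2, tab, window_bp = 20000)
  i <- 21; j <- 61; w <- 5
  expect_equal(agg2$matrix, vals[(i - w):(i + w), (j - w):(j + w)])
  expect_error(ep_aggregate(oe, tab[0, ], 60000), "empty")
})

test_that("rank-sum comparisons are exact for small samples", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(20)
  p <- rank_sum_test(rnorm(300), rnorm(300, 2))
  expect_lt(p, 1e-3)
})

test_that("rank-sum matches exact enumeration for all small splits", {
  enum_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    w_obs <- sum(rank(pooled)[seq_len(n)])
    combos <- utils::combn(length(pooled), n)
    ws <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
    mu <- mean(ws)
    mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  }
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(3:5, 1); m <- sample(3:5, 1)
    x <- round(rnorm(n), 6); y <- round(rnorm(m, 0.5), 6)
    expect_equal(rank_sum_test(x, y), enum_p(x, y), tolerance = 1e-9)
  }
})

test_that("pair-strength comparison runs per set against control", {
  set.seed(4)
  base <- data.frame(chrom = "c", enh_start = 1:40, enh_end = 2:41,
                     prom_start = 101:140, prom_end = 102:141,
                     separation = 20000)
  tabs <- list(control = transform(base, value = rnorm(40, 1)),
               mutantX = transform(base, value = rnorm(40, 1)),
               mutantY = transform(base, value = rnorm(40, 3)))
  sets <- rep(c("s1", "s2"), each = 20)
  res <- compare_pair_strength(tabs, control = "control", sets = sets)
  expect_equal(nrow(res), 4)
  expect_true(all(res$p[res$condition == "mutantY"] < 0.01))
  expect_true(all(res$p[res$condition == "mutantX"] > 0.01))
  # small groups give NA with a warning (one per mutant condition)
  w <- testthat::capture_warnings(
    res2 <- compare_pair_strength(lapply(tabs, function(t) t[1:2, ]),
                                  control = "control"))
  expect_length(w, 2)
  expect_match(w, "fewer than 3", all = TRUE)
  expect_true(all(is.na(res2$p)))
})

test_that("aggregation is invariant to region order", {
  doms <- GRanges("chrT", IRanges(c(20001, 120001, 220001), width = 40000))
  set.seed(2)
  n <- 200
  vals <- matrix(rlnorm(n * n), n); vals <- (vals + t(vals)) / 2
  oe <- oe_obj(vals, bs = 2000)
  a1 <- aggregate_domains(oe, doms, n_pixels = 20)
  a2 <- aggregate_domains(oe, rev(doms), n_pixels = 20)
  expect_equal(a1$matrix, a2$matrix, tolerance = 1e-12)
})
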