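mk_window_table <- function(starts, logFC, FDR, contrast = "A>B",
                            chrom = "chrW", width = 150) {
  data.frame(chrom = chrom, start = starts, end = starts + width,
             contrast = contrast, logFC = logFC, FDR = FDR)
}

test_that("window merging honours tolerance, width and sign rules", {
  # gap of 50 bp <= tol 100: one region
  t1 <- mk_window_table(c(1000, 1200), c(2, 2), c(1e-4, 1e-4))
  r1 <- merge_windows(t1, "A>B")
  expect_length(r1, 1)
  expect_equal(c(start(r1) - 1, end(r1)), c(1000, 1350))
  # a 6,200-bp significant run splits into chunks <= 5,000 bp
  starts <- seq(0, 6050, by = 150)
  t2 <- mk_window_table(starts, rep(2, length(starts)),
                        rep(1e-5, length(starts)))
  r2 <- merge_windows(t2, "A>B")
  expect_gt(length(r2), 1)
  expect_true(all(width(r2) <= 5000))
  # windows of both signs in one run: discarded
  t3 <- mk_window_table(c(1000, 1100), c(2, -2), c(1e-4, 1e-4))
  expect_length(merge_windows(t3, "A>B"), 0)
  # region-level Simes FDR must clear the threshold
  t4 <- mk_window_table(c(1000, 1100), c(2, 2), c(0.2, 0.6))
  expect_length(merge_windows(t4, "A>B"), 0)
  # output regions never contain a gap above tolerance
  set.seed(9)
  starts5 <- sort(sample(seq(0, 2e4, by = 150), 40))
  t5 <- mk_window_table(starts5, rep(1.5, 40), runif(40, 1e-6, 1e-3))
  r5 <- merge_windows(t5, "A>B")
  w5 <- GRanges(t5$chrom, IRanges(t5$start + 1, t5$end))
  for (k in seq_along(r5)) {
    inside <- sort(w5[IRanges::overlapsAny(w5, r5[k])])
    gaps <- start(inside)[-1] - cummax(end(inside))[-length(inside)] - 1
    if (length(gaps)) expect_true(all(gaps <= 100))
  }
})

test_that("tissue-specific sets are three-way intersections minus promoters", {
  mk_regions <- function(starts, ends, sign = 1, chrom = "chrW") {
    gr <- GRanges(rep(chrom, length(starts)), IRanges(starts, ends))
    gr$sign <- rep(sign, length(starts))
    gr$fdr <- rep(1e-4, length(starts))
    gr$n_windows <- rep(2L, length(starts))
    gr
  }
  regions <- list(
    "A>B" = mk_regions(c(1000, 5000, 9000), c(1400, 5400, 9400)),
    "A>C" = mk_regions(c(1100, 20000), c(1500, 20400)),
    "B>A" = mk_regions(3000, 3400),
    "B>C" = mk_regions(3100, 3500),
    "C>A" = mk_regions(integer(0), integer(0)),
    "C>B" = mk_regions(integer(0), integer(0)))
  promoters <- GRanges("chrW", IRanges(3200, 3300))
  sets <- tissue_specific_regions(regions, c("A", "B", "C"), promoters)
  # A: only the 1000-1400/1100-1500 overlap survives (5000 and 9000 regions
  # are not enriched vs C; 20000 not vs B)
  expect_length(sets$A, 1)
  expect_equal(c(start(sets$A), end(sets$A)), c(1100, 1400))
  # B: intersection overlaps a promoter -> excluded
  expect_length(sets$B, 0)
  expect_length(sets$C, 0)
  # sets are mutually exclusive
  expect_length(GenomicRanges::intersect(sets$A, sets$B), 0)
  expect_error(tissue_specific_regions(regions[1:3], c("A", "B", "C"),
                                       promoters), "missing contrast")
})

test_that("gene filtering removes housekeeping and low-TPM genes", {
  gm <- gene_model(
    data.frame(gene_id = paste0("g", 1:4), symbol = paste0("g", 1:4),
               housekeeping = c(TRUE, FALSE, FALSE, FALSE)),
    {
      tx <- GRanges("chrW", IRanges(seq(1000, 4000, 1000), width = 500))
      tx$transcript_id <- paste0("t", 1:4)
      tx$gene_id <- paste0("g", 1:4)
      tx
    })
  expr <- rbind(g1 = c(50, 50, 50),      # housekeeping: dropped
                g2 = c(0.5, 0.9, 1.0),   # mean 0.8: dropped
                g3 = c(0, 0, 4),         # mean 1.33: kept
                g4 = c(10, 1, 1))        # kept
  colnames(expr) <- c("A", "B", "C")
  expect_equal(filter_expressed_genes(gm, expr), c("g3", "g4"))
  expect_warning(filter_expressed_genes(gm, expr[1:3, ]), "missing")
})

test_that("assignment rules fire in order on a constructed locus", {
  # layout on chrW:
  #  gA transcript 10k-20k (+), TSS 10000
  #  gB transcript 40k-45k (+), TSS 40000
  #  gC transcript 120k-125k (-), TSS 125000
  #  boundary bin at 30k; domain [100k,130k)
  tx <- GRanges("chrW", IRanges(c(10000, 40000, 120000),
                                c(20000, 45000, 125000)),
                strand = c("+", "+", "-"))
  tx$transcript_id <- paste0("t", 1:3)
  tx$gene_id <- c("gA", "gB", "gC")
  gm <- gene_model(data.frame(gene_id = c("gA", "gB", "gC"),
                              symbol = c("gA", "gB", "gC"),
                              housekeeping = FALSE), tx)
  cands <- c("gA", "gB", "gC")
  boundaries <- GRanges("chrW", IRanges(30001, 32000))
  domains <- GRanges("chrW", IRanges(100001, 130000))
  enh <- GRanges("chrW", IRanges(
    c(15000,    # inside gA's transcript -> rule 1
      25000,    # closest TSS gA (5 kb) beyond boundary? boundary at 30k is
                # NOT between enh(25-25.2k) and gA TSS(10k); gA wins rule 2
      33000,    # closest is gA's side but boundary 30-32k blocks the path
                # back to gA; gB TSS at 40 kb is unblocked -> rule 2 to gB
      105000),  # inside domain, no transcript overlap; gC TSS in domain
    width = 200))
  res <- assign_enhancers(enh, cands, gm, boundaries, domains)
  expect_equal(res$gene_id, c("gA", "gA", "gB", "gC"))
  expect_equal(res$rule[1], "overlap_single_transcript")
  expect_equal(res$rule[2], "closest_no_boundary")
  expect_equal(res$rule[3], "closest_no_boundary")
  expect_equal(res$distance[3], 40000 - 33199 - 1)
  # rule 3: block every promoter with boundaries so rule 2 cannot fire
  blockers <- GRanges("chrW", IRanges(c(30001, 60000, 106000),
                                      width = c(2000, 200, 200)))
  enh3 <- GRanges("chrW", IRanges(105000, 105200))
  res3 <- assign_enhancers(enh3, cands, gm, blockers, domains)
  expect_equal(res3$rule, "closest_in_domain")
  expect_equal(res3$gene_id, "gC")
  # rule 4: enhancer outside any domain, all paths blocked
  enh4 <- GRanges("chrW", IRanges(60000, 60200))
  blockers4 <- GRanges("chrW", IRanges(c(50000, 70000), width = 1000))
  res4 <- assign_enhancers(enh4, cands, gm, blockers4,
                           GRanges("chrW", IRanges(100001, 130000)))
  expect_equal(res4$rule, "closest_any")
  expect_equal(res4$gene_id, "gB")
  # no candidate promoters on the chromosome: warning + NA
  enh5 <- GRanges("chrZ", IRanges(1000, 1200))
  w <- testthat::capture_warnings(
    res5 <- suppressMessages(assign_enhancers(enh5, cands, gm, boundaries,
                                              domains)))
  expect_true(any(grepl("no candidate", w)))
  expect_true(is.na(res5$gene_id))
})

test_that("enhancer overlapping two transcripts falls through rule 1", {
  tx <- GRanges("chrW", IRanges(c(10000, 12000), c(15000, 18000)),
                strand = "+")
  tx$transcript_id <- c("t1", "t2")
  tx$gene_id <- c("gA", "gB")
  gm <- gene_model(data.frame(gene_id = c("gA", "gB"),
                              symbol = c("gA", "gB"), housekeeping = FALSE),
                   tx)
  enh <- GRanges("chrW", IRanges(13000, 13500))  # overlaps both
  res <- assign_enhancers(enh, c("gA", "gB"), gm,
                          GRanges(), GRanges())
  expect_false(res$rule == "overlap_single_transcript")
  expect_equal(res$gene_id, "gB")  # TSS 12000 is nearer than 10000
})

test_that("expression validation recovers planted genotype effects", {
  set.seed(10)
  genes <- paste0("g", 1:30)
  expr <- cbind(A = rlnorm(30, log(5), 0.4),
                B = rlnorm(30, log(5), 0.4),
                C = rlnorm(30, log(5), 0.4))
  rownames(expr) <- genes
  targets <- genes[1:12]
  expr[targets, "A"] <- expr[targets, "A"] * 8
  assigns <- list(A = data.frame(gene_id = targets))
  val <- validate_assignment_expression(assigns, expr)
  expect_equal(nrow(val), 2)
  expect_true(all(val$p < 0.01))
  expect_true(all(val$median_ratio > 2))
  expect_warning(validate_assignment_expression(
    list(A = data.frame(gene_id = character())), expr), "fewer than 3")
})

test_that("domain size comparison separates planted size classes", {
  set.seed(11)
  big <- GRanges("chrW", IRanges(seq(1, by = 2e5, length.out = 30),
                                 width = round(rnorm(30, 94000, 8000))))
  small <- GRanges("chrW", IRanges(seq(1e7, by = 2e5, length.out = 30),
                                   width = round(rnorm(30, 66000, 8000))))
  domains <- c(big, small)
  features <- GRanges("chrW", IRanges(start(big) + 1000, width = 100))
  res <- domain_size_comparison(domains, features)
  expect_gt(res$mean_with, res$mean_without)
  expect_lt(res$p, 1e-6)
  expect_equal(res$n_with, 30)
  # all domains in one group: no test
  expect_warning(res2 <- domain_size_comparison(big, features), "group")
  expect_true(is.na(res2$p))
})
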