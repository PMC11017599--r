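test_that("representative transcript choice is deterministic and uniform", {
  t1 <- tiny_tss("chr1", 100L, "+", gene_id = "g1")
  expect_equal(representative_transcript(t1)$transcript_id, "g1.t1")

  t3 <- tss_table(data.frame(gene_id = rep(sprintf("g%04d", 1:1000), each = 3),
                             transcript_id = paste0("t", 1:3000),
                             chrom = "chr1",
                             tss_pos = seq_len(3000L),
                             strand = "+"))
  a <- representative_transcript(t3, rng_seed = 42L)
  b <- representative_transcript(t3, rng_seed = 42L)
  expect_identical(a, b)

  # empirical choice frequencies uniform over the 3 slots within 3 SE
  slot <- as.integer(sub("^t", "", a$transcript_id)) %% 3L
  freq <- table(slot) / 1000
  se <- sqrt((1 / 3) * (2 / 3) / 1000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("tissue expression means match direct recomputation", {
  m <- matrix(c(2, 4, 1, 7, 10, 20), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  tm <- c(s1 = "liver", s2 = "liver", s3 = "brain")
  expect_equal(tissue_expression(m, tm, "liver"),
               c(g1 = (2 + 1) / 2, g2 = (4 + 7) / 2))
  expect_equal(tissue_expression(m, tm, "brain"), c(g1 = 10, g2 = 20))
  expect_error(tissue_expression(m, tm, "sperm"), "unknown tissue")

  set.seed(8)
  m2 <- matrix(stats::runif(50), 10, 5,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  tm2 <- setNames(rep("t1", 5), paste0("s", 1:5))
  expect_equal(tissue_expression(m2, tm2, "t1"), rowMeans(m2))
})

test_that("gene-level hotspot status uses any TSS and the most proximal bin", {
  t <- tss_table(data.frame(
    gene_id = c("gA", "gA", "gB"),
    transcript_id = c("gA.t1", "gA.t2", "gB.t1"),
    chrom = "chr1", tss_pos = c(1000L, 2000L, 5000L),
    strand = c("+", "+", "-")))
  hs <- data.frame(chrom = "chr1",
                   pos = c(1003L, 1080L, 2010L, 5010L),
                   strand = c("-", "-", "-", "-"))
  st <- gene_hotspot_status(hs, t)
  # gA template (breaks -, gene +): distances 3, 80 (tss1), 10 (tss2) -> pm5
  expect_equal(st[st$gene_id == "gA" & st$strand_class == "template", ]$bin,
               "pm5")
  # gB: break - on gene - -> nontemplate, |d| = 10 -> pm6_20
  expect_equal(st[st$gene_id == "gB", ]$strand_class, "nontemplate")
  expect_equal(st[st$gene_id == "gB", ]$bin, "pm6_20")

  # hotspots on both strands at |d| = 10 join both strand classes
  hs2 <- data.frame(chrom = "chr1", pos = c(5010L, 5010L),
                    strand = c("+", "-"))
  st2 <- gene_hotspot_status(hs2, t)
  expect_setequal(st2[st2$gene_id == "gB", ]$strand_class,
                  c("template", "nontemplate"))
  expect_equal(unique(st2[st2$gene_id == "gB", ]$bin), "pm6_20")
})

test_that("with/without comparison gives the exact rank-sum p-value", {
  # {5,6,7} vs {1,2,3}: two-sided exact p = 2 * 1/C(6,3) = 0.1
  status <- data.frame(gene_id = c("g1", "g2", "g3"),
                       strand_class = "template",
                       min_abs_distance = 3L, bin = "pm5")
  ev <- c(g1 = 5, g2 = 6, g3 = 7, g4 = 1, g5 = 2, g6 = 3)
  cmp <- with_without_comparison(status, ev, "template")
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$n_with, 3L)
  expect_equal(cmp$median_with, log2(6 + 1))

  # identical groups -> p = 1
  ev2 <- c(g1 = 2, g2 = 2, g3 = 2, g4 = 2, g5 = 2, g6 = 2)
  expect_equal(with_without_comparison(status, ev2, "template")$p_value, 1)

  # empty group -> untestable
  ev3 <- c(g1 = 5, g2 = 6, g3 = 7)
  expect_message(cmp3 <- with_without_comparison(status, ev3, "template"),
                 "untestable")
  expect_true(is.na(cmp3$p_value))
})

test_that("planted expression effect is detected with high power", {
  set.seed(13)
  hits <- 0L
  for (i in 1:20) {
    tpm_with <- stats::rlnorm(200L, meanlog = 1 + log(2), sdlog = 1)
    tpm_without <- stats::rlnorm(200L, meanlog = 1, sdlog = 1)
    ev <- c(setNames(tpm_with, paste0("w", 1:200)),
            setNames(tpm_without, paste0("x", 1:200)))
    status <- data.frame(gene_id = paste0("w", 1:200),
                         strand_class = "template",
                         min_abs_distance = 3L, bin = "pm5")
    p <- with_without_comparison(status, ev, "either")$p_value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("hierarchical bin grouping follows the union-over-tissues rule", {
  expr <- matrix(c(8, 2, 4, 16, 4, 8), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  tm <- c(s1 = "liver", s2 = "brain")
  st_liver <- data.frame(gene_id = c("g1", "g2"),
                         strand_class = c("template", "template"),
                         min_abs_distance = c(3L, 160L),
                         bin = c("pm5", "pm151_200"))
  st_brain <- data.frame(gene_id = "g1", strand_class = "template",
                         min_abs_distance = 60L, bin = "pm51_100")
  hb <- suppressMessages(
    hierarchical_bins(list(liver = st_liver, brain = st_brain), expr, tm))
  g <- hb$groups
  # g1 appears in pm5 (liver value) and pm51_100 (brain value)
  expect_setequal(g[g$gene_id == "g1", ]$bin, c("pm5", "pm51_100"))
  expect_equal(g[g$gene_id == "g1" & g$bin == "pm5", ]$tpm, 8)
  expect_equal(g[g$gene_id == "g1" & g$bin == "pm51_100", ]$tpm, 16)

  # strict most-proximal pooling keeps only the pm5 entry for g1
  hb2 <- suppressMessages(
    hierarchical_bins(list(liver = st_liver, brain = st_brain), expr, tm,
                      pool = "most_proximal"))
  expect_equal(hb2$groups[hb2$groups$gene_id == "g1", ]$bin, "pm5")
})

test_that("planted distance-graded effect yields the monotone template trend", {
  set.seed(29)
  bins <- distance_bins()$bin
  mult <- c(pm5 = 4, pm6_20 = 3.2, pm21_50 = 2.6, pm51_100 = 2.1,
            pm101_150 = 1.7, pm151_200 = 1.4)
  n_per <- 120L
  rows <- list(); evs <- numeric()
  for (b in bins) {
    ids <- paste0(b, "_", seq_len(n_per))
    rows[[b]] <- data.frame(gene_id = ids, strand_class = "template",
                            min_abs_distance = distance_bins()$lo[match(b, bins)],
                            bin = b)
    evs <- c(evs, setNames(mult[[b]] * stats::rlnorm(n_per, 1, 1), ids))
  }
  status <- do.call(rbind, rows)
  expr <- matrix(evs, ncol = 1, dimnames = list(names(evs), "s1"))
  hb <- suppressMessages(
    hierarchical_bins(list(t1 = status), expr, c(s1 = "t1")))
  med <- vapply(bins, function(b)
    median(hb$groups[hb$groups$bin == b, ]$log2_tpm), 0)
  expect_gt(med[["pm5"]], med[["pm151_200"]])
  extreme <- hb$tests[hb$tests$bin_a == "pm5" &
                        hb$tests$bin_b == "pm151_200" &
                        hb$tests$strand_class == "template", ]
  expect_lt(extreme$p_value, 0.05)
})
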