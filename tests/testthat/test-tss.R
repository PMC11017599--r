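test_that("nearest-TSS assignment: distance, strand class and tie-break", {
  t <- tiny_tss("chr1", c(1000L, 5000L), c("+", "-"))
  a <- assign_to_tss(data.frame(chrom = "chr1", pos = 1050L, strand = "+"), t)
  expect_equal(a$tss_pos, 1000L)
  expect_equal(a$signed_distance, 50L)
  expect_equal(a$strand_class, "nontemplate")

  b <- assign_to_tss(data.frame(chrom = "chr1", pos = 1000L, strand = "-"), t)
  expect_equal(b$abs_distance, 0L)
  expect_equal(b$strand_class, "template")

  # equidistant -> smaller genomic coordinate wins
  t2 <- tiny_tss("chr1", c(900L, 1100L), c("+", "+"))
  cc <- assign_to_tss(data.frame(chrom = "chr1", pos = 1000L, strand = "+"), t2)
  expect_equal(cc$tss_pos, 900L)

  # out-of-range positions are dropped
  far <- assign_to_tss(data.frame(chrom = "chr1", pos = 19000L,
                                  strand = "+"), t, max_distance = 5000L)
  expect_equal(nrow(far), 0L)
})

test_that("assignment agrees with the naive all-pairs scan", {
  set.seed(12)
  t <- tiny_tss("chr1", sort(sample.int(50000L, 20L)),
                sample(c("+", "-"), 20L, replace = TRUE))
  p <- data.frame(chrom = "chr1", pos = sample.int(50000L, 400L) - 1L,
                  strand = sample(c("+", "-"), 400L, replace = TRUE))
  got <- assign_to_tss(p, t, max_distance = 5000L)
  tdf <- as.data.frame(t)
  for (i in sample.int(nrow(p), 50L)) {
    want <- bf_nearest_tss(p$chrom[i], p$pos[i], tdf, 5000L)
    row <- got[got$pos == p$pos[i] & got$strand == p$strand[i], ]
    if (is.null(want)) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_equal(row$tss_pos[1], want$tss_pos)
      expect_equal(row$signed_distance[1], want$signed)
    }
  }
})

test_that("the six bins exactly partition the +/-200 core", {
  d <- 0:250
  lab <- breakome:::bin_of_distance(d)
  expect_true(all(!is.na(lab[d <= 200])))
  expect_true(all(is.na(lab[d > 200])))
  b <- distance_bins()
  widths <- table(factor(lab, levels = b$bin))
  expect_equal(as.integer(widths), c(6L, 15L, 30L, 50L, 50L, 50L))
  # each distance falls in exactly one bin whose range contains it
  for (i in seq_len(nrow(b)))
    expect_true(all(d[!is.na(lab) & lab == b$bin[i]] >= b$lo[i] &
                      d[!is.na(lab) & lab == b$bin[i]] <= b$hi[i]))
})

test_that("enrichment ratio R reproduces hand-computed set arithmetic", {
  # one TSS at 10000; non-repeat excludes 1 bp of the inner window and
  # 4400 bp of the outer ring: L200 = 400, L5000 = 5601 (hand-done below)
  t <- tiny_tss("chr1", 10000L, "+")
  nr <- genome_mask("chr1", c(0L, 10001L), c(10000L, 13200L))
  # L200: [9800,10201) & mask = [9800,10000) + [10001,10201) = 200+200 = 400
  # L5000: [5000,15001) & mask = [5000,10000) + [10001,13200) = 5000+3199 = 8199
  pos_in <- data.frame(chrom = "chr1", pos = c(9801:9805, 10002:10006),
                       strand = "+")
  pos_out <- data.frame(chrom = "chr1", pos = 5100:5189, strand = "+")
  er <- enrichment_ratio(rbind(pos_in, pos_out), t, nr,
                         genome_bounds = c(chr1 = 20000L))
  expect_equal(er$M_inner, 10)
  expect_equal(er$M_outer, 100)
  expect_equal(er$L_inner, 400)
  expect_equal(er$L_outer, 8199)
  expect_equal(er$R, (10 / 100) / (400 / 8199))

  # boundary: all positions inside +/-200 -> R = L5000/L200
  er2 <- enrichment_ratio(pos_in, t, nr, genome_bounds = c(chr1 = 20000L))
  expect_equal(er2$R, 8199 / 400)
})

test_that("uniform positions give R near 1", {
  set.seed(21)
  t <- tiny_tss("chr1", seq(20000L, 180000L, by = 20000L),
                rep("+", 9L))
  nr <- genome_mask("chr1", 0L, 200000L)
  m <- mappable_mask(nr)
  p <- simulate_breaks(30000L, m, rng_seed = 3L)
  er <- enrichment_ratio(p, t, nr, genome_bounds = c(chr1 = 200000L))
  q <- er$L_inner / er$L_outer
  se <- sqrt((1 - q) / (q * er$M_outer))
  expect_lt(abs(er$R - 1), 3 * se)
})

test_that("bin odds ratio reproduces the hand-built contingency world", {
  # 20 genes (+ strand), hotspots: 20 template positions at TSS+151,
  # 980 elsewhere (>200 bp from any TSS); full 1 Mb mask
  tpos <- 5000L + (0:19) * 10000L
  t <- tiny_tss("chr1", tpos, rep("+", 20L))
  nr <- genome_mask("chr1", 0L, 1000000L)
  hs <- data.frame(chrom = "chr1",
                   pos = c(tpos + 151L, 8000:8979),
                   strand = c(rep("-", 20L), rep("+", 980L)))
  # M=20, T=1000, L=20*100=2000, LG=1e6 -> OR = (20/1000)/(2000/1e6) = 10
  or <- bin_odds_ratio(hs, t, "pm151_200", "both", nr,
                       genome_bounds = c(chr1 = 1000000L))
  expect_equal(or, 10)
  # template-split count over the halved candidate space
  or_t <- bin_odds_ratio(hs, t, "pm151_200", "template", nr,
                         genome_bounds = c(chr1 = 1000000L))
  expect_equal(or_t, 20)

  tab <- bin_or_table(hs, t, nr, genome_bounds = c(chr1 = 1000000L))
  expect_true(all(tab$T == 1000L))
  expect_true(all(tab$LG == 1e6))
  expect_equal(tab[tab$bin == "pm151_200" & tab$strand_class == "template",
                   ]$M, 20L)
})

test_that("bin counts and ORs equal a brute-force recount on random data", {
  set.seed(31)
  t <- tiny_tss("chr1", sort(sample.int(40000L, 10L) + 5000L),
                sample(c("+", "-"), 10L, replace = TRUE))
  nr <- random_mask(50000L, 10L)
  hs <- data.frame(chrom = "chr1", pos = sample.int(50000L, 3000L) - 1L,
                   strand = sample(c("+", "-"), 3000L, replace = TRUE))
  tab <- bin_or_table(hs, t, nr, genome_bounds = c(chr1 = 50000L))
  tdf <- as.data.frame(t)
  # brute-force per-position nearest-TSS bin + strand class
  cnt <- list()
  for (i in seq_len(nrow(hs))) {
    w <- bf_nearest_tss(hs$chrom[i], hs$pos[i], tdf, 200L)
    if (is.null(w)) next
    lab <- bf_bin_label(abs(w$signed))
    cls <- if (hs$strand[i] != w$gene_strand) "template" else "nontemplate"
    k <- paste(lab, cls)
    cnt[[k]] <- (cnt[[k]] %||% 0L) + 1L
  }
  for (r in seq_len(nrow(tab))) {
    if (tab$strand_class[r] == "both") next
    k <- paste(tab$bin[r], tab$strand_class[r])
    expect_equal(tab$M[r], cnt[[k]] %||% 0L,
                 info = paste("bin", k))
    expect_equal(tab$OR[r],
                 (tab$M[r] / tab$T[r]) / (tab$L[r] / (2 * tab$LG[r])))
  }
  both <- tab[tab$strand_class == "both", ]
  expect_equal(sum(both$M), sum(unlist(cnt)))
  expect_equal(both$OR, (both$M / both$T) / (both$L / both$LG))
})

test_that("uniform hotspots give per-bin ORs near 1", {
  set.seed(41)
  t <- tiny_tss("chr1", seq(10000L, 190000L, by = 10000L), rep("+", 19L))
  nr <- genome_mask("chr1", 0L, 200000L)
  p <- simulate_breaks(40000L, mappable_mask(nr), rng_seed = 5L)
  tab <- bin_or_table(p, t, nr, genome_bounds = c(chr1 = 200000L))
  for (r in seq_len(nrow(tab))) {
    pr <- if (tab$strand_class[r] == "both") tab$L[r] / tab$LG[r]
          else tab$L[r] / (2 * tab$LG[r])
    se <- sqrt((1 - pr) / (tab$T[r] * pr))
    expect_lt(abs(tab$OR[r] - 1), 3.5 * se)
  }
})

test_that("template/nontemplate ratio arithmetic and missing handling", {
  expect_equal(template_nontemplate_ratio(33, 20), 1.65)
  expect_equal(template_nontemplate_ratio(7, 7), 1)
  expect_warning(r0 <- template_nontemplate_ratio(5, 0), "missing")
  expect_true(is.na(r0))
})

test_that("paired signed-rank test matches exact enumeration", {
  # n=3, all differences positive: one-sided p = 1/2^3
  expect_equal(paired_tissue_test(c(2, 3, 4), c(1, 1, 1), "greater"), 0.125)
  expect_equal(paired_tissue_test(c(1, 2), c(1, 2)), 1)
  expect_error(paired_tissue_test(1, 2), "2 pairs")
  # zero differences are excluded, reducing n
  p <- paired_tissue_test(c(2, 3, 5), c(2, 1, 1), "greater")
  expect_equal(p, 0.25)  # n reduces to 2, both positive: 1/4
})

test_that("density profile normalisation and window consistency", {
  t <- tiny_tss("chr1", 10000L, "+")
  nr <- genome_mask("chr1", 0L, 20000L)
  set.seed(51)
  p <- data.frame(chrom = "chr1",
                  pos = sample(5001:14999, 3000L, replace = FALSE),
                  strand = sample(c("+", "-"), 3000L, replace = TRUE))
  prof <- density_profile(p, t, nr, genome_bounds = c(chr1 = 20000L))
  expect_equal(nrow(prof), 1000L)  # 500 bins x 2 strand classes
  expect_true(all(prof$f == 1))    # fully mappable -> f_j = 1
  # with f = 1 the score reduces to n_j / N
  for (sc in c("template", "nontemplate")) {
    pr <- prof[prof$strand_class == sc, ]
    expect_equal(pr$D, pr$n / sum(pr$n))
  }
  # the +/-200 core bins recount the R numerator (up to the d=+200 edge)
  er <- enrichment_ratio(p, t, nr, genome_bounds = c(chr1 = 20000L))
  core <- prof[prof$bin_start >= -200 & prof$bin_end <= 200, ]
  n_at_200 <- sum(p$pos == 10200L)
  expect_equal(sum(core$n), er$M_inner - n_at_200)
})

test_that("partially masked bins are normalised by their mappable fraction", {
  t <- tiny_tss("chr1", 10000L, "+")
  # alternate 10 bp of the left flank is polyA-excluded -> f = 0.5 there
  nr2 <- genome_mask("chr1", 0L, 20000L)
  pa <- genome_mask("chr1", seq(5000L, 9990L, 20L),
                    seq(5010L, 10000L, 20L), role = "polyA_excluded")
  p <- data.frame(chrom = "chr1", pos = c(9005L, 11005L), strand = "+")
  prof <- density_profile(p, t, nr2, pa, genome_bounds = c(chr1 = 20000L))
  row <- prof[prof$strand_class == "nontemplate" & prof$bin_start == -1000, ]
  expect_equal(row$f, 0.5)
  expect_equal(row$D, (1 / 2) / 0.5)
})
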