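small_cfg <- function(...) {
  synthetic_config(genome_length = 2e5L, n_genes = 20L,
                   breaks_per_sample = 3000L, hot_pool_size = 300L,
                   ap_pool_size = 300L, n_tissues = 2L,
                   samples_per_tissue = 3L, rng_seed = 7L, ...)
}

test_that("polyA exclusion mask implements the downstream-of-run rule", {
  g <- as_genome(c(chrA = "CCAAAAAAAACC", chrB = "GGTTTTTTTTGG"))
  m <- polyA_exclusion_mask(g, A_min = 8L, K = 1L)
  mdf <- as.data.frame(m)
  # chrA: A-run at 2..9 (0-based), downstream on + strand -> [10, 11)
  expect_equal(mdf[mdf$chrom == "chrA", c("start", "end")],
               data.frame(start = 10L, end = 11L), ignore_attr = TRUE)
  # chrB: T-run at 2..9, downstream on - strand -> [1, 2)
  expect_equal(mdf[mdf$chrom == "chrB", c("start", "end")],
               data.frame(start = 1L, end = 2L), ignore_attr = TRUE)
  # short runs do not trigger
  expect_equal(nrow(polyA_exclusion_mask(as_genome("CCAAAAACC"), 8L, 1L)), 0L)
})

test_that("generated genome honours composition and mask invariants", {
  cfg <- small_cfg(repeat_fraction = 0, polyA_n = 0L,
                   cpg_island_at_tss = FALSE, gc_content = 0.5)
  b <- generate_genome(cfg)
  expect_equal(mask_length(b$non_repeat), 2e5)
  af <- Biostrings::alphabetFrequency(b$genome[[1]], baseOnly = TRUE)
  gc <- sum(af[c("C", "G")]) / sum(af[c("A", "C", "G", "T")])
  se <- sqrt(0.25 / 2e5)
  expect_lt(abs(gc - 0.5), 3 * se)

  cfg2 <- small_cfg()
  b2 <- generate_genome(cfg2)
  mdf <- as.data.frame(b2$non_repeat)
  expect_true(all(mdf$start >= 0 & mdf$end <= b2$bounds[mdf$chrom]))
  expect_true(all(diff(mdf$start) > 0))          # sorted
  expect_true(all(mdf$start[-1] > mdf$end[-nrow(mdf)] - 1))  # disjoint
  # repeat coverage near the configured fraction (1 kb tiles, p = 0.4)
  frac <- 1 - mask_length(b2$non_repeat) / 2e5
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 200))
  # TSS table valid and spaced
  tdf <- as.data.frame(b2$tss)
  expect_true(all(tdf$tss_pos >= 0 & tdf$tss_pos < 2e5))
  expect_equal(length(unique(tdf$gene_id)), 20L)
})

test_that("generated breaks live in mappable space with valid depths", {
  cfg <- small_cfg()
  b <- generate_genome(cfg)
  out <- generate_breaks(cfg, b)
  m <- mappable_mask(b$non_repeat, b$polyA_excluded)
  for (s in out$samples[1:2]) {
    expect_true(all(in_mask(m, s$records$chrom, s$records$pos)))
    expect_true(all(s$records$depth >= 1L))
    expect_false(anyDuplicated(s$records,
                               by = c("chrom", "pos", "strand")) > 0)
  }
  expect_equal(nrow(out$truth$hot_pool), 300L)
  expect_true(all(in_mask(m, out$truth$hot_pool$chrom,
                          out$truth$hot_pool$pos)))
})

test_that("planted upstream-C bias is realised in emitted positions", {
  cfg <- small_cfg(upstream_C_bias = 0.5)
  b <- generate_genome(cfg)
  out <- generate_breaks(cfg, b)
  sc <- strsplit(as.character(b$genome[[1]]), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rec <- do.call(rbind, lapply(out$samples, function(s)
    as.data.frame(s$records)))
  base <- ifelse(rec$strand == "+", sc[rec$pos + 1L],
                 comp[sc[rec$pos + 1L]])
  cf <- mean(base == "C")
  # events collapse at hot positions, so the position-level fraction sits a
  # little off the event-level target; 0.05 covers that plus sampling noise
  expect_lt(abs(cf - 0.5), 0.05)
})

test_that("planted shared hot pool inflates sample-shared hotspots", {
  cfg <- small_cfg(hot_fraction = 0.3)
  b <- generate_genome(cfg)
  out <- generate_breaks(cfg, b)
  m <- mappable_mask(b$non_repeat, b$polyA_excluded)
  smp <- lapply(out$samples[1:3], mask_filter, mask = m)
  nr <- run_null(smp, hotspot_definition("sample_shared", 1L), m,
                 n_iter = 20L, rng_seed = 11L)
  expect_gt(nr$ratio, 1)
  expect_lt(nr$p_value, 0.01)
})

test_that("AP coupling places AP hot positions on the SSB pool (direct mode)", {
  cfg <- small_cfg(ap_coupling = 0.5, ap_coupling_mode = "direct")
  b <- generate_genome(cfg)
  ssb <- generate_breaks(cfg, b)
  ap <- generate_ap_sites(cfg, b, ssb$truth)
  shared <- length(intersect(pos_key(as.data.frame(ap$truth$ap_pool)),
                             pos_key(as.data.frame(ssb$truth$hot_pool))))
  expect_gt(shared, 0.3 * 300)   # about half the pool is coupled

  # purine bias at the AP site
  sc <- strsplit(as.character(b$genome[[1]]), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rec <- as.data.frame(ap$samples[[1]]$records)
  base <- ifelse(rec$strand == "+", sc[rec$pos + 1L], comp[sc[rec$pos + 1L]])
  expect_gt(mean(base %in% c("A", "G")), 0.6)
})

test_that("expression generator applies the planted effect", {
  cfg <- small_cfg(expression_effect = 3, expression_noise = 0.3)
  b <- generate_genome(cfg)
  ssb <- generate_breaks(cfg, b)
  m <- generate_expression(cfg, ssb$truth, b$tss)
  tm <- attr(m, "tissue_map")
  expect_equal(ncol(m), cfg$n_tissues * cfg$samples_per_tissue)
  expect_true(all(m >= 0))
  flagged <- unique(ssb$truth$gene_flags$gene_id)
  if (length(flagged) >= 3 && length(flagged) <= nrow(m) - 3) {
    ev <- tissue_expression(m, tm, "tissue1")
    expect_gt(median(ev[flagged]), median(ev[setdiff(names(ev), flagged)]))
  }
})

test_that("fixed seed reproduces the emitted bundle byte-for-byte", {
  cfg <- synthetic_config(genome_length = 5e4L, n_genes = 5L,
                          breaks_per_sample = 500L, hot_pool_size = 50L,
                          ap_pool_size = 50L, n_tissues = 1L,
                          samples_per_tissue = 2L, rng_seed = 99L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_breakome(cfg, dir = d1)
  simulate_breakome(cfg, dir = d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("expected enrichment ratio tracks the planted factor", {
  cfg <- small_cfg(tss_enrichment_factor = 5, hot_fraction = 0)
  b <- generate_genome(cfg)
  out <- generate_breaks(cfg, b)
  uni <- breaks_universe(out$samples)
  n_events <- length(out$samples) * cfg$breaks_per_sample
  r_exp <- expected_enrichment_ratio(b, out$truth$weights,
                                     n_events = n_events)
  expect_gt(r_exp, 1.5)
  er <- enrichment_ratio(uni, b$tss, b$non_repeat, b$polyA_excluded,
                         b$bounds)
  expect_lt(abs(er$R - r_exp) / r_exp, 0.15)

  # null construction: e = 1, no pool, no strand bias -> R near 1
  cfg0 <- small_cfg(tss_enrichment_factor = 1, hot_fraction = 0,
                    template_bias = 1, upstream_C_bias = 0,
                    cpg_island_at_tss = FALSE)
  b0 <- generate_genome(cfg0)
  out0 <- generate_breaks(cfg0, b0)
  uni0 <- breaks_universe(out0$samples)
  er0 <- enrichment_ratio(uni0, b0$tss, b0$non_repeat, b0$polyA_excluded,
                          b0$bounds)
  q <- er0$L_inner / er0$L_outer
  se <- sqrt((1 - q) / (q * er0$M_outer))
  expect_lt(abs(er0$R - 1), 3 * se)
})
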