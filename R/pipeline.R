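#' Run the full breakome analysis end-to-end on synthetic data
#'
#' Generates a synthetic study from `config`, then runs every analysis
#' stage: hotspot calling at the three stringencies per tissue, the
#' randomised-placement null, TSS enrichment (R, per-bin odds ratios,
#' density profile, template/nontemplate ratios), SSB-AP overlap in both
#' modes plus CG context, motif composition, and the expression analyses.
#' All tabular outputs are written as TSV under `out_dir` together with a
#' `manifest.json` recording the configuration, seeds and output digests.
#' Re-running with the same config reproduces all outputs byte-identically.
#'
#' @param config a [synthetic_config]
#' @param out_dir output directory
#' @param null_iterations iterations for the null simulation (default 100)
#' @param write_inputs also write the generated input bundle (FASTA, BEDs,
#'   TSVs, truth JSON) under `out_dir/inputs`
#' @return invisibly, a list with all in-memory stage results
#' @export
run_breakome <- function(config = synthetic_config(), out_dir,
                         null_iterations = 100L, write_inputs = FALSE) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_breakome(config,
                           dir = if (write_inputs)
                             file.path(out_dir, "inputs") else NULL)
  bundle <- sim$bundle
  mappable <- mappable_mask(bundle$non_repeat, bundle$polyA_excluded)
  LG <- mask_length(mappable)
  ssb <- lapply(sim$ssb$samples, mask_filter, mask = mappable)
  ap <- lapply(sim$ap$samples, mask_filter, mask = mappable)
  tissues <- unique(vapply(ssb, `[[`, "", "tissue"))
  by_tissue <- function(samples, ti)
    samples[vapply(samples, `[[`, "", "tissue") == ti]

  defs <- list(
    sample_level = hotspot_definition("sample_level", 2L),
    shared_d1 = hotspot_definition("sample_shared", 1L, 2L),
    shared_d2 = hotspot_definition("sample_shared", 2L, 2L))

  # --- hotspots + null -------------------------------------------------
  hs <- list(); null_rows <- list(); hs_rows <- list()
  for (ti in tissues) {
    smp <- by_tissue(ssb, ti)
    uni <- breaks_universe(smp)
    for (dn in names(defs)) {
      h <- call_hotspots(smp, defs[[dn]])
      hs[[ti]][[dn]] <- h
      hs_rows[[paste(ti, dn)]] <- data.table(
        tissue = ti, definition = dn, n_hotspots = nrow(h),
        n_positions = nrow(uni),
        fraction = if (nrow(uni)) nrow(h) / nrow(uni) else NA_real_)
    }
    nr <- run_null(smp, defs$shared_d1, mappable,
                   n_iter = null_iterations,
                   rng_seed = stage_seed(config, "breaks") + match(ti, tissues))
    null_rows[[ti]] <- data.table(
      tissue = ti, real_fraction = nr$real_fraction,
      mean_simulated = nr$mean_simulated, ratio = nr$ratio,
      p_value = nr$p_value, n_iterations = nr$n_iterations)
  }
  hotspot_summary <- rbindlist(hs_rows)
  null_summary <- rbindlist(null_rows)
  fwrite(hotspot_summary, file.path(out_dir, "hotspots_summary.tsv"), sep = "\t")
  fwrite(null_summary, file.path(out_dir, "null_summary.tsv"), sep = "\t")

  # --- TSS enrichment --------------------------------------------------
  r_rows <- list(); or_rows <- list(); tr_rows <- list()
  for (ti in tissues) {
    bg <- breaks_universe(by_tissue(ssb, ti))
    for (set in c("background", "shared_d1")) {
      p <- if (set == "background") bg else hs[[ti]]$shared_d1
      er <- enrichment_ratio(p, bundle$tss, bundle$non_repeat,
                             bundle$polyA_excluded, bundle$bounds)
      r_rows[[paste(ti, set)]] <- data.table(
        tissue = ti, set = set, M200 = er$M_inner, M5000 = er$M_outer,
        L200 = er$L_inner, L5000 = er$L_outer, R = er$R)
    }
    ot <- bin_or_table(hs[[ti]]$shared_d1, bundle$tss, bundle$non_repeat,
                       bundle$polyA_excluded, bundle$bounds)
    or_rows[[ti]] <- cbind(tissue = ti, ot)
    wide <- dcast(ot, bin + lo ~ strand_class, value.var = "M")
    tr_rows[[ti]] <- wide[, .(tissue = ti, bin,
                              template = template, nontemplate = nontemplate,
                              ratio = suppressWarnings(
                                template_nontemplate_ratio(template,
                                                           nontemplate)))]
  }
  fwrite(rbindlist(r_rows), file.path(out_dir, "enrichment_ratios.tsv"),
         sep = "\t")
  fwrite(rbindlist(or_rows), file.path(out_dir, "bin_odds_ratios.tsv"),
         sep = "\t")
  fwrite(rbindlist(tr_rows), file.path(out_dir, "template_ratios.tsv"),
         sep = "\t")
  prof <- density_profile(hs[[tissues[1]]]$shared_d1, bundle$tss,
                          bundle$non_repeat, bundle$polyA_excluded,
                          bundle$bounds)
  fwrite(prof, file.path(out_dir, "density_profile.tsv"), sep = "\t")

  # --- SSB-AP overlap + CG context ------------------------------------
  ap_hs <- lapply(tissues, function(ti)
    call_hotspots(by_tissue(ap, ti), defs$shared_d1))
  names(ap_hs) <- tissues
  ov_rows <- list()
  for (ti in tissues) for (mode in c("direct", "ap_minus_1")) {
    ov <- overlap_odds_ratio(hs[[ti]]$shared_d1, ap_hs[[ti]], LG,
                             mode = mode, genome_bounds = bundle$bounds)
    ov_rows[[paste(ti, mode)]] <- data.table(
      scope = ti, mode = mode, O = ov$O, T = ov$T, M = ov$M, LG = LG,
      OOR = ov$OOR, p_value = ov$p_value)
  }
  merged_ssb <- merged_cohort_hotspots(ssb)
  merged_ap <- merged_cohort_hotspots(ap)
  for (mode in c("direct", "ap_minus_1")) {
    ov <- overlap_odds_ratio(merged_ssb, merged_ap, LG, mode = mode,
                             genome_bounds = bundle$bounds)
    ov_rows[[paste("merged", mode)]] <- data.table(
      scope = "merged", mode = mode, O = ov$O, T = ov$T, M = ov$M, LG = LG,
      OOR = ov$OOR, p_value = ov$p_value)
  }
  fwrite(rbindlist(ov_rows), file.path(out_dir, "overlap.tsv"), sep = "\t")
  cg_rows <- list()
  w200 <- tss_windows(bundle$tss, 200L, bundle$bounds)
  for (region in c("genome", "tss200")) {
    reg <- if (region == "genome") NULL else w200
    posn <- as.data.table(merged_ssb)[, .(chrom, pos, strand)]
    if (region == "tss200")
      posn <- posn[in_mask(w200, posn$chrom, posn$pos), ]
    cg <- if (nrow(posn)) cg_context(posn, bundle$genome) else
      list(n_total = 0L, n_in_cg = 0L, fraction = NA_real_)
    bgf <- cg_background(bundle$genome, mappable, region = reg)
    cg_rows[[region]] <- data.table(
      region = region, n_total = cg$n_total, n_in_cg = cg$n_in_cg,
      fraction = cg$fraction, background = bgf)
  }
  fwrite(rbindlist(cg_rows), file.path(out_dir, "cg_context.tsv"), sep = "\t")

  # --- motif -----------------------------------------------------------
  hot_w <- extract_windows(merged_ssb, bundle$genome)
  bg_pos <- simulate_breaks(min(20000L, nrow(merged_ssb) * 10L), mappable,
                            rng_seed = stage_seed(config, "breaks") + 77L)
  bg_w <- extract_windows(bg_pos, bundle$genome)
  mf <- base_fractions(hot_w)
  motif_dt <- data.table(position = rep(seq_len(ncol(mf)), each = nrow(mf)),
                         base = rep(rownames(mf), ncol(mf)),
                         fraction = as.vector(unclass(mf)),
                         n = attr(mf, "n_sequences"))
  fwrite(motif_dt, file.path(out_dir, "motif_fractions.tsv"), sep = "\t")
  uc <- upstream_c_enrichment(hot_w, bg_w)
  fwrite(data.table(c_hotspot = uc$c_hotspot,
                    c_background = uc$c_background,
                    difference = uc$difference, p_value = uc$p_value),
         file.path(out_dir, "upstream_c.tsv"), sep = "\t")

  # --- expression ------------------------------------------------------
  tissue_map <- attr(sim$expr, "tissue_map")
  status <- lapply(tissues, function(ti)
    gene_hotspot_status(hs[[ti]]$shared_d1, bundle$tss))
  names(status) <- tissues
  ex_rows <- list()
  for (ti in tissues) {
    ev <- tissue_expression(sim$expr, tissue_map, ti)
    for (scope in c("either", "template", "nontemplate")) {
      cmp <- with_without_comparison(status[[ti]], ev, scope)
      ex_rows[[paste(ti, scope)]] <- data.table(
        tissue = ti, strand_scope = scope, n_with = cmp$n_with,
        n_without = cmp$n_without, median_with = cmp$median_with,
        median_without = cmp$median_without, p_value = cmp$p_value)
    }
  }
  fwrite(rbindlist(ex_rows), file.path(out_dir, "expression_with_without.tsv"),
         sep = "\t")
  hb <- hierarchical_bins(status, sim$expr, tissue_map)
  fwrite(hb$groups, file.path(out_dir, "expression_bins_groups.tsv"),
         sep = "\t")
  fwrite(hb$tests, file.path(out_dir, "expression_bins_tests.tsv"),
         sep = "\t")

  # --- manifest --------------------------------------------------------
  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("breakome")),
    rng_seed = config$rng_seed,
    config = config[setdiff(names(config), "enrichment_profile")],
    enrichment_profile = as.list(config$enrichment_profile),
    stages = c("simulate", "hotspots", "null", "tss", "overlap", "motif",
               "expression"),
    null_iterations = null_iterations,
    outputs = as.list(tools::md5sum(outputs)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, hotspots = hs, ap_hotspots = ap_hs,
                 hotspot_summary = hotspot_summary,
                 null_summary = null_summary,
                 enrichment = rbindlist(r_rows),
                 bin_or = rbindlist(or_rows),
                 template_ratios = rbindlist(tr_rows),
                 overlap = rbindlist(ov_rows),
                 cg = rbindlist(cg_rows),
                 expression = rbindlist(ex_rows),
                 expression_bins = hb,
                 out_dir = out_dir))
}

#' Summarise a completed run directory
#'
#' Re-reads the stage TSVs written by [run_breakome()] and returns them as
#' one named list of data.tables, also writing a combined `summary.json`.
#' Missing stage files yield a partial report with warnings.
#'
#' @param out_dir directory produced by [run_breakome()]
#' @return named list of data.tables
#' @export
summarize_breakome <- function(out_dir) {
  files <- c(hotspots = "hotspots_summary.tsv", null = "null_summary.tsv",
             enrichment = "enrichment_ratios.tsv",
             bin_or = "bin_odds_ratios.tsv",
             template_ratios = "template_ratios.tsv",
             density = "density_profile.tsv", overlap = "overlap.tsv",
             cg = "cg_context.tsv", motif = "motif_fractions.tsv",
             upstream_c = "upstream_c.tsv",
             expression = "expression_with_without.tsv",
             expression_bins = "expression_bins_tests.tsv")
  out <- list()
  for (nm in names(files)) {
    path <- file.path(out_dir, files[[nm]])
    if (!file.exists(path)) {
      warning("missing stage output: ", files[[nm]])
      next
    }
    out[[nm]] <- fread(path, sep = "\t")
  }
  jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out)
}
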