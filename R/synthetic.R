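#' Configuration for the synthetic breakome generator
#'
#' Defines the planted structure of a synthetic study: genome composition,
#' TSS layout, sampling design, TSS-proximal enrichment, template-strand
#' bias, shared hot positions, sequence biases, SSB-AP coupling and the
#' expression effect. Defaults describe a desk-scale study of 3 tissues x 4
#' samples on a 2 Mb single-chromosome genome with clear planted signal in
#' every statistic the pipeline measures.
#'
#' @param genome_length total genome length in bp
#' @param n_chromosomes number of chromosomes (equal lengths)
#' @param gc_content background GC fraction
#' @param repeat_fraction fraction of the genome masked as repeat
#' @param polyA_n,polyA_length number and length of planted polyA/polyT runs
#' @param polyA_A_min,polyA_K exclusion rule: positions within K bases
#'   downstream (strand orientation) of a run of >= A_min adenines
#' @param n_genes number of genes
#' @param tss_spacing_min minimum spacing between gene TSSs in bp
#' @param transcripts_per_gene_max transcripts per gene drawn uniformly
#'   from 1..max (extra TSSs offset 0-300 bp downstream)
#' @param n_tissues,samples_per_tissue,breaks_per_sample sampling design
#' @param tss_enrichment_factor mean break-density enrichment e over the
#'   +/- 200 bp TSS windows relative to background (e >= 1; 1 = none)
#' @param enrichment_profile relative weight per distance bin (names as
#'   [distance_bins()]), rescaled so the window mean equals e; the default
#'   increases toward +/- 5
#' @param template_bias template:nontemplate odds beta within +/- 200 bp of
#'   TSSs (1 = no bias)
#' @param hot_fraction fraction h of break events drawn from the shared
#'   hot-position pool
#' @param hot_pool_size number of shared hot positions
#' @param upstream_C_bias target fraction of SSB events whose
#'   strand-oriented base at pos is C (the base 5' of the nick)
#' @param ap_coupling probability c that an AP hot position is coupled to
#'   an SSB hot position
#' @param ap_coupling_mode `"direct"` (same position) or `"offset"` (one
#'   base downstream in strand orientation, recovered by the AP - 1 shift)
#' @param ap_purine_bias target fraction of AP events sitting on a purine
#' @param ap_pool_size AP hot-position pool size
#' @param cpg_island_at_tss plant CpG enrichment in TSS +/- 200 windows
#' @param cpg_rate per-position CpG planting rate inside islands
#' @param expression_effect multiplicative TPM factor gamma for genes whose
#'   TSSs carry a planted hot position within +/- 200 bp
#' @param expression_graded optional named per-bin multipliers (names as
#'   [distance_bins()]) applied by the gene's most proximal template-strand
#'   bin; overrides `expression_effect` for those genes
#' @param expression_base_meanlog,expression_base_sdlog log-normal
#'   parameters of baseline gene TPM
#' @param expression_noise per-sample log-normal noise sd (log scale)
#' @param depth_geom_p geometric depth law: depth = 1 + Geom(p)
#' @param rng_seed master seed; all stages derive their streams from it
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(genome_length = 2e6L, n_chromosomes = 1L,
                             gc_content = 0.42, repeat_fraction = 0.4,
                             polyA_n = 20L, polyA_length = 10L,
                             polyA_A_min = 8L, polyA_K = 1L,
                             n_genes = 200L, tss_spacing_min = 2000L,
                             transcripts_per_gene_max = 3L,
                             n_tissues = 3L, samples_per_tissue = 4L,
                             breaks_per_sample = 20000L,
                             tss_enrichment_factor = 5,
                             enrichment_profile = c(pm5 = 3, pm6_20 = 2.5,
                                                    pm21_50 = 2,
                                                    pm51_100 = 1.5,
                                                    pm101_150 = 1.2,
                                                    pm151_200 = 1),
                             template_bias = 2,
                             hot_fraction = 0.3, hot_pool_size = 2000L,
                             upstream_C_bias = 0.5,
                             ap_coupling = 0.5,
                             ap_coupling_mode = c("direct", "offset"),
                             ap_purine_bias = 0.7, ap_pool_size = 2000L,
                             cpg_island_at_tss = TRUE, cpg_rate = 0.08,
                             expression_effect = 2,
                             expression_graded = NULL,
                             expression_base_meanlog = 1,
                             expression_base_sdlog = 1,
                             expression_noise = 0.5,
                             depth_geom_p = 0.8,
                             rng_seed = 1L) {
  ap_coupling_mode <- match.arg(ap_coupling_mode)
  stopifnot(tss_enrichment_factor >= 1, template_bias >= 0,
            hot_fraction >= 0, hot_fraction <= 1,
            ap_coupling >= 0, ap_coupling <= 1,
            gc_content > 0, gc_content < 1,
            repeat_fraction >= 0, repeat_fraction < 1)
  cfg <- as.list(environment())
  structure(cfg, class = "synthetic_config")
}

# deterministic sub-seeds per stage, kept below 2^31
stage_seed <- function(cfg, stage) {
  offs <- c(genome = 101, breaks = 202, ap = 303, expr = 404)
  as.integer((as.numeric(cfg$rng_seed) * 1000 + offs[[stage]]) %% 2147483647)
}

#' Generate a synthetic genome, masks and TSS table
#'
#' Builds a random genome at the configured GC content, plants polyA/polyT
#' runs and (optionally) CpG-enriched +/- 200 bp islands around TSSs, lays
#' out gene TSSs with minimum spacing, tiles a random repeat mask covering
#' about `repeat_fraction` of the genome, and derives the polyA-adjacency
#' exclusion mask from the sequence by the configured rule.
#'
#' @param config a [synthetic_config]
#' @return list: genome (DNAStringSet), tss (tss_table), non_repeat and
#'   polyA_excluded ([genome_mask]s), bounds
#' @export
generate_genome <- function(config) {
  set.seed(stage_seed(config, "genome"))
  L <- as.integer(config$genome_length / config$n_chromosomes)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  bounds <- setNames(rep(L, config$n_chromosomes), chroms)

  # gene TSS layout with minimum spacing
  margin <- 6000L
  usable <- L - 2L * margin
  genes_per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  step <- usable %/% genes_per_chrom
  if (step < config$tss_spacing_min)
    stop("infeasible TSS spacing: genome too small for n_genes")
  tss_rows <- rbindlist(lapply(seq_along(chroms), function(ci) {
    ng <- min(genes_per_chrom,
              config$n_genes - (ci - 1L) * genes_per_chrom)
    if (ng <= 0L) return(NULL)
    base <- margin + (seq_len(ng) - 1L) * step +
      sample.int(max(step - config$tss_spacing_min, 1L), ng, replace = TRUE)
    gid <- sprintf("g%04d", (ci - 1L) * genes_per_chrom + seq_len(ng))
    gstrand <- sample(c("+", "-"), ng, replace = TRUE)
    ntx <- sample.int(config$transcripts_per_gene_max, ng, replace = TRUE)
    rbindlist(lapply(seq_len(ng), function(g) {
      off <- c(0L, sample.int(300L, ntx[g] - 1L, replace = TRUE))
      data.table(gene_id = gid[g],
                 transcript_id = sprintf("%s.t%d", gid[g], seq_len(ntx[g])),
                 chrom = chroms[ci],
                 tss_pos = pmin(pmax(base[g] +
                                       ifelse(gstrand[g] == "+", 1L, -1L) * off,
                                     0L), L - 1L),
                 strand = gstrand[g])
    }))
  }))
  tss <- tss_table(tss_rows, bounds)

  # sequence with planted polyA/polyT runs and optional CpG islands
  bases <- c("A", "C", "G", "T")
  pb <- c((1 - config$gc_content) / 2, config$gc_content / 2,
          config$gc_content / 2, (1 - config$gc_content) / 2)
  seqs <- lapply(chroms, function(ch) {
    s <- sample(bases, L, replace = TRUE, prob = pb)
    npa <- config$polyA_n %/% config$n_chromosomes
    if (npa > 0L) {
      st <- sample.int(L - config$polyA_length, npa)
      half <- seq_len(npa) %% 2L == 0L
      for (i in seq_len(npa))
        s[st[i]:(st[i] + config$polyA_length - 1L)] <-
          if (half[i]) "T" else "A"
    }
    if (isTRUE(config$cpg_island_at_tss)) {
      tp <- unique(tss[chrom == ch, tss_pos])
      for (t0 in tp) {
        w <- max(t0 - 200L, 0L):min(t0 + 199L, L - 2L)
        starts <- w[runif(length(w)) < config$cpg_rate / 2]
        s[starts + 1L] <- "C"; s[starts + 2L] <- "G"
      }
    }
    s
  })
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste0, "", collapse = ""))
  names(genome) <- chroms

  # repeat mask: random 1 kb tiles
  tile <- 1000L
  rep_rows <- rbindlist(lapply(chroms, function(ch) {
    starts <- seq.int(0L, L - 1L, by = tile)
    hit <- runif(length(starts)) < config$repeat_fraction
    if (!any(hit)) return(NULL)
    data.table(chrom = ch, start = starts[hit],
               end = pmin(starts[hit] + tile, L))
  }))
  non_repeat <- if (nrow(rep_rows)) {
    mask_complement(genome_mask(rep_rows$chrom, rep_rows$start, rep_rows$end,
                                role = "repeat"),
                    bounds, role = "non_repeat")
  } else genome_mask(chroms, rep(0L, length(chroms)), rep(L, length(chroms)),
                     role = "non_repeat")
  polyA_excluded <- polyA_exclusion_mask(genome, config$polyA_A_min,
                                         config$polyA_K)
  list(genome = genome, tss = tss, non_repeat = non_repeat,
       polyA_excluded = polyA_excluded, bounds = bounds, config = config)
}

#' Derive the polyA-adjacency exclusion mask from a genome sequence
#'
#' Excludes every position within `K` bases downstream -- in strand
#' orientation -- of a run of at least `A_min` adenines (runs of A for the
#' + strand, runs of T for the - strand); both strands' exclusions are
#' unioned into one unstranded mask.
#'
#' @param genome a named DNAStringSet
#' @param A_min minimum run length
#' @param K exclusion footprint in bp
#' @return a [genome_mask] with role `"polyA_excluded"`
#' @export
polyA_exclusion_mask <- function(genome, A_min = 8L, K = 1L) {
  rows <- rbindlist(lapply(names(genome), function(ch) {
    s <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    L <- length(s)
    out <- list()
    for (b in c("A", "T")) {
      r <- rle(s == b)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L           # 1-based run starts
      runs <- which(r$values & r$lengths >= A_min)
      if (!length(runs)) next
      if (b == "A") {                            # downstream on + strand
        st <- ends[runs]                         # 0-based: run end position
        en <- pmin(st + K, L)
      } else {                                   # downstream on - strand
        en <- starts[runs] - 1L                  # 0-based end (exclusive)
        st <- pmax(en - K, 0L)
      }
      keep <- en > st
      if (any(keep))
        out[[b]] <- data.table(chrom = ch, start = st[keep], end = en[keep])
    }
    rbindlist(out)
  }))
  if (nrow(rows) == 0L)
    return(genome_mask(character(), integer(), integer(),
                       role = "polyA_excluded"))
  genome_mask(rows$chrom, rows$start, rows$end, role = "polyA_excluded")
}

# Per-slot sampling law for break events. Returns mappable positions with
# per-strand probabilities combining the TSS enrichment profile, the
# template-strand bias, and the strand-oriented upstream-base bias toward
# `bias_bases`. Slots are indexed 1..2n: first all + strand, then - strand.
build_break_weights <- function(bundle, e, profile, beta, base_bias,
                                bias_bases = "C") {
  cfg <- bundle$config
  mp <- as.data.table(mappable_mask(bundle$non_repeat, bundle$polyA_excluded))
  posn <- mp[, .(pos = seq.int(start[1L], end[1L] - 1L)),
             by = .(chrom, start)][, .(chrom, pos)]
  bins <- distance_bins()
  widths <- c(11L, 30L, 60L, 100L, 100L, 100L)
  prof <- profile[bins$bin]
  prof <- prof / sum(prof * widths) * sum(widths)  # window mean of 1
  asg <- assign_to_tss(cbind(posn, strand = "+"), bundle$tss,
                       max_distance = 200L)
  posn[, w := 1]
  posn[, gene_strand := NA_character_]
  if (nrow(asg) > 0L) {
    asg[, bin := bin_of_distance(abs_distance)]
    # 1 + (e-1) * shape: flat at e = 1, window mean e, peaked at +/-5
    posn[asg, on = c("chrom", "pos"),
         `:=`(w = 1 + (e - 1) * prof[match(i.bin, bins$bin)],
              gene_strand = i.gene_strand)]
  }
  # strand split: template odds beta within the windows, even elsewhere
  p_tmpl <- beta / (1 + beta)
  posn[, `:=`(
    p_plus = fifelse(is.na(gene_strand), 0.5,
                     fifelse(gene_strand == "+", 1 - p_tmpl, p_tmpl)))]
  w_plus <- posn$w * posn$p_plus
  w_minus <- posn$w * (1 - posn$p_plus)
  # strand-oriented base at pos, per strand
  chars <- genome_chars(bundle$genome)
  base_plus <- base_minus <- character(nrow(posn))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (ch in unique(posn$chrom)) {
    idx <- which(posn$chrom == ch)
    b <- chars[[ch]][posn$pos[idx] + 1L]
    base_plus[idx] <- b
    base_minus[idx] <- comp[b]
  }
  prob <- c(w_plus, w_minus)
  prob <- prob / sum(prob)
  is_target <- c(base_plus, base_minus) %in% bias_bases
  c0 <- sum(prob[is_target])
  kappa <- if (base_bias > c0 && c0 < 1) (base_bias - c0) / (1 - c0) else 0
  if (kappa > 0) {
    prob_t <- ifelse(is_target, prob / c0, 0)
    prob <- (1 - kappa) * prob + kappa * prob_t
  }
  list(positions = posn[, .(chrom, pos)], prob = prob, n = nrow(posn),
       kappa = kappa, target_fraction = base_bias)
}

slots_to_positions <- function(weights, slot) {
  n <- weights$n
  strand <- ifelse(slot > n, "-", "+")
  i <- ifelse(slot > n, slot - n, slot)
  data.table(chrom = weights$positions$chrom[i],
             pos = weights$positions$pos[i], strand = strand)
}

# weighted sampling of k distinct slots (Efraimidis-Spirakis, log-scale
# keys log(u)/p to avoid the underflow of u^(1/p) at genome scale)
sample_slots_distinct <- function(weights, k) {
  keys <- log(runif(length(weights$prob))) / pmax(weights$prob, 1e-300)
  order(keys, decreasing = TRUE)[seq_len(k)]
}

draw_sample_events <- function(weights, pool_slots, n_events, h, geom_p) {
  n_hot <- rbinom(1L, n_events, h)
  slots <- c(if (n_hot > 0L) sample(pool_slots, n_hot, replace = TRUE),
             if (n_events - n_hot > 0L)
               sample.int(2L * weights$n, n_events - n_hot, replace = TRUE,
                          prob = weights$prob))
  ev <- data.table(slot = slots, depth = 1L + rgeom(length(slots), geom_p))
  rec <- ev[, .(depth = sum(depth)), by = slot]
  cbind(slots_to_positions(weights, rec$slot), depth = rec$depth)
}

#' Generate per-sample SSB break collections with planted structure
#'
#' Each break event is drawn, with probability `hot_fraction`, from a
#' shared hot-position pool (itself sampled from the same positional law),
#' and otherwise from a mixture of uniform background over mappable space
#' and a TSS-proximal component: positions within +/- 200 bp of a TSS carry
#' weight `e x profile(bin)` (window mean e), the strand there follows
#' template odds beta, and the strand-oriented base at pos is biased toward
#' cytosine at the configured rate. Event depths follow 1 + Geom(p);
#' events colliding at one (chrom, pos, strand) are collapsed with depths
#' summed.
#'
#' @param config a [synthetic_config]
#' @param bundle output of [generate_genome()]
#' @return list: samples (list of [break_sample], tissues x samples),
#'   truth (hot pool positions, per-gene planted flags, weights)
#' @export
generate_breaks <- function(config, bundle) {
  set.seed(stage_seed(config, "breaks"))
  weights <- build_break_weights(bundle, config$tss_enrichment_factor,
                                 config$enrichment_profile,
                                 config$template_bias,
                                 config$upstream_C_bias, "C")
  pool_slots <- sample_slots_distinct(weights, config$hot_pool_size)
  pool <- slots_to_positions(weights, pool_slots)
  samples <- list()
  for (ti in seq_len(config$n_tissues)) {
    for (si in seq_len(config$samples_per_tissue)) {
      rec <- draw_sample_events(weights, pool_slots,
                                config$breaks_per_sample,
                                config$hot_fraction, config$depth_geom_p)
      id <- sprintf("t%d_s%d", ti, si)
      samples[[id]] <- break_sample(id, sprintf("tissue%d", ti), rec)
    }
  }
  gene_flags <- gene_hotspot_status(pool, bundle$tss, max_distance = 200L)
  truth <- list(hot_pool = pool, hot_pool_slots = pool_slots,
                gene_flags = gene_flags, weights = weights)
  list(samples = samples, truth = truth)
}

#' Generate per-sample AP-site collections coupled to the SSB hot pool
#'
#' AP positions are uniform over mappable space with a purine bias at the
#' site; the AP hot-position pool is built by taking, with probability
#' `ap_coupling`, positions derived from the SSB hot pool -- identical in
#' `"direct"` mode, one base downstream in strand orientation in
#' `"offset"` mode (so the AP - 1 upstream shift recovers the SSB) -- and
#' uniform draws otherwise.
#'
#' @param config a [synthetic_config]
#' @param bundle output of [generate_genome()]
#' @param truth truth component of [generate_breaks()]
#' @return list: samples (list of break_sample), truth (ap_pool, coupled
#'   flags)
#' @export
generate_ap_sites <- function(config, bundle, truth) {
  set.seed(stage_seed(config, "ap"))
  weights <- build_break_weights(bundle, e = 1,
                                 profile = config$enrichment_profile,
                                 beta = 1,
                                 base_bias = config$ap_purine_bias,
                                 bias_bases = c("A", "G"))
  n_pool <- config$ap_pool_size
  coupled <- runif(n_pool) < config$ap_coupling
  n_coup <- sum(coupled)
  ssb_pool <- truth$hot_pool
  coup_rows <- ssb_pool[sample.int(nrow(ssb_pool), n_coup,
                                   replace = n_coup > nrow(ssb_pool))]
  if (config$ap_coupling_mode == "offset") {
    coup_rows <- copy(coup_rows)
    coup_rows[, pos := pos + ifelse(strand == "+", 1L, -1L)]
    coup_rows <- coup_rows[pos >= 0L & pos < bundle$bounds[chrom]]
  }
  free_slots <- sample_slots_distinct(weights, n_pool - n_coup)
  ap_pool <- unique(rbind(coup_rows[, .(chrom, pos, strand)],
                          slots_to_positions(weights, free_slots)))
  # map pool rows back to slot indices for event drawing
  posmap <- data.table(chrom = weights$positions$chrom,
                       pos = weights$positions$pos,
                       idx = seq_len(weights$n))
  ap1 <- posmap[ap_pool, on = c("chrom", "pos")]
  slot <- ifelse(ap_pool$strand == "+", ap1$idx, ap1$idx + weights$n)
  ok <- !is.na(slot)               # coupled offsets can leave mappable space
  pool_slots <- slot[ok]
  samples <- list()
  for (ti in seq_len(config$n_tissues)) {
    for (si in seq_len(config$samples_per_tissue)) {
      rec <- draw_sample_events(weights, pool_slots,
                                config$breaks_per_sample,
                                config$hot_fraction, config$depth_geom_p)
      id <- sprintf("t%d_s%d", ti, si)
      samples[[id]] <- break_sample(id, sprintf("tissue%d", ti), rec)
    }
  }
  list(samples = samples,
       truth = list(ap_pool = ap_pool[ok], coupled = coupled,
                    mode = config$ap_coupling_mode))
}

#' Generate a TPM expression matrix tied to planted hotspot structure
#'
#' Baseline gene TPM is log-normal; genes whose TSSs carry a planted hot
#' position within +/- 200 bp are multiplied by `expression_effect` (or by
#' the per-bin multiplier of their most proximal template-strand bin when
#' `expression_graded` is set); independent log-normal noise is applied per
#' sample.
#'
#' @param config a [synthetic_config]
#' @param truth truth component of [generate_breaks()]
#' @param tss the tss_table (defines the gene universe)
#' @return genes x samples TPM matrix with a `tissue_map` attribute
#' @export
generate_expression <- function(config, truth, tss) {
  set.seed(stage_seed(config, "expr"))
  genes <- sort(unique(as.data.table(tss)$gene_id))
  base <- rlnorm(length(genes), config$expression_base_meanlog,
                 config$expression_base_sdlog)
  names(base) <- genes
  flags <- as.data.table(truth$gene_flags)
  mult <- rep(1, length(genes)); names(mult) <- genes
  if (nrow(flags)) {
    hit <- unique(flags$gene_id)
    mult[hit] <- config$expression_effect
    if (!is.null(config$expression_graded)) {
      tf <- flags[strand_class == "template"]
      if (nrow(tf)) {
        tf <- tf[, .(bin = bin[which.min(min_abs_distance)]), by = gene_id]
        mult[tf$gene_id] <- config$expression_graded[tf$bin]
      }
    }
  }
  mu <- base * mult
  ids <- as.vector(vapply(seq_len(config$n_tissues), function(ti)
    sprintf("t%d_s%d", ti, seq_len(config$samples_per_tissue)),
    character(config$samples_per_tissue)))
  m <- vapply(ids, function(id)
    mu * rlnorm(length(mu), 0, config$expression_noise),
    numeric(length(mu)))
  rownames(m) <- genes
  tissue_map <- setNames(sub("_s\\d+$", "", ids), ids)
  tissue_map[] <- sub("^t", "tissue", tissue_map)
  attr(m, "tissue_map") <- tissue_map
  m
}

#' Expected TSS enrichment ratio implied by the sampling law
#'
#' Computes the expectation of the enrichment ratio R by direct summation
#' of the realized per-slot sampling probabilities over the merged +/- 200
#' and +/- 5000 bp TSS windows (independent of the pipeline's counting
#' path): `R_exp = (P200 / P5000) / (L200 / L5000)`.
#'
#' When `n_events` is given, the expectation accounts for the fact that
#' the pipeline counts unique positions: the expected unique count of slot
#' s after n draws is `1 - (1 - q_s)^n`, which attenuates dense (hot)
#' windows. `hot_fraction`/`pool_slots` fold the shared hot-pool mixture
#' into the per-slot law the same way the generator draws events.
#'
#' @param bundle output of [generate_genome()]
#' @param weights weights component of the breaks truth
#'   (`truth$weights`)
#' @param inner,outer window half-widths
#' @param n_events total break events pooled into the measured position
#'   set (NULL for the plain probability-mass ratio)
#' @param hot_fraction,pool_slots the generator's hot-pool mixture
#'   (defaults: no pool)
#' @return expected R
#' @export
expected_enrichment_ratio <- function(bundle, weights, inner = 200L,
                                      outer = 5000L, n_events = NULL,
                                      hot_fraction = 0, pool_slots = NULL) {
  w_in <- tss_windows(bundle$tss, inner, bundle$bounds)
  w_out <- tss_windows(bundle$tss, outer, bundle$bounds)
  inside_in <- in_mask(w_in, weights$positions$chrom, weights$positions$pos)
  inside_out <- in_mask(w_out, weights$positions$chrom, weights$positions$pos)
  q <- weights$prob
  if (hot_fraction > 0 && length(pool_slots)) {
    q <- (1 - hot_fraction) * q
    q[pool_slots] <- q[pool_slots] + hot_fraction / length(pool_slots)
  }
  mass <- if (is.null(n_events)) q else 1 - (1 - q)^n_events
  P_in <- sum(mass[c(inside_in, inside_in)])
  P_out <- sum(mass[c(inside_out, inside_out)])
  L_in <- effective_length(w_in, bundle$non_repeat, bundle$polyA_excluded)
  L_out <- effective_length(w_out, bundle$non_repeat, bundle$polyA_excluded)
  (P_in / P_out) / (L_in / L_out)
}

#' Generate a complete synthetic breakome study
#'
#' Runs [generate_genome()], [generate_breaks()], [generate_ap_sites()] and
#' [generate_expression()] under one configuration, optionally writing the
#' full input bundle (FASTA, BED3 masks, TSS TSV, per-sample BED6 SSB and
#' AP files, TPM TSV, truth JSON) to a directory. Fixed seed implies
#' byte-identical output files.
#'
#' @param config a [synthetic_config]
#' @param dir optional output directory
#' @return list: bundle, ssb (samples + truth), ap, expr
#' @export
simulate_breakome <- function(config = synthetic_config(), dir = NULL) {
  bundle <- generate_genome(config)
  ssb <- generate_breaks(config, bundle)
  ap <- generate_ap_sites(config, bundle, ssb$truth)
  expr <- generate_expression(config, ssb$truth, bundle$tss)
  out <- list(bundle = bundle, ssb = ssb, ap = ap, expr = expr,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
    write_mask(bundle$non_repeat, file.path(dir, "non_repeat.bed"))
    write_mask(bundle$polyA_excluded, file.path(dir, "polyA_excluded.bed"))
    write_tss_table(bundle$tss, file.path(dir, "tss.tsv"))
    for (s in ssb$samples)
      write_breaks(s, file.path(dir, sprintf("ssb_%s.bed", s$sample_id)))
    for (s in ap$samples)
      write_breaks(s, file.path(dir, sprintf("ap_%s.bed", s$sample_id)))
    write_expression(expr, file.path(dir, "expression.tsv"))
    truth <- list(
      hot_pool = as.data.frame(ssb$truth$hot_pool),
      gene_flags = as.data.frame(ssb$truth$gene_flags),
      ap_pool = as.data.frame(ap$truth$ap_pool),
      ap_coupling_mode = ap$truth$mode,
      config = config[setdiff(names(config), "enrichment_profile")],
      enrichment_profile = as.list(config$enrichment_profile))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
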