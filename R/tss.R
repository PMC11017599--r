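#' The six TSS distance bins
#'
#' Non-overlapping absolute-distance bins partitioning the +/- 200 bp core
#' around TSSs: |d| <= 5, 6-20, 21-50, 51-100, 101-150, 151-200. Bins are
#' closed on both ends; the +/- 5 bin contains d = 0 (11 positions in all).
#'
#' @return data.table (bin, lo, hi)
#' @export
distance_bins <- function() {
  data.table(bin = c("pm5", "pm6_20", "pm21_50", "pm51_100",
                     "pm101_150", "pm151_200"),
             lo = c(0L, 6L, 21L, 51L, 101L, 151L),
             hi = c(5L, 20L, 50L, 100L, 150L, 200L))
}

bin_of_distance <- function(abs_d) {
  b <- distance_bins()
  idx <- findInterval(abs_d, b$lo)
  lab <- rep(NA_character_, length(abs_d))
  ok <- idx >= 1L & abs_d <= b$hi[pmax(idx, 1L)]
  lab[ok] <- b$bin[idx[ok]]
  lab
}

# representative TSS per unique (chrom, tss_pos): first row in
# (gene_id, transcript_id) order -- deterministic tie resolution
unique_tss <- function(tss) {
  t <- as.data.table(tss)
  setorder(t, chrom, tss_pos, gene_id, transcript_id)
  t[, .SD[1L], by = .(chrom, tss_pos)]
}

#' Assign positions to their nearest TSS
#'
#' For each stranded position, distances to all TSSs on the same chromosome
#' are considered and only the shortest is kept; positions farther than
#' `max_distance` from every TSS are dropped. Equidistant ties resolve to
#' the TSS with the smaller genomic coordinate; among transcripts sharing a
#' TSS coordinate, the lexicographically first (gene_id, transcript_id) row
#' represents the TSS. A break whose strand differs from the gene strand
#' lies on the template strand.
#'
#' @param positions data.table with chrom, pos, strand
#' @param tss a [tss_table]
#' @param max_distance maximum |distance| retained (default 5000)
#' @return data.table with chrom, pos, strand, gene_id, tss_pos,
#'   gene_strand, signed_distance (pos - tss_pos, genome coordinates),
#'   abs_distance, strand_class (`"template"`/`"nontemplate"`)
#' @export
assign_to_tss <- function(positions, tss, max_distance = 5000L) {
  p <- as.data.table(positions)[, .(chrom, pos, strand)]
  t <- unique_tss(tss)
  out <- lapply(split(p, by = "chrom"), function(pc) {
    tc <- t[chrom == pc$chrom[1]]
    if (nrow(tc) == 0L) return(NULL)
    tp <- tc$tss_pos                      # sorted
    i <- findInterval(pc$pos, tp)
    dl <- ifelse(i >= 1L, pc$pos - tp[pmax(i, 1L)], Inf)
    dr <- ifelse(i < length(tp), tp[pmin(i + 1L, length(tp))] - pc$pos, Inf)
    use_left <- dl <= dr                  # tie -> smaller coordinate
    j <- ifelse(use_left, i, i + 1L)
    d <- ifelse(use_left, dl, -dr)        # signed: pos - tss_pos
    keep <- abs(d) <= max_distance
    if (!any(keep)) return(NULL)
    cbind(pc[keep],
          tc[j[keep], .(gene_id, tss_pos, gene_strand)],
          signed_distance = as.integer(ifelse(use_left, 1L, -1L)[keep] *
                                         abs(d)[keep]))
  })
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), gene_id = character(),
                      tss_pos = integer(), gene_strand = character(),
                      signed_distance = integer(), abs_distance = integer(),
                      strand_class = character()))
  res[, abs_distance := abs(signed_distance)]
  res[, strand_class := ifelse(strand != gene_strand,
                               "template", "nontemplate")]
  res[]
}

#' Union of +/- flank windows around all TSSs
#'
#' Positions p with |p - tss| <= flank, i.e. half-open intervals
#' `[t - flank, t + flank + 1)`, merged across TSSs and clipped to
#' chromosome bounds.
#'
#' @param tss a tss_table
#' @param flank window half-width in bp
#' @param genome_bounds named chromosome lengths
#' @return a [genome_mask]
#' @export
tss_windows <- function(tss, flank, genome_bounds) {
  t <- unique_tss(tss)
  genome_mask(t$chrom,
              pmax(t$tss_pos - flank, 0L),
              pmin(t$tss_pos + flank + 1L, genome_bounds[t$chrom]),
              role = sprintf("tss_pm%d", flank))
}

# region whose nearest-TSS distance falls in [lo, hi]:
# union(+/-hi windows) minus union(+/-(lo-1) windows). This matches the
# nearest-TSS assignment used for the bin counts M_i: a base within
# [lo, hi] of one TSS but closer than lo to another belongs to the inner
# bin, not this one.
bin_windows <- function(tss, lo, hi, genome_bounds) {
  outer <- tss_windows(tss, hi, genome_bounds)
  if (lo == 0L) return(outer)
  mask_diff(outer, tss_windows(tss, lo - 1L, genome_bounds), role = "bin")
}

#' TSS enrichment ratio R
#'
#' `R = (M200 / M5000) / (L200 / L5000)` where M200 and M5000 are the
#' numbers of unique stranded positions within the merged +/- 200 bp and
#' +/- 5000 bp windows around TSSs, and L200, L5000 the corresponding
#' effective (non-repeat, non-polyA-adjacent) window lengths. Under uniform
#' placement R is 1; values above 1 quantify TSS-proximal enrichment.
#'
#' @param positions data.table with chrom, pos, strand (deduplicated
#'   internally)
#' @param tss a tss_table
#' @param non_repeat,polyA_excluded masks used for effective lengths
#' @param genome_bounds named chromosome lengths
#' @param inner,outer window half-widths (default 200 / 5000)
#' @return list with M_inner, M_outer, L_inner, L_outer, R
#' @export
enrichment_ratio <- function(positions, tss, non_repeat,
                             polyA_excluded = NULL, genome_bounds,
                             inner = 200L, outer = 5000L) {
  p <- unique(as.data.table(positions)[, .(chrom, pos, strand)])
  w_in <- tss_windows(tss, inner, genome_bounds)
  w_out <- tss_windows(tss, outer, genome_bounds)
  M_in <- sum(in_mask(w_in, p$chrom, p$pos))
  M_out <- sum(in_mask(w_out, p$chrom, p$pos))
  L_in <- effective_length(w_in, non_repeat, polyA_excluded)
  L_out <- effective_length(w_out, non_repeat, polyA_excluded)
  if (M_out == 0) stop("no positions within the outer TSS window")
  if (L_in == 0) stop("effective inner window length is zero")
  list(M_inner = M_in, M_outer = M_out, L_inner = L_in, L_outer = L_out,
       R = (M_in / M_out) / (L_in / L_out))
}

#' Per-distance-bin odds ratios of TSS enrichment
#'
#' For each bin i, `OR_i = (M_i / T_i) / (L_i / LG)`: M_i is the number of
#' positions assigned (nearest-TSS) to the bin, T_i the total number of
#' positions genome-wide in the set, L_i the effective length of the bin's
#' merged windows, and LG the effective non-repeat length of the genome
#' (both lengths excluding polyA-adjacent sequence). That formula is
#' calibrated (uniform placement gives OR = 1) when M_i counts positions of
#' both strands (`strand_class == "both"`). For template/nontemplate-split
#' counts only one strand per base qualifies, so the candidate space halves
#' and those rows use `OR = (M / T) / (L / (2 LG))`; uniform placement then
#' gives 1 for every row.
#'
#' @inheritParams enrichment_ratio
#' @return data.table (bin, lo, hi, strand_class, M, T, L, LG, OR) with
#'   strand_class in both/template/nontemplate
#' @export
bin_or_table <- function(positions, tss, non_repeat, polyA_excluded = NULL,
                         genome_bounds) {
  p <- unique(as.data.table(positions)[, .(chrom, pos, strand)])
  T_i <- nrow(p)
  if (T_i == 0L) stop("empty position set (T = 0)")
  LG <- mask_length(mappable_mask(non_repeat, polyA_excluded))
  asg <- assign_to_tss(p, tss, max_distance = 200L)
  asg[, bin := bin_of_distance(abs_distance)]
  bins <- distance_bins()
  grid <- CJ(bin = bins$bin,
             strand_class = c("both", "template", "nontemplate"))
  cnt <- rbind(asg[!is.na(bin), .(M = .N), by = .(bin, strand_class)],
               asg[!is.na(bin), .(strand_class = "both", M = .N), by = bin])
  grid <- cnt[grid, on = c("bin", "strand_class")]
  grid[is.na(M), M := 0L]
  grid <- bins[grid, on = "bin"]
  Ls <- vapply(seq_len(nrow(bins)), function(i)
    effective_length(bin_windows(tss, bins$lo[i], bins$hi[i], genome_bounds),
                     non_repeat, polyA_excluded), 0)
  grid[, L := Ls[match(bin, bins$bin)]]
  if (any(grid$L == 0)) stop("a distance bin has zero effective length")
  grid[, `:=`(T = T_i, LG = LG)]
  grid[, OR := fifelse(strand_class == "both",
                       (M / T) / (L / LG),
                       (M / T) / (L / (2 * LG)))]
  setorder(grid, lo, strand_class)
  grid[]
}

#' Odds ratio for one distance bin and strand class
#'
#' Convenience wrapper around [bin_or_table()] returning a single OR_i.
#'
#' @inheritParams enrichment_ratio
#' @param bin one of the labels of [distance_bins()]
#' @param strand_class `"both"`, `"template"` or `"nontemplate"`
#' @export
bin_odds_ratio <- function(positions, tss, bin, strand_class, non_repeat,
                           polyA_excluded = NULL, genome_bounds) {
  tab <- as.data.frame(bin_or_table(positions, tss, non_repeat,
                                    polyA_excluded, genome_bounds))
  row <- tab[tab$bin == bin & tab$strand_class == strand_class, ]
  if (nrow(row) != 1L) stop("unknown bin or strand_class")
  row$OR
}

#' Template vs nontemplate count ratio
#'
#' @param template,nontemplate per-bin hotspot counts
#' @return `template / nontemplate`; NA with a warning when the
#'   nontemplate count is zero
#' @export
template_nontemplate_ratio <- function(template, nontemplate) {
  out <- template / nontemplate
  if (any(nontemplate == 0)) {
    warning("nontemplate count is zero; ratio reported as missing")
    out[nontemplate == 0] <- NA_real_
  }
  out
}

# per-chromosome prefix sums of the mappable indicator
mappable_prefix <- function(mappable, genome_bounds) {
  m <- as.data.table(mappable)
  lapply(setNames(names(genome_bounds), names(genome_bounds)), function(ch) {
    v <- logical(genome_bounds[[ch]])
    mc <- m[chrom == ch]
    for (i in seq_len(nrow(mc))) v[(mc$start[i] + 1L):mc$end[i]] <- TRUE
    c(0, cumsum(v))
  })
}

# mappable bp within 0-based half-open [a, b) on chromosome ch
mappable_bp <- function(prefix, ch, a, b) {
  cum <- prefix[[ch]]
  L <- length(cum) - 1L
  a <- pmin(pmax(a, 0L), L); b <- pmin(pmax(b, 0L), L)
  ifelse(b > a, cum[b + 1L] - cum[a + 1L], 0)
}

#' Aggregate TSS density profile
#'
#' The +/- `flank` region around each TSS is split into `2*flank/binwidth`
#' non-overlapping bins (500 bins of 20 bp by default). For each bin j the
#' mean mappable fraction f_j over all TSSs is computed; each position is
#' assigned to its nearest TSS and the bin of its signed genomic distance.
#' The normalised density is `D_j = (n_j / N) / f_j`, computed separately
#' per strand class, with N the class total; D_j is NA where f_j = 0.
#'
#' @inheritParams enrichment_ratio
#' @param flank profile half-width (default 5000)
#' @param binwidth bin width in bp (default 20)
#' @return data.table (bin, bin_start, bin_end, strand_class, n, f, D);
#'   bin_start/bin_end are signed distances relative to the TSS
#' @export
density_profile <- function(positions, tss, non_repeat,
                            polyA_excluded = NULL, genome_bounds,
                            flank = 5000L, binwidth = 20L) {
  nbin <- as.integer(2L * flank / binwidth)
  t <- unique_tss(tss)
  prefix <- mappable_prefix(mappable_mask(non_repeat, polyA_excluded),
                            genome_bounds)
  # mean mappable fraction per bin over all TSSs
  fsum <- numeric(nbin)
  for (ch in unique(t$chrom)) {
    tp <- t[chrom == ch, tss_pos]
    for (j in seq_len(nbin)) {
      a <- tp - flank + (j - 1L) * binwidth
      fsum[j] <- fsum[j] + sum(mappable_bp(prefix, ch, a, a + binwidth))
    }
  }
  f <- fsum / (nrow(t) * binwidth)
  asg <- assign_to_tss(positions, tss, max_distance = flank)
  if (nrow(asg) == 0L) stop("no positions within the profile window")
  asg[, bin := pmin(signed_distance %/% binwidth + nbin %/% 2L + 1L, nbin)]
  out <- CJ(bin = seq_len(nbin),
            strand_class = c("template", "nontemplate"))
  cnt <- asg[, .(n = .N), by = .(bin, strand_class)]
  out <- cnt[out, on = c("bin", "strand_class")]
  out[is.na(n), n := 0L]
  out[, `:=`(bin_start = -flank + (bin - 1L) * binwidth,
             bin_end = -flank + bin * binwidth,
             f = f[bin])]
  out[, N_class := sum(n), by = strand_class]
  out[, D := ifelse(f > 0, (n / N_class) / f, NA_real_)]
  setorder(out, strand_class, bin)
  out[, .(bin, bin_start, bin_end, strand_class, n, f, D)]
}

#' Estimate the TSS-proximal template-strand bias from break events
#'
#' Depth-weighted template:nontemplate event ratio over all positions
#' within `max_distance` of a TSS (nearest-TSS assignment). Weighting by
#' read depth counts break events rather than unique positions, so the
#' estimate is not attenuated by position saturation at dense sites and
#' not inflated by recurrence; it is the natural estimator of the
#' template:nontemplate odds of the underlying break process.
#'
#' @param samples list of [break_sample]s (depth carried per record)
#' @param tss a tss_table
#' @param max_distance window half-width (default 200)
#' @return list: ratio, events_template, events_nontemplate
#' @export
template_bias_estimate <- function(samples, tss, max_distance = 200L) {
  rec <- rbindlist(lapply(samples, function(s) s$records))
  dsum <- rec[, .(depth = sum(depth)), by = .(chrom, pos, strand)]
  asg <- assign_to_tss(dsum[, .(chrom, pos, strand)], tss, max_distance)
  asg <- dsum[asg, on = c("chrom", "pos", "strand")]
  et <- asg[strand_class == "template", sum(depth)]
  en <- asg[strand_class == "nontemplate", sum(depth)]
  list(ratio = et / en, events_template = et, events_nontemplate = en)
}

#' Paired one-sided Wilcoxon signed-rank test across tissues
#'
#' Tests whether the per-tissue values in `a` exceed (or fall below) the
#' paired values in `b`. Zero differences are excluded (standard
#' signed-rank convention); the p-value is exact when there are no ties
#' among the remaining absolute differences.
#'
#' @param a,b equal-length paired numeric vectors (one value per tissue)
#' @param direction `"greater"` tests a > b, `"less"` tests a < b
#' @return one-sided p-value
#' @export
paired_tissue_test <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  suppressWarnings(
    wilcox.test(d, alternative = direction, exact = TRUE)$p.value)
}
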