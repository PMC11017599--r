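#' Pick one representative transcript per gene
#'
#' Gene-level expression is represented by a single annotated transcript
#' chosen uniformly at random per gene; the choice is deterministic under a
#' fixed seed and recorded in the output.
#'
#' @param tss a [tss_table]
#' @param rng_seed integer seed
#' @return data.table (gene_id, transcript_id)
#' @export
representative_transcript <- function(tss, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  t <- as.data.table(tss)
  setorder(t, gene_id, transcript_id)
  t[, .(transcript_id = transcript_id[sample.int(.N, 1L)]), by = gene_id]
}

#' Mean TPM per gene within one tissue
#'
#' @param expr genes x samples TPM matrix
#' @param tissue_map named character vector, sample id -> tissue
#' @param tissue tissue label
#' @return named numeric vector, gene -> mean TPM
#' @export
tissue_expression <- function(expr, tissue_map, tissue) {
  cols <- names(tissue_map)[tissue_map == tissue]
  cols <- intersect(cols, colnames(expr))
  if (length(cols) == 0L) stop("unknown tissue or no samples: ", tissue)
  rowMeans(expr[, cols, drop = FALSE])
}

#' Gene-level hotspot status around TSSs
#'
#' For each gene, considers every annotated TSS of the gene and every
#' hotspot within `max_distance` bp of it, and records -- per strand class
#' (template = hotspot strand opposite the gene strand) -- the minimum
#' absolute distance and the corresponding hierarchical distance bin (the
#' most TSS-proximal of the six bins containing a hotspot on that strand).
#' Genes without any hotspot within range are absent from the result.
#'
#' @param hotspots data.table with chrom, pos, strand
#' @param tss a tss_table
#' @param max_distance window half-width (default 200)
#' @return data.table (gene_id, strand_class, min_abs_distance, bin)
#' @export
gene_hotspot_status <- function(hotspots, tss, max_distance = 200L) {
  h <- unique(as.data.table(hotspots)[, .(chrom, pos, strand)])
  t <- as.data.table(tss)
  empty <- data.table(gene_id = character(), strand_class = character(),
                      min_abs_distance = integer(), bin = character())
  if (nrow(h) == 0L || nrow(t) == 0L) return(empty)
  tw <- t[, .(chrom, start = tss_pos - max_distance,
              end = tss_pos + max_distance, gene_id, gene_strand, tss_pos)]
  hq <- h[, .(chrom, start = pos, end = pos, pos, strand)]
  setkey(tw, chrom, start, end)
  ov <- foverlaps(hq, tw, type = "within", nomatch = NULL)
  if (nrow(ov) == 0L) return(empty)
  ov[, `:=`(abs_distance = abs(pos - tss_pos),
            strand_class = ifelse(strand != gene_strand,
                                  "template", "nontemplate"))]
  res <- ov[, .(min_abs_distance = min(abs_distance)),
            by = .(gene_id, strand_class)]
  res[, bin := bin_of_distance(min_abs_distance)]
  setorder(res, gene_id, strand_class)
  res[]
}

#' Compare expression of genes with vs without TSS-proximal hotspots
#'
#' Two-sided Wilcoxon rank-sum test of `log2(TPM + 1)` between genes that
#' do and do not carry a hotspot within the TSS window, judged over any
#' annotated TSS of the gene and the requested strand scope.
#'
#' @param status output of [gene_hotspot_status()] for the tissue
#' @param expr_values named numeric vector, gene -> TPM (e.g. from
#'   [tissue_expression()]); its names define the full gene universe
#' @param strand_scope `"either"`, `"template"` or `"nontemplate"`
#' @return an `expression_comparison` list: n_with, n_without, median_with,
#'   median_without (medians of log2(TPM+1)), p_value (NA with a message
#'   when a group is empty)
#' @export
with_without_comparison <- function(status, expr_values,
                                    strand_scope = c("either", "template",
                                                     "nontemplate")) {
  strand_scope <- match.arg(strand_scope)
  st <- as.data.table(status)
  if (strand_scope != "either") st <- st[strand_class == strand_scope]
  with_genes <- intersect(unique(st$gene_id), names(expr_values))
  without_genes <- setdiff(names(expr_values), with_genes)
  xa <- log2(expr_values[with_genes] + 1)
  xb <- log2(expr_values[without_genes] + 1)
  p <- if (length(xa) == 0L || length(xb) == 0L) {
    message("with_without_comparison: a group is empty; untestable")
    NA_real_
  } else suppressWarnings(wilcox.test(xa, xb)$p.value)
  if (is.nan(p)) p <- 1   # fully tied groups carry no evidence
  structure(list(strand_scope = strand_scope,
                 n_with = length(xa), n_without = length(xb),
                 median_with = median(xa), median_without = median(xb),
                 p_value = p),
            class = "expression_comparison")
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat(sprintf(
    "<expression_comparison (%s): with n=%d md=%.2f | without n=%d md=%.2f | p=%.3g>\n",
    x$strand_scope, x$n_with, x$median_with, x$n_without, x$median_without,
    x$p_value))
  invisible(x)
}

#' Hierarchical distance-bin expression analysis pooled across tissues
#'
#' Builds the 12 gene groups (6 distance bins x template/nontemplate) used
#' to relate hotspot proximity to expression. Per tissue and strand a gene
#' sits in its most TSS-proximal bin; groups are then pooled as the union
#' over tissues, each gene contributing the mean TPM of the tissue in which
#' it qualified. With `pool = "most_proximal"` a gene is instead restricted
#' to its single most proximal bin across all tissues. Pairwise two-sided
#' rank-sum tests are computed between bins within each strand class.
#'
#' @param status_by_tissue named list (tissue -> [gene_hotspot_status()]
#'   output)
#' @param expr genes x samples TPM matrix
#' @param tissue_map named character vector, sample -> tissue
#' @param pool `"per_tissue"` (union over tissues, default) or
#'   `"most_proximal"`
#' @return list with `groups` (gene_id, tissue, strand_class, bin, tpm,
#'   log2_tpm) and `tests` (strand_class, bin_a, bin_b, n_a, n_b, median_a,
#'   median_b, p_value); empty groups are excluded from tests with a message
#' @export
hierarchical_bins <- function(status_by_tissue, expr, tissue_map,
                              pool = c("per_tissue", "most_proximal")) {
  pool <- match.arg(pool)
  st <- rbindlist(lapply(names(status_by_tissue), function(ti)
    cbind(as.data.table(status_by_tissue[[ti]]), tissue = ti)))
  if (nrow(st) == 0L) stop("no gene hotspot status in any tissue")
  if (pool == "most_proximal") {
    st[, best := min(min_abs_distance), by = .(gene_id, strand_class)]
    st <- st[bin == bin_of_distance(best)][, best := NULL]
  }
  means <- lapply(setNames(names(status_by_tissue), names(status_by_tissue)),
                  function(ti) tissue_expression(expr, tissue_map, ti))
  st[, tpm := vapply(seq_len(.N), function(i)
    unname(means[[tissue[i]]][gene_id[i]]), 0)]
  st <- st[!is.na(tpm)]
  st[, log2_tpm := log2(tpm + 1)]
  bins <- distance_bins()$bin
  tests <- rbindlist(lapply(c("template", "nontemplate"), function(sc) {
    rbindlist(lapply(seq_along(bins)[-length(bins)], function(i) {
      rbindlist(lapply((i + 1):length(bins), function(j) {
        xa <- st[strand_class == sc & bin == bins[i], log2_tpm]
        xb <- st[strand_class == sc & bin == bins[j], log2_tpm]
        if (length(xa) == 0L || length(xb) == 0L) {
          message(sprintf("hierarchical_bins: empty group (%s %s/%s); skipped",
                          sc, bins[i], bins[j]))
          return(NULL)
        }
        data.table(strand_class = sc, bin_a = bins[i], bin_b = bins[j],
                   n_a = length(xa), n_b = length(xb),
                   median_a = median(xa), median_b = median(xb),
                   p_value = suppressWarnings(wilcox.test(xa, xb)$p.value))
      }))
    }))
  }))
  list(groups = st[, .(gene_id, tissue, strand_class, bin, tpm, log2_tpm)],
       tests = tests)
}
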