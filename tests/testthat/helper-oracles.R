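`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force oracles and tiny fixture builders. These deliberately use
# naive per-element scans (and no breakome internals) so they stay
# independent of the implementation paths they check.

make_sample <- function(id, tissue, chrom, pos, strand, depth = 1L) {
  break_sample(id, tissue,
               data.frame(chrom = chrom, pos = pos, strand = strand,
                          depth = depth))
}

random_sample <- function(id, tissue, n, L, chroms = "chr1",
                          max_depth = 3L) {
  key <- unique(data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(L, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE)))
  key$depth <- sample.int(max_depth, nrow(key), replace = TRUE)
  break_sample(id, tissue, key)
}

pos_key <- function(df) paste(df$chrom, df$pos, df$strand)

# enumerate every observed position; count samples meeting the depth cut
bf_sample_shared <- function(samples, min_depth, min_samples) {
  all_pos <- unique(do.call(rbind, lapply(samples, function(s)
    s$records[, c("chrom", "pos", "strand")])))
  keep <- vapply(seq_len(nrow(all_pos)), function(i) {
    k <- pos_key(all_pos[i, ])
    hits <- sum(vapply(samples, function(s) {
      r <- s$records[pos_key(s$records) == k, ]
      nrow(r) == 1L && r$depth >= min_depth
    }, NA))
    hits >= min_samples
  }, NA)
  all_pos[keep, , drop = FALSE]
}

bf_sample_level <- function(samples, min_depth) {
  hits <- do.call(rbind, lapply(samples, function(s)
    s$records[s$records$depth >= min_depth, c("chrom", "pos", "strand")]))
  unique(hits)
}

# naive nearest-TSS scan: all pairwise distances, smallest wins,
# ties to the smaller genomic coordinate
bf_nearest_tss <- function(chrom, pos, tss_df, max_distance) {
  cand <- tss_df[tss_df$chrom == chrom, ]
  cand <- cand[!duplicated(cand$tss_pos), ]
  if (nrow(cand) == 0L) return(NULL)
  d <- abs(pos - cand$tss_pos)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.min(cand$tss_pos[best])]
  if (d[best] > max_distance) return(NULL)
  list(tss_pos = cand$tss_pos[best], gene_strand = cand$gene_strand[best],
       signed = pos - cand$tss_pos[best])
}

bf_bin_label <- function(abs_d) {
  if (abs_d <= 5) "pm5" else if (abs_d <= 20) "pm6_20"
  else if (abs_d <= 50) "pm21_50" else if (abs_d <= 100) "pm51_100"
  else if (abs_d <= 150) "pm101_150" else if (abs_d <= 200) "pm151_200"
  else NA_character_
}

# per-position membership scan for windows |pos - tss| <= flank
bf_count_in_windows <- function(pos_df, tss_df, flank) {
  sum(vapply(seq_len(nrow(pos_df)), function(i) {
    any(tss_df$chrom == pos_df$chrom[i] &
          abs(pos_df$pos[i] - tss_df$tss_pos) <= flank)
  }, NA))
}

# brute-force effective length: per-base membership scan
bf_effective_length <- function(intervals, non_repeat, polyA, L,
                                chrom = "chr1") {
  inside <- function(m, p) {
    mm <- as.data.frame(m)
    any(mm$chrom == chrom & mm$start <= p & p < mm$end)
  }
  total <- 0L
  iv <- as.data.frame(intervals)
  for (r in seq_len(nrow(iv))) {
    for (p in seq.int(iv$start[r], iv$end[r] - 1L)) {
      if (inside(non_repeat, p) &&
          (is.null(polyA) || !inside(polyA, p))) total <- total + 1L
    }
  }
  total
}

# strand-oriented CG test by explicit string handling
bf_cg_hit <- function(seq_chars, pos, strand) {
  L <- length(seq_chars)
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  base_at <- function(k) {        # strand-oriented offset k from pos
    g <- if (strand == "+") pos + k else pos - k
    if (g < 0 || g >= L) return(NA_character_)
    b <- seq_chars[g + 1L]
    if (strand == "+") b else rc[[b]]
  }
  b0 <- base_at(0); b1 <- base_at(1); b2 <- base_at(2)
  if (is.na(b1) || is.na(b2)) return(NA)   # not testable
  (identical(b0, "C") && identical(b1, "G")) ||
    (identical(b1, "C") && identical(b2, "G"))
}

random_mask <- function(L, n_iv = 5L, chrom = "chr1", role = "non_repeat") {
  s <- sort(sample.int(L, 2L * n_iv))
  genome_mask(rep(chrom, n_iv), s[seq(1, 2 * n_iv, 2)] - 1L,
              s[seq(2, 2 * n_iv, 2)], role = role)
}

tiny_tss <- function(chrom, tss_pos, gene_strand,
                     gene_id = sprintf("g%03d", seq_along(tss_pos))) {
  tss_table(data.frame(gene_id = gene_id,
                       transcript_id = paste0(gene_id, ".t1"),
                       chrom = chrom, tss_pos = tss_pos,
                       strand = gene_strand))
}

random_dna <- function(L, prob = rep(0.25, 4)) {
  paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
         collapse = "")
}

as_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- if (is.null(names(seqs))) paste0("chr", seq_along(seqs))
              else names(seqs)
  g
}
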