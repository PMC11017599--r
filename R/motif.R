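#' Extract strand-oriented sequence windows around positions
#'
#' Returns the `2*flank + 1`-mer centred on each position, in strand
#' orientation: windows on the - strand are reverse-complemented so that
#' column 1 is the 5'-most base. The centre column (`flank + 1`) holds the
#' base at `pos` itself -- the base immediately 5' of the nick, which sits
#' between the centre column and the next one. Windows truncated by contig
#' ends are excluded; their count is reported via `message()`.
#'
#' @param positions data.table with chrom, pos, strand
#' @param genome a named DNAStringSet
#' @param flank half-width in bp (default 5)
#' @return character vector of windows (one per retained position)
#' @export
extract_windows <- function(positions, genome, flank = 5L) {
  p <- as.data.table(positions)[, .(chrom, pos, strand)]
  bounds <- genome_bounds(genome)
  ok <- p$pos - flank >= 0L & p$pos + flank < bounds[p$chrom]
  if (any(!ok))
    message(sprintf("extract_windows: excluded %d window(s) truncated by contig ends",
                    sum(!ok)))
  p <- p[ok]
  if (nrow(p) == 0L) return(character())
  out <- character(nrow(p))
  for (ch in unique(p$chrom)) {
    idx <- which(p$chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           start = p$pos[idx] - flank + 1L,
                           end = p$pos[idx] + flank + 1L)
    w <- as.character(v)
    minus <- p$strand[idx] == "-"
    if (any(minus))
      w[minus] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(w[minus])))
    out[idx] <- w
  }
  out
}

#' Positional base fractions of a window set
#'
#' Counts the fraction of each base (A, C, G, T) at each window column.
#' Ambiguous bases (anything else, e.g. N) are excluded from that column's
#' denominator.
#'
#' @param windows character vector of equal-length windows
#' @return a `base_fraction_matrix`: 4 x width numeric matrix (rows A, C,
#'   G, T), with attributes `n_sequences` and `counts`
#' @export
base_fractions <- function(windows) {
  if (length(windows) == 0L) stop("empty window list")
  wl <- unique(nchar(windows))
  if (length(wl) != 1L) stop("windows must share one length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, wl, dimnames = list(bases, NULL))
  for (b in bases) if (b %in% rownames(cm)) counts[b, ] <- cm[b, ]
  denom <- colSums(counts)
  frac <- sweep(counts, 2, pmax(denom, 1), "/")
  structure(frac, n_sequences = length(windows), counts = counts,
            class = c("base_fraction_matrix", class(frac)))
}

#' Signed base-composition differences above a display threshold
#'
#' Retains only cells where the fraction in `a` exceeds that in `b` (or
#' vice versa, with negative sign) by strictly more than `threshold`
#' (default 0.05); everything else is suppressed.
#'
#' @param a,b base fraction matrices of identical shape
#' @param threshold strict display cutoff
#' @return data.table (position, base, difference) of retained cells;
#'   position is the window column index
#' @export
difference_profile <- function(a, b, threshold = 0.05) {
  if (!all(dim(a) == dim(b))) stop("matrices must share shape")
  d <- unclass(a) - unclass(b)
  keep <- which(abs(d) > threshold, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    return(data.table(position = integer(), base = character(),
                      difference = numeric()))
  out <- data.table(position = keep[, 2L],
                    base = rownames(d)[keep[, 1L]],
                    difference = d[keep])
  setorder(out, position, base)
  out[]
}

#' Cytosine enrichment immediately upstream of the break
#'
#' SSBs with 3'-OH termini tend to occur immediately 3' of a cytosine; this
#' compares the C fraction at the centre column (the base 5' of the nick)
#' between a hotspot window set and a background window set, with a
#' two-proportion test.
#'
#' @param hotspot_windows,background_windows equal-width strand-oriented
#'   window sets (see [extract_windows()])
#' @return list: c_hotspot, c_background, difference, p_value
#' @export
upstream_c_enrichment <- function(hotspot_windows, background_windows) {
  fa <- base_fractions(hotspot_windows)
  fb <- base_fractions(background_windows)
  centre <- (ncol(fa) + 1L) %/% 2L
  ca <- unname(attr(fa, "counts")["C", centre])
  cb <- unname(attr(fb, "counts")["C", centre])
  na <- sum(attr(fa, "counts")[, centre])
  nb <- sum(attr(fb, "counts")[, centre])
  p <- suppressWarnings(
    prop.test(c(ca, cb), c(na, nb))$p.value)
  list(c_hotspot = ca / na, c_background = cb / nb,
       difference = ca / na - cb / nb, p_value = p)
}
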