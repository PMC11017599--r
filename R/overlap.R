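#' Chromosome lengths of a genome
#' @param genome a named `Biostrings::DNAStringSet`
#' @return named integer vector
#' @export
genome_bounds <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

# per-chromosome character vectors, cached per call site
genome_chars <- function(genome) {
  lapply(setNames(names(genome), names(genome)), function(ch)
    strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]])
}

#' Shift AP-site coordinates upstream by one base
#'
#' During base-excision repair the APE1 endonuclease nicks immediately 5'
#' of the AP site, so detecting that break against an SSB map requires
#' shifting the AP coordinate upstream by 1 base in strand orientation
#' ("AP - 1"): `pos - 1` on the + strand, `pos + 1` on the - strand.
#' Positions shifted off the chromosome are dropped with a warning.
#'
#' @param positions data.table with chrom, pos, strand
#' @param genome_bounds named chromosome lengths
#' @return data.table of shifted positions
#' @export
shift_ap_upstream <- function(positions, genome_bounds) {
  p <- as.data.table(positions)[, .(chrom, pos, strand)]
  p[, pos := pos + ifelse(strand == "+", -1L, 1L)]
  bad <- p$pos < 0L | p$pos >= genome_bounds[p$chrom]
  if (any(bad)) {
    warning(sprintf("shift_ap_upstream: %d position(s) left chromosome bounds and were dropped",
                    sum(bad)))
    p <- p[!bad]
  }
  p[]
}

#' Overlap odds ratio between SSB and AP position sets
#'
#' `OOR = (O / T) / (M / LG)` where O is the number of positions shared
#' between the SSB and AP sets, T and M the SSB and AP set sizes, and LG
#' the effective non-repeat genome length. In mode `"ap_minus_1"` the AP
#' coordinates are first shifted one base upstream (see
#' [shift_ap_upstream()]) to detect the APE1-generated nick; mode
#' `"direct"` detects the post-fill-in nick of short-patch BER. Overlap is
#' strand-matched by default. A companion Fisher exact p-value is computed
#' from the 2x2 table (overlap vs not) x (SSB position vs rest of the LG
#' candidate space).
#'
#' @param ssb,ap data.tables with chrom, pos, strand
#' @param LG effective non-repeat genome length in bp
#' @param mode `"direct"` or `"ap_minus_1"`
#' @param genome_bounds required when mode = "ap_minus_1" and
#'   `pre_shifted = FALSE`
#' @param strand_matched require matching strand for an overlap (default
#'   TRUE); FALSE compares positions only
#' @param pre_shifted set TRUE when the AP set was already shifted
#' @return an `overlap_result` list: mode, O, T, M, LG, OOR, fraction_ssb
#'   (O/T), fraction_ap (O/M), p_value
#' @export
overlap_odds_ratio <- function(ssb, ap, LG,
                               mode = c("direct", "ap_minus_1"),
                               genome_bounds = NULL, strand_matched = TRUE,
                               pre_shifted = FALSE) {
  mode <- match.arg(mode)
  s <- unique(as.data.table(ssb)[, .(chrom, pos, strand)])
  a <- unique(as.data.table(ap)[, .(chrom, pos, strand)])
  T_i <- nrow(s); M_i <- nrow(a)
  if (T_i == 0L || M_i == 0L) stop("empty SSB or AP set")
  if (mode == "ap_minus_1" && !pre_shifted) {
    if (is.null(genome_bounds))
      stop("genome_bounds required to shift AP coordinates")
    a <- shift_ap_upstream(a, genome_bounds)
  }
  by_cols <- if (strand_matched) c("chrom", "pos", "strand")
             else c("chrom", "pos")
  O <- nrow(unique(s[, ..by_cols])[unique(a[, ..by_cols]),
                                   on = by_cols, nomatch = NULL])
  OOR <- (O / T_i) / (M_i / LG)
  tab <- matrix(c(O, T_i - O, M_i - O, round(LG) - T_i - (M_i - O)), 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  structure(list(mode = mode, O = O, T = T_i, M = M_i, LG = LG, OOR = OOR,
                 fraction_ssb = O / T_i, fraction_ap = O / M_i,
                 p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result %s: O=%d T=%d M=%d OOR=%.3g p=%.3g>\n",
              x$mode, x$O, x$T, x$M, x$OOR, x$p_value))
  invisible(x)
}

# strand-oriented CG context of one chromosome's positions.
# '|' marks the nick, which sits 3' of pos: C|G means base(pos)=C and
# base(pos+1)=G in strand orientation; |CG means base(pos+1)=C and
# base(pos+2)=G.
cg_context_chrom <- function(s, pos, strand) {
  L <- length(s)
  n <- length(pos)
  computable <- ifelse(strand == "+", pos + 3L <= L, pos - 2L >= 0L)
  cg <- icg <- rep(NA, n)
  plus <- strand == "+" & computable
  if (any(plus)) {
    p <- pos[plus]
    cg[plus] <- s[p + 1L] == "C" & s[p + 2L] == "G"
    icg[plus] <- s[p + 2L] == "C" & s[p + 3L] == "G"
  }
  minus <- strand == "-" & computable
  if (any(minus)) {
    p <- pos[minus]
    cg[minus] <- s[p + 1L] == "G" & s[p] == "C"
    icg[minus] <- s[p] == "G" & s[p - 1L] == "C"
  }
  data.table(computable = computable, c_g = cg, cg_next = icg)
}

#' CG-dinucleotide context of break positions
#'
#' Classifies each stranded position by whether the break falls in a CG
#' dinucleotide context on its own strand: either `C|G` (break between the
#' C and the G) or `|CG` (break immediately 5' of a CG), with `|` marking
#' the nick 3' of `pos`. Positions too close to a contig end for the test
#' are excluded from the denominator and counted.
#'
#' @param positions data.table with chrom, pos, strand
#' @param genome a named DNAStringSet
#' @return a `cg_context_result` list: n_total (testable positions),
#'   n_in_cg, fraction, n_c_g, n_cg_next, n_excluded
#' @export
cg_context <- function(positions, genome) {
  p <- as.data.table(positions)[, .(chrom, pos, strand)]
  chars <- genome_chars(genome)
  res <- rbindlist(lapply(split(p, by = "chrom"), function(pc)
    cg_context_chrom(chars[[pc$chrom[1]]], pc$pos, pc$strand)))
  n_excl <- sum(!res$computable)
  ok <- res[computable == TRUE]
  n_cg <- sum(ok$c_g | ok$cg_next)
  structure(list(n_total = nrow(ok), n_in_cg = n_cg,
                 fraction = if (nrow(ok)) n_cg / nrow(ok) else NA_real_,
                 n_c_g = sum(ok$c_g), n_cg_next = sum(ok$cg_next),
                 n_excluded = n_excl),
            class = "cg_context_result")
}

#' Background CG-context fraction of masked genome space
#'
#' Exhaustively applies the same `C|G`-or-`|CG` rule of [cg_context()] to
#' every stranded position of the masked space (optionally further
#' restricted to a region such as the merged TSS windows), and returns the
#' fraction of testable position-strand slots that would fire. This is the
#' expected CG fraction under uniform break placement.
#'
#' @param genome a named DNAStringSet
#' @param mask a genome_mask (e.g. non-repeat space)
#' @param region optional genome_mask restricting the computation
#' @return background fraction
#' @export
cg_background <- function(genome, mask, region = NULL) {
  space <- if (is.null(region)) mask else
    mask_intersect(mask, region, role = "region")
  if (mask_length(space) == 0) stop("empty masked space")
  m <- as.data.table(space)
  fires <- 0; slots <- 0
  chars <- genome_chars(genome)
  for (ch in unique(m$chrom)) {
    s <- chars[[ch]]
    L <- length(s)
    isC <- s == "C"; isG <- s == "G"
    mc <- m[chrom == ch]
    pos <- unlist(lapply(seq_len(nrow(mc)), function(i)
      seq.int(mc$start[i], mc$end[i] - 1L)))
    # + strand, computable when pos <= L - 3 (0-based)
    pp <- pos[pos <= L - 3L]
    fires <- fires + sum((isC[pp + 1L] & isG[pp + 2L]) |
                           (isC[pp + 2L] & isG[pp + 3L]))
    slots <- slots + length(pp)
    # - strand, computable when pos >= 2
    pm <- pos[pos >= 2L]
    fires <- fires + sum((isC[pm] & isG[pm + 1L]) |
                           (isC[pm - 1L] & isG[pm]))
    slots <- slots + length(pm)
  }
  fires / slots
}
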