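#' Genomic masks: sorted, disjoint, half-open intervals
#'
#' A `genome_mask` stores 0-based half-open intervals `[start, end)` per
#' chromosome, sorted and non-overlapping, with a role tag (e.g.
#' `"non_repeat"` for the mappable, repeat-free portion of the genome, or
#' `"polyA_excluded"` for positions adjacent to endogenous polyA stretches
#' where the break-capture chemistry cannot map reads).
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors; 0-based half-open interval bounds
#' @param role mask role tag
#' @param bounds optional named integer vector of chromosome lengths; when
#'   given, intervals must fall within bounds
#' @return a `genome_mask` (a `data.table` with columns chrom, start, end)
#' @export
genome_mask <- function(chrom, start, end, role = "non_repeat", bounds = NULL) {
  dt <- data.table(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end))
  if (any(dt$end < dt$start)) stop("negative-length interval in mask")
  if (!is.null(bounds)) {
    bad <- dt$start < 0L | dt$end > bounds[dt$chrom]
    if (any(bad, na.rm = TRUE) || anyNA(bounds[dt$chrom]))
      stop("mask interval outside chromosome bounds")
  }
  setkey(dt, chrom, start, end)
  # merge touching/overlapping intervals so the disjointness invariant holds
  out <- dt[, {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
    list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }, by = chrom]
  setattr(out, "role", role)
  setattr(out, "class", c("genome_mask", class(out)))
  out[]
}

#' @export
print.genome_mask <- function(x, ...) {
  cat(sprintf("<genome_mask role=%s: %d intervals, %s bp on %d chromosome(s)>\n",
              attr(x, "role") %||% "?", nrow(x),
              format(mask_length(x), big.mark = ","),
              length(unique(x$chrom))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_irl <- function(mask) {
  # IRangesList keyed by chrom, 1-based closed coordinates
  split(IRanges::IRanges(start = mask$start + 1L, end = mask$end),
        mask$chrom)
}

mask_from_irl <- function(irl, role) {
  dt <- rbindlist(lapply(names(irl), function(ch) {
    ir <- IRanges::reduce(irl[[ch]])
    if (length(ir) == 0L) return(NULL)
    data.table(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  }))
  if (nrow(dt) == 0L)
    dt <- data.table(chrom = character(), start = integer(), end = integer())
  genome_mask(dt$chrom, dt$start, dt$end, role = role)
}

mask_binop <- function(a, b, f, role) {
  ia <- as_irl(a); ib <- as_irl(b)
  chroms <- union(names(ia), names(ib))
  empty <- IRanges::IRanges()
  out <- lapply(setNames(chroms, chroms), function(ch)
    f(ia[[ch]] %||% empty, ib[[ch]] %||% empty))
  mask_from_irl(out, role)
}

#' Intersection, difference and union of genome masks
#'
#' Exact base-pair set arithmetic on [genome_mask] objects, delegated to
#' IRanges per chromosome.
#'
#' @param a,b genome masks
#' @param role role tag of the result
#' @return a `genome_mask`
#' @export
mask_intersect <- function(a, b, role = attr(a, "role"))
  mask_binop(a, b, IRanges::intersect, role)

#' @rdname mask_intersect
#' @export
mask_diff <- function(a, b, role = attr(a, "role"))
  mask_binop(a, b, IRanges::setdiff, role)

#' @rdname mask_intersect
#' @export
mask_union <- function(a, b, role = attr(a, "role"))
  mask_binop(a, b, IRanges::union, role)

#' Total mask length in base pairs
#' @param mask a genome mask
#' @return number of bases covered (double, exact)
#' @export
mask_length <- function(mask) sum(as.numeric(mask$end - mask$start))

#' Complement of a mask within chromosome bounds
#' @param mask a genome mask
#' @param bounds named integer vector of chromosome lengths
#' @param role role tag of the result
#' @export
mask_complement <- function(mask, bounds, role = "complement") {
  full <- genome_mask(names(bounds), rep(0L, length(bounds)),
                      as.integer(bounds), role = role)
  mask_diff(full, mask, role = role)
}

#' Membership of single positions in a mask
#' @param mask a genome mask
#' @param chrom,pos vectors of chromosome names and 0-based positions
#' @return logical vector
#' @export
in_mask <- function(mask, chrom, pos) {
  q <- data.table(chrom = as.character(chrom), start = as.integer(pos),
                  end = as.integer(pos) + 1L, idx = seq_along(pos))
  m <- as.data.table(mask)[, .(chrom, start, end)]
  setkey(m, chrom, start, end)
  ov <- foverlaps(q, m, type = "within", nomatch = NULL, which = TRUE)
  res <- rep(FALSE, length(pos))
  res[q$idx[ov$xid]] <- TRUE
  res
}

#' Keep only break records whose position lies inside a mask
#'
#' Hotspot calling and all downstream statistics operate in the non-repeat
#' portion of the genome; this filter applies that restriction. Input order
#' is preserved.
#'
#' @param records a data.table of break records (chrom, pos, strand, depth)
#'   or a [break_sample]
#' @param mask a [genome_mask]
#' @return object of the same type as `records`, subset to in-mask positions
#' @export
mask_filter <- function(records, mask) {
  if (inherits(records, "break_sample")) {
    records$records <- mask_filter(records$records, mask)
    return(records)
  }
  records[in_mask(mask, records$chrom, records$pos)]
}

#' Effective (mappable) length of a set of intervals
#'
#' Computes `| intervals `intersect` non_repeat \ polyA_excluded |` in base
#' pairs, exactly. This is the length normaliser used by the TSS enrichment
#' ratio R and the per-bin odds ratios: window and genome lengths count only
#' non-repeat sequence that is not adjacent to endogenous polyA stretches.
#'
#' @param intervals a genome_mask (or data.table with chrom/start/end) of
#'   query intervals, half-open
#' @param non_repeat non-repeat mask
#' @param polyA_excluded optional polyA-adjacency exclusion mask
#' @return effective length in bp (double)
#' @export
effective_length <- function(intervals, non_repeat, polyA_excluded = NULL) {
  if (any(intervals$end < intervals$start))
    stop("negative-length interval")
  if (!inherits(intervals, "genome_mask"))
    intervals <- genome_mask(intervals$chrom, intervals$start, intervals$end,
                             role = "query")
  eff <- mask_intersect(intervals, non_repeat, role = "effective")
  if (!is.null(polyA_excluded))
    eff <- mask_diff(eff, polyA_excluded, role = "effective")
  mask_length(eff)
}

#' Mappable space: non-repeat minus polyA-adjacent exclusions
#' @param non_repeat non-repeat mask
#' @param polyA_excluded polyA exclusion mask (or NULL)
#' @return a `genome_mask` with role `"mappable"`
#' @export
mappable_mask <- function(non_repeat, polyA_excluded = NULL) {
  if (is.null(polyA_excluded)) {
    m <- genome_mask(non_repeat$chrom, non_repeat$start, non_repeat$end,
                     role = "mappable")
    return(m)
  }
  mask_diff(non_repeat, polyA_excluded, role = "mappable")
}

#' Read / write BED3 interval masks
#' @param path file path
#' @param role role tag for the mask
#' @param bounds optional chromosome bounds
#' @export
read_mask <- function(path, role = "non_repeat", bounds = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end"), select = 1:3)
  genome_mask(dt$chrom, dt$start, dt$end, role = role, bounds = bounds)
}

#' @rdname read_mask
#' @param mask mask to write
#' @export
write_mask <- function(mask, path) {
  fwrite(as.data.table(mask)[, .(chrom, start, end)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}
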