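#' Strand-specific single-nucleotide break samples
#'
#' A `break_sample` holds the deduplicated break records of one biological
#' sample: strand-specific single-nucleotide positions with a read depth
#' (PCR duplicates are assumed already removed upstream). `pos` is 0-based
#' and marks the base immediately 5' of the nick in strand orientation
#' (the base carrying the 3'-OH terminus).
#'
#' @param sample_id sample identifier
#' @param tissue non-empty tissue label
#' @param records data.table/data.frame with columns chrom, pos, strand
#'   (`"+"`/`"-"`) and depth (integer >= 1)
#' @param genome_bounds optional named integer vector of chromosome lengths;
#'   records outside bounds are an error here (use [read_breaks()] for
#'   reject-and-log semantics)
#' @return a `break_sample` object
#' @export
break_sample <- function(sample_id, tissue, records, genome_bounds = NULL) {
  if (!nzchar(tissue)) stop("tissue label must be non-empty")
  rec <- as.data.table(records)
  if (nrow(rec) == 0L) {
    rec <- data.table(chrom = character(), pos = integer(),
                      strand = character(), depth = integer())
  } else {
    rec <- rec[, .(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), depth = as.integer(depth))]
    if (!all(rec$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(rec$depth < 1L)) stop("depth must be >= 1")
    if (anyDuplicated(rec, by = c("chrom", "pos", "strand")))
      stop("duplicate position: (chrom,pos,strand) must be unique within a sample")
    if (!is.null(genome_bounds)) {
      bad <- rec$pos < 0L | rec$pos >= genome_bounds[rec$chrom]
      if (any(bad, na.rm = TRUE) || anyNA(genome_bounds[rec$chrom]))
        stop("break position outside chromosome bounds")
    }
  }
  structure(list(sample_id = sample_id, tissue = tissue, records = rec),
            class = "break_sample")
}

#' @export
print.break_sample <- function(x, ...) {
  cat(sprintf("<break_sample %s (%s): %d positions, %s reads>\n",
              x$sample_id, x$tissue, nrow(x$records),
              format(sum(x$records$depth), big.mark = ",")))
  invisible(x)
}

#' Read a break file (BED6, score column = read depth)
#'
#' Expects tab-separated lines `chrom  start  end  name  depth  strand` with
#' `end == start + 1` (single-nucleotide features). Records outside
#' `genome_bounds` are rejected and their count reported via `message()`.
#'
#' @param path input file
#' @param genome_bounds named integer vector of chromosome lengths
#' @param sample_id,tissue sample metadata (defaults derived from file name)
#' @return a [break_sample]
#' @export
read_breaks <- function(path, genome_bounds, sample_id = NULL,
                        tissue = "unknown") {
  if (is.null(sample_id))
    sample_id <- sub("\\.bed$", "", basename(path))
  if (file.size(path) == 0L)
    return(break_sample(sample_id, tissue, data.frame()))
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t",
          col.names = c("chrom", "start", "end", "name", "depth", "strand"),
          colClasses = list(character = c(1, 4, 6), integer = c(2, 3, 5))),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  if (nrow(dt) > 0L) {
    bad <- which(dt$end != dt$start + 1L)
    if (length(bad))
      stop(sprintf("format error in %s line %d: end != start + 1",
                   path, bad[1]))
    oob <- dt$pos <- dt$start
    oob <- is.na(genome_bounds[dt$chrom]) | dt$pos < 0L |
      dt$pos >= genome_bounds[dt$chrom]
    if (any(oob)) {
      message(sprintf("read_breaks: rejected %d/%d records outside bounds in %s",
                      sum(oob), nrow(dt), basename(path)))
      dt <- dt[!oob]
    }
  } else dt[, pos := integer()]
  break_sample(sample_id, tissue,
               dt[, .(chrom, pos, strand, depth)])
}

#' @rdname read_breaks
#' @param sample a break_sample to write
#' @export
write_breaks <- function(sample, path) {
  rec <- sample$records
  out <- data.table(chrom = rec$chrom, start = rec$pos, end = rec$pos + 1L,
                    name = ".", depth = rec$depth, strand = rec$strand)
  setorder(out, chrom, start, strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' TSS annotation table
#'
#' One row per annotated transcript: gene id, transcript id, chromosome,
#' 0-based TSS position and gene (sense) strand. A gene may own multiple
#' TSSs. A break on the strand opposite the gene strand lies on the
#' template strand.
#'
#' @param df data.frame with columns gene_id, transcript_id, chrom,
#'   tss_pos, strand
#' @param genome_bounds optional chromosome bounds for validation
#' @return a keyed `tss_table` data.table (column `strand` is renamed
#'   `gene_strand` internally)
#' @export
tss_table <- function(df, genome_bounds = NULL) {
  dt <- as.data.table(df)
  if ("strand" %in% names(dt) && !"gene_strand" %in% names(dt))
    setnames(dt, "strand", "gene_strand")
  need <- c("gene_id", "transcript_id", "chrom", "tss_pos", "gene_strand")
  if (!all(need %in% names(dt)))
    stop("tss table needs columns: ", paste(need, collapse = ", "))
  dt <- dt[, .(gene_id = as.character(gene_id),
               transcript_id = as.character(transcript_id),
               chrom = as.character(chrom), tss_pos = as.integer(tss_pos),
               gene_strand = as.character(gene_strand))]
  if (!all(dt$gene_strand %in% c("+", "-"))) stop("gene strand must be +/-")
  if (!is.null(genome_bounds)) {
    bad <- dt$tss_pos < 0L | dt$tss_pos >= genome_bounds[dt$chrom]
    if (any(bad, na.rm = TRUE)) stop("tss_pos outside chromosome bounds")
  }
  setorder(dt, chrom, tss_pos, gene_id, transcript_id)
  setattr(dt, "class", c("tss_table", class(dt)))
  dt[]
}

#' @rdname tss_table
#' @param path TSV file with header gene_id, transcript_id, chrom, tss_pos,
#'   strand
#' @export
read_tss_table <- function(path, genome_bounds = NULL) {
  tss_table(fread(path, sep = "\t", header = TRUE), genome_bounds)
}

#' @rdname tss_table
#' @param tss table to write
#' @export
write_tss_table <- function(tss, path) {
  out <- as.data.table(tss)[, .(gene_id, transcript_id, chrom, tss_pos,
                                strand = gene_strand)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read / write a genes x samples TPM expression matrix
#'
#' TSV with a `gene_id` first column and one column per sample. Values are
#' TPM (>= 0); downstream displays use `log2(TPM + 1)`.
#'
#' @param path TSV path
#' @return numeric matrix, genes in rows
#' @export
read_expression <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  if (any(m < 0)) stop("TPM values must be >= 0")
  m
}

#' @rdname read_expression
#' @param m expression matrix (genes x samples)
#' @export
write_expression <- function(m, path) {
  dt <- data.table(gene_id = rownames(m))
  dt <- cbind(dt, as.data.table(m))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

# distinct (chrom,pos,strand) positions from a list of break samples
pool_positions <- function(samples) {
  unique(rbindlist(lapply(samples, function(s)
    s$records[, .(chrom, pos, strand)])))
}
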