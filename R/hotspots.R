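#' Hotspot stringency definitions
#'
#' Three stringencies are used throughout:
#' * sample-level: positions with depth >= 2 within a single sample
#'   (union over the tissue's samples),
#' * sample-shared, depth >= 1: positions seen in >= 2 independent samples,
#' * sample-shared, depth >= 2: positions with depth >= 2 in >= 2 samples.
#'
#' @param mode `"sample_level"` or `"sample_shared"`
#' @param min_depth minimum within-sample read depth
#' @param min_samples minimum number of distinct samples (sample_shared only)
#' @return a `hotspot_definition`
#' @export
hotspot_definition <- function(mode = c("sample_level", "sample_shared"),
                               min_depth = if (mode == "sample_level") 2L else 1L,
                               min_samples = 2L) {
  mode <- match.arg(mode)
  min_depth <- as.integer(min_depth)
  min_samples <- as.integer(min_samples)
  if (mode == "sample_level" && min_depth < 2L)
    stop("sample_level hotspots require min_depth >= 2")
  if (mode == "sample_shared" && min_samples < 2L)
    stop("sample_shared hotspots require min_samples >= 2")
  structure(list(mode = mode, min_depth = min_depth,
                 min_samples = if (mode == "sample_shared") min_samples else NA_integer_),
            class = "hotspot_definition")
}

#' @export
format.hotspot_definition <- function(x, ...) {
  if (x$mode == "sample_level")
    sprintf("sample_level(depth>=%d)", x$min_depth)
  else
    sprintf("sample_shared(depth>=%d, samples>=%d)", x$min_depth, x$min_samples)
}

#' @export
print.hotspot_definition <- function(x, ...) {
  cat("<hotspot_definition ", format(x), ">\n", sep = ""); invisible(x)
}

new_hotspot_set <- function(positions, definition, tissue) {
  setorder(positions, chrom, pos, strand)
  setattr(positions, "definition", definition)
  setattr(positions, "tissue", tissue)
  setattr(positions, "class", c("hotspot_set", class(positions)))
  positions[]
}

#' Call sample-level hotspots
#'
#' A sample-level hotspot is a (chrom, pos, strand) position where a break
#' was captured by at least `min_depth` independent reads within a single
#' sample; the tissue-level set is the union over the tissue's samples.
#'
#' @param samples list of [break_sample]s from one tissue
#' @param min_depth minimum within-sample depth (>= 2)
#' @return a `hotspot_set`: data.table (chrom, pos, strand, n_samples) where
#'   n_samples counts the samples individually satisfying the depth cut
#' @export
call_sample_level <- function(samples, min_depth = 2L) {
  if (length(samples) == 0L) stop("empty sample list")
  def <- hotspot_definition("sample_level", min_depth = min_depth)
  tissue <- unique(vapply(samples, `[[`, "", "tissue"))
  if (length(tissue) > 1L) stop("all samples must share one tissue")
  hits <- rbindlist(lapply(samples, function(s)
    s$records[depth >= min_depth, .(chrom, pos, strand)]))
  pos <- if (nrow(hits)) hits[, .(n_samples = .N), by = .(chrom, pos, strand)]
  else data.table(chrom = character(), pos = integer(),
                  strand = character(), n_samples = integer())
  new_hotspot_set(pos, def, tissue)
}

#' Call sample-shared hotspots
#'
#' A sample-shared hotspot is a position where the within-sample depth
#' reaches `min_depth` in at least `min_samples` distinct samples of the
#' tissue.
#'
#' @param samples list of [break_sample]s (>= 2)
#' @param min_depth minimum within-sample depth
#' @param min_samples minimum number of samples (>= 2)
#' @param tissue tissue label attached to the result (default: the samples'
#'   common label, or `"merged"` when samples span tissues)
#' @return a `hotspot_set` with an n_samples column
#' @export
call_sample_shared <- function(samples, min_depth = 1L, min_samples = 2L,
                               tissue = NULL) {
  if (length(samples) < 2L) stop("sample_shared calling needs >= 2 samples")
  if (min_samples > length(samples))
    stop("min_samples exceeds the number of samples")
  def <- hotspot_definition("sample_shared", min_depth = min_depth,
                            min_samples = min_samples)
  if (is.null(tissue)) {
    tl <- unique(vapply(samples, `[[`, "", "tissue"))
    tissue <- if (length(tl) == 1L) tl else "merged"
  }
  hits <- rbindlist(lapply(samples, function(s)
    s$records[depth >= min_depth, .(chrom, pos, strand)]))
  pos <- if (nrow(hits)) {
    cnt <- hits[, .(n_samples = .N), by = .(chrom, pos, strand)]
    cnt[n_samples >= min_samples]
  } else data.table(chrom = character(), pos = integer(),
                    strand = character(), n_samples = integer())
  new_hotspot_set(pos, def, tissue)
}

#' Call hotspots under a given definition
#' @param samples list of break samples
#' @param definition a [hotspot_definition]
#' @param ... passed on (e.g. `tissue` for sample-shared calling)
#' @export
call_hotspots <- function(samples, definition, ...) {
  if (definition$mode == "sample_level")
    call_sample_level(samples, min_depth = definition$min_depth)
  else
    call_sample_shared(samples, min_depth = definition$min_depth,
                       min_samples = definition$min_samples, ...)
}

#' Pooled distinct break positions of a tissue
#'
#' The universe against which hotspot fractions are reported: all distinct
#' (chrom, pos, strand) break positions pooled over the tissue's samples
#' (after non-repeat filtering).
#'
#' @param samples list of break samples
#' @return data.table of distinct positions
#' @export
breaks_universe <- function(samples) pool_positions(samples)

#' Fraction of the break universe called as hotspots
#' @param hotspots a hotspot_set
#' @param universe pooled distinct break positions (see [breaks_universe()])
#' @return `|hotspots| / |universe|`
#' @export
hotspot_fraction <- function(hotspots, universe) {
  if (nrow(universe) == 0L) stop("empty breaks universe")
  nrow(hotspots) / nrow(universe)
}

#' Cohort-merged sample-shared hotspots
#'
#' Sample-shared calling across all samples of all tissues at once (sharing
#' is allowed across tissue boundaries). Used when per-tissue hotspot sets
#' are too small, e.g. for TSS-proximal SSB-AP overlap.
#'
#' @param all_samples list of break samples from any tissues (>= 2)
#' @inheritParams call_sample_shared
#' @export
merged_cohort_hotspots <- function(all_samples, min_depth = 1L,
                                   min_samples = 2L) {
  call_sample_shared(all_samples, min_depth = min_depth,
                     min_samples = min_samples, tissue = "merged")
}
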