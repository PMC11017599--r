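#' Draw uniform random break positions over mappable space
#'
#' Samples `n` distinct (chrom, pos, strand) triples uniformly, without
#' replacement, from the positions covered by `mappable_space` crossed with
#' the two strands. This is the randomised-placement null used to judge
#' whether observed hotspot fractions exceed chance.
#'
#' @param n number of positions to draw
#' @param mappable_space a [genome_mask] of mappable positions
#' @param rng_seed optional integer seed
#' @return data.table (chrom, pos, strand)
#' @export
simulate_breaks <- function(n, mappable_space, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- as.integer(n)
  m <- as.data.table(mappable_space)
  lens <- m$end - m$start
  S <- sum(as.numeric(lens))
  if (n > 2 * S) stop("n exceeds mappable capacity (positions x 2 strands)")
  if (n == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character()))
  k <- sample.int(2 * S, n)            # distinct slots over positions x strands
  strand <- ifelse(k > S, "-", "+")
  posidx <- ifelse(k > S, k - S, k)    # 1-based index into mappable positions
  cum <- cumsum(as.numeric(lens))
  row <- findInterval(posidx - 0.5, c(0, cum))
  pos <- m$start[row] + as.integer(posidx - c(0, cum)[row] - 1)
  data.table(chrom = m$chrom[row], pos = pos, strand = strand)
}

#' Randomised-placement null for hotspot occurrence
#'
#' For each of `n_iter` iterations, every sample's break positions are
#' regenerated uniformly at random over the mappable space (same position
#' count per sample), hotspots are re-called with the identical definition,
#' and the hotspot fraction of the simulated pooled universe is recorded.
#' The observed fraction is then compared against the simulated vector with
#' a two-sided one-sample Student t test, and summarised as the ratio
#' `real_fraction / mean(simulated_fractions)`.
#'
#' Simulated depths are resampled from each real sample's empirical depth
#' distribution (`depth_mode = "empirical"`, the default) so that
#' depth-thresholded definitions are exercised; `depth_mode = "min_depth"`
#' instead sets every simulated depth to the definition's threshold.
#'
#' @param samples list of [break_sample]s (already non-repeat-filtered)
#' @param definition a [hotspot_definition]
#' @param mappable_space mask over which positions are regenerated
#' @param real_fraction observed hotspot fraction under the same definition
#'   and mask; computed from `samples` when NULL
#' @param n_iter number of iterations (default 100)
#' @param rng_seed integer seed; the run is bit-reproducible given the seed
#' @param depth_mode `"empirical"` or `"min_depth"`
#' @return a `null_result` list: n_iterations, simulated_fractions,
#'   real_fraction, ratio, p_value
#' @export
run_null <- function(samples, definition, mappable_space,
                     real_fraction = NULL, n_iter = 100L, rng_seed = NULL,
                     depth_mode = c("empirical", "min_depth")) {
  depth_mode <- match.arg(depth_mode)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(real_fraction)) {
    hs <- call_hotspots(samples, definition)
    real_fraction <- hotspot_fraction(hs, breaks_universe(samples))
  }
  counts <- vapply(samples, function(s) nrow(s$records), 0L)
  depths <- lapply(samples, function(s) s$records$depth)
  sims <- vapply(seq_len(n_iter), function(it) {
    sim_samples <- lapply(seq_along(samples), function(i) {
      posn <- simulate_breaks(counts[i], mappable_space)
      posn[, depth := if (depth_mode == "empirical" && length(depths[[i]]))
        sample(depths[[i]], .N, replace = TRUE) else definition$min_depth]
      structure(list(sample_id = paste0("sim_", i),
                     tissue = samples[[i]]$tissue, records = posn),
                class = "break_sample")
    })
    hs <- call_hotspots(sim_samples, definition)
    uni <- breaks_universe(sim_samples)
    if (nrow(uni) == 0L) 0 else nrow(hs) / nrow(uni)
  }, 0)
  mean_sim <- mean(sims)
  ratio <- if (mean_sim > 0) real_fraction / mean_sim else Inf
  if (sd(sims) == 0) {
    warning("simulated fractions have zero variance; p-value degenerate")
    p <- if (all(sims == real_fraction)) 1 else NA_real_
  } else {
    p <- t.test(sims, mu = real_fraction, alternative = "two.sided")$p.value
  }
  structure(list(n_iterations = n_iter, simulated_fractions = sims,
                 real_fraction = real_fraction, mean_simulated = mean_sim,
                 ratio = ratio, p_value = p,
                 definition = definition, seed = rng_seed),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf(
    "<null_result %s: real=%.3g mean(sim)=%.3g ratio=%.3g p=%.3g (%d iter)>\n",
    format(x$definition), x$real_fraction, x$mean_simulated, x$ratio,
    x$p_value, x$n_iterations))
  invisible(x)
}
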