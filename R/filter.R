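# Locus/sample inclusion rules: per-sample minimum depth, without-replacement
# subsampling to a fixed depth, and a minimum number of qualifying samples.

# Seed the RNG for the calling function's lifetime, restoring prior state.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible())
  withr::local_seed(seed, .local_envir = envir)
  invisible()
}

#' Which samples reach the minimum read count at each locus?
#'
#' A sample qualifies at a locus iff its summed allele counts (read depth)
#' at that locus reach `min_count`.
#'
#' @param loci Long locus tibble (see [read_loci()]).
#' @param min_count Minimum reads per sample per locus (default 10).
#' @return Tibble with one row per (locus, sample): `locus_id`, `sample`,
#'   `depth`, `qualifies`.
#' @export
qualify_samples <- function(loci, min_count = 10) {
  assert_loci_tbl(loci)
  loci %>%
    group_by(.data$locus_id, .data$sample) %>%
    summarise(depth = sum(.data$count), .groups = "drop") %>%
    mutate(qualifies = .data$depth >= min_count)
}

# Vectorized sequential multivariate-hypergeometric draw. `counts` is the
# count column of a long table sorted so each (locus, sample) group is
# contiguous; `grp` an integer group id per row; `target` the per-group
# depth. Groups whose total is <= target pass through unchanged.
subsample_counts_grouped <- function(counts, grp, target) {
  # grp must be 1..G with each group's rows contiguous and in order
  totals <- as.vector(rowsum(counts, grp))
  runs <- rle(grp)$lengths
  first <- cumsum(c(1L, head(runs, -1L)))
  aidx <- seq_along(grp) - rep(first, runs) + 1L
  k <- runs
  do <- totals > target
  out <- counts
  rem_total <- totals
  rem_target <- ifelse(do, target, totals)
  for (j in seq_len(max(k) - 1L)) {
    rows <- which(aidx == j)
    g <- grp[rows]
    active <- do[g] & k[g] > j
    r <- rows[active]; ga <- g[active]
    if (length(r) > 0) {
      drawn <- stats::rhyper(length(r), m = counts[r],
                             n = rem_total[ga] - counts[r],
                             k = rem_target[ga])
      out[r] <- drawn
      rem_total[ga] <- rem_total[ga] - counts[r]
      rem_target[ga] <- rem_target[ga] - drawn
    }
  }
  # last allele of each active group takes the remainder
  last_rows <- which(aidx == k[grp])
  gl <- grp[last_rows]
  act <- do[gl]
  out[last_rows[act]] <- rem_target[gl[act]]
  out
}

#' Downsample an allele-count vector to a fixed depth
#'
#' Draws `target` reads without replacement from the pool described by
#' `counts` (multivariate hypergeometric), so the result sums exactly to
#' `target` with every entry bounded by the original. Vectors already at or
#' below the target are returned unchanged only when equal to it; a total
#' below the target is a contract violation (qualify first).
#'
#' @param counts Non-negative integer vector of per-allele read counts.
#' @param target Target total depth.
#' @return Integer vector of the same length summing to `target`.
#' @export
subsample_counts <- function(counts, target) {
  n <- sum(counts)
  if (n < target) {
    abort(sprintf("Cannot subsample %d reads down to %d", n, target))
  }
  if (n == target) return(as.integer(counts))
  as.integer(subsample_counts_grouped(as.numeric(counts),
                                      rep(1L, length(counts)),
                                      target))
}

#' Drop loci observed in fewer than `min_found` qualifying samples
#'
#' @param loci Long locus tibble already restricted to qualifying
#'   (locus, sample) entries.
#' @param min_found Minimum number of qualifying samples for a locus to be
#'   retained at all (default 1).
#' @return Filtered long locus tibble; attribute `provenance` gains
#'   `loci_dropped_min_found`.
#' @export
apply_min_found <- function(loci, min_found = 1) {
  assert_loci_tbl(loci)
  samples <- sample_ids(loci)
  found <- loci %>%
    distinct(.data$locus_id, .data$sample) %>%
    count(.data$locus_id, name = "n_samples")
  keep_ids <- found$locus_id[found$n_samples >= min_found]
  out <- loci %>% filter(.data$locus_id %in% keep_ids)
  out <- set_loci_attrs(out, samples)
  prov <- attr(loci, "provenance") %||% list()
  prov$loci_dropped_min_found <- nrow(found) - length(keep_ids)
  attr(out, "provenance") <- prov
  attr(out, "skip_log") <- attr(loci, "skip_log")
  out
}

#' Apply the full locus/sample inclusion pipeline
#'
#' Stages, in order: (1) a sample is included at a locus only if its read
#' depth there is at least `min_count`; (2) included counts deeper than
#' `subsample` are downsampled without replacement to exactly `subsample`
#' reads (counts already equal to the target pass through); (3) loci
#' qualifying in fewer than `min_found` samples are removed entirely.
#' Staging qualification before subsampling means subsampling can never
#' change qualification status, so the pipeline is idempotent for
#' `subsample == min_count`.
#'
#' Randomness: a single seeded generator; hypergeometric draws are made
#' allele-rank-major over the (locus, sample) groups in (locus_id, sample
#' order) order, so runs are bit-reproducible given the seed and input
#' order.
#'
#' @param loci Long locus tibble from [read_loci()].
#' @param min_count Minimum reads per sample per locus (default 10).
#' @param subsample Target depth for downsampling; 0 disables. Must not
#'   exceed `min_count` when both are active.
#' @param min_found Minimum qualifying samples per locus (default 1).
#' @param seed Optional integer seed for the subsampling draws.
#' @return A `poolpg_filtered` tibble (long locus layout) containing only
#'   included (locus, sample) entries, with attributes `samples`, `params`
#'   and `provenance` (loci in, loci out, loci dropped, per-sample included
#'   locus counts).
#' @export
filter_loci <- function(loci, min_count = 10, subsample = 10, min_found = 1,
                        seed = NULL) {
  assert_loci_tbl(loci)
  if (min_found < 1) abort("`min_found` must be >= 1")
  if (subsample > 0 && subsample > min_count) {
    abort("`subsample` must not exceed `min_count` when both are active")
  }
  samples <- sample_ids(loci)
  local_seed(seed)

  n_loci_in <- n_distinct(loci$locus_id)

  qual <- qualify_samples(loci, min_count = min_count)
  kept <- loci %>%
    inner_join(qual %>% filter(.data$qualifies) %>%
                 select("locus_id", "sample", "depth"),
               by = c("locus_id", "sample")) %>%
    arrange(.data$locus_id, match(.data$sample, samples))

  if (subsample > 0 && nrow(kept) > 0) {
    grp_key <- paste(kept$locus_id, match(kept$sample, samples))
    grp <- match(grp_key, unique(grp_key))
    kept$count <- as.integer(
      subsample_counts_grouped(as.numeric(kept$count), grp, subsample))
  }
  kept$depth <- NULL

  out <- set_loci_attrs(kept, samples)
  attr(out, "provenance") <- list(loci_in = n_loci_in)
  out <- apply_min_found(out, min_found = min_found)

  prov <- attr(out, "provenance")
  prov$loci_out <- n_distinct(out$locus_id)
  # loci whose rows all failed min_count count as min_found drops too
  prov$loci_dropped_min_found <- prov$loci_in - prov$loci_out
  prov$included_per_sample <- out %>%
    distinct(.data$locus_id, .data$sample) %>%
    count(.data$sample, name = "included_loci") %>%
    tidyr::complete(sample = samples,
                    fill = list(included_loci = 0L)) %>%
    arrange(match(.data$sample, samples))
  attr(out, "provenance") <- prov
  attr(out, "params") <- list(min_count = min_count, subsample = subsample,
                              min_found = min_found, seed = seed)
  class(out) <- unique(c("poolpg_filtered", class(out)))
  out
}
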