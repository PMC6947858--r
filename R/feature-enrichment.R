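# Distance- and count-matched permutation background for interacting
# regions, feature-overlap z-scores, and the conditional co-factor test.
#
# Background sets preserve, per bait, both the number of interacting
# regions and their 50-kb distance-bin multiset; baited fragments are
# removed from the surrogate pool.

#' Build distance-matched background region sets
#'
#' For each observed region (bait, prey at distance d), every background
#' set receives one surrogate fragment drawn uniformly from the non-baited
#' fragments whose midpoint distance to the bait falls in the same
#' `bin_width` distance bin (`floor(d / bin_width)`). Sampling is without
#' replacement within a set per bait and independent across sets. When a
#' bin holds fewer candidates than needed, the nearest non-empty bins are
#' pooled in (a message reports the fallback).
#'
#' @param regions Region tibble with `bait_frag`, `prey_frag`, `distance`
#'   (one cell line / capture at a time is the intended use).
#' @param fragments Fragment map tibble.
#' @param bait_frag_ids All baited fragment ids (removed from the pool).
#' @param n_sets Number of background sets (default 100).
#' @param bin_width Distance bin width in bp (default 50 kb).
#' @param seed Integer seed recorded with the output.
#' @return Tibble: `set_index`, `bait_frag`, `surrogate_frag`, `bin`
#'   (the matched observed bin label).
#' @export
build_background_sets <- function(regions, fragments, bait_frag_ids,
                                  n_sets = 100, bin_width = 50000, seed = 1L) {
  if (nrow(regions) == 0) stop("no regions to build a background for")
  mid <- fragment_midpoint(fragments)
  regions$bin <- floor(regions$distance / bin_width)
  need <- dplyr::count(regions, .data$bait_frag, .data$bin, name = "k")
  withr::with_seed(seed, {
    out <- purrr::map_dfr(unique(need$bait_frag), function(b) {
      i <- match(b, fragments$frag_id)
      pool_idx <- which(fragments$chrom == fragments$chrom[i] &
                          !fragments$frag_id %in% bait_frag_ids)
      pool_bin <- floor(abs(mid[pool_idx] - mid[i]) / bin_width)
      pool_id <- fragments$frag_id[pool_idx]
      nb <- need[need$bait_frag == b, ]
      purrr::map_dfr(seq_len(nrow(nb)), function(r) {
        bin <- nb$bin[r]; k <- nb$k[r]
        cand <- pool_id[pool_bin == bin]
        if (length(cand) < k) {
          # pool in nearest non-empty bins until enough candidates
          for (delta in seq_len(max(pool_bin, bin) + 1)) {
            for (bb in c(bin - delta, bin + delta)) {
              if (length(cand) >= k) break
              cand <- unique(c(cand, pool_id[pool_bin == bb]))
            }
            if (length(cand) >= k) break
          }
          if (length(cand) == 0) {
            stop("no surrogate candidates for bait ", b, " in bin ", bin)
          }
          message("background bin fallback for bait ", b, ", bin ", bin)
        }
        draws <- vapply(seq_len(n_sets), function(s) {
          sample(cand, k, replace = length(cand) < k)
        }, integer(k))
        tibble::tibble(
          set_index = rep(seq_len(n_sets), each = k),
          bait_frag = b,
          surrogate_frag = as.integer(draws),
          bin = bin
        )
      })
    })
    attr(out, "seed") <- seed
    out
  })
}

# Fragment ids overlapping (>= 1 bp) at least one peak interval.
fragments_overlapping_peaks <- function(fragments, peaks) {
  if (nrow(peaks) == 0) return(integer(0))
  hits <- integer(0)
  for (cc in intersect(unique(fragments$chrom), unique(peaks$chrom))) {
    fr <- fragments[fragments$chrom == cc, ]
    pk <- peaks[peaks$chrom == cc, ]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(fr$start + 1, fr$end),
      IRanges::IRanges(pk$start + 1, pk$end)
    )
    hits <- c(hits, fr$frag_id[unique(S4Vectors::queryHits(ov))])
  }
  hits
}

#' Feature-overlap enrichment z-score
#'
#' Counts the interacting regions whose prey fragment overlaps at least one
#' peak of the feature (fragment-level binary overlap) and compares the
#' count to the same statistic over the matched background sets:
#' `z = (observed - null_mean) / null_sd`, with `z = 0` by convention (and
#' a warning) when the null SD is zero. Counting at the region level keeps
#' every background set exactly size-matched to the observed set.
#'
#' @param regions Region tibble (`prey_frag`, ...).
#' @param peaks Peak tibble (`chrom`, `start`, `end`) for one feature.
#' @param background_sets Output of [build_background_sets()].
#' @param fragments Fragment map tibble.
#' @param feature_name,cell_line Labels copied into the result.
#' @return One-row tibble: `feature_name`, `cell_line`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `n_sets`.
#' @export
enrichment_z <- function(regions, peaks, background_sets, fragments,
                         feature_name = NA_character_,
                         cell_line = NA_character_) {
  if (nrow(regions) == 0) stop("zero regions: enrichment undefined")
  overlap_ids <- fragments_overlapping_peaks(fragments, peaks)
  uniq <- dplyr::distinct(regions[, c("bait_frag", "prey_frag")])
  observed <- sum(uniq$prey_frag %in% overlap_ids)
  null_counts <- vapply(
    split(background_sets$surrogate_frag, background_sets$set_index),
    function(s) sum(s %in% overlap_ids), integer(1)
  )
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  if (is.na(null_sd) || null_sd == 0) {
    warning("null SD is zero; z set to 0 by convention")
    z <- 0
  } else {
    z <- (observed - null_mean) / null_sd
  }
  tibble::tibble(
    feature_name = feature_name, cell_line = cell_line,
    observed = observed, null_mean = null_mean,
    null_sd = ifelse(is.na(null_sd), 0, null_sd), z = z,
    n_sets = length(null_counts)
  )
}

#' Enrichment z-scores over all features and cell lines
#'
#' Convenience wrapper: builds one background per cell line (matched to
#' that cell line's regions) and computes [enrichment_z()] for every
#' feature/cell-line peak track.
#'
#' @param regions Region tibble with `cell_line`.
#' @param peaks Peak tibble with `feature_name` and `cell_label`.
#' @param fragments Fragment map tibble.
#' @param bait_frag_ids All baited fragment ids.
#' @param n_sets,bin_width,seed Passed to [build_background_sets()].
#' @param matched_only When `TRUE` (default), each cell line's regions are
#'   intersected only with peaks of the same `cell_label`.
#' @return Tibble of enrichment results, one row per feature x cell line.
#' @export
enrich_features <- function(regions, peaks, fragments, bait_frag_ids,
                            n_sets = 100, bin_width = 50000, seed = 1L,
                            matched_only = TRUE) {
  cells <- unique(regions$cell_line)
  purrr::map_dfr(seq_along(cells), function(ci) {
    cl <- cells[ci]
    rg <- regions[regions$cell_line == cl, ]
    bg <- build_background_sets(rg, fragments, bait_frag_ids,
                                n_sets = n_sets, bin_width = bin_width,
                                seed = seed + ci)
    pk_cell <- if (matched_only) peaks[peaks$cell_label == cl, ] else peaks
    purrr::map_dfr(unique(pk_cell$feature_name), function(feat) {
      enrichment_z(rg, pk_cell[pk_cell$feature_name == feat, ], bg,
                   fragments, feature_name = feat, cell_line = cl)
    })
  })
}

#' Conditional co-factor enrichment test
#'
#' Among interacting-region fragments, tests whether fragments bound by
#' feature A are enriched for feature B (2x2 Fisher's exact test,
#' two-sided). The odds ratio is the sample cross-product ratio with a
#' Haldane 0.5 correction when any cell is zero. Degenerate margins (all or
#' none of the fragments carry A, or B) return `NA` statistics.
#'
#' @param regions Region tibble (`prey_frag`).
#' @param peaks_a,peaks_b Peak tibbles for the two features.
#' @param fragments Fragment map tibble.
#' @return One-row tibble: `n_fragments`, `odds_ratio`, `p_value`, and the
#'   2x2 cell counts.
#' @export
conditional_cofactor_test <- function(regions, peaks_a, peaks_b, fragments) {
  frags <- unique(regions$prey_frag)
  has_a <- frags %in% fragments_overlapping_peaks(fragments, peaks_a)
  has_b <- frags %in% fragments_overlapping_peaks(fragments, peaks_b)
  n11 <- sum(has_a & has_b); n10 <- sum(has_a & !has_b)
  n01 <- sum(!has_a & has_b); n00 <- sum(!has_a & !has_b)
  if (all(has_a) || !any(has_a) || all(has_b) || !any(has_b)) {
    message("degenerate margin: conditional test undefined")
    return(tibble::tibble(n_fragments = length(frags),
                          odds_ratio = NA_real_, p_value = NA_real_,
                          n11 = n11, n10 = n10, n01 = n01, n00 = n00))
  }
  tab <- matrix(c(n11, n01, n10, n00), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  cc <- if (any(tab == 0)) 0.5 else 0
  or <- ((n11 + cc) * (n00 + cc)) / ((n10 + cc) * (n01 + cc))
  tibble::tibble(n_fragments = length(frags), odds_ratio = or, p_value = p,
                 n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}
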