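# Capture target fragment selection and 120-mer bait sequence QC.
#
# Baits are designed to both ends of restriction fragments. A candidate
# 120-mer is accepted when its GC content lies in [25%, 65%], its longest
# homopolymer run is at most 2 bases, and it sits within 330 bp of the
# nearer fragment end. Masked (lowercase or N) bases fail QC.

#' Select variant-capture target fragments
#'
#' Returns the fragments containing at least one credible causal variant
#' (CCV), with the variants they carry.
#'
#' @param variants Variant tibble (`variant_id`, `chrom`, `pos`, ...).
#' @param fragments Fragment map tibble.
#' @return Tibble with one row per (fragment, variant) membership:
#'   `frag`, `variant_id`, `signal_id`.
#' @export
select_vc_fragments <- function(variants, fragments) {
  if (nrow(variants) == 0) {
    return(tibble::tibble(frag = integer(), variant_id = character(),
                          signal_id = character()))
  }
  frag <- locate_fragment(fragments, variants$chrom, variants$pos)
  dplyr::arrange(
    tibble::tibble(frag = frag, variant_id = variants$variant_id,
                   signal_id = variants$signal_id),
    .data$frag
  )
}

#' Select promoter-capture target fragments
#'
#' Returns fragments containing at least one gene TSS lying within `window`
#' bp (inclusive) of at least one CCV position on the same chromosome.
#'
#' @param genes Gene tibble (one row per TSS).
#' @param variants Variant tibble.
#' @param fragments Fragment map tibble.
#' @param window Maximum TSS-to-CCV distance in bp (default 1 Mb).
#' @return Tibble with one row per (fragment, gene): `frag`, `gene_id`.
#' @export
select_pc_fragments <- function(genes, variants, fragments, window = 1e6) {
  if (nrow(genes) == 0) {
    return(tibble::tibble(frag = integer(), gene_id = character()))
  }
  near <- vapply(seq_len(nrow(genes)), function(i) {
    vv <- variants[variants$chrom == genes$chrom[i], ]
    nrow(vv) > 0 && any(abs(vv$pos - genes$tss[i]) <= window)
  }, logical(1))
  g <- genes[near, ]
  if (nrow(g) == 0) {
    return(tibble::tibble(frag = integer(), gene_id = character()))
  }
  out <- tibble::tibble(
    frag = locate_fragment(fragments, g$chrom, g$tss),
    gene_id = g$gene_id
  )
  dplyr::arrange(dplyr::distinct(out), .data$frag)
}

#' Bait sequence quality control
#'
#' Vectorised QC of candidate 120-mer bait sequences against a fragment.
#' A candidate is accepted iff GC content is between `gc_range[1]` and
#' `gc_range[2]` (inclusive), the longest homopolymer run is at most
#' `max_homopolymer`, and the nearer bait boundary lies within
#' `max_end_distance` bp of the nearer fragment end. Non-ACGT characters
#' (including lowercase masking) reject with reason `ambiguous_base`.
#'
#' @param candidate Character vector of candidate bait sequences.
#' @param frag_start,frag_end Fragment boundaries (0-based half-open).
#' @param bait_start 0-based start of each candidate within the chromosome.
#' @param bait_length Required bait length (default 120).
#' @param gc_range Inclusive GC bounds as fractions (default `c(0.25, 0.65)`).
#' @param max_homopolymer Longest allowed run of one base (default 2).
#' @param max_end_distance Maximum distance from the nearer fragment end
#'   (default 330 bp).
#' @return Tibble with `accept` (logical) and `reasons` (comma-separated
#'   reason codes among `ambiguous_base`, `gc`, `homopolymer`, `distance`;
#'   empty when accepted).
#' @export
qc_bait <- function(candidate, frag_start, frag_end, bait_start,
                    bait_length = 120L, gc_range = c(0.25, 0.65),
                    max_homopolymer = 2L, max_end_distance = 330L) {
  n <- length(candidate)
  frag_start <- rep_len(frag_start, n)
  frag_end <- rep_len(frag_end, n)
  bait_start <- rep_len(bait_start, n)
  if (any(nchar(candidate) != bait_length)) {
    stop("all candidates must have length ", bait_length)
  }
  bait_end <- bait_start + bait_length
  if (any(bait_start < frag_start | bait_end > frag_end)) {
    stop("bait interval must lie inside its fragment")
  }
  ambiguous <- grepl("[^ACGT]", candidate)
  gc <- stringr::str_count(candidate, "[GC]") / bait_length
  gc_ok <- gc >= gc_range[1] & gc <= gc_range[2]
  run_ok <- !grepl(sprintf("([ACGTN])\\1{%d,}", max_homopolymer), candidate)
  dist_ok <- pmin(bait_start - frag_start, frag_end - bait_end) <= max_end_distance
  reasons <- mapply(function(a, g, r, d) {
    paste(c(if (a) "ambiguous_base", if (!g) "gc", if (!r) "homopolymer",
            if (!d) "distance"), collapse = ",")
  }, ambiguous, gc_ok, run_ok, dist_ok)
  tibble::tibble(
    accept = !ambiguous & gc_ok & run_ok & dist_ok,
    gc = gc,
    reasons = unname(reasons)
  )
}

#' Design baits for target fragments
#'
#' For each target fragment, candidate 120-mers are enumerated in 1-bp steps
#' from each fragment end inward until the end-distance limit; the accepted
#' candidate closest to the end is chosen for that end. Fragments shorter
#' than the bait length, or with no accepted candidate on either end, are
#' reported unbaitable.
#'
#' @param fragments Fragment map tibble.
#' @param target_frag_ids Fragment ids to design baits for.
#' @param sequences Named character vector of chromosome sequences (masked
#'   bases as lowercase or `N`; these fail QC).
#' @param bait_length,gc_range,max_homopolymer,max_end_distance QC
#'   parameters, see [qc_bait()].
#' @return A list with `baits` (tibble: `frag_id`, `end` in left/right,
#'   `chrom`, `start`, `end_pos`, `sequence`) and `report` (tibble:
#'   `frag_id`, `end`, `status`, `reasons` of the closest rejected candidate
#'   when no candidate passed).
#' @export
design_baits <- function(fragments, target_frag_ids, sequences,
                         bait_length = 120L, gc_range = c(0.25, 0.65),
                         max_homopolymer = 2L, max_end_distance = 330L) {
  targets <- fragments[fragments$frag_id %in% target_frag_ids, ]
  if (nrow(targets) < length(unique(target_frag_ids))) {
    stop("unknown target fragment id(s)")
  }
  res <- purrr::pmap(targets, function(frag_id, chrom, start, end) {
    seq <- sequences[[chrom]]
    if (is.null(seq)) stop("no sequence for chromosome ", chrom)
    design_fragment_ends(frag_id, chrom, start, end, seq, bait_length,
                         gc_range, max_homopolymer, max_end_distance)
  })
  baits <- dplyr::bind_rows(purrr::map(res, "baits"))
  report <- dplyr::bind_rows(purrr::map(res, "report"))
  list(baits = baits, report = report)
}

design_fragment_ends <- function(frag_id, chrom, start, end, seq, bait_length,
                                 gc_range, max_homopolymer, max_end_distance) {
  if (end - start < bait_length) {
    return(list(
      baits = NULL,
      report = tibble::tibble(frag_id = frag_id, end = c("left", "right"),
                              status = "unbaitable",
                              reasons = "fragment_too_short")
    ))
  }
  one_end <- function(side) {
    # candidate starts ordered end-proximal first
    if (side == "left") {
      starts <- start + 0:min(max_end_distance, end - start - bait_length)
    } else {
      starts <- (end - bait_length) -
        0:min(max_end_distance, end - start - bait_length)
    }
    cand <- substr(rep(seq, length(starts)), starts + 1, starts + bait_length)
    qc <- qc_bait(cand, start, end, starts, bait_length, gc_range,
                  max_homopolymer, max_end_distance)
    hit <- which(qc$accept)[1]
    if (!is.na(hit)) {
      list(
        bait = tibble::tibble(frag_id = frag_id, end = side, chrom = chrom,
                              start = starts[hit],
                              end_pos = starts[hit] + bait_length,
                              sequence = cand[hit]),
        rep = tibble::tibble(frag_id = frag_id, end = side, status = "baited",
                             reasons = "")
      )
    } else {
      list(
        bait = NULL,
        rep = tibble::tibble(frag_id = frag_id, end = side,
                             status = "rejected", reasons = qc$reasons[1])
      )
    }
  }
  l <- one_end("left"); r <- one_end("right")
  list(baits = dplyr::bind_rows(l$bait, r$bait),
       report = dplyr::bind_rows(l$rep, r$rep))
}
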