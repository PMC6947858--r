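# Thresholding of scored interactions, VIR/PIR derivation, and the
# descriptive statistics reported per capture arm.

#' High-confidence CHiCAGO filter
#'
#' Retains intrachromosomal interactions with `chicago_score >= score_min`
#' and `distance <= max_dist` (both thresholds inclusive).
#'
#' @param interactions Interaction tibble with `distance` and
#'   `intrachromosomal` (see [add_interaction_distance()]).
#' @param score_min Minimum CHiCAGO-style score (default 5).
#' @param max_dist Maximum interaction distance in bp (default 2 Mb).
#' @return The retained subset.
#' @export
filter_chicago <- function(interactions, score_min = 5, max_dist = 2e6) {
  dplyr::filter(
    interactions,
    .data$intrachromosomal,
    .data$distance <= max_dist,
    .data$chicago_score >= score_min
  )
}

#' High-confidence Peaky (MPPC) filter
#'
#' Retains intrachromosomal interactions with `mppc >= mppc_min` and
#' `distance <= max_dist`; interactions with absent MPPC are dropped.
#'
#' @inheritParams filter_chicago
#' @param mppc_min Minimum marginal posterior probability of contact
#'   (default 0.1).
#' @return The retained subset.
#' @export
filter_peaky <- function(interactions, mppc_min = 0.1, max_dist = 2e6) {
  dplyr::filter(
    interactions,
    .data$intrachromosomal,
    .data$distance <= max_dist,
    !is.na(.data$mppc),
    .data$mppc >= mppc_min
  )
}

#' Derive variant- and promoter-interacting regions
#'
#' Labels each retained bait-prey pair as a VIR (variant-capture bait) or
#' PIR (promoter-capture bait) and records which scoring scheme(s) passed
#' it. Interactions whose bait is not in the bait table raise an error.
#'
#' @param chicago CHiCAGO-filtered interaction tibble (may be `NULL`).
#' @param peaky Peaky-filtered interaction tibble (may be `NULL`).
#' @param baits Bait table (`frag_id`, `capture`).
#' @return Region tibble: `bait_frag`, `prey_frag`, `cell_line`, `capture`,
#'   `kind` (VIR/PIR), `passing` (chicago/peaky/both), `distance`.
#' @export
derive_interacting_regions <- function(chicago = NULL, peaky = NULL, baits) {
  key_cols <- c("bait_frag", "prey_frag", "cell_line", "capture", "distance")
  tag <- function(x, lab) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    out <- dplyr::distinct(dplyr::select(x, dplyr::all_of(key_cols)))
    out$method <- lab
    out
  }
  all <- dplyr::bind_rows(tag(chicago, "chicago"), tag(peaky, "peaky"))
  if (is.null(all) || nrow(all) == 0) {
    return(tibble::tibble(bait_frag = integer(), prey_frag = integer(),
                          cell_line = character(), capture = character(),
                          kind = character(), passing = character(),
                          distance = numeric()))
  }
  unknown <- setdiff(unique(all$bait_frag),
                     baits$frag_id[baits$capture %in% c("VC", "PC")])
  if (length(unknown) > 0) {
    stop("interaction bait fragment(s) not in bait table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  regions <- dplyr::summarise(
    dplyr::group_by(all, .data$bait_frag, .data$prey_frag, .data$cell_line,
                    .data$capture, .data$distance),
    passing = if (dplyr::n_distinct(.data$method) > 1) "both"
              else .data$method[1],
    .groups = "drop"
  )
  bait_capture <- baits$capture[match(regions$bait_frag, baits$frag_id)]
  regions$kind <- ifelse(bait_capture == "VC", "VIR", "PIR")
  dplyr::relocate(regions, "kind", "passing", .after = "capture")
}

#' Per-bait interacting-region counts and per-cell-line medians
#'
#' Counts retained prey fragments per bait and summarises the median count
#' per cell line and capture arm. Baits with zero retained preys do not
#' appear (medians describe detected interacting baits).
#'
#' @param regions Output of [derive_interacting_regions()].
#' @return A list with `per_bait` (bait-level counts) and `medians`
#'   (`cell_line`, `capture`, `kind`, `median_regions_per_bait`).
#' @export
region_count_summary <- function(regions) {
  per_bait <- dplyr::count(
    regions, .data$cell_line, .data$capture, .data$kind, .data$bait_frag,
    name = "n_regions"
  )
  medians <- dplyr::summarise(
    dplyr::group_by(per_bait, .data$cell_line, .data$capture, .data$kind),
    median_regions_per_bait = stats::median(.data$n_regions),
    n_baits = dplyr::n(),
    .groups = "drop"
  )
  list(per_bait = per_bait, medians = medians)
}

#' Promoter/CCV contact fractions of interacting regions
#'
#' Per cell line: the fraction of distinct VIR prey fragments that are
#' promoter fragments, and the fraction of distinct PIR prey fragments that
#' are CCV-containing fragments. Fractions are `NA` when the corresponding
#' region set is empty.
#'
#' @param regions Output of [derive_interacting_regions()].
#' @param promoter_frag_ids Fragment ids containing at least one TSS.
#' @param ccv_frag_ids Fragment ids containing at least one CCV.
#' @return Tibble: `cell_line`, `vir_promoter_fraction`, `pir_ccv_fraction`.
#' @export
contact_fractions <- function(regions, promoter_frag_ids, ccv_frag_ids) {
  frac <- function(preys, set) {
    u <- unique(preys)
    if (length(u) == 0) NA_real_ else mean(u %in% set)
  }
  dplyr::summarise(
    dplyr::group_by(regions, .data$cell_line),
    vir_promoter_fraction = frac(.data$prey_frag[.data$kind == "VIR"],
                                 promoter_frag_ids),
    pir_ccv_fraction = frac(.data$prey_frag[.data$kind == "PIR"],
                            ccv_frag_ids),
    .groups = "drop"
  )
}

#' Fraction of interactions contained within one TAD
#'
#' An interaction is contained when its bait midpoint and prey midpoint fall
#' inside the same TAD interval. Returns 0 for an empty TAD set.
#'
#' @param interactions Filtered interaction tibble.
#' @param tads TAD tibble (`chrom`, `start`, `end`; non-overlapping).
#' @param fragments Fragment map tibble.
#' @return A single fraction.
#' @export
tad_containment_fraction <- function(interactions, tads, fragments) {
  if (nrow(interactions) == 0) return(NA_real_)
  if (nrow(tads) == 0) return(0)
  mid <- fragment_midpoint(fragments)
  names(mid) <- as.character(fragments$frag_id)
  ch <- fragments$chrom
  names(ch) <- as.character(fragments$frag_id)
  tad_of <- function(chrom, pos) {
    # label of the containing TAD, NA when outside all
    out <- rep(NA_character_, length(pos))
    for (cc in unique(chrom)) {
      tt <- tads[tads$chrom == cc, ]
      tt <- tt[order(tt$start), ]
      idx <- which(chrom == cc)
      if (nrow(tt) == 0) next
      j <- findInterval(pos[idx], tt$start)
      inside <- j >= 1 & pos[idx] < tt$end[pmax(j, 1)]
      out[idx[inside]] <- paste(cc, j[inside])
    }
    out
  }
  b <- as.character(interactions$bait_frag)
  p <- as.character(interactions$prey_frag)
  tb <- tad_of(ch[b], mid[b])
  tp <- tad_of(ch[p], mid[p])
  mean(!is.na(tb) & !is.na(tp) & tb == tp)
}

#' Cross-capture concordance of interaction scores
#'
#' Matches interactions common to the VC and PC arms by unordered fragment
#' pair and cell line, keeping pairs scored > 0 in both, and reports the
#' per-cell-line Pearson correlation of the scores, raw and after the
#' inverse hyperbolic sine (asinh) transform. Cell lines with fewer than 3
#' matched pairs get `NA`.
#'
#' @param vc,pc Interaction tibbles for the two capture arms.
#' @return Tibble: `cell_line`, `n_matched`, `r_raw`, `r_asinh`.
#' @export
capture_concordance <- function(vc, pc) {
  keyed <- function(x) {
    tibble::tibble(
      lo = pmin(x$bait_frag, x$prey_frag),
      hi = pmax(x$bait_frag, x$prey_frag),
      cell_line = x$cell_line,
      score = x$chicago_score
    ) |>
      dplyr::filter(.data$score > 0) |>
      dplyr::group_by(.data$lo, .data$hi, .data$cell_line) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  }
  m <- dplyr::inner_join(keyed(vc), keyed(pc),
                         by = c("lo", "hi", "cell_line"),
                         suffix = c("_vc", "_pc"))
  dplyr::summarise(
    dplyr::group_by(m, .data$cell_line),
    n_matched = dplyr::n(),
    r_raw = if (dplyr::n() >= 3) {
      stats::cor(.data$score_vc, .data$score_pc)
    } else NA_real_,
    r_asinh = if (dplyr::n() >= 3) {
      stats::cor(asinh(.data$score_vc), asinh(.data$score_pc))
    } else NA_real_,
    .groups = "drop"
  )
}

#' Spearman correlation of CHiCAGO and MPPC scores
#'
#' Average-rank (tie-aware) Spearman correlation between the two scoring
#' schemes over bait-prey pairs with an MPPC present, globally or per bait.
#' Constant vectors yield `NA`.
#'
#' @param interactions Interaction tibble.
#' @param by `"global"` (default) or `"bait"`.
#' @return Tibble with `rho` and `n_pairs` (plus `bait_frag` for
#'   `by = "bait"`).
#' @export
score_correlation <- function(interactions, by = c("global", "bait")) {
  by <- match.arg(by)
  x <- dplyr::filter(interactions, !is.na(.data$mppc))
  rho <- function(a, b) {
    if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(NA_real_)
    }
    stats::cor(a, b, method = "spearman")
  }
  if (by == "global") {
    tibble::tibble(rho = rho(x$chicago_score, x$mppc), n_pairs = nrow(x))
  } else {
    dplyr::summarise(
      dplyr::group_by(x, .data$bait_frag),
      rho = rho(.data$chicago_score, .data$mppc),
      n_pairs = dplyr::n(), .groups = "drop"
    )
  }
}

# Wide score matrix: rows = (bait, prey, capture), columns = cell lines
# (ordered lexicographically for deterministic downstream tie-breaks).
score_matrix <- function(interactions, max_dist) {
  x <- dplyr::filter(interactions, .data$intrachromosomal,
                     .data$distance < max_dist)
  wide <- tidyr::pivot_wider(
    dplyr::select(x, "bait_frag", "prey_frag", "capture", "cell_line",
                  "chicago_score"),
    names_from = "cell_line", values_from = "chicago_score", values_fill = 0
  )
  m <- as.matrix(wide[, -(1:3), drop = FALSE])
  m[, order(colnames(m)), drop = FALSE]
}

#' Hierarchical clustering of cell lines on interaction profiles
#'
#' Restricts to interactions shorter than `max_dist` with a score of at
#' least `score_min` in at least one cell line, selects the `top_n`
#' interactions with most variance (all when fewer), and agglomerates cell
#' lines by average linkage on Euclidean distances between their score
#' profiles. Ties are broken deterministically by lexicographic cell-line
#' order.
#'
#' @param interactions Interaction tibble.
#' @param top_n Number of most-variable interactions retained (default
#'   1000).
#' @param score_min Row-inclusion score threshold (default 5).
#' @param max_dist Maximum interaction length, exclusive (default 2 Mb).
#' @return A `chic_hclust` object wrapping the [stats::hclust()] merge tree.
#' @export
cluster_cell_lines <- function(interactions, top_n = 1000, score_min = 5,
                               max_dist = 2e6) {
  m <- score_matrix(interactions, max_dist)
  if (ncol(m) < 2) stop("clustering requires at least 2 cell lines")
  m <- m[apply(m, 1, max) >= score_min, , drop = FALSE]
  if (nrow(m) == 0) stop("no interaction passes the score threshold")
  v <- apply(m, 1, stats::var)
  m <- m[utils::head(order(v, decreasing = TRUE), top_n), , drop = FALSE]
  hc <- stats::hclust(stats::dist(t(m)), method = "average")
  structure(
    list(hclust = hc, cell_lines = colnames(m), n_interactions = nrow(m)),
    class = "chic_hclust"
  )
}

#' Principal component analysis of cell-line interaction profiles
#'
#' Includes intrachromosomal interactions shorter than `max_dist` with a
#' positive score in at least one cell line; zero-variance rows are dropped,
#' remaining rows are scaled to unit variance, and the cell-line profiles
#' are decomposed into principal components.
#'
#' @param interactions Interaction tibble.
#' @param max_dist Maximum interaction length, exclusive (default 2 Mb).
#' @return A `chic_pca` object with component scores per cell line and
#'   explained-variance ratios.
#' @export
pca_cell_lines <- function(interactions, max_dist = 2e6) {
  m <- score_matrix(interactions, max_dist)
  if (ncol(m) < 2) stop("PCA requires at least 2 cell lines")
  m <- m[apply(m, 1, max) > 0, , drop = FALSE]
  v <- apply(m, 1, stats::var)
  m <- m[v > 0, , drop = FALSE]
  if (nrow(m) == 0) stop("all interaction rows have zero variance")
  pr <- stats::prcomp(t(m), center = TRUE, scale. = TRUE)
  scores <- tibble::as_tibble(pr$x, rownames = "cell_line")
  var_ratio <- pr$sdev^2 / sum(pr$sdev^2)
  structure(
    list(scores = scores, var_explained = var_ratio, n_interactions = nrow(m)),
    class = "chic_pca"
  )
}
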