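# eQTL-supported interactions and the promoter-randomization permutation
# test of their excess, binned by interaction distance.

#' Flag eQTL-supported interactions
#'
#' An interaction is flagged when one end fragment contains at least one
#' eSNP and the other end is a promoter fragment of the corresponding
#' eGene (both orientations, covering the promoter- and variant-capture
#' analyses). eQTL records whose eGene is absent from the gene annotation
#' are skipped with a message reporting the count.
#'
#' @param interactions Filtered interaction tibble.
#' @param eqtls eQTL tibble (`chrom`, `pos`, `egene_id`, `fdr`), already
#'   FDR-filtered.
#' @param genes Gene tibble with `promoter_frag` (see [read_gene_table()]).
#' @param fragments Fragment map tibble.
#' @return The interactions with a logical `eqtl_supported` column.
#' @export
eqtl_supported_interactions <- function(interactions, eqtls, genes,
                                        fragments) {
  known <- eqtls$egene_id %in% genes$gene_id
  if (any(!known)) {
    message(sum(!known), " eQTL record(s) with unknown eGene skipped")
    eqtls <- eqtls[known, ]
  }
  if (nrow(eqtls) == 0) {
    interactions$eqtl_supported <- rep(FALSE, nrow(interactions))
    return(interactions)
  }
  esnp_frag <- locate_fragment(fragments, eqtls$chrom, eqtls$pos)
  # pairs (eSNP fragment, promoter fragment of its eGene)
  links <- dplyr::distinct(dplyr::inner_join(
    tibble::tibble(esnp_frag = esnp_frag, egene_id = eqtls$egene_id),
    dplyr::select(genes, "gene_id", "promoter_frag"),
    by = c("egene_id" = "gene_id"),
    relationship = "many-to-many"
  )[, c("esnp_frag", "promoter_frag")])
  key <- function(a, b) paste(a, b)
  link_keys <- c(key(links$esnp_frag, links$promoter_frag),
                 key(links$promoter_frag, links$esnp_frag))
  interactions$eqtl_supported <-
    key(interactions$bait_frag, interactions$prey_frag) %in% link_keys
  interactions
}

#' Promoter-randomization permutation null for eQTL-loop co-occurrence
#'
#' Keeps the bait-prey interaction network fixed and, in each permutation,
#' relabels every baited promoter fragment by a promoter fragment drawn
#' uniformly from the same chromosome's promoter pool (without replacement:
#' distinct baits receive distinct surrogates when the pool allows). The
#' eQTL-supported interaction count is re-tallied per distance bin.
#'
#' @param interactions Filtered promoter-capture interaction tibble (baits
#'   are promoter fragments; distances present).
#' @param eqtls FDR-filtered eQTL tibble.
#' @param genes Gene tibble with `promoter_frag`.
#' @param fragments Fragment map tibble.
#' @param n_perm Number of permutations (default 10,000).
#' @param breaks Distance bin edges in bp; default a single global bin.
#' @param seed Integer seed.
#' @return An `eqtl_perm` list: `observed` (per-bin counts), `null_counts`
#'   (bins x n_perm matrix), `bin_labels`, `n_perm`, `seed`.
#' @export
permute_promoter_assignment <- function(interactions, eqtls, genes, fragments,
                                        n_perm = 10000, breaks = NULL,
                                        seed = 1L) {
  if (is.null(breaks)) breaks <- c(0, Inf)
  known <- eqtls$egene_id %in% genes$gene_id
  eqtls <- eqtls[known, ]
  # unit of counting: one interaction per bait-prey pair per cell line
  ints <- dplyr::distinct(
    dplyr::select(interactions, "bait_frag", "prey_frag", "cell_line",
                  "distance")
  )
  bin_idx <- cut(ints$distance, breaks = breaks, right = TRUE,
                 include.lowest = TRUE, labels = FALSE)
  n_bins <- length(breaks) - 1
  bin_labels <- paste0("(", utils::head(breaks, -1), ",",
                       utils::tail(breaks, -1), "]")

  # promoter pool per chromosome
  pool <- dplyr::distinct(
    tibble::tibble(frag = genes$promoter_frag,
                   chrom = genes$chrom)
  )
  baited <- unique(ints$bait_frag)
  bait_chrom <- fragments$chrom[match(baited, fragments$frag_id)]
  for (cc in unique(bait_chrom)) {
    if (sum(bait_chrom == cc) > sum(pool$chrom == cc)) {
      stop("chromosome ", cc, " has more baited promoters than pool promoters")
    }
  }

  # support lookup: S[p, q] = TRUE iff promoter fragment p paired with prey
  # fragment q is eQTL-supported (eSNP in q whose eGene has a promoter in p)
  pool_ids <- pool$frag
  prey_ids <- unique(ints$prey_frag)
  S <- matrix(FALSE, nrow = length(pool_ids), ncol = length(prey_ids),
              dimnames = list(as.character(pool_ids),
                              as.character(prey_ids)))
  if (nrow(eqtls) > 0) {
    esnp_frag <- locate_fragment(fragments, eqtls$chrom, eqtls$pos)
    links <- dplyr::distinct(dplyr::inner_join(
      tibble::tibble(esnp_frag = esnp_frag, egene_id = eqtls$egene_id),
      dplyr::select(genes, "gene_id", "promoter_frag"),
      by = c("egene_id" = "gene_id"),
      relationship = "many-to-many"
    ))
    links <- links[links$esnp_frag %in% prey_ids &
                     links$promoter_frag %in% pool_ids, ]
    if (nrow(links) > 0) {
      S[cbind(as.character(links$promoter_frag),
              as.character(links$esnp_frag))] <- TRUE
    }
  }

  bait_pos <- match(as.character(ints$bait_frag), rownames(S))
  prey_pos <- match(as.character(ints$prey_frag), colnames(S))
  # baits must themselves be promoter fragments (identity mapping observed)
  if (anyNA(bait_pos)) {
    stop("bait fragment(s) not in the promoter pool; supply PC interactions")
  }
  tally <- function(map_pos) {
    flags <- S[cbind(map_pos[match(ints$bait_frag, baited)], prey_pos)]
    vapply(seq_len(n_bins), function(b) sum(flags[bin_idx == b]), integer(1))
  }
  observed <- tally(match(as.character(baited), rownames(S)))

  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      surro <- integer(length(baited))
      for (cc in unique(bait_chrom)) {
        sel <- bait_chrom == cc
        cand <- which(pool$chrom == cc)
        surro[sel] <- sample(cand, sum(sel))
      }
      tally(surro)
    }, integer(n_bins))
  })
  null_counts <- matrix(null_counts, nrow = n_bins)
  structure(
    list(observed = observed, null_counts = null_counts,
         bin_labels = bin_labels, n_perm = n_perm, seed = seed),
    class = "eqtl_perm"
  )
}

#' Empirical enrichment test of eQTL-supported interactions
#'
#' Upper-tail add-one empirical p per distance bin:
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, with significance
#' stars at 0.05, 0.01 and 0.001.
#'
#' @param perm An `eqtl_perm` object from [permute_promoter_assignment()],
#'   or a vector of observed per-bin counts.
#' @param null_counts When `perm` is a vector: matrix of null counts
#'   (bins x permutations).
#' @return Tibble: `bin_label`, `observed`, `null_mean`, `p_emp`, `stars`.
#' @export
eqtl_enrichment_test <- function(perm, null_counts = NULL) {
  if (inherits(perm, "eqtl_perm")) {
    observed <- perm$observed
    null_counts <- perm$null_counts
    labels <- perm$bin_labels
  } else {
    observed <- perm
    if (is.null(null_counts)) stop("null_counts required")
    null_counts <- matrix(null_counts, nrow = length(observed))
    labels <- as.character(seq_along(observed))
  }
  n_perm <- ncol(null_counts)
  p <- vapply(seq_along(observed), function(b) {
    (1 + sum(null_counts[b, ] >= observed[b])) / (1 + n_perm)
  }, numeric(1))
  stars <- dplyr::case_when(
    p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ ""
  )
  tibble::tibble(
    bin_label = labels, observed = observed,
    null_mean = rowMeans(null_counts), p_emp = p, stars = stars
  )
}
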