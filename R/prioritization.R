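# Sequential CHiCAGO -> Peaky fine-mapping of CCVs, candidate target gene
# rules, headline summaries, and PWM allele-effect scoring.

#' CCV-gene promoter interaction evidence
#'
#' Joins the CHiCAGO- and Peaky-filtered interaction sets against the CCV
#' and promoter fragment maps: one evidence row per interaction linking a
#' CCV-containing fragment of a known signal with a promoter fragment of a
#' known gene, in either bait/prey orientation. The scoring scheme is
#' recorded as `chicago`, `peaky`, or `both`. Each row carries the number
#' of distinct intervening genes skipped by the interaction.
#'
#' @param chicago,peaky Filtered interaction tibbles (either may be `NULL`).
#' @param variants Variant tibble with `frag` (see [read_variant_table()]).
#' @param genes Gene tibble with `promoter_frag`.
#' @param fragments Fragment map tibble.
#' @return Evidence tibble: `signal_id`, `gene_id`, `cell_line`, `capture`,
#'   `method`, `bait_frag`, `prey_frag`, `n_skipped_promoters`.
#' @export
ccv_promoter_interactions <- function(chicago = NULL, peaky = NULL,
                                      variants, genes, fragments) {
  ccv_frags <- dplyr::distinct(
    tibble::tibble(frag = variants$frag, signal_id = variants$signal_id)
  )
  prom_frags <- dplyr::distinct(
    tibble::tibble(frag = genes$promoter_frag, gene_id = genes$gene_id)
  )
  one_set <- function(x, lab) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    x <- dplyr::select(x, "bait_frag", "prey_frag", "cell_line", "capture")
    # orientation 1: CCV end is the bait, promoter end is the prey
    o1 <- dplyr::inner_join(x, ccv_frags, by = c("bait_frag" = "frag"),
                            relationship = "many-to-many")
    o1 <- dplyr::inner_join(o1, prom_frags, by = c("prey_frag" = "frag"),
                            relationship = "many-to-many")
    # orientation 2: promoter bait, CCV prey
    o2 <- dplyr::inner_join(x, prom_frags, by = c("bait_frag" = "frag"),
                            relationship = "many-to-many")
    o2 <- dplyr::inner_join(o2, ccv_frags, by = c("prey_frag" = "frag"),
                            relationship = "many-to-many")
    out <- dplyr::bind_rows(o1, o2)
    if (nrow(out) == 0) return(NULL)
    out$method <- lab
    dplyr::distinct(out)
  }
  all <- dplyr::bind_rows(one_set(chicago, "chicago"), one_set(peaky, "peaky"))
  if (is.null(all) || nrow(all) == 0) {
    return(tibble::tibble(signal_id = character(), gene_id = character(),
                          cell_line = character(), capture = character(),
                          method = character(), bait_frag = integer(),
                          prey_frag = integer(),
                          n_skipped_promoters = integer()))
  }
  ev <- dplyr::summarise(
    dplyr::group_by(all, .data$signal_id, .data$gene_id, .data$cell_line,
                    .data$capture, .data$bait_frag, .data$prey_frag),
    method = if (dplyr::n_distinct(.data$method) > 1) "both"
             else .data$method[1],
    .groups = "drop"
  )
  ev$n_skipped_promoters <- count_skipped_promoters(
    ev$bait_frag, ev$prey_frag, genes, own_gene = ev$gene_id
  )
  dplyr::relocate(ev, "method", .after = "capture")
}

#' Count gene promoters skipped by an interaction
#'
#' Number of distinct genes having at least one promoter fragment strictly
#' between the interaction's two end fragments (fragment ids strictly
#' between the endpoints), excluding the interaction's own target gene.
#'
#' @param bait_frag,prey_frag Fragment id vectors (equal length).
#' @param genes Gene tibble with `promoter_frag`.
#' @param own_gene Optional gene id vector excluded per interaction.
#' @return Integer vector of skipped-gene counts.
#' @export
count_skipped_promoters <- function(bait_frag, prey_frag, genes,
                                    own_gene = NULL) {
  pf <- dplyr::distinct(
    tibble::tibble(frag = genes$promoter_frag, gene_id = genes$gene_id)
  )
  pf <- pf[order(pf$frag), ]
  lo <- pmin(bait_frag, prey_frag)
  hi <- pmax(bait_frag, prey_frag)
  vapply(seq_along(lo), function(i) {
    inside <- pf$gene_id[pf$frag > lo[i] & pf$frag < hi[i]]
    if (!is.null(own_gene)) inside <- setdiff(inside, own_gene[i])
    length(unique(inside))
  }, integer(1))
}

#' Define candidate target genes
#'
#' Aggregates CCV-promoter evidence to (signal, gene) pairs supported in at
#' least `min_cell_lines` distinct cell lines, pooling evidence across
#' capture arms and scoring schemes (a cell line counts once however
#' supported). `both_methods` flags genes with at least one CHiCAGO and at
#' least one Peaky row; `n_skipped_promoters` is the minimum over the
#' supporting interactions.
#'
#' @param evidence Output of [ccv_promoter_interactions()].
#' @param min_cell_lines Minimum distinct supporting cell lines (default 2).
#' @return Candidate tibble: `signal_id`, `gene_id`, `cell_lines`
#'   (comma-collapsed), `n_cell_lines`, `captures`, `methods`,
#'   `both_methods`, `n_skipped_promoters`.
#' @export
define_candidate_genes <- function(evidence, min_cell_lines = 2) {
  if (nrow(evidence) == 0) {
    return(tibble::tibble(signal_id = character(), gene_id = character(),
                          cell_lines = character(), n_cell_lines = integer(),
                          captures = character(), methods = character(),
                          both_methods = logical(),
                          n_skipped_promoters = integer()))
  }
  methods_of <- function(m) {
    u <- unique(unlist(ifelse(m == "both", list(c("chicago", "peaky")),
                              as.list(m))))
    sort(u)
  }
  out <- dplyr::summarise(
    dplyr::group_by(evidence, .data$signal_id, .data$gene_id),
    cell_lines = paste(sort(unique(.data$cell_line)), collapse = ","),
    n_cell_lines = dplyr::n_distinct(.data$cell_line),
    captures = paste(sort(unique(.data$capture)), collapse = ","),
    methods = paste(methods_of(.data$method), collapse = ","),
    both_methods = all(c("chicago", "peaky") %in% methods_of(.data$method)),
    n_skipped_promoters = min(.data$n_skipped_promoters),
    .groups = "drop"
  )
  dplyr::filter(out, .data$n_cell_lines >= min_cell_lines)
}

#' Sequential CHiCAGO -> Peaky CCV prioritization
#'
#' A signal is *detectable* through a promoter bait and cell line when the
#' bait's CHiCAGO-filtered preys include at least one CCV fragment of the
#' signal. A CCV is then prioritized iff it lies in a prey fragment with
#' MPPC at or above the Peaky threshold from such a bait in the same cell
#' line — Peaky refines the CHiCAGO stretch down to the direct contacts.
#' Signals failing the CHiCAGO gate are reported via a message and yield no
#' prioritized CCVs.
#'
#' @param chicago CHiCAGO-filtered promoter-capture interactions.
#' @param peaky Peaky-filtered promoter-capture interactions.
#' @param variants Variant tibble with `frag`.
#' @param genes Gene tibble with `promoter_frag` (identifies promoter
#'   baits).
#' @param fragments Fragment map tibble.
#' @return Tibble, one row per prioritized CCV: `variant_id`, `signal_id`,
#'   `prey_frag`, `cell_lines`, `max_mppc`, `max_chicago`.
#' @export
prioritize_ccvs <- function(chicago, peaky, variants, genes, fragments) {
  empty <- tibble::tibble(variant_id = character(), signal_id = character(),
                          prey_frag = integer(), cell_lines = character(),
                          max_mppc = numeric(), max_chicago = numeric())
  ccv <- dplyr::distinct(
    tibble::tibble(frag = variants$frag, variant_id = variants$variant_id,
                   signal_id = variants$signal_id)
  )
  prom <- unique(genes$promoter_frag)
  chic <- chicago[chicago$bait_frag %in% prom, ]
  pk <- peaky[peaky$bait_frag %in% prom, ]
  # CHiCAGO gate: (bait, cell line, signal) triples with a CCV prey
  gate <- dplyr::distinct(
    dplyr::inner_join(
      dplyr::select(chic, "bait_frag", "prey_frag", "cell_line"),
      ccv, by = c("prey_frag" = "frag"), relationship = "many-to-many"
    )[, c("bait_frag", "cell_line", "signal_id")]
  )
  gated_signals <- unique(gate$signal_id)
  ungated <- setdiff(unique(ccv$signal_id), gated_signals)
  if (length(ungated) > 0) {
    message("signal(s) without a CHiCAGO-passing promoter-CCV interaction: ",
            paste(sort(ungated), collapse = ", "))
  }
  if (nrow(gate) == 0 || nrow(pk) == 0) return(empty)
  cand <- dplyr::inner_join(pk, ccv, by = c("prey_frag" = "frag"),
                            relationship = "many-to-many")
  cand <- dplyr::semi_join(cand, gate,
                           by = c("bait_frag", "cell_line", "signal_id"))
  if (nrow(cand) == 0) return(empty)
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(cand, .data$variant_id, .data$signal_id,
                      .data$prey_frag),
      cell_lines = paste(sort(unique(.data$cell_line)), collapse = ","),
      max_mppc = max(.data$mppc),
      max_chicago = max(.data$chicago_score),
      .groups = "drop"
    ),
    .data$signal_id, .data$variant_id
  )
}

#' Headline summaries of candidate target genes
#'
#' Emits the per-signal gene counts and the headline tallies: signals whose
#' protein-coding candidates number 1-2, genes linked to 2 or more
#' independent signals, the fraction of signal-gene pairs skipping at least
#' one annotated promoter, genes supported by both scoring schemes, and the
#' fraction of signals interacting with at least 2 promoter-containing
#' fragments.
#'
#' @param candidates Output of [define_candidate_genes()].
#' @param genes Gene tibble (for biotypes).
#' @param evidence Optional evidence table (for the promoter-fragment
#'   count per signal); when absent that column is `NA`.
#' @return A list: `per_signal` (tibble of per-signal candidate counts) and
#'   `summary` (one-row tibble of headline counts).
#' @export
summarize_targets <- function(candidates, genes, evidence = NULL) {
  biotype <- genes$biotype[match(candidates$gene_id, genes$gene_id)]
  candidates$coding <- biotype == "coding"
  per_signal <- dplyr::summarise(
    dplyr::group_by(candidates, .data$signal_id),
    n_genes = dplyr::n_distinct(.data$gene_id),
    n_coding = dplyr::n_distinct(.data$gene_id[.data$coding]),
    .groups = "drop"
  )
  multi <- dplyr::count(candidates, .data$gene_id, name = "n_signals")
  frac_ge2_prom <- NA_real_
  if (!is.null(evidence) && nrow(evidence) > 0) {
    prom_per_signal <- dplyr::summarise(
      dplyr::group_by(evidence, .data$signal_id),
      n_prom_frags = dplyr::n_distinct(
        ifelse(.data$capture == "PC", .data$bait_frag, .data$prey_frag)
      ),
      .groups = "drop"
    )
    frac_ge2_prom <- mean(prom_per_signal$n_prom_frags >= 2)
  }
  summary <- tibble::tibble(
    n_candidate_genes = dplyr::n_distinct(candidates$gene_id),
    n_signals = dplyr::n_distinct(candidates$signal_id),
    n_coding_genes = dplyr::n_distinct(candidates$gene_id[candidates$coding]),
    n_signals_coding_le2 = sum(per_signal$n_coding >= 1 &
                                 per_signal$n_coding <= 2),
    n_multisignal_genes = sum(multi$n_signals >= 2),
    frac_pairs_skipping = if (nrow(candidates) > 0) {
      mean(candidates$n_skipped_promoters >= 1)
    } else NA_real_,
    n_both_method_genes = dplyr::n_distinct(
      candidates$gene_id[candidates$both_methods]
    ),
    frac_signals_ge2_promoter_frags = frac_ge2_prom
  )
  list(per_signal = per_signal, summary = summary)
}

#' Position weight matrix
#'
#' Constructs a per-position base-probability matrix. Rows are motif
#' positions; columns `A`, `C`, `G`, `T` must each sum to 1 within 1e-6.
#'
#' @param prob Numeric matrix (positions x 4) of base probabilities, with
#'   columns in A, C, G, T order.
#' @param background Background base probabilities (default uniform).
#' @return A `pwm` object.
#' @export
pwm <- function(prob, background = rep(0.25, 4)) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  colnames(prob) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    stop("each PWM position must sum to 1 (tolerance 1e-6)")
  }
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  structure(list(prob = prob, background = stats::setNames(
    background, c("A", "C", "G", "T")
  )), class = "pwm")
}

#' Build a PWM from a count matrix
#'
#' Normalizes a JASPAR-style count matrix to probabilities with a
#' per-cell pseudocount.
#'
#' @param counts Count matrix (positions x 4, columns A, C, G, T).
#' @param pseudocount Added to every cell before normalization
#'   (default 0.01).
#' @param background Background base probabilities.
#' @return A `pwm` object.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.01,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts) + pseudocount
  pwm(counts / rowSums(counts), background)
}

#' Allele effect on a PWM match score
#'
#' Scores a motif-length site sequence as the sum of `log2(p / background)`
#' over positions, with the variant position substituted by the risk and
#' protective alleles in turn. Zero matrix probabilities are floored at
#' 1e-4 with a warning.
#'
#' @param pwm A [pwm()] object.
#' @param site_sequence Site sequence, same length as the motif.
#' @param variant_offset 1-based position of the variant within the motif.
#' @param allele_risk,allele_prot The two alleles (single bases).
#' @return One-row tibble: `score_risk`, `score_prot`, `delta`
#'   (risk - protective), `direction` (increase/decrease/neutral, sign of
#'   delta with tolerance 1e-9).
#' @export
pwm_allele_delta <- function(pwm, site_sequence, variant_offset,
                             allele_risk, allele_prot) {
  stopifnot(inherits(pwm, "pwm"))
  L <- nrow(pwm$prob)
  if (nchar(site_sequence) != L) {
    stop("site sequence length must equal motif length (", L, ")")
  }
  if (variant_offset < 1 || variant_offset > L) {
    stop("variant_offset outside the motif")
  }
  score_site <- function(seq) {
    bases <- strsplit(toupper(seq), "")[[1]]
    if (any(!bases %in% c("A", "C", "G", "T"))) {
      stop("site sequence contains non-ACGT base")
    }
    p <- pwm$prob[cbind(seq_len(L), match(bases, c("A", "C", "G", "T")))]
    if (any(p == 0)) {
      warning("zero PWM probability floored at 1e-4")
      p <- pmax(p, 1e-4)
    }
    sum(log2(p / pwm$background[bases]))
  }
  sub_allele <- function(allele) {
    paste0(substr(site_sequence, 1, variant_offset - 1), allele,
           substr(site_sequence, variant_offset + 1, L))
  }
  s_risk <- score_site(sub_allele(allele_risk))
  s_prot <- score_site(sub_allele(allele_prot))
  delta <- s_risk - s_prot
  direction <- if (abs(delta) <= 1e-9) "neutral"
               else if (delta > 0) "increase" else "decrease"
  tibble::tibble(score_risk = s_risk, score_prot = s_prot, delta = delta,
                 direction = direction)
}
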