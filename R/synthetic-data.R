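# Seeded synthetic Capture Hi-C datasets with ground truth.
#
# The generator emits score-level data only (no reads): a fragment map, risk
# signals with credible causal variants (CCVs), genes, TADs, feature peaks,
# eQTLs, and a scored interaction table carrying both a CHiCAGO-style score
# and a Peaky-style MPPC. Planted "direct" contacts receive a strong CHiCAGO
# boost plus a high MPPC; their fragment neighbourhoods receive a tapering
# CHiCAGO-only boost, reproducing the long collateral stretches of
# significant fragments around a small number of direct contacts that
# motivate sequential CHiCAGO/Peaky fine-mapping.

#' Simulation configuration
#'
#' Defaults describe a compact two-chromosome genome with the cell-line
#' panel structure of a dual-capture breast study: six cell lines in two
#' latent groups (ER-positive vs the rest) driving cell-type-specific loops.
#'
#' @param seed Integer seed; a fixed seed makes [simulate_dataset()] output
#'   byte-identical across runs.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param site_density Expected restriction sites per kb (HindIII-like
#'   density of 0.25/kb gives ~4 kb fragments).
#' @param n_regions Number of risk regions.
#' @param signals_per_region Independent signals per region.
#' @param ccvs_per_signal CCVs per signal (1 causal + distractors spread
#'   over the neighbouring fragments of the CHiCAGO stretch).
#' @param n_genes Total genes (>= number of signals; each signal gets one
#'   true target gene).
#' @param coding_fraction Fraction of genes with `coding` biotype.
#' @param cell_lines Tibble with columns `cell_line`, `group` (two latent
#'   groups).
#' @param decay_scale Distance-decay scale (bp) of the baseline score.
#' @param baseline_amplitude Expected baseline score at distance 0.
#' @param n_true_contacts_per_bait Planted direct contacts per bait; 0
#'   disables all planted structure.
#' @param stretch_halfwidth Half-width (in fragments) of the collateral
#'   CHiCAGO stretch around each direct contact.
#' @param score_noise_sd SD of the additive Gaussian score noise
#'   (scores truncated at 0).
#' @param contact_boost CHiCAGO score boost at a direct contact.
#' @param mppc_pass_prob Probability that a direct contact draws an MPPC
#'   above the 0.1 threshold.
#' @param mppc_background_shape2 Beta(1, shape2) shape for background MPPC.
#' @param score_mppc_rho Gaussian-copula correlation between the score
#'   noise and the background MPPC (both scoring schemes read the same
#'   underlying counts, so their ranks co-vary even off true contacts).
#' @param peak_background_rate Per-fragment probability of a feature peak.
#' @param peak_enrichment_factor Rate multiplier (>= 1) at direct-contact
#'   prey fragments for the enriched features.
#' @param enriched_features,neutral_features Feature labels to plant as
#'   enriched at true interacting regions / at background rate everywhere.
#' @param eqtl_loop_fraction Fraction of true CCV-promoter loops receiving a
#'   supporting eQTL record.
#' @param eqtl_background_rate Expected spurious eQTL records per fragment
#'   (Poisson mean; each record names a random same-chromosome eGene).
#' @param tad_fraction Fraction of extra direct contacts constrained within
#'   one TAD.
#' @param shared_contact_fraction Fraction of direct contacts present in
#'   both latent groups (the rest are specific to one group).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 3e6,
                       site_density = 0.25,
                       n_regions = 6L,
                       signals_per_region = 2L,
                       ccvs_per_signal = 8L,
                       n_genes = 40L,
                       coding_fraction = 0.7,
                       cell_lines = default_cell_lines(),
                       decay_scale = 3e5,
                       baseline_amplitude = 3,
                       n_true_contacts_per_bait = 1L,
                       stretch_halfwidth = 5L,
                       score_noise_sd = 1,
                       contact_boost = 8,
                       mppc_pass_prob = 0.95,
                       mppc_background_shape2 = 100,
                       score_mppc_rho = 0.4,
                       peak_background_rate = 0.1,
                       peak_enrichment_factor = 5,
                       enriched_features = c("ATAC", "H3K27ac"),
                       neutral_features = "H3K27me3",
                       eqtl_loop_fraction = 0.5,
                       eqtl_background_rate = 0.01,
                       tad_fraction = 0.7,
                       shared_contact_fraction = 0.5) {
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length = chrom_length, site_density = site_density,
    n_regions = as.integer(n_regions),
    signals_per_region = as.integer(signals_per_region),
    ccvs_per_signal = as.integer(ccvs_per_signal),
    n_genes = as.integer(n_genes), coding_fraction = coding_fraction,
    cell_lines = cell_lines, decay_scale = decay_scale,
    baseline_amplitude = baseline_amplitude,
    n_true_contacts_per_bait = as.integer(n_true_contacts_per_bait),
    stretch_halfwidth = as.integer(stretch_halfwidth),
    score_noise_sd = score_noise_sd, contact_boost = contact_boost,
    mppc_pass_prob = mppc_pass_prob,
    mppc_background_shape2 = mppc_background_shape2,
    score_mppc_rho = score_mppc_rho,
    peak_background_rate = peak_background_rate,
    peak_enrichment_factor = peak_enrichment_factor,
    enriched_features = enriched_features,
    neutral_features = neutral_features,
    eqtl_loop_fraction = eqtl_loop_fraction,
    eqtl_background_rate = eqtl_background_rate,
    tad_fraction = tad_fraction,
    shared_contact_fraction = shared_contact_fraction
  )
  rates <- c(coding_fraction = coding_fraction,
             mppc_pass_prob = mppc_pass_prob,
             peak_background_rate = peak_background_rate,
             eqtl_loop_fraction = eqtl_loop_fraction,
             tad_fraction = tad_fraction,
             shared_contact_fraction = shared_contact_fraction)
  if (any(rates < 0 | rates > 1)) {
    stop("rate/probability parameters must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  if (peak_enrichment_factor < 1) stop("peak_enrichment_factor must be >= 1")
  if (eqtl_background_rate < 0) stop("eqtl_background_rate must be >= 0")
  if (site_density <= 0 || decay_scale <= 0 || score_noise_sd < 0) {
    stop("site_density and decay_scale must be positive, score_noise_sd >= 0")
  }
  if (abs(score_mppc_rho) >= 1) stop("score_mppc_rho must be in (-1, 1)")
  if (!all(c("cell_line", "group") %in% names(cfg$cell_lines))) {
    stop("cell_lines must have columns cell_line, group")
  }
  n_signals <- cfg$n_regions * cfg$signals_per_region
  if (cfg$n_genes < n_signals) stop("n_genes must be >= number of signals")
  structure(cfg, class = "sim_config")
}

#' Default six-line breast cell panel with latent ER groups
#' @return Tibble with `cell_line` and `group`.
#' @export
default_cell_lines <- function() {
  tibble::tibble(
    cell_line = c("B80T5", "MCF10A", "MCF7", "T47D", "MDAMB231", "Hs578T"),
    group = c("ERneg", "ERneg", "ERpos", "ERpos", "ERneg", "ERneg")
  )
}

#' Simulate a complete capture Hi-C dataset
#'
#' Generates fragments, signals/CCVs, genes, TADs, feature peaks, eQTLs and
#' a dual-capture scored interaction table, together with a ground-truth
#' manifest for parameter-recovery tests. Baseline CHiCAGO-style scores
#' decay as `baseline_amplitude * exp(-d / decay_scale)` with additive
#' Gaussian noise truncated at zero. Direct contacts add `contact_boost` to
#' the score and draw a high MPPC; fragments within `stretch_halfwidth` of a
#' direct contact's prey receive a linearly tapering CHiCAGO-only boost.
#' Group-specific contacts appear only in the cell lines of their latent
#' group.
#'
#' @param config A [sim_config()] object.
#' @return A named list: `fragments`, `variants`, `signals`, `genes`,
#'   `peaks`, `tads`, `eqtls`, `interactions`, `truth`, `config`. `truth`
#'   holds `true_contacts` (bait, prey, cell line), `causal_ccvs`,
#'   `true_target_pairs` and `enriched_feature_names`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  L <- cfg$chrom_length

  ## fragment map: Poisson-process cut sites
  frag_list <- lapply(chroms, function(ch) {
    gaps <- stats::rexp(ceiling(L / 1000 * cfg$site_density * 2) + 20,
                        rate = cfg$site_density / 1000)
    cuts <- cumsum(gaps)
    cuts <- floor(cuts[cuts < L - 1])
    bounds <- unique(c(0, cuts, L))
    tibble::tibble(chrom = ch, start = bounds[-length(bounds)], end = bounds[-1])
  })
  fragments <- dplyr::bind_rows(frag_list)
  fragments$frag_id <- seq_len(nrow(fragments))
  fragments <- dplyr::select(fragments, "frag_id", "chrom", "start", "end")
  mid <- fragment_midpoint(fragments)

  ## TADs: non-overlapping blocks with small gaps
  tads <- dplyr::bind_rows(lapply(chroms, function(ch) {
    starts <- c(); ends <- c(); pos <- stats::runif(1, 0, 5e4)
    while (pos < L - 2e5) {
      len <- stats::runif(1, 4e5, 9e5)
      starts <- c(starts, pos); ends <- c(ends, min(pos + len, L))
      pos <- pos + len + stats::runif(1, 2e4, 6e4)
    }
    tibble::tibble(chrom = ch, start = floor(starts), end = floor(ends))
  }))

  ## signals and CCVs: regions spread along each chromosome, signals
  ## deterministically spaced within a region so their CHiCAGO stretches
  ## stay distinct
  n_signals <- cfg$n_regions * cfg$signals_per_region
  region_chrom <- rep_len(chroms, cfg$n_regions)
  region_center <- unlist(lapply(chroms, function(ch) {
    k <- sum(region_chrom == ch)
    if (k == 0) return(numeric(0))
    L * seq_len(k) / (k + 1) + stats::runif(k, -1e5, 1e5)
  }))[order(order(region_chrom))]
  m <- cfg$signals_per_region
  sig_offsets <- (seq_len(m) - (m + 1) / 2) * 3e5
  sig <- tibble::tibble(
    signal_id = sprintf("S%02d", seq_len(n_signals)),
    region_id = rep(sprintf("R%02d", seq_len(cfg$n_regions)),
                    each = cfg$signals_per_region),
    chrom = rep(region_chrom, each = cfg$signals_per_region),
    center = rep(region_center, each = cfg$signals_per_region) +
      rep(sig_offsets, cfg$n_regions) + stats::runif(n_signals, -5e4, 5e4)
  )
  sig$center <- pmin(pmax(sig$center, 5e4), L - 5e4)
  sig$anchor_frag <- locate_fragment(fragments, sig$chrom, sig$center)

  h <- cfg$stretch_halfwidth
  # containing TAD of a position, or NULL
  tad_of_pos <- function(ch, p) {
    tt <- tads[tads$chrom == ch & tads$start <= p & p < tads$end, ]
    if (nrow(tt)) tt[1, ] else NULL
  }
  distr_span <- max(1L, min(3L, h))
  variants <- purrr::pmap_dfr(sig, function(signal_id, region_id, chrom, center,
                                            anchor_frag) {
    anchor <- fragments[fragments$frag_id == anchor_frag, ]
    n_ccv <- cfg$ccvs_per_signal
    pos <- floor(stats::runif(1, anchor$start, anchor$end - 1)) # causal CCV
    frag <- anchor_frag
    if (n_ccv > 1) {
      offs <- sample(setdiff(-distr_span:distr_span, 0), n_ccv - 1, replace = TRUE)
      dfr <- anchor_frag + offs
      dfr <- pmin(pmax(dfr, min(fragments$frag_id[fragments$chrom == chrom])),
                  max(fragments$frag_id[fragments$chrom == chrom]))
      dtab <- fragments[match(dfr, fragments$frag_id), ]
      pos <- c(pos, floor(stats::runif(n_ccv - 1, dtab$start, dtab$end - 1)))
      frag <- c(frag, dfr)
    }
    alle <- t(vapply(seq_len(n_ccv), function(i) sample(c("A", "C", "G", "T"), 2),
                     character(2)))
    tibble::tibble(
      variant_id = sprintf("rs%s_%d", sub("^S", "", signal_id), seq_len(n_ccv)),
      chrom = chrom, pos = pos,
      risk_allele = alle[, 1], protective_allele = alle[, 2],
      signal_id = signal_id, frag = frag,
      causal = seq_len(n_ccv) == 1
    )
  })

  signals <- tibble::tibble(
    signal_id = sig$signal_id, region_id = sig$region_id,
    er_association = sample(c("ERpos", "ERneg", "both"), n_signals,
                            replace = TRUE)
  )

  ## genes: one true target per signal, the rest placed clear of stretches
  chrom_max <- tapply(fragments$frag_id, fragments$chrom, max)
  chrom_min <- tapply(fragments$frag_id, fragments$chrom, min)
  target_tss <- vapply(seq_len(n_signals), function(i) {
    s <- sig[i, ]
    td <- tad_of_pos(s$chrom, s$center)
    within <- !is.null(td) && stats::runif(1) < cfg$tad_fraction
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (within && tries <= 50L) {
        tss <- stats::runif(1, td$start + 1e3, td$end - 1e3)
      } else {
        tss <- s$center + sample(c(-1, 1), 1) * stats::runif(1, 2e5, 8e5)
      }
      in_td <- !is.null(td) && tss >= td$start && tss < td$end
      side_ok <- if (tries > 100L) TRUE else if (within) in_td else !in_td
      if (tss > 1e3 && tss < L - 1e3 && side_ok &&
            abs(tss - s$center) > 2.5e4) {
        f <- locate_fragment(fragments, s$chrom, tss)
        # promoter fragment must stay clear of every CCV stretch
        if (min(abs(f - variants$frag)) > h) return(tss)
      }
    }
  }, numeric(1))
  exclusion <- unique(c(
    unlist(lapply(variants$frag, function(f) (f - h):(f + h))),
    unlist(lapply(locate_fragment(fragments, sig$chrom, target_tss),
                  function(f) (f - h):(f + h)))
  ))
  n_other <- cfg$n_genes - n_signals
  other_tss <- numeric(0); other_chrom <- character(0)
  while (length(other_tss) < n_other) {
    ch <- sample(chroms, 1)
    tss <- floor(stats::runif(1, 1e3, L - 1e3))
    f <- locate_fragment(fragments, ch, tss)
    if (!f %in% exclusion) {
      other_tss <- c(other_tss, tss); other_chrom <- c(other_chrom, ch)
    }
  }
  genes <- tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
    name = sprintf("GENE%03d", seq_len(cfg$n_genes)),
    biotype = ifelse(stats::runif(cfg$n_genes) < cfg$coding_fraction,
                     "coding", "noncoding"),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    chrom = c(sig$chrom, other_chrom),
    tss = floor(c(target_tss, other_tss))
  )
  genes$promoter_frag <- locate_fragment(fragments, genes$chrom, genes$tss)

  ## bait sets
  vc_baits <- sort(unique(variants$frag))
  pc_frag <- select_pc_fragments(genes, variants, fragments)
  pc_baits <- sort(unique(pc_frag$frag))
  baits <- dplyr::bind_rows(
    tibble::tibble(frag_id = vc_baits, capture = "VC"),
    tibble::tibble(frag_id = pc_baits, capture = "PC")
  )

  ## direct contacts
  groups <- unique(cfg$cell_lines$group)
  draw_spec <- function(n) {
    shared <- stats::runif(n) < cfg$shared_contact_fraction
    grp <- sample(groups, n, replace = TRUE)
    ifelse(shared, "both", grp)
  }
  contacts <- tibble::tibble(bait_frag = integer(), prey_frag = integer(),
                             spec = character(), signal_id = character(),
                             gene_id = character())
  if (cfg$n_true_contacts_per_bait * nrow(baits) > nrow(fragments)) {
    stop("config implies more true contacts than available fragments")
  }
  if (cfg$n_true_contacts_per_bait >= 1L) {
    # one contact per signal: target gene promoter (bait) <-> causal CCV frag
    sig_contacts <- tibble::tibble(
      bait_frag = genes$promoter_frag[seq_len(n_signals)],
      prey_frag = variants$frag[variants$causal],
      spec = draw_spec(n_signals),
      signal_id = sig$signal_id,
      gene_id = genes$gene_id[seq_len(n_signals)]
    )
    # extra random direct contacts so that every bait carries its quota
    quota <- cfg$n_true_contacts_per_bait
    used <- table(c(sig_contacts$bait_frag, sig_contacts$prey_frag))
    special <- unique(c(variants$frag, genes$promoter_frag,
                        unlist(lapply(c(variants$frag, genes$promoter_frag),
                                      function(f) (f - h):(f + h)))))
    extra <- purrr::map_dfr(baits$frag_id, function(b) {
      have <- if (!is.na(used[as.character(b)])) used[as.character(b)] else 0L
      need <- quota - have
      if (need <= 0) return(NULL)
      fb <- fragments[fragments$frag_id == b, ]
      fb_mid <- fragment_midpoint(fb)
      cand <- fragments$frag_id[fragments$chrom == fb$chrom &
                                  abs(mid - fb_mid) > 2e4 &
                                  abs(mid - fb_mid) < 1.9e6]
      cand <- setdiff(cand, special)
      if (length(cand) == 0) return(NULL)
      cand_mid <- mid[match(cand, fragments$frag_id)]
      d <- abs(cand_mid - fb_mid)
      w <- exp(-d / cfg$decay_scale)
      # a tad_fraction share of contacts stays within the bait's TAD
      td <- tad_of_pos(fb$chrom, fb_mid)
      in_td <- if (is.null(td)) rep(FALSE, length(cand)) else {
        cand_mid >= td$start & cand_mid < td$end
      }
      prey <- integer(0)
      n_in <- stats::rbinom(1, need, cfg$tad_fraction)
      if (any(in_td) && n_in > 0) {
        k <- min(n_in, sum(in_td))
        prey <- sample(cand[in_td], k, prob = w[in_td])
      }
      n_out <- need - length(prey)
      pool_out <- setdiff(cand[!in_td], prey)
      if (n_out > 0 && length(pool_out) > 0) {
        wo <- w[match(pool_out, cand)]
        prey <- c(prey, sample(pool_out, min(n_out, length(pool_out)),
                               prob = wo))
      }
      if (length(prey) == 0) return(NULL)
      tibble::tibble(bait_frag = b, prey_frag = prey,
                     spec = draw_spec(length(prey)),
                     signal_id = NA_character_, gene_id = NA_character_)
    })
    contacts <- dplyr::bind_rows(sig_contacts, extra)
  }

  ## interaction table with distance-decay baseline + boosts
  cells <- cfg$cell_lines
  pair_tbl <- purrr::map_dfr(c("VC", "PC"), function(arm) {
    bset <- if (arm == "VC") vc_baits else pc_baits
    bi <- match(bset, fragments$frag_id)
    purrr::map_dfr(unique(fragments$chrom[bi]), function(ch) {
      bb <- bi[fragments$chrom[bi] == ch]
      fi <- which(fragments$chrom == ch)
      d <- abs(outer(mid[bb], mid[fi], "-"))
      keep <- which(d > 0 & d <= 2.1e6, arr.ind = TRUE)
      tibble::tibble(bait_frag = fragments$frag_id[bb[keep[, 1]]],
                     prey_frag = fragments$frag_id[fi[keep[, 2]]],
                     capture = arm, distance = d[keep])
    })
  })
  pair_tbl <- tidyr::crossing(pair_tbl, cell_line = cells$cell_line)

  boost_tbl <- contact_boost_table(contacts, fragments, cells, h,
                                   cfg$contact_boost)
  pair_tbl <- dplyr::left_join(
    pair_tbl, boost_tbl, by = c("bait_frag", "prey_frag", "cell_line")
  )
  pair_tbl$boost <- dplyr::coalesce(pair_tbl$boost, 0)
  pair_tbl$direct <- dplyr::coalesce(pair_tbl$direct, FALSE)

  n <- nrow(pair_tbl)
  base <- cfg$baseline_amplitude * exp(-pair_tbl$distance / cfg$decay_scale)
  eps <- stats::rnorm(n)
  score <- pmax(0, base + pair_tbl$boost + cfg$score_noise_sd * eps)
  # background MPPC shares rank structure with the score noise (Gaussian
  # copula) while keeping its Beta(1, shape2) marginal
  rho <- cfg$score_mppc_rho
  u <- stats::pnorm(rho * eps + sqrt(1 - rho^2) * stats::rnorm(n))
  mppc <- stats::qbeta(u, 1, cfg$mppc_background_shape2)
  if (any(pair_tbl$direct)) {
    idx <- which(pair_tbl$direct)
    pass <- stats::runif(length(idx)) < cfg$mppc_pass_prob
    mppc[idx[pass]] <- stats::runif(sum(pass), 0.2, 0.95)
    mppc[idx[!pass]] <- stats::runif(sum(!pass), 0.02, 0.08)
  }
  interactions <- tibble::tibble(
    bait_frag = pair_tbl$bait_frag, prey_frag = pair_tbl$prey_frag,
    cell_line = pair_tbl$cell_line, capture = pair_tbl$capture,
    chicago_score = round(score, 4), mppc = round(mppc, 4)
  )
  interactions <- add_interaction_distance(interactions, fragments)

  ## contact expansion to cell lines (ground truth)
  cell_of_spec <- function(spec) {
    if (spec == "both") cells$cell_line else cells$cell_line[cells$group == spec]
  }
  true_contacts <- if (nrow(contacts)) {
    tidyr::unnest(
      dplyr::mutate(contacts, cell_line = purrr::map(spec, cell_of_spec)),
      "cell_line"
    )[, c("bait_frag", "prey_frag", "cell_line", "signal_id", "gene_id")]
  } else {
    tibble::tibble(bait_frag = integer(), prey_frag = integer(),
                   cell_line = character(), signal_id = character(),
                   gene_id = character())
  }

  ## feature peaks: background everywhere, boosted at direct-contact preys
  all_features <- c(cfg$enriched_features, cfg$neutral_features)
  prey_by_cell <- split(true_contacts$prey_frag, true_contacts$cell_line)
  peaks <- purrr::map_dfr(all_features, function(feat) {
    enriched <- feat %in% cfg$enriched_features
    purrr::map_dfr(cells$cell_line, function(cl) {
      p <- rep(cfg$peak_background_rate, nrow(fragments))
      if (enriched && !is.null(prey_by_cell[[cl]])) {
        hit <- fragments$frag_id %in% prey_by_cell[[cl]]
        p[hit] <- pmin(1, cfg$peak_background_rate * cfg$peak_enrichment_factor)
      }
      take <- stats::runif(nrow(fragments)) < p
      fr <- fragments[take, ]
      if (nrow(fr) == 0) return(NULL)
      w <- fr$end - fr$start
      tibble::tibble(
        chrom = fr$chrom,
        start = floor(fr$start + 0.25 * w),
        end = floor(fr$start + 0.75 * w),
        feature_name = feat, cell_label = cl
      )
    })
  })

  ## eQTLs: supporting records at true loops + background noise
  eq_sig <- NULL
  if (nrow(contacts)) {
    sc <- contacts[!is.na(contacts$signal_id), ]
    take <- stats::runif(nrow(sc)) < cfg$eqtl_loop_fraction
    sc <- sc[take, , drop = FALSE]
    if (nrow(sc)) {
      cv <- variants[variants$causal, ]
      m <- match(sc$signal_id, cv$signal_id)
      eq_sig <- tibble::tibble(
        chrom = cv$chrom[m], pos = cv$pos[m],
        egene_id = sc$gene_id, fdr = stats::runif(nrow(sc), 0, 0.049)
      )
    }
  }
  n_rec <- stats::rpois(nrow(fragments), cfg$eqtl_background_rate)
  eq_bg <- NULL
  if (sum(n_rec) > 0) {
    fr <- fragments[rep(seq_len(nrow(fragments)), n_rec), ]
    gene_pool <- split(genes$gene_id, genes$chrom)
    egene <- rep(NA_character_, nrow(fr))
    for (idx in split(seq_len(nrow(fr)), fr$chrom)) {
      g <- gene_pool[[fr$chrom[idx[1]]]]
      if (!is.null(g)) egene[idx] <- sample(g, length(idx), replace = TRUE)
    }
    eq_bg <- tibble::tibble(
      chrom = fr$chrom,
      pos = floor(stats::runif(nrow(fr), fr$start, fr$end - 1)),
      egene_id = egene, fdr = stats::runif(nrow(fr), 0, 0.049)
    )
    eq_bg <- eq_bg[!is.na(eq_bg$egene_id), ]
  }
  eqtls <- dplyr::bind_rows(eq_sig, eq_bg)
  if (is.null(eqtls) || nrow(eqtls) == 0) {
    eqtls <- tibble::tibble(chrom = character(), pos = numeric(),
                            egene_id = character(), fdr = numeric())
  }

  truth <- list(
    true_contacts = true_contacts,
    causal_ccvs = variants$variant_id[variants$causal],
    true_target_pairs = if (nrow(contacts)) {
      unique(true_contacts[!is.na(true_contacts$signal_id),
                           c("signal_id", "gene_id")])
    } else {
      tibble::tibble(signal_id = character(), gene_id = character())
    },
    enriched_feature_names = cfg$enriched_features
  )

  list(
    fragments = fragments,
    variants = dplyr::select(variants, -"causal"),
    signals = signals,
    genes = genes,
    baits = baits,
    peaks = peaks,
    tads = tads,
    eqtls = eqtls,
    interactions = interactions,
    truth = truth,
    config = cfg
  )
}

# Expand direct contacts into per-cell-line score boosts: full boost plus
# high MPPC at the contact itself, tapering CHiCAGO-only boost over the
# +/- halfwidth fragment neighbourhood of the prey, in both bait/prey
# orientations.
contact_boost_table <- function(contacts, fragments, cells, halfwidth, boost) {
  if (nrow(contacts) == 0) {
    return(tibble::tibble(bait_frag = integer(), prey_frag = integer(),
                          cell_line = character(), boost = numeric(),
                          direct = logical()))
  }
  ks <- -halfwidth:halfwidth
  both_orient <- dplyr::bind_rows(
    contacts[, c("bait_frag", "prey_frag", "spec")],
    dplyr::rename(contacts[, c("bait_frag", "prey_frag", "spec")],
                  bait_frag = "prey_frag", prey_frag = "bait_frag")
  )
  stretch <- tidyr::crossing(both_orient, k = ks)
  stretch$nbr <- stretch$prey_frag + stretch$k
  # neighbour must exist on the same chromosome as the prey
  chrom_of <- fragments$chrom[match(stretch$nbr, fragments$frag_id)]
  prey_chrom <- fragments$chrom[match(stretch$prey_frag, fragments$frag_id)]
  stretch <- stretch[!is.na(chrom_of) & chrom_of == prey_chrom, ]
  stretch$boost <- boost * (1 - abs(stretch$k) / (halfwidth + 1))
  stretch$direct <- stretch$k == 0L
  cell_map <- dplyr::bind_rows(
    tibble::tibble(spec = "both",
                   cell_line = list(cells$cell_line)),
    purrr::map_dfr(unique(cells$group), function(g) {
      tibble::tibble(spec = g,
                     cell_line = list(cells$cell_line[cells$group == g]))
    })
  )
  stretch <- tidyr::unnest(
    dplyr::inner_join(stretch, cell_map, by = "spec"), "cell_line"
  )
  out <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(bait_frag = stretch$bait_frag, prey_frag = stretch$nbr,
                     cell_line = stretch$cell_line, boost = stretch$boost,
                     direct = stretch$direct),
      .data$bait_frag, .data$prey_frag, .data$cell_line
    ),
    boost = max(.data$boost), direct = any(.data$direct), .groups = "drop"
  )
  out
}

#' Write a simulated dataset to a directory
#'
#' Emits every component in the package's external formats (tab-separated
#' tables, BED for peaks and TADs) plus ground-truth tables and a
#' `manifest.tsv` listing an MD5 checksum per file. The truth tables are
#' test-only; the pipeline never reads them.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Tibble manifest (file, md5), invisibly written as `manifest.tsv`.
#' @export
write_dataset <- function(dataset, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    stop("cannot write to directory: ", dir)
  }
  fp <- function(f) file.path(dir, f)
  write_fragment_map(dataset$fragments, fp("fragments.tsv"))
  readr::write_tsv(dataset$variants, fp("variants.tsv"))
  readr::write_tsv(dataset$signals, fp("signals.tsv"))
  readr::write_tsv(dataset$genes, fp("genes.tsv"))
  readr::write_tsv(dataset$baits, fp("baits.tsv"))
  pk <- dataset$peaks
  write_bed(tibble::tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
                           name = pk$feature_name, score = 0, strand = ".",
                           cell = pk$cell_label), fp("peaks.bed"))
  write_bed(dataset$tads, fp("tads.bed"))
  readr::write_tsv(dataset$eqtls, fp("eqtls.tsv"))
  write_interaction_table(dataset$interactions, fp("interactions.tsv"))
  readr::write_tsv(dataset$truth$true_contacts, fp("truth_contacts.tsv"))
  readr::write_tsv(tibble::tibble(variant_id = dataset$truth$causal_ccvs),
                   fp("truth_causal_ccvs.tsv"))
  readr::write_tsv(dataset$truth$true_target_pairs, fp("truth_target_pairs.tsv"))
  readr::write_tsv(
    tibble::tibble(feature_name = dataset$truth$enriched_feature_names),
    fp("truth_enriched_features.tsv")
  )
  files <- setdiff(list.files(dir), "manifest.tsv")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
  readr::write_tsv(manifest, fp("manifest.tsv"))
  manifest
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the emitted files.
#' @return A list shaped like the output of [simulate_dataset()] (without
#'   `config`; `truth` is `NULL` when the truth tables are absent).
#' @export
read_dataset <- function(dir) {
  fp <- function(f) file.path(dir, f)
  fragments <- read_fragment_map(fp("fragments.tsv"))
  pk <- read_bed(fp("peaks.bed"))
  peaks <- tibble::tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
                          feature_name = pk$name, cell_label = pk$extra7)
  truth <- NULL
  if (file.exists(fp("truth_contacts.tsv"))) {
    truth <- list(
      true_contacts = readr::read_tsv(fp("truth_contacts.tsv"),
                                      show_col_types = FALSE),
      causal_ccvs = readr::read_tsv(fp("truth_causal_ccvs.tsv"),
                                    show_col_types = FALSE)$variant_id,
      true_target_pairs = readr::read_tsv(fp("truth_target_pairs.tsv"),
                                          show_col_types = FALSE),
      enriched_feature_names = readr::read_tsv(
        fp("truth_enriched_features.tsv"), show_col_types = FALSE
      )$feature_name
    )
  }
  list(
    fragments = fragments,
    variants = read_variant_table(fp("variants.tsv"), fragments),
    signals = readr::read_tsv(fp("signals.tsv"), show_col_types = FALSE),
    genes = read_gene_table(fp("genes.tsv"), fragments),
    baits = readr::read_tsv(fp("baits.tsv"), show_col_types = FALSE),
    peaks = peaks,
    tads = read_tad_table(fp("tads.bed")),
    eqtls = read_eqtl_table(fp("eqtls.tsv"), filter = FALSE),
    interactions = read_interaction_table(fp("interactions.tsv"), fragments),
    truth = truth
  )
}
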