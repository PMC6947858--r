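# Evidence joins, the 2-cell-line candidate rule, sequential CCV
# fine-mapping, skipped promoters, summaries, PWM allele scoring.

toy_prio_world <- function() {
  fr <- toy_fragments(n = 100, width = 1000)
  variants <- tibble::tibble(
    variant_id = c("rsA", "rsB"), chrom = "chr1", pos = c(10500, 11500),
    risk_allele = "A", protective_allele = "G",
    signal_id = c("S1", "S1")
  )
  variants$frag <- locate_fragment(fr, variants$chrom, variants$pos)
  genes <- tibble::tibble(
    gene_id = c("G1", "G2"), name = c("GENE1", "GENE2"),
    biotype = c("coding", "noncoding"), strand = "+", chrom = "chr1",
    tss = c(50500, 70500)
  )
  genes$promoter_frag <- locate_fragment(fr, genes$chrom, genes$tss)
  list(fr = fr, variants = variants, genes = genes)
}

test_that("evidence rows require one CCV end and one promoter end", {
  w <- toy_prio_world()
  chic <- toy_interactions(
    bait = c(11L, 51L, 11L), prey = c(51L, 12L, 30L),
    capture = c("VC", "PC", "VC"), fragments = w$fr
  )
  ev <- ccv_promoter_interactions(chic, NULL, w$variants, w$genes, w$fr)
  # VC bait on a CCV fragment reaching the G1 promoter -> one row;
  # PC bait on G1 promoter reaching a CCV fragment -> one row;
  # prey fragment 30 holds neither a CCV nor a promoter -> no row
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$capture, c("VC", "PC"))
  expect_true(all(ev$signal_id == "S1" & ev$gene_id == "G1"))
  expect_true(all(ev$method == "chicago"))
})

test_that("evidence join matches a brute-force oracle on a random fixture", {
  withr::with_seed(404, {
    fr <- toy_fragments(n = 300, width = 1000)
    variants <- tibble::tibble(
      variant_id = sprintf("rs%d", 1:20), chrom = "chr1",
      pos = sample(0:299, 20) * 1000 + 500,
      risk_allele = "A", protective_allele = "G",
      signal_id = sample(c("S1", "S2", "S3"), 20, replace = TRUE)
    )
    variants$frag <- locate_fragment(fr, variants$chrom, variants$pos)
    genes <- tibble::tibble(
      gene_id = sprintf("G%02d", 1:10), name = gene_id,
      biotype = "coding", strand = "+", chrom = "chr1",
      tss = sample(0:299, 10) * 1000 + 500
    )
    genes$promoter_frag <- locate_fragment(fr, genes$chrom, genes$tss)
    ints <- toy_interactions(
      bait = sample(1:300, 100, replace = TRUE),
      prey = sample(1:300, 100, replace = TRUE),
      cell = sample(c("MCF7", "T47D"), 100, replace = TRUE),
      fragments = fr
    )
    ints <- dplyr::distinct(ints[ints$bait_frag != ints$prey_frag, ])
  })
  ev <- ccv_promoter_interactions(ints, NULL, variants, genes, fr)
  # quadratic oracle over interactions x (signal, gene)
  oracle <- 0L
  for (i in seq_len(nrow(ints))) {
    for (s in unique(variants$signal_id)) {
      sf <- variants$frag[variants$signal_id == s]
      for (g in genes$gene_id) {
        gf <- genes$promoter_frag[genes$gene_id == g]
        hit <- (ints$bait_frag[i] %in% sf && ints$prey_frag[i] %in% gf) ||
          (ints$bait_frag[i] %in% gf && ints$prey_frag[i] %in% sf)
        if (hit) oracle <- oracle + 1L
      }
    }
  }
  expect_equal(nrow(ev), oracle)
})

test_that("candidate genes need two cell lines, pooled across routes", {
  w <- toy_prio_world()
  chic <- toy_interactions(11L, 51L, cell = "MCF7", capture = "VC",
                           fragments = w$fr)
  pk <- toy_interactions(51L, 11L, cell = "T47D", capture = "PC",
                         score = 2, mppc = 0.4, fragments = w$fr)
  # MCF7-only support: excluded
  ev1 <- ccv_promoter_interactions(chic, NULL, w$variants, w$genes, w$fr)
  expect_equal(nrow(define_candidate_genes(ev1)), 0)
  # MCF7 via VC/chicago + T47D via PC/peaky: included, methods pooled
  ev2 <- ccv_promoter_interactions(chic, pk, w$variants, w$genes, w$fr)
  cand <- define_candidate_genes(ev2)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$methods, "chicago,peaky")
  expect_true(cand$both_methods)
  expect_equal(cand$captures, "PC,VC")
  # raising the cell-line requirement never adds candidates
  expect_equal(nrow(define_candidate_genes(ev2, min_cell_lines = 3)), 0)
})

test_that("sequential fine-mapping keeps only MPPC-passing CCV fragments", {
  # a 9q33.1-style stretch: 24 CHiCAGO preys from one promoter bait with
  # 29 CCVs spread over them, and exactly one CCV fragment passing MPPC
  fr <- toy_fragments(n = 500, width = 1000)
  genes <- tibble::tibble(gene_id = "PAPPA_like", name = "PAPPA_like",
                          biotype = "coding", strand = "+", chrom = "chr1",
                          tss = 10500)
  genes$promoter_frag <- locate_fragment(fr, genes$chrom, genes$tss)
  stretch <- 350:373 # 24 contiguous prey fragments, ~340 kb away
  withr::with_seed(12, {
    ccv_frags <- sample(stretch, 29, replace = TRUE)
  })
  target_frag <- 360L
  ccv_frags[1] <- target_frag
  variants <- tibble::tibble(
    variant_id = sprintf("rs%03d", seq_along(ccv_frags)), chrom = "chr1",
    pos = (ccv_frags - 1) * 1000 + 500,
    risk_allele = "A", protective_allele = "G", signal_id = "S1"
  )
  variants$frag <- locate_fragment(fr, variants$chrom, variants$pos)
  chic <- toy_interactions(11L, stretch, score = 6, fragments = fr)
  pk <- toy_interactions(11L, target_frag, score = 6, mppc = 0.45,
                         fragments = fr)
  pri <- prioritize_ccvs(chic, pk, variants, genes, fr)
  expect_setequal(pri$variant_id, variants$variant_id[variants$frag ==
                                                        target_frag])
  expect_true(all(pri$prey_frag == target_frag))
  expect_equal(unique(pri$max_mppc), 0.45)

  # no fragment reaches the MPPC threshold: nothing is prioritized
  pri0 <- prioritize_ccvs(chic, pk[0, ], variants, genes, fr)
  expect_equal(nrow(pri0), 0)

  # a signal with no CHiCAGO gate is reported and yields nothing
  v2 <- variants
  v2$signal_id <- "S_ungated"
  v2$frag <- 100L
  v2$pos <- 99500
  expect_message(
    pri2 <- prioritize_ccvs(chic, pk, v2, genes, fr),
    "S_ungated"
  )
  expect_equal(nrow(pri2), 0)

  # dropping the Peaky filter can only enlarge the prioritized set
  pk_all <- toy_interactions(11L, stretch, score = 6, mppc = 0.45,
                             fragments = fr)
  pri_all <- prioritize_ccvs(chic, pk_all, variants, genes, fr)
  expect_true(all(pri$variant_id %in% pri_all$variant_id))
  expect_gte(nrow(pri_all), nrow(pri))
})

test_that("prioritization recovers planted causal CCVs on synthetic truth", {
  hits <- sapply(1:5, function(s) {
    ds <- simulate_dataset(small_config(s + 400))
    v <- located_variants(ds)
    chic <- dplyr::filter(filter_chicago(ds$interactions), capture == "PC")
    pk <- dplyr::filter(filter_peaky(ds$interactions), capture == "PC")
    pri <- suppressMessages(prioritize_ccvs(chic, pk, v, ds$genes,
                                            ds$fragments))
    causal <- ds$truth$causal_ccvs
    distractors <- setdiff(v$variant_id, causal)
    c(recall = mean(causal %in% pri$variant_id),
      excluded = 1 - mean(distractors %in% pri$variant_id))
  })
  expect_gte(mean(hits["recall", ]), 0.9)
  expect_gte(mean(hits["excluded", ]), 0.8)
})

test_that("skipped promoter counts are gene-level and match a linear scan", {
  fr <- toy_fragments(n = 100, width = 1000)
  genes <- tibble::tibble(
    gene_id = c("G1", "G2", "G3"), name = gene_id, biotype = "coding",
    strand = "+", chrom = "chr1", tss = c(50500, 50600, 80500)
  )
  genes$promoter_frag <- locate_fragment(fr, genes$chrom, genes$tss)
  # adjacent fragments skip nothing
  expect_equal(count_skipped_promoters(10L, 11L, genes), 0L)
  # one intervening promoter fragment hosting two genes counts 2
  expect_equal(count_skipped_promoters(40L, 60L, genes), 2L)
  # own gene is excluded
  expect_equal(count_skipped_promoters(40L, 60L, genes, own_gene = "G1"), 1L)

  withr::with_seed(71, {
    b <- sample(1:100, 50, replace = TRUE)
    p <- sample(1:100, 50, replace = TRUE)
  })
  got <- count_skipped_promoters(b, p, genes)
  oracle <- vapply(seq_along(b), function(i) {
    lo <- min(b[i], p[i]); hi <- max(b[i], p[i])
    length(unique(genes$gene_id[genes$promoter_frag > lo &
                                  genes$promoter_frag < hi]))
  }, integer(1))
  expect_equal(got, oracle)
})

test_that("target summaries tally coding, multi-signal and skipping genes", {
  genes <- tibble::tibble(
    gene_id = c("G1", "G2", "G3"), name = paste0("GENE", 1:3),
    biotype = c("coding", "coding", "noncoding"), strand = "+",
    chrom = "chr1", tss = c(1, 2, 3), promoter_frag = c(1L, 2L, 3L)
  )
  cand <- tibble::tibble(
    signal_id = c("S1", "S2", "S2"), gene_id = c("G1", "G1", "G3"),
    cell_lines = "A,B", n_cell_lines = 2L, captures = "PC",
    methods = c("chicago", "chicago,peaky", "peaky"),
    both_methods = c(FALSE, TRUE, FALSE),
    n_skipped_promoters = c(0L, 2L, 1L)
  )
  out <- summarize_targets(cand, genes)
  s <- out$summary
  expect_equal(s$n_candidate_genes, 2)
  expect_equal(s$n_coding_genes, 1)
  # both signals have exactly one coding candidate
  expect_equal(s$n_signals_coding_le2, 2)
  # G1 is linked to two signals
  expect_equal(s$n_multisignal_genes, 1)
  expect_equal(s$frac_pairs_skipping, 2 / 3)
  expect_equal(s$n_both_method_genes, 1)
})

test_that("PWM allele scoring matches hand-computed log-odds", {
  m <- rbind(c(0.4, 0.2, 0.2, 0.2),
             c(0.7, 0.1, 0.1, 0.1),
             c(0.25, 0.25, 0.25, 0.25))
  p <- pwm(m)
  # substitute position 2: A (0.7) vs G (0.1); other positions cancel
  res <- pwm_allele_delta(p, "CAT", 2, "A", "G")
  expect_equal(res$delta, log2(0.7 / 0.25) - log2(0.1 / 0.25))
  expect_equal(res$direction, "increase")
  # identical alleles are neutral
  res0 <- pwm_allele_delta(p, "CAT", 2, "A", "A")
  expect_equal(res0$delta, 0)
  expect_equal(res0$direction, "neutral")
  # max- vs min-probability base gives a positive delta
  res1 <- pwm_allele_delta(p, "CCT", 1, "A", "C")
  expect_gt(res1$delta, 0)
  # zero probabilities are floored with a warning
  m2 <- rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  expect_warning(rz <- pwm_allele_delta(pwm(m2), "AA", 1, "C", "A"),
                 "floored")
  expect_equal(rz$score_risk - rz$score_prot,
               log2(1e-4 / 0.25) - log2(1 / 0.25))
  # malformed matrices are rejected
  expect_error(pwm(rbind(c(0.5, 0.5, 0.1, 0))), "sum to 1")
  # count matrices normalize with a pseudocount
  pc <- pwm_from_counts(rbind(c(8, 0, 2, 0)))
  expect_equal(sum(pc$prob), 1)
  expect_gt(pc$prob[1, "C"], 0)
})
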