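# Interaction thresholding, VIR/PIR summaries, concordance, clustering, PCA.

test_that("CHiCAGO and Peaky filters apply inclusive thresholds", {
  fr <- toy_fragments(n = 4100, width = 1000)
  x <- toy_interactions(
    bait = rep(1L, 5),
    prey = c(2001L, 1500L, 10L, 2500L, 1000L),
    score = c(5.0, 4.99, 12, 8, 6),
    mppc = c(0.10, 0.5, NA, 0.09, 0.2),
    fragments = fr
  )
  expect_equal(x$distance[1], 2e6) # exactly at the distance bound
  chic <- filter_chicago(x)
  # kept: score 5.0 at exactly 2 Mb, score 12, score 6;
  # dropped: score 4.99 (score), score 8 at 2.5 Mb (distance)
  expect_equal(sort(chic$chicago_score), c(5.0, 6, 12))

  pk <- filter_peaky(x)
  # kept: mppc 0.10 (inclusive), 0.5, 0.2; dropped: absent, 0.09 + distance
  expect_equal(sort(pk$mppc), c(0.10, 0.2, 0.5))

  # interchromosomal interactions are dropped regardless of score
  fr2 <- toy_fragments(n = 5, width = 1000, chroms = c("chr1", "chr2"))
  y <- toy_interactions(1L, 8L, score = 12, fragments = fr2)
  expect_equal(nrow(filter_chicago(y)), 0)
})

test_that("filters are idempotent, order-independent, and monotone", {
  ds <- simulate_dataset(small_config(3))
  x <- ds$interactions
  c1 <- filter_chicago(x)
  expect_equal(filter_chicago(c1), c1)
  # order independence of score and distance sub-filters
  a <- filter_chicago(dplyr::filter(x, .data$distance <= 2e6,
                                    .data$intrachromosomal))
  b <- dplyr::filter(filter_chicago(x, max_dist = Inf), .data$distance <= 2e6)
  expect_equal(dplyr::arrange(a, bait_frag, prey_frag, cell_line, capture),
               dplyr::arrange(b, bait_frag, prey_frag, cell_line, capture))
  # monotone: raising the threshold never adds interactions
  c_hi <- filter_chicago(x, score_min = 7)
  expect_true(nrow(c_hi) <= nrow(c1))
  expect_true(all(paste(c_hi$bait_frag, c_hi$prey_frag, c_hi$cell_line,
                        c_hi$capture) %in%
                    paste(c1$bait_frag, c1$prey_frag, c1$cell_line,
                          c1$capture)))
  p1 <- filter_peaky(x)
  expect_equal(filter_peaky(p1), p1)
})

test_that("region derivation conserves records and medians match a direct tally", {
  fr <- toy_fragments(n = 50, width = 1000)
  baits <- tibble::tibble(frag_id = c(1L, 10L, 20L, 30L),
                          capture = c("VC", "VC", "PC", "PC"))
  # 3 baits with 2 / 5 / 9 preys -> median 5
  x <- toy_interactions(
    bait = rep(c(1L, 10L, 20L), c(2, 5, 9)),
    prey = c(2:3, 11:15, 21:29),
    capture = rep(c("VC", "VC", "PC"), c(2, 5, 9)),
    fragments = fr
  )
  reg <- derive_interacting_regions(x, NULL, baits)
  expect_equal(nrow(reg), nrow(x))
  med <- region_count_summary(reg)$medians
  expect_equal(med$median_regions_per_bait[med$kind == "VIR"], 3.5)
  expect_equal(med$median_regions_per_bait[med$kind == "PIR"], 9)
  expect_equal(reg$kind[reg$bait_frag == 1][1], "VIR")

  # single bait: median equals its count
  x1 <- toy_interactions(20L, 21:25, fragments = fr)
  m1 <- region_count_summary(derive_interacting_regions(x1, NULL, baits))
  expect_equal(m1$medians$median_regions_per_bait, 5)

  # unknown bait errors
  bad <- toy_interactions(7L, 8L, fragments = fr)
  expect_error(derive_interacting_regions(bad, NULL, baits), "bait")

  # synthetic dataset: medians equal an independent group-and-count oracle
  ds <- simulate_dataset(small_config(11))
  chic <- filter_chicago(ds$interactions)
  regs <- derive_interacting_regions(chic, NULL, ds$baits)
  med2 <- region_count_summary(regs)$medians
  oracle <- stats::aggregate(
    prey_frag ~ cell_line + capture + bait_frag, data = chic, FUN = length
  )
  for (i in seq_len(nrow(med2))) {
    o <- oracle[oracle$cell_line == med2$cell_line[i] &
                  oracle$capture == med2$capture[i], "prey_frag"]
    expect_equal(med2$median_regions_per_bait[i], stats::median(o))
  }
})

test_that("regions passing both schemes are labelled 'both'", {
  fr <- toy_fragments(n = 20, width = 1000)
  baits <- tibble::tibble(frag_id = 1L, capture = "PC")
  chic <- toy_interactions(1L, c(5L, 6L), score = 6, fragments = fr)
  pk <- toy_interactions(1L, c(6L, 7L), score = 2, mppc = 0.5, fragments = fr)
  reg <- derive_interacting_regions(chic, pk, baits)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$passing[reg$prey_frag == 5], "chicago")
  expect_equal(reg$passing[reg$prey_frag == 6], "both")
  expect_equal(reg$passing[reg$prey_frag == 7], "peaky")
})

test_that("contact fractions hit the degenerate and planted cases", {
  fr <- toy_fragments(n = 30, width = 1000)
  baits <- tibble::tibble(frag_id = c(1L, 20L), capture = c("VC", "PC"))
  x <- toy_interactions(bait = c(1L, 1L, 20L, 20L),
                        prey = c(5L, 6L, 25L, 26L),
                        capture = c("VC", "VC", "PC", "PC"), fragments = fr)
  reg <- derive_interacting_regions(x, NULL, baits)
  # all VIR preys are promoter fragments -> 1; disjoint CCV set -> 0
  cf <- contact_fractions(reg, promoter_frag_ids = c(5L, 6L),
                          ccv_frag_ids = c(9L))
  expect_equal(cf$vir_promoter_fraction, 1)
  expect_equal(cf$pir_ccv_fraction, 0)
  # empty region set -> missing
  cf2 <- contact_fractions(reg[reg$kind == "VIR", ], c(5L, 6L), c(9L))
  expect_true(is.na(cf2$pir_ccv_fraction))

  # planted fraction recovered within a binomial interval
  ds <- simulate_dataset(small_config(21))
  chic <- filter_chicago(ds$interactions)
  regs <- derive_interacting_regions(chic, NULL, ds$baits)
  v <- located_variants(ds)
  cf3 <- contact_fractions(regs, unique(ds$genes$promoter_frag),
                           unique(v$frag))
  # VIR preys genuinely include each signal's target promoter; the
  # recovered fraction must be positive and well below 1
  expect_true(all(cf3$vir_promoter_fraction > 0 &
                    cf3$vir_promoter_fraction < 0.6))
})

test_that("TAD containment counts pairs with both midpoints in one TAD", {
  fr <- toy_fragments(n = 30, width = 1000)
  tads <- tibble::tibble(chrom = "chr1", start = c(0, 12000),
                         end = c(10000, 25000))
  x <- toy_interactions(bait = c(1L, 1L, 2L, 13L),
                        prey = c(5L, 15L, 11L, 20L), fragments = fr)
  # in-TAD: (1,5) and (13,20); split: (1,15); 11 is outside both TADs
  expect_equal(tad_containment_fraction(x, tads, fr), 0.5)
  expect_equal(tad_containment_fraction(x, tads[0, ], fr), 0)
})

test_that("cross-capture concordance matches the closed-form Pearson", {
  fr <- toy_fragments(n = 20, width = 1000)
  vc <- toy_interactions(bait = c(1L, 2L, 3L), prey = c(5L, 6L, 7L),
                         capture = "VC", score = c(1, 2, 3), fragments = fr)
  pc <- toy_interactions(bait = c(5L, 6L, 7L), prey = c(1L, 2L, 3L),
                         capture = "PC", score = c(3, 1, 2), fragments = fr)
  cc <- capture_concordance(vc, pc)
  expect_equal(cc$r_raw, -0.5)
  # perfect linearity: r = 1 raw, and asinh preserves rank order
  pc2 <- pc
  pc2$chicago_score <- 2 * vc$chicago_score
  cc2 <- capture_concordance(vc, pc2)
  expect_equal(cc2$r_raw, 1)
  expect_equal(
    rank(asinh(vc$chicago_score)), rank(vc$chicago_score)
  )
  # fewer than 3 matched pairs -> missing
  cc3 <- capture_concordance(vc[1:2, ], pc[1:2, ])
  expect_true(is.na(cc3$r_raw))
})

test_that("Spearman correlation handles ties by average ranks", {
  fr <- toy_fragments(n = 20, width = 1000)
  x <- toy_interactions(1L, c(5L, 6L, 7L, 8L), score = c(1, 2, 2, 3),
                        mppc = c(0.1, 0.2, 0.3, 0.3), fragments = fr)
  got <- score_correlation(x)$rho
  # hand-computed average ranks: score (1, 2.5, 2.5, 4), mppc (1, 2, 3.5, 3.5)
  expect_equal(got, stats::cor(c(1, 2.5, 2.5, 4), c(1, 2, 3.5, 3.5)))
  # strictly increasing map -> rho = 1; reversed ranks -> -1
  y <- toy_interactions(1L, c(5L, 6L, 7L, 8L), score = c(1, 2, 3, 4),
                        mppc = c(0.1, 0.2, 0.3, 0.4), fragments = fr)
  y$mppc <- y$chicago_score^2 / 100
  expect_equal(score_correlation(y)$rho, 1)
  y$mppc <- rev(y$chicago_score) / 10
  expect_equal(score_correlation(y)$rho, -1)
  # constant vector -> missing
  x$mppc <- 0.5
  expect_true(is.na(score_correlation(x)$rho))
})

test_that("average-linkage clustering reproduces manual UPGMA arithmetic", {
  fr <- toy_fragments(n = 50, width = 1000)
  # construct 3 cell-line profiles with pairwise Euclidean distances 1, 2, 3:
  # colA/colB differ by 1, colA/colC by 2, colB/colC by 3 is impossible in
  # metric space with 3 points unless it satisfies triangle inequality
  # (1 + 2 = 3, degenerate collinear) - use scores along one axis
  mk <- function(cell, v) {
    toy_interactions(1L, c(5L, 6L), cell = cell, score = v, fragments = fr)
  }
  x <- dplyr::bind_rows(mk("A", c(10, 0)), mk("B", c(11, 0)),
                        mk("C", c(8, 0)))
  hc <- cluster_cell_lines(x, score_min = 5)$hclust
  # distances: A-B = 1, A-C = 2, B-C = 3; first merge A,B at height 1;
  # then C joins at average of (2, 3) = 2.5
  expect_equal(hc$height, c(1, 2.5))
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("A", "B"))

  # identical columns merge first at height 0
  y <- dplyr::bind_rows(mk("A", c(10, 6)), mk("B", c(10, 6)),
                        mk("C", c(20, 9)))
  hc2 <- cluster_cell_lines(y, score_min = 5)$hclust
  expect_equal(hc2$height[1], 0)
  expect_error(cluster_cell_lines(mk("A", c(10, 6))), "2 cell lines")
})

test_that("clustering recovers the latent cell-line groups", {
  ds <- simulate_dataset(sim_config(seed = 8))
  cl <- cut_cell_lines(cluster_cell_lines(ds$interactions), k = 2)
  grp <- ds$config$cell_lines$group[
    match(cl$cell_line, ds$config$cell_lines$cell_line)
  ]
  # top-level split separates the two latent groups exactly
  expect_equal(length(unique(paste(grp, cl$cluster))), 2)
})

test_that("PCA is unit-variance scaled and consistent for duplicate columns", {
  fr <- toy_fragments(n = 50, width = 1000)
  mk <- function(cell, v) {
    toy_interactions(1L, c(5L, 6L, 7L), cell = cell, score = v,
                     fragments = fr)
  }
  x <- dplyr::bind_rows(mk("A", c(1, 5, 2)), mk("B", c(1, 5, 2)),
                        mk("C", c(4, 1, 9)))
  p <- pca_cell_lines(x)
  sc <- p$scores
  expect_equal(sc$PC1[sc$cell_line == "A"], sc$PC1[sc$cell_line == "B"])
  expect_equal(sum(p$var_explained), 1)

  # 2x2 toy: PC1 direction matches a hand eigen-decomposition of the
  # scaled profiles
  y <- dplyr::bind_rows(mk("A", c(1, 2, 0))[1:2, ], mk("B", c(3, 6, 0))[1:2, ])
  p2 <- pca_cell_lines(y)
  m <- matrix(c(1, 3, 2, 6), nrow = 2) # rows = cells, cols = interactions
  ms <- scale(m)
  ev <- eigen(stats::cov(ms))
  hand_pc1 <- ms %*% ev$vectors[, 1]
  got_pc1 <- p2$scores$PC2 # both variables perfectly correlated: 1 real PC
  expect_equal(abs(p2$scores$PC1), abs(as.numeric(hand_pc1)),
               tolerance = 1e-8)
  # zero-variance matrix errors
  z <- dplyr::bind_rows(mk("A", c(5, 5, 5)), mk("B", c(5, 5, 5)))
  expect_error(pca_cell_lines(z), "zero variance")
})
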