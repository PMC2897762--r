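test_that("n-mer scores are zero on an injected flat z-track and merge revcomp classes", {
  set.seed(4)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                      collapse = ""))
  flat <- make_track(rep(0, 2000), kind = "z")
  tab <- nmer_depletion_scores(flat, g, n = 5)
  expect_true(all(tab$depletion[tab$n_instances > 0] == 0))
  # one row per merged class (odd n: no palindromes, so 4^5 / 2)
  expect_equal(nrow(tab), 4^5 / 2)
  expect_identical(tab$nmer, pmin(tab$nmer, rc(tab$nmer)))
  q1 <- tab[tab$nmer == pmin("AACGT", rc("AACGT")), ]
  expect_equal(nrow(q1), 1)
  expect_warning(nmer_depletion_scores(flat, g, n = 3), "unusual")
})

test_that("n-mer scores are invariant under reverse-complementing the genome", {
  fx <- default_fixture()
  zt <- log2_z_track(fx$track)
  tab1 <- nmer_depletion_scores(zt, fx$truth$genome, n = 5)
  grc <- c(chr1 = rc(fx$truth$genome[["chr1"]]))
  ztr <- make_track(rev(zt$chr1$values), rev(zt$chr1$mask), kind = "z")
  tab2 <- nmer_depletion_scores(ztr, grc, n = 5)
  expect_equal(tab1$depletion, tab2$depletion, tolerance = 1e-9)
  expect_identical(tab1$n_instances, tab2$n_instances)
})

test_that("a 7-mer planted only in deep NFRs ranks first among all merged classes", {
  cfg <- species_config(polyA_rate = 0, nfr_kmer = "GCGTAAC",
                        nfr_kmer_copies = 4,
                        gene_class = rep(c("growth", "stress", "neutral"),
                                         each = 20))
  tr <- simulate_species(cfg, seed = 21)
  rd <- simulate_reads(tr, seed = 22)
  zt <- log2_z_track(occupancy_track(rd, c(chr1 = nchar(tr$genome[["chr1"]]))))
  tab <- nmer_depletion_scores(zt, tr$genome, n = 7)
  # rank among adequately sampled classes: scores of classes with only a
  # couple of genomic instances are sampling noise, not sequence preference
  tab <- tab[tab$n_instances >= 10, ]
  key <- pmin("GCGTAAC", rc("GCGTAAC"))
  expect_gte(tab$n_instances[tab$nmer == key], 50)
  expect_equal(rank(-tab$depletion, ties.method = "min")[tab$nmer == key], 1)
})

test_that("relative depletion is a power-2 contrast with element-wise species maxima", {
  t1 <- tibble::tibble(nmer = c("AAA", "AAC"), depletion = c(1, 0.5),
                       n_instances = c(10L, 10L), region_scope = "genome")
  same <- relative_depletion(t1, t1)
  expect_true(all(same$relative == 1))
  t2 <- t1; t2$depletion <- t1$depletion - 1
  expect_true(all(relative_depletion(t1, t2)$relative == 2))
  expect_error(relative_depletion(t1, t1[1, ]), "key")
  # max over species equals the element-wise maximum
  sp <- list(t1, t2, tibble::tibble(nmer = t1$nmer, depletion = c(0, 2),
                                    n_instances = 5L, region_scope = "genome"))
  mx <- do.call(pmax, lapply(sp, function(d) d$depletion))
  expect_equal(mx, c(1, 2))
})

test_that("maximal tract finding matches examples and a brute-force oracle", {
  g1 <- find_polya_tracts(c(chr1 = "CCAAAAACC"), max_mismatch = 0)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$length, 5)
  expect_equal(g1$mismatches, 0)
  expect_equal(g1$base, "A")
  g2 <- find_polya_tracts(c(chr1 = "AAAAGAAAA"), max_mismatch = 1)
  expect_equal(nrow(g2[g2$k == 0, ]), 0)            # two 4-runs, both < 5
  k1 <- g2[g2$k == 1, ]
  expect_equal(nrow(k1), 1)
  expect_equal(k1$length, 9)
  expect_equal(k1$mismatches, 1)
  g3 <- find_polya_tracts(c(chr1 = "GGTTTTTTGG"), max_mismatch = 0)
  expect_equal(g3$base, "T")
  expect_equal(g3$length, 6)
  # randomized oracle comparison
  for (s in 1:5) {
    seqs <- withr::with_seed(s, paste(sample(c("A", "C", "G", "T"), 60,
                                             replace = TRUE,
                                             prob = c(.4, .1, .1, .4)),
                                      collapse = ""))
    got <- find_polya_tracts(c(chr1 = seqs), max_mismatch = 3)
    for (k in 0:3) for (b in c("A", "T")) {
      want <- tract_oracle(seqs, b, k)
      have <- got[got$k == k & got$base == b, c("start", "end")]
      expect_equal(dplyr::arrange(have, start),
                   dplyr::arrange(want, start), ignore_attr = TRUE,
                   info = sprintf("seed %d k %d base %s", s, k, b))
    }
  }
})

test_that("tract annotation is invariant under strand flip of the genome", {
  fx <- default_fixture()
  s <- fx$truth$genome[["chr1"]]
  L <- nchar(s)
  a <- find_polya_tracts(c(chr1 = s), max_mismatch = 2)
  b <- find_polya_tracts(c(chr1 = rc(s)), max_mismatch = 2)
  b_m <- tibble::tibble(start = L - b$end, end = L - b$start, k = b$k,
                        length = b$length)
  for (k in 0:2) {
    expect_equal(dplyr::arrange(a[a$k == k, c("start", "end", "length")],
                                start),
                 dplyr::arrange(b_m[b_m$k == k, c("start", "end", "length")],
                                start), ignore_attr = TRUE)
  }
})

test_that("per-class scores use empirical means when abundant, the fitted line when rare", {
  # hand-built ztrack: -z over a tract of length l equals 0.2 * l
  lens <- c(5, 6, 7, 8, 12)
  counts <- c(120, 120, 120, 120, 3)
  pos <- 0L; rows <- list(); zvals <- numeric(20000)
  for (i in seq_along(lens)) {
    for (j in seq_len(counts[i])) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = "chr1", start = pos, end = pos + lens[i],
        length = lens[i], mismatches = 0L, base = "A", k = 0L)
      zvals[(pos + 1):(pos + lens[i])] <- -0.2 * lens[i]
      pos <- pos + lens[i] + 2L
    }
  }
  tracts <- dplyr::bind_rows(rows)
  zt <- make_track(zvals[1:pos], kind = "z")
  cs <- tract_depletion_scores(tracts, zt)
  ab <- cs[cs$length <= 8, ]
  expect_false(any(ab$extrapolated))
  expect_equal(ab$score, 0.2 * ab$length, tolerance = 1e-9)
  rare <- cs[cs$length == 12, ]
  expect_true(rare$extrapolated)
  # rare class gets the line value; planted relation is linear with slope 0.2
  expect_equal(rare$score, 0.2 * 12, tolerance = 1e-6)
})

test_that("quantization ladder and k-iteration replacement follow the stated rules", {
  expect_equal(nucarch:::quantize_fold_level(3.5), 8)   # 2^3.5 = 11.3-fold
  expect_equal(round(2^3.5, 1), 11.3)
  expect_equal(nucarch:::quantize_fold_level(0.5), 0)   # 1.41-fold: below 2
  expect_equal(nucarch:::quantize_fold_level(c(1.01, 2.01, 6)),
               c(2, 4, 32))
  # k = 2 tract at level 8 does NOT replace an overlapping k = 0 level-8 tract
  tracts <- tibble::tibble(chrom = "chr1",
                           start = c(10L, 8L), end = c(20L, 24L),
                           length = c(10L, 16L), mismatches = c(0L, 2L),
                           base = "A", k = c(0L, 2L))
  scores <- tibble::tibble(k = c(0L, 2L), length = c(10L, 16L),
                           n = 200L, empirical_score = c(3.2, 3.4),
                           fitted_score = NA_real_, score = c(3.2, 3.4),
                           extrapolated = FALSE)
  agg <- quantize_and_aggregate(tracts, scores)
  expect_equal(agg$k, 0L)
  # strictly higher level does replace
  scores2 <- scores; scores2$score[2] <- 4.2          # level 16
  agg2 <- quantize_and_aggregate(tracts, scores2)
  expect_equal(agg2$k, 2L)
})

test_that("the aggregated annotation is non-overlapping and depletion grows with planted length", {
  fx <- default_fixture()
  zt <- log2_z_track(fx$track)
  tt <- find_polya_tracts(fx$truth$genome, max_mismatch = 8)
  cs <- suppressWarnings(tract_depletion_scores(tt, zt))
  agg <- quantize_and_aggregate(tt, cs)
  a <- agg[order(agg$chrom, agg$start), ]
  expect_true(all(utils::head(a$end, -1) <= utils::tail(a$start, -1) |
                    utils::head(a$chrom, -1) != utils::tail(a$chrom, -1)))
  # planted tracts (8-20 bp, in deep NFRs) drive a positive score-vs-L slope
  k0 <- cs[cs$k == 0 & cs$n >= 2, ]
  expect_gt(coef(lm(empirical_score ~ length, data = k0,
                    weights = k0$n))[2], 0)
})

test_that("NFR Poly(dA:dT) strength sums quantized levels by midpoint containment", {
  nfrs <- tibble::tibble(gene_id = c("g1", "g2", "g3"), side = "5",
                         chrom = "chr1", start = c(100L, 300L, 500L),
                         end = c(200L, 400L, 600L))
  tracts <- tibble::tibble(chrom = "chr1",
                           start = c(110L, 150L, 390L),
                           end = c(130L, 170L, 410L),
                           quantized_level = c(8, 4, 8))
  st <- nfr_polya_strength(nfrs, tracts)
  # two tracts in g1 sum to 12; the third tract's midpoint (400) falls
  # exactly on g2's half-open NFR end, so g2 is empty
  expect_equal(st$polyA_strength, c(12, 0, 0))
  expect_equal(st$polyA_strength_max, c(8, 0, 0))
})
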