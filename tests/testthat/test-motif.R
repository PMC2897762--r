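rand_promoters <- function(n = 30, len = 400, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(gene_id = sprintf("g%04d", 1:n), chrom = "chr1",
                   start = (1:n - 1) * len, end = (1:n) * len, strand = "+",
                   seq = vapply(1:n, function(i)
                     paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = ""), character(1)))
  })
}

test_that("PWM objects validate, round-trip through MEME-like text", {
  p <- consensus_pwm("m1", "ACGTAC")
  expect_s3_class(p, "nucarch_pwm")
  expect_equal(rowSums(p$mat), rep(1, 6), tolerance = 1e-9)
  expect_true(all(p$mat > 0))
  tf <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(p, consensus_pwm("m2", "TTTTGGA")), tf)
  back <- read_meme(tf, pseudocount = 0)
  expect_equal(names(back), c("m1", "m2"))
  expect_equal(back$m1$mat, p$mat, tolerance = 1e-5)
})

test_that("a near-one-hot PWM hits exactly the planted occurrences on both strands", {
  pr <- rand_promoters(6, 300, seed = 9)
  plant <- function(s, at, what) {
    paste0(substr(s, 1, at - 1), what, substr(s, at + nchar(what), nchar(s)))
  }
  pr$seq[1] <- plant(pr$seq[1], 50, "ACGTAC")
  pr$seq[2] <- plant(pr$seq[2], 120, rc("ACGTAC"))   # minus-strand occurrence
  p <- consensus_pwm("onehot", "ACGTAC", conc = 0.997)
  # the score gap between exact matches and 1-mismatch windows is huge, so
  # any threshold between their p-values retains exactly the exact matches
  hits <- scan_promoters(p, pr, p_thresh = 1e-3)
  # every retained window is an exact match to the consensus or its revcomp
  for (i in seq_len(nrow(hits))) {
    g <- pr[pr$gene_id == hits$gene_id[i], ]
    w <- substr(g$seq, hits$start[i] - g$start + 1,
                hits$end[i] - g$start)
    expect_true(w %in% c("ACGTAC", rc("ACGTAC")))
  }
  expect_true(any(hits$gene_id == "g0001" & hits$start == pr$start[1] + 49))
  expect_true(any(hits$gene_id == "g0002" & hits$strand == "-"))
})

test_that("scanner p-values are calibrated on pure background sequence", {
  pr <- rand_promoters(40, 400, seed = 3)
  p <- consensus_pwm("cal", "TGACGTCA", conc = 0.8)
  all_sites <- scan_promoters(p, pr, p_thresh = 1.0000001)
  n_windows <- nrow(all_sites)
  for (alpha in c(0.01, 0.05)) {
    fp <- mean(all_sites$p_value < alpha)
    se <- sqrt(alpha * (1 - alpha) / n_windows)
    expect_lt(abs(fp - alpha), 2 * se + 2e-3,
              label = sprintf("alpha %.2f rate %.4f", alpha, fp))
  }
})

test_that("the promoter cap keeps the best max_promoters promoters", {
  pr <- rand_promoters(60, 60, seed = 5)
  pr$seq <- paste0(substr(pr$seq, 1, 20), "ACGTACGT",
                   substr(pr$seq, 29, 60))
  p <- consensus_pwm("capped", "ACGTACGT", conc = 0.99)
  hits <- scan_promoters(p, pr, p_thresh = 0.01, max_promoters = 40)
  expect_equal(length(unique(hits$gene_id)), 40)
  expect_true(all(tapply(hits$best_in_promoter, hits$gene_id, sum) == 1))
})

test_that("NFR affinity matches closed forms and brute-force enumeration", {
  bg0 <- rep(0.25, 4)
  # PWM identical to the background: every window contributes 1 per strand
  flat <- pwm("flat", matrix(0.25, nrow = 3, ncol = 4), pseudocount = 0)
  s <- "ACGTACGTA"
  expect_equal(nfr_affinity(flat, s, bg0), 2 * (nchar(s) - 3 + 1))
  expect_equal(nfr_affinity(flat, "AC", bg0), 0)      # shorter than the motif
  # L = 2 brute force: 3 windows x 2 strands
  m2 <- pwm("m2", rbind(c(.7, .1, .1, .1), c(.1, .1, .1, .7)),
            pseudocount = 0)
  s4 <- "ACGT"
  hand <- 0
  for (k in 1:3) {
    w <- substr(s4, k, k + 1)
    wrc <- rc(w)
    pr_of <- function(x) m2$mat[1, substr(x, 1, 1)] * m2$mat[2, substr(x, 2, 2)]
    hand <- hand + pr_of(w) / 0.0625 + pr_of(wrc) / 0.0625
  }
  expect_equal(nfr_affinity(m2, s4, bg0), unname(hand))
  expect_error(nfr_affinity(m2, s4, c(0, 1, 1, 1)), "positive")
  # strand symmetry: affinity of the reverse complement sequence is identical
  fx_s <- "GGATACCCGTTA"
  expect_equal(nfr_affinity(m2, fx_s, bg0), nfr_affinity(m2, rc(fx_s), bg0))
})

test_that("instances are binned by center containment into disjoint regions", {
  regions <- tibble::tibble(
    gene_id = "g1",
    region = c("Nuc+1", "5'NFR", "Nuc-1", "NFR2", "Nuc-2"),
    start = c(500L, 400L, 253L, 180L, 33L),
    end = c(647L, 500L, 400L, 253L, 180L))
  mk <- function(center) tibble::tibble(motif_id = "m", gene_id = "g1",
                                        chrom = "chr1",
                                        start = center - 3L, end = center + 4L,
                                        strand = "+", score = 1, p_value = 0.01)
  b1 <- bin_motif_instances(mk(450L), regions)
  expect_equal(b1$region, "5'NFR"); expect_equal(b1$linker_class, "Linkers")
  b2 <- bin_motif_instances(mk(300L), regions)
  expect_equal(b2$region, "Nuc-1"); expect_equal(b2$linker_class, "Nucs")
  b3 <- bin_motif_instances(mk(32L), regions)   # one past Nuc-2's edge
  expect_equal(b3$region, "outside")
  b4 <- bin_motif_instances(dplyr::mutate(mk(450L), gene_id = "gX"), regions)
  expect_equal(b4$region, "outside")
  expect_false(b4$regions_resolved)
})

test_that("NFR fractions and z-scores follow the two-point closed form", {
  binned <- dplyr::bind_rows(
    tibble::tibble(species_id = "s1", motif_id = "mA",
                   linker_class = c(rep("Linkers", 2), rep("Nucs", 8))),
    tibble::tibble(species_id = "s1", motif_id = "mB",
                   linker_class = c(rep("Linkers", 8), rep("Nucs", 2),
                                    "outside")))
  fm <- nfr_fraction_matrix(binned)
  expect_equal(sort(fm$fraction), c(0.2, 0.8))
  expect_equal(sort(fm$zscore), c(-1, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(fm$fraction_all[fm$motif_id == "mB"], 8 / 11)
})

test_that("activator and repressor calls follow the linker/nucleosome expression contrast", {
  mk_sites <- function(motif, classes, genes) {
    tibble::tibble(motif_id = motif, gene_id = genes, chrom = "chr1",
                   start = 1L, end = 8L, strand = "+", score = 1,
                   p_value = 1e-5, region = "x", linker_class = classes)
  }
  expr <- tibble::tibble(gene_id = sprintf("g%03d", 1:60),
                         expression = rep(c(3, -3), each = 30) +
                           withr::with_seed(8, rnorm(60, 0, 0.3)))
  hi <- expr$gene_id[1:30]; lo <- expr$gene_id[31:60]
  act <- mk_sites("act", rep(c("Linkers", "Nucs"), each = 15), c(hi[1:15], lo[1:15]))
  call_a <- linker_vs_nuc_expression(act, expr)
  expect_equal(call_a$call, "activator-like")
  expect_gt(call_a$S_KS, 2)
  expect_gt(call_a$mean_expr_linkers, call_a$mean_expr_nucs)
  # swapping the classes flips the call
  swp <- dplyr::mutate(act, linker_class = ifelse(linker_class == "Linkers",
                                                  "Nucs", "Linkers"))
  call_r <- linker_vs_nuc_expression(swp, expr)
  expect_equal(call_r$call, "repressor-like")
  expect_equal(call_r$S_KS, -call_a$S_KS, tolerance = 1e-9)
  # identical distributions: insignificant score near zero
  nul <- mk_sites("nul", rep(c("Linkers", "Nucs"), 15),
                  rep(expr$gene_id[1:15], each = 2))
  call_n <- linker_vs_nuc_expression(nul, expr)
  expect_lt(abs(call_n$S_KS), 1.31)        # |S| < -log10(0.05)
  # too few sites in a class: no-call sentinel
  few <- mk_sites("few", c(rep("Linkers", 3), rep("Nucs", 20)),
                  expr$gene_id[1:23])
  expect_true(is.na(linker_vs_nuc_expression(few, expr)$call))
})

test_that("planted motifs reproduce the linker-preference contrast of GRFs vs stress factors", {
  fx <- default_fixture()
  tr <- fx$truth
  pr <- promoter_sequences(tr$genome, tr$genes)
  bg <- markov_background(pr$seq, 3)
  regions <- gene_promoter_regions(fx$calls, fx$nfrs, tr$genes)
  scan_bin <- function(ids, p_thresh) {
    out <- dplyr::bind_rows(lapply(default_pwms()[ids], function(p) {
      h <- scan_promoters(p, pr, bg = bg, p_thresh = p_thresh)
      if (nrow(h)) bin_motif_instances(h, regions) else NULL
    }))
    out$species_id <- "s1"
    out
  }
  # architectural contrast at a stringent per-site threshold (the toy
  # genome's chance near-matches would dominate a looser one)
  arch <- scan_bin(c("grf1", "stress_tf"), 2e-5)
  fm <- nfr_fraction_matrix(arch)
  expect_gte(fm$fraction[fm$motif_id == "grf1"], 0.8)
  expect_lte(fm$fraction[fm$motif_id == "stress_tf"], 0.35)
  binned <- scan_bin(c("act_tf", "rep_tf"), 1e-4)
  calls <- linker_vs_nuc_expression(binned, fx$expr)
  expect_equal(calls$call[calls$motif_id == "act_tf"], "activator-like")
  expect_gt(calls$S_KS[calls$motif_id == "act_tf"], 2)
  expect_equal(calls$call[calls$motif_id == "rep_tf"], "repressor-like")
})

test_that("the paired Wilcoxon preference test handles its degenerate cases", {
  inst <- tibble::tibble(motif_id = "m", gene_id = "g1", chrom = "chr1",
                         start = 10L, end = 17L, strand = "+", score = 1,
                         p_value = 1e-4)
  prom <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                         end = 100L, strand = "+", seq = "")
  flat <- make_track(rep(1, 200))
  # x == y for the single pair -> below min_pairs -> no-call
  one <- motif_depletion_preference(inst, flat, prom)
  expect_true(is.na(one$p_value))
  # 20 pairs, all sites depleted: exact two-sided minimum 2/2^20
  insts <- dplyr::bind_rows(lapply(1:20, function(i)
    dplyr::mutate(inst, gene_id = sprintf("g%02d", i),
                  start = 200L * (i - 1L) + 10L, end = 200L * (i - 1L) + 17L)))
  proms <- dplyr::bind_rows(lapply(1:20, function(i)
    dplyr::mutate(prom, gene_id = sprintf("g%02d", i),
                  start = 200L * (i - 1L), end = 200L * (i - 1L) + 100L)))
  v <- rep(1, 4000)
  for (i in 1:20) v[(200 * (i - 1) + 11):(200 * (i - 1) + 17)] <- 0.1 / i
  dep <- motif_depletion_preference(insts, make_track(v), proms)
  expect_equal(dep$n_pairs, 20)
  expect_equal(dep$p_value, 2 / 2^20, tolerance = 1e-9)
  expect_lt(dep$mean_site_log2, dep$mean_promoter_log2)
  # flat track: x equals y for every pair, P = 1 by convention
  flat_res <- motif_depletion_preference(insts, make_track(rep(1, 4000)),
                                         proms)
  expect_equal(flat_res$p_value, 1)
})

test_that("promoter extraction truncates at neighbor ORFs and is strand-aware", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          strand = c("+", "+"),
                          cds_start = c(100L, 700L), cds_end = c(500L, 900L))
  set.seed(2)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                      collapse = ""))
  pr <- promoter_sequences(g, genes)
  expect_equal(pr$start[pr$gene_id == "a"], 0)      # clipped at chrom start
  expect_equal(pr$start[pr$gene_id == "b"], 500)    # truncated at gene a
  expect_equal(nchar(pr$seq[2]), 200)
  gm <- dplyr::mutate(genes, strand = "-")
  prm <- promoter_sequences(g, gm)
  expect_equal(prm$start[prm$gene_id == "a"], 500)  # upstream is rightward
  expect_equal(prm$end[prm$gene_id == "a"], 700)    # truncated at gene b
  expect_equal(prm$seq[1], unname(rc(substr(g, 501, 700))))
})
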