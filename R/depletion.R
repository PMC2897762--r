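all_nmers <- function(n) {
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), n),
                                  stringsAsFactors = FALSE)))
}

region_vector <- function(intervals, L) {
  # logical per-base membership (index = base + 1) for 0-based half-open ivs
  v <- logical(L)
  if (nrow(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      s <- max(0L, intervals$start[i]); e <- min(L, intervals$end[i])
      if (e > s) v[(s + 1L):e] <- TRUE
    }
  }
  v
}

#' Anti-nucleosomal depletion scores for all n-mers
#'
#' Every genomic instance of an n-mer contributes the mean of the negative
#' z-normalized log2 occupancy over its n-base footprint (masked bases
#' excluded; fully masked instances skipped). An n-mer and its reverse
#' complement are merged into one strand-symmetric class (palindromes count
#' once per site), so high scores mark sequences that nucleosomes avoid.
#'
#' @param ztrack A z-kind `nucarch_track` from [log2_z_track()].
#' @param genome Named character vector of chromosome sequences.
#' @param n N-mer length; 5-8 is the intended range (other values are
#'   allowed with a warning).
#' @param scope `"genome"`, `"coding"` or `"promoter"` — restricts instances
#'   to bases inside the annotation (requires `genes` when restricted).
#' @param genes Gene tibble (for restricted scopes).
#' @param promoter_window Upstream window defining promoters (bp).
#' @return Tibble with one row per reverse-complement-merged class: `nmer`
#'   (lexicographically smaller representative), `depletion`, `n_instances`,
#'   `region_scope`.
#' @export
nmer_depletion_scores <- function(ztrack, genome, n = 7L,
                                  scope = c("genome", "coding", "promoter"),
                                  genes = NULL, promoter_window = 1000L) {
  scope <- match.arg(scope)
  if (n < 5 || n > 8) warn("n outside 5..8: allowed but unusual.")
  if (scope != "genome" && is.null(genes))
    abort("`genes` is required for coding/promoter scope.")
  keys_all <- character(0); vals_all <- numeric(0)
  for (cn in names(genome)) {
    s <- genome[[cn]]
    L <- nchar(s)
    if (L < n) next
    z <- ztrack[[cn]]$values
    zz <- ifelse(is.na(z), 0, z)
    cz <- c(0, cumsum(zz)); cg <- c(0, cumsum(!is.na(z)))
    p <- 1:(L - n + 1)
    ssum <- cz[p + n] - cz[p]
    scnt <- cg[p + n] - cg[p]
    val <- ifelse(scnt > 0, -ssum / scnt, NA_real_)
    keep <- scnt > 0
    if (scope != "genome") {
      ivs <- if (scope == "coding") {
        g <- genes[genes$chrom == cn, ]
        tibble(start = g$cds_start, end = g$cds_end)
      } else {
        g <- genes[genes$chrom == cn, ]
        tibble(start = ifelse(g$strand == "+",
                              pmax(g$cds_start - promoter_window, 0L),
                              g$cds_end),
               end = ifelse(g$strand == "+", g$cds_start,
                            pmin(g$cds_end + promoter_window, L)))
      }
      inr <- region_vector(ivs, L)
      ci <- c(0, cumsum(inr))
      keep <- keep & (ci[p + n] - ci[p]) == n     # footprint fully inside
    }
    if (!any(keep)) next
    kms <- substring(s, p[keep], p[keep] + n - 1L)
    keys_all <- c(keys_all, kms)
    vals_all <- c(vals_all, val[keep])
  }
  keys <- pmin(keys_all, revcomp_chr(keys_all))
  classes <- all_nmers(n)
  classes <- sort(unique(pmin(classes, revcomp_chr(classes))))
  idx <- match(keys, classes)
  sums <- rep(0, length(classes)); cnts <- rep(0L, length(classes))
  agg_s <- tapply(vals_all, idx, sum)
  agg_n <- tapply(vals_all, idx, length)
  ii <- as.integer(names(agg_s))
  sums[ii] <- agg_s; cnts[ii] <- agg_n
  tibble(nmer = classes,
         depletion = ifelse(cnts > 0, sums / cnts, NA_real_),
         n_instances = cnts, region_scope = scope)
}

#' Depletion relative to an intrinsic (in-vitro-like) landscape
#'
#' `relative = 2^(in vivo depletion - in vitro depletion)` per merged n-mer
#' class: values above 1 mark sequences more nucleosome-depleted in vivo
#' than their intrinsic sequence preference explains.
#'
#' @param table_vivo,table_vitro Outputs of [nmer_depletion_scores()] with
#'   matching `n` and scope.
#' @return Joined tibble with `depletion_vivo`, `depletion_vitro`,
#'   `relative`.
#' @export
relative_depletion <- function(table_vivo, table_vitro) {
  if (!setequal(table_vivo$nmer, table_vitro$nmer))
    abort("n-mer tables do not share a key set (mismatched n or merge).")
  vv <- table_vivo %>% select("nmer", depletion_vivo = "depletion",
                              n_vivo = "n_instances")
  vt <- table_vitro %>% select("nmer", depletion_vitro = "depletion",
                               n_vitro = "n_instances")
  inner_join(vv, vt, by = "nmer") %>%
    mutate(relative = 2^(.data$depletion_vivo - .data$depletion_vitro))
}

find_tracts_one <- function(m, L, cn, base, k, min_len) {
  W <- which(m)
  if (!length(W)) return(NULL)
  Fv <- c(0L, which(!m), L + 1L)            # mismatch positions + sentinels
  M <- length(Fv) - 2L
  js <- 0:max(0L, M - k)
  s_raw <- Fv[js + 1L] + 1L
  e_idx <- pmin(js + k + 2L, M + 2L)
  e_raw <- Fv[e_idx] - 1L
  # trim endpoints to matching bases
  si <- findInterval(s_raw - 1L, W) + 1L
  ei <- findInterval(e_raw, W)
  ok <- si <= length(W) & ei >= 1 & ei >= si
  if (!any(ok)) return(NULL)
  ts <- W[si[ok]]; te <- W[ei[ok]]
  len <- te - ts + 1L
  keep <- len >= min_len
  if (!any(keep)) return(NULL)
  ts <- ts[keep]; te <- te[keep]; len <- len[keep]
  # mismatches inside the trimmed tract
  nmatch <- findInterval(te, W) - findInterval(ts - 1L, W)
  mm <- len - nmatch
  d <- tibble(start = ts - 1L, end = te, length = len, mismatches = mm) %>%
    distinct()
  # drop tracts contained in another tract of the same k
  o <- order(d$start, -d$end)
  d <- d[o, ]
  prev_max <- c(-1L, cummax(d$end))[seq_len(nrow(d))]
  d <- d[d$end > prev_max, ]
  d$chrom <- cn; d$base <- base; d$k <- k
  d
}

#' Find maximal Poly(dA:dT) tracts with allowed mismatches
#'
#' For each mismatch allowance `k = 0, ..., max_mismatch`, finds every
#' maximal run of A (and, separately, of T) of length >= `min_len` that
#' contains at most `k` non-matching bases; tract endpoints are matching
#' bases and maximality means the tract cannot be extended without exceeding
#' `k` mismatches. PolyA and PolyT form one strand-symmetric class
#' downstream.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param min_len Minimum tract length (default 5).
#' @param max_mismatch Largest mismatch allowance (default 20).
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open), `length`,
#'   `mismatches`, `base` ("A"/"T"), `k`.
#' @export
find_polya_tracts <- function(genome, min_len = 5L, max_mismatch = 20L) {
  out <- list()
  for (cn in names(genome)) {
    s <- genome[[cn]]
    chars <- strsplit(s, "")[[1]]
    for (base in c("A", "T")) {
      m <- chars == base
      for (k in 0:max_mismatch) {
        out[[length(out) + 1]] <- find_tracts_one(m, nchar(s), cn, base, k,
                                                  min_len)
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(start = integer(), end = integer(), length = integer(),
                  mismatches = integer(), chrom = character(),
                  base = character(), k = integer()))
  }
  res %>% select("chrom", "start", "end", "length", "mismatches", "base", "k")
}

tract_instance_scores <- function(tracts, ztrack) {
  out <- numeric(nrow(tracts))
  for (cn in unique(tracts$chrom)) {
    idx <- which(tracts$chrom == cn)
    z <- ztrack[[cn]]$values
    zz <- ifelse(is.na(z), 0, z)
    cz <- c(0, cumsum(zz)); cg <- c(0, cumsum(!is.na(z)))
    s <- tracts$start[idx]; e <- tracts$end[idx]
    sm <- cz[e + 1L] - cz[s + 1L]
    ct <- cg[e + 1L] - cg[s + 1L]
    out[idx] <- ifelse(ct > 0, -(sm / ct), NA_real_)
  }
  out
}

#' Per-(length, mismatch) Poly(dA:dT) depletion scores with line fallback
#'
#' Empirical score of a (L, k) class = mean of the per-instance mean
#' negative z-occupancy over all tracts of that length and mismatch
#' allowance. Because long tracts are rare, a weighted linear fit of score
#' versus L (weights = instance counts, one line per k) is used in place of
#' the empirical mean for classes with fewer than `min_instances`
#' occurrences.
#'
#' @param tracts Output of [find_polya_tracts()].
#' @param ztrack A z-kind `nucarch_track`.
#' @param min_instances Count below which the fitted line replaces the
#'   empirical mean (default 100).
#' @return Tibble: `k`, `length`, `n`, `empirical_score`, `fitted_score`,
#'   `score` (the assigned value), `extrapolated`.
#' @export
tract_depletion_scores <- function(tracts, ztrack, min_instances = 100L) {
  tracts$inst_score <- tract_instance_scores(tracts, ztrack)
  cls <- tracts %>%
    filter(!is.na(.data$inst_score)) %>%
    group_by(.data$k, .data$length) %>%
    summarise(n = n(), empirical_score = mean(.data$inst_score),
              .groups = "drop")
  cls %>%
    group_by(.data$k) %>%
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$length)) < 2) {
        warn(sprintf("k=%s: fewer than 2 tract lengths; line fit skipped.",
                     key$k))
        d$fitted_score <- NA_real_
        d$score <- d$empirical_score
        d$extrapolated <- FALSE
        return(d)
      }
      fit <- lm(empirical_score ~ length, data = d, weights = d$n)
      d$fitted_score <- as.numeric(predict(fit, d))
      d$extrapolated <- d$n < min_instances
      d$score <- ifelse(d$extrapolated, d$fitted_score, d$empirical_score)
      d
    }) %>%
    ungroup()
}

quantize_fold_level <- function(score) {
  fold <- 2^score
  ladder <- c(2, 4, 8, 16, 32)
  vapply(fold, function(f) {
    ex <- ladder[ladder < f]
    if (length(ex)) max(ex) else 0
  }, numeric(1))
}

#' Quantize tract scores and aggregate to a non-overlapping annotation
#'
#' Each tract's fold depletion is `2^score`, quantized to the highest level
#' among 2, 4, 8, 16, 32 that the fold strictly exceeds (0 if below 2; e.g.
#' a score of 3.5 gives fold 11.3 and level 8). Tracts are then aggregated
#' over mismatch allowances k = 0 to 20: a higher-k tract replaces the
#' lower-k tract(s) it overlaps only when its quantized level is strictly
#' higher; the result is pairwise non-overlapping.
#'
#' @param tracts Output of [find_polya_tracts()].
#' @param class_scores Output of [tract_depletion_scores()].
#' @return Tibble of final tract annotations: coordinates, `length`,
#'   `mismatches`, `k`, `score`, `fold`, `quantized_level`.
#' @export
quantize_and_aggregate <- function(tracts, class_scores) {
  tr <- tracts %>%
    inner_join(select(class_scores, "k", "length", "score"),
               by = c("k", "length")) %>%
    mutate(fold = 2^.data$score,
           quantized_level = quantize_fold_level(.data$score))
  keep_rows <- integer(0)
  for (cn in unique(tr$chrom)) {
    rows <- which(tr$chrom == cn)
    trc <- tr[rows, ]
    L <- max(trc$end)
    ord <- rows[order(trc$k, -trc$quantized_level, trc$start)]
    own <- integer(L)                 # per-base owner (index into acc_*)
    acc_s <- integer(0); acc_e <- integer(0); acc_lv <- numeric(0)
    acc_row <- integer(0); alive <- logical(0)
    lv_all <- tr$quantized_level
    for (ri in ord) {
      s <- tr$start[ri]; e <- tr$end[ri]; lv <- lv_all[ri]
      span <- (s + 1L):e
      o <- own[span]
      o <- unique(o[o > 0L])
      if (length(o)) {
        if (lv <= max(acc_lv[o])) next
        for (id in o) {               # strictly higher level: evict
          own[(acc_s[id] + 1L):acc_e[id]] <- 0L
          alive[id] <- FALSE
        }
      }
      id <- length(acc_s) + 1L
      acc_s[id] <- s; acc_e[id] <- e; acc_lv[id] <- lv
      acc_row[id] <- ri; alive[id] <- TRUE
      own[span] <- id
    }
    keep_rows <- c(keep_rows, acc_row[alive])
  }
  out <- tr[keep_rows, ]
  out[order(out$chrom, out$start), ]
}

#' Poly(dA:dT) strength inside each gene's 5' NFR
#'
#' Sums the quantized fold-depletion levels of aggregated tracts whose
#' midpoint lies inside the gene's 5' NFR (0 if none); the maximum level is
#' reported alongside as an alternative aggregation.
#'
#' @param nfrs Output of [find_nfrs()] (5' rows are used).
#' @param tracts_final Output of [quantize_and_aggregate()].
#' @return Tibble: `gene_id`, `polyA_strength` (sum), `polyA_strength_max`.
#' @export
nfr_polya_strength <- function(nfrs, tracts_final) {
  n5 <- nfrs[nfrs$side == "5", ]
  mid <- (tracts_final$start + tracts_final$end) %/% 2L
  purrr::map_dfr(seq_len(nrow(n5)), function(i) {
    hit <- tracts_final$chrom == n5$chrom[i] &
      mid >= n5$start[i] & mid < n5$end[i]
    tibble(gene_id = n5$gene_id[i],
           polyA_strength = sum(tracts_final$quantized_level[hit]),
           polyA_strength_max = if (any(hit))
             max(tracts_final$quantized_level[hit]) else 0)
  })
}
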