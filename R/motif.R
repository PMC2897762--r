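BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param mat Numeric L x 4 matrix of base probabilities, columns A, C, G, T.
#' @param pseudocount Added to every entry at construction, then rows are
#'   renormalized, so all entries are strictly positive.
#' @return A `nucarch_pwm`: list with `motif_id`, `mat` (rows sum to 1),
#'   `length`.
#' @export
pwm <- function(motif_id, mat, pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4, all(mat >= 0))
  colnames(mat) <- BASES
  mat <- mat + pseudocount
  mat <- mat / rowSums(mat)
  structure(list(motif_id = motif_id, mat = mat, length = nrow(mat)),
            class = "nucarch_pwm")
}

#' Near-consensus PWM from a consensus string
#'
#' @param motif_id Motif identifier.
#' @param consensus Consensus sequence over ACGT.
#' @param conc Probability mass on the consensus base (rest spread evenly).
#' @return A `nucarch_pwm`.
#' @export
consensus_pwm <- function(motif_id, consensus, conc = 0.91) {
  b <- match(strsplit(toupper(consensus), "")[[1]], BASES)
  stopifnot(!any(is.na(b)))
  m <- matrix((1 - conc) / 3, nrow = length(b), ncol = 4)
  m[cbind(seq_along(b), b)] <- conc
  pwm(motif_id, m, pseudocount = 0)
}

pwm_revcomp <- function(p) {
  m <- p$mat[rev(seq_len(p$length)), rev(seq_len(4)), drop = FALSE]
  colnames(m) <- BASES
  structure(list(motif_id = p$motif_id, mat = m, length = p$length),
            class = "nucarch_pwm")
}

encode_seq <- function(s) match(strsplit(s, "")[[1]], BASES)

#' Write / read PWMs in minimal MEME-like text
#'
#' A plain-text exchange format: a version header, alphabet line, and per
#' motif a `MOTIF <id>` line followed by a `letter-probability matrix:` line
#' and L rows of 4 probabilities.
#'
#' @param pwms Named list of `nucarch_pwm`.
#' @param path File path.
#' @return `read_meme()` returns a named list of `nucarch_pwm` (pseudocount
#'   applied at load); `write_meme()` returns `path` invisibly.
#' @export
write_meme <- function(pwms, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  for (p in pwms) {
    lines <- c(lines, paste("MOTIF", p$motif_id),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       p$length),
               apply(p$mat, 1, function(r) paste(sprintf("%.6f", r),
                                                 collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme
#' @param pseudocount Pseudocount applied on load.
#' @export
read_meme <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1
      while (j <= length(lines) && !grepl("letter-probability", lines[j])) j <- j + 1
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1):(j + w)]
      m <- do.call(rbind, lapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
      out[[id]] <- pwm(id, m, pseudocount)
      i <- j + w + 1
    } else i <- i + 1
  }
  out
}

#' Extract promoter sequences
#'
#' The promoter of a gene is up to `window` bp upstream of its translation
#' start, truncated where a neighboring ORF overlaps the region, and
#' returned 5' to 3' (reverse-complemented for minus-strand genes).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param genes Gene tibble.
#' @param window Upstream window (default 1000 bp).
#' @return Tibble: `gene_id`, `chrom`, `start`, `end` (genomic, 0-based
#'   half-open), `strand`, `seq`.
#' @export
promoter_sequences <- function(genome, genes, window = 1000L) {
  purrr::pmap_dfr(genes, function(gene_id, chrom, strand, cds_start, cds_end,
                                  ...) {
    L <- nchar(genome[[chrom]])
    others <- genes[genes$gene_id != gene_id & genes$chrom == chrom, ]
    if (strand == "+") {
      rs <- max(0L, cds_start - window); re <- cds_start
      ov <- others[others$cds_start < re & others$cds_end > rs, ]
      if (nrow(ov)) rs <- max(c(rs, pmin(ov$cds_end, re)))
    } else {
      rs <- cds_end; re <- min(L, cds_end + window)
      ov <- others[others$cds_start < re & others$cds_end > rs, ]
      if (nrow(ov)) re <- min(c(re, pmax(ov$cds_start, rs)))
    }
    if (re <= rs) {
      return(tibble(gene_id = gene_id, chrom = chrom, start = rs, end = rs,
                    strand = strand, seq = ""))
    }
    sq <- substring(genome[[chrom]], rs + 1L, re)
    if (strand == "-") sq <- revcomp_chr(sq)
    tibble(gene_id = gene_id, chrom = chrom, start = rs, end = re,
           strand = strand, seq = sq)
  })
}

#' Estimate a Markov background model from promoter sequences
#'
#' Transition probabilities of order `order` (plus the ramp-up marginals of
#' orders 0..order-1) with add-one smoothing, estimated from the
#' concatenated promoter set of a species.
#'
#' @param seqs Character vector of sequences.
#' @param order Markov order (default 3).
#' @return A `nucarch_markov_bg` object (list of log-probability arrays).
#' @export
markov_background <- function(seqs, order = 3L) {
  seqs <- seqs[nchar(seqs) > 0]
  if (!length(seqs)) abort("no sequences for background estimation.")
  logp <- vector("list", order + 1)
  for (o in 0:order) {
    counts <- rep(1, 4^(o + 1))           # add-one smoothing
    for (s in seqs) {
      code <- encode_seq(s)
      n <- length(code)
      if (n < o + 1) next
      # index of (o+1)-mer ending at position i
      idx <- code[(o + 1):n] - 1L
      if (o > 0) for (d in 1:o) idx <- idx + (code[(o + 1 - d):(n - d)] - 1L) * 4^d
      tb <- tabulate(idx + 1L, nbins = 4^(o + 1))
      counts <- counts + tb
    }
    arr <- array(counts, dim = rep(4, o + 1))
    # normalize over the last (emitted) base given the context
    if (o == 0) {
      arr <- arr / sum(arr)
    } else {
      m <- matrix(counts, nrow = 4)       # rows = emitted base, cols = context
      m <- sweep(m, 2, colSums(m), "/")
      arr <- array(m, dim = rep(4, o + 1))
    }
    logp[[o + 1]] <- log(arr)
  }
  structure(list(order = order, logp = logp), class = "nucarch_markov_bg")
}

# log background likelihood of every window of length L in coded sequence,
# with within-window order ramp-up (first base order 0, second order 1, ...)
window_bg_loglik <- function(code, L, bg) {
  n <- length(code)
  if (n < L) return(numeric(0))
  ks <- 1:(n - L + 1)
  ll <- numeric(length(ks))
  for (j in 1:L) {
    o <- min(j - 1, bg$order)
    pos <- ks + j - 1
    idx <- code[pos]
    if (o == 0) {
      ll <- ll + bg$logp[[1]][idx]
    } else {
      lin <- idx - 1L
      for (d in 1:o) lin <- lin + (code[pos - d] - 1L) * 4^d
      ll <- ll + bg$logp[[o + 1]][lin + 1L]
    }
  }
  ll
}

window_pwm_loglik <- function(code, p) {
  L <- p$length
  n <- length(code)
  if (n < L) return(numeric(0))
  lp <- log(p$mat)
  ks <- 1:(n - L + 1)
  ll <- numeric(length(ks))
  for (j in 1:L) ll <- ll + lp[j, code[ks + j - 1]]
  ll
}

# exact (enumeration) or Monte Carlo null distribution of the LLR under bg;
# returns function(q) = P(LLR >= q)
llr_null_tail <- function(p, bg, exact_max_len = 10L, mc_n = 2e5,
                          mc_seed = 1L) {
  L <- p$length
  if (L <= exact_max_len) {
    combos <- as.matrix(expand.grid(rep(list(1:4), L)))
    lp <- log(p$mat)
    lb0 <- numeric(nrow(combos)); lpw <- numeric(nrow(combos))
    for (j in 1:L) {
      o <- min(j - 1, bg$order)
      idx <- combos[, j]
      if (o == 0) lb0 <- lb0 + bg$logp[[1]][idx]
      else {
        lin <- idx - 1L
        for (d in 1:o) lin <- lin + (combos[, j - d] - 1L) * 4^d
        lb0 <- lb0 + bg$logp[[o + 1]][lin + 1L]
      }
      lpw <- lpw + lp[j, idx]
    }
    llr <- lpw - lb0
    prob <- exp(lb0)
    o2 <- order(llr)
    lsort <- llr[o2]; csum <- cumsum(prob[o2])
    tot <- sum(prob)
    function(q) {
      pos <- findInterval(q - 1e-12, lsort)
      pmin(pmax(tot - ifelse(pos > 0, csum[pmax(pos, 1)] * (pos > 0), 0), 0), 1)
    }
  } else {
    sims <- withr::with_seed(mc_seed, {
      m <- matrix(0L, nrow = mc_n, ncol = L)
      for (j in 1:L) {
        o <- min(j - 1, bg$order)
        if (o == 0) {
          m[, j] <- sample(1:4, mc_n, replace = TRUE, prob = exp(bg$logp[[1]]))
        } else {
          lin <- m[, j - 1] - 1L
          if (o > 1) for (d in 2:o) lin <- lin + (m[, j - d] - 1L) * 4^(d - 1)
          # draw conditional on context
          probs <- exp(matrix(bg$logp[[o + 1]], nrow = 4))
          u <- runif(mc_n)
          cp <- apply(probs, 2, cumsum)
          m[, j] <- vapply(seq_len(mc_n), function(i) {
            sum(u[i] > cp[, lin[i] + 1L]) + 1L
          }, integer(1))
        }
      }
      m
    })
    lp <- log(p$mat)
    lpw <- numeric(mc_n); lb0 <- numeric(mc_n)
    for (j in 1:L) {
      o <- min(j - 1, bg$order)
      idx <- sims[, j]
      if (o == 0) lb0 <- lb0 + bg$logp[[1]][idx]
      else {
        lin <- idx - 1L
        for (d in 1:o) lin <- lin + (sims[, j - d] - 1L) * 4^d
        lb0 <- lb0 + bg$logp[[o + 1]][lin + 1L]
      }
      lpw <- lpw + lp[j, idx]
    }
    null_llr <- sort(lpw - lb0)
    function(q) {
      pos <- findInterval(q - 1e-12, null_llr)
      (1 + (mc_n - pos)) / (mc_n + 1)
    }
  }
}

#' Scan promoters for significant motif instances
#'
#' Scores every window of every promoter (both strands) by the
#' log-likelihood ratio of the PWM against a Markov background model of
#' order `bg_order` estimated from the full promoter set. Per-site p-values
#' are the probability of an equal-or-higher score under the background
#' model, computed by exact enumeration of the score distribution for short
#' motifs and by fixed-seed Monte Carlo for long ones. Sites with
#' `p < p_thresh` are kept; if more than `max_promoters` promoters carry
#' hits, only the `max_promoters` promoters with the best (smallest) site
#' p-value are retained. The best site per promoter is flagged so both the
#' "all significant sites" and "best site per promoter" views are available.
#'
#' @param p A `nucarch_pwm`.
#' @param promoters Output of [promoter_sequences()].
#' @param bg Optional precomputed [markov_background()]; estimated from
#'   `promoters` when `NULL`.
#' @param bg_order Background Markov order (default 3).
#' @param p_thresh Significance threshold (default 0.05).
#' @param max_promoters Promoter cap (default 1000).
#' @param mc_seed Seed for the Monte Carlo null when enumeration is
#'   infeasible.
#' @return Tibble of instances: `motif_id`, `gene_id`, `chrom`, `start`,
#'   `end` (genomic), `strand` (site strand in genome coordinates), `score`
#'   (LLR), `p_value`, `best_in_promoter`.
#' @export
scan_promoters <- function(p, promoters, bg = NULL, bg_order = 3L,
                           p_thresh = 0.05, max_promoters = 1000L,
                           mc_seed = 1L) {
  if (is.null(bg)) bg <- markov_background(promoters$seq, bg_order)
  prc <- pwm_revcomp(p)
  tail_f <- llr_null_tail(p, bg, mc_seed = mc_seed)
  tail_r <- llr_null_tail(prc, bg, mc_seed = mc_seed)
  n_short <- 0L
  hits <- purrr::map_dfr(seq_len(nrow(promoters)), function(i) {
    pr <- promoters[i, ]
    if (nchar(pr$seq) < p$length) { n_short <<- n_short + 1L; return(NULL) }
    code <- encode_seq(pr$seq)
    lb <- window_bg_loglik(code, p$length, bg)
    sf <- window_pwm_loglik(code, p) - lb
    sr <- window_pwm_loglik(code, prc) - lb
    pf <- tail_f(sf); pr_ <- tail_r(sr)
    ks <- seq_along(sf)
    d <- bind_rows(
      tibble(k = ks, score = sf, p_value = pf, match_rc = FALSE),
      tibble(k = ks, score = sr, p_value = pr_, match_rc = TRUE)
    ) %>% filter(.data$p_value < p_thresh)
    if (nrow(d) == 0) return(NULL)
    # promoter offset k (1-based, 5'->3') to genomic coordinates
    if (pr$strand == "+") {
      gs <- pr$start + d$k - 1L
      strand_site <- ifelse(d$match_rc, "-", "+")
    } else {
      gs <- pr$end - (d$k - 1L) - p$length
      strand_site <- ifelse(d$match_rc, "+", "-")
    }
    tibble(motif_id = p$motif_id, gene_id = pr$gene_id, chrom = pr$chrom,
           start = gs, end = gs + p$length, strand = strand_site,
           score = d$score, p_value = d$p_value)
  })
  if (n_short > 0)
    warn(sprintf("%d promoters shorter than the motif were skipped.", n_short))
  if (nrow(hits) == 0) return(bind_cols(hits, tibble(best_in_promoter = logical(0))))
  best <- hits %>% group_by(.data$gene_id) %>%
    summarise(best_p = min(.data$p_value), .groups = "drop") %>%
    arrange(.data$best_p)
  if (nrow(best) > max_promoters) {
    keep_genes <- best$gene_id[seq_len(max_promoters)]
    hits <- hits[hits$gene_id %in% keep_genes, ]
  }
  hits %>% group_by(.data$gene_id) %>%
    mutate(best_in_promoter = rank(.data$p_value, ties.method = "first") == 1L) %>%
    ungroup()
}

#' Motif affinity score of an NFR sequence
#'
#' `A(P, S)`: the sum over all allowable window positions of the product of
#' per-base PWM-to-background probability ratios, accumulated over both
#' strands. Sequences shorter than the motif score 0. Larger values mean
#' the NFR sequence is a better match for the factor.
#'
#' @param p A `nucarch_pwm`.
#' @param nfr_sequence Character sequence of the NFR.
#' @param bg0 Length-4 vector of 0-order background base frequencies
#'   (typically promoter base frequencies; must be positive).
#' @return Scalar affinity.
#' @export
nfr_affinity <- function(p, nfr_sequence, bg0) {
  if (any(bg0 <= 0)) abort("background frequencies must be positive.")
  bg0 <- bg0 / sum(bg0)
  if (nchar(nfr_sequence) < p$length) return(0)
  code <- encode_seq(nfr_sequence)
  lb <- log(bg0)
  one <- function(pp) {
    lr <- log(pp$mat) - matrix(lb, nrow = pp$length, ncol = 4, byrow = TRUE)
    L <- pp$length
    ks <- 1:(length(code) - L + 1)
    ll <- numeric(length(ks))
    for (j in 1:L) ll <- ll + lr[j, code[ks + j - 1]]
    sum(exp(ll))
  }
  one(p) + one(pwm_revcomp(p))
}

#' Resolve per-gene promoter regions for motif binning
#'
#' Five disjoint regions per gene: the footprints of Nuc+1, Nuc-1 and Nuc-2
#' (dyad +/- 73 bp), the 5' NFR, and NFR2 (the linker between the Nuc-1 and
#' Nuc-2 footprints).
#'
#' @param calls Calls with occupancy.
#' @param nfrs [find_nfrs()] output.
#' @param genes Gene tibble.
#' @param occ_floor Call retention floor (as elsewhere).
#' @return Tibble: `gene_id`, `region`, `start`, `end`.
#' @export
gene_promoter_regions <- function(calls, nfrs, genes, occ_floor = 0.4) {
  ret <- retain_calls(calls, occ_floor)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, ]
    n5 <- nfrs[nfrs$gene_id == gene$gene_id & nfrs$side == "5", ]
    n3 <- nfrs[nfrs$gene_id == gene$gene_id & nfrs$side == "3", ]
    if (!nrow(n5) || !nrow(n3)) return(NULL)
    ctx <- gene_call_context(ret, gene, n5, n3)
    fp <- function(idx) {
      if (!length(idx) || is.na(idx[1])) return(NULL)
      d <- ctx$calls$dyad[idx[1]]
      c(d - 73L, d + 74L)
    }
    p1 <- fp(ctx$plus); m1 <- fp(ctx$minus); m2 <- fp(ctx$minus[-1])
    rows <- list(tibble(region = "5'NFR", start = n5$start, end = n5$end))
    if (!is.null(p1)) rows <- c(rows, list(tibble(region = "Nuc+1", start = p1[1], end = p1[2])))
    if (!is.null(m1)) rows <- c(rows, list(tibble(region = "Nuc-1", start = m1[1], end = m1[2])))
    if (!is.null(m2)) rows <- c(rows, list(tibble(region = "Nuc-2", start = m2[1], end = m2[2])))
    if (!is.null(m1) && !is.null(m2)) {
      s <- min(m1[1], m2[1]); e <- max(m1[2], m2[2])
      inner <- sort(c(m1, m2))[2:3]       # gap between the two footprints
      if (inner[2] > inner[1])
        rows <- c(rows, list(tibble(region = "NFR2", start = inner[1],
                                    end = inner[2])))
    }
    bind_cols(tibble(gene_id = gene$gene_id), bind_rows(rows))
  })
}

#' Bin motif instances into promoter chromatin regions
#'
#' Assigns each instance the region containing its center (Nuc+1, 5'NFR,
#' Nuc-1, Nuc-2, NFR2, else "outside") within its own gene's coordinate
#' frame, plus the coarser `linker_class`: Linkers (5'NFR, NFR2), Nucs
#' (Nuc+1, Nuc-1, Nuc-2) or outside. Instances of genes without resolved
#' regions are labeled outside and flagged.
#'
#' @param instances [scan_promoters()] output.
#' @param regions [gene_promoter_regions()] output.
#' @return `instances` plus `region`, `linker_class`, `regions_resolved`.
#' @export
bin_motif_instances <- function(instances, regions) {
  center <- (instances$start + instances$end - 1L) %/% 2L
  reg <- character(nrow(instances)); resolved <- logical(nrow(instances))
  for (i in seq_len(nrow(instances))) {
    r <- regions[regions$gene_id == instances$gene_id[i], ]
    resolved[i] <- nrow(r) > 0
    hit <- which(r$start <= center[i] & center[i] < r$end)
    reg[i] <- if (length(hit)) r$region[hit[1]] else "outside"
  }
  instances %>%
    mutate(region = reg,
           linker_class = case_when(
             reg %in% c("5'NFR", "NFR2") ~ "Linkers",
             reg %in% c("Nuc+1", "Nuc-1", "Nuc-2") ~ "Nucs",
             TRUE ~ "outside"),
           regions_resolved = resolved)
}

#' Motif-by-species NFR fractions with per-species z-scores
#'
#' For each motif and species, the fraction of binned instances falling in
#' Linkers among those in Linkers or Nucs (the all-instances denominator is
#' emitted alongside as `fraction_all`); fractions are then z-scored within
#' each species across motifs so species with globally wider NFRs remain
#' comparable.
#'
#' @param binned Binned instances with a `species_id` column.
#' @return Tibble: `species_id`, `motif_id`, `n_linkers`, `n_nucs`,
#'   `fraction`, `fraction_all`, `zscore`.
#' @export
nfr_fraction_matrix <- function(binned) {
  d <- binned %>%
    group_by(.data$species_id, .data$motif_id) %>%
    summarise(n_linkers = sum(.data$linker_class == "Linkers"),
              n_nucs = sum(.data$linker_class == "Nucs"),
              n_total = n(), .groups = "drop") %>%
    mutate(fraction = if_else(.data$n_linkers + .data$n_nucs > 0,
                              .data$n_linkers / (.data$n_linkers + .data$n_nucs),
                              NA_real_),
           fraction_all = .data$n_linkers / .data$n_total)
  d %>% group_by(.data$species_id) %>%
    mutate(zscore = (.data$fraction - mean(.data$fraction, na.rm = TRUE)) /
             sd(.data$fraction, na.rm = TRUE)) %>%
    ungroup()
}

#' Activator/repressor inference from linker-versus-nucleosome expression
#'
#' Each site inherits its gene's expression level; per motif, a signed
#' two-sample K-S test compares expression at Linkers sites versus Nucs
#' sites. A positive score (linker sites in higher-expressed genes) is
#' activator-like; negative is repressor-like. A gene-level deduplicated
#' variant (one value per gene per class) is emitted alongside to expose the
#' site-level pseudo-replication.
#'
#' @param binned Binned instances (one or more motifs).
#' @param expression Tibble `gene_id`, `expression`.
#' @param min_sites Minimum sites per class for a call (default 10).
#' @return Tibble per motif: class counts, mean expression per class,
#'   `K_KS`, `P_KS`, `S_KS`, gene-level `S_KS_gene`, and `call`
#'   (`"activator-like"`, `"repressor-like"`, or `NA` for no-call).
#' @export
linker_vs_nuc_expression <- function(binned, expression, min_sites = 10L) {
  d <- binned %>%
    filter(.data$linker_class %in% c("Linkers", "Nucs")) %>%
    left_join(expression, by = "gene_id")
  purrr::map_dfr(unique(d$motif_id), function(mid) {
    x <- d[d$motif_id == mid, ]
    lv <- x$expression[x$linker_class == "Linkers"]
    nv <- x$expression[x$linker_class == "Nucs"]
    gl <- x %>% distinct(.data$gene_id, .data$linker_class, .data$expression)
    lvg <- gl$expression[gl$linker_class == "Linkers"]
    nvg <- gl$expression[gl$linker_class == "Nucs"]
    if (length(lv) < min_sites || length(nv) < min_sites) {
      return(tibble(motif_id = mid, n_linker_sites = length(lv),
                    n_nuc_sites = length(nv),
                    mean_expr_linkers = mean(lv), mean_expr_nucs = mean(nv),
                    K_KS = NA_real_, P_KS = NA_real_, S_KS = NA_real_,
                    S_KS_gene = NA_real_, call = NA_character_))
    }
    ks <- ks_enrichment(lv, nv)
    ksg <- ks_enrichment(lvg, nvg)
    tibble(motif_id = mid, n_linker_sites = length(lv),
           n_nuc_sites = length(nv),
           mean_expr_linkers = mean(lv), mean_expr_nucs = mean(nv),
           K_KS = ks$K_KS, P_KS = ks$P_KS, S_KS = ks$S_KS,
           S_KS_gene = ksg$S_KS,
           call = if_else(ks$S_KS >= 0, "activator-like", "repressor-like"))
  })
}

#' Motif preference for nucleosome-depleted sequence
#'
#' Pairs, per site, the mean log2 occupancy over the site footprint (x)
#' with the mean log2 occupancy over that site's whole promoter (y), and
#' tests the paired differences with the Wilcoxon signed-rank test
#' (two-sided; exact for 25 or fewer informative pairs). Small P with x < y
#' means the motif sits in locally depleted sequence.
#'
#' @param instances Motif instances (with `gene_id`).
#' @param track Occupancy `nucarch_track`.
#' @param promoters [promoter_sequences()] output (for promoter intervals).
#' @param pseudocount Added before log2.
#' @param min_pairs No-call below this many complete pairs (default 5).
#' @return Tibble per motif: `n_pairs`, `mean_site_log2`,
#'   `mean_promoter_log2`, `p_value`.
#' @export
motif_depletion_preference <- function(instances, track, promoters,
                                       pseudocount = 0.01, min_pairs = 5L) {
  pr <- promoters %>% select("gene_id", prom_start = "start",
                             prom_end = "end", prom_chrom = "chrom")
  d <- instances %>% left_join(pr, by = "gene_id")
  d$x <- purrr::pmap_dbl(list(d$chrom, d$start, d$end), function(cn, s, e) {
    v <- track_window_mean(track, cn, s, e)
    if (is.na(v)) NA_real_ else log2(v + pseudocount)
  })
  d$y <- purrr::pmap_dbl(list(d$prom_chrom, d$prom_start, d$prom_end),
                         function(cn, s, e) {
    v <- track_window_mean(track, cn, s, e)
    if (is.na(v)) NA_real_ else log2(v + pseudocount)
  })
  purrr::map_dfr(unique(d$motif_id), function(mid) {
    x <- d$x[d$motif_id == mid]; y <- d$y[d$motif_id == mid]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < min_pairs) {
      return(tibble(motif_id = mid, n_pairs = n,
                    mean_site_log2 = mean(x), mean_promoter_log2 = mean(y),
                    p_value = NA_real_))
    }
    dd <- x - y
    pv <- if (all(dd == 0)) 1 else
      suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                   exact = sum(dd != 0) <= 25)$p.value)
    tibble(motif_id = mid, n_pairs = n, mean_site_log2 = mean(x),
           mean_promoter_log2 = mean(y), p_value = pv)
  })
}
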