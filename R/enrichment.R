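ks_asymptotic_p <- function(K, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * K
  if (lambda < 1e-3) return(1)    # series is numerically useless at lambda ~ 0
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, .Machine$double.xmin), 1)
}

#' Signed two-sample Kolmogorov-Smirnov enrichment
#'
#' Quantifies how a gene set's values differ from the background (all other
#' genes). `K_KS` is the maximum absolute difference between the two
#' empirical CDFs evaluated at the pooled sample points; `P_KS` comes from
#' the asymptotic two-sample Smirnov distribution with effective sample size
#' n1*n2/(n1+n2); and the signed score `S_KS = +/- log10(P_KS)` is positive
#' when the set's values are shifted high (its CDF lies below the
#' background's at the argmax) and negative when shifted low, with
#' `|S_KS| = -log10(P_KS)`.
#'
#' @param values_in_set,values_background Numeric vectors; `NA`s are dropped.
#' @return One-row tibble: `n_set`, `n_bg`, `K_KS`, `P_KS`, `S_KS`.
#' @export
ks_enrichment <- function(values_in_set, values_background) {
  x <- values_in_set[!is.na(values_in_set)]
  y <- values_background[!is.na(values_background)]
  if (length(x) == 0 || length(y) == 0) {
    return(tibble(n_set = length(x), n_bg = length(y), K_KS = NA_real_,
                  P_KS = NA_real_, S_KS = NA_real_))
  }
  pts <- sort(unique(c(x, y)))
  Fx <- findInterval(pts, sort(x)) / length(x)   # right-continuous ECDFs
  Fy <- findInterval(pts, sort(y)) / length(y)
  d <- Fx - Fy
  i <- which.max(abs(d))
  K <- abs(d[i])
  p <- ks_asymptotic_p(K, length(x), length(y))
  dir <- if (d[i] < 0) 1 else -1                 # set CDF below => set high
  tibble(n_set = length(x), n_bg = length(y), K_KS = K, P_KS = p,
         S_KS = dir * (-log10(p)))
}

#' K-S enrichment of features across gene sets
#'
#' For every (feature, set) pair, runs [ks_enrichment()] of the set members'
#' values against all other genes, then controls the FDR per feature across
#' sets with Benjamini-Hochberg. Sets with fewer than `min_size` members that
#' have a value are skipped.
#'
#' @param data Tibble with a `gene_id` column and one column per feature.
#' @param sets Tibble `set_id`, `gene_id`.
#' @param features Feature column names (default: all non-`gene_id` columns).
#' @param min_size Minimum set size (default 10).
#' @param q FDR level (default 0.05).
#' @return Long tibble: `feature_id`, `set_id`, `n_set`, `n_bg`, `K_KS`,
#'   `P_KS`, `S_KS`, `significant`.
#' @export
ks_enrichment_table <- function(data, sets, features = NULL, min_size = 10L,
                                q = 0.05) {
  if (is.null(features)) features <- setdiff(names(data), "gene_id")
  out <- purrr::map_dfr(features, function(f) {
    v <- data[[f]]
    ok <- !is.na(v)
    rows <- purrr::map_dfr(unique(sets$set_id), function(sid) {
      members <- data$gene_id %in% sets$gene_id[sets$set_id == sid]
      if (sum(members & ok) < min_size) {
        return(tibble(set_id = sid, n_set = sum(members & ok),
                      n_bg = sum(!members & ok), K_KS = NA_real_,
                      P_KS = NA_real_, S_KS = NA_real_))
      }
      bind_cols(tibble(set_id = sid),
                ks_enrichment(v[members], v[!members]))
    })
    rows$significant <- bh_fdr(rows$P_KS, q)$significant
    bind_cols(tibble(feature_id = f), rows)
  })
  out
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`; returns per-test significance flags and
#' the largest rejected raw p-value (the effective threshold). `NA`
#' p-values are never rejected.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List: `significant` (logical vector), `threshold` (largest
#'   rejected raw p, or `NA` if nothing is rejected).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  adj <- p.adjust(pvalues, method = "BH")
  sig <- !is.na(adj) & adj <= q
  list(significant = sig,
       threshold = if (any(sig)) max(pvalues[sig]) else NA_real_)
}

#' Right-tail hypergeometric overlap p-value
#'
#' Probability that `k` or more elements intersect random subsets of sizes
#' `n` and `m` drawn from a superset of `N` elements — the standard overlap
#' test for, e.g., genes with a motif against a functional category.
#'
#' @param N Superset size. @param n,m Subset sizes. @param k Observed overlap.
#' @return `P_HG` in (0, 1\].
#' @export
hypergeom_right_tail <- function(N, n, m, k) {
  if (k < 0 || k > min(n, m) || n > N || m > N)
    abort("infeasible overlap configuration.")
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Project gene sets onto another species through an orthology table
#'
#' Maps each member of each reference set through its orthogroup to the
#' target species and unions the hits (one-to-many orthologs all enter the
#' projected set; members with no ortholog are dropped). Sets smaller than
#' `min_size` after projection are flagged `skip` so enrichment scans ignore
#' them.
#'
#' @param sets Tibble `set_id`, `gene_id` on the reference species.
#' @param orthology Tibble `orthogroup`, `species_id`, `gene_id`.
#' @param species_id Target species id.
#' @param min_size Minimum projected set size (default 10).
#' @return Tibble `set_id`, `gene_id`, `set_size`, `skip`.
#' @export
project_gene_sets <- function(sets, orthology, species_id, min_size = 10L) {
  if (!species_id %in% orthology$species_id)
    abort(sprintf("species '%s' not in orthology table.", species_id))
  ref <- orthology[, c("orthogroup", "gene_id")]
  tgt <- orthology[orthology$species_id == species_id,
                   c("orthogroup", "gene_id")]
  names(tgt)[2] <- "target_gene"
  proj <- sets %>%
    inner_join(ref, by = "gene_id") %>%
    inner_join(tgt, by = "orthogroup", relationship = "many-to-many") %>%
    distinct(.data$set_id, .data$target_gene) %>%
    rename(gene_id = "target_gene") %>%
    group_by(.data$set_id) %>%
    mutate(set_size = n(), skip = n() < min_size) %>%
    ungroup()
  proj
}
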