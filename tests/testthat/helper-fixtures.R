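# Shared synthetic dataset built once per test run. The configuration is the
# package's reference study condition: 60 genes (20 per regulatory class),
# nucleosome spacing 165 bp, coverage 30 fragments per dyad, fragments
# 147 +/- 8 bp with 10 bp positional jitter.
.fx_env <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (!is.null(.fx_env$fx)) return(.fx_env$fx)
  cfg <- species_config(gene_class = rep(c("growth", "stress", "neutral"),
                                         each = 20))
  tr <- simulate_species(cfg, seed = 101)
  rd <- simulate_reads(tr, coverage = 30, frag_len_mean = 147,
                       frag_len_sd = 8, jitter_sd = 10, seed = 102)
  gl <- c(chr1 = nchar(tr$genome[["chr1"]]))
  trk <- occupancy_track(rd, gl)
  calls <- attach_occupancy(call_nucleosomes(rd, gl, frag_len = 147), trk)
  nfrs <- find_nfrs(calls, trk, tr$genes)
  ex <- simulate_expression(tr, seed = 103)
  .fx_env$fx <- list(truth = tr, reads = rd, glen = gl, track = trk,
                     calls = calls, nfrs = nfrs, expr = ex)
  .fx_env$fx
}

# hand-built track object for closed-form tests
make_track <- function(values, mask = NULL, chrom = "chr1", kind = "occupancy") {
  if (is.null(mask)) mask <- rep(FALSE, length(values))
  v <- values; v[mask] <- NA_real_
  structure(setNames(list(list(values = v, mask = mask)), chrom),
            class = "nucarch_track", kind = kind,
            genome_lengths = setNames(length(values), chrom))
}

make_calls <- function(dyads, occupancy = 1, chrom = "chr1") {
  tibble::tibble(chrom = chrom, dyad = as.integer(dyads),
                 peak_height = 1, fuzziness = 0, width = 147,
                 occupancy = rep_len(occupancy, length(dyads)))
}

rc <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAStringSet(x)))

# --- independent oracles -----------------------------------------------------

# exhaustive greedy oracle: given candidate peaks (dyad, height), accept in
# order of decreasing height (ties: leftmost) unless within min_dist of an
# accepted dyad
greedy_oracle <- function(dyads, heights, min_dist = 127) {
  ord <- order(-heights, dyads)
  acc <- integer(0)
  for (i in ord) {
    if (!length(acc) || all(abs(acc - dyads[i]) >= min_dist))
      acc <- c(acc, dyads[i])
  }
  sort(acc)
}

# exact two-sample K-S permutation p-value by full enumeration
ks_perm_p <- function(x, y) {
  ks_stat <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(findInterval(pts, sort(a)) / length(a) -
              findInterval(pts, sort(b)) / length(b)))
  }
  obs <- ks_stat(x, y)
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  stats <- apply(idx, 2, function(ii) ks_stat(pool[ii], pool[-ii]))
  mean(stats >= obs - 1e-12)
}

# brute-force maximal Poly tract oracle on a short string
tract_oracle <- function(s, base, k, min_len = 5) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  cand <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (ch[i] != base || ch[j] != base) next
    mm <- sum(ch[i:j] != base)
    if (mm <= k && (j - i + 1) >= min_len) cand[[length(cand) + 1]] <- c(i, j)
  }
  if (!length(cand)) return(tibble::tibble(start = integer(), end = integer()))
  m <- do.call(rbind, cand)
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, 1] <= m[r, 1] & m[, 2] >= m[r, 2] &
           (m[, 1] != m[r, 1] | m[, 2] != m[r, 2]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  tibble::tibble(start = m[, 1] - 1L, end = m[, 2])
}

# brute-force k-mer multiplicity (both strands, revcomp-merged) per position
kmer_unique_oracle <- function(genome, k) {
  lapply(genome, function(s) {
    L <- nchar(s)
    if (L < k) return(rep(TRUE, L))
    starts <- 1:(L - k + 1)
    kms <- substring(s, starts, starts + k - 1)
    all_counts <- table(unlist(lapply(genome, function(g) {
      Lg <- nchar(g)
      if (Lg < k) return(character(0))
      km <- substring(g, 1:(Lg - k + 1), k:Lg)
      pmin(km, rc(km))
    })))
    uniq <- all_counts[pmin(kms, rc(kms))] == 1
    masked <- vapply(1:L, function(p) {
      cover <- starts[starts <= p & starts + k - 1 >= p]
      if (!length(cover)) return(TRUE)
      !any(uniq[cover])
    }, logical(1))
    masked
  })
}
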