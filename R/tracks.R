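#' Mappability mask from k-mer uniqueness
#'
#' A base is masked (excluded) when every k-mer covering it occurs more than
#' once in the genome, counting a k-mer and its reverse complement as the same
#' class — i.e. the base cannot be uniquely located by a read of length `k`.
#' Bases not covered by any full k-mer (chromosome shorter than `k`) are
#' masked.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param k Read length in bp (default 36).
#' @return Named list of logical vectors, `TRUE` = masked.
#' @export
mappability_mask <- function(genome, k = 36L) {
  if (length(genome) == 0 || all(nchar(genome) == 0)) abort("empty genome.")
  stopifnot(k >= 1)
  per_chrom <- lapply(genome, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  })
  all_kmers <- unlist(per_chrom, use.names = FALSE)
  keys <- pmin(all_kmers, revcomp_chr(all_kmers))
  uk <- unique(keys)
  cnt <- tabulate(match(keys, uk), nbins = length(uk))
  pos_cnt <- cnt[match(keys, uk)]
  off <- 0L
  out <- lapply(per_chrom, function(km) {
    L <- if (length(km)) length(km) + k - 1L else NA_integer_
    if (!length(km)) return(logical(0))
    uniq <- as.integer(pos_cnt[(off + 1L):(off + length(km))] == 1L)
    off <<- off + length(km)
    S <- length(km)
    cs <- c(0L, cumsum(uniq))
    p <- seq_len(L)
    lo <- pmax(1L, p - k + 1L); hi <- pmin(p, S)
    covered <- hi >= lo & (cs[hi + 1L] - cs[lo]) > 0L
    !covered
  })
  # chromosomes shorter than k: fully masked
  purrr::imap(out, function(m, nm) {
    L <- nchar(genome[[nm]])
    if (length(m) == 0) rep(TRUE, L) else m
  })
}

chrom_coverage <- function(starts, ends, L) {
  # 0-based half-open intervals, clipped; returns per-base counts (index = base+1)
  s <- pmax(starts, 0L); e <- pmin(ends, L)
  ok <- e > s
  d <- numeric(L + 1L)
  if (any(ok)) {
    ta <- tabulate(s[ok] + 1L, nbins = L)
    tb <- tabulate(e[ok] + 1L, nbins = L + 1L)
    d[seq_len(L)] <- ta
    d <- d - tb
  }
  cumsum(d[seq_len(L)])
}

#' Build a normalized per-base nucleosome occupancy track
#'
#' Each read is extended to `extension` bp from its 5' end (plus-strand reads
#' cover `[start, start+extension)`; minus-strand reads cover
#' `[end-extension, end)` with `end = start + read_length`), extended
#' intervals are clipped at chromosome bounds and summed per base. Bases whose
#' raw coverage exceeds `outlier_multiplier` times the median raw coverage
#' over unmasked bases are added to the mask (single pass), and the remaining
#' values are divided by their mean so that unmasked occupancy averages 1.
#'
#' @param reads Tibble with `chrom`, `start` (0-based), `strand`,
#'   `read_length`.
#' @param genome_lengths Named integer vector of chromosome lengths.
#' @param extension Extension length in bp (default 100).
#' @param outlier_multiplier Outlier threshold as a multiple of the median
#'   (default 10).
#' @param mappability Optional mask from [mappability_mask()].
#' @return A `nucarch_track` object: per chromosome, `values` (normalized
#'   occupancy, `NA` at masked bases) and `mask` (logical, `TRUE` = masked).
#' @export
occupancy_track <- function(reads, genome_lengths, extension = 100L,
                            outlier_multiplier = 10, mappability = NULL) {
  if (nrow(reads) == 0) abort("`reads` is empty.")
  chroms <- names(genome_lengths)
  per <- lapply(chroms, function(cn) {
    L <- genome_lengths[[cn]]
    r <- reads[reads$chrom == cn, ]
    plus <- r$strand == "+"
    s <- ifelse(plus, r$start, r$start + r$read_length - extension)
    raw <- chrom_coverage(as.integer(s), as.integer(s) + as.integer(extension), L)
    mask <- if (is.null(mappability)) rep(FALSE, L) else mappability[[cn]]
    list(raw = raw, mask = mask)
  })
  names(per) <- chroms
  unm <- unlist(lapply(per, function(x) x$raw[!x$mask]))
  if (!length(unm)) abort("normalization failed: every base is masked.")
  med <- median(unm)
  per <- lapply(per, function(x) {
    x$mask <- x$mask | (x$raw > outlier_multiplier * med)
    x
  })
  mu <- mean(unlist(lapply(per, function(x) x$raw[!x$mask])))
  if (!is.finite(mu) || mu <= 0)
    abort("normalization failed: zero coverage over unmasked bases.")
  per <- lapply(per, function(x) {
    v <- x$raw / mu
    v[x$mask] <- NA_real_
    list(values = v, mask = x$mask)
  })
  structure(per, class = "nucarch_track", kind = "occupancy",
            genome_lengths = genome_lengths)
}

#' Log2 z-normalized occupancy track
#'
#' Takes log2(occupancy + pseudocount) and standardizes it to mean 0,
#' variance 1 over unmasked bases, the form used for k-mer and tract
#' depletion scoring.
#'
#' @param track A `nucarch_track` from [occupancy_track()].
#' @param pseudocount Added before the log so zero-occupancy bases stay
#'   finite (> 0; default 0.01 on the normalized scale).
#' @return A `nucarch_track` with `kind = "z"`; `values` hold z-scores.
#' @export
log2_z_track <- function(track, pseudocount = 0.01) {
  stopifnot(inherits(track, "nucarch_track"), pseudocount > 0)
  z <- unlist(lapply(track, function(x) log2(x$values[!x$mask] + pseudocount)))
  mu <- mean(z); s <- sd(z)
  if (!is.finite(s) || s == 0) abort("degenerate track: zero variance.")
  per <- lapply(track, function(x) {
    v <- (log2(x$values + pseudocount) - mu) / s
    list(values = v, mask = x$mask)
  })
  structure(per, class = "nucarch_track", kind = "z",
            genome_lengths = attr(track, "genome_lengths"))
}

#' Mean track value over a 0-based half-open window
#'
#' Masked bases are excluded; returns `NA` when every base in the window is
#' masked or the window is empty after clipping.
#'
#' @param track A `nucarch_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Scalar mean (or `NA_real_`).
#' @export
track_window_mean <- function(track, chrom, start, end) {
  x <- track[[chrom]]
  if (is.null(x)) abort(sprintf("chromosome '%s' not in track.", chrom))
  L <- length(x$values)
  s <- max(0L, floor(start)); e <- min(L, ceiling(end))
  if (e <= s) return(NA_real_)
  v <- x$values[(s + 1L):e]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}
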