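#' Estimate mean fragment length by strand cross-correlation
#'
#' Plus-strand read starts and minus-strand read ends (half-open end,
#' `start + read_length`) are binned per base; the Pearson correlation
#' between the plus profile and the minus profile shifted by `s` peaks when
#' `s` equals the typical MNase-protected fragment length. In published
#' mononucleosome data this peak falls between roughly 127 and 153 bp.
#'
#' @param reads Read tibble (`chrom`, `start`, `strand`, `read_length`).
#' @param genome_lengths Named chromosome lengths.
#' @param min_shift,max_shift Searched shift range in bp.
#' @return An object of class `"fragment_length_estimate"`: `shift_bp` (the
#'   argmax), `correlation_profile` (tibble of shift vs correlation) and
#'   `peak_sd` (second-moment spread around the peak).
#' @export
estimate_fragment_length <- function(reads, genome_lengths,
                                     min_shift = 50L, max_shift = 300L) {
  by_strand <- split(reads, reads$strand)
  if (!all(c("+", "-") %in% names(by_strand)))
    abort("both strands must be represented in `reads`.")
  if (any(vapply(by_strand, nrow, 1L) < 100))
    warn("fewer than 100 reads on a strand; fragment-length estimate may be unstable.")
  chroms <- names(genome_lengths)
  vecs <- lapply(chroms, function(cn) {
    L <- genome_lengths[[cn]]
    r <- reads[reads$chrom == cn, ]
    p <- r[r$strand == "+", ]; m <- r[r$strand == "-", ]
    P <- tabulate(p$start + 1L, nbins = L + 1L)
    M <- tabulate(m$start + m$read_length + 1L, nbins = L + 1L)
    list(P = P, M = M)
  })
  shifts <- min_shift:max_shift
  profile <- vapply(shifts, function(s) {
    x <- unlist(lapply(vecs, function(v) v$P[1:(length(v$P) - s)]))
    y <- unlist(lapply(vecs, function(v) v$M[(1 + s):length(v$M)]))
    suppressWarnings(cor(x, y))
  }, numeric(1))
  profile[is.na(profile)] <- -Inf
  best <- which.max(profile)
  shift_bp <- shifts[best]
  win <- abs(shifts - shift_bp) <= 40
  w <- pmax(profile[win] - min(profile[win][is.finite(profile[win])]), 0)
  peak_sd <- if (sum(w) > 0)
    sqrt(sum(w * (shifts[win] - shift_bp)^2) / sum(w)) else NA_real_
  structure(list(shift_bp = shift_bp,
                 correlation_profile = tibble(shift = shifts,
                                              correlation = profile),
                 peak_sd = peak_sd),
            class = "fragment_length_estimate")
}

#' @export
print.fragment_length_estimate <- function(x, ...) {
  cat(sprintf("Fragment length estimate: %d bp (peak sd %.1f bp)\n",
              x$shift_bp, x$peak_sd))
  invisible(x)
}

#' @export
glance.fragment_length_estimate <- function(x, ...) {
  tibble(shift_bp = x$shift_bp, peak_sd = x$peak_sd,
         peak_correlation = max(x$correlation_profile$correlation))
}

#' @export
tidy.fragment_length_estimate <- function(x, ...) x$correlation_profile

gaussian_smooth_counts <- function(counts, kernel_sd) {
  t <- ceiling(4 * kernel_sd)          # truncate at +/- 4 sd
  kern <- dnorm(seq(-t, t), sd = kernel_sd)
  padded <- c(numeric(t), counts, numeric(t))
  sm <- stats::filter(padded, kern, sides = 2)
  as.numeric(sm[(t + 1):(t + length(counts))])
}

#' Call nucleosomes by Parzen-window smoothing with greedy selection
#'
#' Read starts are shifted by half the fragment length toward the dyad they
#' flank (plus strand: `start + floor(frag_len/2)`; minus strand: rightmost
#' base minus `floor(frag_len/2)`). A Gaussian kernel (sd `kernel_sd`,
#' truncated at 4 sd) is placed at every shifted center and summed into a
#' smoothed landscape; its local maxima are candidate dyads. Candidates are
#' accepted tallest-first (ties broken by leftmost dyad) and a candidate is
#' rejected when its `footprint` bp footprint would overlap an already
#' accepted call by more than `max_overlap` bp — i.e. accepted dyads are at
#' least `footprint - max_overlap` bp apart.
#'
#' @param reads Read tibble.
#' @param genome_lengths Named chromosome lengths.
#' @param frag_len Mean fragment length in bp (e.g. from
#'   [estimate_fragment_length()]).
#' @param kernel_sd Parzen-window sd in bp (default 30).
#' @param max_overlap Maximum footprint overlap in bp (default 20).
#' @param footprint Nucleosome footprint in bp (default 147).
#' @return Tibble of calls: `chrom`, `dyad` (0-based), `peak_height`,
#'   `fuzziness` (sd of contributing shifted centers within +/-73 bp),
#'   `width` (full width at half maximum, clipped at flanking minima) and
#'   `occupancy` (`NA` until [attach_occupancy()]).
#' @export
call_nucleosomes <- function(reads, genome_lengths, frag_len,
                             kernel_sd = 30, max_overlap = 20L,
                             footprint = 147L) {
  stopifnot(frag_len > 0, kernel_sd > 0)
  empty <- tibble(chrom = character(), dyad = integer(),
                  peak_height = numeric(), fuzziness = numeric(),
                  width = numeric(), occupancy = numeric())
  if (nrow(reads) == 0) {
    warn("no reads: returning an empty call set.")
    return(empty)
  }
  half <- as.integer(floor(frag_len / 2))
  min_dist <- footprint - max_overlap
  out <- lapply(names(genome_lengths), function(cn) {
    L <- genome_lengths[[cn]]
    r <- reads[reads$chrom == cn, ]
    if (nrow(r) == 0) return(NULL)
    centers <- ifelse(r$strand == "+",
                      r$start + half,
                      r$start + r$read_length - 1L - half)
    centers <- pmin(pmax(centers, 0L), L - 1L)
    counts <- tabulate(centers + 1L, nbins = L)
    sm <- gaussian_smooth_counts(counts, kernel_sd)
    i <- 2:(L - 1)
    is_peak <- sm[i] > sm[i - 1] & sm[i] >= sm[i + 1] & sm[i] > 0
    cand <- i[is_peak]                      # R index; dyad = cand - 1
    if (!length(cand)) return(NULL)
    ord <- order(-sm[cand], cand)
    blocked <- logical(L)
    acc <- integer(0)
    for (ci in cand[ord]) {
      if (blocked[ci]) next
      acc <- c(acc, ci)
      blocked[max(1L, ci - (min_dist - 1L)):min(L, ci + (min_dist - 1L))] <- TRUE
    }
    acc <- sort(acc)
    cs <- sort(centers)
    fuzz <- vapply(acc, function(ci) {
      d <- ci - 1L
      lo <- findInterval(d - 73 - 0.5, cs) + 1L
      hi <- findInterval(d + 73 + 0.5, cs)
      if (hi - lo + 1L <= 1L) 0 else sd(cs[lo:hi])
    }, numeric(1))
    wid <- vapply(acc, function(ci) {
      h2 <- sm[ci] / 2
      l <- ci
      while (l > 1 && sm[l - 1] > h2 && sm[l - 1] <= sm[l]) l <- l - 1
      rgt <- ci
      while (rgt < L && sm[rgt + 1] > h2 && sm[rgt + 1] <= sm[rgt]) rgt <- rgt + 1
      as.numeric(rgt - l + 1L)
    }, numeric(1))
    tibble(chrom = cn, dyad = acc - 1L, peak_height = sm[acc],
           fuzziness = fuzz, width = wid, occupancy = NA_real_)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Attach normalized occupancy to nucleosome calls
#'
#' Occupancy is the mean normalized track value over the call's footprint
#' (`dyad +/- 73` bp, i.e. `[dyad-73, dyad+74)`), unmasked bases only. Calls
#' whose footprint is fully masked get `NA`.
#'
#' @param calls Call tibble from [call_nucleosomes()].
#' @param track A `nucarch_track` (occupancy kind).
#' @param footprint Footprint width in bp (default 147; window is
#'   `dyad - (footprint-1)/2` to `dyad + (footprint+1)/2`).
#' @return `calls` with the `occupancy` column filled.
#' @export
attach_occupancy <- function(calls, track, footprint = 147L) {
  if (nrow(calls) == 0) return(calls)
  if (!all(unique(calls$chrom) %in% names(track)))
    abort("call chromosomes missing from track.")
  half <- (footprint - 1L) %/% 2L
  calls$occupancy <- purrr::map2_dbl(calls$chrom, calls$dyad, function(cn, d) {
    track_window_mean(track, cn, d - half, d + half + 1L)
  })
  calls
}
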