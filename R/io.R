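#' Genome FASTA I/O
#'
#' Thin wrappers over Biostrings keeping the package's internal
#' representation (named character vector of chromosome sequences).
#'
#' @param genome Named character vector.
#' @param path File path.
#' @return `read_genome_fasta()` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read and write reads as BED6
#'
#' Reads are stored one line per read: `chrom start end name score strand`,
#' 0-based half-open, with `end - start` the read length.
#'
#' @param reads Read tibble.
#' @param path File path.
#' @return `read_reads_bed()` returns a read tibble.
#' @export
write_reads_bed <- function(reads, path) {
  readr::write_tsv(tibble(chrom = reads$chrom, start = reads$start,
                          end = reads$start + reads$read_length,
                          name = sprintf("read%06d", seq_len(nrow(reads))),
                          score = 0L, strand = reads$strand),
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                           "score", "strand"),
                       col_types = "ciicic", progress = FALSE)
  tibble(chrom = d$chrom, start = d$start, strand = d$strand,
         read_length = d$end - d$start)
}

#' Write a track as bedGraph (values) and BED (mask)
#'
#' Runs of equal value are merged into bedGraph intervals; masked bases are
#' written as `NA`-free gaps in the bedGraph and as merged intervals in the
#' mask BED.
#'
#' @param track A `nucarch_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  rows <- purrr::imap_dfr(track, function(x, cn) {
    v <- x$values
    r <- rle(ifelse(is.na(v), NA_real_, round(v, 6)))
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- !is.na(r$values)
    tibble(chrom = cn, start = s[keep], end = e[keep], value = r$values[keep])
  })
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_track_bedgraph
#' @export
write_mask_bed <- function(track, path) {
  rows <- purrr::imap_dfr(track, function(x, cn) {
    r <- rle(x$mask)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values
    tibble(chrom = cn, start = s[keep], end = e[keep])
  })
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}

#' Write nucleosome calls as BED6
#'
#' One line per call covering the 147 bp footprint; the score column carries
#' the smoothed peak height scaled to 0-1000.
#'
#' @param calls Call tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  sc <- calls$peak_height
  sc <- if (length(sc) && max(sc) > 0) round(1000 * sc / max(sc)) else sc
  readr::write_tsv(tibble(chrom = calls$chrom, start = calls$dyad - 73L,
                          end = calls$dyad + 74L,
                          name = sprintf("nuc%05d", seq_len(nrow(calls))),
                          score = sc, strand = "."),
                   path, col_names = FALSE)
  invisible(path)
}

#' Gene-set I/O in GMT-like TSV
#'
#' One line per set: set id, description, then member gene ids, tab
#' separated.
#'
#' @param sets Tibble `set_id`, `gene_id`.
#' @param path File path.
#' @return `read_gene_sets_gmt()` returns a tibble `set_id`, `gene_id`.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- sets %>% group_by(.data$set_id) %>%
    summarise(line = paste(c(.data$set_id[1], "na", .data$gene_id),
                           collapse = "\t"), .groups = "drop")
  writeLines(lines$line, path)
  invisible(path)
}

#' @rdname write_gene_sets_gmt
#' @export
read_gene_sets_gmt <- function(path) {
  purrr::map_dfr(strsplit(readLines(path), "\t"), function(f) {
    if (length(f) < 3) return(NULL)
    tibble(set_id = f[1], gene_id = f[-(1:2)])
  })
}

#' Echo a generator configuration to YAML
#'
#' @param config A [species_config()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  cfg <- unclass(config)
  cfg$pwm_set <- lapply(cfg$pwm_set, function(p)
    list(motif_id = p$motif_id, mat = apply(p$mat, 1, as.list)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
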