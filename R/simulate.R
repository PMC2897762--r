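#' Generator settings for one synthetic species
#'
#' Builds the configuration object consumed by [simulate_species()]. The
#' defaults describe a compact but structurally realistic yeast-like genome:
#' genes are laid out as non-overlapping cassettes, each consisting of two
#' upstream nucleosomes, a 5' nucleosome-free region (NFR) whose width depends
#' on the gene's regulatory class, a nucleosome array over the coding region
#' with fixed inter-dyad spacing, and a 3' NFR. Growth-class genes receive
#' deep, wide 5' NFRs carrying Poly(dA:dT) tracts and general regulatory
#' factor (GRF) motif sites; stress-class genes have narrow, partially filled
#' NFRs and a motif planted under their Nuc-1 nucleosome.
#'
#' @param n_genes Number of genes (>= 1).
#' @param chrom_length Chromosome length in bp, or `NULL` to size the
#'   chromosome exactly to the gene cassettes. If given and too small for the
#'   layout, a sizing error names the violated budget.
#' @param spacing_bp Inter-dyad distance of the planted nucleosome arrays.
#' @param nfr_width_by_class Named vector of planted 5' NFR widths (bp) for
#'   the `growth`, `stress` and `neutral` classes.
#' @param nfr3_width Planted 3' NFR width (bp), shared by all classes.
#' @param nucs_per_gene Nucleosomes planted over each coding region.
#' @param pad Intergenic padding between cassettes (bp).
#' @param class_probs Sampling probabilities of the three gene classes.
#' @param gene_class Optional explicit class assignment (character vector of
#'   length `n_genes`); overrides `class_probs` sampling. Used to share one
#'   class structure across the species of a multi-species simulation.
#' @param polyA_rate Probability that a growth gene's 5' NFR carries a planted
#'   Poly(dA:dT) tract. Stress genes never do.
#' @param tract_len_range Length range (bp) of planted tracts.
#' @param pwm_set Named list of position weight matrices (see [default_pwms()]).
#' @param motif_rate Probability of planting the class's motif per gene.
#' @param nfr_fill_rate Named per-class rate (fraction of per-dyad coverage)
#'   of spurious fragments sampled inside the 5' NFR: 0 gives a fully deep
#'   NFR, larger values progressively fill it. This is the knob that couples
#'   gene class to NFR depth.
#' @param nfr_kmer Optional k-mer (character) planted inside every growth
#'   gene's 5' NFR, for anti-nucleosomal k-mer recovery experiments.
#' @param nfr_kmer_copies Copies of `nfr_kmer` planted per NFR.
#' @param frac_minus Fraction of genes placed on the minus strand.
#' @param gc_content Background GC content of the i.i.d. random sequence.
#' @return A list of class `"nucarch_config"`.
#' @export
species_config <- function(n_genes = 60,
                           chrom_length = NULL,
                           spacing_bp = 165,
                           nfr_width_by_class = c(growth = 150, stress = 80, neutral = 110),
                           nfr3_width = 80,
                           nucs_per_gene = 6,
                           pad = 100,
                           class_probs = c(growth = 1/3, stress = 1/3, neutral = 1/3),
                           gene_class = NULL,
                           polyA_rate = 0.8,
                           tract_len_range = c(8, 20),
                           pwm_set = default_pwms(),
                           motif_rate = 0.9,
                           nfr_fill_rate = c(growth = 0, stress = 0.4, neutral = 0.15),
                           nfr_kmer = NULL,
                           nfr_kmer_copies = 2,
                           frac_minus = 0.5,
                           gc_content = 0.5) {
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  stopifnot(all(c("growth", "stress", "neutral") %in% names(nfr_width_by_class)),
            all(c("growth", "stress", "neutral") %in% names(nfr_fill_rate)))
  cfg <- list(n_genes = n_genes, chrom_length = chrom_length,
              spacing_bp = spacing_bp, nfr_width_by_class = nfr_width_by_class,
              nfr3_width = nfr3_width, nucs_per_gene = nucs_per_gene, pad = pad,
              class_probs = class_probs, gene_class = gene_class,
              polyA_rate = polyA_rate, tract_len_range = tract_len_range,
              pwm_set = pwm_set, motif_rate = motif_rate,
              nfr_fill_rate = nfr_fill_rate, nfr_kmer = nfr_kmer,
              nfr_kmer_copies = nfr_kmer_copies, frac_minus = frac_minus,
              gc_content = gc_content)
  structure(cfg, class = "nucarch_config")
}

#' Built-in toy position weight matrices
#'
#' Five synthetic motifs used by the generator: two GRF-like motifs planted
#' only in growth-gene 5' NFRs (`grf1`, `grf2`); a stress-condition factor
#' motif planted only under stress genes' Nuc-1 nucleosome (`stress_tf`); an
#' activator-like motif (`act_tf`) planted in growth NFRs (functional,
#' high-expression context) and under stress genes' Nuc-1 (non-functional,
#' low-expression context); and a repressor-like motif (`rep_tf`) with the
#' mirrored placement (stress NFRs + growth Nuc-1). Each is a near-consensus
#' PWM.
#'
#' @param conc Probability on the consensus base at each position.
#' @return Named list of `nucarch_pwm` objects.
#' @export
default_pwms <- function(conc = 0.91) {
  list(grf1      = consensus_pwm("grf1", "TTACCCGGT", conc),
       grf2      = consensus_pwm("grf2", "CGTGCGAT", conc),
       stress_tf = consensus_pwm("stress_tf", "AGGGGCTAG", conc),
       act_tf    = consensus_pwm("act_tf", "TGACTCAT", conc),
       rep_tf    = consensus_pwm("rep_tf", "GTCACGTA", conc))
}

sample_base <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate one species with exported ground truth
#'
#' Generates a single-chromosome genome together with the full record of what
#' was planted: gene models, true nucleosome dyads, 5'/3' NFR intervals,
#' Poly(dA:dT) tracts, and motif sites. Every downstream recovery test scores
#' itself against these truth tables. Identical `(config, seed)` gives
#' byte-identical output.
#'
#' @param config A [species_config()] object.
#' @param seed Integer seed; all randomness derives from it.
#' @param species_id Label used to prefix gene ids.
#' @return A list of class `"species_truth"` with elements `species_id`,
#'   `genome` (named character vector of chromosome sequences), `genes`,
#'   `dyads`, `nfrs`, `tracts`, `motif_sites` (tibbles, 0-based half-open
#'   coordinates), `spacing_bp` and `config`.
#' @export
simulate_species <- function(config = species_config(), seed = 1L,
                             species_id = "s1") {
  stopifnot(inherits(config, "nucarch_config"))
  withr::with_seed(seed, simulate_species_impl(config, species_id))
}

simulate_species_impl <- function(cfg, species_id) {
  n <- cfg$n_genes
  classes <- if (!is.null(cfg$gene_class)) {
    stopifnot(length(cfg$gene_class) == n)
    cfg$gene_class
  } else {
    sample(names(cfg$class_probs), n, replace = TRUE, prob = cfg$class_probs)
  }
  strands <- ifelse(runif(n) < cfg$frac_minus, "-", "+")
  w5 <- unname(cfg$nfr_width_by_class[classes])
  w3 <- cfg$nfr3_width
  sp <- cfg$spacing_bp
  nn <- cfg$nucs_per_gene
  # cassette (plus orientation): pad | Nuc-2, Nuc-1 | 5'NFR | gene nucs | 3'NFR
  up_extent <- sp + 147                    # upstream dyads' footprint span
  cass_len <- cfg$pad + up_extent + w5 + 73 + (nn - 1) * sp + 74 + w3
  starts <- cfg$pad + c(0, cumsum(head(cass_len, -1)))
  need <- sum(cass_len) + 2 * cfg$pad
  L <- if (is.null(cfg$chrom_length)) need else cfg$chrom_length
  if (L < need) {
    abort(sprintf(paste0("chrom_length %d too small: %d genes with this ",
                         "layout need at least %d bp."), L, n, need))
  }

  genes <- vector("list", n); dyads <- vector("list", n); nfrs <- vector("list", n)
  for (i in seq_len(n)) {
    x0 <- starts[i]
    nfr5_s <- x0 + up_extent
    nfr5_e <- nfr5_s + w5[i]
    atg <- nfr5_e
    d_gene <- atg + 73 + (seq_len(nn) - 1L) * sp
    d_up <- c(nfr5_s - 74 - sp, nfr5_s - 74)        # Nuc-2, Nuc-1
    cds_end <- d_gene[nn] + 74
    nfr3_s <- cds_end; nfr3_e <- cds_end + w3
    if (strands[i] == "-") {
      # mirror the cassette within [x0, x0 + body_len)
      body_len <- up_extent + w5[i] + 73 + (nn - 1) * sp + 74 + w3
      mirr_pt <- function(p) x0 + (x0 + body_len - 1) - p       # point mirror
      mirr_iv <- function(s, e) c(2 * x0 + body_len - e, 2 * x0 + body_len - s)
      d_all <- mirr_pt(c(d_up, d_gene))
      iv5 <- mirr_iv(nfr5_s, nfr5_e); iv3 <- mirr_iv(nfr3_s, nfr3_e)
      cds <- mirr_iv(atg, cds_end)
      nfr5_s <- iv5[1]; nfr5_e <- iv5[2]; nfr3_s <- iv3[1]; nfr3_e <- iv3[2]
      cds_start <- cds[1]; cds_end <- cds[2]
      d_up <- d_all[1:2]; d_gene <- d_all[-(1:2)]
    } else {
      cds_start <- atg
    }
    gid <- sprintf("%s_g%03d", species_id, i)
    genes[[i]] <- tibble(gene_id = gid, chrom = "chr1", strand = strands[i],
                         cds_start = cds_start, cds_end = cds_end,
                         gene_class = classes[i])
    roles <- c("-2", "-1", paste0("+", seq_len(nn)))
    dyads[[i]] <- tibble(gene_id = gid, chrom = "chr1",
                         dyad = c(d_up, d_gene), role = roles)
    nfrs[[i]] <- tibble(gene_id = gid, chrom = "chr1",
                        side = c("5", "3"),
                        start = c(nfr5_s, nfr3_s), end = c(nfr5_e, nfr3_e),
                        width = c(nfr5_e - nfr5_s, nfr3_e - nfr3_s),
                        fill_rate = unname(cfg$nfr_fill_rate[classes[i]]))
  }
  genes <- bind_rows(genes); dyads <- bind_rows(dyads); nfrs <- bind_rows(nfrs)

  seq_chars <- sample_base(L, cfg$gc_content)

  # plant Poly(dA:dT) tracts centered in growth 5'NFRs
  tracts <- list()
  g5 <- nfrs %>% filter(.data$side == "5") %>%
    left_join(select(genes, "gene_id", "gene_class"), by = "gene_id")
  for (i in seq_len(nrow(g5))) {
    if (g5$gene_class[i] != "growth" || runif(1) >= cfg$polyA_rate) next
    tl <- sample(seq(cfg$tract_len_range[1], cfg$tract_len_range[2]), 1)
    mid <- (g5$start[i] + g5$end[i]) %/% 2
    s <- mid - tl %/% 2
    base <- sample(c("A", "T"), 1)
    seq_chars[(s + 1):(s + tl)] <- base
    tracts[[length(tracts) + 1]] <-
      tibble(gene_id = g5$gene_id[i], chrom = "chr1", start = s, end = s + tl,
             length = tl, base = base, mismatches = 0L)
  }
  tracts <- if (length(tracts)) bind_rows(tracts) else
    tibble(gene_id = character(), chrom = character(), start = integer(),
           end = integer(), length = integer(), base = character(),
           mismatches = integer())

  # plant motif sites: GRFs in growth 5'NFRs, stress TF under Nuc-1
  plant <- function(seq_chars, pos, motif, strand) {
    cons <- pwm_consensus(motif)
    s <- if (strand == "-") revcomp_chr(cons) else cons
    seq_chars[(pos + 1):(pos + nchar(s))] <- strsplit(s, "")[[1]]
    seq_chars
  }
  sites <- list()
  add_site <- function(pwm_id, gene_id, pos, strand, region) {
    sites[[length(sites) + 1]] <<- tibble(
      pwm_id = pwm_id, gene_id = gene_id, chrom = "chr1", start = pos,
      end = pos + nchar(pwm_consensus(cfg$pwm_set[[pwm_id]])),
      strand = strand, region = region)
  }
  nuc1_up <- dyads %>% filter(.data$role == "-1")
  plant_at <- function(gid, pwm_id, pos, region) {
    st <- sample(c("+", "-"), 1)
    seq_chars <<- plant(seq_chars, pos, cfg$pwm_set[[pwm_id]], st)
    add_site(pwm_id, gid, pos, st, region)
  }
  for (i in seq_len(n)) {
    gid <- genes$gene_id[i]
    iv <- g5[g5$gene_id == gid, ]
    d1 <- nuc1_up$dyad[nuc1_up$gene_id == gid]
    # NFR sites sit >= 16 bp from the planted NFR edge so that small errors
    # in detected NFR boundaries do not change their region assignment
    if (classes[i] == "growth") {
      if (runif(1) < cfg$motif_rate && !is.null(cfg$pwm_set$grf1)) {
        plant_at(gid, "grf1", iv$start + 16L, "5'NFR")
        if (!is.null(cfg$pwm_set$grf2) && runif(1) < 0.5)
          plant_at(gid, "grf2", iv$start + 28L, "5'NFR")
      }
      if (runif(1) < cfg$motif_rate && !is.null(cfg$pwm_set$act_tf)) {
        la <- nchar(pwm_consensus(cfg$pwm_set$act_tf))
        plant_at(gid, "act_tf", iv$end - la - 16L, "5'NFR")
      }
      if (runif(1) < cfg$motif_rate && !is.null(cfg$pwm_set$rep_tf))
        plant_at(gid, "rep_tf", d1 - 3L, "Nuc-1")
    }
    if (classes[i] == "stress") {
      if (runif(1) < cfg$motif_rate && !is.null(cfg$pwm_set$stress_tf))
        plant_at(gid, "stress_tf", d1 - 3L, "Nuc-1")
      if (runif(1) < cfg$motif_rate && !is.null(cfg$pwm_set$act_tf))
        plant_at(gid, "act_tf", d1 - 25L, "Nuc-1")
      if (runif(1) < cfg$motif_rate && !is.null(cfg$pwm_set$rep_tf))
        plant_at(gid, "rep_tf", iv$start + 16L, "5'NFR")
    }
    if (classes[i] == "growth" && !is.null(cfg$nfr_kmer)) {
      kl <- nchar(cfg$nfr_kmer)
      for (cpy in seq_len(cfg$nfr_kmer_copies)) {
        pos <- iv$start + 38 + (cpy - 1L) * (kl + 3L)
        seq_chars[(pos + 1):(pos + kl)] <- strsplit(cfg$nfr_kmer, "")[[1]]
      }
    }
  }
  sites <- if (length(sites)) bind_rows(sites) else
    tibble(pwm_id = character(), gene_id = character(), chrom = character(),
           start = integer(), end = integer(), strand = character(),
           region = character())

  structure(list(
    species_id = species_id,
    genome = setNames(paste(seq_chars, collapse = ""), "chr1"),
    genes = genes, dyads = dyads, nfrs = nfrs, tracts = tracts,
    motif_sites = sites, spacing_bp = sp, config = cfg
  ), class = "species_truth")
}

pwm_consensus <- function(pwm) {
  paste(colnames(pwm$mat)[max.col(pwm$mat)], collapse = "")
}

#' Simulate mononucleosome sequencing reads
#'
#' Samples MNase-protected fragments around the planted dyads and emits, for
#' each fragment, a plus-strand read at its left end and a minus-strand read
#' ending at its right end (read coordinates are 0-based half-open, BED
#' style). In `"in_vivo"` mode fragment centers sit on planted dyads (with
#' optional positional jitter) and stress/neutral 5' NFRs receive extra
#' "fill" fragments at their class's `nfr_fill_rate`, so NFR depth tracks
#' gene class. In `"in_vitro"` mode planted NFRs and GRF sites have no
#' effect: fragment centers are uniform over the chromosome except that
#' footprints overlapping a planted Poly(dA:dT) tract are rejected, mimicking
#' purely sequence-intrinsic nucleosome exclusion.
#'
#' @param truth A `species_truth` object.
#' @param coverage Mean fragments sampled per planted dyad (> 0).
#' @param frag_len_mean,frag_len_sd Fragment length distribution (bp);
#'   `frag_len_mean` must lie in \[100, 250\].
#' @param jitter_sd Gaussian jitter (bp) of fragment centers around dyads.
#' @param read_length Sequenced read length (bp).
#' @param mode `"in_vivo"` (default) or `"in_vitro"` (see Details).
#' @param tract_repulsion In vitro: rejection probability for fragments whose
#'   footprint overlaps a planted tract.
#' @param seed Integer seed.
#' @return Tibble with columns `chrom`, `start`, `strand`, `read_length`,
#'   `fragment_length_truth`.
#' @export
simulate_reads <- function(truth, coverage = 30, frag_len_mean = 147,
                           frag_len_sd = 8, jitter_sd = 10, read_length = 36L,
                           mode = c("in_vivo", "in_vitro"),
                           tract_repulsion = 0.95, seed = 1L) {
  mode <- match.arg(mode)
  if (coverage <= 0) abort("`coverage` must be > 0.")
  if (frag_len_mean < 100 || frag_len_mean > 250)
    abort("`frag_len_mean` must lie in [100, 250].")
  withr::with_seed(seed, {
    L <- nchar(truth$genome[["chr1"]])
    if (mode == "in_vivo") {
      centers <- rep(truth$dyads$dyad, rpois(nrow(truth$dyads), coverage))
      if (jitter_sd > 0) centers <- centers + round(rnorm(length(centers), 0, jitter_sd))
      nf <- truth$nfrs %>% filter(.data$side == "5", .data$fill_rate > 0)
      if (nrow(nf)) {
        nfill <- rpois(nrow(nf), coverage * nf$fill_rate * 2)
        mid <- (nf$start + nf$end) %/% 2
        fc <- rep(mid, nfill) +
          round(rnorm(sum(nfill), 0, rep(pmax(nf$width / 4, 5), nfill)))
        centers <- c(centers, fc)
      }
    } else {
      n_frag <- round(nrow(truth$dyads) * coverage)
      centers <- round(runif(n_frag, 74, L - 75))
      if (nrow(truth$tracts)) {
        hit <- purrr::map_lgl(centers, function(ct) {
          any(truth$tracts$start < ct + 74 & truth$tracts$end > ct - 73)
        })
        drop <- hit & runif(length(centers)) < tract_repulsion
        centers <- centers[!drop]
      }
    }
    fl <- pmax(60L, round(rnorm(length(centers), frag_len_mean, frag_len_sd)))
    fs <- centers - fl %/% 2L
    fe <- fs + fl
    keep <- fs >= 0 & fe <= L
    fs <- fs[keep]; fe <- fe[keep]; fl <- fl[keep]
    tibble(chrom = "chr1",
           start = c(fs, fe - read_length),
           strand = rep(c("+", "-"), each = length(fs)),
           read_length = read_length,
           fragment_length_truth = c(fl, fl)) %>%
      arrange(.data$start, .data$strand)
  })
}

#' Simulate per-gene expression
#'
#' Log2 expression = class mean + Gaussian noise; deterministic under a fixed
#' seed. With `noise_sd = 0` every gene sits exactly at its class mean.
#'
#' @param truth A `species_truth` object.
#' @param class_means Named log2 means for `growth`, `stress`, `neutral`.
#' @param noise_sd Gaussian noise sd in log2 units (>= 0).
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `gene_class`, `expression`.
#' @export
simulate_expression <- function(truth,
                                class_means = c(growth = 2, stress = -2, neutral = 0),
                                noise_sd = 0.5, seed = 1L) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  withr::with_seed(seed, {
    g <- truth$genes
    mu <- unname(class_means[g$gene_class])
    tibble(gene_id = g$gene_id, gene_class = g$gene_class,
           expression = mu + rnorm(nrow(g), 0, noise_sd))
  })
}

#' Simulate a set of related species with orthology and projected gene sets
#'
#' Generates `n_species` species from one base configuration with optional
#' per-species overrides (e.g. different nucleosome spacing or NFR widths).
#' Gene classes are drawn once and shared, so the i-th gene of every species
#' belongs to one orthogroup and one regulatory class; the orthology table is
#' a bijection. Gene sets (the growth and stress classes of species 1, plus
#' random sets) are defined on species 1 and projectable to the others via
#' [project_gene_sets()].
#'
#' @param base_config A [species_config()].
#' @param n_species Number of species (>= 2).
#' @param divergence Named list (by species id `s2`, `s3`, ...) of config
#'   overrides, e.g. `list(s2 = list(spacing_bp = 177))`.
#' @param n_random_sets Random gene sets of size `random_set_size` added to
#'   the growth/stress sets.
#' @param random_set_size Members per random set.
#' @param seed Integer seed.
#' @return List with `truths` (named list of `species_truth`), `orthology`
#'   (tibble: `orthogroup`, `species_id`, `gene_id`) and `gene_sets` (tibble:
#'   `set_id`, `gene_id`, on species 1).
#' @export
simulate_multispecies <- function(base_config = species_config(),
                                  n_species = 3, divergence = list(),
                                  n_random_sets = 3, random_set_size = 20,
                                  seed = 1L) {
  if (n_species < 2) abort("`n_species` must be >= 2.")
  ids <- paste0("s", seq_len(n_species))
  classes <- withr::with_seed(seed, {
    sample(names(base_config$class_probs), base_config$n_genes,
           replace = TRUE, prob = base_config$class_probs)
  })
  truths <- lapply(seq_len(n_species), function(i) {
    cfg <- base_config
    cfg$gene_class <- classes
    ov <- divergence[[ids[i]]]
    for (nm in names(ov)) {
      if (nm == "nfr_width") cfg$nfr_width_by_class[] <- ov[[nm]]
      else cfg[[nm]] <- ov[[nm]]
    }
    simulate_species(cfg, seed = seed + i, species_id = ids[i])
  })
  names(truths) <- ids
  og <- sprintf("og%04d", seq_len(base_config$n_genes))
  orthology <- purrr::map_dfr(truths, function(tr) {
    tibble(orthogroup = og, species_id = tr$species_id,
           gene_id = tr$genes$gene_id)
  })
  g1 <- truths[[1]]$genes
  sets <- list(
    tibble(set_id = "growth_genes",
           gene_id = g1$gene_id[g1$gene_class == "growth"]),
    tibble(set_id = "stress_genes",
           gene_id = g1$gene_id[g1$gene_class == "stress"])
  )
  rand_sets <- withr::with_seed(seed + 7777L, {
    purrr::map(seq_len(n_random_sets), function(k) {
      tibble(set_id = sprintf("random_%02d", k),
             gene_id = sample(g1$gene_id, min(random_set_size, nrow(g1))))
    })
  })
  list(truths = truths, orthology = orthology,
       gene_sets = bind_rows(c(sets, rand_sets)))
}
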