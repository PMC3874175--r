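# Synthetic two-species data generator.
#
# Emits every input the pipeline consumes — two orthologous annotated
# genomes whose first introns are longer and more length-conserved than
# other introns, planted conserved motif sites, midpoint-defined ChIP
# peaks, a bipartite PDI network with exponential in-degrees and tunable
# promoter/intron TF overlap, and co-expression scores generated from the
# combined Jaccard similarity — together with the ground truth needed to
# verify every stage. A single master seed fans out into named child
# streams (genome, orthologs, motifs, peaks, pdi, coexpression) so that
# toggling one component does not perturb the draws of another.

#' Simulation configuration
#'
#' Defaults are calibrated to the magnitudes the analysis expects of a
#' nematode genome: median first-intron length ~74 bp vs ~57 bp for other
#' introns (with heavy log-normal tails so mean lengths are near 290/250
#' bp), ~76% conventional genes, promoter in-degree rate 0.145 and
#' first-intron rate 0.3, and first-intron length jitter across species
#' smaller than that of other introns.
#'
#' @param seed Master seed (integer).
#' @param n_genes Number of genes per species.
#' @param exon_count_range Min/max coding exons per gene.
#' @param exon_len_meanlog,exon_len_sdlog Log-normal exon length parameters
#'   (lengths are rounded to codon multiples, minimum 30 bp).
#' @param first_intron_meanlog,first_intron_sdlog Log-normal parameters of
#'   first-intron length (median `exp(meanlog)`).
#' @param other_intron_meanlog,other_intron_sdlog Same for non-first introns.
#' @param min_intron Minimum intron length (shorter draws are clamped,
#'   with a warning when clamping is extensive).
#' @param intergenic_range Min/max intergenic gap in bp.
#' @param frac_utr5_intron,frac_alt_start,frac_operon_downstream
#'   Independent probabilities of the three non-conventional criteria
#'   (defaults jointly give ~24% non-conventional genes).
#' @param frac_operon_first Probability of being the first gene of an
#'   operon (still conventional).
#' @param substitution_rate Per-codon probability of a third-position
#'   substitution in species-B exons.
#' @param frac_structure_violation Fraction of ortholog pairs where
#'   species B merges two adjacent exons (breaking identical structure).
#' @param sigma_first,sigma_other SD of the log-normal intron length
#'   multiplier between species, per intron class.
#' @param gc GC content of background sequence.
#' @param n_tfs TF pool size (ids `TF001`...).
#' @param n_pwms Number of TFs with a PWM (taken from the head of the
#'   pool).
#' @param pwm_width,pwm_strictness PWM width and consensus-base
#'   probability; the default strictness makes one mismatch fail the
#'   default occupancy threshold, so planted-signal recovery is clean.
#' @param motif_rate_promoter,motif_rate_first,motif_rate_other Expected
#'   planted (potentially conserved) motifs per fragment of each class.
#' @param motif_background_rate Expected species-specific (non-conserved)
#'   planted motifs per fragment, emulating the abundant non-conserved
#'   predicted sites seen with permissive occupancy thresholds.
#' @param p_conserved Probability that a planted motif is also planted in
#'   the orthologous fragment of the other species.
#' @param chip_rate_promoter,chip_rate_first,chip_rate_other,chip_rate_exon
#'   Expected planted ChIP binding events per fragment of each class (the
#'   first/other intron default ratio is 1/0.7 ~ 1.43).
#' @param chip_peak_width,chip_jitter Peak width (bp) and SD of midpoint
#'   jitter around the planted position.
#' @param chip_background_per_kb Uniform background peaks per kb of genome.
#' @param lambda_promoter,lambda_intron Exponential in-degree rates of the
#'   PDI network (per-region mean interactions are their reciprocals).
#' @param overlap_rho Probability that an intron interaction re-uses a TF
#'   bound to the same gene's promoter.
#' @param coexp_alpha,coexp_sigma Co-expression model: score =
#'   `clip(alpha * J_combined + Normal(0, sigma), -1, 1)`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L,
                       exon_count_range = c(3L, 7L),
                       exon_len_meanlog = log(140), exon_len_sdlog = 0.35,
                       first_intron_meanlog = log(74),
                       first_intron_sdlog = 1.65,
                       other_intron_meanlog = log(57),
                       other_intron_sdlog = 1.7,
                       min_intron = 25L,
                       intergenic_range = c(500L, 3000L),
                       frac_utr5_intron = 0.10, frac_alt_start = 0.08,
                       frac_operon_downstream = 0.08,
                       frac_operon_first = 0.03,
                       substitution_rate = 0.10,
                       frac_structure_violation = 0.15,
                       sigma_first = 0.15, sigma_other = 0.6,
                       gc = 0.36,
                       n_tfs = 30L, n_pwms = 10L,
                       pwm_width = 8L, pwm_strictness = 0.91,
                       motif_rate_promoter = 2.0, motif_rate_first = 1.5,
                       motif_rate_other = 1.0,
                       motif_background_rate = 2.0,
                       p_conserved = 0.8,
                       chip_rate_promoter = 3.0, chip_rate_first = 1.0,
                       chip_rate_other = 0.7, chip_rate_exon = 0.2,
                       chip_peak_width = 200L, chip_jitter = 20,
                       chip_background_per_kb = 0.5,
                       lambda_promoter = 0.145, lambda_intron = 0.3,
                       overlap_rho = 0.2,
                       coexp_alpha = 0.8, coexp_sigma = 0.2) {
  cfg <- as.list(environment())
  probs <- c(frac_utr5_intron, frac_alt_start, frac_operon_downstream,
             frac_operon_first, p_conserved, overlap_rho, gc,
             pwm_strictness)
  stopifnot(all(probs >= 0 & probs <= 1),
            sigma_first >= 0, sigma_other >= 0,
            lambda_promoter > 0, lambda_intron > 0,
            coexp_sigma >= 0, n_pwms <= n_tfs,
            exon_count_range[1] >= 2L,
            all(c(motif_rate_promoter, motif_rate_first, motif_rate_other,
                  motif_background_rate, chip_rate_promoter,
                  chip_rate_first, chip_rate_other, chip_rate_exon) >= 0))
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate strict synthetic PWMs
#'
#' Each PWM has a random consensus with `strictness` probability on the
#' consensus base at every position, the remainder split equally.
#'
#' @param n_pwms Number of matrices.
#' @param width Motif width.
#' @param strictness Consensus base probability.
#' @param tf_ids TF labels (default `TF001`...).
#' @return Named list of [pwm] objects with a `consensus` attribute each.
#' @export
make_pwms <- function(n_pwms, width = 8L, strictness = 0.91,
                      tf_ids = sprintf("TF%03d", seq_len(n_pwms))) {
  out <- list()
  for (k in seq_len(n_pwms)) {
    cons <- sample(4L, width, replace = TRUE)
    m <- matrix((1 - strictness) / 3, width, 4L)
    m[cbind(seq_len(width), cons)] <- strictness
    p <- pwm(tf_ids[k], m)
    attr(p, "consensus") <- paste(BASES[cons], collapse = "")
    out[[tf_ids[k]]] <- p
  }
  out
}

# draw per-gene structure for one species-A gene, transcriptional order
draw_gene_structure <- function(cfg) {
  n_ex <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1L)
  exon_len <- pmax(30L, 3L * round_half_up(
    stats::rlnorm(n_ex, cfg$exon_len_meanlog, cfg$exon_len_sdlog) / 3))
  n_in <- n_ex - 1L
  intron_len <- integer(n_in)
  if (n_in >= 1L)
    intron_len[1L] <- max(cfg$min_intron, round_half_up(
      stats::rlnorm(1L, cfg$first_intron_meanlog, cfg$first_intron_sdlog)))
  if (n_in >= 2L)
    intron_len[2:n_in] <- pmax(cfg$min_intron, round_half_up(
      stats::rlnorm(n_in - 1L, cfg$other_intron_meanlog,
                    cfg$other_intron_sdlog)))
  list(exon_len = as.integer(exon_len), intron_len = intron_len)
}

# lay genes on one chromosome; lens are per-gene transcriptional-order
# exon/intron lengths. Returns gene models + total length.
layout_genes <- function(ids, strands, lens, flags, cfg) {
  genes <- vector("list", length(ids))
  cursor <- 200L
  for (g in seq_along(ids)) {
    gap <- as.integer(round(stats::runif(1, cfg$intergenic_range[1],
                                         cfg$intergenic_range[2])))
    pos <- cursor + gap
    ex_tx <- lens[[g]]$exon_len
    in_tx <- lens[[g]]$intron_len
    n <- length(ex_tx)
    # genomic order: reverse the transcriptional order on the minus strand
    ex_gen <- if (strands[g] == "+") ex_tx else rev(ex_tx)
    in_gen <- if (strands[g] == "+") in_tx else rev(in_tx)
    starts <- integer(n); ends <- integer(n)
    p <- pos
    for (i in seq_len(n)) {
      starts[i] <- p; ends[i] <- p + ex_gen[i]
      p <- ends[i] + if (i < n) in_gen[i] else 0L
    }
    genes[[g]] <- gene_model(
      ids[g], "chrI", strands[g], cbind(starts, ends),
      utr5_introns = if (flags$utr5[g]) 1L else 0L,
      alt_first_exons = if (flags$alt[g]) 2L else 1L,
      operon_position = flags$operon[g])
    cursor <- ends[n]
  }
  names(genes) <- ids
  list(genes = genes, total = cursor + 200L)
}

# genomic 1-based positions and bases for planting `motif` at a
# strand-corrected fragment offset; applied in bulk at the end
plant_edit <- function(frag, offset, motif) {
  w <- nchar(motif)
  if (frag$strand == "+") {
    at <- frag$start + offset
    list(at = (at + 1L):(at + w), chars = strsplit(motif, "")[[1]])
  } else {
    at <- frag$end - offset - w
    list(at = (at + 1L):(at + w),
         chars = strsplit(revcomp_chr(motif), "")[[1]])
  }
}

# choose k non-overlapping offsets for width-w plants in a fragment of
# length len; gives up on a draw after a few tries
plant_offsets <- function(k, len, w, taken = integer(0)) {
  out <- integer(0)
  for (i in seq_len(k)) {
    for (try in 1:20) {
      o <- sample.int(len - w + 1L, 1L) - 1L
      if (!any(abs(c(out, taken) - o) < w)) { out <- c(out, o); break }
      o <- NA_integer_
    }
    if (!is.na(o)) out[length(out)] <- o
  }
  out
}

#' Generate an orthologous two-species synthetic genome pair
#'
#' Species A is a random annotated genome; species B is derived from it by
#' synonymous-position exon substitutions, per-class log-normal intron
#' length multipliers (`exp(Normal(0, sigma_class))`), and exon-merge
#' structure violations in a configured fraction of genes. Conserved motif
#' consensus sites are planted into promoters and introns of both species,
#' plus species-specific background sites. Deterministic given the seed.
#'
#' @param cfg A [sim_config].
#' @return List of class `intron_sim`: `config`, `genome_a`, `genome_b`,
#'   `genes_a`, `genes_b`, `orthologs`, `pwms`, `truth` (conventional
#'   flags, planted motifs, structure violations).
#' @export
sim_genome_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  ids_a <- sprintf("ga%04d", seq_len(n))
  ids_b <- sprintf("gb%04d", seq_len(n))

  ## --- stream: genome (species A structure + sequence) ---
  st <- with_seed(child_seed(cfg$seed, "genome"), {
    lens_a <- replicate(n, draw_gene_structure(cfg), simplify = FALSE)
    strands_a <- sample(c("+", "-"), n, replace = TRUE)
    flags <- list(utr5 = stats::runif(n) < cfg$frac_utr5_intron,
                  alt = stats::runif(n) < cfg$frac_alt_start,
                  operon = {
                    op <- rep("none", n)
                    op[stats::runif(n) < cfg$frac_operon_first] <- "first"
                    op[stats::runif(n) < cfg$frac_operon_downstream] <-
                      "downstream"
                    op
                  })
    la <- layout_genes(ids_a, strands_a, lens_a, flags, cfg)
    chars_a <- random_dna(la$total, cfg$gc)
    list(lens_a = lens_a, strands_a = strands_a, flags = flags,
         layout_a = la, chars_a = chars_a)
  })

  ## --- stream: orthologs (species B structure + sequence) ---
  stb <- with_seed(child_seed(cfg$seed, "orthologs"), {
    strands_b <- sample(c("+", "-"), n, replace = TRUE)
    violated <- stats::runif(n) < cfg$frac_structure_violation
    lens_b <- vector("list", n)
    merged_at <- rep(NA_integer_, n)
    for (g in seq_len(n)) {
      ex <- st$lens_a[[g]]$exon_len
      inl <- st$lens_a[[g]]$intron_len
      cls_sd <- c(cfg$sigma_first,
                  rep(cfg$sigma_other, max(length(inl) - 1L, 0L)))
      inb <- pmax(cfg$min_intron, round_half_up(
        inl * exp(stats::rnorm(length(inl), 0, cls_sd[seq_along(inl)]))))
      if (violated[g] && length(ex) >= 3L) {
        k <- sample.int(length(ex) - 1L, 1L)
        ex <- c(ex[seq_len(k - 1L)], ex[k] + ex[k + 1L],
                ex[-seq_len(k + 1L)])
        inb <- inb[-k]
        merged_at[g] <- k
      } else violated[g] <- FALSE
      lens_b[[g]] <- list(exon_len = as.integer(ex),
                          intron_len = as.integer(inb))
    }
    lb <- layout_genes(ids_b, strands_b, lens_b, st$flags, cfg)
    # assemble species-B chromosome: background everywhere, then write the
    # exon sequences derived from A (third-codon-position substitutions)
    chars_b <- random_dna(lb$total, cfg$gc)
    for (g in seq_len(n)) {
      ga <- st$layout_a$genes[[g]]
      # coding-strand exon sequence of A, transcriptional order, concatenated
      fr_a <- ga$exons
      seq_a <- character(nrow(fr_a))
      for (i in seq_len(nrow(fr_a)))
        seq_a[i] <- paste(st$chars_a[(fr_a[i, 1] + 1L):fr_a[i, 2]],
                          collapse = "")
      if (ga$strand == "-")
        seq_a <- rev(vapply(seq_a, revcomp_chr, ""))
      coding <- paste(seq_a, collapse = "")
      third <- seq(3L, nchar(coding), by = 3L)
      hit <- third[stats::runif(length(third)) < cfg$substitution_rate]
      cv <- strsplit(coding, "")[[1]]
      if (length(hit))
        cv[hit] <- sample(c("A", "C", "G", "T"), length(hit),
                          replace = TRUE)
      # split back into B's exons (merges preserve total coding length)
      exb <- lens_b[[g]]$exon_len
      stopifnot(sum(exb) == length(cv))
      cuts <- cumsum(exb)
      gb <- lb$genes[[g]]
      exb_seqs <- substring(paste(cv, collapse = ""),
                            c(1L, head(cuts, -1L) + 1L), cuts)
      # write into B chromosome, genomic order
      ord <- if (gb$strand == "+") seq_along(exb_seqs) else
        rev(seq_along(exb_seqs))
      for (i in seq_along(ord)) {
        sq <- exb_seqs[ord[i]]
        if (gb$strand == "-") sq <- revcomp_chr(sq)
        chars_b[(gb$exons[i, 1] + 1L):gb$exons[i, 2]] <-
          strsplit(sq, "")[[1]]
      }
    }
    list(strands_b = strands_b, violated = violated, merged_at = merged_at,
         layout_b = lb, chars_b = chars_b)
  })

  genes_a <- st$layout_a$genes
  genes_b <- stb$layout_b$genes

  ## --- stream: motifs (PWMs + conserved/background planting) ---
  chars_a <- st$chars_a
  chars_b <- stb$chars_b
  mt <- with_seed(child_seed(cfg$seed, "motifs"), {
    pwms <- make_pwms(cfg$n_pwms, cfg$pwm_width, cfg$pwm_strictness,
                      sprintf("TF%03d", seq_len(cfg$n_pwms)))
    consensus <- vapply(pwms, attr, "", "consensus")
    frag_a <- gene_fragments(genes_a, genome = NULL)
    frag_b <- gene_fragments(genes_b, genome = NULL)
    keyify <- function(f) paste(f$kind, f$index)
    planted <- list()
    w <- cfg$pwm_width
    rate_of <- function(kind, index)
      switch(kind, promoter = cfg$motif_rate_promoter,
             intron = if (index == 1L) cfg$motif_rate_first else
               cfg$motif_rate_other,
             exon = 0)
    frag_a <- frag_a[frag_a$kind != "exon", , drop = FALSE]
    frag_b <- frag_b[frag_b$kind != "exon", , drop = FALSE]
    key_b_all <- paste(frag_b$gene_id, keyify(frag_b))
    edits_a <- list(); edits_b <- list()
    rec <- list(species = character(0), gene_id = character(0),
                kind = character(0), index = integer(0), tf = character(0),
                offset = integer(0), conserved = logical(0))
    add_rec <- function(...) {
      v <- list(...)
      for (f in names(v)) rec[[f]][length(rec[[f]]) + 1L] <<- v[[f]]
    }
    gene_of_b <- stats::setNames(ids_b, ids_a)
    taken_b <- stats::setNames(vector("list", nrow(frag_b)), key_b_all)
    for (r in seq_len(nrow(frag_a))) {
      fr <- frag_a[r, ]
      k <- stats::rpois(1L, rate_of(fr$kind, fr$index))
      k_bg_a <- stats::rpois(1L, cfg$motif_background_rate)
      k_bg_b <- stats::rpois(1L, cfg$motif_background_rate)
      key_b <- paste(gene_of_b[[fr$gene_id]], keyify(fr))
      rb <- match(key_b, key_b_all)
      fr_b <- if (!is.na(rb)) frag_b[rb, ] else NULL
      if (fr$length >= w) {
        offs_c <- plant_offsets(k, fr$length, w)
        offs_bg <- plant_offsets(k_bg_a, fr$length, w, offs_c)
        offs <- c(offs_c, offs_bg)
        tfs <- sample(names(pwms), length(offs), replace = TRUE)
        cons_flag <- c(stats::runif(length(offs_c)) < cfg$p_conserved,
                       rep(FALSE, length(offs_bg)))
        for (i in seq_along(offs)) {
          edits_a[[length(edits_a) + 1L]] <-
            plant_edit(fr, offs[i], consensus[tfs[i]])
          ok_b <- FALSE
          if (cons_flag[i] && !is.null(fr_b) && fr_b$length >= w) {
            ob <- plant_offsets(1L, fr_b$length, w, taken_b[[rb]])
            if (length(ob)) {
              taken_b[[rb]] <- c(taken_b[[rb]], ob)
              edits_b[[length(edits_b) + 1L]] <-
                plant_edit(fr_b, ob, consensus[tfs[i]])
              add_rec(species = "B", gene_id = fr_b$gene_id,
                      kind = fr$kind, index = fr$index, tf = tfs[i],
                      offset = ob, conserved = TRUE)
              ok_b <- TRUE
            }
          }
          add_rec(species = "A", gene_id = fr$gene_id, kind = fr$kind,
                  index = fr$index, tf = tfs[i], offset = offs[i],
                  conserved = ok_b)
        }
      }
      # species-B-only background plants
      if (k_bg_b > 0L && !is.null(fr_b) && fr_b$length >= w) {
        obs <- plant_offsets(k_bg_b, fr_b$length, w, taken_b[[rb]])
        taken_b[[rb]] <- c(taken_b[[rb]], obs)
        tfb <- sample(names(pwms), length(obs), replace = TRUE)
        for (i in seq_along(obs)) {
          edits_b[[length(edits_b) + 1L]] <-
            plant_edit(fr_b, obs[i], consensus[tfb[i]])
          add_rec(species = "B", gene_id = fr_b$gene_id, kind = fr_b$kind,
                  index = fr_b$index, tf = tfb[i], offset = obs[i],
                  conserved = FALSE)
        }
      }
    }
    if (length(edits_a))
      chars_a[unlist(lapply(edits_a, `[[`, "at"))] <-
        unlist(lapply(edits_a, `[[`, "chars"))
    if (length(edits_b))
      chars_b[unlist(lapply(edits_b, `[[`, "at"))] <-
        unlist(lapply(edits_b, `[[`, "chars"))
    list(pwms = pwms,
         planted = data.frame(rec, stringsAsFactors = FALSE))
  })

  genome_a <- genome("speciesA",
                     Biostrings::DNAStringSet(stats::setNames(
                       paste(chars_a, collapse = ""), "chrI")))
  genome_b <- genome("speciesB",
                     Biostrings::DNAStringSet(stats::setNames(
                       paste(chars_b, collapse = ""), "chrI")))
  conv <- conventional_table(genes_a)
  structure(list(
    config = cfg,
    genome_a = genome_a, genome_b = genome_b,
    genes_a = genes_a, genes_b = genes_b,
    orthologs = data.frame(gene_a = ids_a, gene_b = ids_b,
                           stringsAsFactors = FALSE),
    pwms = mt$pwms,
    truth = list(conventional = conv,
                 planted_motifs = mt$planted,
                 structure_violation = data.frame(
                   gene_a = ids_a, violated = stb$violated,
                   merged_exon = stb$merged_at, stringsAsFactors = FALSE))),
    class = "intron_sim")
}

#' @export
print.intron_sim <- function(x, ...) {
  cat(sprintf("intron_sim: %d gene pairs, seed %d\n", x$config$n_genes,
              x$config$seed))
  invisible(x)
}

#' Simulate ChIP peaks over a synthetic genome
#'
#' Binding events are planted per fragment at class-specific Poisson rates
#' (positions uniform within the fragment, TFs uniform over the pool),
#' peaks are centred on the event position plus Gaussian midpoint jitter,
#' and uniform background peaks are added genome-wide. Species A only.
#'
#' @param sim An [sim_genome_pair] result.
#' @param jitter,background_per_kb Optional overrides of the config values.
#' @return List: `peaks` (data.frame as [chip_peaks]) and `truth`
#'   (per-fragment planted distinct-TF counts).
#' @export
simulate_chip_peaks <- function(sim, jitter = NULL,
                                background_per_kb = NULL) {
  cfg <- sim$config
  jitter <- jitter %||% cfg$chip_jitter
  bg_per_kb <- background_per_kb %||% cfg$chip_background_per_kb
  w <- cfg$chip_peak_width
  frags <- gene_fragments(sim$genes_a, genome = NULL)
  chrom_len <- Biostrings::width(sim$genome_a$seqs)[1]
  rate_of <- c(promoter = cfg$chip_rate_promoter,
               first_intron = cfg$chip_rate_first,
               other_intron = cfg$chip_rate_other,
               exon = cfg$chip_rate_exon)
  with_seed(child_seed(cfg$seed, "peaks"), {
    cls <- region_class(frags$kind, frags$index)
    k <- stats::rpois(nrow(frags), rate_of[cls] * (frags$length > 0))
    rows <- list(); tf_truth <- vector("list", nrow(frags))
    for (i in which(k > 0L)) {
      pos <- frags$start[i] + sample.int(frags$length[i], k[i],
                                         replace = TRUE) - 1L
      tfs <- sprintf("TF%03d", sample.int(cfg$n_tfs, k[i], replace = TRUE))
      mid <- pos + round_half_up(stats::rnorm(k[i], 0, jitter))
      mid <- pmin(pmax(mid, w %/% 2L), chrom_len - w + w %/% 2L - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        tf_id = tfs, chrom = frags$chrom[i], start = mid - w %/% 2L,
        stringsAsFactors = FALSE)
      tf_truth[[i]] <- unique(tfs)
    }
    n_bg <- round_half_up(bg_per_kb * chrom_len / 1000)
    if (n_bg > 0) {
      mid <- sample.int(chrom_len - w, n_bg) + w %/% 2L - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        tf_id = sprintf("TF%03d", sample.int(cfg$n_tfs, n_bg,
                                             replace = TRUE)),
        chrom = "chrI", start = mid - w %/% 2L, stringsAsFactors = FALSE)
    }
    pk <- do.call(rbind, rows)
    truth <- frags[, c("gene_id", "kind", "index")]
    truth$n_planted_tfs <- vapply(tf_truth, length, integer(1))
    list(peaks = chip_peaks(pk$tf_id, pk$chrom, pk$start, pk$start + w),
         truth = truth)
  })
}

#' Simulate a PDI network and co-expression scores
#'
#' Per-gene promoter in-degree is `round(Exp(lambda_promoter))` and
#' first-intron in-degree `round(Exp(lambda_intron))` (round half-up — the
#' discrete emulation of the continuous in-degree model); intron TF
#' identities re-use a promoter TF with probability `overlap_rho`.
#' Co-expression per gene pair is `clip(alpha * J_combined +
#' Normal(0, sigma), -1, 1)` where `J_combined` is the Jaccard similarity
#' of the pooled TF sets.
#'
#' @param gene_ids Genes to include (default `hd01`..`hd24`, emulating a
#'   24-gene family panel).
#' @param cfg A [sim_config].
#' @param with_coexpression Also generate pairwise co-expression scores
#'   (quadratic in the number of genes; disable for large panels).
#' @return List: `edges` (tf/gene/region_kind), `coexpression`
#'   (gene_a/gene_b/score, NULL when disabled), `truth` (drawn in-degrees
#'   and true combined Jaccard per pair).
#' @export
simulate_pdi_network <- function(gene_ids = sprintf("hd%02d", 1:24),
                                 cfg = sim_config(),
                                 with_coexpression = TRUE) {
  n <- length(gene_ids)
  net <- with_seed(child_seed(cfg$seed, "pdi"), {
    tf_v <- list(); gene_v <- list(); kind_v <- list()
    deg <- data.frame(gene = gene_ids, promoter = 0L, intron = 0L)
    sets <- list()
    for (g in seq_len(n)) {
      dp <- min(round_half_up(stats::rexp(1, cfg$lambda_promoter)),
                cfg$n_tfs)
      di <- round_half_up(stats::rexp(1, cfg$lambda_intron))
      tp <- if (dp > 0) sprintf("TF%03d", sample.int(cfg$n_tfs, dp)) else
        character(0)
      ti <- character(0)
      for (j in seq_len(di)) {
        ti <- c(ti, if (stats::runif(1) < cfg$overlap_rho && length(tp))
          sample(tp, 1L) else sprintf("TF%03d", sample.int(cfg$n_tfs, 1L)))
      }
      ti <- unique(ti)
      deg$promoter[g] <- dp; deg$intron[g] <- di
      sets[[gene_ids[g]]] <- list(promoter = tp, intron = ti)
      k <- length(tf_v) + 1L
      tf_v[[k]] <- c(tp, ti)
      gene_v[[k]] <- rep(gene_ids[g], length(tp) + length(ti))
      kind_v[[k]] <- c(rep("promoter", length(tp)),
                       rep("first_intron", length(ti)))
    }
    list(edges = data.frame(tf = unlist(tf_v) %||% character(0),
                            gene = unlist(gene_v) %||% character(0),
                            region_kind = unlist(kind_v) %||% character(0),
                            stringsAsFactors = FALSE),
         degrees = deg, sets = sets)
  })
  coexp <- NULL
  if (with_coexpression) {
    coexp <- with_seed(child_seed(cfg$seed, "coexpression"), {
      np <- (n * (n - 1L)) %/% 2L
      ga <- gb <- character(np); J <- numeric(np)
      k <- 0L
      pooled <- lapply(net$sets, function(s) unique(c(s$promoter,
                                                      s$intron)))
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        k <- k + 1L
        ga[k] <- gene_ids[i]; gb[k] <- gene_ids[j]
        J[k] <- jaccard_similarity(pooled[[gene_ids[i]]],
                                   pooled[[gene_ids[j]]])
      }
      score <- pmin(pmax(cfg$coexp_alpha * ifelse(is.na(J), 0, J) +
                           stats::rnorm(np, 0, cfg$coexp_sigma), -1), 1)
      data.frame(gene_a = ga, gene_b = gb, score = score,
                 jaccard_true = J, stringsAsFactors = FALSE)
    })
  }
  list(edges = net$edges,
       coexpression = if (!is.null(coexp))
         coexp[, c("gene_a", "gene_b", "score")],
       truth = list(degrees = net$degrees,
                    jaccard_combined = if (!is.null(coexp))
                      coexp[, c("gene_a", "gene_b", "jaccard_true")]))
}

# GRanges rows for one species' annotation
annotation_granges <- function(genes) {
  rows <- list()
  for (g in genes) {
    span <- coding_span(g)
    utr <- NULL
    if (g$utr5_introns > 0L) {
      # two 5'-UTR blocks separated by a gap encode one UTR intron
      if (g$strand == "+") {
        utr <- cbind(c(span[1] - 120L, span[1] - 40L),
                     c(span[1] - 90L, span[1]))
      } else {
        utr <- cbind(c(span[2], span[2] + 90L),
                     c(span[2] + 40L, span[2] + 120L))
      }
      utr[utr < 0L] <- 0L
    }
    lo <- if (is.null(utr)) span[1] else min(span[1], utr[, 1])
    hi <- if (is.null(utr)) span[2] else max(span[2], utr[, 2])
    mk <- function(type, s0, e0, id, parent = NA_character_, extra = list())
      c(list(chrom = g$chrom, start = s0 + 1L, end = e0, strand = g$strand,
             type = type, ID = id, Parent = parent,
             # exon lengths are codon multiples, so every CDS is in phase 0
             phase = if (type == "CDS") 0L else NA_integer_), extra)
    rows[[length(rows) + 1L]] <- mk("gene", lo, hi, g$gene_id, extra = list(
      operon_position = g$operon_position,
      alt_first_exons = g$alt_first_exons))
    mrna <- paste0(g$gene_id, ".t1")
    rows[[length(rows) + 1L]] <- mk("mRNA", lo, hi, mrna, g$gene_id)
    for (i in seq_len(nrow(g$exons)))
      rows[[length(rows) + 1L]] <- mk("CDS", g$exons[i, 1], g$exons[i, 2],
                                      sprintf("%s.cds%d", g$gene_id, i),
                                      mrna)
    if (!is.null(utr)) for (i in seq_len(nrow(utr)))
      rows[[length(rows) + 1L]] <- mk("five_prime_UTR", utr[i, 1],
                                      utr[i, 2],
                                      sprintf("%s.utr%d", g$gene_id, i),
                                      mrna)
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               strand = r$strand, type = r$type, ID = r$ID,
               Parent = r$Parent, phase = r$phase,
               operon_position = r$operon_position %||% NA_character_,
               alt_first_exons = r$alt_first_exons %||% NA_integer_,
               stringsAsFactors = FALSE)))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$phase <- df$phase
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(lapply(df$Parent, function(p)
    if (is.na(p)) character(0) else p))
  gr$operon_position <- df$operon_position
  gr$alt_first_exons <- df$alt_first_exons
  gr
}

#' Write all synthetic inputs to a directory
#'
#' Emits per species a FASTA and GFF3, the ortholog TSV, the PWM set (TSV
#' and MEME minimal), and the ground truth as JSON.
#'
#' @param sim An [sim_genome_pair] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta_a = file.path(dir, "species_a.fa"),
    gff_a = file.path(dir, "species_a.gff3"),
    fasta_b = file.path(dir, "species_b.fa"),
    gff_b = file.path(dir, "species_b.gff3"),
    orthologs = file.path(dir, "orthologs.tsv"),
    pwms_tsv = file.path(dir, "pwms.tsv"),
    pwms_meme = file.path(dir, "pwms.meme"),
    truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(sim$genome_a$seqs, paths$fasta_a)
  Biostrings::writeXStringSet(sim$genome_b$seqs, paths$fasta_b)
  rtracklayer::export(annotation_granges(sim$genes_a), paths$gff_a,
                      format = "gff3")
  rtracklayer::export(annotation_granges(sim$genes_b), paths$gff_b,
                      format = "gff3")
  write_ortholog_pairs(sim$orthologs, paths$orthologs)
  write_pwms_tsv(sim$pwms, paths$pwms_tsv)
  write_pwms_meme(sim$pwms, paths$pwms_meme)
  jsonlite::write_json(sim$truth, paths$truth, dataframe = "columns",
                       na = "null")
  invisible(paths)
}

#' Write PWMs in MEME minimal format
#' @param pwms Named list of [pwm] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pwms_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$tf_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       p$width), con)
    for (i in seq_len(p$width))
      writeLines(paste(sprintf("%.6f", p$matrix[i, ]), collapse = " "),
                 con)
    writeLines("", con)
  }
  invisible(path)
}
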