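# End-to-end orchestration: classify -> fragments -> conservation -> scan
# -> chip -> pdi -> degree, with per-stage outputs and a summary JSON that
# echoes every threshold used (auditability).

#' Pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Seed routed to every random component.
#' @param simulate Generate inputs with the synthetic module instead of
#'   reading them from paths.
#' @param sim A [sim_config] used when `simulate = TRUE` (its seed is
#'   overridden by `seed`).
#' @param gff3_a,fasta_a,gff3_b,fasta_b,orthologs,pwms,chip_bed,pdi,coexpression
#'   Input paths used when `simulate = FALSE`.
#' @param stages Character vector of stages to run, a subset of
#'   `classify`, `conserve`, `scan`, `chip`, `pdi`, `degree`.
#' @param promoter_span Promoter cap in bp.
#' @param conservation_min_len Intron length-conservation cutoff (bp).
#' @param long_intron_cutoff First-intron length defining the "long"
#'   selection for family enrichment (bp).
#' @param occupancy_threshold Motif occupancy call threshold.
#' @param j_cut PDI-similarity cut.
#' @param coexp_cuts Two co-expression cuts.
#' @param projection_bins Upper bin edges for the genome projection.
#' @param min_align_score Exon alignment score threshold.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("introntf_"), seed = 1L,
                            simulate = TRUE, sim = NULL,
                            gff3_a = NULL, fasta_a = NULL,
                            gff3_b = NULL, fasta_b = NULL,
                            orthologs = NULL, pwms = NULL,
                            chip_bed = NULL, pdi = NULL,
                            coexpression = NULL,
                            stages = c("classify", "conserve", "scan",
                                       "chip", "pdi", "degree"),
                            promoter_span = 2000L,
                            conservation_min_len = 500L,
                            long_intron_cutoff = 250L,
                            occupancy_threshold = 0.09,
                            j_cut = 0.3, coexp_cuts = c(0.2, 0.5),
                            projection_bins = c(64, 128, 256, 512),
                            min_align_score = 50) {
  stopifnot(promoter_span > 0, conservation_min_len > 0,
            long_intron_cutoff > 0, occupancy_threshold > 0,
            occupancy_threshold < 1, all(diff(projection_bins) > 0))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the first-intron analysis pipeline
#'
#' Runs the selected stages in order, writes per-stage TSV/JSON outputs
#' under `config$out_dir`, and finishes with `summary.json` echoing the
#' configuration (thresholds and seed). A stage failure stops with an
#' error naming the stage; outputs of completed stages are preserved.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a named list with each stage's results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  run_stage <- function(name, expr) {
    stage_log(name, "running")
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## inputs
  if (config$simulate) {
    scfg <- config$sim %||% sim_config()
    scfg$seed <- config$seed
    sim <- run_stage("simulate", {
      s <- sim_genome_pair(scfg)
      write_sim(s, file.path(config$out_dir, "inputs"))
      s
    })
    genes_a <- sim$genes_a; genome_a <- sim$genome_a
    genes_b <- sim$genes_b; genome_b <- sim$genome_b
    orthologs <- sim$orthologs
    ems <- lapply(sim$pwms, pwm_to_energy,
                  threshold = config$occupancy_threshold)
    chip <- simulate_chip_peaks(sim)$peaks
    pdi_sim <- simulate_pdi_network(cfg = scfg)
    pdi_edges <- pdi_sim$edges
    coexp <- pdi_sim$coexpression
    res$sim <- sim
  } else {
    for (p in c("gff3_a", "fasta_a")) if (is.null(config[[p]]) ||
                                          !file.exists(config[[p]]))
      stop(sprintf("input '%s' missing: %s", p, config[[p]] %||% "<unset>"))
    ann_a <- run_stage("annotation", load_annotation(config$gff3_a,
                                                     config$fasta_a, "A"))
    genes_a <- ann_a$genes; genome_a <- ann_a$genome
    genes_b <- NULL; genome_b <- NULL; orthologs <- NULL
    if (!is.null(config$gff3_b)) {
      ann_b <- run_stage("annotation", load_annotation(config$gff3_b,
                                                       config$fasta_b, "B"))
      genes_b <- ann_b$genes; genome_b <- ann_b$genome
      orthologs <- read_ortholog_pairs(config$orthologs)
    }
    ems <- NULL
    if ("scan" %in% config$stages) {
      if (is.null(config$pwms) || !file.exists(config$pwms))
        stop(sprintf("PWM file missing: %s", config$pwms %||% "<unset>"))
      pw <- if (grepl("\\.meme$", config$pwms))
        read_pwms_meme(config$pwms) else read_pwms_tsv(config$pwms)
      ems <- lapply(pw, pwm_to_energy,
                    threshold = config$occupancy_threshold)
    }
    chip <- if (!is.null(config$chip_bed)) read_chip_peaks(config$chip_bed)
    pdi_edges <- if (!is.null(config$pdi)) read_pdi_tsv(config$pdi)
    coexp <- if (!is.null(config$coexpression))
      read_coexpression_tsv(config$coexpression)
  }

  ## classify + fragments
  conv <- run_stage("classify", conventional_table(genes_a))
  utils::write.table(conv, file.path(config$out_dir, "conventional.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  frags <- run_stage("fragments",
                     gene_fragments(genes_a, genome_a,
                                    config$promoter_span))
  conv_genes <- conv$gene_id[conv$is_conventional]
  frags_conv <- frags[frags$gene_id %in% conv_genes, , drop = FALSE]
  write_fragments_bed(frags, file.path(config$out_dir, "fragments.bed"))
  res$conventional <- conv
  res$fragments <- frags

  first_introns <- frags_conv[frags_conv$kind == "intron" &
                                frags_conv$index == 1L, , drop = FALSE]

  ## conservation
  if ("conserve" %in% config$stages && !is.null(genes_b)) {
    res$conservation <- run_stage("conserve", {
      pr <- orthologs[orthologs$gene_a %in% conv_genes, , drop = FALSE]
      cc <- conservation_comparison(pr, genes_a, genes_b, genome_a,
                                    genome_b,
                                    min_len = config$conservation_min_len,
                                    min_score = config$min_align_score,
                                    random_null = TRUE,
                                    null_seed = child_seed(config$seed,
                                                           "pipeline"))
      utils::write.table(cc$records,
                         file.path(config$out_dir,
                                   "conservation_records.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(cc$summary,
                           file.path(config$out_dir,
                                     "conservation_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      cc
    })
  }

  ## motif scanning / conserved predicted interactions
  if ("scan" %in% config$stages && !is.null(ems)) {
    res$scan <- run_stage("scan", {
      idg <- res$conservation$identical_structure_genes %||% character(0)
      if (length(idg)) {
        frag_a <- gene_fragments(genes_a[idg], genome_a,
                                 config$promoter_span)
        map <- stats::setNames(orthologs$gene_b, orthologs$gene_a)
        frag_b <- gene_fragments(genes_b[unname(map[idg])], genome_b,
                                 config$promoter_span)
        key_b <- paste(frag_b$gene_id, frag_b$kind, frag_b$index)
        pair_key <- paste(unname(map[frag_a$gene_id]), frag_a$kind,
                          frag_a$index)
        m <- match(pair_key, key_b)
        fp <- data.frame(gene_a = frag_a$gene_id, kind = frag_a$kind,
                         index = frag_a$index, seq_a = frag_a$seq,
                         seq_b = frag_b$seq[m], stringsAsFactors = FALSE)
        fp <- fp[!is.na(fp$seq_b), , drop = FALSE]
        mc <- mean_conserved_by_region(fp, ems)
        utils::write.table(mc$per_class,
                           file.path(config$out_dir,
                                     "conserved_predicted.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        mc
      } else list(per_class = NULL, note = "no identical-structure genes")
    })
  }

  ## chip assignment
  if ("chip" %in% config$stages && !is.null(chip)) {
    res$chip <- run_stage("chip", {
      asg <- assign_peaks(chip, frags_conv)
      write_assignments_tsv(asg, file.path(config$out_dir,
                                           "chip_assignments.tsv"))
      summ <- region_binding_summary(asg)
      fi <- asg[asg$kind == "intron" & asg$index == 1L & asg$length > 0, ]
      corr <- if (nrow(fi) >= 3L)
        length_binding_correlation(fi$length, fi$n_tfs) else NULL
      prom <- asg[asg$kind == "promoter", ]
      key <- match(fi$gene_id, prom$gene_id)
      oi <- promoter_intron_overlap(prom$tfs[key], fi$tfs)
      list(assignments = asg, summary = summ, correlation = corr,
           oi = data.frame(gene_id = fi$gene_id, oi = oi))
    })
  }

  ## pdi network statistics
  if ("pdi" %in% config$stages && !is.null(pdi_edges)) {
    res$pdi <- run_stage("pdi", {
      net <- pdi_network(pdi_edges,
                         if (config$simulate) "synthetic" else "input")
      genes <- sort(unique(net$edges$gene))
      out <- list(network = net)
      for (mode in c("promoter", "intron", "combined")) {
        st <- similarity_table(net, genes, mode, coexp)
        out[[paste0("similarity_", mode)]] <- st
        out[[paste0("enrichment_", mode)]] <-
          coexpression_enrichment(st, config$j_cut, config$coexp_cuts)
      }
      if (nrow(first_introns)) {
        screened <- tf_sets(net, mode = "intron")
        sg <- intersect(names(screened), first_introns$gene_id)
        if (length(sg) >= 5L) {
          sl <- first_introns$length[match(sg, first_introns$gene_id)]
          cnt <- lengths(screened[sg])
          out$projection <- genome_projection(sl, cnt,
                                              first_introns$length,
                                              config$projection_bins)
        }
      }
      out
    })
  }

  ## degree models
  if ("degree" %in% config$stages && !is.null(pdi_edges)) {
    res$degree <- run_stage("degree", {
      net <- pdi_network(pdi_edges, "any")
      gp <- tf_sets(net, mode = "promoter")
      gi <- tf_sets(net, mode = "intron")
      genes <- sort(union(names(gp), names(gi)))
      dp <- lengths(gp[genes]); dp[is.na(names(gp[genes]))] <- 0L
      di <- lengths(gi[genes])
      cmp <- compare_degree_models(unname(dp), unname(di))
      jsonlite::write_json(
        cmp[c("hypoexp_rates", "predicted_mean", "observed_mean",
              "loglik_hypoexp", "loglik_exponential", "ks_hypoexp",
              "ks_exponential", "winner")],
        file.path(config$out_dir, "degree_models.json"),
        auto_unbox = TRUE, digits = NA)
      cmp
    })
  }

  echo <- config[c("seed", "stages", "promoter_span",
                   "conservation_min_len", "long_intron_cutoff",
                   "occupancy_threshold", "j_cut", "coexp_cuts",
                   "projection_bins", "min_align_score", "simulate")]
  jsonlite::write_json(echo, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log("pipeline", "done: ", config$out_dir)
  invisible(res)
}
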