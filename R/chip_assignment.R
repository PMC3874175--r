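# Assignment of ChIP peak midpoints to gene fragments and per-region
# binding statistics. A peak is represented by its midpoint
# floor((start + end)/2); it is assigned to every fragment (across all
# genes) whose half-open interval contains the midpoint, and per fragment
# the number of DISTINCT TFs is counted.

#' Build a ChIP peak table
#'
#' @param tf_id TF labels.
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open peak intervals.
#' @return Data.frame with a `midpoint` column (`floor((start + end)/2)`,
#'   so even-length peaks round down).
#' @export
chip_peaks <- function(tf_id, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("peak intervals must satisfy start < end")
  data.frame(tf_id = tf_id, chrom = chrom, start = start, end = end,
             midpoint = as.integer((start + end) %/% 2L),
             stringsAsFactors = FALSE)
}

#' Read ChIP peaks from BED
#'
#' Column 4 carries the TF name. `dialect = "bed"` is the standard 0-based
#' half-open BED; `dialect = "one_based"` treats coordinates as 1-based
#' closed (as some peak exports do) and shifts the start.
#'
#' @param path BED file.
#' @param dialect `"bed"` or `"one_based"`.
#' @return Peak data.frame as from [chip_peaks].
#' @export
read_chip_peaks <- function(path, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (dialect == "one_based") {
    # file columns were 1-based closed [s, e]: import read them as BED, so
    # start(gr) = s + 1 while the true 0-based start is s - 1
    start0 <- start0 - 1L
  }
  chip_peaks(as.character(gr$name), as.character(GenomicRanges::seqnames(gr)),
             start0, end0)
}

#' Assign peak midpoints to fragments
#'
#' @param peaks Peak data.frame ([chip_peaks]).
#' @param fragments Fragment data.frame ([gene_fragments]).
#' @return `fragments` with list-column `tfs` (distinct TFs whose peak
#'   midpoints fall inside the fragment) and integer column `n_tfs`.
#'   Peaks on chromosomes absent from the fragment table are skipped with
#'   a logged count.
#' @export
assign_peaks <- function(peaks, fragments) {
  known <- unique(fragments$chrom)
  drop <- !(peaks$chrom %in% known)
  if (any(drop))
    stage_log("chip", sum(drop), " peak(s) on unknown chromosomes skipped")
  peaks <- peaks[!drop, , drop = FALSE]
  frag_gr <- GenomicRanges::GRanges(
    fragments$chrom, IRanges::IRanges(fragments$start + 1L, fragments$end))
  mid_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$midpoint + 1L, peaks$midpoint + 1L))
  ov <- GenomicRanges::findOverlaps(mid_gr, frag_gr)
  tfs_by_frag <- split(peaks$tf_id[S4Vectors::queryHits(ov)],
                       S4Vectors::subjectHits(ov))
  out <- fragments
  out$tfs <- replicate(nrow(out), character(0), simplify = FALSE)
  idx <- as.integer(names(tfs_by_frag))
  out$tfs[idx] <- lapply(tfs_by_frag, function(x) sort(unique(x)))
  out$n_tfs <- vapply(out$tfs, length, integer(1))
  out
}

#' Per-region summary of TF binding
#'
#' @param assignments Output of [assign_peaks].
#' @param exclude_zero_length Drop zero-length (degenerate) fragments from
#'   the statistics (default TRUE, with a logged count).
#' @return List with `per_class` (region class, mean, sem, n of distinct-TF
#'   counts) and `first_vs_other_ratio`.
#' @export
region_binding_summary <- function(assignments, exclude_zero_length = TRUE) {
  a <- assignments
  if (exclude_zero_length) {
    nz <- a$length > 0L
    if (any(!nz)) stage_log("chip", sum(!nz),
                            " zero-length fragment(s) excluded")
    a <- a[nz, , drop = FALSE]
  }
  cls <- region_class(a$kind, a$index)
  per_class <- do.call(rbind, lapply(split(a$n_tfs, cls), function(x)
    data.frame(mean = mean(x), sem = sem(x), n = length(x))))
  per_class <- cbind(class = rownames(per_class), per_class)
  rownames(per_class) <- NULL
  mf <- per_class$mean[per_class$class == "first_intron"]
  mo <- per_class$mean[per_class$class == "other_intron"]
  list(per_class = per_class,
       first_vs_other_ratio = if (length(mf) && length(mo) && mo > 0)
         mf / mo else NA_real_)
}

#' Correlation between first-intron length and TF count
#'
#' @param lengths First-intron lengths (bp).
#' @param counts Distinct-TF counts per intron.
#' @return Data.frame with Pearson r on raw and log10 length, Spearman rho,
#'   and two-sided p-values; statistics are NA with a note when a variable
#'   has zero variance.
#' @export
length_binding_correlation <- function(lengths, counts) {
  stopifnot(length(lengths) == length(counts))
  if (length(lengths) < 3L) stop("need at least 3 introns")
  run <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(est = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    c(est = unname(ct$estimate), p = ct$p.value)
  }
  pe <- run(lengths, counts, "pearson")
  pl <- run(log10(lengths), counts, "pearson")
  sp <- run(lengths, counts, "spearman")
  data.frame(statistic = c("pearson_r", "pearson_r_log10", "spearman_rho"),
             estimate = c(pe["est"], pl["est"], sp["est"]),
             p_value = c(pe["p"], pl["p"], sp["p"]),
             n = length(lengths), row.names = NULL)
}

#' Promoter/first-intron overlap fraction (O/I)
#'
#' @param promoter_tfs,intron_tfs Character vectors (TF sets) or lists of
#'   such vectors for per-gene vectorised use.
#' @return `|promoter ∩ intron| / |intron|`, or NA when the intron set is
#'   empty (such genes are excluded from O/I histograms).
#' @export
promoter_intron_overlap <- function(promoter_tfs, intron_tfs) {
  one <- function(p, i) {
    i <- unique(i); p <- unique(p)
    if (!length(i)) return(NA_real_)
    length(intersect(p, i)) / length(i)
  }
  if (is.list(promoter_tfs) || is.list(intron_tfs)) {
    mapply(one, promoter_tfs, intron_tfs)
  } else one(promoter_tfs, intron_tfs)
}

#' Write peak-to-fragment assignments as TSV
#' @param assignments Output of [assign_peaks].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assignments_tsv <- function(assignments, path) {
  df <- assignments[, c("gene_id", "kind", "index", "n_tfs")]
  df$tfs <- vapply(assignments$tfs, paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
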