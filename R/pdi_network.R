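# Gene-centered protein-DNA interaction (PDI) network statistics:
# in-degree bookkeeping, Jaccard PDI similarity vs co-expression, the
# genome-wide projection of screen results, and gene-family enrichment.

PDI_KINDS <- c("promoter", "first_intron")

#' Construct a PDI network
#'
#' @param edges Data.frame with columns `tf`, `gene`, `region_kind`
#'   (`promoter` or `first_intron`).
#' @param provenance Label for the data source (eY1H/ChIP/synthetic).
#' @return Object of class `pdi_network` (deduplicated edge set).
#' @export
pdi_network <- function(edges, provenance = "unknown") {
  stopifnot(all(c("tf", "gene", "region_kind") %in% names(edges)))
  if (!all(edges$region_kind %in% PDI_KINDS))
    stop("region_kind must be one of: ", paste(PDI_KINDS, collapse = ", "))
  edges <- unique(edges[, c("tf", "gene", "region_kind")])
  structure(list(edges = edges, provenance = provenance),
            class = "pdi_network")
}

#' @export
print.pdi_network <- function(x, ...) {
  cat(sprintf("pdi_network (%s): %d edges, %d TFs, %d genes\n",
              x$provenance, nrow(x$edges), length(unique(x$edges$tf)),
              length(unique(x$edges$gene))))
  invisible(x)
}

#' Per-gene TF sets from a PDI network
#'
#' @param network A [pdi_network].
#' @param genes Genes to report (default: all in the network).
#' @param mode `"promoter"`, `"intron"`, or `"combined"` (TF sets pooled
#'   across both region kinds before any similarity computation).
#' @return Named list of character TF sets (possibly empty).
#' @export
tf_sets <- function(network, genes = NULL,
                    mode = c("combined", "promoter", "intron")) {
  mode <- match.arg(mode)
  e <- network$edges
  e <- switch(mode,
              promoter = e[e$region_kind == "promoter", ],
              intron = e[e$region_kind == "first_intron", ],
              combined = e)
  genes <- genes %||% sort(unique(network$edges$gene))
  sets <- split(e$tf, factor(e$gene, levels = genes))
  lapply(sets, function(x) sort(unique(x)))
}

#' Jaccard PDI similarity between two TF sets
#'
#' @param set_a,set_b Character vectors of TF ids.
#' @return `|A ∩ B| / |A ∪ B|`; NA when both sets are empty (undefined).
#' @export
jaccard_similarity <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (!length(a) && !length(b)) return(NA_real_)
  ni <- length(intersect(a, b))
  nu <- length(union(a, b))
  stopifnot(nu == length(a) + length(b) - ni)  # union/intersection identity
  ni / nu
}

#' Pairwise PDI similarity + co-expression table
#'
#' One record per unordered gene pair; in `combined` mode the TF sets are
#' pooled across promoter and first intron before the Jaccard computation
#' (so combined similarity is not a function of the two per-region indices).
#'
#' @param network A [pdi_network].
#' @param genes Character vector of genes to pair.
#' @param mode Similarity mode, see [tf_sets].
#' @param coexpression Optional data.frame `gene_a`, `gene_b`, `score`;
#'   missing pairs are flagged with NA.
#' @return Data.frame `gene_a`, `gene_b`, `jaccard`, `coexpression`.
#' @export
similarity_table <- function(network, genes,
                             mode = c("combined", "promoter", "intron"),
                             coexpression = NULL) {
  mode <- match.arg(mode)
  sets <- tf_sets(network, genes, mode)
  cx <- NULL
  if (!is.null(coexpression)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    cx <- stats::setNames(coexpression$score,
                          key(coexpression$gene_a, coexpression$gene_b))
  }
  n <- length(genes)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k + 1L
    sc <- if (!is.null(cx))
      unname(cx[paste(pmin(genes[i], genes[j]), pmax(genes[i], genes[j]),
                      sep = "\r")]) else NA_real_
    rows[[k]] <- data.frame(
      gene_a = genes[i], gene_b = genes[j],
      jaccard = jaccard_similarity(sets[[genes[i]]], sets[[genes[j]]]),
      coexpression = sc, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Co-expression enrichment across PDI-similarity bins
#'
#' Gene pairs are split into low/high PDI similarity at `j_cut` and into
#' low/medium/high co-expression at `coexp_cuts`. The primary p-value is a
#' 2x2 Fisher's exact test of medium+high vs low co-expression between the
#' two similarity bins; the full 2x3 exact (Freeman-Halton) p is also
#' reported. Pairs with undefined similarity or missing co-expression are
#' excluded with logged counts.
#'
#' @param records Output of [similarity_table].
#' @param j_cut Similarity cut (default 0.3; high is `J >= j_cut`).
#' @param coexp_cuts Two co-expression cuts (default `c(0.2, 0.5)`).
#' @return List with the 2x3 `table`, `p_2x2`, `p_2x3`, and exclusion
#'   counts.
#' @export
coexpression_enrichment <- function(records, j_cut = 0.3,
                                    coexp_cuts = c(0.2, 0.5)) {
  stopifnot(length(coexp_cuts) == 2L, coexp_cuts[1] < coexp_cuts[2])
  n_undef <- sum(is.na(records$jaccard))
  n_nocx <- sum(is.na(records$coexpression) & !is.na(records$jaccard))
  if (n_undef) stage_log("pdi", n_undef, " pair(s) with undefined J excluded")
  if (n_nocx) stage_log("pdi", n_nocx, " pair(s) without co-expression excluded")
  r <- records[!is.na(records$jaccard) & !is.na(records$coexpression), ]
  jbin <- factor(ifelse(r$jaccard >= j_cut, "high_J", "low_J"),
                 levels = c("low_J", "high_J"))
  cbin <- cut(r$coexpression, c(-Inf, coexp_cuts, Inf),
              labels = c("low", "medium", "high"), right = FALSE)
  tab <- table(jbin, cbin)
  collapsed <- cbind(low = tab[, "low"],
                     med_high = tab[, "medium"] + tab[, "high"])
  p22 <- if (all(rowSums(collapsed) > 0) && all(colSums(collapsed) > 0))
    stats::fisher.test(collapsed)$p.value else NA_real_
  p23 <- if (all(rowSums(tab) > 0) && sum(colSums(tab) > 0) >= 2)
    stats::fisher.test(tab)$p.value else NA_real_
  list(table = tab, p_2x2 = p22, p_2x3 = p23,
       n_pairs = nrow(r), n_undefined_J = n_undef,
       n_missing_coexpression = n_nocx)
}

#' Project screen statistics to the genome by first-intron length bins
#'
#' The screened introns are binned by length, per-bin fraction-bound and
#' mean interaction counts are computed, and the genome-wide expectation is
#' the weighted average with weights equal to the genome-wide bin
#' occupancy.
#'
#' @param screen_lengths,screen_counts First-intron lengths and distinct-TF
#'   counts for the screened genes.
#' @param genome_lengths Genome-wide first-intron lengths of the projection
#'   universe (conventional genes).
#' @param bin_upper Upper edges of the length bins; the defaults give the
#'   screening bins `<65, 65-128, 129-256, 257-512, >512`.
#' @return List with `per_bin` data.frame, `projected_fraction_bound`,
#'   `projected_mean_interactions`, and `partial` (TRUE when a bin with
#'   genome-wide mass has no screened intron; flagged bins are dropped from
#'   the weighted average and the weights renormalised).
#' @export
genome_projection <- function(screen_lengths, screen_counts, genome_lengths,
                              bin_upper = c(64, 128, 256, 512)) {
  stopifnot(length(screen_lengths) == length(screen_counts),
            all(diff(bin_upper) > 0))
  brk <- c(-Inf, bin_upper, Inf)
  labs <- c(sprintf("<%d", bin_upper[1] + 1),
            sprintf("%d-%d", bin_upper[-length(bin_upper)] + 1,
                    bin_upper[-1]),
            sprintf(">%d", bin_upper[length(bin_upper)]))
  sbin <- cut(screen_lengths, brk, labels = labs)
  gbin <- cut(genome_lengths, brk, labels = labs)
  weight <- as.numeric(table(gbin)) / length(genome_lengths)
  per_bin <- data.frame(
    bin = labs, genome_weight = weight,
    n_screened = as.integer(table(sbin)),
    frac_bound = vapply(labs, function(b) {
      x <- screen_counts[sbin == b]
      if (length(x)) mean(x > 0) else NA_real_
    }, numeric(1)),
    mean_interactions = vapply(labs, function(b) {
      x <- screen_counts[sbin == b]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1)),
    row.names = NULL)
  flagged <- per_bin$genome_weight > 0 & per_bin$n_screened == 0L
  use <- per_bin$n_screened > 0L
  w <- per_bin$genome_weight[use] / sum(per_bin$genome_weight[use])
  list(per_bin = per_bin,
       projected_fraction_bound = sum(w * per_bin$frac_bound[use]),
       projected_mean_interactions = sum(w * per_bin$mean_interactions[use]),
       partial = any(flagged))
}

#' Gene-family enrichment among genes with long first introns
#'
#' One-sided hypergeometric test per family with Benjamini-Hochberg
#' correction across families, the generic analogue of a functional
#' annotation enrichment of the long-first-intron gene set.
#'
#' @param selection Character vector of selected genes (e.g. first intron
#'   longer than 250 bp).
#' @param families Named list: family id -> character vector of member
#'   genes.
#' @param universe All genes under consideration.
#' @return Data.frame sorted by q: family, family size, selection size,
#'   overlap, hypergeometric `p`, BH `q`.
#' @export
family_enrichment <- function(selection, families, universe) {
  selection <- intersect(unique(selection), universe)
  N <- length(unique(universe))
  n <- length(selection)
  rows <- lapply(names(families), function(f) {
    fam <- intersect(unique(families[[f]]), universe)
    k <- length(intersect(fam, selection))
    p <- stats::phyper(k - 1L, length(fam), N - length(fam), n,
                       lower.tail = FALSE)
    data.frame(family = f, family_size = length(fam), selection_size = n,
               overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$q, out$p), , drop = FALSE]
}

#' Screen bookkeeping
#'
#' Arithmetic of a gene-centered screen: removing auto-active/low-quality
#' baits, counting baits with at least one interaction, and the positive
#' rate over all bait-TF combinations tested.
#'
#' @param n_baits Baits constructed.
#' @param n_removed Baits removed (auto-active / low confidence).
#' @param n_zero Screened baits with no interaction.
#' @param n_interactions Positive interactions detected.
#' @param n_tested Bait-TF combinations tested.
#' @return List: `n_screened`, `n_bound`, `positive_rate_pct`.
#' @export
screen_bookkeeping <- function(n_baits, n_removed, n_zero, n_interactions,
                               n_tested) {
  stopifnot(is_count(n_baits), is_count(n_removed), is_count(n_zero))
  n_screened <- n_baits - n_removed
  list(n_screened = n_screened,
       n_bound = n_screened - n_zero,
       positive_rate_pct = 100 * n_interactions / n_tested)
}

#' Read PDI edges from TSV
#' @param path 3-column TSV `tf`, `gene`, `region_kind` (with header).
#' @return Data.frame of edges.
#' @export
read_pdi_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "gene", "region_kind") %in% names(df)))
  df
}

#' Read pairwise co-expression scores from TSV
#' @param path 3-column TSV `gene_a`, `gene_b`, `score` (with header).
#' @return Data.frame of scores.
#' @export
read_coexpression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(df)))
  df
}
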