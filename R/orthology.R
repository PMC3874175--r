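# Orthologous exon mapping by translated local alignment, and the
# cross-species intron length-conservation analysis.
#
# tBlastx-style comparison is done in-process: every coding exon of species
# A is scored against every coding exon of the species-B ortholog by the
# best of the 3x3 forward-frame translated Smith-Waterman local alignments
# (BLOSUM62, affine gaps). Reciprocal best hits above a score threshold
# define the exon correspondence; genes whose correspondence is the identity
# mapping over equal exon counts have "identical exon-intron structure" and
# enter the length-conservation comparison.

translate_frames <- function(dna) {
  n <- nchar(dna)
  out <- character(3L)
  for (f in 1:3) {
    len <- ((n - f + 1L) %/% 3L) * 3L
    if (len < 3L) next
    sub <- substr(dna, f, f + len - 1L)
    out[f] <- tryCatch(
      as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(sub)))),
      error = function(e)   # ambiguity codes: resolve fuzzy codons
        as.character(suppressWarnings(Biostrings::translate(
          Biostrings::DNAString(sub), if.fuzzy.codon = "solve"))))
  }
  out[nzchar(out)]
}

#' Score matrix of translated local alignments between two exon sets
#'
#' @param exons_a,exons_b Character vectors of exon sequences (coding
#'   strand, transcriptional order).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return Numeric matrix `length(exons_a) x length(exons_b)` of best
#'   3-frame x 3-frame local alignment scores (BLOSUM62).
#' @keywords internal
translated_score_matrix <- function(exons_a, exons_b, gap_opening = 11,
                                    gap_extension = 1) {
  na <- length(exons_a); nb <- length(exons_b)
  if (any(nchar(exons_a) < 3L) || any(nchar(exons_b) < 3L))
    warning("exon(s) shorter than one codon scored 0")
  aa_a <- lapply(exons_a, translate_frames)
  aa_b <- lapply(exons_b, translate_frames)
  S <- matrix(0, na, nb)
  flat_a <- unlist(aa_a); flat_b <- unlist(aa_b)
  if (!length(flat_a) || !length(flat_b)) return(S)
  idx_a <- rep(seq_len(na), lengths(aa_a))
  idx_b <- rep(seq_len(nb), lengths(aa_b))
  # one element-wise batch over the full frame x frame cross product
  ii <- rep(seq_along(flat_a), times = length(flat_b))
  jj <- rep(seq_along(flat_b), each = length(flat_a))
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(flat_a[ii]),
    Biostrings::AAStringSet(flat_b[jj]), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension, scoreOnly = TRUE)
  cell <- cbind(idx_a[ii], idx_b[jj])
  for (k in seq_along(sc))
    S[cell[k, 1L], cell[k, 2L]] <- max(S[cell[k, 1L], cell[k, 2L]], sc[k])
  S
}

#' Map orthologous exons between two genes by translated alignment
#'
#' Keeps exon pairs that are reciprocal best hits with score at or above
#' `min_score`; score ties are broken in favour of the smaller index
#' difference `|i - j|`, and unresolved ties void the one-to-one property.
#'
#' @param exons_a,exons_b Character vectors of exon sequences in
#'   transcriptional order.
#' @param min_score Minimum alignment score for a pair to be kept.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return A list of class `exon_correspondence`: `pairs` (data.frame
#'   `exon_a`, `exon_b`, `score`), `is_one_to_one`, `is_identical_structure`.
#' @export
align_exons_translated <- function(exons_a, exons_b, min_score = 50,
                                   gap_opening = 11, gap_extension = 1) {
  stopifnot(length(exons_a) >= 1L, length(exons_b) >= 1L)
  S <- translated_score_matrix(exons_a, exons_b, gap_opening, gap_extension)
  na <- nrow(S); nb <- ncol(S)
  pairs <- list(); ambiguous <- FALSE
  best_of <- function(scores, self, n_other) {
    m <- max(scores)
    cand <- which(scores == m)
    if (length(cand) > 1L) {
      d <- abs(cand - self)
      cand <- cand[d == min(d)]
      if (length(cand) > 1L) return(NA_integer_)  # unresolved tie
    }
    cand
  }
  for (i in seq_len(na)) {
    if (max(S[i, ]) < min_score) next
    j <- best_of(S[i, ], i, nb)
    if (is.na(j)) { ambiguous <- TRUE; next }
    i_back <- best_of(S[, j], j, na)
    if (is.na(i_back)) { ambiguous <- TRUE; next }
    if (i_back == i)
      pairs[[length(pairs) + 1L]] <- data.frame(exon_a = i, exon_b = j,
                                                score = S[i, j])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(exon_a = integer(0), exon_b = integer(0), score = numeric(0))
  one2one <- !ambiguous && nrow(pairs) > 0L &&
    !anyDuplicated(pairs$exon_a) && !anyDuplicated(pairs$exon_b) &&
    all(diff(pairs$exon_b[order(pairs$exon_a)]) > 0L)
  identical_structure <- one2one && na == nb && nrow(pairs) == na &&
    all(pairs$exon_a == pairs$exon_b)
  structure(list(pairs = pairs, is_one_to_one = one2one,
                 is_identical_structure = identical_structure,
                 score_matrix = S),
            class = "exon_correspondence")
}

#' Intron length-conservation ratio
#'
#' Ratio of the larger over the smaller of two orthologous intron lengths;
#' 1 means perfectly conserved length.
#'
#' @param len_a,len_b Positive intron lengths (vectorised).
#' @return Numeric ratio(s) >= 1.
#' @export
intron_length_ratio <- function(len_a, len_b) {
  if (any(len_a <= 0) || any(len_b <= 0))
    stop("intron lengths must be positive")
  pmax(len_a, len_b) / pmin(len_a, len_b)
}

# transcriptional-order intron lengths of a gene model
intron_lengths_tx <- function(gene) {
  ex <- gene$exons
  n <- nrow(ex)
  if (n < 2L) return(integer(0))
  lens <- ex[-1L, 1L] - ex[-n, 2L]
  if (gene$strand == "-") lens <- rev(lens)
  as.integer(lens)
}

#' Cross-species intron length-conservation comparison
#'
#' For each ortholog pair with identical exon-intron structure, builds one
#' length-ratio record per intron ordinal, drops introns at or below
#' `min_len` bp in both species, and compares the ratio distribution of
#' first introns against all other introns with a two-sided Mann-Whitney U
#' test. Optionally also builds a random-pair null by permuting the
#' species-B genes and recomputing first-intron ratios.
#'
#' @param pairs Data.frame with columns `gene_a`, `gene_b`.
#' @param genes_a,genes_b Named lists of [gene_model] objects.
#' @param genome_a,genome_b [genome] objects (needed for exon sequences).
#' @param min_len Conservation length cutoff in bp (default 500): an intron
#'   pair is kept when the larger of the two lengths exceeds it.
#' @param min_score Alignment score threshold passed to
#'   [align_exons_translated].
#' @param random_null Logical; also compute the permuted-pair null.
#' @param null_seed Seed for the permutation.
#' @return List with `records` (per-intron data.frame), `summary`
#'   (medians, n, U, p), `identical_structure_genes`, and optionally
#'   `null` (ratios + median).
#' @export
conservation_comparison <- function(pairs, genes_a, genes_b,
                                    genome_a, genome_b, min_len = 500L,
                                    min_score = 50, random_null = FALSE,
                                    null_seed = 1L) {
  exon_seqs <- function(gene, genome) {
    fr <- extract_fragments(gene, genome)
    fr <- fr[fr$kind == "exon", ]
    fr$seq[order(fr$index)]
  }
  ident <- logical(nrow(pairs))
  intron_tab <- list()
  for (k in seq_len(nrow(pairs))) {
    ga <- genes_a[[pairs$gene_a[k]]]
    gb <- genes_b[[pairs$gene_b[k]]]
    if (is.null(ga) || is.null(gb))
      stop(sprintf("ortholog pair %s/%s references unknown gene",
                   pairs$gene_a[k], pairs$gene_b[k]))
    corr <- align_exons_translated(exon_seqs(ga, genome_a),
                                   exon_seqs(gb, genome_b),
                                   min_score = min_score)
    ident[k] <- corr$is_identical_structure
    if (!ident[k]) next
    la <- intron_lengths_tx(ga)
    lb <- intron_lengths_tx(gb)
    if (!length(la)) next
    intron_tab[[length(intron_tab) + 1L]] <- data.frame(
      gene_a = ga$gene_id, gene_b = gb$gene_id,
      intron_index = seq_along(la), length_a = la, length_b = lb,
      stringsAsFactors = FALSE)
  }
  records <- if (length(intron_tab)) do.call(rbind, intron_tab) else
    data.frame(gene_a = character(0), gene_b = character(0),
               intron_index = integer(0), length_a = integer(0),
               length_b = integer(0))
  if (nrow(records)) {
    records$ratio <- intron_length_ratio(records$length_a, records$length_b)
    records$passes_filter <- pmax(records$length_a,
                                  records$length_b) > min_len
  } else {
    records$ratio <- numeric(0); records$passes_filter <- logical(0)
  }
  kept <- records[records$passes_filter, , drop = FALSE]
  first <- kept$ratio[kept$intron_index == 1L]
  other <- kept$ratio[kept$intron_index > 1L]
  test <- if (length(first) >= 2L && length(other) >= 2L)
    suppressWarnings(stats::wilcox.test(first, other,
                                        alternative = "two.sided"))
  else NULL
  out <- list(
    records = records,
    summary = list(
      n_pairs = nrow(pairs),
      n_identical_structure = sum(ident),
      n_records_kept = nrow(kept),
      n_first = length(first), n_other = length(other),
      median_first = if (length(first)) stats::median(first) else NA_real_,
      median_other = if (length(other)) stats::median(other) else NA_real_,
      U = if (!is.null(test)) unname(test$statistic) else NA_real_,
      p_value = if (!is.null(test)) test$p.value else NA_real_),
    identical_structure_genes = pairs$gene_a[ident])
  if (random_null) {
    first_len_a <- vapply(pairs$gene_a[ident], function(g)
      intron_lengths_tx(genes_a[[g]])[1L] %||% NA_integer_, integer(1))
    first_len_b <- vapply(pairs$gene_b[ident], function(g)
      intron_lengths_tx(genes_b[[g]])[1L] %||% NA_integer_, integer(1))
    ok <- !is.na(first_len_a) & !is.na(first_len_b)
    fa <- first_len_a[ok]; fb <- first_len_b[ok]
    perm <- with_seed(null_seed, sample(length(fb)))
    # avoid self-pairs so the null is over non-orthologous gene pairs
    fixed <- which(perm == seq_along(perm))
    if (length(fixed) > 1L) perm[fixed] <- perm[c(fixed[-1L], fixed[1L])]
    nb <- fb[perm]
    keep <- pmax(fa, nb) > min_len & perm != seq_along(perm)
    null_ratios <- intron_length_ratio(fa[keep], nb[keep])
    out$null <- list(ratios = null_ratios,
                     median = if (length(null_ratios))
                       stats::median(null_ratios) else NA_real_)
  }
  out
}

#' Read a two-column ortholog pair table
#'
#' @param path TSV with columns `gene_a`, `gene_b` (header optional).
#' @return Data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_pairs <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- grepl("gene_a", first, fixed = TRUE)
  df <- utils::read.delim(path, header = hdr, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_a", "gene_b")
  df[, c("gene_a", "gene_b")]
}

#' Write an ortholog pair table
#' @param pairs Data.frame with `gene_a`, `gene_b`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ortholog_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("gene_a", "gene_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
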