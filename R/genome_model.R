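# Gene models, conventional-gene classification and fragment extraction.
#
# Internal coordinates are 0-based half-open throughout; GFF3/BED readers and
# writers convert at the boundary. Fragment (exon/intron) indices are 1-based
# in the gene's transcriptional 5'->3' direction, so the "first intron" is
# the intron nearest the start codon on both strands.

#' Construct a genome object
#'
#' A genome is a species label plus a set of named chromosome sequences.
#'
#' @param species_id Character label for the species.
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences.
#' @return An object of class `genome` with elements `species_id` and `seqs`.
#' @export
genome <- function(species_id, seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(methods::is(seqs, "DNAStringSet"))
  nm <- names(seqs)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop("chromosome names must be present and unique")
  if (any(Biostrings::width(seqs) == 0L))
    stop("chromosome sequences must be non-empty")
  structure(list(species_id = species_id, seqs = seqs), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome '%s': %d chromosome(s), %.0f bp total\n",
              x$species_id, length(x$seqs), sum(Biostrings::width(x$seqs))))
  invisible(x)
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with columns `start`, `end`: the coding exons
#'   as 0-based half-open genomic intervals, in genomic order.
#' @param utr5_introns Number of introns upstream of the start codon.
#' @param alt_first_exons Number of distinct first coding exons.
#' @param operon_position One of `"none"`, `"first"`, `"downstream"`.
#' @param chrom_length Optional chromosome length for bounds checking.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       utr5_introns = 0L, alt_first_exons = 1L,
                       operon_position = "none", chrom_length = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene must have at least one coding exon")
  o <- order(exons[, 1L])
  exons <- exons[o, , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("exon intervals must be non-empty")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop(sprintf("gene %s: overlapping coding exons", gene_id))
  if (any(exons[, 1L] < 0L))
    stop(sprintf("gene %s: exon before chromosome start", gene_id))
  if (!is.null(chrom_length) && any(exons[, 2L] > chrom_length))
    stop(sprintf("gene %s: exon beyond chromosome end", gene_id))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!operon_position %in% c("none", "first", "downstream"))
    stop("operon_position must be none/first/downstream")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons,
                 utr5_introns = as.integer(utr5_introns),
                 alt_first_exons = as.integer(alt_first_exons),
                 operon_position = operon_position),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d (%s), %d exon(s)\n", x$gene_id,
              x$chrom, coding_span(x)[1], coding_span(x)[2], x$strand,
              nrow(x$exons)))
  invisible(x)
}

# 0-based half-open genomic interval covered by the coding exons
coding_span <- function(gene) {
  c(gene$exons[1L, 1L], gene$exons[nrow(gene$exons), 2L])
}

#' Load gene models from GFF3 + FASTA
#'
#' Reads protein-coding gene models from a GFF3 file (features `gene`,
#' `mRNA`, `CDS` and optionally `five_prime_UTR`) and chromosome sequences
#' from a FASTA file. Operon membership and alternative-start counts are
#' taken from `operon_position=` and `alt_first_exons=` attributes on the
#' `gene` feature; the number of 5'-UTR introns is derived from gaps between
#' `five_prime_UTR` blocks. GFF3 1-based closed coordinates are converted to
#' the package's internal 0-based half-open convention.
#'
#' @param gff3_path Path to a GFF3 annotation file.
#' @param fasta_path Path to the genome FASTA file.
#' @param species_id Label for the genome (defaults to the FASTA file name).
#' @return A list with elements `genome` (a [genome] object) and `genes`
#'   (named list of [gene_model] objects).
#' @export
load_annotation <- function(gff3_path, fasta_path,
                            species_id = basename(fasta_path)) {
  stopifnot(file.exists(gff3_path), file.exists(fasta_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gn <- genome(species_id, seqs)

  gff <- rtracklayer::import(gff3_path, format = "gff3")
  typ <- as.character(gff$type)
  chr <- as.character(GenomicRanges::seqnames(gff))
  bad <- setdiff(unique(chr), names(seqs))
  if (length(bad)) {
    off <- which(chr %in% bad)[1L]
    stop(sprintf("GFF3 chromosome '%s' absent from FASTA (feature %s)",
                 chr[off], gff$ID[off] %||% "<unnamed>"))
  }

  is_gene <- typ == "gene"
  gene_ids <- as.character(gff$ID[is_gene])
  gene_meta <- data.frame(
    gene_id = gene_ids,
    operon_position = as.character(
      (gff$operon_position %||% rep(NA, length(typ)))[is_gene]),
    alt_first_exons = suppressWarnings(as.integer(
      (gff$alt_first_exons %||% rep(NA, length(typ)))[is_gene])),
    stringsAsFactors = FALSE)
  gene_meta$operon_position[is.na(gene_meta$operon_position)] <- "none"
  gene_meta$alt_first_exons[is.na(gene_meta$alt_first_exons)] <- 1L

  # mRNA -> gene map (Parent is a CharacterList)
  parent1 <- function(p) vapply(as.list(p), function(v)
    if (length(v)) v[[1L]] else NA_character_, character(1))
  is_mrna <- typ == "mRNA"
  mrna2gene <- stats::setNames(parent1(gff$Parent[is_mrna]),
                               as.character(gff$ID[is_mrna]))

  feature_gene <- function(sel) {
    p <- parent1(gff$Parent[sel])
    ifelse(p %in% names(mrna2gene), unname(mrna2gene[p]), p)
  }

  is_cds <- typ == "CDS"
  cds_gene <- feature_gene(is_cds)
  cds_start0 <- GenomicRanges::start(gff)[is_cds] - 1L
  cds_end0 <- GenomicRanges::end(gff)[is_cds]
  cds_chr <- chr[is_cds]
  cds_strand <- as.character(GenomicRanges::strand(gff))[is_cds]

  is_utr <- typ == "five_prime_UTR"
  utr_gene <- if (any(is_utr)) feature_gene(is_utr) else character(0)
  utr_start0 <- GenomicRanges::start(gff)[is_utr] - 1L
  utr_end0 <- GenomicRanges::end(gff)[is_utr]

  genes <- list()
  skipped <- 0L
  for (g in gene_ids) {
    sel <- which(cds_gene == g)
    if (!length(sel)) next
    ex <- cbind(start = cds_start0[sel], end = cds_end0[sel])
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    # merge CDS rows split only by phase bookkeeping; reject overlaps
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) {
      warning(sprintf("gene %s: malformed CDS chain, skipped", g))
      skipped <- skipped + 1L
      next
    }
    n_utr_introns <- 0L
    usel <- which(utr_gene == g)
    if (length(usel) > 1L) {
      ur <- IRanges::reduce(IRanges::IRanges(utr_start0[usel] + 1L,
                                             utr_end0[usel]))
      n_utr_introns <- length(ur) - 1L
    }
    meta <- gene_meta[gene_meta$gene_id == g, , drop = FALSE]
    genes[[g]] <- gene_model(
      gene_id = g, chrom = cds_chr[sel[1L]], strand = cds_strand[sel[1L]],
      exons = ex, utr5_introns = n_utr_introns,
      alt_first_exons = meta$alt_first_exons[1L],
      operon_position = meta$operon_position[1L],
      chrom_length = Biostrings::width(seqs)[match(cds_chr[sel[1L]],
                                                   names(seqs))])
  }
  if (skipped) stage_log("annotation", skipped, " gene(s) skipped")
  list(genome = gn, genes = genes)
}

#' Classify a gene as conventional or not
#'
#' A gene is "conventional" when it has no intron in its 5'-UTR, a unique
#' first coding exon (no alternative start), and is not located downstream
#' within an operon. Conventional genes are the analysis universe for
#' first-intron statistics, because only for them is the first intron the
#' intron closest to the transcription start.
#'
#' @param gene A [gene_model].
#' @return A one-row data.frame with the three criterion flags and
#'   `is_conventional`.
#' @export
classify_conventional <- function(gene) {
  has_utr5 <- gene$utr5_introns > 0L
  has_alt <- gene$alt_first_exons > 1L
  op_down <- gene$operon_position == "downstream"
  data.frame(gene_id = gene$gene_id,
             has_utr5_intron = has_utr5,
             has_alt_start = has_alt,
             is_operon_downstream = op_down,
             is_conventional = !(has_utr5 || has_alt || op_down),
             stringsAsFactors = FALSE)
}

#' Classify a list of gene models
#'
#' @param genes List of [gene_model] objects.
#' @return Data.frame with one row per gene, as [classify_conventional].
#' @export
conventional_table <- function(genes) {
  do.call(rbind, lapply(genes, classify_conventional))
}

fragment_row <- function(gene_id, kind, index, chrom, start, end, strand,
                         seq = NA_character_) {
  data.frame(gene_id = gene_id, kind = kind, index = as.integer(index),
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, length = as.integer(end - start),
             seq = seq, stringsAsFactors = FALSE)
}

fragment_seq <- function(genome, chrom, start, end, strand) {
  if (end <= start) return("")
  s <- Biostrings::subseq(genome$seqs[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Define a gene's promoter fragment
#'
#' The promoter runs from the start codon (ATG) up to `max_span` bp upstream
#' in the transcription orientation, truncated at the nearest boundary
#' (start codon or 3'-end, whichever is closer) of any neighbouring gene,
#' and at the chromosome edge. Note the anchor is the start codon, not the
#' TSS, so the gene's own 5'-UTR lies inside the promoter fragment.
#'
#' @param gene A [gene_model].
#' @param neighbors List of [gene_model] objects on the same chromosome
#'   (the gene itself is ignored if present).
#' @param genome Optional [genome]; when given, the fragment carries its
#'   strand-corrected sequence and the chromosome edge is known.
#' @param max_span Maximum promoter span in bp (default 2000).
#' @param neighbor_bounds Optional precomputed numeric vector of neighbour
#'   coding-span boundaries (start codons and 3' ends), overriding
#'   `neighbors`.
#' @return One fragment row (`kind = "promoter"`, `index = 1`); zero-length
#'   promoters (abutting neighbour) are retained with `length = 0`.
#' @export
define_promoter <- function(gene, neighbors = NULL, genome = NULL,
                            max_span = 2000L, neighbor_bounds = NULL,
                            chrom_len = NULL) {
  span <- coding_span(gene)
  chrom_len <- chrom_len %||% (if (!is.null(genome))
    Biostrings::width(genome$seqs)[match(gene$chrom, names(genome$seqs))]
  else NA_integer_)
  nb_bounds <- neighbor_bounds %||% unlist(lapply(neighbors, function(nb) {
    if (nb$gene_id == gene$gene_id || nb$chrom != gene$chrom) return(NULL)
    coding_span(nb)
  }))
  if (gene$strand == "+") {
    atg <- span[1L]
    lo <- max(0L, atg - max_span)
    if (atg - max_span < 0L && is.null(nb_bounds))
      stage_log("promoter", gene$gene_id, ": truncated at chromosome start")
    cand <- nb_bounds[nb_bounds > lo & nb_bounds <= atg]
    if (length(cand)) lo <- max(cand)
    start <- lo; end <- atg
  } else {
    atg <- span[2L]
    hi <- atg + max_span
    if (!is.na(chrom_len) && hi > chrom_len) {
      hi <- chrom_len
    }
    cand <- nb_bounds[nb_bounds < hi & nb_bounds >= atg]
    if (length(cand)) hi <- min(cand)
    start <- atg; end <- hi
  }
  seq <- if (!is.null(genome))
    fragment_seq(genome, gene$chrom, start, end, gene$strand)
  else NA_character_
  fr <- fragment_row(gene$gene_id, "promoter", 1L, gene$chrom, start, end,
                     gene$strand, seq)
  if (fr$length == 0L)
    stage_log("promoter", gene$gene_id, ": zero-length promoter (degenerate)")
  fr
}

#' Extract exon and intron fragments of a gene
#'
#' Exons and introns are numbered 1..n in the gene's transcriptional 5'->3'
#' direction (on the minus strand, index 1 is the fragment with the highest
#' genomic coordinate). Sequences are strand-corrected. Exon and intron
#' fragments tile the coding span exactly.
#'
#' @param gene A [gene_model].
#' @param genome A [genome]; set to NULL to skip sequence extraction.
#' @return Data.frame of fragment rows (`kind` in `exon`/`intron`).
#' @export
extract_fragments <- function(gene, genome = NULL) {
  ex <- gene$exons
  if (!is.null(genome)) {
    clen <- Biostrings::width(genome$seqs)[match(gene$chrom,
                                                 names(genome$seqs))]
    if (is.na(clen)) stop(sprintf("chromosome %s not in genome", gene$chrom))
    if (ex[1L, 1L] < 0L || ex[nrow(ex), 2L] > clen)
      stop(sprintf("gene %s: interval outside chromosome", gene$gene_id))
  }
  n <- nrow(ex)
  # genomic-order indices; flip for minus strand
  ex_idx <- if (gene$strand == "+") seq_len(n) else rev(seq_len(n))
  kind <- rep("exon", n); idx <- ex_idx
  starts <- ex[, 1L]; ends <- ex[, 2L]
  if (n > 1L) {
    in_idx <- if (gene$strand == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
    kind <- c(kind, rep("intron", n - 1L))
    idx <- c(idx, in_idx)
    starts <- c(starts, ex[-n, 2L])
    ends <- c(ends, ex[-1L, 1L])
  }
  out <- data.frame(gene_id = gene$gene_id, kind = kind,
                    index = as.integer(idx), chrom = gene$chrom,
                    start = as.integer(starts), end = as.integer(ends),
                    strand = gene$strand,
                    length = as.integer(ends - starts),
                    seq = NA_character_, stringsAsFactors = FALSE)
  out <- out[order(out$kind, out$index), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(genome)) out <- fill_fragment_seqs(out, genome)
  out
}

# batched strand-corrected sequence extraction for a fragment table
fill_fragment_seqs <- function(fragments, genome) {
  for (ch in unique(fragments$chrom)) {
    ii <- which(fragments$chrom == ch)
    ss <- Biostrings::extractAt(
      genome$seqs[[ch]],
      IRanges::IRanges(fragments$start[ii] + 1L, fragments$end[ii]))
    neg <- fragments$strand[ii] == "-"
    if (any(neg)) ss[neg] <- Biostrings::reverseComplement(ss[neg])
    fragments$seq[ii] <- as.character(ss)
  }
  fragments
}

#' Extract all fragments (promoter + exons + introns) for a set of genes
#'
#' @param genes Named list of [gene_model] objects.
#' @param genome A [genome] or NULL.
#' @param max_span Promoter span cap in bp.
#' @return Data.frame of fragment rows for every gene.
#' @export
gene_fragments <- function(genes, genome = NULL, max_span = 2000L) {
  chroms <- vapply(genes, `[[`, "", "chrom")
  spans <- t(vapply(genes, coding_span, integer(2)))
  out <- vector("list", length(genes))
  clens <- if (!is.null(genome))
    stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    same <- chroms == g$chrom
    same[k] <- FALSE
    nb <- as.numeric(t(spans[same, , drop = FALSE]))
    out[[k]] <- rbind(
      define_promoter(g, genome = NULL, max_span = max_span,
                      neighbor_bounds = nb,
                      chrom_len = if (!is.null(genome)) clens[[g$chrom]]),
      extract_fragments(g, genome = NULL))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(genome)) res <- fill_fragment_seqs(res, genome)
  res
}

#' Region class of a fragment
#'
#' Collapses fragment kind/index into the region classes used by the
#' binding summaries: `promoter`, `first_intron`, `other_intron`, `exon`.
#'
#' @param kind Fragment kind vector.
#' @param index Fragment index vector.
#' @return Character vector of region classes.
#' @export
region_class <- function(kind, index) {
  ifelse(kind == "promoter", "promoter",
         ifelse(kind == "exon", "exon",
                ifelse(index == 1L, "first_intron", "other_intron")))
}

#' Write fragments as BED6
#'
#' Name column is `geneid|kind|index`; internal 0-based half-open intervals
#' map directly onto BED.
#'
#' @param fragments Fragment data.frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fragments_bed <- function(fragments, path) {
  gr <- GenomicRanges::GRanges(
    fragments$chrom,
    IRanges::IRanges(fragments$start + 1L, fragments$end),
    strand = fragments$strand,
    name = paste(fragments$gene_id, fragments$kind, fragments$index,
                 sep = "|"),
    score = 0L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write fragment sequences as FASTA
#'
#' @param fragments Fragment data.frame with a `seq` column.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fragments_fasta <- function(fragments, path) {
  keep <- !is.na(fragments$seq) & nzchar(fragments$seq)
  ss <- Biostrings::DNAStringSet(fragments$seq[keep])
  names(ss) <- paste(fragments$gene_id, fragments$kind, fragments$index,
                     sep = "|")[keep]
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
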