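# Independent brute-force oracles and shared fixtures.

# --- cached simulations (one R session runs all test files) -----------
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, n_genes, seed, cfg = NULL) {
  if (is.null(.sim_cache[[name]])) {
    cfg <- cfg %||% sim_config(seed = seed, n_genes = n_genes)
    .sim_cache[[name]] <- sim_genome_pair(cfg)
  }
  .sim_cache[[name]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_sim <- function() cached_sim("small", 40L, 11L)

# --- brute-force motif scan oracle ------------------------------------
# direct per-window enumeration, fully independent of scan_fragment
oracle_scan <- function(seq, em) {
  w <- em$width
  n <- nchar(seq)
  revcomp <- function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  hits <- list()
  if (n >= w) {
    for (off in 0:(n - w)) {
      win <- substr(seq, off + 1, off + w)
      for (strand in c("+", "-")) {
        s <- if (strand == "+") win else revcomp(win)
        b <- strsplit(s, "")[[1]]
        bi <- match(b, c("A", "C", "G", "T"))
        if (anyNA(bi)) next
        E <- sum(em$epsilon[cbind(seq_len(w), bi)])
        occ <- 1 / (1 + exp(E - em$mu))
        if (occ >= em$threshold)
          hits[[length(hits) + 1]] <- data.frame(
            offset = off, strand = strand, energy = E, occupancy = occ,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      energy = numeric(0), occupancy = numeric(0)))
  h <- do.call(rbind, hits)
  h <- h[order(h$offset, h$strand), ]
  h <- h[!duplicated(h$offset), ]   # collapse double calls to plus strand
  rownames(h) <- NULL
  h
}

# --- brute-force peak-to-fragment containment -------------------------
oracle_assign <- function(peaks, fragments) {
  out <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    tfs <- character(0)
    for (j in seq_len(nrow(peaks))) {
      m <- peaks$midpoint[j]
      if (peaks$chrom[j] == fragments$chrom[i] &&
          m >= fragments$start[i] && m < fragments$end[i])
        tfs <- c(tfs, peaks$tf_id[j])
    }
    out[[i]] <- sort(unique(tfs))
  }
  out
}

# --- exhaustive monotone-bijection membership -------------------------
# all strictly monotone partial bijections between 1..na and 1..nb
oracle_is_monotone_bijection <- function(pairs, na, nb) {
  if (nrow(pairs) == 0) return(FALSE)
  enumerate <- function(k) {
    # all strictly increasing index subsets of size k
    utils::combn(na, k, simplify = FALSE)
  }
  for (k in seq_len(min(na, nb))) {
    for (ia in utils::combn(na, k, simplify = FALSE))
      for (ib in utils::combn(nb, k, simplify = FALSE)) {
        cand <- data.frame(exon_a = ia, exon_b = ib)
        if (nrow(cand) == nrow(pairs) &&
            all(cand$exon_a == sort(pairs$exon_a)) &&
            all(cand$exon_b == pairs$exon_b[order(pairs$exon_a)]))
          return(TRUE)
      }
  }
  FALSE
}

# --- random DNA -------------------------------------------------------
random_seq <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# --- tiny two-gene annotation written by hand -------------------------
write_tiny_annotation <- function(dir = tempfile("ann_")) {
  dir.create(dir)
  fasta <- file.path(dir, "g.fa")
  gff <- file.path(dir, "g.gff3")
  set.seed(421)
  chrom <- random_seq(1200)
  writeLines(c(">chrZ", chrom), fasta)
  writeLines(c(
    "##gff-version 3",
    "chrZ\ttest\tgene\t101\t400\t.\t+\t.\tID=gplus;operon_position=none;alt_first_exons=1",
    "chrZ\ttest\tmRNA\t101\t400\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "chrZ\ttest\tCDS\t101\t200\t.\t+\t0\tID=gplus.c1;Parent=gplus.t1",
    "chrZ\ttest\tCDS\t301\t400\t.\t+\t0\tID=gplus.c2;Parent=gplus.t1",
    "chrZ\ttest\tgene\t601\t900\t.\t-\t.\tID=gminus;operon_position=none;alt_first_exons=1",
    "chrZ\ttest\tmRNA\t601\t900\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "chrZ\ttest\tCDS\t601\t700\t.\t-\t0\tID=gminus.c1;Parent=gminus.t1",
    "chrZ\ttest\tCDS\t801\t900\t.\t-\t0\tID=gminus.c2;Parent=gminus.t1"),
    gff)
  list(fasta = fasta, gff = gff, chrom = chrom)
}
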