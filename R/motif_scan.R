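# PWM -> binding-energy scoring and occupancy-thresholded site calling.
#
# Each PWM column (position) is converted to per-base energies
# eps_i(b) = ln(max_b' f_i(b') / f_i(b)) after pseudocount regularisation,
# so the consensus base has energy exactly 0. A window's energy is the sum
# of its per-position energies (units kT) and is mapped to a predicted
# occupancy by the sigmoid 1/(1 + exp(E - mu)). Sites are called where the
# occupancy reaches the threshold (0.09 by default), equivalently where
# E <= mu + ln(1/threshold - 1) ~ 2.3135 kT at the defaults.

BASES <- c("A", "C", "G", "T")

#' Construct a position probability matrix object
#'
#' @param tf_id TF label.
#' @param matrix Numeric matrix, one row per position, columns A, C, G, T.
#' @return An object of class `pwm`.
#' @export
pwm <- function(tf_id, matrix) {
  m <- as.matrix(matrix)
  colnames(m) <- BASES
  if (nrow(m) < 4L) stop("PWM width must be >= 4")
  if (any(m < 0)) stop("PWM entries must be non-negative")
  if (any(rowSums(m) <= 0)) stop("PWM row of all zeros")
  structure(list(tf_id = tf_id, matrix = m, width = nrow(m)), class = "pwm")
}

#' Convert a PWM to an energy matrix
#'
#' @param x A [pwm].
#' @param pseudocount Probability added to every entry before
#'   renormalisation (keeps energies finite for zero entries).
#' @param mu Chemical-potential offset of the occupancy sigmoid.
#' @param threshold Occupancy call threshold in (0, 1).
#' @return An object of class `energy_matrix` with fields `tf_id`,
#'   `epsilon` (positions x 4, kT, row minima exactly 0), `mu`, `threshold`.
#' @export
pwm_to_energy <- function(x, pseudocount = 1e-3, mu = 0, threshold = 0.09) {
  stopifnot(inherits(x, "pwm"), pseudocount > 0,
            threshold > 0, threshold < 1)
  p <- x$matrix + pseudocount
  p <- p / rowSums(p)
  eps <- log(apply(p, 1L, max)) - log(p)   # consensus row minimum exactly 0
  structure(list(tf_id = x$tf_id, epsilon = eps, width = nrow(eps),
                 mu = mu, threshold = threshold),
            class = "energy_matrix")
}

#' Occupancy of a window with binding energy E
#' @param energy Energy in kT.
#' @param mu Chemical potential offset.
#' @return Occupancy in (0, 1): `1/(1 + exp(energy - mu))`.
#' @export
occupancy <- function(energy, mu = 0) 1 / (1 + exp(energy - mu))

#' Energy cutoff equivalent to an occupancy threshold
#' @param threshold Occupancy threshold in (0, 1).
#' @param mu Chemical potential offset.
#' @return The energy E such that `occupancy(E, mu) == threshold`.
#' @export
energy_cutoff <- function(threshold, mu = 0) mu + log(1 / threshold - 1)

revcomp_chr <- function(s) {
  v <- rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]])
  paste(v, collapse = "")
}

# integer codes 1..4 for ACGT, NA otherwise
encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], BASES)
}

scan_codes <- function(codes, eps) {
  w <- nrow(eps)
  n <- length(codes) - w + 1L
  if (n < 1L) return(data.frame(offset = integer(0), energy = numeric(0)))
  idx <- outer(seq_len(w) - 1L, seq_len(n), "+")   # w x n positions
  cvals <- codes[idx]
  E <- colSums(matrix(eps[cbind(rep(seq_len(w), n), cvals)], nrow = w))
  data.frame(offset = seq_len(n) - 1L, energy = E)[!is.na(E), , drop = FALSE]
}

#' Scan a fragment sequence with an energy matrix
#'
#' Every window on both strands is scored; windows containing N are
#' skipped. Sites whose occupancy reaches the matrix threshold are
#' returned sorted by offset. A palindromic double call (both strands at
#' the same offset) collapses to the plus-strand site.
#'
#' @param seq Fragment sequence (character scalar).
#' @param em An [pwm_to_energy] energy matrix.
#' @return Data.frame with columns `tf_id`, `offset` (0-based, plus-strand
#'   coordinates within the fragment), `strand`, `energy`, `occupancy`.
#' @export
scan_fragment <- function(seq, em) {
  stopifnot(inherits(em, "energy_matrix"))
  empty <- data.frame(tf_id = character(0), offset = integer(0),
                      strand = character(0), energy = numeric(0),
                      occupancy = numeric(0), stringsAsFactors = FALSE)
  if (is.na(seq) || nchar(seq) < em$width) return(empty)
  codes <- encode_seq(seq)
  L <- length(codes)
  fwd <- scan_codes(codes, em$epsilon)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- scan_codes(rev(5L - codes), em$epsilon)
  # offset o' on the reverse complement maps to L - width - o' on the plus
  rc$offset <- L - em$width - rc$offset
  rc$strand <- rep("-", nrow(rc))
  hits <- rbind(fwd, rc)
  hits$occupancy <- occupancy(hits$energy, em$mu)
  hits <- hits[hits$occupancy >= em$threshold, , drop = FALSE]
  # agreement of the two equivalent call formulations, asserted per call
  stopifnot(all(hits$energy <= energy_cutoff(em$threshold, em$mu) + 1e-9))
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  dup <- duplicated(hits$offset)
  hits <- hits[!dup, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  data.frame(tf_id = em$tf_id, offset = hits$offset, strand = hits$strand,
             energy = hits$energy, occupancy = hits$occupancy,
             stringsAsFactors = FALSE)
}

#' TFs predicted to interact with a fragment
#'
#' @param seq Fragment sequence.
#' @param ems List of energy matrices (possibly several per TF).
#' @return Character vector of distinct `tf_id`s with at least one called
#'   site.
#' @export
predicted_tfs <- function(seq, ems) {
  hits <- vapply(ems, function(em) nrow(scan_fragment(seq, em)) > 0L,
                 logical(1))
  unique(vapply(ems[hits], `[[`, "", "tf_id"))
}

#' Conserved predicted TF interactions between orthologous fragments
#'
#' @param seq_a,seq_b Orthologous fragment sequences (same kind and
#'   ordinal, identical-structure gene pair).
#' @param ems List of energy matrices.
#' @return List with `tfs` (intersection of the two predicted TF sets) and
#'   `no_data` (TRUE when neither fragment has any predicted site for any
#'   TF; such fragments are excluded from per-region averages).
#' @export
conserved_predicted_tfs <- function(seq_a, seq_b, ems) {
  ta <- predicted_tfs(seq_a, ems)
  tb <- predicted_tfs(seq_b, ems)
  list(tfs = intersect(ta, tb),
       no_data = length(ta) == 0L && length(tb) == 0L)
}

#' Mean conserved predicted interactions per region class
#'
#' @param frag_pairs Data.frame of orthologous fragment pairs with columns
#'   `gene_a`, `kind`, `index`, `seq_a`, `seq_b`.
#' @param ems List of energy matrices.
#' @return List with `per_class` (data.frame: region class, mean, sem, n,
#'   n_no_data) and `first_vs_other` (Mann-Whitney U comparison of
#'   conserved counts in first vs other introns).
#' @export
mean_conserved_by_region <- function(frag_pairs, ems) {
  cls <- region_class(frag_pairs$kind, frag_pairs$index)
  cons <- integer(nrow(frag_pairs))
  nodata <- logical(nrow(frag_pairs))
  for (i in seq_len(nrow(frag_pairs))) {
    r <- conserved_predicted_tfs(frag_pairs$seq_a[i], frag_pairs$seq_b[i],
                                 ems)
    cons[i] <- length(r$tfs)
    nodata[i] <- r$no_data
  }
  per_class <- do.call(rbind, lapply(split(seq_along(cls), cls), function(ii) {
    use <- ii[!nodata[ii]]
    data.frame(class = cls[ii[1]],
               mean = if (length(use)) mean(cons[use]) else NA_real_,
               sem = sem(cons[use]),
               n = length(use), n_no_data = sum(nodata[ii]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  fi <- cons[cls == "first_intron" & !nodata]
  oi <- cons[cls == "other_intron" & !nodata]
  test <- if (length(fi) >= 2L && length(oi) >= 2L)
    suppressWarnings(stats::wilcox.test(fi, oi)) else NULL
  list(per_class = per_class,
       counts = data.frame(class = cls, conserved = cons, no_data = nodata,
                           stringsAsFactors = FALSE),
       first_vs_other = list(
         mean_first = if (length(fi)) mean(fi) else NA_real_,
         mean_other = if (length(oi)) mean(oi) else NA_real_,
         ratio = if (length(fi) && length(oi) && mean(oi) > 0)
           mean(fi) / mean(oi) else NA_real_,
         p_value = if (!is.null(test)) test$p.value else NA_real_))
}

#' Read PWMs from MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix:` sections. The
#' motif name is used as the TF id unless it carries a `name/tf` suffix.
#'
#' @param path MEME minimal file.
#' @return Named list of [pwm] objects.
#' @export
read_pwms_meme <- function(path) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\s", lines)
  if (!length(motif_at)) stop("no MOTIF blocks found in ", path)
  out <- list()
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    nm <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[i])), "\\s+")[[1]][1]
    j <- i
    while (j <= length(lines) &&
           !grepl("letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) stop("motif ", nm, ": no probability matrix")
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1",
                                         lines[j])))
    rows <- lines[(j + 1L):(j + w)]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])))
    out[[nm]] <- pwm(nm, m)
  }
  out
}

#' Read PWMs from a 4-column TSV
#'
#' Expected columns: `tf`, `pos`, then `A`, `C`, `G`, `T` probabilities.
#'
#' @param path TSV file with a header.
#' @return Named list of [pwm] objects.
#' @export
read_pwms_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "pos", BASES) %in% names(df)))
  out <- lapply(split(df, df$tf), function(d) {
    d <- d[order(d$pos), ]
    pwm(d$tf[1], as.matrix(d[, BASES]))
  })
  out[unique(df$tf)]
}

#' Write PWMs as a 4-column TSV
#' @param pwms Named list of [pwm] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pwms_tsv <- function(pwms, path) {
  rows <- lapply(pwms, function(p)
    data.frame(tf = p$tf_id, pos = seq_len(p$width), p$matrix,
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write predicted sites as BED6
#'
#' Occupancy is written in the score column scaled by 1000 and clamped to
#' [0, 1000].
#'
#' @param sites Data.frame of predicted sites with fragment genomic anchors
#'   (`chrom`, `frag_start`, columns from [scan_fragment], and `width`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites_bed <- function(sites, path) {
  if (!nrow(sites)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(sites$frag_start + sites$offset + 1L,
                     sites$frag_start + sites$offset + sites$width),
    strand = sites$strand, name = sites$tf_id,
    score = pmin(1000L, pmax(0L, as.integer(round(sites$occupancy * 1000)))))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
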