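# Gene models, conventional classification, promoters and fragments.

test_that("GFF3 coordinates convert to 0-based half-open on both strands", {
  ann <- write_tiny_annotation()
  res <- load_annotation(ann$gff, ann$fasta)
  gp <- res$genes[["gplus"]]
  expect_equal(unname(gp$exons[, "start"]), c(100L, 300L))
  expect_equal(unname(gp$exons[, "end"]), c(200L, 400L))
  expect_identical(gp$strand, "+")
  gm <- res$genes[["gminus"]]
  expect_equal(unname(gm$exons[, "start"]), c(600L, 800L))
  expect_equal(unname(gm$exons[, "end"]), c(700L, 900L))
  expect_identical(gm$strand, "-")
})

test_that("annotation loader fails on a missing chromosome, skips bad CDS", {
  ann <- write_tiny_annotation()
  bad <- sub("chrZ\ttest\tgene\t101", "chrY\ttest\tgene\t101",
             readLines(ann$gff))
  bad <- gsub("^chrZ(\ttest\t(mRNA|CDS)\t[1-4])", "chrY\\1", bad)
  badf <- tempfile(fileext = ".gff3")
  writeLines(bad, badf)
  expect_error(load_annotation(badf, ann$fasta), "chrY")

  # overlapping CDS rows -> gene skipped with a warning, other gene kept
  lines <- readLines(ann$gff)
  lines <- sub("CDS\t301\t400", "CDS\t150\t400", lines)
  ovf <- tempfile(fileext = ".gff3")
  writeLines(lines, ovf)
  expect_warning(res <- load_annotation(ovf, ann$fasta), "malformed")
  expect_false("gplus" %in% names(res$genes))
  expect_true("gminus" %in% names(res$genes))
})

test_that("conventional classification follows the three criteria", {
  mk <- function(...) gene_model("g", "chrI", "+",
                                 cbind(c(0L, 200L), c(100L, 300L)), ...)
  expect_true(classify_conventional(mk())$is_conventional)
  expect_false(classify_conventional(mk(utr5_introns = 2L))$is_conventional)
  expect_false(
    classify_conventional(mk(alt_first_exons = 2L))$is_conventional)
  # downstream position in an operon disqualifies; first gene does not
  expect_false(classify_conventional(
    mk(operon_position = "downstream"))$is_conventional)
  expect_true(classify_conventional(
    mk(operon_position = "first"))$is_conventional)
  st <- classify_conventional(mk(utr5_introns = 1L, alt_first_exons = 2L,
                                 operon_position = "downstream"))
  expect_identical(st$is_conventional,
                   !(st$has_utr5_intron || st$has_alt_start ||
                       st$is_operon_downstream))
})

test_that("promoter spans up to 2 kb and truncates at neighbours", {
  g <- gene_model("g", "chrI", "+", cbind(5000L, 5300L))
  # no neighbour within 2 kb
  p <- define_promoter(g, list())
  expect_equal(p$length, 2000L)
  expect_equal(c(p$start, p$end), c(3000L, 5000L))
  # neighbour 3'-end 800 bp upstream of the ATG
  nb <- gene_model("n", "chrI", "+", cbind(3000L, 4200L))
  p <- define_promoter(g, list(nb))
  expect_equal(p$length, 800L)
  expect_equal(p$start, 4200L)
  # abutting neighbour -> zero-length promoter, retained
  nb2 <- gene_model("n2", "chrI", "+", cbind(3000L, 5000L))
  expect_message(p <- define_promoter(g, list(nb2)), "zero-length")
  expect_equal(p$length, 0L)
  # minus strand: promoter downstream in genomic coordinates
  gm <- gene_model("gm", "chrI", "-", cbind(5000L, 5300L))
  nbm <- gene_model("n3", "chrI", "+", cbind(6100L, 6400L))
  p <- define_promoter(gm, list(nbm))
  expect_equal(c(p$start, p$end), c(5300L, 6100L))
})

test_that("fragments alternate, tile the coding span and number 5'->3'", {
  g <- gene_model("g", "chrI", "+", cbind(c(100L, 300L), c(200L, 400L)))
  fr <- extract_fragments(g)
  expect_equal(sum(fr$kind == "intron"), 1L)
  expect_equal(fr$index[fr$kind == "intron"], 1L)
  # minus strand: intron nearest the start codon (highest genomic
  # coordinate) gets index 1
  gm <- gene_model("g", "chrI", "-",
                   cbind(c(100L, 300L, 500L), c(200L, 400L, 600L)))
  fr <- extract_fragments(gm)
  in1 <- fr[fr$kind == "intron" & fr$index == 1L, ]
  expect_equal(c(in1$start, in1$end), c(400L, 500L))
  ex1 <- fr[fr$kind == "exon" & fr$index == 1L, ]
  expect_equal(ex1$start, 500L)
})

test_that("fragment tiling holds across a simulated genome", {
  sim <- small_sim()
  for (g in sim$genes_a[1:15]) {
    fr <- extract_fragments(g, sim$genome_a)
    span <- coding_span <- range(c(fr$start, fr$end))
    expect_equal(sum(fr$length), diff(span))
    expect_equal(sum(nchar(fr$seq)), sum(fr$length))
  }
})

test_that("reverse-complementing the chromosome leaves fragments invariant", {
  sim <- small_sim()
  g <- sim$genes_a[[3]]
  L <- Biostrings::width(sim$genome_a$seqs)[1]
  rc_genome <- genome("rc", Biostrings::reverseComplement(sim$genome_a$seqs))
  names(rc_genome$seqs) <- names(sim$genome_a$seqs)
  flip <- gene_model(g$gene_id, g$chrom, if (g$strand == "+") "-" else "+",
                     cbind(L - g$exons[, "end"], L - g$exons[, "start"]),
                     g$utr5_introns, g$alt_first_exons, g$operon_position)
  fr <- extract_fragments(g, sim$genome_a)
  fr2 <- extract_fragments(flip, rc_genome)
  key <- function(d) d[order(d$kind, d$index), c("kind", "index", "seq")]
  expect_equal(key(fr2), key(fr), ignore_attr = TRUE)
})

test_that("synthetic genome round-trips through GFF3/FASTA unchanged", {
  sim <- small_sim()
  d <- tempfile("rt_")
  paths <- write_sim(sim, d)
  res <- load_annotation(paths$gff_a, paths$fasta_a)
  expect_length(res$genes, length(sim$genes_a))
  for (id in names(sim$genes_a)[1:20]) {
    expect_equal(res$genes[[id]]$exons, sim$genes_a[[id]]$exons,
                 ignore_attr = TRUE)
    expect_identical(res$genes[[id]]$strand, sim$genes_a[[id]]$strand)
    expect_identical(res$genes[[id]]$operon_position,
                     sim$genes_a[[id]]$operon_position)
    expect_equal(res$genes[[id]]$utr5_introns,
                 sim$genes_a[[id]]$utr5_introns)
  }
  expect_identical(as.character(res$genome$seqs[["chrI"]]),
                   as.character(sim$genome_a$seqs[["chrI"]]))
  # conventional flags recomputed from the re-read annotation match truth
  conv <- conventional_table(res$genes)
  expect_equal(conv$is_conventional[match(conv$gene_id,
                                          sim$truth$conventional$gene_id)],
               sim$truth$conventional$is_conventional)
})

test_that("fragment BED export uses 0-based half-open intervals", {
  sim <- small_sim()
  fr <- gene_fragments(sim$genes_a[1:3], sim$genome_a)
  bed <- tempfile(fileext = ".bed")
  write_fragments_bed(fr, bed)
  got <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(got$V2, fr$start)
  expect_equal(got$V3, fr$end)
  expect_equal(got$V4, paste(fr$gene_id, fr$kind, fr$index, sep = "|"))
})
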