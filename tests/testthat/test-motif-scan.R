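# Energy matrices, occupancy site calling, conserved predicted TFs.

strict_pwm <- function(consensus, tf = "TFX", strictness = 0.97) {
  ci <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - strictness) / 3, length(ci), 4)
  m[cbind(seq_along(ci), ci)] <- strictness
  pwm(tf, m)
}

test_that("energies are log-ratios to the consensus base", {
  # uniform position carries no information: all energies zero
  em <- pwm_to_energy(pwm("u", matrix(0.25, 4, 4)))
  expect_equal(unname(em$epsilon), matrix(0, 4, 4), ignore_attr = TRUE)
  # hand arithmetic for a strongly biased row with pseudocount 1e-3
  p <- c(0.97, 0.01, 0.01, 0.01) + 1e-3
  p <- p / sum(p)
  em <- pwm_to_energy(pwm("b", matrix(c(0.97, 0.01, 0.01, 0.01),
                                      4, 4, byrow = TRUE)),
                      pseudocount = 1e-3)
  expect_equal(unname(em$epsilon[1, "A"]), 0)
  expect_equal(unname(em$epsilon[1, "C"]), log(p[1] / p[2]))
  # deterministic row: pseudocount keeps energies finite and symmetric
  det <- matrix(c(1, 0, 0, 0), 4, 4, byrow = TRUE)
  em <- pwm_to_energy(pwm("d", det))
  expect_true(all(is.finite(em$epsilon)))
  expect_equal(unname(em$epsilon[1, "C"]), unname(em$epsilon[1, "G"]))
  expect_equal(unname(em$epsilon[1, "G"]), unname(em$epsilon[1, "T"]))
  expect_equal(unname(apply(em$epsilon, 1, min)), rep(0, 4))
  expect_error(pwm("z", matrix(0, 4, 4)), "zero")
})

test_that("occupancy threshold is equivalent to the energy cutoff", {
  expect_equal(occupancy(0), 0.5)
  expect_equal(energy_cutoff(0.09), log(1 / 0.09 - 1))
  expect_equal(energy_cutoff(0.09), 2.3136, tolerance = 1e-4)
  E <- seq(-3, 6, by = 0.25)
  expect_equal(occupancy(E) >= 0.09, E <= energy_cutoff(0.09))
})

test_that("a planted consensus is the only call for a strict matrix", {
  set.seed(301)
  cons <- "ACGTACGT"
  em <- pwm_to_energy(strict_pwm(cons))
  frag <- paste0(random_seq(30), cons, random_seq(30))
  # guard against chance second occurrences in the random flanks
  hits <- scan_fragment(frag, em)
  planted <- hits[hits$offset == 30, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$energy, 0)
  expect_equal(planted$occupancy, 0.5)
})

test_that("a uniform matrix calls every window", {
  em <- pwm_to_energy(pwm("u", matrix(0.25, 6, 4)))
  frag <- random_seq(40)
  hits <- scan_fragment(frag, em)
  expect_equal(hits$offset, 0:(40 - 6))
  expect_equal(hits$occupancy, rep(0.5, 35))
  # shorter than the motif: empty result, not an error
  expect_equal(nrow(scan_fragment("ACGT", em)), 0L)
  # windows containing the N (offsets 5..10 for width 6) are skipped
  withN <- paste0(random_seq(10), "N", random_seq(10))
  hits <- scan_fragment(withN, em)
  expect_false(any(hits$offset %in% 5:10))
  expect_true(all(c(0:4, 11:15) %in% hits$offset))
})

test_that("scan matches exhaustive enumeration on random fragments", {
  set.seed(302)
  pwms <- replicate(4, {
    m <- matrix(runif(6 * 4), 6, 4)
    pwm("r", m / rowSums(m))
  }, simplify = FALSE)
  for (p in pwms) {
    em <- pwm_to_energy(p, threshold = 0.35)  # moderate selectivity
    for (i in 1:10) {
      frag <- random_seq(sample(20:80, 1))
      got <- scan_fragment(frag, em)
      want <- oracle_scan(frag, em)
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$energy, want$energy, tolerance = 1e-12)
    }
  }
})

test_that("reverse-complement scanning mirrors the site list", {
  set.seed(303)
  m <- matrix(runif(7 * 4), 7, 4)
  em <- pwm_to_energy(pwm("r", m / rowSums(m)), threshold = 0.3)
  frag <- random_seq(60)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", frag), "")[[1]]),
              collapse = "")
  a <- scan_fragment(frag, em)
  b <- scan_fragment(rc, em)
  expect_equal(sort(60 - 7 - a$offset), sort(b$offset))
  expect_equal(sort(a$energy), sort(b$energy), tolerance = 1e-12)
})

test_that("occupancy decreases monotonically with consensus mismatches", {
  em <- pwm_to_energy(strict_pwm("AAAAAAAA"))
  seqs <- c("AAAAAAAA", "AAAACAAA", "AAGACAAA", "TAGACAAA")
  occ <- vapply(seqs, function(s) {
    h <- scan_fragment(s, pwm_to_energy(strict_pwm("AAAAAAAA"),
                                        threshold = 1e-9))
    h$occupancy[h$strand == "+"][1]
  }, numeric(1))
  expect_true(all(diff(occ) < 0))
})

test_that("predicted TFs have set semantics and a no-data marker", {
  cons <- "ACGTACGT"
  em1 <- pwm_to_energy(strict_pwm(cons, "tf1"))
  em2 <- pwm_to_energy(strict_pwm(cons, "tf1"))   # second matrix, same TF
  em3 <- pwm_to_energy(strict_pwm("GGGGCCCC", "tf3"))
  frag <- paste0("TTTTTTTTTT", cons, "TTTTTTTTTT")
  expect_equal(predicted_tfs(frag, list(em1, em2, em3)), "tf1")
  expect_length(predicted_tfs("TTTTTTTTTTTT", list(em1, em3)), 0L)
  # conserved = intersection; one-sided prediction is dropped
  fragB <- paste0("AAAAAAAAAA", cons, "AAAAAAAAAA")
  r <- conserved_predicted_tfs(frag, fragB, list(em1, em3))
  expect_equal(r$tfs, "tf1")
  expect_false(r$no_data)
  r2 <- conserved_predicted_tfs(frag, "TTTTTTTTTTTT", list(em1, em3))
  expect_length(r2$tfs, 0L)
  expect_false(r2$no_data)   # site in A only: data, not conserved
  r3 <- conserved_predicted_tfs("TTTTTTTT", "TTTTTTTT", list(em3))
  expect_true(r3$no_data)
})

test_that("three planted motifs of distinct TFs are exactly recovered", {
  sim <- small_sim()
  ems <- lapply(sim$pwms, pwm_to_energy)
  cons <- vapply(sim$pwms, attr, "", "consensus")
  set.seed(304)
  frag <- paste0(random_seq(20), cons[2], random_seq(15), cons[5],
                 random_seq(15), cons[8], random_seq(20))
  expect_setequal(predicted_tfs(frag, ems), names(sim$pwms)[c(2, 5, 8)])
})

test_that("per-region conserved means handle edge cases", {
  cons <- "ACGTTGCA"
  em <- pwm_to_energy(strict_pwm(cons, "tf1"))
  fp <- data.frame(
    gene_a = c("g1", "g1", "g2"),
    kind = c("intron", "intron", "intron"),
    index = c(1L, 2L, 1L),
    seq_a = c(paste0("TTTTTTTT", cons), "TTTTTTTTTT",
              paste0(cons, cons, "TT")),
    seq_b = c(paste0(cons, "GGGGGGGG"), "TTTTTTTTTT",
              paste0("TT", cons)),
    stringsAsFactors = FALSE)
  mc <- mean_conserved_by_region(fp, list(em))
  per <- mc$per_class
  # one TF conserved in both first introns; the no-site intron is no-data
  expect_equal(per$mean[per$class == "first_intron"], 1)
  expect_equal(per$n[per$class == "other_intron"], 0L)
  expect_equal(per$n_no_data[per$class == "other_intron"], 1L)
  # single observation: SEM reported as 0 with n recorded
  expect_equal(per$sem[per$class == "first_intron"], 0)
})

test_that("PWM readers round-trip MEME minimal and TSV", {
  sim <- small_sim()
  tsv <- tempfile(fileext = ".tsv")
  meme <- tempfile(fileext = ".meme")
  write_pwms_tsv(sim$pwms, tsv)
  write_pwms_meme(sim$pwms, meme)
  p1 <- read_pwms_tsv(tsv)
  p2 <- read_pwms_meme(meme)
  expect_equal(names(p1), names(sim$pwms))
  expect_equal(names(p2), names(sim$pwms))
  for (nm in names(sim$pwms)) {
    expect_equal(p1[[nm]]$matrix, sim$pwms[[nm]]$matrix,
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(p2[[nm]]$matrix, sim$pwms[[nm]]$matrix,
                 ignore_attr = TRUE, tolerance = 1e-5)
  }
})
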