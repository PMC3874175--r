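# PDI network similarity, enrichment, projection and family statistics.

test_that("Jaccard index follows the set formula", {
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(jaccard_similarity(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_true(is.na(jaccard_similarity(character(0), character(0))))
  expect_equal(jaccard_similarity(c("a"), character(0)), 0.0)
  # symmetry on random sets
  set.seed(501)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(1:10, 1))
    expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
  }
})

test_that("similarity tables cover all unordered pairs in every mode", {
  edges <- data.frame(
    tf = c("t1", "t2", "t1", "t3", "t4"),
    gene = c("g1", "g1", "g2", "g2", "g3"),
    region_kind = c("promoter", "first_intron", "promoter",
                    "first_intron", "first_intron"))
  net <- pdi_network(edges, "test")
  genes <- c("g1", "g2", "g3")
  st <- similarity_table(net, genes, "combined")
  expect_equal(nrow(st), 3L)
  # promoter-only TFs vs intron-only TFs pool in combined mode
  stp <- similarity_table(net, genes, "promoter")
  sti <- similarity_table(net, genes, "intron")
  g12 <- function(d) d$jaccard[d$gene_a == "g1" & d$gene_b == "g2"]
  expect_equal(g12(stp), 1.0)           # {t1} vs {t1}
  expect_equal(g12(sti), 0.0)           # {t2} vs {t3}
  expect_equal(g12(st), 1 / 3)          # {t1,t2} vs {t1,t3}
  # 24 genes -> 276 records, all within [0, 1]
  sim <- simulate_pdi_network(cfg = sim_config(seed = 5))
  net24 <- pdi_network(sim$edges, "synthetic")
  g24 <- sprintf("hd%02d", 1:24)
  st24 <- similarity_table(net24, g24, "combined", sim$coexpression)
  expect_equal(nrow(st24), 276L)
  ok <- !is.na(st24$jaccard)
  expect_true(all(st24$jaccard[ok] >= 0 & st24$jaccard[ok] <= 1))
  expect_true(all(!is.na(st24$coexpression)))
})

test_that("combined similarity is not determined by the per-region pair", {
  # two gene pairs with identical (J_promoter, J_intron) but different
  # pooled similarity
  e1 <- data.frame(tf = c("a", "b", "a", "b", "c", "d"),
                   gene = c("x", "x", "y", "y", "x", "y"),
                   region_kind = c("promoter", "promoter", "promoter",
                                   "promoter", "first_intron",
                                   "first_intron"))
  e2 <- data.frame(tf = c("a", "b", "a", "b", "a", "b"),
                   gene = c("x", "x", "y", "y", "x", "y"),
                   region_kind = c("promoter", "promoter", "promoter",
                                   "promoter", "first_intron",
                                   "first_intron"))
  J <- function(e, mode) similarity_table(pdi_network(e), c("x", "y"),
                                          mode)$jaccard
  expect_equal(J(e1, "promoter"), J(e2, "promoter"))
  expect_equal(J(e1, "intron"), J(e2, "intron"))
  expect_false(isTRUE(all.equal(J(e1, "combined"), J(e2, "combined"))))
})

test_that("co-expression enrichment contingency logic is exact", {
  mk <- function(J, cx) data.frame(gene_a = "a", gene_b = "b",
                                   jaccard = J, coexpression = cx)
  # proportional table: no association
  rec <- rbind(
    do.call(rbind, replicate(10, mk(0.1, 0.1), simplify = FALSE)),
    do.call(rbind, replicate(10, mk(0.1, 0.6), simplify = FALSE)),
    do.call(rbind, replicate(5, mk(0.5, 0.1), simplify = FALSE)),
    do.call(rbind, replicate(5, mk(0.5, 0.6), simplify = FALSE)))
  enr <- coexpression_enrichment(rec)
  expect_equal(enr$p_2x2, 1.0)
  # extreme 10/0/0 vs 0/0/10 table vs enumeration: the two-sided Fisher
  # p equals 2 / C(20, 10)
  rec2 <- rbind(
    do.call(rbind, replicate(10, mk(0.1, 0.0), simplify = FALSE)),
    do.call(rbind, replicate(10, mk(0.6, 0.9), simplify = FALSE)))
  enr2 <- coexpression_enrichment(rec2)
  expect_equal(enr2$p_2x2, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(unname(as.vector(enr2$table)),
               c(10, 0, 0, 0, 0, 10))
  # undefined-J and missing co-expression pairs are excluded with counts
  rec3 <- rbind(rec2, mk(NA, 0.5), mk(0.4, NA))
  expect_message(enr3 <- coexpression_enrichment(rec3), "undefined")
  expect_equal(enr3$n_undefined_J, 1L)
  expect_equal(enr3$n_missing_coexpression, 1L)
  expect_equal(enr3$n_pairs, 20L)
})

test_that("genome projection equals the weighted-average oracle", {
  set.seed(502)
  glen <- round(exp(rnorm(2000, log(100), 1.2)))
  slen <- round(exp(rnorm(150, log(100), 1.2)))
  scnt <- rpois(150, slen / 200)
  pr <- genome_projection(slen, scnt, glen)
  # direct weighted-average oracle
  brk <- c(-Inf, 64, 128, 256, 512, Inf)
  gb <- cut(glen, brk); sb <- cut(slen, brk)
  w <- as.numeric(table(gb)) / length(glen)
  fb <- vapply(levels(gb), function(b) mean(scnt[sb == b] > 0), numeric(1))
  mi <- vapply(levels(gb), function(b) mean(scnt[sb == b]), numeric(1))
  expect_equal(pr$projected_fraction_bound, sum(w * fb), tolerance = 1e-12)
  expect_equal(pr$projected_mean_interactions, sum(w * mi),
               tolerance = 1e-12)
  expect_false(pr$partial)
  # all screened introns bound
  pr1 <- genome_projection(slen, rep(2, 150), glen)
  expect_equal(pr1$projected_fraction_bound, 1.0)
  # single populated bin: projection equals that bin's statistics
  pr2 <- genome_projection(rep(100, 30), rep(c(0, 1), 15), rep(90, 500))
  expect_equal(pr2$projected_fraction_bound, 0.5)
  expect_equal(pr2$projected_mean_interactions, 0.5)
  # empty screened bin with genome mass flags the projection
  pr3 <- genome_projection(rep(100, 10), rpois(10, 1), c(rep(100, 50),
                                                         rep(1000, 50)))
  expect_true(pr3$partial)
})

test_that("family enrichment matches hypergeometric enumeration", {
  universe <- sprintf("g%03d", 1:100)
  sel <- universe[1:10]
  fams <- list(whole = universe, inside = universe[1:5],
               outside = universe[90:94])
  enr <- family_enrichment(sel, fams, universe)
  expect_equal(enr$p[enr$family == "whole"], 1.0)
  # P(all 5 of a 5-gene family inside a 10-gene selection): enumeration
  # over the hypergeometric tail
  p_exact <- sum(vapply(5:5, function(k)
    choose(5, k) * choose(95, 10 - k) / choose(100, 10), numeric(1)))
  expect_equal(enr$p[enr$family == "inside"], p_exact, tolerance = 1e-12)
  expect_true(enr$q[enr$family == "inside"] >= enr$p[enr$family == "inside"])
  # single family: q equals p
  e1 <- family_enrichment(sel, fams["inside"], universe)
  expect_equal(e1$q, e1$p)
  # BH q-values are non-decreasing in the p-sorted order
  set.seed(503)
  fams2 <- lapply(1:8, function(i) sample(universe, 12))
  names(fams2) <- paste0("f", 1:8)
  e2 <- family_enrichment(sel, fams2, universe)
  o <- order(e2$p)
  expect_true(all(diff(e2$q[o]) >= -1e-12))
})

test_that("screen bookkeeping arithmetic holds", {
  bk <- screen_bookkeeping(164, 10, 56, 585, 133210)
  expect_equal(bk$n_screened, 154)
  expect_equal(bk$n_bound, 98)
  expect_equal(round(bk$positive_rate_pct, 1), 0.4)
})

test_that("PDI and co-expression TSV readers round-trip", {
  sim <- simulate_pdi_network(cfg = sim_config(seed = 8))
  pf <- tempfile(fileext = ".tsv"); cf <- tempfile(fileext = ".tsv")
  write.table(sim$edges, pf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$coexpression, cf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_pdi_tsv(pf), sim$edges, ignore_attr = TRUE)
  got <- read_coexpression_tsv(cf)
  expect_equal(got$score, sim$coexpression$score, tolerance = 1e-9)
})
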