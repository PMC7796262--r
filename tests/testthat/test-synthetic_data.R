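test_that("planted zipper sets honour the degenerate probability settings", {
  z1 <- gen_zipper_set(1, n_heptads = 5, p_leu_d = 1.0, seed = 7)
  d_res <- vapply(z1$truth[[1]]$heptads, function(h) h$residues[["d"]],
                  character(1))
  expect_equal(d_res, rep("L", 5))

  z0 <- gen_zipper_set(5, n_heptads = 5, p_leu_d = 0.0, seed = 7)
  for (tr in z0$truth) {
    expect_false(any(vapply(tr$heptads, function(h) h$residues[["d"]],
                            character(1)) == "L"))
  }

  # no proline inside any planted zipper; exactly one basic-region motif
  z <- gen_zipper_set(20, n_heptads = 4, seed = 42)
  for (i in seq_along(z$proteins)) {
    expect_equal(nrow(find_basic_regions(z$proteins[[i]])), 1)
    reg <- unlist(lapply(z$truth[[i]]$heptads, function(h) h$residues))
    expect_false("P" %in% reg)
  }
  expect_error(gen_zipper_set(2, p_leu_d = 1.5, seed = 1), "probabilities")
})

test_that("planted d-position leucine fraction is binomial around p_leu_d", {
  z <- gen_zipper_set(200, n_heptads = 5, p_leu_d = 0.65, seed = 1)
  d_res <- unlist(lapply(z$truth, function(tr) {
    vapply(tr$heptads, function(h) h$residues[["d"]], character(1))
  }))
  expect_length(d_res, 1000)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.65) / 1000
  expect_gte(mean(d_res == "L"), ci[1])
  expect_lte(mean(d_res == "L"), ci[2])
})

test_that("generators are deterministic given the seed", {
  a <- gen_zipper_set(5, seed = 99)
  b <- gen_zipper_set(5, seed = 99)
  expect_identical(a, b)
  expect_identical(gen_codon_pair(50, omega = 0.5, seed = 3),
                   gen_codon_pair(50, omega = 0.5, seed = 3))
  expect_identical(gen_promoters(2, c("CAAT-box" = 2), length = 300, seed = 5),
                   gen_promoters(2, c("CAAT-box" = 2), length = 300, seed = 5))
  expect_identical(gen_expression(2, 4, 4, 3, seed = 8),
                   gen_expression(2, 4, 4, 3, seed = 8))
  # generator randomness does not leak into the global RNG
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_zipper_set(3, seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("codon-pair simulator respects stop exclusion and zero intensity", {
  p0 <- gen_codon_pair(100, omega = 1, expected_subs_per_codon = 0, seed = 2)
  expect_identical(p0$seq_a$bases, p0$seq_b$bases)
  expect_equal(p0$realized$syn + p0$realized$nonsyn, 0)

  p <- gen_codon_pair(500, omega = 1.0, expected_subs_per_codon = 0.3, seed = 3)
  for (s in list(p$seq_a$bases, p$seq_b$bases)) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
  # at omega = 1 the realized per-site event ratio is about 1
  sites <- vapply(substring(p$ancestor, seq(1, nchar(p$ancestor), 3),
                            seq(3, nchar(p$ancestor), 3)),
                  function(cd) ng_sites(cd)[["s"]], numeric(1))
  S <- sum(sites); N <- 3 * 500 - S
  rate_ratio <- (p$realized$nonsyn / N) / (p$realized$syn / S)
  expect_gt(rate_ratio, 0.6)
  expect_lt(rate_ratio, 1.6)
  expect_error(gen_codon_pair(10, omega = -1, seed = 1), "omega")
})

test_that("planted gene models encode the requested phases", {
  g <- gen_gene_models(list(c(0L, 0L)), seed = 1)
  expect_equal(g$truth$intron_phases, c(0L, 0L))
  expect_true(g$truth$symmetric[2])
  expect_equal(g$truth$exon_classes[2], "(0,0)")

  single <- gen_gene_models(list(), seed = 2)
  expect_true(single$truth$intronless)

  expect_error(gen_gene_models(list(c(0L, 1L), c(2L, 0L)), seed = 3),
               "not realizable")
})

test_that("planted promoters expose exact truth counts", {
  pm <- gen_promoters(1, c("CAAT-box" = 3), length = 400, seed = 11)
  expect_equal(unname(pm$truth[1, "CAAT-box"]), 3L)
  sc <- scan_motifs(pm$promoters[[1]],
                    default_cre_motifs()[default_cre_motifs()$name == "CAAT-box", ])
  expect_equal(unname(sc$counts[["CAAT-box"]]), 3L)

  # palindromic G-box plants count once
  pg <- gen_promoters(1, c("G-box" = 2), length = 400, seed = 12)
  sg <- scan_motifs(pg$promoters[[1]],
                    default_cre_motifs()[default_cre_motifs()$name == "G-box", ])
  expect_equal(unname(sg$counts[["G-box"]]), 2L)

  # all-zero planting scrubs the background clean
  pz <- gen_promoters(1, c("CAAT-box" = 0, "ARE" = 0), length = 400, seed = 13)
  sz <- scan_motifs(pz$promoters[[1]],
                    default_cre_motifs()[default_cre_motifs()$name %in%
                                           c("CAAT-box", "ARE"), ])
  expect_equal(sum(sz$counts), 0L)
})

test_that("planted expression structure is recoverable at high separation", {
  e <- gen_expression(2, 10, 6, separation = 8, seed = 21)
  hc <- hcluster(e$matrix)
  cut <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(paste(cut, e$labels))), 2)

  # duplicate rows merge first at height zero
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  hc2 <- hcluster(m)
  expect_equal(hc2$height[1], 0)
})
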