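test_that("per-codon site fractions match neighbor enumeration", {
  expect_equal(ng_sites("TTT")[["s"]], 1 / 3)
  expect_equal(ng_sites("TTA")[["s"]], 2 / 3)
  expect_equal(ng_sites("TGG")[["s"]], 0)
  expect_error(ng_sites("TAA"), "sense")
  # every sense codon against the independent enumerator; site conservation
  for (cd in sample(ORACLE_SENSE, 15)) {
    s <- ng_sites(cd)
    expect_equal(s[["s"]], oracle_sites(cd), tolerance = 1e-12)
    expect_equal(s[["s"]] + s[["n"]], 3)
  }
})

test_that("pathway-averaged difference counts agree with explicit orderings", {
  # one-step, two-step and three-step cases including a stop-avoiding path
  cases <- list(c("TTT", "TTA"), c("TTT", "CTA"), c("ATG", "TGG"),
                c("TGT", "AGA"), c("AAA", "CCC"), c("TCA", "TTA"))
  for (cs in cases) {
    got <- ng_pair_counts(cs[1], cs[2])
    want <- oracle_pair_counts(cs[1], cs[2])
    expect_equal(got[["sd"]], want[["sd"]], tolerance = 1e-12)
    expect_equal(got[["nd"]], want[["nd"]], tolerance = 1e-12)
    expect_equal(sum(got), sum(strsplit(cs[1], "")[[1]] !=
                                 strsplit(cs[2], "")[[1]]))
  }
})

test_that("protein-guided codon alignment threads codons under gaps", {
  a <- nucleotide_record("a", "ATGAAATTTGGCTAA")  # terminal stop trimmed
  ident <- align_codons(a, a)
  expect_equal(length(ident$codons_a), 4)
  expect_true(all(ident$codons_a == ident$codons_b))

  # deleting one codon yields exactly one gap column
  b <- nucleotide_record("b", "ATGAAAGGC")
  aln <- align_codons(a, b)
  expect_equal(sum(is.na(aln$codons_b) & !is.na(aln$codons_a)), 1)

  expect_error(align_codons(nucleotide_record("x", "ATGTAAAAG"), a),
               "internal stop codon at codon 2")
  expect_error(align_codons(nucleotide_record("y", "ATGA"), a),
               "divisible by 3")

  p <- gen_codon_pair(100, omega = 0.5, expected_subs_per_codon = 0.2, seed = 5)
  expect_equal(length(align_codons(p$seq_a, p$seq_b)$codons_a), 100)
})

test_that("divergence estimation matches the hand-enumerated single column", {
  est <- ng_estimate(list(id_a = "a", id_b = "b",
                          codons_a = "TTT", codons_b = "TTA"))
  expect_equal(est$S, 0.5)
  expect_equal(est$N, 2.5)
  expect_equal(est$Sd, 0)
  expect_equal(est$Nd, 1)
  expect_equal(est$pN, 0.4)
  expect_equal(est$Ka, -0.75 * log(1 - 4 * 0.4 / 3), tolerance = 1e-12)
  expect_true(est$flags$ks_zero)
  expect_true(is.na(est$ratio))

  ident <- ng_estimate(list(id_a = "a", id_b = "b",
                            codons_a = c("TTT", "GGG"),
                            codons_b = c("TTT", "GGG")))
  expect_equal(ident$Sd + ident$Nd, 0)
  expect_true(ident$flags$ks_zero)

  # saturation flags instead of producing distances
  sat <- ng_estimate(list(id_a = "a", id_b = "b",
                          codons_a = c("AAA", "CCC", "GGG", "TTA"),
                          codons_b = c("CCC", "GGG", "TTT", "ATG")))
  expect_true(sat$flags$jc_saturated)
})

test_that("divergence estimation is symmetric and conserves sites", {
  p <- gen_codon_pair(200, omega = 0.4, expected_subs_per_codon = 0.2, seed = 61)
  ab <- ng_estimate(align_codons(p$seq_a, p$seq_b))
  ba <- ng_estimate(align_codons(p$seq_b, p$seq_a))
  for (f in c("S", "N", "Sd", "Nd", "Ks", "Ka", "ratio")) {
    expect_equal(ab[[f]], ba[[f]], tolerance = 1e-12)
  }
  expect_equal(ab$S + ab$N, 3 * ab$n_codons)
  expect_lte(ab$Sd + ab$Nd,
             sum(strsplit(p$seq_a$bases, "")[[1]] !=
                   strsplit(p$seq_b$bases, "")[[1]]))
})

test_that("selection classification bands around neutrality", {
  expect_equal(classify_selection(0.29), "purifying")
  expect_equal(classify_selection(1.0), "neutral")
  expect_equal(classify_selection(1.04), "neutral")
  expect_equal(classify_selection(1.2), "positive")
  flagged <- ng_estimate(list(id_a = "a", id_b = "b",
                              codons_a = "TTT", codons_b = "TTT"))
  expect_equal(classify_selection(flagged), "undetermined")
})

test_that("duplication typing separates tandem from segmental pairs", {
  mk <- function(id, chrom, start, end) {
    gene_model(id, chrom, 1L, exons = rbind(c(start, end)),
               cds_spans = rbind(c(start, start + 299)))
  }
  a <- mk("a", "chr1", 10000, 12000)
  b <- mk("b", "chr1", 20000, 22000)     # 8 kb gap
  c_ <- mk("c", "chr2", 10000, 12000)
  far <- mk("far", "chr1", 500000, 502000)
  expect_equal(classify_duplication(a, b)$type, "tandem")
  expect_equal(classify_duplication(a, c_)$type, "segmental")
  expect_equal(classify_duplication(a, far)$type, "segmental")
  # many intervening genes defeat the tandem call even on one chromosome
  between <- lapply(seq_len(40), function(i) {
    mk(paste0("mid", i), "chr1", 12000 + i * 180, 12100 + i * 180)
  })
  ev <- classify_duplication(a, b, models = c(list(a, b), between),
                             max_distance = 100)
  expect_equal(ev$type, "segmental")
  expect_equal(ev$evidence$intervening, 40)
})

test_that("printed-table ratio arithmetic uses half-up rounding", {
  expect_equal(ratio_from_table(0.18, 0.63), 0.29)
  expect_equal(ratio_from_table(0.69, 1.43), 0.48)
  expect_equal(ratio_from_table(0.39, 2.86), 0.14)
  expect_equal(ratio_from_table(0.125, 1), 0.13)  # half rounds up
  expect_error(ratio_from_table(0.1, 0), "ks > 0")
})
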