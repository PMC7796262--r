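test_that("position frequencies recount exactly from raw registers", {
  z <- gen_zipper_set(40, n_heptads = 6, seed = 31)
  fam <- annotate_family(z$proteins)
  pf <- position_frequencies(fam$annotations, window = c(0, 4))
  # oracle: direct indicator recount from the truth registers
  for (letter in c("a", "d", "e", "g")) {
    recount <- table(unlist(lapply(z$truth, function(tr) {
      vapply(Filter(function(h) h$index <= 4, tr$heptads),
             function(h) h$residues[[letter]], character(1))
    })))
    expect_equal(pf$counts[[letter]][names(recount)],
                 stats::setNames(as.integer(recount), names(recount)))
  }
  # per-letter percentages sum to 100
  for (letter in letters[1:7]) {
    expect_equal(sum(pf$percentages[[letter]]), 100, tolerance = 1e-9)
  }
  # rounded summaries are within half a point of the exact ratios
  expect_true(all(abs(pf$summary - pf$summary_rounded) <= 0.5, na.rm = TRUE))
})

test_that("planted composition summary lands in the 99% binomial band", {
  z <- gen_zipper_set(200, n_heptads = 5, p_leu_d = 0.65, seed = 37)
  fam <- annotate_family(z$proteins)
  pf <- position_frequencies(fam$annotations)
  expect_equal(pf$n_heptads, 1000)
  ci <- 100 * qbinom(c(0.005, 0.995), 1000, 0.65) / 1000
  expect_gte(pf$summary[["pct_L_at_d"]], ci[1])
  expect_lte(pf$summary[["pct_L_at_d"]], ci[2])
  expect_error(position_frequencies(fam$annotations, window = c(3, 1)),
               "window")
})

test_that("g-e' classification follows the charge rules and is symmetric", {
  expect_equal(classify_ge_pair("E", "K"), "attractive")
  expect_equal(classify_ge_pair("E", "D"), "repulsive")
  expect_equal(classify_ge_pair("K", "R"), "repulsive")
  expect_equal(classify_ge_pair("E", "Q"), "incomplete")
  expect_equal(classify_ge_pair("H", "D"), "incomplete")  # H is uncharged
  expect_equal(classify_ge_pair(NA, "K"), "incomplete")
  for (x in zipperscan:::AA_STANDARD) {
    for (y in zipperscan:::AA_STANDARD) {
      expect_identical(classify_ge_pair(x, y), classify_ge_pair(y, x))
    }
  }
})

test_that("a-a' rule table covers the stated cases and defaults to neutral", {
  expect_equal(classify_aa_pair("V", "V"), "favorable")
  expect_equal(classify_aa_pair("I", "I"), "favorable")
  expect_equal(classify_aa_pair("R", "R"), "favorable")
  expect_equal(classify_aa_pair("N", "V"), "hetero_favoring")
  expect_equal(classify_aa_pair("V", "N"), "hetero_favoring")
  expect_equal(classify_aa_pair("N", "I"), "destabilizing")
  expect_equal(classify_aa_pair("K", "E"), "destabilizing")
  expect_equal(classify_aa_pair("K", "K"), "destabilizing")
  expect_equal(classify_aa_pair("A", "S"), "neutral")
  expect_equal(classify_aa_pair("N", "N"), "neutral")
})

test_that("homodimer profiles match an explicit contact enumeration", {
  ann <- random_annotation(4, seed = 41)
  prof <- homodimer_profile(ann)
  expect_equal(nrow(prof), 3)  # k = 0..2 have a k+1 partner
  for (row in seq_len(nrow(prof))) {
    k <- prof$heptad_index[row]
    g <- ann$heptads[[k + 1]]$residues[["g"]]
    e_next <- ann$heptads[[k + 2]]$residues[["e"]]
    a <- ann$heptads[[k + 1]]$residues[["a"]]
    expect_identical(prof$ge_class[row], classify_ge_pair(g, e_next))
    expect_identical(prof$aa_class[row], classify_aa_pair(a, a))
  }

  # degenerate all-E-g / all-K-e zipper is uniformly attractive
  uni <- random_annotation(5, seed = 43)
  for (i in seq_along(uni$heptads)) {
    uni$heptads[[i]]$residues[["g"]] <- "E"
    uni$heptads[[i]]$residues[["e"]] <- "K"
  }
  expect_true(all(homodimer_profile(uni)$ge_class == "attractive"))
  for (i in seq_along(uni$heptads)) uni$heptads[[i]]$residues[["e"]] <- "R"
  for (i in seq_along(uni$heptads)) uni$heptads[[i]]$residues[["g"]] <- "K"
  expect_true(all(homodimer_profile(uni)$ge_class == "repulsive"))

  short <- random_annotation(1, seed = 47)
  expect_warning(out <- homodimer_profile(short), "fewer than two")
  expect_equal(nrow(out), 0)

  # the alternative same-heptad register convention is available
  same_k <- homodimer_profile(ann, e_offset = 0)
  expect_equal(nrow(same_k), 4)
  expect_identical(same_k$ge_class[1],
                   classify_ge_pair(ann$heptads[[1]]$residues[["g"]],
                                    ann$heptads[[1]]$residues[["e"]]))
})

test_that("group pattern table reports modal classes per heptad", {
  mk_ann <- function(id, g_res, e_res, n = 4) {
    a <- random_annotation(n, seed = 53)
    a$protein_id <- id
    for (i in seq_len(n)) {
      a$heptads[[i]]$residues[["g"]] <- g_res
      a$heptads[[i]]$residues[["e"]] <- e_res
    }
    a
  }
  anns <- list(mk_ann("StbZIP55", "E", "K"), mk_ann("StbZIP54", "E", "K"),
               mk_ann("StbZIP17", "K", "K"), mk_ann("StbZIP28", "K", "K"),
               mk_ann("StbZIP33", "E", "R"))
  tab <- group_pattern_table(anns, load_table1_fixture())
  g_rows <- tab[tab$group == "G", ]
  expect_true(all(g_rows$modal_class == "attractive"))
  expect_true(all(g_rows$frequency == 1))
  b_rows <- tab[tab$group == "B", ]
  expect_true(all(b_rows$modal_class == "repulsive"))
  # mixed 2:1 gives modal frequency 2/3
  expect_true(all(abs(b_rows$frequency - 2 / 3) < 1e-9))

  bad <- anns
  bad[[1]]$protein_id <- "NotInCatalog"
  expect_error(group_pattern_table(bad, load_table1_fixture()),
               "not present in catalog")
})
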