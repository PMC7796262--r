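test_that("basic-region motif scan reports all overlapping N-x7-R/K hits", {
  hit <- find_basic_regions(protein_record("p", "AANAAAAAAARAA"))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$n_pos, 3)   # 1-based position of the N
  expect_equal(hit$rk_pos, 11)

  expect_equal(nrow(find_basic_regions(protein_record("p", "NKKKKKKKK"))), 1)
  expect_equal(nrow(find_basic_regions(protein_record("p", "NAAAAAAAQ"))), 0)

  # overlapping matches are all reported
  two <- find_basic_regions(protein_record("p", "NNAAAAAAKRAAA"))
  expect_equal(two$n_pos, c(1, 2))
  # 16-residue context clipped at the sequence start
  expect_equal(two$span_start, c(1, 1))
  expect_equal(two$span_end, two$rk_pos)
})

test_that("register assignment anchors at the first downstream leucine", {
  # N at 1, K at 9, anchor L at 13 = d of L0; P at 21 (= e of would-be L1)
  p <- protein_record("p", "NAAAAAAAKAAALAAAAAAAPAAAA")
  hit <- find_basic_regions(p)
  ann <- assign_register(p, hit[1, ])
  expect_equal(ann$anchor_pos, 13)
  expect_equal(n_complete_heptads(ann), 1)
  expect_equal(ann$terminated_by, "disruptor")
  expect_equal(ann$heptads[[1]]$residues[["d"]], "L")
  expect_equal(names(ann$heptads[[1]]$residues), letters[1:7])

  # no leucine and no aliphatic downstream: empty heptads, not an error
  none <- protein_record("q", "NAAAAAAAKAAAAAAA")
  ann2 <- assign_register(none, find_basic_regions(none)[1, ])
  expect_length(ann2$heptads, 0)
  expect_equal(ann2$terminated_by, "end_of_sequence")

  # aliphatic fallback anchor is flagged weak
  weak <- protein_record("r", "NAAAAAAAKAAAVAAAAAAAAAA")
  ann3 <- assign_register(weak, find_basic_regions(weak)[1, ])
  expect_true(ann3$weak_anchor)
  expect_equal(ann3$anchor_pos, 13)

  # anchor at the last residue: single truncated heptad
  last <- protein_record("s", "NAAAAAAAKAAL")
  ann4 <- assign_register(last, find_basic_regions(last)[1, ])
  expect_length(ann4$heptads, 1)
  expect_equal(ann4$terminated_by, "end_of_sequence")
  expect_true("d" %in% names(ann4$heptads[[1]]$residues))
  expect_false("e" %in% names(ann4$heptads[[1]]$residues))
})

test_that("register arithmetic ties every letter to its anchor offset", {
  z <- gen_zipper_set(30, n_heptads = c(3, 6, 10), seed = 17)
  fam <- annotate_family(z$proteins)
  offsets <- c(a = -3L, b = -2L, c = -1L, d = 0L, e = 1L, f = 2L, g = 3L)
  for (ann in fam$annotations) {
    cs <- strsplit(z$proteins[[ann$protein_id]]$residues, "")[[1]]
    for (h in ann$heptads) {
      for (l in names(h$residues)) {
        pos <- ann$anchor_pos + 7L * h$index + offsets[[l]]
        expect_identical(h$residues[[l]], cs[pos])
      }
    }
  }
})

test_that("family annotation recovers planted registers and rejects non-hits", {
  z <- gen_zipper_set(80, n_heptads = c(3, 5, 8), seed = 23)
  proteins <- c(z$proteins,
                list(noise = protein_record("noise", "MAAAAAGGGGSSSSTTTT")))
  fam <- annotate_family(proteins)
  expect_equal(fam$rejected, "noise")
  expect_length(fam$annotations, 80)
  for (id in names(z$truth)) {
    expect_true(registers_equal(fam$annotations[[id]], z$truth[[id]]))
  }

  # annotating the same sequence twice is idempotent
  again <- annotate_family(z$proteins)
  expect_identical(fam$annotations[names(z$truth)], again$annotations)
})

test_that("among multiple hits the one yielding most complete heptads wins", {
  # the first motif anchors on a leucine immediately followed by proline
  # (zero complete heptads); the second precedes a three-heptad zipper
  seq <- paste0("NAAAAAAAKLPQQQQQQ",
                "NSSSSSSSR", "AAALAAAAAALAAAAAALAAAP")
  p <- protein_record("two", seq)
  hits <- find_basic_regions(p)
  expect_gte(nrow(hits), 2)
  fam <- annotate_family(list(p))
  chosen <- fam$annotations$two
  # brute force over all hits agrees
  counts <- vapply(seq_len(nrow(hits)), function(i) {
    n_complete_heptads(assign_register(p, hits[i, ]))
  }, integer(1))
  expect_equal(n_complete_heptads(chosen), max(counts))
  expect_equal(chosen$n_pos, hits$n_pos[which.max(counts)])
})

test_that("the disruptor set is configurable", {
  # glycine in the second heptad stops tiling only when G is a disruptor
  p <- protein_record("g", "NAAAAAAAKAAALAAAAAAGLAAAAAAALAAAP")
  hit <- find_basic_regions(p)[1, ]
  default <- assign_register(p, hit)
  strict <- assign_register(p, hit, disruptors = c("P", "G"))
  expect_gt(length(default$heptads), length(strict$heptads))
  expect_equal(strict$terminated_by, "disruptor")
})
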