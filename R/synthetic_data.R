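# Synthetic inputs with exposed ground truth for every analysis stage:
# proteins with planted basic regions and heptad registers, codon-sequence
# pairs diverged under a target dN/dS, gene models with planted intron
# phases, promoters with planted motif counts, and expression matrices with
# planted cluster structure. Every generator is deterministic given its
# seed and isolates its randomness from the global RNG.

# Background alphabet used inside planted zippers at positions that carry
# no signature: excludes the disruptor (P), the anchor aliphatics (L,I,V,M),
# the basic-region asparagine (N) and the charged set (D,E,K,R) so that the
# planted signature frequencies are exact and the planted anchor is the
# first aliphatic/leucine downstream of the basic region.
ZIPPER_BG <- c("A", "S", "T", "G", "Q", "H", "F", "Y", "W", "C")
A_SET <- c("N", "I", "V", "M")

#' Generate proteins with planted zipper registers
#'
#' Each protein is built as: a flank free of asparagine (so the planted
#' motif is the only basic-region match), the basic-region motif (N, seven
#' non-disruptor residues, R or K), the zipper (`n_heptads` heptads of
#' seven residues, register a-g, with the L0 d position four residues after
#' the R/K), a proline that terminates helix tiling, and a final flank.
#' Residues at a/d/e/g are drawn per the spec probabilities; all other
#' zipper positions use a neutral background alphabet so the planted
#' frequencies are exact. When the L0 d position draws no leucine, the
#' d-position draws are permuted so any leucine among them appears at L0
#' first -- this keeps the planted anchor identifiable while leaving the
#' aggregate d-position composition exactly binomial with `p_leu_d`.
#'
#' @param n_proteins number of proteins.
#' @param n_heptads heptads per protein (scalar, or a vector sampled
#'   uniformly per protein); at least 3.
#' @param p_leu_d probability of leucine at the d position (family surveys
#'   report about 0.65).
#' @param p_charged_g,p_charged_e probability of a charged residue
#'   (D, E, K, R) at g and e (surveys report about 0.43 and 0.28).
#' @param p_a_set probability of drawing from {N, I, V, M} at a (about
#'   0.30); the L0 heptad realizes this set as N so the anchor stays
#'   unambiguous.
#' @param flank_len flank length before the basic region and after the
#'   zipper.
#' @param seed integer seed.
#' @return list with `proteins` (list of [protein_record()]) and `truth`
#'   (list of `zipper_annotation` ground truth, 1-based positions).
#' @export
gen_zipper_set <- function(n_proteins, n_heptads = 5, p_leu_d = 0.65,
                           p_charged_g = 0.43, p_charged_e = 0.28,
                           p_a_set = 0.30, flank_len = 15, seed) {
  probs <- c(p_leu_d, p_charged_g, p_charged_e, p_a_set)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  stopifnot(n_proteins >= 1, all(n_heptads >= 3), flank_len >= 0)
  with_seed(seed, {
    proteins <- vector("list", n_proteins)
    truth <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      nh <- if (length(n_heptads) > 1L) sample_one(n_heptads) else n_heptads
      pre <- sample_vec(setdiff(AA_STANDARD, "N"), flank_len)
      inner <- sample_vec(setdiff(AA_STANDARD, c("N", "P")), 7L)
      rk <- sample_one(c("R", "K"))

      d_res <- ifelse(stats::runif(nh) < p_leu_d, "L", NA)
      d_res[is.na(d_res)] <- sample_vec(c("I", "V", "M"), sum(is.na(d_res)))
      if (d_res[1L] != "L" && any(d_res == "L")) {
        j <- which(d_res == "L")[1L]   # bring a leucine to L0: anchor stays
        d_res[c(1L, j)] <- d_res[c(j, 1L)]  # planted, composition unchanged
      }
      heptads <- vector("list", nh)
      zipper <- character(0)
      for (k in seq_len(nh)) {
        a <- if (stats::runif(1) < p_a_set) {
          if (k == 1L) "N" else sample_one(A_SET)
        } else sample_one(ZIPPER_BG)
        e <- if (stats::runif(1) < p_charged_e) sample_one(AA_CHARGED) else sample_one(ZIPPER_BG)
        g <- if (stats::runif(1) < p_charged_g) sample_one(AA_CHARGED) else sample_one(ZIPPER_BG)
        res <- c(a = a, b = sample_one(ZIPPER_BG), c = sample_one(ZIPPER_BG),
                 d = d_res[k], e = e, f = sample_one(ZIPPER_BG), g = g)
        heptads[[k]] <- new_heptad(k - 1L, res)
        zipper <- c(zipper, res)
      }
      # the trailing flank excludes N/K/R (an a-position asparagine in the
      # last heptad must not pair with a flank basic residue into a second
      # basic-region motif) and L (an all-aliphatic zipper must not have
      # its anchor captured by a flank leucine)
      post <- c("P", sample_vec(setdiff(AA_STANDARD, c("N", "L", "K", "R")),
                                flank_len))
      seq <- paste(c(pre, "N", inner, rk, zipper, post), collapse = "")
      id <- sprintf("synth%03d", i)
      n_pos <- as.integer(flank_len) + 1L
      rk_pos <- n_pos + 8L
      proteins[[i]] <- protein_record(id, seq)
      truth[[i]] <- structure(
        list(protein_id = id, n_pos = n_pos, rk_pos = rk_pos,
             anchor_pos = rk_pos + 4L, weak_anchor = d_res[1L] != "L",
             heptads = heptads, terminated_by = "disruptor"),
        class = "zipper_annotation")
    }
    names(proteins) <- names(truth) <- vapply(proteins, function(p) p$id,
                                              character(1))
    list(proteins = proteins, truth = truth)
  })
}

#' Generate a codon-sequence pair diverged under a target dN/dS
#'
#' Draws a uniform ancestor over sense codons and evolves two independent
#' descendant lineages by proposal/acceptance: candidate single-nucleotide
#' changes are proposed uniformly over positions and alternative bases
#' (a Poisson number of proposals with mean
#' `n_codons * expected_subs_per_codon` per lineage), candidates creating a
#' stop codon are rejected, and the remaining candidates are accepted with
#' probability `min(1, omega)` when nonsynonymous and `min(1, 1/omega)`
#' when synonymous -- so the realized nonsynonymous/synonymous rate ratio
#' has expectation `omega`. The realized accepted event counts are returned
#' as ground truth.
#'
#' @param n_codons number of codons.
#' @param omega target dN/dS (> 0).
#' @param expected_subs_per_codon proposal intensity per codon per lineage.
#' @param seed integer seed.
#' @return list with `seq_a`, `seq_b` ([nucleotide_record()]s),
#'   `ancestor`, and `realized` (accepted `syn`/`nonsyn` counts summed over
#'   both lineages).
#' @export
gen_codon_pair <- function(n_codons, omega = 0.5,
                           expected_subs_per_codon = 0.15, seed) {
  if (!is.numeric(omega) || omega <= 0) stop("omega must be > 0")
  stopifnot(n_codons >= 1, expected_subs_per_codon >= 0)
  p_nonsyn <- min(1, omega)
  p_syn <- min(1, 1 / omega)
  with_seed(seed, {
    ancestor <- sample_vec(SENSE_CODONS, n_codons)
    evolve <- function(codons) {
      syn <- 0L; nonsyn <- 0L
      n_prop <- stats::rpois(1L, n_codons * expected_subs_per_codon)
      if (n_prop > 0L) {
        for (rep in seq_len(n_prop)) {
          ci <- sample.int(n_codons, 1L)
          pos <- sample.int(3L, 1L)
          cur <- codons[ci]
          alt <- sample_one(setdiff(DNA_BASES, substr(cur, pos, pos)))
          cand <- cur
          substr(cand, pos, pos) <- alt
          if (GENETIC_CODE[[cand]] == "*") next  # never create a stop
          is_syn <- GENETIC_CODE[[cand]] == GENETIC_CODE[[cur]]
          p_acc <- if (is_syn) p_syn else p_nonsyn
          if (stats::runif(1) < p_acc) {
            codons[ci] <- cand
            if (is_syn) syn <- syn + 1L else nonsyn <- nonsyn + 1L
          }
        }
      }
      list(codons = codons, syn = syn, nonsyn = nonsyn)
    }
    a <- evolve(ancestor)
    b <- evolve(ancestor)
    list(
      seq_a = nucleotide_record("lineage_a", paste(a$codons, collapse = "")),
      seq_b = nucleotide_record("lineage_b", paste(b$codons, collapse = "")),
      ancestor = paste(ancestor, collapse = ""),
      realized = list(syn = a$syn + b$syn, nonsyn = a$nonsyn + b$nonsyn)
    )
  })
}

#' Generate a gene model with planted intron phases
#'
#' Builds one gene whose internal coding exons carry the requested
#' flanking-phase pairs. `phase_pairs` lists the intended (left, right)
#' intron phases of each internal exon; consecutive pairs must chain
#' (the right phase of one internal exon is the left phase of the next),
#' and an empty list yields a single-exon (intronless) gene. Exon lengths
#' are drawn from `exon_len_range` and adjusted to the residue class (mod
#' 3) each phase requires; the total CDS length is always divisible by 3.
#'
#' @param phase_pairs list of length-2 integer vectors, phases in
#'   {0, 1, 2}, one per internal exon; `list()` for an intronless gene.
#' @param exon_len_range,intron_len_range length ranges (bp).
#' @param strand `"+"` or `"-"`.
#' @param gene_id identifier for the generated gene.
#' @param flank bp of plain chromosome sequence on each side.
#' @param seed integer seed.
#' @return list with `gff3` (character lines), `fasta` (character lines),
#'   `model` (the [gene_model()]), and `truth` (the planted
#'   `gene_structure_profile`).
#' @export
gen_gene_models <- function(phase_pairs, exon_len_range = c(60, 300),
                            intron_len_range = c(80, 200), strand = "+",
                            gene_id = "syngene1", flank = 300, seed) {
  stopifnot(strand %in% c("+", "-"))
  phase_pairs <- lapply(phase_pairs, as.integer)
  for (p in phase_pairs) {
    if (length(p) != 2L || !all(p %in% 0:2)) {
      stop("each phase pair must be two phases in {0, 1, 2}")
    }
  }
  m <- length(phase_pairs)
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      if (phase_pairs[[j]][2L] != phase_pairs[[j + 1L]][1L]) {
        stop("phase pairs are not realizable: right phase of internal exon ",
             j, " must equal left phase of internal exon ", j + 1L)
      }
    }
  }
  # intron phases implied by the internal-exon pairs; n_exons = m + 2
  # (or a single exon when no internal exons are requested)
  intron_phase <- if (m == 0L) integer(0) else
    c(phase_pairs[[1L]][1L], vapply(phase_pairs, `[`, integer(1), 2L))
  n_exons <- length(intron_phase) + 1L

  with_seed(seed, {
    # cumulative CDS length before intron i must be = intron_phase[i] mod 3
    lens <- integer(n_exons)
    cum <- 0L
    targets <- c(intron_phase, 0L)  # final virtual phase 0: total % 3 == 0
    for (i in seq_len(n_exons)) {
      base <- sample.int(exon_len_range[2L] - exon_len_range[1L] + 1L, 1L) +
        exon_len_range[1L] - 1L
      need <- (targets[i] - cum) %% 3L
      len <- base + ((need - base %% 3L) %% 3L)
      lens[i] <- len
      cum <- (cum + len) %% 3L
    }
    introns <- if (n_exons > 1L) {
      sample.int(intron_len_range[2L] - intron_len_range[1L] + 1L,
                 n_exons - 1L, replace = TRUE) + intron_len_range[1L] - 1L
    } else integer(0)

    # transcript order 5'->3'; genomic layout depends on strand
    tx_lens <- lens
    genomic_lens <- if (strand == "+") tx_lens else rev(tx_lens)
    genomic_introns <- if (strand == "+") introns else rev(introns)
    starts <- integer(n_exons)
    pos <- flank + 1L
    exons <- matrix(0L, n_exons, 2L)
    for (i in seq_len(n_exons)) {
      exons[i, ] <- c(pos, pos + genomic_lens[i] - 1L)
      pos <- pos + genomic_lens[i] +
        if (i < n_exons) genomic_introns[i] else 0L
    }
    chrom_len <- pos - 1L + flank
    chrom_seq <- paste(sample_vec(DNA_BASES, chrom_len), collapse = "")
    model <- gene_model(gene_id, "chr1", if (strand == "+") 1L else -1L,
                        exons = exons, cds_spans = exons,
                        transcript_id = paste0(gene_id, ".1"))
    left <- c(0L, intron_phase)
    right <- c(intron_phase, 0L)
    truth <- structure(
      list(gene_id = gene_id, intron_phases = intron_phase,
           exon_classes = sprintf("(%d,%d)", left, right),
           left = left, right = right, symmetric = left == right,
           intronless = n_exons == 1L, partial = FALSE),
      class = "gene_structure_profile")
    list(gff3 = gff3_text(model),
         fasta = c(">chr1", chrom_seq),
         model = model, truth = truth)
  })
}

#' Generate promoters with planted motif counts
#'
#' Each promoter is a random background of the requested GC content into
#' which the requested number of non-overlapping motif instances is
#' planted (IUPAC ambiguity codes realized at random). After planting, any
#' spurious match of a listed motif arising from the background is removed
#' by resampling bases outside the planted sites, so a scanner recovers
#' the planted counts exactly. Motif sets in which one listed motif can
#' match inside another's planted site cannot be cleaned and raise an
#' error.
#'
#' @param n_promoters number of promoters.
#' @param motif_counts named integer vector: planted count per motif name
#'   (names must appear in `motifs`). Listed motifs with no entry are
#'   planted zero times and cleaned from the background.
#' @param motifs motif table as from [default_cre_motifs()]. By default the
#'   bundled table restricted to the names in `motif_counts`: passing a
#'   larger table demands that the extra motifs have zero background
#'   matches too, which is impossible when one listed motif can occur
#'   inside another's planted site (e.g. ABRE inside a planted G-box).
#' @param length promoter length in bp (default 2000).
#' @param gc_background background GC fraction.
#' @param seed integer seed.
#' @return list with `promoters` (list of [nucleotide_record()]) and
#'   `truth` (matrix, promoters x motifs, of planted counts).
#' @export
gen_promoters <- function(n_promoters = 1, motif_counts,
                          motifs = NULL, length = 2000,
                          gc_background = 0.4, seed) {
  if (is.null(motifs)) {
    motifs <- default_cre_motifs()
    motifs <- motifs[motifs$name %in% names(motif_counts), , drop = FALSE]
  }
  validate_motifs(motifs)
  stopifnot(is.numeric(motif_counts), !is.null(names(motif_counts)),
            all(names(motif_counts) %in% motifs$name),
            all(motif_counts >= 0), length >= 1,
            gc_background >= 0, gc_background <= 1)
  patterns <- stats::setNames(toupper(motifs$pattern), motifs$name)
  full_counts <- stats::setNames(integer(nrow(motifs)), motifs$name)
  full_counts[names(motif_counts)] <- as.integer(motif_counts)
  widths <- nchar(patterns)
  gap <- max(widths)  # spacing so planted sites cannot create junction hits
  if (sum(full_counts * (widths[names(full_counts)] + 2L * gap)) > length) {
    stop("planted motifs do not fit without overlap in ", length, " bp")
  }
  base_probs <- c(A = (1 - gc_background) / 2, C = gc_background / 2,
                  G = gc_background / 2, T = (1 - gc_background) / 2)
  with_seed(seed, {
    promoters <- vector("list", n_promoters)
    for (i in seq_len(n_promoters)) {
      seq <- sample(DNA_BASES, length, replace = TRUE, prob = base_probs)
      # place planted instances left to right with enforced spacing
      slots <- list()
      cursor <- 1L
      for (nm in names(full_counts)) {
        cnt <- full_counts[[nm]]
        if (cnt == 0L) next
        for (rep in seq_len(cnt)) {
          w <- widths[[nm]]
          inst <- realize_iupac(patterns[[nm]])
          start <- cursor + sample.int(gap, 1L)
          stopifnot(start + w - 1L <= length)
          seq[start:(start + w - 1L)] <- chars(inst)
          slots[[length(slots) + 1L]] <- c(start, start + w - 1L)
          cursor <- start + w - 1L + gap
        }
      }
      planted <- if (length(slots)) do.call(rbind, slots) else
        matrix(0L, 0L, 2L)
      seq <- scrub_spurious(seq, patterns, planted, full_counts, base_probs)
      promoters[[i]] <- nucleotide_record(sprintf("synprom%03d", i),
                                          paste(seq, collapse = ""))
    }
    truth <- matrix(rep(full_counts, each = n_promoters), nrow = n_promoters,
                    dimnames = list(vapply(promoters, function(p) p$id,
                                           character(1)),
                                    names(full_counts)))
    list(promoters = promoters, truth = truth)
  })
}

realize_iupac <- function(pattern) {
  amb <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(chars(pattern), function(ch) sample_one(chars(amb[[ch]])),
               character(1)), collapse = "")
}

# Resample background bases until each listed motif matches only at its
# planted sites (both strands, palindromes once).
scrub_spurious <- function(seq, patterns, planted, counts, base_probs) {
  in_planted <- rep(FALSE, length(seq))
  if (nrow(planted) > 0L) {
    for (r in seq_len(nrow(planted))) {
      in_planted[planted[r, 1L]:planted[r, 2L]] <- TRUE
    }
  }
  for (iter in seq_len(500L)) {
    subj <- Biostrings::DNAString(paste(seq, collapse = ""))
    dirty <- FALSE
    for (nm in names(patterns)) {
      pat <- Biostrings::DNAString(patterns[[nm]])
      hits <- Biostrings::matchPattern(pat, subj, fixed = "subject")
      ranges <- cbind(Biostrings::start(hits), Biostrings::end(hits))
      if (!is_rc_palindrome(patterns[[nm]])) {
        rc <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                       subj, fixed = "subject")
        ranges <- rbind(ranges, cbind(Biostrings::start(rc),
                                      Biostrings::end(rc)))
      }
      n_expected <- counts[[nm]]
      if (nrow(ranges) == n_expected) next
      for (r in seq_len(nrow(ranges))) {
        span <- ranges[r, 1L]:ranges[r, 2L]
        if (all(in_planted[span])) next  # a planted site (or nested in one)
        editable <- span[!in_planted[span]]
        pos <- sample_one(editable)
        seq[pos] <- sample_one(setdiff(DNA_BASES, seq[pos]))
        dirty <- TRUE
      }
      if (!dirty && nrow(ranges) != n_expected) {
        stop("cannot scrub motif '", nm, "': a listed motif matches inside ",
             "another motif's planted site")
      }
    }
    if (!dirty) return(seq)
  }
  stop("failed to remove spurious motif matches after 500 passes")
}

#' Generate an expression matrix with planted cluster structure
#'
#' Genes fall into `groups` blocks; each block is elevated by `separation`
#' log2 units in its own subset of samples (samples are split evenly among
#' the groups) over a common baseline, with Gaussian noise. With large
#' separation, complete-linkage clustering cut at the number of groups
#' recovers the labels exactly.
#'
#' @param groups number of gene groups.
#' @param genes_per_group genes per group.
#' @param samples number of samples (at least `groups`).
#' @param separation effect size (log2 units) between in-block and
#'   out-of-block means.
#' @param baseline baseline log2 expression.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return list with `matrix` (genes x samples, log2 scale) and `labels`
#'   (integer group per gene).
#' @export
gen_expression <- function(groups, genes_per_group, samples,
                           separation, baseline = 2, noise_sd = 1, seed) {
  stopifnot(groups >= 1, genes_per_group >= 1, samples >= groups,
            separation >= 0, noise_sd >= 0)
  with_seed(seed, {
    n_genes <- groups * genes_per_group
    labels <- rep(seq_len(groups), each = genes_per_group)
    sample_group <- rep(seq_len(groups), length.out = samples)
    mu <- matrix(baseline, n_genes, samples)
    for (g in seq_len(groups)) {
      mu[labels == g, sample_group == g] <- baseline + separation
    }
    mat <- mu + matrix(stats::rnorm(n_genes * samples, sd = noise_sd),
                       n_genes, samples)
    dimnames(mat) <- list(sprintf("gene_g%d_%03d", labels,
                                  stats::ave(labels, labels, FUN = seq_along)),
                          sprintf("sample_%02d", seq_len(samples)))
    list(matrix = mat, labels = stats::setNames(labels, rownames(mat)))
  })
}
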