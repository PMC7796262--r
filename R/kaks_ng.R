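# Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction,
# protein-guided codon alignment, and tandem/segmental duplication
# classification for given paralog pairs.

GENETIC_CODE <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
STOP_CODONS <- names(GENETIC_CODE)[GENETIC_CODE == "*"]

codon_aa <- function(codon) unname(GENETIC_CODE[codon])

codon_neighbors <- function(codon) {
  cs <- chars(codon)
  out <- character(9L)
  i <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(DNA_BASES, cs[pos])) {
      n <- cs
      n[pos] <- alt
      i <- i + 1L
      out[i] <- paste(n, collapse = "")
    }
  }
  out
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three codon positions, the fraction of the three possible
#' single-nucleotide changes that are synonymous is computed; changes that
#' create a stop codon count as nonsynonymous. The synonymous site count `s`
#' is the sum of the three fractions and the nonsynonymous count is `3 - s`
#' (the counting step of the Nei-Gojobori method).
#'
#' @param codon a sense codon (3-letter DNA string).
#' @return named numeric vector `c(s = , n = )` with `s + n == 3`.
#' @examples
#' ng_sites("TTT")  # s = 1/3
#' ng_sites("TGG")  # s = 0 (tryptophan)
#' @export
ng_sites <- function(codon) {
  stopifnot(is_string(codon), nchar(codon) == 3L)
  codon <- toupper(codon)
  if (!codon %in% SENSE_CODONS) {
    stop("'", codon, "' is not a sense codon")
  }
  aa <- codon_aa(codon)
  s <- 0
  cs <- chars(codon)
  for (pos in 1:3) {
    syn <- 0L
    for (alt in setdiff(DNA_BASES, cs[pos])) {
      n <- cs
      n[pos] <- alt
      naa <- codon_aa(paste(n, collapse = ""))
      if (naa != "*" && naa == aa) syn <- syn + 1L
    }
    s <- s + syn / 3
  }
  c(s = s, n = 3 - s)
}

#' Pathway-averaged substitution counts between two codons
#'
#' Counts synonymous (`sd`) and nonsynonymous (`nd`) differences between two
#' sense codons, averaged over all orderings of the differing positions
#' (the pathway averaging of the Nei-Gojobori method). Pathways passing
#' through a stop codon are skipped; if every pathway hits a stop, the
#' average falls back to all pathways with stop transitions counted as
#' nonsynonymous.
#'
#' @param codon_a,codon_b sense codons.
#' @param skip_stop_paths skip stop-traversing pathways (default, the
#'   documented convention); set `FALSE` to average over all pathways.
#' @return named numeric vector `c(sd = , nd = )`; `sd + nd` equals the
#'   number of differing positions.
#' @export
ng_pair_counts <- function(codon_a, codon_b, skip_stop_paths = TRUE) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!codon_a %in% SENSE_CODONS || !codon_b %in% SENSE_CODONS) {
    stop("both codons must be sense codons")
  }
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  # depth-first accumulation over orderings of the differing positions;
  # each branch contributes the TOTAL counts of its valid pathways so the
  # final division by the pathway count is a uniform average over pathways
  walk <- function(cur, target, allow_stop) {
    diffs <- which(chars(cur) != chars(target))
    if (length(diffs) == 0L) return(c(sd = 0, nd = 0, valid = 1))
    acc <- c(sd = 0, nd = 0, valid = 0)
    for (pos in diffs) {
      nxt <- chars(cur)
      nxt[pos] <- chars(target)[pos]
      nxt <- paste(nxt, collapse = "")
      aa_cur <- codon_aa(cur); aa_nxt <- codon_aa(nxt)
      if (aa_nxt == "*" && !allow_stop) next
      step_syn <- (aa_cur == aa_nxt && aa_cur != "*")
      rest <- walk(nxt, target, allow_stop)
      nv <- rest[["valid"]]
      if (nv > 0) {
        acc <- acc + c(sd = (as.numeric(step_syn) + rest[["sd"]]) * nv,
                       nd = (as.numeric(!step_syn) + rest[["nd"]]) * nv,
                       valid = nv)
      }
    }
    if (acc[["valid"]] == 0) return(c(sd = 0, nd = 0, valid = 0))
    c(sd = acc[["sd"]] / acc[["valid"]], nd = acc[["nd"]] / acc[["valid"]],
      valid = acc[["valid"]])
  }
  res <- walk(codon_a, codon_b, allow_stop = !skip_stop_paths)
  if (res[["valid"]] == 0) res <- walk(codon_a, codon_b, allow_stop = TRUE)
  c(sd = res[["sd"]], nd = res[["nd"]])
}

# Cached lookup tables over the 61 sense codons, built on first use.
.ng_cache <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (is.null(.ng_cache$SD)) {
    n <- length(SENSE_CODONS)
    SD <- matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
    ND <- SD
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        cnt <- ng_pair_counts(SENSE_CODONS[i], SENSE_CODONS[j])
        SD[i, j] <- cnt[["sd"]]
        ND[i, j] <- cnt[["nd"]]
      }
    }
    sites <- t(vapply(SENSE_CODONS, ng_sites, numeric(2)))
    .ng_cache$SD <- SD
    .ng_cache$ND <- ND
    .ng_cache$S_SITES <- sites[, "s"]
  }
  .ng_cache
}

split_codons <- function(bases) {
  n <- nchar(bases)
  substring(bases, seq(1L, n, 3L), seq(3L, n, 3L))
}

validate_cds <- function(record, trim_terminal_stop = TRUE) {
  bases <- record_seq(record)
  if (nchar(bases) %% 3L != 0L) {
    stop("CDS length of '", record$id, "' (", nchar(bases),
         ") is not divisible by 3")
  }
  codons <- split_codons(bases)
  if (trim_terminal_stop && length(codons) > 0L &&
      codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  internal_stop <- which(codons %in% STOP_CODONS)
  if (length(internal_stop) > 0L) {
    stop("internal stop codon at codon ", internal_stop[1L], " in '",
         record$id, "'")
  }
  if (any(grepl("N", codons, fixed = TRUE))) {
    stop("ambiguous base (N) in CDS '", record$id, "'")
  }
  codons
}

#' Protein-guided pairwise codon alignment
#'
#' Translates both coding sequences, aligns the proteins globally
#' (BLOSUM62 substitution scores, linear gap penalty), and threads the
#' codons back under the protein alignment. Terminal stop codons are
#' trimmed before translation; internal stops are an error.
#'
#' @param cds_a,cds_b [nucleotide_record()] coding sequences with lengths
#'   divisible by 3.
#' @param gap_penalty linear per-residue gap penalty for the protein
#'   alignment (default 8).
#' @param substitution_matrix name of the amino-acid scoring matrix.
#' @return an object of class `codon_alignment`: ids plus two equal-length
#'   codon vectors (`NA` marks a gap column).
#' @export
align_codons <- function(cds_a, cds_b, gap_penalty = 8,
                         substitution_matrix = "BLOSUM62") {
  codons_a <- validate_cds(cds_a)
  codons_b <- validate_cds(cds_b)
  if (length(codons_a) == 0L || length(codons_b) == 0L) {
    stop("empty CDS after trimming the terminal stop codon")
  }
  prot_a <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(codons_a, collapse = ""))))
  prot_b <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(codons_b, collapse = ""))))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = 0, gapExtension = gap_penalty)
  pa <- chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- chars(as.character(Biostrings::alignedSubject(aln)))
  ia <- 0L; ib <- 0L
  col_a <- col_b <- rep(NA_character_, length(pa))
  for (k in seq_along(pa)) {
    if (pa[k] != "-") { ia <- ia + 1L; col_a[k] <- codons_a[ia] }
    if (pb[k] != "-") { ib <- ib + 1L; col_b[k] <- codons_b[ib] }
  }
  structure(list(id_a = cds_a$id, id_b = cds_b$id,
                 codons_a = col_a, codons_b = col_b),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  ng <- sum(!is.na(x$codons_a) & !is.na(x$codons_b))
  cat("<codon_alignment>", x$id_a, "vs", x$id_b, "-",
      length(x$codons_a), "columns,", ng, "non-gap\n")
  invisible(x)
}

#' Nei-Gojobori divergence estimate for a codon alignment
#'
#' Computes average synonymous/nonsynonymous site counts (S, N),
#' pathway-averaged difference counts (Sd, Nd), proportions (pS, pN) and
#' Jukes-Cantor corrected distances (Ks, Ka) over the non-gap columns of a
#' codon alignment. The Ka/Ks ratio is reported only when both corrections
#' are defined and Ks > 0; otherwise the estimate carries a `ks_zero` or
#' `jc_saturated` flag.
#'
#' @param alignment a `codon_alignment` from [align_codons()], or any list
#'   with `codons_a`/`codons_b` character vectors.
#' @return an object of class `divergence_estimate` with fields `S`, `N`,
#'   `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio` and `flags`.
#' @export
ng_estimate <- function(alignment) {
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  keep <- !is.na(ca) & !is.na(cb)
  ca <- toupper(ca[keep]); cb <- toupper(cb[keep])
  if (length(ca) == 0L) stop("alignment has no non-gap columns")
  bad <- c(ca, cb)[!(c(ca, cb) %in% SENSE_CODONS)]
  if (length(bad) > 0L) stop("non-sense codon '", bad[1L], "' in alignment")
  tab <- ng_tables()
  S <- (sum(tab$S_SITES[ca]) + sum(tab$S_SITES[cb])) / 2
  N <- 3 * length(ca) - S
  idx <- cbind(match(ca, SENSE_CODONS), match(cb, SENSE_CODONS))
  Sd <- sum(tab$SD[idx])
  Nd <- sum(tab$ND[idx])
  # a site class can be empty for tiny alignments (e.g. a lone TGG column
  # has no synonymous sites); with no differences there the proportion is 0
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(pS)
  Ka <- jc(pN)
  flags <- list(
    jc_saturated = is.na(Ks) || is.na(Ka),
    ks_zero = !is.na(Ks) && Ks == 0
  )
  flags$ok <- !flags$jc_saturated && !flags$ks_zero
  structure(list(id_a = alignment$id_a, id_b = alignment$id_b,
                 n_codons = length(ca), S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, Ks = Ks, Ka = Ka,
                 ratio = if (flags$ok) Ka / Ks else NA_real_,
                 flags = flags),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat("<divergence_estimate>", x$id_a, "vs", x$id_b, "\n")
  cat(sprintf("  S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ks = %s, Ka = %s, Ka/Ks = %s\n",
              format(x$Ks, digits = 4), format(x$Ka, digits = 4),
              format(x$ratio, digits = 4)))
  set <- names(Filter(isTRUE, x$flags))
  if (length(set)) cat("  flags:", paste(set, collapse = ", "), "\n")
  invisible(x)
}

#' Selection-regime classification from a Ka/Ks estimate
#'
#' Ka/Ks below 1 indicates purifying (negative) selection, about 1 neutral
#' evolution, and above 1 positive selection; a tolerance band around 1
#' absorbs estimation noise in the neutral call.
#'
#' @param est a `divergence_estimate` (or a bare Ka/Ks value).
#' @param tol half-width of the neutral band around 1.
#' @return one of `"purifying"`, `"neutral"`, `"positive"`,
#'   `"undetermined"`.
#' @export
classify_selection <- function(est, tol = 0.05) {
  ratio <- if (inherits(est, "divergence_estimate")) {
    if (!isTRUE(est$flags$ok)) return("undetermined")
    est$ratio
  } else est
  if (is.na(ratio)) return("undetermined")
  if (ratio < 1 - tol) "purifying"
  else if (ratio > 1 + tol) "positive"
  else "neutral"
}

#' Classify a paralog pair as tandem or segmental duplication
#'
#' A pair is called tandem when both genes sit on the same chromosome and
#' are close -- few intervening annotated genes or a small genomic gap;
#' everything else is called segmental. The thresholds are pragmatic
#' stand-ins for a full collinearity analysis and are exposed as arguments.
#'
#' @param model_a,model_b [gene_model()] objects for the two paralogs.
#' @param models optional list of all gene models, used to count intervening
#'   genes on the shared chromosome.
#' @param max_intervening maximum number of annotated genes between the pair
#'   for a tandem call.
#' @param max_distance maximum genomic gap (bp) between the pair for a
#'   tandem call.
#' @return an object of class `duplication_event` with fields `pair`,
#'   `type`, and `evidence`.
#' @export
classify_duplication <- function(model_a, model_b, models = NULL,
                                 max_intervening = 5, max_distance = 100000) {
  stopifnot(inherits(model_a, "gene_model"), inherits(model_b, "gene_model"))
  span <- function(m) range(c(m$exons, m$cds_spans))
  sa <- span(model_a); sb <- span(model_b)
  same_chrom <- identical(model_a$chrom, model_b$chrom)
  gap <- NA_integer_
  intervening <- NA_integer_
  if (same_chrom) {
    gap <- max(0L, max(sa[1], sb[1]) - min(sa[2], sb[2]) - 1L)
    if (!is.null(models)) {
      lo <- min(sa[2], sb[2]); hi <- max(sa[1], sb[1])
      intervening <- sum(vapply(models, function(m) {
        if (!identical(m$chrom, model_a$chrom)) return(FALSE)
        if (m$gene_id %in% c(model_a$gene_id, model_b$gene_id)) return(FALSE)
        s <- span(m)
        s[1] > lo && s[2] < hi
      }, logical(1)))
    }
  }
  tandem <- same_chrom &&
    ((!is.na(intervening) && intervening <= max_intervening) ||
       gap <= max_distance)
  structure(list(pair = c(model_a$gene_id, model_b$gene_id),
                 type = if (tandem) "tandem" else "segmental",
                 evidence = list(chrom_a = model_a$chrom,
                                 chrom_b = model_b$chrom,
                                 gap_bp = gap, intervening = intervening)),
            class = "duplication_event")
}

#' @export
print.duplication_event <- function(x, ...) {
  cat("<duplication_event>", paste(x$pair, collapse = "/"), "-", x$type, "\n")
  invisible(x)
}

#' Ka/Ks ratio as printed in divergence tables
#'
#' Divides Ka by Ks and rounds half-up to two decimals, the presentation
#' convention of published divergence tables.
#'
#' @param ka,ks nonnegative numeric vectors; `ks` must be positive.
#' @return `ka/ks` rounded half-up to 2 decimals.
#' @examples
#' ratio_from_table(0.18, 0.63)  # 0.29
#' @export
ratio_from_table <- function(ka, ks) {
  stopifnot(all(ka >= 0), all(ks > 0))
  round_half_up(ka / ks, 2)
}
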