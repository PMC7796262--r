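# Promoter extraction and cis-regulatory element (CRE) scanning.

#' Default cis-regulatory element motif table
#'
#' The bundled motif table: the three canonical ACGT-core boxes (A-box
#' TACGTA, C-box GACGTC, G-box CACGTG) plus common plant promoter elements
#' whose IUPAC strings are this package's transcription of the public
#' PlantCARE consensus -- editable configuration, not authoritative ground
#' truth. Categories follow the development / hormone / stress / core
#' grouping used in promoter surveys.
#'
#' @return data.frame with columns `name`, `pattern`, `category`.
#' @export
default_cre_motifs <- function() {
  p <- fixture_path("cre_motifs.tsv")
  df <- utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#")
  validate_motifs(df)
  df
}

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

validate_motifs <- function(motifs) {
  stopifnot(is.data.frame(motifs),
            all(c("name", "pattern", "category") %in% names(motifs)))
  if (anyDuplicated(motifs$name)) stop("duplicate motif names")
  for (i in seq_len(nrow(motifs))) {
    bad <- setdiff(chars(toupper(motifs$pattern[i])), IUPAC_LETTERS)
    if (length(bad) > 0L) {
      stop("invalid IUPAC letter '", bad[1L], "' in motif '",
           motifs$name[i], "'")
    }
  }
  invisible(motifs)
}

is_rc_palindrome <- function(pattern) {
  p <- Biostrings::DNAString(pattern)
  as.character(Biostrings::reverseComplement(p)) == as.character(p)
}

#' Extract a promoter upstream of the transcription start site
#'
#' Returns the `length` bases immediately 5' of the TSS in transcript
#' orientation: upstream on the genomic plus strand for plus-strand genes,
#' and the reverse complement of the downstream flank for minus-strand
#' genes. The window is clipped (with a warning) at the chromosome edge.
#'
#' @param model a [gene_model()].
#' @param genome the genome sequence: a list of [nucleotide_record()]s, a
#'   named character vector, or a `DNAStringSet`.
#' @param length promoter length in bp (default 2000).
#' @return a [nucleotide_record()] named `<gene_id>_promoter`.
#' @export
extract_promoter <- function(model, genome, length = 2000) {
  stopifnot(inherits(model, "gene_model"), length >= 1)
  seqs <- normalize_genome(genome)
  if (!model$chrom %in% names(seqs)) {
    stop("chromosome '", model$chrom, "' not present in genome")
  }
  chrom_seq <- seqs[[model$chrom]]
  clen <- nchar(chrom_seq)
  if (model$strand == 1L) {
    end <- model$tss - 1L
    if (end < 1L) stop("zero-length promoter: TSS of '", model$gene_id,
                       "' is at the chromosome start")
    start <- model$tss - length
    if (start < 1L) {
      warning("promoter of '", model$gene_id, "' clipped at chromosome start")
      start <- 1L
    }
    out <- substr(chrom_seq, start, end)
  } else {
    start <- model$tss + 1L
    if (start > clen) stop("zero-length promoter: TSS of '", model$gene_id,
                           "' is at the chromosome end")
    end <- model$tss + length
    if (end > clen) {
      warning("promoter of '", model$gene_id, "' clipped at chromosome end")
      end <- clen
    }
    out <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(chrom_seq, start, end))))
  }
  nucleotide_record(paste0(model$gene_id, "_promoter"), out)
}

normalize_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.list(genome)) {
    stats::setNames(vapply(genome, record_seq, character(1)),
                    vapply(genome, function(r) r$id, character(1)))
  } else if (is.character(genome)) {
    genome
  } else stop("unsupported genome representation")
}

#' Count cis-regulatory element occurrences in a promoter
#'
#' Counts all (possibly overlapping) matches of each IUPAC motif on the
#' promoter and, when `both_strands`, on its reverse complement.
#' Reverse-complement-palindromic motifs (such as the G-box CACGTG) are
#' counted on one strand only so a single site is never counted twice.
#'
#' @param promoter a [nucleotide_record()] (or plain string).
#' @param motifs motif table as from [default_cre_motifs()].
#' @param both_strands scan both strands (default `TRUE`).
#' @return object of class `cre_profile`: `gene_id`, `counts` (named
#'   integer vector over motif names), and `category_totals`.
#' @export
scan_motifs <- function(promoter, motifs = default_cre_motifs(),
                        both_strands = TRUE) {
  if (is.character(promoter)) promoter <- nucleotide_record("promoter", promoter)
  stopifnot(inherits(promoter, "nucleotide_record"))
  validate_motifs(motifs)
  subj <- Biostrings::DNAString(promoter$bases)
  counts <- integer(nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(toupper(motifs$pattern[i]))
    n <- Biostrings::countPattern(pat, subj, fixed = "subject")
    if (both_strands && !is_rc_palindrome(motifs$pattern[i])) {
      n <- n + Biostrings::countPattern(Biostrings::reverseComplement(pat),
                                        subj, fixed = "subject")
    }
    counts[i] <- n
  }
  names(counts) <- motifs$name
  structure(list(gene_id = promoter$id, counts = counts,
                 category_totals = tapply(counts, motifs$category, sum)),
            class = "cre_profile")
}

#' @export
print.cre_profile <- function(x, ...) {
  cat("<cre_profile>", x$gene_id, "-", sum(x$counts), "total sites\n")
  print(x$counts)
  invisible(x)
}

#' Family-wide CRE count matrix
#'
#' Stacks per-promoter profiles into a gene-by-motif count matrix and
#' derives the per-motif min/max across genes (the banding statistic used
#' to shade family-wide CRE grids).
#'
#' @param profiles list of `cre_profile` objects over a common motif set.
#' @return list with `matrix` (genes x motifs) and `range` (data.frame:
#'   motif, min, max).
#' @export
family_cre_matrix <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  motif_names <- names(profiles[[1L]]$counts)
  mat <- do.call(rbind, lapply(profiles, function(p) {
    stopifnot(identical(names(p$counts), motif_names))
    p$counts
  }))
  rownames(mat) <- vapply(profiles, function(p) p$gene_id, character(1))
  list(matrix = mat,
       range = data.frame(motif = motif_names,
                          min = apply(mat, 2L, min),
                          max = apply(mat, 2L, max),
                          row.names = NULL))
}
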