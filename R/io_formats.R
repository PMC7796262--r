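# Sequence records, FASTA/GFF3 readers and writers, and the bundled
# family-catalog and paralog-pair tables.

#' Protein sequence record
#'
#' A minimal identified protein sequence. Residues are restricted to the 20
#' canonical amino-acid letters plus `X` (unknown); `X` is tolerated because
#' genome-derived proteomes contain it, but downstream frequency statistics
#' exclude it from denominators.
#'
#' @param id single non-empty string, unique within a collection.
#' @param residues amino-acid string; lower case is folded to upper case.
#' @param description optional free-text description.
#' @return an object of class `protein_record` with fields `id`,
#'   `description` and `residues`.
#' @examples
#' protein_record("g1", "MKNL")
#' @export
protein_record <- function(id, residues, description = "") {
  stopifnot(is_string(id), nzchar(id), is_string(residues))
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("residues must be non-empty for record '", id, "'")
  bad <- regexpr(paste0("[^", paste(c(AA_STANDARD, "X"), collapse = ""), "]"),
                 residues)
  if (bad > 0L) {
    stop("invalid residue '", substr(residues, bad, bad), "' at position ",
         bad, " in record '", id, "'")
  }
  structure(list(id = id, description = description, residues = residues),
            class = "protein_record")
}

#' Nucleotide sequence record
#'
#' @param id single non-empty string.
#' @param bases nucleotide string over A, C, G, T, N; lower case folded.
#' @param description optional free text.
#' @return an object of class `nucleotide_record`.
#' @examples
#' nucleotide_record("a", "acgt")
#' @export
nucleotide_record <- function(id, bases, description = "") {
  stopifnot(is_string(id), nzchar(id), is_string(bases))
  bases <- toupper(bases)
  if (!nzchar(bases)) stop("bases must be non-empty for record '", id, "'")
  bad <- regexpr("[^ACGTN]", bases)
  if (bad > 0L) {
    stop("invalid base '", substr(bases, bad, bad), "' at position ",
         bad, " in record '", id, "'")
  }
  structure(list(id = id, description = description, bases = bases),
            class = "nucleotide_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, paste0("(", nchar(x$residues), " aa)"), "\n")
  invisible(x)
}

#' @export
print.nucleotide_record <- function(x, ...) {
  cat("<nucleotide_record>", x$id, paste0("(", nchar(x$bases), " bp)"), "\n")
  invisible(x)
}

record_seq <- function(record) {
  if (inherits(record, "protein_record")) record$residues else record$bases
}

#' Read a FASTA file
#'
#' Parses a (multi-record) FASTA file into validated sequence records.
#' Sequences are uppercased and checked against the requested alphabet;
#' an illegal character is reported with the offending record and position.
#'
#' @param path path to a FASTA file.
#' @param type `"protein"` (20 canonical letters plus X) or `"dna"`
#'   (A, C, G, T, N).
#' @return a list of [protein_record()] or [nucleotide_record()] objects,
#'   named by record id.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in '", path, "'")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate record id '", ids[duplicated(ids)][1L], "' in '", path, "'")
  }
  recs <- lapply(seq_along(set), function(i) {
    s <- as.character(set[[i]])
    if (type == "protein") protein_record(ids[i], s, desc[i])
    else nucleotide_record(ids[i], s, desc[i])
  })
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records list of [protein_record()] or [nucleotide_record()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.list(records), length(records) > 0L)
  seqs <- vapply(records, record_seq, character(1))
  ids <- vapply(records, function(r) r$id, character(1))
  desc <- vapply(records, function(r) r$description, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ifelse(nzchar(desc), paste(ids, desc), ids)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Gene model
#'
#' A transcript-level gene model with genomic exon and CDS intervals.
#' All coordinates are 1-based inclusive (the GFF3 convention) and kept in
#' genomic order regardless of strand; the strand determines transcript
#' orientation for downstream phase and promoter arithmetic.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome/sequence name.
#' @param strand `+1` or `-1`.
#' @param exons two-column matrix (start, end) of exon intervals, 1-based
#'   inclusive, non-overlapping, sorted by start.
#' @param cds_spans two-column matrix of coding intervals, same conventions.
#' @param transcript_id optional transcript identifier.
#' @return an object of class `gene_model` with a `tss` field (the 5'-most
#'   transcribed coordinate respecting strand) and a `partial` flag set when
#'   the total CDS length is not divisible by 3.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_spans,
                       transcript_id = gene_id) {
  stopifnot(is_string(gene_id), is_string(chrom), strand %in% c(1L, -1L, 1, -1))
  strand <- as.integer(strand)
  exons <- as_interval_matrix(exons, "exons")
  cds_spans <- as_interval_matrix(cds_spans, "cds_spans")
  tss <- if (strand == 1L) min(exons[, 1L]) else max(exons[, 2L])
  cds_len <- sum(cds_spans[, 2L] - cds_spans[, 1L] + 1L)
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons, cds_spans = cds_spans, tss = tss,
         partial = (cds_len %% 3L) != 0L),
    class = "gene_model"
  )
}

as_interval_matrix <- function(x, what) {
  x <- matrix(as.integer(as.matrix(x)), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(x) == 0L) stop("gene model needs at least one interval in ", what)
  if (any(x[, 1L] > x[, 2L])) stop("interval start > end in ", what)
  x <- x[order(x[, 1L]), , drop = FALSE]
  if (nrow(x) > 1L && any(x[-1L, 1L] <= x[-nrow(x), 2L])) {
    stop("overlapping intervals in ", what)
  }
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$gene_id, "on", x$chrom,
      if (x$strand == 1L) "(+)" else "(-)",
      nrow(x$exons), "exon(s),", nrow(x$cds_spans), "CDS span(s), tss =",
      x$tss, if (x$partial) "[partial CDS]" else "", "\n")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features and returns one [gene_model()] per
#' gene, choosing as representative the mRNA with the longest total CDS
#' (ties broken lexicographically by transcript id). CDS features lacking a
#' parent transcript are a structural error. When `fasta_path` is supplied,
#' feature coordinates are checked against the sequence bounds.
#'
#' @param path GFF3 file (requires the `##gff-version 3` pragma).
#' @param fasta_path optional genome FASTA for coordinate range checks.
#' @return named list of `gene_model` objects.
#' @export
read_gff3 <- function(path, fasta_path = NULL) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  if (!grepl("^##gff-version\\s+3", first)) {
    stop("GFF3 format error: missing '##gff-version 3' pragma in '", path, "'")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- if (!is.null(meta$ID)) as.character(meta$ID) else rep(NA_character_, length(gr))
  parents <- if (!is.null(meta$Parent)) {
    vapply(as.list(meta$Parent),
           function(p) if (length(p)) p[[1L]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  tx_ids <- ids[mrna_idx]
  tx_gene <- parents[mrna_idx]
  if (anyNA(tx_ids)) stop("mRNA feature without ID in '", path, "'")

  bad_cds <- type == "CDS" & (is.na(parents) | !(parents %in% tx_ids))
  if (any(bad_cds)) {
    stop("structural error: CDS feature without a parent mRNA in '", path, "'")
  }

  chrom_len <- NULL
  if (!is.null(fasta_path)) {
    genome <- read_fasta(fasta_path, type = "dna")
    chrom_len <- vapply(genome, function(r) nchar(r$bases), integer(1))
  }

  models <- list()
  for (g in unique(tx_gene)) {
    cand <- tx_ids[tx_gene == g]
    built <- lapply(sort(cand), function(tx) {
      sel_e <- which(type == "exon" & parents == tx)
      sel_c <- which(type == "CDS" & parents == tx)
      if (length(sel_c) == 0L) return(NULL)
      if (length(sel_e) == 0L) sel_e <- sel_c  # CDS-only annotations
      chrom <- as.character(GenomicRanges::seqnames(gr))[sel_e[1L]]
      strand <- if (as.character(BiocGenerics::strand(gr))[sel_e[1L]] == "-") -1L else 1L
      if (!is.null(chrom_len)) {
        if (!chrom %in% names(chrom_len)) {
          stop("range error: chromosome '", chrom, "' absent from FASTA")
        }
        if (max(BiocGenerics::end(gr)[c(sel_e, sel_c)]) > chrom_len[[chrom]]) {
          stop("range error: feature beyond end of '", chrom, "'")
        }
      }
      gene_model(
        gene_id = g, chrom = chrom, strand = strand,
        exons = cbind(BiocGenerics::start(gr)[sel_e], BiocGenerics::end(gr)[sel_e]),
        cds_spans = cbind(BiocGenerics::start(gr)[sel_c], BiocGenerics::end(gr)[sel_c]),
        transcript_id = tx
      )
    })
    built <- Filter(Negate(is.null), built)
    if (length(built) == 0L) next
    cds_tot <- vapply(built, function(m) sum(m$cds_spans[, 2] - m$cds_spans[, 1] + 1L),
                      numeric(1))
    # representative model: longest CDS; candidates are pre-sorted by tx id,
    # so which.max resolves ties lexicographically
    models[[g]] <- built[[which.max(cds_tot)]]
  }
  if (length(models) == 0L) stop("no gene models with CDS found in '", path, "'")
  models[order(names(models))]
}

#' Write gene models to GFF3
#'
#' @param models list of [gene_model()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  writeLines(gff3_text(models), path)
  invisible(path)
}

# Serialize gene models as GFF3 lines (also used by the synthetic generator).
gff3_text <- function(models) {
  if (inherits(models, "gene_model")) models <- list(models)
  lines <- "##gff-version 3"
  for (m in models) {
    std <- if (m$strand == 1L) "+" else "-"
    span <- range(c(m$exons, m$cds_spans))
    row <- function(type, s, e, attrs, phase = ".") {
      paste(m$chrom, "zipperscan", type, s, e, ".", std, phase, attrs,
            sep = "\t")
    }
    lines <- c(lines,
               row("gene", span[1], span[2], paste0("ID=", m$gene_id)),
               row("mRNA", span[1], span[2],
                   paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, row("exon", m$exons[i, 1], m$exons[i, 2],
                            paste0("ID=", m$transcript_id, ".exon", i,
                                   ";Parent=", m$transcript_id)))
    }
    cds <- m$cds_spans
    ord <- if (m$strand == 1L) seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    cum <- 0L
    for (i in ord) {
      phase <- (3L - (cum %% 3L)) %% 3L
      lines <- c(lines, row("CDS", cds[i, 1], cds[i, 2],
                            paste0("ID=", m$transcript_id, ".cds;Parent=",
                                   m$transcript_id),
                            phase = phase))
      cum <- cum + cds[i, 2] - cds[i, 1] + 1L
    }
  }
  lines
}

# md5 checksums of the bundled fixtures, frozen at transcription time.
TABLE1_MD5 <- "84a0f4b10c994647672c29e631430468"
TABLE2_MD5 <- "3a0ec90af847f74ecb8aaa0905f8c710"

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "zipperscan")
  if (!nzchar(p)) stop("bundled fixture '", file, "' not found")
  p
}

check_fixture <- function(path, expected) {
  if (!grepl("^[0-9a-f]{32}$", expected)) return(invisible(TRUE))
  got <- unname(tools::md5sum(path))
  if (!identical(got, expected)) {
    stop("integrity error: fixture '", basename(path),
         "' does not match its recorded checksum")
  }
  invisible(TRUE)
}

#' Bundled family catalog (functional groups)
#'
#' The 80-member potato bZIP family catalog: gene name, genome locus id,
#' functional group (A--N, S) and synonym where one exists. Bundled with the
#' package and checksum-verified at load.
#'
#' @return data.frame with columns `gene_name`, `locus_id`, `group`,
#'   `synonym`.
#' @export
load_table1_fixture <- function() {
  p <- fixture_path("table1_family_catalog.tsv")
  check_fixture(p, TABLE1_MD5)
  df <- utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = NULL)
  stopifnot(!anyDuplicated(df$gene_name),
            all(df$group %in% c(LETTERS[1:11], "M", "N", "S")))
  df
}

#' Bundled paralog-pair divergence table
#'
#' The 22 printed paralog-pair rows with their nonsynonymous (Ka) and
#' synonymous (Ks) distances and Ka/Ks ratios, exactly as published.
#'
#' @return data.frame with columns `gene_a`, `gene_b`, `ka`, `ks`, `ratio`.
#' @export
load_table2_fixture <- function() {
  p <- fixture_path("table2_paralog_pairs.tsv")
  check_fixture(p, TABLE2_MD5)
  df <- utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(nrow(df) == 22L, all(df$ka >= 0), all(df$ks > 0),
            all(df$ratio >= 0))
  df
}
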