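# Intron phase and exon symmetry from gene models.
#
# The phase of an intron is its position relative to codon boundaries:
# phase 0 falls between codons, phase 1 after the first base of a codon,
# phase 2 after the second. Each coding exon is labelled by its flanking
# phase pair, e.g. (0,0); an exon is symmetric when both flanks share the
# same phase. Terminal exons get a virtual phase 0 at the CDS start/end.

#' Intron phases and exon symmetry of a gene model
#'
#' Orders the CDS spans 5' to 3' in transcript orientation (reversed for
#' minus-strand genes), computes intron phases from cumulative coding
#' lengths, and labels every coding exon with its flanking phase pair.
#' Phases are computed on the CDS only; UTR exons are ignored. A CDS whose
#' total length is not divisible by 3 is processed anyway and flagged
#' `partial` (its final virtual phase is then nonzero).
#'
#' @param model a [gene_model()] with at least one CDS span.
#' @return object of class `gene_structure_profile`: `gene_id`,
#'   `intron_phases` (integer vector over CDS-internal introns),
#'   `exon_classes` (character labels like `"(0,0)"`), `left`/`right`
#'   phase vectors, `symmetric` (logical per exon), `intronless`, and
#'   `partial`.
#' @export
intron_phases <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  cds <- model$cds_spans
  if (nrow(cds) == 0L) stop("gene model '", model$gene_id, "' has no CDS spans")
  ord <- if (model$strand == 1L) order(cds[, 1L]) else order(-cds[, 1L])
  lens <- (cds[, 2L] - cds[, 1L] + 1L)[ord]
  total <- sum(lens)
  partial <- (total %% 3L) != 0L
  if (partial) {
    warning("CDS of '", model$gene_id, "' is not divisible by 3; ",
            "profile flagged partial")
  }
  cum <- cumsum(lens)
  phases <- as.integer(cum[-length(cum)] %% 3L)  # empty when single exon
  left <- c(0L, phases)
  right <- c(phases, as.integer(total %% 3L))
  structure(
    list(gene_id = model$gene_id,
         intron_phases = phases,
         exon_classes = sprintf("(%d,%d)", left, right),
         left = left, right = right,
         symmetric = left == right,
         intronless = length(lens) == 1L,
         partial = partial),
    class = "gene_structure_profile")
}

#' @export
print.gene_structure_profile <- function(x, ...) {
  cat("<gene_structure_profile>", x$gene_id, "-",
      if (x$intronless) "intronless" else
        paste0("phases [", paste(x$intron_phases, collapse = ","), "]"),
      paste(x$exon_classes, collapse = " "),
      if (x$partial) "[partial]" else "", "\n")
  invisible(x)
}

#' Per-group gene-structure summary
#'
#' Joins structure profiles to the family catalog and tallies, per
#' functional group, the exon-class patterns and the number of intronless
#' genes -- the tabular form of group-wise structural conservation.
#'
#' @param profiles list of `gene_structure_profile` objects (ids matching
#'   the catalog's `gene_name`), or [gene_model()] objects (profiled on the
#'   fly).
#' @param catalog data.frame with `gene_name` and `group` columns.
#' @return list with `genes` (per-gene data.frame: group, pattern,
#'   intronless) and `groups` (per-group data.frame: size, intronless
#'   count, distinct patterns).
#' @export
family_structure_table <- function(profiles, catalog) {
  stopifnot(is.list(profiles), is.data.frame(catalog),
            all(c("gene_name", "group") %in% names(catalog)))
  profiles <- lapply(profiles, function(p) {
    if (inherits(p, "gene_model")) intron_phases(p) else p
  })
  ids <- vapply(profiles, function(p) p$gene_id, character(1))
  grp <- catalog$group[match(ids, catalog$gene_name)]
  if (anyNA(grp)) {
    stop("profiles not present in catalog: ",
         paste(utils::head(ids[is.na(grp)], 3), collapse = ", "))
  }
  genes <- data.frame(
    gene_id = ids, group = grp,
    pattern = vapply(profiles, function(p) paste(p$exon_classes, collapse = " "),
                     character(1)),
    n_exons = vapply(profiles, function(p) length(p$exon_classes), integer(1)),
    intronless = vapply(profiles, function(p) p$intronless, logical(1)),
    row.names = NULL)
  groups <- do.call(rbind, lapply(split(genes, genes$group), function(d) {
    data.frame(group = d$group[1L], n_genes = nrow(d),
               n_intronless = sum(d$intronless),
               patterns = paste(sort(unique(d$pattern)), collapse = " | "))
  }))
  rownames(groups) <- NULL
  list(genes = genes, groups = groups)
}
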