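# Basic-region detection and leucine-zipper heptad register assignment.
#
# The bZIP signature is a basic region carrying an invariant asparagine
# followed seven residues later by arginine or lysine (N-x7-R/K), then a
# C-terminal leucine zipper whose coiled-coil heptads are labelled with
# register letters a-g, leucine canonically at d. Heptads are indexed L0,
# L1, ... counting from the first leucine in the d position after the basic
# region; tiling stops at a helix-disrupting residue (proline by default).

REGISTER_LETTERS <- c("a", "b", "c", "d", "e", "f", "g")

#' Find basic-region motifs (N-x7-R/K)
#'
#' Scans a protein left to right for all (possibly overlapping) matches of
#' the pattern: asparagine, seven arbitrary residues, then arginine or
#' lysine. Positions are 1-based.
#'
#' @param protein a [protein_record()].
#' @return data.frame with one row per hit: `n_pos` (position of the N),
#'   `rk_pos` (`n_pos + 8`), and `span_start`/`span_end`, the 16-residue
#'   basic-region context ending at `rk_pos` (clipped at the sequence
#'   start). Zero rows when there is no match.
#' @export
find_basic_regions <- function(protein) {
  stopifnot(inherits(protein, "protein_record"))
  m <- gregexpr("(?=N.{7}[RK])", protein$residues, perl = TRUE)[[1L]]
  n_pos <- as.integer(m[m > 0L])
  data.frame(
    n_pos = n_pos,
    rk_pos = n_pos + 8L,
    span_start = pmax(1L, n_pos + 8L - 15L),
    span_end = n_pos + 8L
  )
}

new_heptad <- function(index, residues) list(index = index, residues = residues)

heptad_is_complete <- function(h) length(h$residues) == 7L

#' Number of complete heptads in an annotation
#'
#' @param annotation a `zipper_annotation`.
#' @return integer count of heptads carrying all seven register letters.
#' @export
n_complete_heptads <- function(annotation) {
  sum(vapply(annotation$heptads, heptad_is_complete, logical(1)))
}

#' Assign the heptad register downstream of a basic-region hit
#'
#' Anchors the zipper at the first leucine after the R/K of the basic
#' region: that leucine takes register letter `d` of heptad L0, the up to
#' three preceding positions (never before `rk_pos + 1`) take `a`, `b`, `c`,
#' and subsequent heptads tile every seven residues. Tiling stops at the
#' first disruptor residue, at the sequence end, or after `max_heptads`
#' complete heptads. When no leucine exists downstream the first aliphatic
#' residue (I, V or M) anchors the register instead and the annotation is
#' flagged `weak_anchor`; with no candidate at all the annotation has no
#' heptads. Heptads after L0 are retained whether or not their own d
#' position carries leucine.
#'
#' @param protein a [protein_record()].
#' @param hit one row of [find_basic_regions()] output (or a list with
#'   `n_pos` and `rk_pos`).
#' @param max_heptads maximum number of heptads to tile (default 10, the
#'   upper end of reported plant zipper lengths).
#' @param disruptors residues that terminate the helix; proline by default,
#'   configurable (e.g. `c("P", "G")`).
#' @return an object of class `zipper_annotation`: `protein_id`, `n_pos`,
#'   `rk_pos`, `anchor_pos`, `weak_anchor`, ordered `heptads` (each an
#'   `index` plus a named residue map over register letters), and
#'   `terminated_by` (one of `"disruptor"`, `"end_of_sequence"`,
#'   `"max_heptads"`).
#' @export
assign_register <- function(protein, hit, max_heptads = 10,
                            disruptors = "P") {
  stopifnot(inherits(protein, "protein_record"), max_heptads >= 1)
  cs <- chars(protein$residues)
  n_pos <- as.integer(hit$n_pos)
  rk_pos <- as.integer(hit$rk_pos)
  if (is.na(n_pos) || is.na(rk_pos) || rk_pos - n_pos != 8L ||
      rk_pos > length(cs) || cs[n_pos] != "N" || !cs[rk_pos] %in% c("R", "K")) {
    stop("hit is not a valid basic-region match for '", protein$id, "'")
  }
  empty <- function() structure(
    list(protein_id = protein$id, n_pos = n_pos, rk_pos = rk_pos,
         anchor_pos = NA_integer_, weak_anchor = FALSE, heptads = list(),
         terminated_by = "end_of_sequence"),
    class = "zipper_annotation")

  from <- rk_pos + 1L
  if (from > length(cs)) return(empty())
  tail_res <- cs[from:length(cs)]
  anchor_rel <- match("L", tail_res)
  weak <- FALSE
  if (is.na(anchor_rel)) {
    anchor_rel <- which(tail_res %in% c("I", "V", "M"))[1L]
    weak <- TRUE
  }
  if (is.na(anchor_rel)) return(empty())
  anchor <- from + anchor_rel - 1L

  heptads <- list()
  terminated <- NULL
  k <- 0L
  while (is.null(terminated)) {
    if (k >= max_heptads) {
      terminated <- "max_heptads"
      break
    }
    s <- anchor - 3L + 7L * k
    if (k == 0L) s <- max(s, from)
    e <- anchor + 3L + 7L * k
    if (s > length(cs)) {
      terminated <- "end_of_sequence"
      break
    }
    pos <- s:min(e, length(cs))
    letters_k <- REGISTER_LETTERS[(pos - (anchor + 7L * k)) + 4L]
    res <- cs[pos]
    dis <- which(res %in% disruptors)
    if (length(dis) > 0L) {
      terminated <- "disruptor"
      if (k == 0L && dis[1L] > 1L) {
        kept <- seq_len(dis[1L] - 1L)
        heptads[[1L]] <- new_heptad(0L, stats::setNames(res[kept], letters_k[kept]))
      }
      break
    }
    h <- new_heptad(k, stats::setNames(res, letters_k))
    heptads[[k + 1L]] <- h
    if (e > length(cs)) terminated <- "end_of_sequence"
    k <- k + 1L
  }
  structure(
    list(protein_id = protein$id, n_pos = n_pos, rk_pos = rk_pos,
         anchor_pos = anchor, weak_anchor = weak, heptads = heptads,
         terminated_by = terminated),
    class = "zipper_annotation")
}

#' @export
print.zipper_annotation <- function(x, ...) {
  cat("<zipper_annotation>", x$protein_id,
      sprintf("N@%s R/K@%s anchor@%s", x$n_pos, x$rk_pos, x$anchor_pos),
      "-", length(x$heptads), "heptad(s),",
      n_complete_heptads(x), "complete, terminated by", x$terminated_by,
      if (isTRUE(x$weak_anchor)) "[weak anchor]" else "", "\n")
  invisible(x)
}

#' Annotate a protein family with heptad registers
#'
#' For every protein, all basic-region hits are evaluated and the annotation
#' retained is the one whose downstream region yields the greatest number of
#' complete heptads, ties resolved in favour of the left-most hit. Proteins
#' with no basic-region motif are collected in a `rejected` list.
#'
#' @param proteins list of [protein_record()] objects.
#' @inheritParams assign_register
#' @return list with `annotations` (list of `zipper_annotation`, named by
#'   protein id) and `rejected` (character vector of ids with no hit).
#' @export
annotate_family <- function(proteins, max_heptads = 10, disruptors = "P") {
  stopifnot(is.list(proteins), length(proteins) > 0L)
  annotations <- list()
  rejected <- character(0)
  for (p in proteins) {
    hits <- find_basic_regions(p)
    if (nrow(hits) == 0L) {
      rejected <- c(rejected, p$id)
      next
    }
    anns <- lapply(seq_len(nrow(hits)), function(i) {
      assign_register(p, hits[i, ], max_heptads = max_heptads,
                      disruptors = disruptors)
    })
    counts <- vapply(anns, n_complete_heptads, integer(1))
    annotations[[p$id]] <- anns[[which.max(counts)]]  # first max = left-most
  }
  list(annotations = annotations, rejected = rejected)
}

#' Flatten annotations to a summary table
#'
#' @param annotations list of `zipper_annotation` objects.
#' @return data.frame with one row per protein: positions, heptad counts,
#'   termination cause and anchor strength.
#' @export
annotation_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    data.frame(protein_id = a$protein_id, n_pos = a$n_pos, rk_pos = a$rk_pos,
               anchor_pos = a$anchor_pos, n_heptads = length(a$heptads),
               n_complete = n_complete_heptads(a),
               weak_anchor = a$weak_anchor, terminated_by = a$terminated_by,
               row.names = NULL)
  }))
}
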