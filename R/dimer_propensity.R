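# Position-composition statistics over heptad registers and the
# attractive/repulsive classification of inter-helical residue contacts.
#
# In a parallel coiled coil the g position of one heptad contacts the e
# position of the FOLLOWING heptad on the partner helix (the g-e' salt
# bridge): opposite charges attract and favour homodimerization, like
# charges repel and favour heterodimerization. The a-a' core contact
# contributes too: homotypic V, I or R packs favourably, N-V favours
# heterodimers, N-I and charge-charge contacts destabilize.

#' Residue composition by register position
#'
#' Counts residues at each register letter over the heptads of a window
#' (default L0-L4, the window conventionally used for composition
#' statistics) and derives per-letter percentages. `X` residues are
#' excluded from all denominators. Four summary percentages are exposed:
#' leucine at d, charged residues (D, E, K, R) at g and at e, and the
#' core-position set {N, I, V, M} at a; summaries are rounded half-up to
#' integers for reporting.
#'
#' @param annotations list of `zipper_annotation` objects (or the
#'   `annotations` element of [annotate_family()] output).
#' @param window inclusive heptad-index range, default `c(0, 4)`.
#' @param complete_only count only complete heptads (all seven letters)?
#'   Default `FALSE`: truncated heptads contribute the letters they have.
#' @return an object of class `position_frequencies`: `counts` and
#'   `percentages` (per-letter named vectors), `n_heptads`, and a `summary`
#'   vector with `pct_L_at_d`, `pct_charged_g`, `pct_charged_e`,
#'   `pct_core_a`.
#' @export
position_frequencies <- function(annotations, window = c(0, 4),
                                 complete_only = FALSE) {
  if (!is.null(annotations$annotations)) annotations <- annotations$annotations
  stopifnot(is.list(annotations), length(annotations) > 0L)
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L]) {
    stop("`window` must be an inclusive index range c(lo, hi)")
  }
  counts <- stats::setNames(
    lapply(REGISTER_LETTERS, function(l) integer(0)), REGISTER_LETTERS)
  n_heptads <- 0L
  for (a in annotations) {
    for (h in a$heptads) {
      if (h$index < window[1L] || h$index > window[2L]) next
      if (complete_only && !heptad_is_complete(h)) next
      n_heptads <- n_heptads + 1L
      for (l in names(h$residues)) {
        r <- h$residues[[l]]
        if (r == "X") next
        cur <- counts[[l]]
        counts[[l]][r] <- (if (r %in% names(cur)) cur[[r]] else 0L) + 1L
      }
    }
  }
  percentages <- lapply(counts, function(v) {
    if (length(v) == 0L) return(numeric(0))
    100 * v / sum(v)
  })
  pct_of <- function(letter, residues) {
    v <- counts[[letter]]
    if (length(v) == 0L || sum(v) == 0L) return(NA_real_)
    100 * sum(v[names(v) %in% residues]) / sum(v)
  }
  summary <- c(
    pct_L_at_d = pct_of("d", "L"),
    pct_charged_g = pct_of("g", AA_CHARGED),
    pct_charged_e = pct_of("e", AA_CHARGED),
    pct_core_a = pct_of("a", c("N", "I", "V", "M"))
  )
  structure(list(window = window, n_heptads = n_heptads, counts = counts,
                 percentages = percentages,
                 summary = summary,
                 summary_rounded = round_half_up(summary)),
            class = "position_frequencies")
}

#' @export
print.position_frequencies <- function(x, ...) {
  cat("<position_frequencies> heptads L", x$window[1L], "-L", x$window[2L],
      " (n = ", x$n_heptads, ")\n", sep = "")
  s <- x$summary_rounded
  cat(sprintf("  %%L at d = %s | %%charged at g = %s | %%charged at e = %s | %%{N,I,V,M} at a = %s\n",
              s[["pct_L_at_d"]], s[["pct_charged_g"]],
              s[["pct_charged_e"]], s[["pct_core_a"]]))
  invisible(x)
}

#' Classify a g-e' electrostatic contact
#'
#' Both residues acidic (D/E) or both basic (K/R) gives a repulsive pair;
#' one acidic and one basic gives an attractive pair; any uncharged or
#' missing residue leaves the contact incomplete. Histidine is treated as
#' uncharged. The rule is symmetric in its arguments.
#'
#' @param res_g residue at position g of heptad k.
#' @param res_e_next residue at position e of the next heptad on the
#'   partner helix (or `NA` when absent).
#' @return `"attractive"`, `"repulsive"`, or `"incomplete"`.
#' @examples
#' classify_ge_pair("E", "K")  # attractive
#' classify_ge_pair("E", "D")  # repulsive
#' @export
classify_ge_pair <- function(res_g, res_e_next) {
  acidic <- c("D", "E"); basic <- c("K", "R")
  if (is.null(res_g) || is.null(res_e_next) ||
      is.na(res_g) || is.na(res_e_next)) return("incomplete")
  in_a <- c(res_g %in% acidic, res_e_next %in% acidic)
  in_b <- c(res_g %in% basic, res_e_next %in% basic)
  if (all(in_a) || all(in_b)) return("repulsive")
  if (any(in_a) && any(in_b)) return("attractive")
  "incomplete"
}

#' Classify an a-a' core contact
#'
#' Rule table: homotypic V-V, I-I or R-R is favourable; N-V (either order)
#' favours heterodimerization; N-I is destabilizing; two charged residues
#' (D, E, K, R) are destabilizing; every other combination is neutral (the
#' table is deliberately not extrapolated beyond these stated rules).
#'
#' @param res_a_self,res_a_partner residues at the a positions of the two
#'   helices.
#' @return one of `"favorable"`, `"hetero_favoring"`, `"destabilizing"`,
#'   `"neutral"`.
#' @export
classify_aa_pair <- function(res_a_self, res_a_partner) {
  if (is.null(res_a_self) || is.null(res_a_partner) ||
      is.na(res_a_self) || is.na(res_a_partner)) return("neutral")
  pair <- sort(c(res_a_self, res_a_partner))
  if (pair[1L] == pair[2L] && pair[1L] %in% c("V", "I", "R")) return("favorable")
  if (identical(pair, c("N", "V"))) return("hetero_favoring")
  if (identical(pair, c("I", "N"))) return("destabilizing")
  if (all(pair %in% AA_CHARGED)) return("destabilizing")
  "neutral"
}

#' Homodimer contact profile of a zipper
#'
#' Pairs an annotation against itself in parallel register: position g of
#' heptad k contacts position e of heptad `k + e_offset` on the partner
#' copy (offset 1, the coiled-coil convention, by default), and position a
#' of heptad k contacts its own a. One assessment is produced per heptad k
#' for which the g-side residue exists.
#'
#' @param annotation a `zipper_annotation` with at least two heptads.
#' @param e_offset partner-heptad offset for the e residue (1 by
#'   convention; 0 available as the alternative register convention).
#' @return data.frame with columns `heptad_index`, `ge_class`, `aa_class`.
#'   Fewer than two heptads yields an empty frame with a warning.
#' @export
homodimer_profile <- function(annotation, e_offset = 1) {
  stopifnot(inherits(annotation, "zipper_annotation"), e_offset %in% c(0, 1))
  hs <- annotation$heptads
  empty <- data.frame(heptad_index = integer(0), ge_class = character(0),
                      aa_class = character(0))
  if (length(hs) < 2L) {
    warning("fewer than two heptads in '", annotation$protein_id,
            "'; no contacts to assess")
    return(empty)
  }
  by_index <- stats::setNames(hs, vapply(hs, function(h) as.character(h$index),
                                         character(1)))
  rows <- lapply(hs, function(h) {
    partner <- by_index[[as.character(h$index + e_offset)]]
    if (is.null(partner)) return(NULL)  # no partner heptad: contact undefined
    g <- h$residues[["g"]]
    e_next <- partner$residues[["e"]]
    a <- h$residues[["a"]]
    data.frame(
      heptad_index = h$index,
      ge_class = classify_ge_pair(if (is.null(g)) NA else g,
                                  if (is.null(e_next)) NA else e_next),
      aa_class = classify_aa_pair(if (is.null(a)) NA else a,
                                  if (is.null(a)) NA else a)
    )
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) empty else out
}

#' Modal contact-class pattern by functional group
#'
#' Joins annotations to the family catalog and reports, per functional
#' group and heptad index, the modal g-e' contact class and its frequency
#' -- the concrete form of the qualitative observation that attractive/
#' repulsive heptad patterns are conserved within groups.
#'
#' @param annotations list of `zipper_annotation` objects whose
#'   `protein_id`s appear in the catalog's `gene_name` column.
#' @param catalog data.frame as returned by [load_table1_fixture()]
#'   (columns `gene_name`, `group`).
#' @param e_offset passed to [homodimer_profile()].
#' @return data.frame with columns `group`, `heptad_index`, `modal_class`,
#'   `frequency`, `n`.
#' @export
group_pattern_table <- function(annotations, catalog, e_offset = 1) {
  if (!is.null(annotations$annotations)) annotations <- annotations$annotations
  stopifnot(is.data.frame(catalog),
            all(c("gene_name", "group") %in% names(catalog)))
  allowed <- c(LETTERS[1:11], "M", "N", "S")
  if (!all(catalog$group %in% allowed)) {
    stop("unknown group label: ",
         paste(setdiff(unique(catalog$group), allowed), collapse = ", "))
  }
  ids <- vapply(annotations, function(a) a$protein_id, character(1))
  missing <- setdiff(ids, catalog$gene_name)
  if (length(missing) > 0L) {
    stop("annotations not present in catalog: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  groups <- catalog$group[match(ids, catalog$gene_name)]
  rows <- list()
  for (g in sort(unique(groups))) {
    profs <- lapply(annotations[groups == g], function(a) {
      suppressWarnings(homodimer_profile(a, e_offset = e_offset))
    })
    prof <- do.call(rbind, profs)
    if (is.null(prof) || nrow(prof) == 0L) next
    for (k in sort(unique(prof$heptad_index))) {
      cls <- prof$ge_class[prof$heptad_index == k]
      tab <- sort(table(cls), decreasing = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, heptad_index = k, modal_class = names(tab)[1L],
        frequency = unname(tab[1L]) / length(cls), n = length(cls))
    }
  }
  do.call(rbind, rows)
}
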