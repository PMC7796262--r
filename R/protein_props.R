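# Protein physicochemical properties: length, average-isotope molecular
# weight, and isoelectric point from the EMBOSS pKa set.

# Average-isotope residue masses (Da), conventional whole-protein values.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' EMBOSS pKa constants
#'
#' The ionizable-group pKa set distributed with EMBOSS (termini plus the
#' side chains of C, D, E, H, K, R, Y), shipped as a named vector so an
#' alternative set can be swapped in.
#'
#' @return named numeric vector with elements `Nterm`, `Cterm`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y`.
#' @export
emboss_pka <- function() {
  c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
    H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

#' Average-isotope molecular weight
#'
#' Sum of average residue masses plus one water, in kilodaltons. `X`
#' residues are an error unless `allow_x` substitutes a generic residue
#' mass for them.
#'
#' @param protein a [protein_record()] (or plain residue string).
#' @param allow_x substitute `x_mass` for X residues instead of failing?
#' @param x_mass mass used per X residue when `allow_x` (Da).
#' @return molecular weight in kDa (full precision; round for reporting).
#' @examples
#' molecular_weight(protein_record("g", "G"))  # 0.0750672 kDa
#' @export
molecular_weight <- function(protein, allow_x = FALSE, x_mass = 110.0) {
  if (is.character(protein)) protein <- protein_record("protein", protein)
  stopifnot(inherits(protein, "protein_record"))
  cs <- chars(protein$residues)
  n_x <- sum(cs == "X")
  if (n_x > 0L && !allow_x) {
    stop("'", protein$id, "' contains X residues; set allow_x = TRUE to ",
         "substitute an average residue mass")
  }
  (sum(AA_AVG_MASS[cs[cs != "X"]]) + n_x * x_mass + WATER_MASS) / 1000
}

# Net charge at a given pH: Henderson-Hasselbalch fractional charges of the
# N-terminus, C-terminus and ionizable side chains. Strictly decreasing in
# pH, so the isoelectric point is its unique root.
protein_net_charge <- function(counts, pka, pH) {
  pos_groups <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
                  H = unname(counts["H"]))
  neg_groups <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
                  C = unname(counts["C"]), Y = unname(counts["Y"]))
  pos <- sum(pos_groups / (1 + 10^(pH - pka[names(pos_groups)])))
  neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - pH)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the protein's net charge is zero. The charge
#' function (termini plus K, R, H, D, E, C, Y side chains, fractional
#' charges from the pKa set) is strictly decreasing in pH, so bisection on
#' `[0, 14]` converges to the unique root. `X` residues carry no charge
#' and are ignored.
#'
#' @param protein a [protein_record()] (or plain residue string).
#' @param pka named pKa vector, default [emboss_pka()].
#' @param tol bisection interval tolerance in pH units.
#' @return the isoelectric point (pH units).
#' @examples
#' isoelectric_point(protein_record("p", "AAAA"))  # (3.6 + 8.6) / 2 = 6.1
#' @export
isoelectric_point <- function(protein, pka = emboss_pka(), tol = 1e-3) {
  if (is.character(protein)) protein <- protein_record("protein", protein)
  stopifnot(inherits(protein, "protein_record"))
  cs <- chars(protein$residues)
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(cs == a), numeric(1))
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, pka, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Property table for a protein family
#'
#' Per-protein length, molecular weight and isoelectric point, plus the
#' min/max ranges conventionally quoted for a family survey.
#'
#' @param proteins list of [protein_record()] objects.
#' @param allow_x passed to [molecular_weight()].
#' @return list with `properties` (data.frame: protein_id, length, mw_kda
#'   rounded to 2 decimals, pi rounded to 2 decimals) and `ranges`
#'   (data.frame: property, min, max -- computed before rounding for
#'   length, after the conventional 2-decimal rounding for MW and pI).
#' @export
family_properties <- function(proteins, allow_x = TRUE) {
  stopifnot(is.list(proteins), length(proteins) > 0L)
  props <- data.frame(
    protein_id = vapply(proteins, function(p) p$id, character(1)),
    length = vapply(proteins, function(p) nchar(p$residues), integer(1)),
    mw_kda = round_half_up(vapply(proteins, molecular_weight, numeric(1),
                                  allow_x = allow_x), 2),
    pi = round_half_up(vapply(proteins, isoelectric_point, numeric(1)), 2),
    row.names = NULL)
  ranges <- data.frame(
    property = c("length", "mw_kda", "pi"),
    min = c(min(props$length), min(props$mw_kda), min(props$pi)),
    max = c(max(props$length), max(props$mw_kda), max(props$pi)))
  list(properties = props, ranges = ranges)
}
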