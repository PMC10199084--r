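#' HOMO-LUMO gap
#'
#' The gap between the highest occupied and lowest unoccupied molecular
#' orbital energies, HLG = LUMO - HOMO (eV). A smaller gap indicates higher
#' chemical reactivity. Physically meaningful inputs have HOMO <= LUMO;
#' violations are flagged with a warning but still computed.
#'
#' @param homo HOMO energy in eV.
#' @param lumo LUMO energy in eV.
#' @return gap in eV, vectorised.
#' @examples
#' homo_lumo_gap(-5.26, -3.01) # 2.25 eV
#' @export
homo_lumo_gap <- function(homo, lumo) {
  if (any(!is.finite(homo)) || any(!is.finite(lumo))) {
    stop("orbital energies must be finite", call. = FALSE)
  }
  if (any(homo > lumo)) {
    warning("HOMO above LUMO for some inputs; gap is negative", call. = FALSE)
  }
  lumo - homo
}

#' Flag printed HOMO-LUMO gaps that disagree with the orbital energies
#'
#' Recomputes the gap from the orbital energies and compares it with a
#' reported gap column, flagging internally inconsistent rows (such tables do
#' occur in practice, e.g. a peptide row whose tabulated gap does not equal
#' LUMO - HOMO).
#'
#' @param homo,lumo orbital energies in eV.
#' @param reported_hlg the tabulated gap in eV.
#' @param tol absolute tolerance in eV. Default 0.01.
#' @return tibble with `computed`, `reported`, `consistent`.
#' @export
hlg_consistency <- function(homo, lumo, reported_hlg, tol = 0.01) {
  computed <- homo_lumo_gap(homo, lumo)
  tibble::tibble(
    computed = computed,
    reported = reported_hlg,
    consistent = is.finite(reported_hlg) &
      abs(computed - reported_hlg) <= tol + sqrt(.Machine$double.eps)
  )
}

#' Adduct stabilization energy
#'
#' Stabilization of a peptide-ligand adduct relative to its separated
#' components, from their (electrostatic potential) energies:
#' delta = E(adduct) - \[E(compound) + E(peptide)\].
#'
#' Tables of this quantity are conventionally printed as a negative binding
#' energy (more negative = more stable), so alongside the literal `delta`
#' the result carries `stabilization = -abs(delta)`; magnitudes are what the
#' two conventions share and what comparisons should use.
#'
#' @param e_adduct,e_compound,e_peptide energies in kcal/mol, vectorised.
#' @return tibble with the inputs, `delta` (literal difference) and
#'   `stabilization` (negative-magnitude convention).
#' @examples
#' adduct_stabilization(-56.58, -48.31, -62.08) # |delta| = 53.81 kcal/mol
#' @export
adduct_stabilization <- function(e_adduct, e_compound, e_peptide) {
  if (any(!is.finite(c(e_adduct, e_compound, e_peptide)))) {
    stop("all energies must be finite", call. = FALSE)
  }
  delta <- e_adduct - (e_compound + e_peptide)
  tibble::tibble(e_adduct = e_adduct, e_compound = e_compound,
                 e_peptide = e_peptide, delta = delta,
                 stabilization = -abs(delta))
}

#' Rank entities by an energy value
#'
#' Stable, tie-aware ranking: ties share the mean rank, and the output rows
#' are ordered by rank with the original input order preserved among exact
#' ties.
#'
#' @param ids unique identifiers.
#' @param values energies (kcal/mol or eV).
#' @param direction `"ascending"` (most negative first; the convention for
#'   binding/stabilization energies) or `"descending"`.
#' @return tibble with `id`, `value`, `rank`, ordered by rank.
#' @export
rank_by_energy <- function(ids, values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (anyDuplicated(ids) > 0) {
    stop(sprintf("duplicate id: %s", ids[duplicated(ids)][1]), call. = FALSE)
  }
  if (length(ids) != length(values)) stop("ids and values differ in length", call. = FALSE)
  key <- if (direction == "ascending") values else -values
  rk <- rank(key, ties.method = "average")
  ord <- order(key) # stable: order() preserves input order among ties
  tibble::tibble(id = ids[ord], value = values[ord], rank = rk[ord])
}
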