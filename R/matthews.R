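#' Symmetry-operator count for common space groups
#'
#' Resolves a Hermann-Mauguin symbol to the number of symmetry operators
#' (general-position multiplicity) from a built-in table covering the space
#' groups most common for protein crystals.  Spacing and case are ignored, so
#' `"P 62 2 2"`, `"P6222"` and `"p 62 2 2"` are equivalent.
#'
#' @param space_group Hermann-Mauguin symbol.
#' @return Integer operator count.
#' @export
#' @examples
#' space_group_multiplicity("P 62 2 2") # 12
#' space_group_multiplicity("P 43")     # 4
space_group_multiplicity <- function(space_group) {
  key <- toupper(gsub("[[:space:]]", "", space_group))
  hit <- .space_group_mult[key]
  if (is.na(hit)) {
    abort(
      paste0("space group '", space_group, "' is not in the built-in table"),
      class = "cnbdkit_domain_error"
    )
  }
  unname(hit)
}

.space_group_mult <- c(
  "P1" = 1L,
  "P21" = 2L, "P1211" = 2L, "C2" = 4L, "C121" = 4L,
  "P212121" = 4L, "P21212" = 4L, "P222" = 4L, "C2221" = 8L, "I222" = 8L,
  "P41" = 4L, "P43" = 4L, "P42" = 4L, "P4" = 4L,
  "P41212" = 8L, "P43212" = 8L, "P4122" = 8L, "P4322" = 8L, "I4" = 8L,
  "P3" = 3L, "P31" = 3L, "P32" = 3L,
  "P3121" = 6L, "P3221" = 6L, "P312" = 6L, "P321" = 6L,
  "R3" = 9L, "R32" = 18L, "H3" = 9L, "H32" = 18L,
  "P6" = 6L, "P61" = 6L, "P65" = 6L, "P62" = 6L, "P64" = 6L, "P63" = 6L,
  "P6122" = 12L, "P6522" = 12L, "P6222" = 12L, "P6422" = 12L, "P6322" = 12L,
  "P622" = 12L,
  "P23" = 12L, "I23" = 24L, "P213" = 12L, "I213" = 24L,
  "F23" = 48L, "P432" = 24L, "I432" = 48L, "F432" = 96L
)

#' Unit-cell volume from cell constants
#'
#' General triclinic volume
#' \deqn{V = abc \sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma
#'   + 2\cos\alpha \cos\beta \cos\gamma}.}
#'
#' @param crystal A [crystal_info()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(crystal) {
  stopifnot(inherits(crystal, "crystal_info"))
  ca <- cos(crystal$alpha * pi / 180)
  cb <- cos(crystal$beta * pi / 180)
  cg <- cos(crystal$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) {
    abort("degenerate cell: non-positive metric determinant",
      class = "cnbdkit_domain_error"
    )
  }
  crystal$a * crystal$b * crystal$c * sqrt(arg)
}

#' Matthews coefficient and solvent content
#'
#' Computes the crystal volume per Dalton of protein (the Matthews
#' coefficient, \eqn{V_M}) and the derived solvent fraction
#' \eqn{1 - 1.23 / V_M}, where 1.23 is the conventional conversion built from
#' the partial specific volume of protein.
#'
#' @param crystal A [crystal_info()].
#' @param molecules_per_asu Protein molecules per asymmetric unit.
#' @param molecular_weight Molecular weight of one molecule, in Daltons.
#' @return A one-row tibble with `cell_volume` (cubic Angstrom),
#'   `matthews_vm` (cubic Angstrom per Dalton) and `solvent_fraction`.
#' @export
#' @examples
#' cr <- crystal_info(107, 107, 171, 90, 90, 120, "P 62 2 2")
#' matthews_solvent(cr, molecules_per_asu = 2,
#'                  molecular_weight = protein_mw(n_residues = 136))
matthews_solvent <- function(crystal, molecules_per_asu, molecular_weight) {
  stopifnot(inherits(crystal, "crystal_info"))
  if (!is.finite(molecules_per_asu) || molecules_per_asu <= 0 ||
    !is.finite(molecular_weight) || molecular_weight <= 0) {
    abort("molecules_per_asu and molecular_weight must be positive",
      class = "cnbdkit_domain_error"
    )
  }
  v <- cell_volume(crystal)
  vm <- v / (crystal$asu_multiplicity * molecules_per_asu * molecular_weight)
  tibble(
    cell_volume = v,
    matthews_vm = vm,
    solvent_fraction = 1 - 1.23 / vm
  )
}

# Average residue masses (Da) for amino acids in a peptide chain
# (monomer mass minus water).
.aa_residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

#' Average-mass molecular weight of a protein
#'
#' From a one-letter sequence, sums average residue masses plus one water.
#' When only a residue count is known, uses the composition-weighted average
#' residue mass of a typical protein (111.13 Da); the resulting
#' Matthews/solvent numbers should then be read with a few-percent MW
#' uncertainty in mind.
#'
#' @param sequence One-letter amino-acid sequence (string); optional.
#' @param n_residues Residue count, used only when `sequence` is `NULL`.
#' @return Molecular weight in Daltons.
#' @export
#' @examples
#' protein_mw("ACDEFG")
#' protein_mw(n_residues = 136)
protein_mw <- function(sequence = NULL, n_residues = NULL) {
  water <- 18.0153
  if (!is.null(sequence)) {
    aa <- strsplit(toupper(gsub("[[:space:]]", "", sequence)), "")[[1]]
    unknown <- setdiff(aa, names(.aa_residue_mass))
    if (length(unknown) > 0) {
      abort(paste0(
        "unknown amino-acid code(s): ", paste(unique(unknown), collapse = ", ")
      ), class = "cnbdkit_domain_error")
    }
    return(sum(.aa_residue_mass[aa]) + water)
  }
  if (is.null(n_residues) || n_residues <= 0) {
    abort("supply a sequence or a positive n_residues",
      class = "cnbdkit_domain_error"
    )
  }
  # 111.1254 Da: average residue mass weighted by typical protein composition
  n_residues * 111.1254 + water
}
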