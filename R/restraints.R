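# Side-chain chi torsion definitions: for each residue type, the ordered
# atom quadruples of chi1..chi4.
.chi_atoms <- list(
  ARG = list(
    chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
    chi3 = c("CB", "CG", "CD", "NE"), chi4 = c("CG", "CD", "NE", "CZ")
  ),
  ASN = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "OD1")),
  ASP = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "OD1")),
  CYS = list(chi1 = c("N", "CA", "CB", "SG")),
  GLN = list(
    chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
    chi3 = c("CB", "CG", "CD", "OE1")
  ),
  GLU = list(
    chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
    chi3 = c("CB", "CG", "CD", "OE1")
  ),
  HIS = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "ND1")),
  ILE = list(chi1 = c("N", "CA", "CB", "CG1"), chi2 = c("CA", "CB", "CG1", "CD1")),
  LEU = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  LYS = list(
    chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
    chi3 = c("CB", "CG", "CD", "CE"), chi4 = c("CG", "CD", "CE", "NZ")
  ),
  MET = list(
    chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "SD"),
    chi3 = c("CB", "CG", "SD", "CE")
  ),
  PHE = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  PRO = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  SER = list(chi1 = c("N", "CA", "CB", "OG")),
  THR = list(chi1 = c("N", "CA", "CB", "OG1")),
  TRP = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  TYR = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  VAL = list(chi1 = c("N", "CA", "CB", "CG1"))
)

# Torsions whose terminal group is two-fold symmetric (carboxylate and
# aromatic-ring flips): angular comparison is done modulo 180 degrees.
.symmetric_chi <- c(ASP = "chi2", GLU = "chi3", PHE = "chi2", TYR = "chi2")

#' Backbone and side-chain torsions of a protein model
#'
#' Computes phi, psi and side-chain chi torsions (standard quadruples, chi1-4)
#' for every residue of the selected chains.  Torsions whose atoms are
#' incomplete are simply absent from the result.
#'
#' @param model A [structure_model()].
#' @param chain Chain identifier(s); `NULL` for all protein chains.
#' @return A tibble: `chain`, `res_seq`, `res_name`, `torsion`, `angle`.
#' @export
model_torsions <- function(model, chain = NULL) {
  stopifnot(inherits(model, "structure_model"))
  atoms <- collapse_alt_locs(model)$atoms |> filter(!.data$is_hetero)
  chains <- chain %||% unique(atoms$chain)
  out <- list()
  for (ch in chains) {
    res <- residue_index(filter(atoms, .data$chain == ch))
    nres <- nrow(res)
    for (k in seq_len(nres)) {
      r <- res[k, ]
      get <- function(nm, rr = r) atom_xyz(atoms, ch, rr$res_seq, rr$i_code, nm)
      n_k <- get("N"); ca_k <- get("CA"); c_k <- get("C")
      add <- function(name, p1, p2, p3, p4) {
        if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4)) {
          return()
        }
        ang <- tryCatch(dihedral_angle(p1, p2, p3, p4), error = function(e) NULL)
        if (is.null(ang)) {
          return()
        }
        out[[length(out) + 1]] <<- tibble(
          chain = ch, res_seq = r$res_seq, res_name = r$res_name,
          torsion = name, angle = ang
        )
      }
      if (k > 1) {
        prev <- res[k - 1, ]
        c_prev <- get("C", prev)
        if (!is.null(c_prev) && !is.null(n_k) &&
          atom_distance(c_prev, n_k) < 2.5) {
          add("phi", c_prev, n_k, ca_k, c_k)
        }
      }
      if (k < nres) {
        nxt <- res[k + 1, ]
        n_next <- get("N", nxt)
        if (!is.null(c_k) && !is.null(n_next) &&
          atom_distance(c_k, n_next) < 2.5) {
          add("psi", n_k, ca_k, c_k, n_next)
        }
      }
      chis <- .chi_atoms[[r$res_name]]
      if (!is.null(chis)) {
        for (cn in names(chis)) {
          quad <- lapply(chis[[cn]], get)
          add(cn, quad[[1]], quad[[2]], quad[[3]], quad[[4]])
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(
      chain = character(), res_seq = integer(), res_name = character(),
      torsion = character(), angle = double()
    ))
  }
  bind_rows(out)
}

#' Select reference-model dihedral restraints by angular threshold
#'
#' For low-resolution refinement it is common to restrain the working model's
#' torsions to those of a higher-resolution reference structure of the same
#' protein, but only where the two already agree: a reference torsion is
#' imposed only if the absolute circular deviation between the models is
#' within a threshold (default 15 degrees), so the reference guides topology
#' without forcing genuinely different conformations.  This function
#' implements exactly that selection rule.
#'
#' Deviations are wrapped differences in `(-180, 180]`; torsions with two-fold
#' symmetric termini (carboxylate and aromatic-ring flips: Asp chi2, Glu chi3,
#' Phe/Tyr chi2) are compared modulo 180 degrees so a nomenclature flip does
#' not disqualify an otherwise identical torsion.  Residues are paired by
#' author residue number and matching chain.
#'
#' @param working,reference [structure_model()]s sharing a residue numbering.
#' @param threshold Selection threshold in degrees (default 15; must be
#'   positive).
#' @param chain Chain(s) to compare; `NULL` for all shared chains.
#' @return A tibble: `chain`, `res_seq`, `res_name`, `torsion`,
#'   `reference_angle`, `working_angle`, `deviation`, `selected`.
#' @export
select_reference_dihedrals <- function(working, reference, threshold = 15,
                                       chain = NULL) {
  if (threshold <= 0) {
    abort("threshold must be positive", class = "cnbdkit_domain_error")
  }
  tw <- model_torsions(working, chain = chain)
  tr <- model_torsions(reference, chain = chain)
  shared <- inner_join(
    rename(tw, working_angle = "angle"),
    tr |> select("chain", "res_seq", "torsion", reference_angle = "angle"),
    by = c("chain", "res_seq", "torsion")
  )
  if (nrow(shared) == 0) {
    abort("no torsion is computable in both models",
      class = "cnbdkit_selection_error"
    )
  }
  shared |>
    mutate(
      symmetric = .data$torsion == dplyr::coalesce(
        unname(.symmetric_chi[.data$res_name]), ""
      ),
      deviation = ifelse(
        .data$symmetric,
        wrap_half(.data$working_angle - .data$reference_angle),
        wrap_angle(.data$working_angle - .data$reference_angle)
      ),
      selected = abs(.data$deviation) <= threshold
    ) |>
    select(
      "chain", "res_seq", "res_name", "torsion",
      "reference_angle", "working_angle", "deviation", "selected"
    )
}

# Wrapped difference reduced by a 180-degree terminal symmetry: result in
# (-90, 90].
wrap_half <- function(x) {
  out <- x - 180 * round(x / 180)
  out[out <= -90] <- 90
  out
}
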