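#' Tidy macromolecular structure models
#'
#' A `structure_model` is a light container for a hierarchical coordinate set
#' flattened into a tidy atom table: one row per atom, with its chain, residue
#' and atom-level identifiers as columns.  All geometry in the package operates
#' on this table with ordinary data-frame verbs, so intermediate results can be
#' inspected, filtered and joined like any other tibble.
#'
#' The atom table has the columns
#' \describe{
#'   \item{serial}{integer atom serial number}
#'   \item{atom}{atom name, normalized (see [normalize_atom_name()])}
#'   \item{alt_loc}{alternate-location indicator, `""` when absent}
#'   \item{res_name}{3-letter residue or ligand code}
#'   \item{chain}{chain identifier}
#'   \item{res_seq}{author-assigned residue number (kept verbatim)}
#'   \item{i_code}{insertion code, `""` when absent}
#'   \item{x, y, z}{coordinates in Angstrom}
#'   \item{occupancy}{occupancy in `[0, 1]`}
#'   \item{b_factor}{isotropic B-factor in Angstrom^2}
#'   \item{element}{element symbol}
#'   \item{is_hetero}{`TRUE` for HETATM-class records (ligands, ions, water)}
#' }
#'
#' @param atoms A data frame with the columns listed above.
#' @param crystal Optional crystal description as returned by [crystal_info()].
#' @param source_id Free-text label for provenance (file name, accession, ...).
#'
#' @return An object of class `structure_model`: a list with elements `atoms`
#'   (tibble), `crystal` (list or `NULL`) and `source_id` (string).
#' @seealso [read_structure()], [select_atoms()]
#' @export
#' @examples
#' m <- build_dipeptide(omega = 0)
#' m
#' m$atoms
structure_model <- function(atoms, crystal = NULL, source_id = "") {
  atoms <- as_tibble(atoms)
  required <- c(
    "serial", "atom", "alt_loc", "res_name", "chain", "res_seq", "i_code",
    "x", "y", "z", "occupancy", "b_factor", "element", "is_hetero"
  )
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "atom table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  atoms <- atoms[, required]
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      abort("atom coordinates must be finite")
    }
    occ <- atoms$occupancy
    if (any(!is.na(occ) & (occ < 0 | occ > 1))) {
      abort("occupancy must lie in [0, 1]")
    }
    if (any(!is.na(atoms$b_factor) & atoms$b_factor < 0)) {
      abort("b_factor must be >= 0")
    }
  }
  structure(
    list(atoms = atoms, crystal = crystal, source_id = source_id),
    class = "structure_model"
  )
}

#' Crystal cell and symmetry description
#'
#' Bundles the unit-cell constants and space group of a crystal form, resolving
#' the symmetry-operator count (`asu_multiplicity`) from a built-in table of
#' space groups via [space_group_multiplicity()] unless given explicitly.
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @param space_group Hermann-Mauguin symbol (spacing is ignored, e.g.
#'   `"P 62 2 2"` and `"P6222"` are equivalent).
#' @param z_asu Molecules per asymmetric unit (optional bookkeeping).
#' @param asu_multiplicity Symmetry-operator count; looked up from
#'   `space_group` when `NULL`.
#'
#' @return A list of class `crystal_info`.
#' @export
#' @examples
#' crystal_info(107, 107, 171, 90, 90, 120, "P 62 2 2")
crystal_info <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                         space_group = "P 1", z_asu = NA_integer_,
                         asu_multiplicity = NULL) {
  lens <- c(a = a, b = b, c = c)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort("cell lengths must be positive and finite")
  }
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180)) {
    abort("cell angles must lie in (0, 180) degrees")
  }
  if (is.null(asu_multiplicity)) {
    asu_multiplicity <- space_group_multiplicity(space_group)
  }
  if (!is.finite(asu_multiplicity) || asu_multiplicity < 1) {
    abort("asu_multiplicity must be >= 1")
  }
  structure(
    list(
      a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
      space_group = space_group, z_asu = z_asu,
      asu_multiplicity = as.integer(asu_multiplicity)
    ),
    class = "crystal_info"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  at <- x$atoms
  n_ch <- length(unique(at$chain[!at$is_hetero]))
  n_res <- nrow(distinct(
    filter(at, !.data$is_hetero),
    .data$chain, .data$res_seq, .data$i_code
  ))
  n_het <- nrow(distinct(
    filter(at, .data$is_hetero),
    .data$chain, .data$res_seq, .data$i_code, .data$res_name
  ))
  cat(sprintf(
    "<structure_model> %s\n  %d atoms | %d protein chain(s), %d residues | %d hetero group(s)\n",
    if (nzchar(x$source_id)) x$source_id else "(unnamed)",
    nrow(at), n_ch, n_res, n_het
  ))
  if (!is.null(x$crystal)) {
    cr <- x$crystal
    cat(sprintf(
      "  cell %.2f %.2f %.2f  %.1f %.1f %.1f  %s\n",
      cr$a, cr$b, cr$c, cr$alpha, cr$beta, cr$gamma, cr$space_group
    ))
  }
  invisible(x)
}

#' @export
print.crystal_info <- function(x, ...) {
  cat(sprintf(
    "<crystal_info> %s  a=%.2f b=%.2f c=%.2f  alpha=%.1f beta=%.1f gamma=%.1f  (multiplicity %d)\n",
    x$space_group, x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$asu_multiplicity
  ))
  invisible(x)
}

#' Normalize atom names across deposition dialects
#'
#' Ribose atom names drift across depositions and tables: the same atom is
#' written `O2*`, `O2'` or `O2′`.  All package functions compare atom names
#' after mapping `*` and the unicode prime to the ASCII prime and upper-casing.
#'
#' @param x Character vector of atom names.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_atom_name(c("O2*", "o2'", "C1′"))
normalize_atom_name <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub("*", "'", x, fixed = TRUE)
  gsub("′", "'", x)
}

#' Reduce alternate locations to a single conformer
#'
#' Keeps, for each (chain, residue, atom name), the highest-occupancy alternate
#' location, breaking ties by alphabetical `alt_loc`.  Atoms without alternates
#' pass through unchanged.  All geometry functions apply this rule internally
#' so that derived quantities are deterministic.
#'
#' @param model A [structure_model()].
#' @return A `structure_model` with at most one conformer per atom.
#' @export
collapse_alt_locs <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (nrow(at) == 0 || all(at$alt_loc == "")) {
    return(model)
  }
  at <- at |>
    group_by(.data$chain, .data$res_seq, .data$i_code, .data$res_name, .data$atom) |>
    arrange(dplyr::desc(.data$occupancy), .data$alt_loc, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$serial)
  structure_model(at, crystal = model$crystal, source_id = model$source_id)
}

# Residues of a model as a keyed tibble (one row per residue), in model order.
residue_index <- function(atoms) {
  atoms |>
    distinct(.data$chain, .data$res_seq, .data$i_code, .data$res_name, .data$is_hetero) |>
    arrange(.data$chain, .data$res_seq, .data$i_code)
}
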