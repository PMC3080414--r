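#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors in Angstrom.
#' @return Distance in Angstrom.
#' @export
#' @examples
#' atom_distance(c(0, 0, 0), c(3, 4, 0))
atom_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort("coordinates must be finite", class = "cnbdkit_domain_error")
  }
  sqrt(sum((a - b)^2))
}

#' Signed dihedral angle of four points
#'
#' Standard atan2 construction: with bond vectors `b1 = p2 - p1`,
#' `b2 = p3 - p2`, `b3 = p4 - p3`, the torsion is
#' `atan2((b1 x b2) . b3 * |b2|, (b1 x b2) . (b2 x b3))`.  The result is in
#' degrees on `(-180, 180]`; it is invariant under rigid transforms and
#' changes sign under mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors in Angstrom.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b2^2) < 1e-12) {
    abort("degenerate dihedral: central atoms coincide",
      class = "cnbdkit_domain_error"
    )
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    abort("degenerate dihedral: colinear bounding triple",
      class = "cnbdkit_domain_error"
    )
  }
  ang <- atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  wrap_angle(ang * 180 / pi)
}

cross3 <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

#' Wrap an angle in degrees to (-180, 180]
#'
#' @param x Angles in degrees.
#' @return Wrapped angles; exactly -180 maps to +180.
#' @export
wrap_angle <- function(x) {
  out <- x - 360 * round(x / 360)
  out[out <= -180] <- 180
  out
}

# Coordinates of one named atom in one residue; NULL when absent.
atom_xyz <- function(atoms, chain, res_seq, i_code, name) {
  hit <- atoms[
    atoms$chain == chain & atoms$res_seq == res_seq &
      atoms$i_code == i_code & atoms$atom == name,
  ]
  if (nrow(hit) == 0) {
    return(NULL)
  }
  c(hit$x[[1]], hit$y[[1]], hit$z[[1]])
}

#' Scan a chain for cis peptide bonds
#'
#' Computes the backbone omega torsion (CA_i, C_i, N_{i+1}, CA_{i+1}) for each
#' consecutive residue pair and classifies it: cis when `|omega| <= 30` deg,
#' trans when `|wrap(omega - 180)| <= 30` deg, ambiguous otherwise.  Pairs with
#' missing backbone atoms are skipped with a warning.  Non-proline cis
#' peptides are rare and structurally notable, so `involves_proline` is
#' reported per link.
#'
#' @param model A [structure_model()].
#' @param chain Chain identifier; `NULL` scans every protein chain.
#' @param cis_window Half-width of the cis/trans windows in degrees
#'   (default 30).
#' @return A tibble with one row per peptide link: `chain`, `res_seq_i`,
#'   `res_name_i`, `res_seq_j`, `res_name_j`, `omega`, `classification`,
#'   `is_cis`, `involves_proline`.
#' @export
#' @examples
#' peptide_omega_scan(build_dipeptide(omega = 0))
peptide_omega_scan <- function(model, chain = NULL, cis_window = 30) {
  stopifnot(inherits(model, "structure_model"))
  atoms <- collapse_alt_locs(model)$atoms
  atoms <- filter(atoms, !.data$is_hetero)
  chains <- chain %||% unique(atoms$chain)
  out <- list()
  for (ch in chains) {
    res <- residue_index(filter(atoms, .data$chain == ch))
    if (nrow(res) < 2) next
    for (k in seq_len(nrow(res) - 1)) {
      ri <- res[k, ]
      rj <- res[k + 1, ]
      ca_i <- atom_xyz(atoms, ch, ri$res_seq, ri$i_code, "CA")
      c_i <- atom_xyz(atoms, ch, ri$res_seq, ri$i_code, "C")
      n_j <- atom_xyz(atoms, ch, rj$res_seq, rj$i_code, "N")
      ca_j <- atom_xyz(atoms, ch, rj$res_seq, rj$i_code, "CA")
      if (is.null(ca_i) || is.null(c_i) || is.null(n_j) || is.null(ca_j)) {
        warn(sprintf(
          "skipping peptide link %s%d-%d: incomplete backbone", ch,
          ri$res_seq, rj$res_seq
        ))
        next
      }
      # Only bonded neighbours define an omega; a chain break (C-N far beyond
      # a covalent bond) is skipped rather than classified.
      if (atom_distance(c_i, n_j) > 2.5) next
      omega <- dihedral_angle(ca_i, c_i, n_j, ca_j)
      cls <- if (abs(omega) <= cis_window) {
        "cis"
      } else if (abs(wrap_angle(omega - 180)) <= cis_window) {
        "trans"
      } else {
        "ambiguous"
      }
      out[[length(out) + 1]] <- tibble(
        chain = ch,
        res_seq_i = ri$res_seq, res_name_i = ri$res_name,
        res_seq_j = rj$res_seq, res_name_j = rj$res_name,
        omega = omega,
        classification = cls,
        is_cis = cls == "cis",
        involves_proline = ri$res_name == "PRO" | rj$res_name == "PRO"
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      chain = character(), res_seq_i = integer(), res_name_i = character(),
      res_seq_j = integer(), res_name_j = character(), omega = double(),
      classification = character(), is_cis = logical(),
      involves_proline = logical()
    ))
  }
  bind_rows(out)
}

#' Glycosidic torsion and syn/anti classification of purine nucleotides
#'
#' Computes the purine glycosidic torsion chi on the atom quadruple
#' O4'-C1'-N9-C4 (names normalized, so `O4*` dialects work) and classifies the
#' base orientation: syn when chi lies in the closed interval `[-90, 90]`
#' degrees, anti otherwise (IUPAC convention).
#'
#' @param model A [structure_model()], or `NULL` when `residue` is given.
#' @param chain,res_seq Identify the nucleotide residue within `model`.
#' @param residue Alternatively, a tibble of atom rows for one residue.
#' @return A one-row tibble: `chain`, `res_seq`, `res_name`, `kind`, `angle`,
#'   `classification`.
#' @export
#' @examples
#' nt <- build_purine_nucleotide(chi = 45, base = "guanine")
#' glycosidic_chi(nt)
glycosidic_chi <- function(model = NULL, chain = NULL, res_seq = NULL,
                           residue = NULL) {
  if (is.null(residue)) {
    stopifnot(inherits(model, "structure_model"))
    atoms <- collapse_alt_locs(model)$atoms
    if (!is.null(chain)) atoms <- filter(atoms, .data$chain %in% !!chain)
    if (!is.null(res_seq)) atoms <- filter(atoms, .data$res_seq %in% !!res_seq)
    residue <- atoms
  }
  residue <- as_tibble(residue)
  key <- distinct(residue, .data$chain, .data$res_seq, .data$i_code)
  if (nrow(key) != 1) {
    abort("glycosidic_chi expects atoms of exactly one residue",
      class = "cnbdkit_lookup_error"
    )
  }
  need <- c("O4'", "C1'", "N9", "C4")
  pts <- lapply(need, function(nm) {
    atom_xyz(residue, key$chain, key$res_seq, key$i_code, nm)
  })
  missing <- need[vapply(pts, is.null, logical(1))]
  if (length(missing) > 0) {
    abort(paste0(
      "nucleotide is missing glycosidic atom(s): ",
      paste(missing, collapse = ", ")
    ), class = "cnbdkit_missing_atom_error")
  }
  chi <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  tibble(
    chain = key$chain, res_seq = key$res_seq,
    res_name = residue$res_name[[1]],
    kind = "chi_glycosidic",
    angle = chi,
    # closed syn interval [-90, 90]; the 1e-9 guard keeps an exactly-built
    # +/-90 boundary fixture on the syn side despite floating-point wrap
    classification = if (abs(chi) <= 90 + 1e-9) "syn" else "anti"
  )
}

# Residues anchoring each part of the cyclic-nucleotide pocket: the P-helix
# backbone amides and the conserved arginine grip the sugar phosphate
# (site 1), the threonine at the end of the cassette bridges phosphate and
# base (site 2), and the beta5 cis-peptide pair docks the purine ring
# (site 3); two hydrophobic neighbours of site 3 are annotated separately.
.pocket_site_map <- list(
  site1 = c(182, 183, 184, 185, 192),
  site2 = 193,
  site3 = c(172, 173),
  near_site3 = c(165, 175)
)

#' Protein-ligand contacts with hydrogen-bond/van-der-Waals classification
#'
#' Reports every protein-atom/ligand-atom pair within `vdw_cutoff`.  A pair is
#' classed `hydrogen_bond` when its distance is at most `hbond_cutoff` and
#' both atoms are nitrogen or oxygen (donor/acceptor chemistry on heavy atoms;
#' no angular term, since typical crystal structures at this resolution carry
#' no hydrogens).  A sulfur atom within `hbond_cutoff` of an N/O partner keeps
#' class `vdw` but is flagged `extended_hbond`, matching how Cys SG to purine
#' N7 interactions are conventionally reported.  Each contact carries a
#' binding-site label from the cyclic-nucleotide pocket map (sites 1-3, or
#' `near_site3`, or `none`).
#'
#' @param model A [structure_model()].
#' @param ligand_chain,ligand_res_seq Identify the ligand residue.
#' @param hbond_cutoff Hydrogen-bond distance cutoff in Angstrom (default 3.5).
#' @param vdw_cutoff Reporting cutoff in Angstrom (default 4.0); must be at
#'   least `hbond_cutoff`.
#' @param include_hetero Also report contacts from other hetero groups to the
#'   ligand (default `FALSE`: protein atoms only).
#' @return A tibble ordered by protein residue then distance: `chain`,
#'   `res_seq`, `res_name`, `atom`, `element`, `ligand_atom`, `distance`,
#'   `contact_class`, `extended_hbond`, `site_label`.
#' @export
find_contacts <- function(model, ligand_chain, ligand_res_seq,
                          hbond_cutoff = 3.5, vdw_cutoff = 4.0,
                          include_hetero = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (hbond_cutoff <= 0 || vdw_cutoff <= 0 || hbond_cutoff > vdw_cutoff) {
    abort("need 0 < hbond_cutoff <= vdw_cutoff", class = "cnbdkit_domain_error")
  }
  atoms <- collapse_alt_locs(model)$atoms
  lig <- filter(
    atoms,
    .data$chain == ligand_chain, .data$res_seq == ligand_res_seq
  )
  if (nrow(lig) == 0) {
    abort(sprintf(
      "ligand %s/%s not found in model", ligand_chain, ligand_res_seq
    ), class = "cnbdkit_lookup_error")
  }
  env <- filter(
    atoms,
    !(.data$chain == ligand_chain & .data$res_seq == ligand_res_seq)
  )
  if (!include_hetero) {
    env <- filter(env, !.data$is_hetero)
  }
  if (nrow(env) == 0) {
    return(empty_contact_table())
  }
  # all-pairs distances, then threshold; pocket-sized problems are tiny
  d2 <- outer(env$x, lig$x, "-")^2 + outer(env$y, lig$y, "-")^2 +
    outer(env$z, lig$z, "-")^2
  hit <- which(d2 <= vdw_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(empty_contact_table())
  }
  pe <- env[hit[, 1], ]
  pl <- lig[hit[, 2], ]
  dist <- sqrt(d2[hit])
  no <- c("N", "O")
  is_hb <- dist <= hbond_cutoff & pe$element %in% no & pl$element %in% no
  ext <- dist <= hbond_cutoff & !is_hb &
    ((pe$element == "S" & pl$element %in% no) |
      (pl$element == "S" & pe$element %in% no))
  out <- tibble(
    chain = pe$chain, res_seq = pe$res_seq, res_name = pe$res_name,
    atom = pe$atom, element = pe$element,
    ligand_atom = pl$atom,
    distance = dist,
    contact_class = ifelse(is_hb, "hydrogen_bond", "vdw"),
    extended_hbond = ext,
    site_label = site_label_for(pe$res_seq)
  )
  arrange(out, .data$chain, .data$res_seq, .data$distance)
}

site_label_for <- function(res_seq) {
  out <- rep("none", length(res_seq))
  for (lab in names(.pocket_site_map)) {
    out[res_seq %in% .pocket_site_map[[lab]]] <- lab
  }
  out
}

empty_contact_table <- function() {
  tibble(
    chain = character(), res_seq = integer(), res_name = character(),
    atom = character(), element = character(), ligand_atom = character(),
    distance = double(), contact_class = character(),
    extended_hbond = logical(), site_label = character()
  )
}

#' Cysteine pairs at disulfide-forming distance
#'
#' Lists all pairs of distinct cysteine residues whose SG-SG distance is at
#' most `cutoff`, within and across chains.  The default cutoff of 4.5
#' Angstrom is deliberately wider than the 2.05 Angstrom bonded distance so
#' that reduced cysteine pairs poised to form a disulfide upon oxidation are
#' also reported.
#'
#' @param model A [structure_model()].
#' @param cutoff SG-SG distance cutoff in Angstrom.
#' @return A tibble: `chain_i`, `res_seq_i`, `chain_j`, `res_seq_j`,
#'   `distance`.
#' @export
find_disulfide_candidates <- function(model, cutoff = 4.5) {
  stopifnot(inherits(model, "structure_model"))
  if (cutoff <= 0) {
    abort("cutoff must be positive", class = "cnbdkit_domain_error")
  }
  sg <- collapse_alt_locs(model)$atoms |>
    filter(.data$res_name == "CYS", .data$atom == "SG")
  n <- nrow(sg)
  if (n < 2) {
    return(tibble(
      chain_i = character(), res_seq_i = integer(),
      chain_j = character(), res_seq_j = integer(), distance = double()
    ))
  }
  pairs <- utils::combn(n, 2)
  d <- sqrt(
    (sg$x[pairs[1, ]] - sg$x[pairs[2, ]])^2 +
      (sg$y[pairs[1, ]] - sg$y[pairs[2, ]])^2 +
      (sg$z[pairs[1, ]] - sg$z[pairs[2, ]])^2
  )
  keep <- d <= cutoff
  tibble(
    chain_i = sg$chain[pairs[1, keep]],
    res_seq_i = sg$res_seq[pairs[1, keep]],
    chain_j = sg$chain[pairs[2, keep]],
    res_seq_j = sg$res_seq[pairs[2, keep]],
    distance = d[keep]
  ) |>
    arrange(.data$distance)
}

#' Per-residue C-alpha B-factor profile
#'
#' Extracts C-alpha B-factors along a chain in residue order and, for each
#' named residue span, the mean over residues present.  Useful for comparing
#' local flexibility (for example the beta4/beta5 region of a
#' cyclic-nucleotide binding domain) across related structures; for such
#' comparisons, normalize each chain by its own chain-wide mean to remove
#' overall-scale differences between crystals.
#'
#' @param model A [structure_model()].
#' @param chain Chain identifier.
#' @param regions Named list of `c(first, last)` residue spans.
#' @return An object of class `bfactor_profile`: list with `chain`, `entries`
#'   (tibble `res_seq`, `b_factor`), `region_means` (tibble `region`,
#'   `first`, `last`, `n_residues`, `mean_b`, with `NaN` mean and a warning
#'   for spans absent from the chain) and `chain_mean`.
#' @export
bfactor_profile <- function(model, chain, regions = list()) {
  stopifnot(inherits(model, "structure_model"))
  ca <- collapse_alt_locs(model)$atoms |>
    filter(
      !.data$is_hetero, .data$chain == !!chain, .data$atom == "CA"
    ) |>
    arrange(.data$res_seq, .data$i_code)
  if (nrow(ca) == 0) {
    abort(sprintf("chain %s has no C-alpha atoms", chain),
      class = "cnbdkit_lookup_error"
    )
  }
  entries <- tibble(res_seq = ca$res_seq, b_factor = ca$b_factor)
  region_means <- purrr::imap(regions, function(span, nm) {
    inside <- entries$b_factor[entries$res_seq >= span[1] & entries$res_seq <= span[2]]
    if (length(inside) == 0) {
      warn(sprintf("region '%s' (%d-%d) has no residues in chain %s",
        nm, span[1], span[2], chain))
    }
    tibble(
      region = nm, first = span[1], last = span[2],
      n_residues = length(inside), mean_b = mean(inside)
    )
  }) |> bind_rows()
  if (nrow(region_means) == 0) {
    region_means <- tibble(
      region = character(), first = double(), last = double(),
      n_residues = integer(), mean_b = double()
    )
  }
  structure(
    list(
      chain = chain, entries = entries, region_means = region_means,
      chain_mean = mean(entries$b_factor)
    ),
    class = "bfactor_profile"
  )
}

#' @export
print.bfactor_profile <- function(x, ...) {
  cat(sprintf(
    "<bfactor_profile> chain %s: %d residues, chain mean %.1f A^2\n",
    x$chain, nrow(x$entries), x$chain_mean
  ))
  if (nrow(x$region_means) > 0) {
    print(x$region_means)
  }
  invisible(x)
}

#' @rdname bfactor_profile
#' @param x A `bfactor_profile`.
#' @param ... Unused.
#' @method tidy bfactor_profile
#' @export
tidy.bfactor_profile <- function(x, ...) {
  mutate(x$entries, chain = x$chain, relative_b = .data$b_factor / x$chain_mean)
}

#' @rdname bfactor_profile
#' @param object A `bfactor_profile`.
#' @method autoplot bfactor_profile
#' @export
autoplot.bfactor_profile <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$res_seq, y = .data$b_factor)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Residue", y = expression("C" * alpha * " B-factor (" * ring(A)^2 * ")"),
      title = paste("Chain", object$chain)
    )
  if (nrow(object$region_means) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$region_means,
      ggplot2::aes(xmin = .data$first, xmax = .data$last),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p
}
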