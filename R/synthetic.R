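#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: returns the point `d` at distance
#' `bond` from `c`, with angle `b-c-d` equal to `angle` and torsion
#' `a-b-c-d` equal to `torsion`.  The workhorse of the synthetic fixture
#' builders; the requested torsion is achieved to floating-point precision.
#'
#' @param a,b,c Numeric 3-vectors (reference frame).
#' @param bond Bond length c-d (Angstrom).
#' @param angle Bond angle b-c-d (degrees).
#' @param torsion Torsion a-b-c-d (degrees).
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(
    -bond * cos(ang),
    bond * sin(ang) * cos(tor),
    bond * sin(ang) * sin(tor)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal peptide internal coordinates (standard engh-huber-like values).
.pep <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.4
)

#' Build an ideal dipeptide at a chosen omega torsion
#'
#' Constructs a two-residue peptide with ideal bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom) whose backbone omega torsion
#' (CA1-C1-N2-CA2) equals `omega` exactly.  Residues get a CB atom when their
#' type has one, so the fixture also exercises residue-name-dependent logic
#' (e.g. proline flags in cis-peptide scans).
#'
#' @param omega Peptide omega torsion in degrees, in (-180, 180].
#' @param residue_names Length-2 character vector of 3-letter codes.
#' @param chain Chain identifier for the fixture.
#' @return A [structure_model()] with one chain and two residues.
#' @export
#' @examples
#' peptide_omega_scan(build_dipeptide(omega = 0))
build_dipeptide <- function(omega, residue_names = c("ALA", "ALA"),
                            chain = "A") {
  if (omega <= -180 || omega > 180) {
    abort("omega must lie in (-180, 180]", class = "cnbdkit_domain_error")
  }
  residue_names <- toupper(residue_names)
  p <- .pep
  psi1 <- 140 # arbitrary but fixed; does not affect omega
  phi2 <- -120
  n1 <- c(0, 0, 0)
  ca1 <- c(p$n_ca, 0, 0)
  # C1 in the xy-plane at the ideal N-CA-C angle
  th <- (180 - p$ang_n_ca_c) * pi / 180
  c1 <- ca1 + p$ca_c * c(cos(th), sin(th), 0)
  n2 <- place_atom(n1, ca1, c1, p$c_n, p$ang_ca_c_n, psi1)
  o1 <- place_atom(n1, ca1, c1, p$c_o, p$ang_ca_c_o, psi1 + 180)
  ca2 <- place_atom(ca1, c1, n2, p$n_ca, p$ang_c_n_ca, omega)
  c2 <- place_atom(c1, n2, ca2, p$ca_c, p$ang_n_ca_c, phi2)
  o2 <- place_atom(n2, ca2, c2, p$c_o, p$ang_ca_c_o, 120)
  rows <- list(
    list("N", n1, "N", 1L), list("CA", ca1, "C", 1L),
    list("C", c1, "C", 1L), list("O", o1, "O", 1L),
    list("N", n2, "N", 2L), list("CA", ca2, "C", 2L),
    list("C", c2, "C", 2L), list("O", o2, "O", 2L)
  )
  if (residue_names[1] != "GLY") {
    cb1 <- place_atom(c1, n1, ca1, p$ca_cb, p$ang_n_ca_cb, 122.5)
    rows <- append(rows, list(list("CB", cb1, "C", 1L)), after = 4)
  }
  if (residue_names[2] != "GLY") {
    cb2 <- place_atom(c2, n2, ca2, p$ca_cb, p$ang_n_ca_cb, 122.5)
    rows <- append(rows, list(list("CB", cb2, "C", length(rows))))
  }
  atoms <- purrr::imap(rows, function(r, i) {
    tibble(
      serial = i, atom = r[[1]], alt_loc = "",
      res_name = residue_names[r[[4]]], chain = chain,
      res_seq = r[[4]], i_code = "",
      x = r[[2]][1], y = r[[2]][2], z = r[[2]][3],
      occupancy = 1, b_factor = 20, element = r[[3]], is_hetero = FALSE
    )
  }) |> bind_rows()
  # last CB row carried a bogus residue index marker; fix residue 2 CB
  atoms$res_seq[atoms$res_seq > 2] <- 2L
  atoms$res_name[atoms$atom == "CB" & atoms$res_seq == 2L] <- residue_names[2]
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, source_id = sprintf("dipeptide omega=%g", omega))
}

#' Build a purine nucleotide at a chosen glycosidic torsion
#'
#' Internal-coordinate template of a ribonucleotide (ribose, purine base,
#' optional 3',5'-cyclic phosphate) placed so the glycosidic torsion
#' O4'-C1'-N9-C4 equals `chi` exactly.  Geometry is idealized (planar sugar,
#' planar base with standard bond lengths/angles): the fixture's purpose is
#' exact, known torsions and plausible contact geometry, not chemical-grade
#' coordinates.  Atom names use the normalized prime dialect (`O4'`, `C1'`).
#'
#' @param chi Glycosidic torsion in degrees, in (-180, 180].
#' @param base `"guanine"` (residue code CGM-like chemistry, with O6/N2) or
#'   `"adenine"` (N6).
#' @param cyclic_phosphate Include the 3',5'-cyclic phosphate (default TRUE).
#' @param chain,res_seq,res_name Identifiers for the fixture residue;
#'   `res_name` defaults to `"CGM"` for guanine and `"CMP"` for adenine.
#' @param offset Translation applied to all atoms (to position the ligand
#'   relative to other fixture atoms).
#' @return A [structure_model()] containing the single hetero residue.
#' @export
#' @examples
#' glycosidic_chi(build_purine_nucleotide(chi = 45, base = "guanine"))
build_purine_nucleotide <- function(chi, base = c("guanine", "adenine"),
                                    cyclic_phosphate = TRUE, chain = "A",
                                    res_seq = 301L, res_name = NULL,
                                    offset = c(0, 0, 0)) {
  base <- match.arg(base)
  if (chi <= -180 || chi > 180) {
    abort("chi must lie in (-180, 180]", class = "cnbdkit_domain_error")
  }
  res_name <- res_name %||% if (base == "guanine") "CGM" else "CMP"
  # planar ribose ring as a regular pentagon (pucker is irrelevant here)
  r_ring <- 1.4 / (2 * sin(pi / 5))
  ring_names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  ring_angle <- pi / 2 - (seq_along(ring_names) - 1) * 2 * pi / 5
  coords <- list()
  for (i in seq_along(ring_names)) {
    coords[[ring_names[i]]] <- c(
      r_ring * cos(ring_angle[i]), r_ring * sin(ring_angle[i]), 0
    )
  }
  coords[["O2'"]] <- place_atom(
    coords[["O4'"]], coords[["C1'"]], coords[["C2'"]], 1.41, 112, -118
  )
  coords[["O3'"]] <- place_atom(
    coords[["C1'"]], coords[["C2'"]], coords[["C3'"]], 1.42, 112, 118
  )
  coords[["C5'"]] <- place_atom(
    coords[["C2'"]], coords[["C3'"]], coords[["C4'"]], 1.51, 114, -118
  )
  coords[["O5'"]] <- place_atom(
    coords[["C3'"]], coords[["C4'"]], coords[["C5'"]], 1.42, 110, 60
  )
  if (cyclic_phosphate) {
    coords[["P"]] <- place_atom(
      coords[["C4'"]], coords[["C5'"]], coords[["O5'"]], 1.60, 120, 180
    )
    coords[["O1P"]] <- place_atom(
      coords[["C5'"]], coords[["O5'"]], coords[["P"]], 1.48, 110, 60
    )
    coords[["O2P"]] <- place_atom(
      coords[["C5'"]], coords[["O5'"]], coords[["P"]], 1.48, 110, -60
    )
  }
  # base: N9 off C1', then C4 at the requested chi; the remaining ring atoms
  # follow with planar (0/180) torsions relative to the base plane
  coords[["N9"]] <- place_atom(
    coords[["C2'"]], coords[["O4'"]], coords[["C1'"]], 1.47, 108, -122
  )
  coords[["C4"]] <- place_atom(
    coords[["O4'"]], coords[["C1'"]], coords[["N9"]], 1.37, 126, chi
  )
  coords[["C5"]] <- place_atom(
    coords[["C1'"]], coords[["N9"]], coords[["C4"]], 1.37, 106, 180
  )
  coords[["N3"]] <- place_atom(
    coords[["C1'"]], coords[["N9"]], coords[["C4"]], 1.35, 127, 0
  )
  coords[["C8"]] <- place_atom(
    coords[["C5"]], coords[["C4"]], coords[["N9"]], 1.37, 106, 0
  )
  coords[["N7"]] <- place_atom(
    coords[["N9"]], coords[["C4"]], coords[["C5"]], 1.39, 110, 0
  )
  coords[["C6"]] <- place_atom(
    coords[["N9"]], coords[["C4"]], coords[["C5"]], 1.42, 132, 180
  )
  coords[["N1"]] <- place_atom(
    coords[["C4"]], coords[["C5"]], coords[["C6"]], 1.36, 117, 180
  )
  coords[["C2"]] <- place_atom(
    coords[["C5"]], coords[["C6"]], coords[["N1"]], 1.37, 118, 0
  )
  if (base == "guanine") {
    coords[["O6"]] <- place_atom(
      coords[["C4"]], coords[["C5"]], coords[["C6"]], 1.23, 120, 0
    )
    coords[["N2"]] <- place_atom(
      coords[["C6"]], coords[["N1"]], coords[["C2"]], 1.34, 120, 180
    )
  } else {
    coords[["N6"]] <- place_atom(
      coords[["C4"]], coords[["C5"]], coords[["C6"]], 1.34, 120, 0
    )
  }
  nm <- names(coords)
  atoms <- tibble(
    serial = seq_along(nm),
    atom = nm,
    alt_loc = "",
    res_name = res_name,
    chain = chain,
    res_seq = as.integer(res_seq),
    i_code = "",
    x = vapply(coords, `[`, numeric(1), 1) + offset[1],
    y = vapply(coords, `[`, numeric(1), 2) + offset[2],
    z = vapply(coords, `[`, numeric(1), 3) + offset[3],
    occupancy = 1,
    b_factor = 20,
    element = substr(gsub("[^A-Z]", "", nm), 1, 1),
    is_hetero = TRUE
  )
  structure_model(
    atoms,
    source_id = sprintf("%s nucleotide chi=%g", base, chi)
  )
}

#' Random rotation matrix
#'
#' Uniform (Haar) random proper rotation, built from a normalized quaternion
#' of four standard normal deviates.  Deterministic for a given seed.
#'
#' @param seed Optional integer seed.
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed %||% NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Noised and rigidly transformed copy of a structure
#'
#' Adds isotropic Gaussian displacement (standard deviation `sigma` per
#' coordinate) to every atom, then applies a rigid transform.  With
#' `sigma = 0` and the identity transform the copy is bitwise identical.
#' Deterministic per `seed`.
#'
#' @param model A [structure_model()].
#' @param sigma Noise standard deviation per coordinate (Angstrom, >= 0).
#' @param rotation 3 x 3 rotation matrix, `"random"`, or `NULL` (identity).
#' @param translation Length-3 translation, `"random"`, or `NULL` (zero).
#' @param seed Integer seed (mandatory when anything is stochastic).
#' @return A transformed `structure_model`.
#' @export
#' @examples
#' m <- build_dipeptide(omega = 180)
#' m2 <- perturb_chain(m, sigma = 0, rotation = "random", seed = 7)
perturb_chain <- function(model, sigma = 0, rotation = NULL,
                          translation = NULL, seed = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (sigma < 0) {
    abort("sigma must be >= 0", class = "cnbdkit_domain_error")
  }
  stochastic <- sigma > 0 || identical(rotation, "random") ||
    identical(translation, "random")
  if (stochastic && is.null(seed)) {
    abort("a seed is mandatory for stochastic perturbations",
      class = "cnbdkit_domain_error"
    )
  }
  if (!is.null(seed)) set.seed(seed)
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (sigma > 0) {
    xyz <- xyz + matrix(rnorm(length(xyz), sd = sigma), ncol = 3)
  }
  rot <- if (identical(rotation, "random")) {
    random_rotation()
  } else {
    rotation %||% diag(3)
  }
  tra <- if (identical(translation, "random")) {
    rnorm(3, sd = 10)
  } else {
    translation %||% c(0, 0, 0)
  }
  xyz <- sweep(xyz %*% t(rot), 2, tra, "+")
  at$x <- xyz[, 1]
  at$y <- xyz[, 2]
  at$z <- xyz[, 3]
  structure_model(at, crystal = model$crystal,
    source_id = paste0(model$source_id, " (perturbed)"))
}

#' Simulated titration with Gaussian heat noise
#'
#' [simulate_titration()] output plus i.i.d. Gaussian noise on each injection
#' heat.  Deterministic per seed; `heat_sigma = 0` reproduces the noiseless
#' curve exactly.
#'
#' @param params A [one_site_params()].
#' @param design A [titration_design()].
#' @param heat_sigma Heat noise standard deviation in ucal (>= 0).
#' @param seed Integer seed (mandatory when `heat_sigma > 0`).
#' @return A `titration_curve` tibble.
#' @export
noisy_titration <- function(params, design, heat_sigma = 0, seed = NULL) {
  if (heat_sigma < 0) {
    abort("heat_sigma must be >= 0", class = "cnbdkit_domain_error")
  }
  if (heat_sigma > 0 && is.null(seed)) {
    abort("a seed is mandatory for noisy titrations",
      class = "cnbdkit_domain_error"
    )
  }
  curve <- simulate_titration(params, design)
  if (heat_sigma > 0) {
    set.seed(seed)
    curve$heat_ucal <- curve$heat_ucal + rnorm(nrow(curve), sd = heat_sigma)
    curve$ndh_kcal_mol <- curve$heat_ucal * 1e-6 /
      (design$syringe_concentration * curve$injection_volume) / 1000
  }
  curve
}
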