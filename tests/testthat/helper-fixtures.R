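# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately written with different constructions than the
# package internals they check.

# --- model assembly -------------------------------------------------------

atom_row <- function(name, xyz, res_seq = 1L, res_name = "ALA", chain = "A",
                     element = substr(name, 1, 1), hetero = FALSE, b = 20,
                     occ = 1, alt = "") {
  tibble::tibble(
    serial = 0L, atom = name, alt_loc = alt, res_name = res_name,
    chain = chain, res_seq = as.integer(res_seq), i_code = "",
    x = xyz[1], y = xyz[2], z = xyz[3], occupancy = occ, b_factor = b,
    element = element, is_hetero = hetero
  )
}

make_model <- function(rows, crystal = NULL, source_id = "fixture") {
  at <- dplyr::bind_rows(rows)
  at$serial <- seq_len(nrow(at))
  structure_model(at, crystal = crystal, source_id = source_id)
}

# Polypeptide backbone (N, CA, C per residue) from phi/psi/omega sequences,
# built by natural extension with ideal internal coordinates.
build_polypeptide <- function(n, phi = -57, psi = -47, omega = 180,
                              res_names = "ALA", chain = "A",
                              res_start = 1L, b_factor = 20) {
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  res_names <- rep_len(toupper(res_names), n)
  pos <- list()
  pos[["N1"]] <- c(0, 0, 0)
  pos[["CA1"]] <- c(1.458, 0, 0)
  th <- (180 - 111.0) * pi / 180
  pos[["C1"]] <- pos[["CA1"]] + 1.525 * c(cos(th), sin(th), 0)
  for (i in 2:n) {
    pos[[paste0("N", i)]] <- place_atom(
      pos[[paste0("N", i - 1)]], pos[[paste0("CA", i - 1)]],
      pos[[paste0("C", i - 1)]], 1.329, 116.2, psi[i - 1]
    )
    pos[[paste0("CA", i)]] <- place_atom(
      pos[[paste0("CA", i - 1)]], pos[[paste0("C", i - 1)]],
      pos[[paste0("N", i)]], 1.458, 121.7, omega[i]
    )
    pos[[paste0("C", i)]] <- place_atom(
      pos[[paste0("C", i - 1)]], pos[[paste0("N", i)]],
      pos[[paste0("CA", i)]], 1.525, 111.0, phi[i]
    )
  }
  rows <- list()
  for (i in seq_len(n)) {
    rs <- res_start + i - 1L
    rows[[length(rows) + 1]] <- atom_row(
      "N", pos[[paste0("N", i)]], rs, res_names[i], chain,
      element = "N", b = b_factor
    )
    rows[[length(rows) + 1]] <- atom_row(
      "CA", pos[[paste0("CA", i)]], rs, res_names[i], chain,
      element = "C", b = b_factor
    )
    rows[[length(rows) + 1]] <- atom_row(
      "C", pos[[paste0("C", i)]], rs, res_names[i], chain,
      element = "C", b = b_factor
    )
  }
  make_model(rows, source_id = sprintf("poly-%d", n))
}

# Aspartate-like single residue with explicit chi1/chi2, for symmetric-torsion
# tests; optionally with the carboxylate oxygens swapped (chi2 + 180).
build_asp_residue <- function(chi1 = -65, chi2 = -20, flip_carboxylate = FALSE,
                              chain = "A", res_seq = 1L) {
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  th <- (180 - 111.0) * pi / 180
  cc <- ca + 1.525 * c(cos(th), sin(th), 0)
  cb <- place_atom(cc, n, ca, 1.521, 110.4, 122.5)
  cg <- place_atom(n, ca, cb, 1.516, 112.6, chi1)
  od1 <- place_atom(ca, cb, cg, 1.249, 118.4, chi2 + if (flip_carboxylate) 180 else 0)
  od2 <- place_atom(ca, cb, cg, 1.249, 118.4, chi2 + if (flip_carboxylate) 0 else 180)
  make_model(list(
    atom_row("N", n, res_seq, "ASP", chain, "N"),
    atom_row("CA", ca, res_seq, "ASP", chain, "C"),
    atom_row("C", cc, res_seq, "ASP", chain, "C"),
    atom_row("CB", cb, res_seq, "ASP", chain, "C"),
    atom_row("CG", cg, res_seq, "ASP", chain, "C"),
    atom_row("OD1", od1, res_seq, "ASP", chain, "O"),
    atom_row("OD2", od2, res_seq, "ASP", chain, "O")
  ))
}

rigid_transform_points <- function(xyz, rot, tra) {
  sweep(xyz %*% t(rot), 2, tra, "+")
}

# --- independent oracles --------------------------------------------------

# Dihedral via the two-plane normal-vector formula with an acos magnitude and
# an explicit sign term (different construction than the package's atan2).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2],
    b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2],
    b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosv <- max(-1, min(1, cosv))
  ang <- acos(cosv) * 180 / pi
  if (sum(n1 * b3) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Brute-force minimum RMSD over rigid motions: numerical minimization over a
# quaternion parameterization from many fixed starts.  Slow but independent
# of the SVD route.
oracle_min_rmsd <- function(a, b, n_starts = 20) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  obj <- function(q) {
    r <- quat_to_rot(q)
    sqrt(mean(rowSums((a0 - b0 %*% t(r))^2)))
  }
  set.seed(99)
  starts <- rbind(diag(4), matrix(rnorm(4 * n_starts), ncol = 4))
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    res <- stats::optim(starts[k, ], obj, method = "BFGS",
      control = list(reltol = 1e-15, maxit = 500))
    best <- min(best, res$value)
  }
  best
}

# All-pairs contact detection by explicit nested loops, mirroring the
# documented classification rules.
oracle_contacts <- function(model, ligand_chain, ligand_res_seq,
                            hbond_cutoff = 3.5, vdw_cutoff = 4.0) {
  at <- collapse_alt_locs(model)$atoms
  lig <- at[at$chain == ligand_chain & at$res_seq == ligand_res_seq, ]
  env <- at[!(at$chain == ligand_chain & at$res_seq == ligand_res_seq) &
    !at$is_hetero, ]
  out <- list()
  for (i in seq_len(nrow(env))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt(sum((c(env$x[i], env$y[i], env$z[i]) -
        c(lig$x[j], lig$y[j], lig$z[j]))^2))
      if (d <= vdw_cutoff) {
        hb <- d <= hbond_cutoff && env$element[i] %in% c("N", "O") &&
          lig$element[j] %in% c("N", "O")
        out[[length(out) + 1]] <- data.frame(
          chain = env$chain[i], res_seq = env$res_seq[i], atom = env$atom[i],
          ligand_atom = lig$atom[j], distance = d,
          contact_class = if (hb) "hydrogen_bond" else "vdw"
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      chain = character(), res_seq = integer(), atom = character(),
      ligand_atom = character(), distance = double(),
      contact_class = character()
    ))
  }
  do.call(rbind, out)
}

contact_key <- function(df) {
  sort(paste(df$chain, df$res_seq, df$atom, df$ligand_atom, df$contact_class,
    sep = "|"))
}

# --- deposited-entry access ----------------------------------------------

# Deposited crystallographic entries are not redistributable inside the
# package; tests that measure against them load from a user-provided copy.
deposited_model <- function(accession) {
  path <- deposited_structure_path(accession)
  if (is.na(path)) {
    return(NULL)
  }
  read_structure(path)
}

missing_deposited_msg <- function(accession) {
  sprintf(
    paste0(
      "deposited entry %s is not available offline: place %s.pdb under the ",
      "package's extdata/deposited/ directory or set ",
      "options(cnbdkit.deposited_dir = ...) to run this measurement"
    ),
    toupper(accession), tolower(accession)
  )
}

chain_ca <- function(model, chain = "A") {
  at <- model$atoms
  at <- at[!at$is_hetero & at$chain == chain & at$atom == "CA", ]
  at <- at[order(at$res_seq), ]
  as.matrix(at[, c("x", "y", "z")])
}

# Unit normal of the purine plane at N7 (perpendicular probe directions keep
# a test probe clear of the other base atoms).
base_normal_at_n7 <- function(nt) {
  xyz <- function(nm) {
    at <- nt$atoms[nt$atoms$atom == nm, ]
    c(at$x[1], at$y[1], at$z[1])
  }
  v1 <- xyz("C5") - xyz("N7")
  v2 <- xyz("C8") - xyz("N7")
  nv <- c(
    v1[2] * v2[3] - v1[3] * v2[2],
    v1[3] * v2[1] - v1[1] * v2[3],
    v1[1] * v2[2] - v1[2] * v2[1]
  )
  nv / sqrt(sum(nv^2))
}
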