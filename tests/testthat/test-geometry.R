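test_that("distances are Euclidean and symmetric", {
  expect_equal(atom_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  a <- c(-1.2, 0.5, 7)
  b <- c(2, -3, 1.5)
  expect_equal(atom_distance(a, b), atom_distance(b, a))
  expect_error(atom_distance(c(Inf, 0, 0), b), class = "cnbdkit_domain_error")
})

test_that("dihedral angles hit the cis/trans limits and reject degeneracy", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, 1, 0)), 0)
  expect_equal(abs(dihedral_angle(p1, p2, p3, c(1, -1, 0))), 180)
  expect_error(dihedral_angle(p1, p2, p2, c(1, 1, 0)), class = "cnbdkit_domain_error")
  expect_error(
    dihedral_angle(c(2, 0, 0), p2, p3, c(1, 1, 0)), # colinear triple
    class = "cnbdkit_domain_error"
  )
})

test_that("dihedral agrees with the plane-normal oracle on random quadruples", {
  set.seed(42)
  worst <- 0
  n_done <- 0
  while (n_done < 1000) {
    pts <- matrix(stats::rnorm(12, sd = 3), ncol = 3)
    ok <- tryCatch(
      {
        got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
        want <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
        worst <- max(worst, abs(wrap_angle(got - want)))
        TRUE
      },
      cnbdkit_domain_error = function(e) FALSE
    )
    if (ok) n_done <- n_done + 1
  }
  expect_lt(worst, 1e-9)
})

test_that("distance and dihedral are rigid-invariant and dihedral mirrors", {
  set.seed(7)
  pts <- matrix(stats::rnorm(12, sd = 2), ncol = 3)
  d0 <- atom_distance(pts[1, ], pts[2, ])
  t0 <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  for (k in 1:100) {
    rot <- random_rotation()
    tra <- stats::rnorm(3, sd = 20)
    moved <- rigid_transform_points(pts, rot, tra)
    expect_lt(abs(atom_distance(moved[1, ], moved[2, ]) - d0), 1e-9)
    expect_lt(
      abs(wrap_angle(
        dihedral_angle(moved[1, ], moved[2, ], moved[3, ], moved[4, ]) - t0
      )),
      1e-9
    )
  }
  mirrored <- pts
  mirrored[, 3] <- -mirrored[, 3]
  expect_equal(
    dihedral_angle(mirrored[1, ], mirrored[2, ], mirrored[3, ], mirrored[4, ]),
    -t0,
    tolerance = 1e-9
  )
})

test_that("peptide omega scan classifies constructed dipeptides", {
  cases <- list(
    list(omega = 0, class = "cis"),
    list(omega = 180, class = "trans"),
    list(omega = 29.9, class = "cis"),
    list(omega = 30.1, class = "ambiguous"),
    list(omega = -150.5, class = "trans")
  )
  for (cs in cases) {
    s <- peptide_omega_scan(build_dipeptide(cs$omega))
    expect_equal(nrow(s), 1)
    expect_equal(s$omega, cs$omega, tolerance = 1e-6)
    expect_equal(s$classification, cs$class)
  }
  pro <- peptide_omega_scan(build_dipeptide(5, residue_names = c("ALA", "PRO")))
  expect_true(pro$involves_proline)
  expect_true(pro$is_cis)
})

test_that("an all-trans helix contains no cis links and gaps are skipped", {
  helix <- build_polypeptide(30, phi = -57, psi = -47, omega = 180)
  s <- peptide_omega_scan(helix)
  expect_equal(nrow(s), 29)
  expect_false(any(s$is_cis))
  expect_true(all(s$classification == "trans"))
  # drop one backbone C: both adjacent links become incomplete
  broken <- helix
  broken$atoms <- dplyr::filter(
    broken$atoms,
    !(.data$res_seq == 10 & .data$atom == "C")
  )
  expect_warning(s2 <- peptide_omega_scan(broken), "incomplete backbone")
  expect_equal(nrow(s2), 28)
})

test_that("glycosidic chi classification has a closed syn interval", {
  for (chi in c(45, 89.9, 90, -90, 0)) {
    g <- glycosidic_chi(build_purine_nucleotide(chi, "guanine"))
    expect_equal(g$angle, chi, tolerance = 1e-6)
    expect_equal(g$classification, "syn")
  }
  for (chi in c(-150, 90.0001, -90.0001, 180)) {
    g <- glycosidic_chi(build_purine_nucleotide(chi, "adenine"))
    expect_equal(g$classification, "anti")
  }
  incomplete <- build_purine_nucleotide(45, "guanine")
  incomplete$atoms <- dplyr::filter(incomplete$atoms, .data$atom != "N9")
  expect_error(
    glycosidic_chi(incomplete),
    regexp = "N9",
    class = "cnbdkit_missing_atom_error"
  )
})

test_that("contact detection classifies, partitions and validates cutoffs", {
  probe_far <- make_model(list(
    atom_row("N", c(0, 0, 0), res_seq = 1, element = "N"),
    atom_row("P", c(10, 0, 0), res_seq = 2, res_name = "PO4",
      element = "P", hetero = TRUE)
  ))
  expect_equal(
    nrow(find_contacts(probe_far, "A", 2, hbond_cutoff = 3.5, vdw_cutoff = 4)),
    0
  )

  nt <- build_purine_nucleotide(60, "guanine")
  n7 <- as.numeric(select_atoms(nt, atom = "N7")[, c("x", "y", "z")])
  # approach perpendicular to the base plane so no other base atom comes
  # inside the hydrogen-bond cutoff
  dir <- base_normal_at_n7(nt)
  model <- make_model(list(
    nt$atoms,
    atom_row("N", n7 + 2.8 * dir, res_seq = 10, res_name = "GLY", element = "N"),
    atom_row("SG", n7 + 3.3 * -dir, res_seq = 11, res_name = "CYS", element = "S")
  ))
  ct <- find_contacts(model, "A", 301)
  expect_true(all(ct$contact_class %in% c("hydrogen_bond", "vdw")))
  hb <- dplyr::filter(ct, .data$contact_class == "hydrogen_bond")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.8, tolerance = 1e-6)
  # sulfur inside the hbond cutoff is vdw-class but flagged extended
  sg <- dplyr::filter(ct, .data$atom == "SG", .data$ligand_atom == "N7")
  expect_equal(sg$contact_class, "vdw")
  expect_true(sg$extended_hbond)
  expect_error(
    find_contacts(model, "A", 301, hbond_cutoff = 5, vdw_cutoff = 4),
    class = "cnbdkit_domain_error"
  )
  expect_error(find_contacts(model, "Z", 301), class = "cnbdkit_lookup_error")
})

test_that("contact detection equals the brute-force all-pairs oracle", {
  set.seed(11)
  for (rep in 1:5) {
    nt <- build_purine_nucleotide(stats::runif(1, -179, 180), "adenine")
    rows <- list(nt$atoms)
    for (k in 1:25) {
      elem <- sample(c("N", "O", "C", "S"), 1)
      rows[[length(rows) + 1]] <- atom_row(
        paste0(elem, k), stats::rnorm(3, sd = 4),
        res_seq = 100 + k, res_name = "GLY", element = elem
      )
    }
    model <- make_model(rows)
    got <- find_contacts(model, "A", 301)
    want <- oracle_contacts(model, "A", 301)
    expect_equal(contact_key(got), contact_key(want))
  }
})

test_that("disulfide candidates are SG pairs within the cutoff", {
  lone <- make_model(list(
    atom_row("SG", c(0, 0, 0), res_seq = 1, res_name = "CYS", element = "S")
  ))
  expect_equal(nrow(find_disulfide_candidates(lone)), 0)

  pair <- make_model(list(
    atom_row("SG", c(0, 0, 0), res_seq = 133, res_name = "CYS", element = "S"),
    atom_row("SG", c(2.05, 0, 0), res_seq = 211, res_name = "CYS", element = "S"),
    atom_row("SG", c(20, 0, 0), res_seq = 50, res_name = "CYS", element = "S")
  ))
  got <- find_disulfide_candidates(pair)
  expect_equal(nrow(got), 1)
  expect_equal(got$distance, 2.05, tolerance = 1e-9)
  expect_setequal(c(got$res_seq_i, got$res_seq_j), c(133, 211))
  expect_equal(nrow(find_disulfide_candidates(pair, cutoff = 1)), 0)
})

test_that("B-factor profiles report entries and region means", {
  flat <- build_polypeptide(20, b_factor = 50)
  pf <- bfactor_profile(flat, "A", regions = list(mid = c(5, 10)))
  expect_true(all(pf$entries$b_factor == 50))
  expect_equal(pf$region_means$mean_b, 50)
  expect_equal(pf$chain_mean, 50)

  ramp <- build_polypeptide(20)
  ramp$atoms$b_factor <- ramp$atoms$res_seq
  pf2 <- suppressWarnings(
    bfactor_profile(ramp, "A", regions = list(mid = c(5, 10), out = c(100, 110)))
  )
  expect_equal(
    pf2$region_means$mean_b[pf2$region_means$region == "mid"],
    mean(5:10)
  )
  expect_true(is.nan(
    pf2$region_means$mean_b[pf2$region_means$region == "out"]
  ))
  expect_warning(
    bfactor_profile(ramp, "A", regions = list(out = c(100, 110))),
    "no residues"
  )
  td <- tidy(pf2)
  expect_equal(td$relative_b, td$b_factor / pf2$chain_mean)
})
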