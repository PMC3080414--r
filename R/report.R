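#' Discover ligand residues in a model
#'
#' Chemical-component naming for the same ligand drifts across depositions
#' (cGMP has appeared as PCG, CGP, 35G, ...), so rather than hard-coding
#' codes, ligands are discovered at read time: every non-water hetero residue
#' whose name is in `ligand_names` (or, when `NULL`, every non-water hetero
#' residue with at least `min_atoms` atoms) is reported, and the discovered
#' names are logged.
#'
#' @param model A [structure_model()].
#' @param ligand_names Optional character vector restricting residue names.
#' @param min_atoms Minimum atom count for auto-discovery (default 4, which
#'   keeps phosphate ions but drops monoatomic ions).
#' @return A tibble: `chain`, `res_seq`, `i_code`, `res_name`, `n_atoms`.
#' @export
discover_ligands <- function(model, ligand_names = NULL, min_atoms = 4) {
  stopifnot(inherits(model, "structure_model"))
  het <- collapse_alt_locs(model)$atoms |>
    filter(.data$is_hetero, !.data$res_name %in% c("HOH", "WAT", "DOD")) |>
    group_by(.data$chain, .data$res_seq, .data$i_code, .data$res_name) |>
    summarise(n_atoms = n(), .groups = "drop")
  out <- if (is.null(ligand_names)) {
    filter(het, .data$n_atoms >= min_atoms)
  } else {
    filter(het, .data$res_name %in% toupper(ligand_names))
  }
  if (nrow(out) > 0) {
    inform(paste0(
      "ligand residue name(s) present: ",
      paste(sort(unique(out$res_name)), collapse = ", ")
    ))
  }
  arrange(out, .data$chain, .data$res_seq)
}

#' Contact report for every ligand in a structure
#'
#' Runs [find_contacts()] for each (discovered or named) ligand, classifies
#' its glycosidic conformation when the glycosidic quadruple is present, and
#' counts inter-molecule hydrogen bonds (ligand to protein chains other than
#' its own).  Optionally writes one TSV per ligand plus a JSON summary.
#'
#' @param structure A [structure_model()] or a coordinate file path.
#' @param ligand_names Optional residue-name restriction (see
#'   [discover_ligands()]).
#' @param hbond_cutoff,vdw_cutoff Classification cutoffs in Angstrom.
#' @param output_dir Optional directory for TSV/JSON report files.
#' @return A list of class `contact_report`: `ligands` (tibble with one row
#'   per ligand: identity, conformation, contact counts, inter-molecule
#'   hydrogen-bond count) and `contacts` (named list of contact tibbles).
#' @export
run_contacts <- function(structure, ligand_names = NULL, hbond_cutoff = 3.5,
                         vdw_cutoff = 4.0, output_dir = NULL) {
  model <- as_structure(structure)
  ligs <- discover_ligands(model, ligand_names)
  if (nrow(ligs) == 0) {
    abort("no ligand residues found in model", class = "cnbdkit_lookup_error")
  }
  contacts <- list()
  rows <- list()
  for (k in seq_len(nrow(ligs))) {
    lg <- ligs[k, ]
    key <- sprintf("%s_%s_%d", lg$res_name, lg$chain, lg$res_seq)
    ct <- find_contacts(
      model, lg$chain, lg$res_seq,
      hbond_cutoff = hbond_cutoff, vdw_cutoff = vdw_cutoff
    )
    conf <- tryCatch(
      glycosidic_chi(model, chain = lg$chain, res_seq = lg$res_seq)$classification,
      error = function(e) NA_character_
    )
    inter_hb <- ct |>
      filter(.data$contact_class == "hydrogen_bond", .data$chain != lg$chain)
    contacts[[key]] <- ct
    rows[[k]] <- tibble(
      ligand = key, res_name = lg$res_name, chain = lg$chain,
      res_seq = lg$res_seq, conformation = conf,
      n_contacts = nrow(ct),
      n_hbonds = sum(ct$contact_class == "hydrogen_bond"),
      n_intermolecular_hbonds = nrow(inter_hb)
    )
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_tsv(ct, file.path(output_dir, paste0("contacts_", key, ".tsv")))
    }
  }
  out <- structure(
    list(ligands = bind_rows(rows), contacts = contacts),
    class = "contact_report"
  )
  if (!is.null(output_dir)) {
    jsonlite::write_json(
      list(
        source = model$source_id,
        cutoffs = list(hbond = hbond_cutoff, vdw = vdw_cutoff),
        ligands = out$ligands
      ),
      file.path(output_dir, "contacts_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

#' @export
print.contact_report <- function(x, ...) {
  cat("<contact_report>\n")
  print(x$ligands)
  invisible(x)
}

#' Pocket distance table in the published row convention
#'
#' Condenses a contact table to one row per (protein atom, ligand atom) pair
#' restricted to the cyclic-nucleotide pocket residues, using the row
#' convention of published protein-ligand distance tables for this domain:
#' leucine CD1/CD2 contacts are reported as the minimum over the pair under
#' the synthetic key `CD(min)`.
#'
#' @param contacts A contact tibble from [find_contacts()].
#' @return A tibble: `res_seq`, `res_name`, `atom`, `ligand_atom`,
#'   `distance`, `contact_class`, `site_label`.
#' @export
pocket_distance_table <- function(contacts) {
  pocket <- contacts |>
    filter(.data$site_label != "none") |>
    mutate(atom = ifelse(
      .data$res_name == "LEU" & .data$atom %in% c("CD1", "CD2"),
      "CD(min)", .data$atom
    )) |>
    group_by(
      .data$res_seq, .data$res_name, .data$atom, .data$ligand_atom,
      .data$contact_class, .data$site_label
    ) |>
    summarise(distance = min(.data$distance), .groups = "drop") |>
    arrange(.data$res_seq, .data$atom, .data$distance)
  select(
    pocket, "res_seq", "res_name", "atom", "ligand_atom", "distance",
    "contact_class", "site_label"
  )
}

#' Superposition report for two chains
#'
#' Thin wrapper around [align_with_rejection()] that accepts file paths or
#' models and returns a JSON-ready report (and optionally writes it, plus the
#' superposed moving chain as PDB).
#'
#' @param structure_a,structure_b [structure_model()]s or file paths.
#' @param chain_a,chain_b Chain identifiers.
#' @inheritParams align_with_rejection
#' @param output_dir Optional directory for `superpose.json` (and
#'   `superposed.pdb`).
#' @param write_coords Also write the superposed coordinates (default FALSE).
#' @return The `superposition_result`, with the report list in attribute
#'   `report`.
#' @export
run_superpose <- function(structure_a, chain_a, structure_b, chain_b,
                          mode = c("by_number", "by_alignment"),
                          max_cycles = 5, reject_cutoff = 2.0,
                          output_dir = NULL, write_coords = FALSE) {
  mode <- match.arg(mode)
  model_a <- as_structure(structure_a)
  model_b <- as_structure(structure_b)
  fit <- align_with_rejection(
    model_a, chain_a, model_b, chain_b,
    mode = mode, max_cycles = max_cycles, reject_cutoff = reject_cutoff
  )
  report <- list(
    source_a = model_a$source_id, chain_a = chain_a,
    source_b = model_b$source_id, chain_b = chain_b,
    mode = mode, reject_cutoff = reject_cutoff,
    rmsd = fit$rmsd, n_matched = fit$n_matched,
    cycles_run = fit$cycles_run,
    rotation = fit$rotation, translation = fit$translation,
    rejected = fit$rejected
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(output_dir, "superpose.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    if (write_coords) {
      moved <- model_b
      xyz <- apply_superposition(
        fit, as.matrix(moved$atoms[, c("x", "y", "z")])
      )
      moved$atoms$x <- xyz[, 1]
      moved$atoms$y <- xyz[, 2]
      moved$atoms$z <- xyz[, 3]
      write_structure(moved, file.path(output_dir, "superposed.pdb"))
    }
  }
  attr(fit, "report") <- report
  fit
}

#' One-site ITC fit report
#'
#' Fits the one-site model to a titration (a `titration_curve`, or a
#' delimited text file read with [read_titration()]) and returns a
#' JSON-ready report with the fitted parameters, derived thermodynamics,
#' Wiseman c value and convergence flag; optionally writes the report and an
#' observed-versus-fitted TSV.
#'
#' @param titration A `titration_curve` or a file path.
#' @param design A [titration_design()] (required for file input).
#' @inheritParams fit_one_site
#' @param output_dir Optional directory for `itc_fit.json` and
#'   `itc_fit.tsv`.
#' @return The `itc_fit` object, with the report list in attribute `report`.
#' @export
run_itc <- function(titration, design = NULL, init = NULL,
                    discard_first = FALSE, output_dir = NULL) {
  curve <- if (is.character(titration)) {
    read_titration(titration, design = design)
  } else {
    titration
  }
  fit <- fit_one_site(curve,
    design = design, init = init,
    discard_first = discard_first
  )
  report <- list(
    n = fit$params$n, n_se = fit$n_se,
    ka = fit$params$ka, ka_se = fit$ka_se, kd = fit$kd,
    dh_cal_mol = fit$params$dh, dh_se = fit$dh_se,
    dg_cal_mol = fit$dg, ds_cal_mol_k = fit$ds,
    temperature_k = fit$design$temperature,
    c_value = fit$c_value, converged = fit$converged,
    residual_norm_ucal = fit$residual_norm
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(output_dir, "itc_fit.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    readr::write_tsv(fit$fitted, file.path(output_dir, "itc_fit.tsv"))
  }
  attr(fit, "report") <- report
  fit
}

as_structure <- function(x) {
  if (inherits(x, "structure_model")) {
    return(x)
  }
  if (is.character(x) && length(x) == 1) {
    return(read_structure(x))
  }
  abort("expected a structure_model or a coordinate file path",
    class = "cnbdkit_usage_error"
  )
}

#' Published reference protein-ligand distances
#'
#' The protein-ligand distance table published alongside the deposited
#' PKG I-beta CNBD-A structures (cGMP complex, syn- and anti-cAMP complex,
#' partial-apo cAMP and phosphate sites), shipped as plain TSV.  Distances
#' are in Angstrom; the `flagged` column marks the one published cell whose
#' ligand-atom label is inconsistent with phosphate chemistry and should be
#' compared against coordinates rather than taken at face value.
#'
#' @return A tibble: `complex`, `res_seq`, `res_name`, `atom`, `ligand_atom`,
#'   `distance`, `contact_class`, `flagged`.
#' @export
reference_contact_distances <- function() {
  path <- system.file("extdata", "reference_ligand_distances.tsv",
    package = "cnbdkit"
  )
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Locate a deposited coordinate file
#'
#' Deposited crystallographic entries are not shipped with the package; this
#' helper finds them when the user has placed them under
#' `inst/extdata/deposited/` (before install) or in the directory named by
#' `options(cnbdkit.deposited_dir = ...)`.
#'
#' @param accession 4-character accession (case-insensitive).
#' @return The file path, or `NA_character_` when not available.
#' @export
deposited_structure_path <- function(accession) {
  acc <- tolower(accession)
  candidates <- c(
    file.path(
      getOption("cnbdkit.deposited_dir", ""),
      paste0(acc, c(".pdb", ".cif", ".ent"))
    ),
    system.file("extdata", "deposited", paste0(acc, ".pdb"), package = "cnbdkit"),
    system.file("extdata", "deposited", paste0(acc, ".cif"), package = "cnbdkit")
  )
  hit <- candidates[nzchar(candidates) & file.exists(candidates)]
  if (length(hit) == 0) {
    return(NA_character_)
  }
  hit[[1]]
}
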