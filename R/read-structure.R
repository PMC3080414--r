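#' Read a coordinate file into a structure model
#'
#' Parses PDB or mmCIF coordinates (via \pkg{bio3d}) into a tidy
#' [structure_model()].  All ATOM and HETATM records are kept, including
#' alternate locations; crystal metadata (CRYST1 record or `_cell`/`_symmetry`
#' items) is attached when present.  Atom names are normalized with
#' [normalize_atom_name()] so deposition dialects (`O2*` vs `O2'`) compare
#' equal downstream.
#'
#' @param source Path to a coordinate file, or a character vector holding the
#'   file's text (anything containing a newline, or of length > 1, is treated
#'   as text).
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (default).  Auto-detection uses
#'   the file extension, falling back to content sniffing (`data_` block
#'   header means mmCIF).
#' @return A [structure_model()].
#' @export
#' @examples
#' path <- tempfile(fileext = ".pdb")
#' write_structure(build_dipeptide(omega = 0), path)
#' read_structure(path)
read_structure <- function(source, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  path <- source
  if (length(source) > 1 || any(grepl("\n", source, fixed = TRUE))) {
    path <- tempfile(fileext = ".coords")
    writeLines(unlist(strsplit(source, "\n", fixed = TRUE)), path)
    on.exit(unlink(path), add = TRUE)
  }
  if (!file.exists(path)) {
    abort(paste0("cannot read coordinate file: ", path), class = "cnbdkit_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- guess_coord_format(path, lines)
  }
  switch(format,
    pdb = read_structure_pdb(path, lines),
    mmcif = read_structure_mmcif(path, lines),
    abort(paste0("unknown coordinate format: ", format), class = "cnbdkit_usage_error")
  )
}

guess_coord_format <- function(path, lines) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) {
    return("mmcif")
  }
  if (ext %in% c("pdb", "ent")) {
    return("pdb")
  }
  head_lines <- lines[nzchar(trimws(lines))]
  if (length(head_lines) > 0 && grepl("^data_", head_lines[[1]])) {
    return("mmcif")
  }
  "pdb"
}

read_structure_pdb <- function(path, lines) {
  coord_idx <- grep("^(ATOM  |HETATM)", lines)
  # Validate the fixed-width numeric fields up front so a malformed line is
  # reported by number instead of surfacing as a cryptic downstream NA.
  for (i in coord_idx) {
    ln <- lines[[i]]
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(xyz))) {
      abort(
        sprintf("malformed coordinate fields on line %d of %s", i, path),
        class = "cnbdkit_parse_error"
      )
    }
  }
  if (length(coord_idx) == 0) {
    return(structure_model(
      empty_atom_table(),
      crystal = parse_cryst1(lines),
      source_id = basename(path)
    ))
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) {
      abort(
        paste0("failed to parse PDB file ", path, ": ", conditionMessage(e)),
        class = "cnbdkit_parse_error"
      )
    }
  )
  structure_model(
    atom_table_from_bio3d(pdb$atom),
    crystal = parse_cryst1(lines),
    source_id = basename(path)
  )
}

read_structure_mmcif <- function(path, lines) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) {
      abort(
        paste0("failed to parse mmCIF file ", path, ": ", conditionMessage(e)),
        class = "cnbdkit_parse_error"
      )
    }
  )
  structure_model(
    atom_table_from_bio3d(pdb$atom),
    crystal = parse_cif_cell(lines),
    source_id = basename(path)
  )
}

empty_atom_table <- function() {
  tibble(
    serial = integer(), atom = character(), alt_loc = character(),
    res_name = character(), chain = character(), res_seq = integer(),
    i_code = character(), x = double(), y = double(), z = double(),
    occupancy = double(), b_factor = double(), element = character(),
    is_hetero = logical()
  )
}

atom_table_from_bio3d <- function(at) {
  blank <- function(v) ifelse(is.na(v), "", trimws(v))
  element <- blank(at$elesy)
  no_elem <- !nzchar(element)
  if (any(no_elem)) {
    element[no_elem] <- guess_element(at$elety[no_elem])
  }
  tibble(
    serial = as.integer(at$eleno),
    atom = normalize_atom_name(at$elety),
    alt_loc = blank(at$alt),
    res_name = toupper(trimws(at$resid)),
    chain = blank(at$chain),
    res_seq = as.integer(at$resno),
    i_code = blank(at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    element = toupper(element),
    is_hetero = at$type == "HETATM"
  )
}

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", toupper(trimws(atom_name)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA2"), two, one)
}

parse_cryst1 <- function(lines) {
  idx <- grep("^CRYST1", lines)
  if (length(idx) == 0) {
    return(NULL)
  }
  ln <- lines[[idx[1]]]
  num <- function(from, to) suppressWarnings(as.numeric(substr(ln, from, to)))
  a <- num(7, 15); b <- num(16, 24); cc <- num(25, 33)
  alpha <- num(34, 40); beta <- num(41, 47); gamma <- num(48, 54)
  sg <- trimws(substr(ln, 56, 66))
  if (any(is.na(c(a, b, cc, alpha, beta, gamma))) || a <= 0) {
    return(NULL)
  }
  # A 1 A placeholder cell is the PDB convention for "no crystal".
  if (a == 1 && b == 1 && cc == 1) {
    return(NULL)
  }
  mult <- tryCatch(space_group_multiplicity(sg), error = function(e) NA_integer_)
  if (is.na(mult)) {
    warn(paste0("unknown space group '", sg, "'; crystal metadata dropped"))
    return(NULL)
  }
  crystal_info(a, b, cc, alpha, beta, gamma, space_group = sg)
}

parse_cif_cell <- function(lines) {
  item <- function(tag) {
    hit <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(hit) == 0) {
      return(NA)
    }
    val <- trimws(sub(paste0("^", tag, "\\s+"), "", hit[[1]]))
    gsub("^['\"]|['\"]$", "", sub("\\(\\d+\\)$", "", val))
  }
  a <- suppressWarnings(as.numeric(item("_cell\\.length_a")))
  b <- suppressWarnings(as.numeric(item("_cell\\.length_b")))
  cc <- suppressWarnings(as.numeric(item("_cell\\.length_c")))
  alpha <- suppressWarnings(as.numeric(item("_cell\\.angle_alpha")))
  beta <- suppressWarnings(as.numeric(item("_cell\\.angle_beta")))
  gamma <- suppressWarnings(as.numeric(item("_cell\\.angle_gamma")))
  sg <- item("_symmetry\\.space_group_name_H-M")
  if (any(is.na(c(a, b, cc, alpha, beta, gamma))) || is.na(sg)) {
    return(NULL)
  }
  mult <- tryCatch(space_group_multiplicity(sg), error = function(e) NA_integer_)
  if (is.na(mult)) {
    warn(paste0("unknown space group '", sg, "'; crystal metadata dropped"))
    return(NULL)
  }
  crystal_info(a, b, cc, alpha, beta, gamma, space_group = sg)
}

#' Write a structure model as a PDB file
#'
#' Emits single-model PDB text (ATOM/HETATM records, plus a CRYST1 record when
#' crystal metadata is present).  Coordinates are written at the format's
#' native 0.001-Angstrom precision, so a write/read round trip reproduces them
#' to that precision.
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  lines <- character(0)
  if (!is.null(model$crystal)) {
    cr <- model$crystal
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cr$a, cr$b, cr$c, cr$alpha, cr$beta, cr$gamma, cr$space_group,
      cr$asu_multiplicity
    ))
  }
  if (nrow(at) > 0) {
    # PDB atom-name column convention: names shorter than 4 characters start
    # in column 14 unless the element symbol is two letters.
    fmt_name <- function(nm, el) {
      ifelse(nchar(nm) >= 4 | nchar(el) == 2, sprintf("%-4s", nm),
        sprintf(" %-3s", nm)
      )
    }
    rec <- ifelse(at$is_hetero, "HETATM", "ATOM  ")
    lines <- c(lines, sprintf(
      "%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, at$serial %% 100000L, fmt_name(at$atom, at$element),
      substr(paste0(at$alt_loc, " "), 1, 1), at$res_name,
      substr(paste0(at$chain, " "), 1, 1), at$res_seq,
      substr(paste0(at$i_code, " "), 1, 1),
      at$x, at$y, at$z, at$occupancy, at$b_factor, at$element
    ))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Select atoms from a structure model
#'
#' Filters the atom table on any combination of chain, residue number, residue
#' name, atom name and hetero flag.  Criteria left `NULL` do not constrain the
#' selection; with no criteria at all, every atom is returned.  Atom and
#' residue names are compared after [normalize_atom_name()] / upper-casing, so
#' `"og1"` and `"O2*"` match their deposited spellings.  A contradictory
#' selection yields an empty table, not an error.
#'
#' @param model A [structure_model()].
#' @param chain,res_seq,res_name,atom Optional vectors of admissible values.
#' @param hetero Optional logical: `TRUE` restricts to HETATM records, `FALSE`
#'   to ATOM records.
#' @return A tibble of matching atom rows, in model order.
#' @export
#' @examples
#' m <- build_dipeptide(omega = 180)
#' select_atoms(m, atom = "CA")
select_atoms <- function(model, chain = NULL, res_seq = NULL, res_name = NULL,
                         atom = NULL, hetero = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (!is.null(chain)) {
    at <- filter(at, .data$chain %in% !!chain)
  }
  if (!is.null(res_seq)) {
    at <- filter(at, .data$res_seq %in% !!res_seq)
  }
  if (!is.null(res_name)) {
    at <- filter(at, .data$res_name %in% toupper(!!res_name))
  }
  if (!is.null(atom)) {
    at <- filter(at, .data$atom %in% normalize_atom_name(!!atom))
  }
  if (!is.null(hetero)) {
    at <- filter(at, .data$is_hetero == !!hetero)
  }
  at
}
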