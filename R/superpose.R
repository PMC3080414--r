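#' Pair equivalent residues between two chains
#'
#' Builds the residue correspondence used for superposition.  `by_number`
#' intersects author-assigned residue numbers that carry a C-alpha atom in
#' both chains (the right choice when both chains are the same construct).
#' `by_alignment` derives pairs from a global sequence alignment
#' (Needleman-Wunsch via \pkg{Biostrings}), so chains with offset numbering
#' still pair correctly; for identical sequences it reduces to `by_number`.
#'
#' @param model_a,model_b [structure_model()]s.
#' @param chain_a,chain_b Chain identifiers.
#' @param mode `"by_number"` (default) or `"by_alignment"`.
#' @return A tibble of class `residue_pairing`: `res_seq_a`, `res_seq_b`, plus
#'   attribute `mode`.
#' @export
pair_residues <- function(model_a, chain_a, model_b, chain_b,
                          mode = c("by_number", "by_alignment")) {
  mode <- match.arg(mode)
  ca_a <- chain_calpha(model_a, chain_a)
  ca_b <- chain_calpha(model_b, chain_b)
  if (nrow(ca_a) == 0 || nrow(ca_b) == 0) {
    abort("both chains must contain C-alpha atoms", class = "cnbdkit_pairing_error")
  }
  if (mode == "by_number") {
    common <- intersect(ca_a$res_seq, ca_b$res_seq)
    pairs <- tibble(res_seq_a = sort(common), res_seq_b = sort(common))
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("by_alignment pairing needs the Biostrings package")
    }
    seq_a <- paste(bio3d::aa321(ca_a$res_name), collapse = "")
    seq_b <- paste(bio3d::aa321(ca_b$res_name), collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      seq_a, seq_b,
      type = "global",
      substitutionMatrix = NULL, gapOpening = 10, gapExtension = 0.5
    )
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ia <- 0L
    ib <- 0L
    ra <- integer(0)
    rb <- integer(0)
    for (k in seq_along(pa)) {
      if (pa[k] != "-") ia <- ia + 1L
      if (pb[k] != "-") ib <- ib + 1L
      if (pa[k] != "-" && pb[k] != "-") {
        ra <- c(ra, ca_a$res_seq[ia])
        rb <- c(rb, ca_b$res_seq[ib])
      }
    }
    pairs <- tibble(res_seq_a = ra, res_seq_b = rb)
  }
  if (nrow(pairs) == 0) {
    abort("no equivalent residues between the two chains",
      class = "cnbdkit_pairing_error"
    )
  }
  attr(pairs, "mode") <- mode
  class(pairs) <- c("residue_pairing", class(pairs))
  pairs
}

# C-alpha atoms of a protein chain, one per residue (first insertion kept),
# in residue order.
chain_calpha <- function(model, chain) {
  stopifnot(inherits(model, "structure_model"))
  collapse_alt_locs(model)$atoms |>
    filter(!.data$is_hetero, .data$chain == !!chain, .data$atom == "CA") |>
    arrange(.data$res_seq, .data$i_code) |>
    distinct(.data$res_seq, .keep_all = TRUE)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation `R` (proper, `det(R) = +1`) and translation `t`
#' minimizing the RMSD of `coords_b` onto `coords_a` over rigid motions, via
#' the SVD of the covariance matrix with determinant correction.  The
#' transform maps a point `x` of B to `R x + t`.
#'
#' @param coords_a,coords_b Numeric matrices (n x 3), n >= 3, equal rows;
#'   row i of A corresponds to row i of B.
#' @return An object of class `superposition_result`: list with `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd`, `n_matched`, `cycles_run` (0
#'   for a single pass) and `rejected` (empty tibble).
#' @export
kabsch_fit <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (ncol(coords_a) != 3 || ncol(coords_b) != 3 ||
    nrow(coords_a) != nrow(coords_b)) {
    abort("coordinate sets must be equal-length n x 3 matrices",
      class = "cnbdkit_domain_error"
    )
  }
  if (nrow(coords_a) < 3) {
    abort("at least 3 point pairs are required",
      class = "cnbdkit_degenerate_error"
    )
  }
  cen_a <- colMeans(coords_a)
  cen_b <- colMeans(coords_b)
  a0 <- sweep(coords_a, 2, cen_a)
  b0 <- sweep(coords_b, 2, cen_b)
  h <- t(b0) %*% a0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cen_a - rot %*% cen_b)
  moved <- b0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((a0 - moved)^2)))
  new_superposition_result(rot, trans, rmsd,
    n_matched = nrow(coords_a), cycles_run = 0L,
    rejected = empty_rejected_table()
  )
}

new_superposition_result <- function(rotation, translation, rmsd, n_matched,
                                     cycles_run, rejected) {
  structure(
    list(
      rotation = rotation, translation = translation, rmsd = rmsd,
      n_matched = as.integer(n_matched), cycles_run = as.integer(cycles_run),
      rejected = rejected
    ),
    class = "superposition_result"
  )
}

empty_rejected_table <- function() {
  tibble(res_seq_a = integer(), res_seq_b = integer(), deviation = double())
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(
    "<superposition_result> rmsd %.3f A over %d pairs (%d rejection cycle(s), %d pair(s) rejected)\n",
    x$rmsd, x$n_matched, x$cycles_run, nrow(x$rejected)
  ))
  invisible(x)
}

#' @rdname kabsch_fit
#' @param x,object A `superposition_result`.
#' @param ... Unused.
#' @method glance superposition_result
#' @export
glance.superposition_result <- function(x, ...) {
  tibble(
    rmsd = x$rmsd, n_matched = x$n_matched, cycles_run = x$cycles_run,
    n_rejected = nrow(x$rejected)
  )
}

#' Apply a fitted superposition to coordinates
#'
#' @param fit A `superposition_result`.
#' @param coords An n x 3 matrix of points in the moving (B) frame.
#' @return The transformed n x 3 matrix.
#' @export
apply_superposition <- function(fit, coords) {
  stopifnot(inherits(fit, "superposition_result"))
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Superpose two chains with iterative outlier rejection
#'
#' Pairs equivalent C-alpha atoms ([pair_residues()]), fits by [kabsch_fit()],
#' drops every pair whose post-fit deviation exceeds `reject_cutoff`, and
#' refits, until no pair is dropped or `max_cycles` is reached.  This emulates
#' the outlier-rejecting alignments behind "equivalent N C-alpha atoms"
#' counts printed for crystal-form comparisons.  The RMSD is non-increasing
#' across cycles.
#'
#' @inheritParams pair_residues
#' @param max_cycles Maximum rejection cycles (default 5).
#' @param reject_cutoff Post-fit deviation cutoff in Angstrom (default 2.0);
#'   `Inf` reduces to a single plain fit on the full pairing.
#' @return A `superposition_result`; `rejected` lists the dropped pairs with
#'   the deviation at which each was dropped.
#' @export
align_with_rejection <- function(model_a, chain_a, model_b, chain_b,
                                 mode = c("by_number", "by_alignment"),
                                 max_cycles = 5, reject_cutoff = 2.0) {
  mode <- match.arg(mode)
  pairing <- pair_residues(model_a, chain_a, model_b, chain_b, mode = mode)
  ca_a <- chain_calpha(model_a, chain_a)
  ca_b <- chain_calpha(model_b, chain_b)
  xa <- as.matrix(ca_a[match(pairing$res_seq_a, ca_a$res_seq), c("x", "y", "z")])
  xb <- as.matrix(ca_b[match(pairing$res_seq_b, ca_b$res_seq), c("x", "y", "z")])
  keep <- rep(TRUE, nrow(pairing))
  rejected <- empty_rejected_table()
  fit <- NULL
  cycles <- 0L
  repeat {
    if (sum(keep) < 3) {
      abort("outlier rejection removed (almost) every pair",
        class = "cnbdkit_rejection_collapse_error"
      )
    }
    fit <- kabsch_fit(xa[keep, , drop = FALSE], xb[keep, , drop = FALSE])
    dev <- sqrt(rowSums((xa - apply_superposition(fit, xb))^2))
    drop_now <- keep & dev > reject_cutoff
    if (!any(drop_now) || cycles >= max_cycles) break
    rejected <- bind_rows(rejected, tibble(
      res_seq_a = pairing$res_seq_a[drop_now],
      res_seq_b = pairing$res_seq_b[drop_now],
      deviation = dev[drop_now]
    ))
    keep <- keep & !drop_now
    cycles <- cycles + 1L
  }
  new_superposition_result(
    fit$rotation, fit$translation, fit$rmsd,
    n_matched = sum(keep), cycles_run = cycles, rejected = rejected
  )
}
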