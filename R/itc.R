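#' Gas constant in cal/(mol K)
#' @export
R_CAL <- 1.987

#' Titration design for an ITC experiment
#'
#' Describes the experimental design of a single-cell isothermal titration
#' calorimetry run: macromolecule in the cell, ligand in the syringe,
#' injection schedule and temperature.  Defaults reproduce a typical VP-ITC
#' configuration for a high-affinity cyclic-nucleotide binder: 15 uM
#' macromolecule in a 1.43 mL cell, 250 uM ligand delivered as 28 injections
#' of 5 uL at 30 C (final molar ratio about 1.65).
#'
#' @param cell_concentration Macromolecule concentration in the cell (mol/L).
#' @param syringe_concentration Ligand concentration in the syringe (mol/L).
#' @param cell_volume Active cell volume V0 (L).
#' @param injection_volumes Ordered injection volumes (L); at least 2.
#' @param temperature Temperature (K).
#' @return A list of class `titration_design`.
#' @export
#' @examples
#' titration_design()
titration_design <- function(cell_concentration = 15e-6,
                             syringe_concentration = 250e-6,
                             cell_volume = 1.43e-3,
                             injection_volumes = rep(5e-6, 28),
                             temperature = 303.15) {
  vals <- c(
    cell_concentration, syringe_concentration, cell_volume,
    injection_volumes, temperature
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all design quantities must be positive and finite",
      class = "cnbdkit_domain_error"
    )
  }
  if (length(injection_volumes) < 2) {
    abort("at least two injections are required", class = "cnbdkit_domain_error")
  }
  structure(
    list(
      cell_concentration = cell_concentration,
      syringe_concentration = syringe_concentration,
      cell_volume = cell_volume,
      injection_volumes = injection_volumes,
      temperature = temperature
    ),
    class = "titration_design"
  )
}

#' One-site binding parameters
#'
#' @param n Binding sites per macromolecule (dimensionless, > 0).
#' @param ka Association constant (1/(mol/L), > 0).
#' @param dh Binding enthalpy (cal/mol).
#' @return A list of class `one_site_params`.  `kd` (= 1/`ka`) is included
#'   for convenience.
#' @export
#' @examples
#' one_site_params(n = 1, ka = 1 / 12e-9, dh = -12500)
one_site_params <- function(n, ka, dh) {
  if (!is.finite(n) || n <= 0 || !is.finite(ka) || ka <= 0 || !is.finite(dh)) {
    abort("need n > 0, ka > 0 and finite dh", class = "cnbdkit_domain_error")
  }
  structure(
    list(n = n, ka = ka, dh = dh, kd = 1 / ka),
    class = "one_site_params"
  )
}

# Total concentrations in the cell after cumulative injected volume v,
# under the standard perfusion (displacement) dilution rule of a
# constant-volume cell.
itc_totals <- function(design, cum_volume) {
  v0 <- design$cell_volume
  f <- cum_volume / v0
  list(
    m_tot = design$cell_concentration * (1 - f / 2) / (1 + f / 2),
    x_tot = design$syringe_concentration * f / (1 + f / 2)
  )
}

# Cumulative heat content of the cell (cal) at total concentrations m, x.
one_site_q <- function(n, ka, dh, m_tot, x_tot, v0) {
  r <- x_tot / (n * m_tot)
  inv_c <- 1 / (n * ka * m_tot)
  disc <- (1 + r + inv_c)^2 - 4 * r
  if (any(disc < 0)) {
    abort("negative discriminant in one-site model",
      class = "cnbdkit_domain_error"
    )
  }
  (n * m_tot * dh * v0 / 2) * (1 + r + inv_c - sqrt(disc))
}

#' Simulate a one-site ITC titration (Wiseman isotherm)
#'
#' Forward model of a single-site titration.  After injection i the total
#' cell heat content is
#' \deqn{Q_i = \frac{n M_i \Delta H V_0}{2}\left[1 + \frac{X_i}{n M_i} +
#'   \frac{1}{n K_a M_i} - \sqrt{\left(1 + \frac{X_i}{n M_i} +
#'   \frac{1}{n K_a M_i}\right)^2 - \frac{4 X_i}{n M_i}}\right]}
#' with total concentrations \eqn{M_i, X_i} following the constant-volume
#' displacement-dilution rule, and the measured heat of injection i is
#' \deqn{q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2},}
#' the trapezoidal correction accounting for liquid displaced into the
#' inactive tube.
#'
#' @param params A [one_site_params()].
#' @param design A [titration_design()].
#' @return A tibble of class `titration_curve`, one row per injection:
#'   `injection`, `injection_volume` (L), `molar_ratio` (X_t/M_t),
#'   `heat_ucal` (ucal) and `ndh_kcal_mol` (kcal per mol of injectant), with
#'   the design stored in attribute `design`.
#' @export
#' @examples
#' curve <- simulate_titration(
#'   one_site_params(n = 1, ka = 1 / 12e-9, dh = -12500),
#'   titration_design()
#' )
#' head(curve)
simulate_titration <- function(params, design) {
  stopifnot(inherits(params, "one_site_params"), inherits(design, "titration_design"))
  heats <- one_site_heats(
    c(params$n, log(params$ka), params$dh), design
  )
  cum_v <- cumsum(design$injection_volumes)
  totals <- itc_totals(design, cum_v)
  out <- tibble(
    injection = seq_along(design$injection_volumes),
    injection_volume = design$injection_volumes,
    molar_ratio = totals$x_tot / totals$m_tot,
    heat_ucal = heats * 1e6,
    ndh_kcal_mol = heats /
      (design$syringe_concentration * design$injection_volumes) / 1000
  )
  attr(out, "design") <- design
  class(out) <- c("titration_curve", class(out))
  out
}

# Injection heats (cal) for parameter vector theta = (n, log_ka, dh).
one_site_heats <- function(theta, design) {
  n <- theta[1]
  ka <- exp(theta[2])
  dh <- theta[3]
  v0 <- design$cell_volume
  cum_v <- cumsum(design$injection_volumes)
  totals <- itc_totals(design, cum_v)
  q <- one_site_q(n, ka, dh, totals$m_tot, totals$x_tot, v0)
  q_prev <- c(0, q[-length(q)])
  q - q_prev + (design$injection_volumes / v0) * (q + q_prev) / 2
}

#' Derived binding thermodynamics
#'
#' From an association constant and enthalpy: `kd = 1/ka`,
#' `dg = -R T log(ka)` with R = 1.987 cal/(mol K), and `ds = (dh - dg)/T`.
#'
#' @param ka Association constant (1/(mol/L)).
#' @param dh Binding enthalpy (cal/mol).
#' @param temperature Temperature (K).
#' @return A one-row tibble: `kd` (mol/L), `dg` (cal/mol), `ds`
#'   (cal/(mol K)).
#' @export
#' @examples
#' derive_thermo(ka = 1 / 12e-9, dh = -12500, temperature = 303.15)
derive_thermo <- function(ka, dh, temperature) {
  if (!is.finite(ka) || ka <= 0 || !is.finite(temperature) || temperature <= 0) {
    abort("need ka > 0 and temperature > 0", class = "cnbdkit_domain_error")
  }
  dg <- -R_CAL * temperature * log(ka)
  tibble(kd = 1 / ka, dg = dg, ds = (dh - dg) / temperature)
}

#' Fit the one-site model to a titration curve
#'
#' Damped (Levenberg-Marquardt) least squares on the per-injection heats over
#' `(n, log Ka, dH)`, via \pkg{minpack.lm}.  The automatic initializer is
#' deterministic: `n = 1`, `dH` from the first-injection normalized heat, and
#' `Ka` from the steepness of the isotherm around the equivalence point, so
#' identical inputs give identical fits.  Non-convergence is reported through
#' the `converged` flag rather than an error.
#'
#' The Wiseman `c` value (`n Ka M_t0`) is reported prominently: for `c`
#' far above ~1000 the isotherm approaches a step and `Ka` is only weakly
#' determined by the data, which shows up as a large relative `ka_se`.
#'
#' @param curve A `titration_curve` (from [simulate_titration()],
#'   [noisy_titration()] or [read_titration()]), or any data frame with a
#'   `heat_ucal` column matching the design's injections.
#' @param design A [titration_design()]; taken from the curve's attribute
#'   when `NULL`.
#' @param init Optional [one_site_params()] starting point.
#' @param discard_first Drop the first injection from the fit (conventional
#'   when the first injection is unreliable); default `FALSE`.
#' @return An object of class `itc_fit`: list with `params`
#'   ([one_site_params()]), standard errors (`n_se`, `ka_se`, `dh_se`),
#'   derived `kd`, `dg`, `ds` (via [derive_thermo()]), `c_value`,
#'   `residual_norm` (ucal), `converged`, `fitted` (tibble of observed vs
#'   fitted heats) and the `design`.
#' @export
#' @examples
#' truth <- one_site_params(n = 1, ka = 1 / 12e-9, dh = -12500)
#' fit <- fit_one_site(simulate_titration(truth, titration_design()))
#' glance(fit)
fit_one_site <- function(curve, design = NULL, init = NULL,
                         discard_first = FALSE) {
  design <- design %||% attr(curve, "design")
  if (is.null(design)) {
    abort("no titration_design supplied or attached to the curve",
      class = "cnbdkit_domain_error"
    )
  }
  obs_ucal <- curve$heat_ucal
  n_inj <- length(design$injection_volumes)
  if (length(obs_ucal) != n_inj) {
    abort("curve and design disagree on the number of injections",
      class = "cnbdkit_domain_error"
    )
  }
  use <- rep(TRUE, n_inj)
  if (discard_first) use[1] <- FALSE
  if (sum(use) < 4) {
    abort("fewer usable injections than free parameters",
      class = "cnbdkit_fit_error"
    )
  }
  if (is.null(init)) {
    init <- auto_init_one_site(obs_ucal, design)
  }
  theta0 <- c(init$n, log(init$ka), init$dh)
  resid_fn <- function(theta) {
    th <- theta
    th[1] <- abs(th[1]) # n > 0 without a hard constraint
    model <- one_site_heats(th, design) * 1e6
    (model - obs_ucal)[use]
  }
  lm_fit <- minpack.lm::nls.lm(
    par = theta0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-14, ptol = 1e-14
    )
  )
  theta <- lm_fit$par
  theta[1] <- abs(theta[1])
  converged <- lm_fit$info %in% 1:4
  # standard errors from the local quadratic approximation
  se <- tryCatch(
    {
      covm <- solve(lm_fit$hessian) * lm_fit$deviance / max(1, sum(use) - 3)
      sqrt(pmax(diag(covm), 0))
    },
    error = function(e) rep(NA_real_, 3)
  )
  params <- one_site_params(theta[1], exp(theta[2]), theta[3])
  thermo <- derive_thermo(params$ka, params$dh, design$temperature)
  fitted_ucal <- one_site_heats(theta, design) * 1e6
  structure(
    list(
      params = params,
      n_se = se[1],
      ka_se = params$ka * se[2], # delta method from log Ka
      dh_se = se[3],
      kd = thermo$kd, dg = thermo$dg, ds = thermo$ds,
      c_value = params$n * params$ka * design$cell_concentration,
      residual_norm = sqrt(sum((fitted_ucal - obs_ucal)[use]^2)),
      converged = converged,
      info = lm_fit$info,
      fitted = tibble(
        injection = seq_len(n_inj),
        molar_ratio = curve$molar_ratio %||%
          simulate_titration(params, design)$molar_ratio,
        observed_ucal = obs_ucal,
        fitted_ucal = fitted_ucal,
        used = use
      ),
      design = design
    ),
    class = "itc_fit"
  )
}

# Deterministic automatic initializer: n = 1; dH from the first normalized
# heat; Ka from the half-width of the transition region of the isotherm.
auto_init_one_site <- function(obs_ucal, design) {
  q1 <- obs_ucal[1] * 1e-6
  dh0 <- q1 / (design$syringe_concentration * design$injection_volumes[1])
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1000
  cum_v <- cumsum(design$injection_volumes)
  totals <- itc_totals(design, cum_v)
  ratio <- totals$x_tot / totals$m_tot
  # injections bracketing the equivalence point carry the slope information;
  # estimate c from the spread of molar ratio over the central heat drop
  ndh <- obs_ucal / (design$syringe_concentration * design$injection_volumes * 1e6)
  lo <- 0.2 * ndh[1]
  hi <- 0.8 * ndh[1]
  in_band <- which(
    (ndh - lo) * (ndh - hi) <= 0 & sign(ndh) == sign(ndh[1])
  )
  width <- if (length(in_band) >= 2) {
    max(ratio[in_band]) - min(ratio[in_band])
  } else {
    0.1
  }
  width <- max(width, 1e-3)
  c0 <- min(max(4 / width, 1), 1e4)
  one_site_params(
    n = 1,
    ka = c0 / design$cell_concentration,
    dh = abs(dh0) * sign(dh0)
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    paste0(
      "<itc_fit> one-site model (%s)\n",
      "  n  = %.4f (se %.2g)\n",
      "  Kd = %.4g M (Ka %.4g 1/M, se %.2g)\n",
      "  dH = %.4g kcal/mol (se %.2g)  dG = %.4g kcal/mol  dS = %.4g cal/(mol K)\n",
      "  c  = %.3g, residual norm %.3g ucal\n"
    ),
    if (x$converged) "converged" else "NOT converged",
    p$n, x$n_se, x$kd, p$ka, x$ka_se,
    p$dh / 1000, x$dh_se / 1000, x$dg / 1000, x$ds,
    x$c_value, x$residual_norm
  ))
  invisible(x)
}

#' @rdname fit_one_site
#' @param x,object An `itc_fit`.
#' @param ... Unused.
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble(
    term = c("n", "ka", "dh"),
    estimate = c(x$params$n, x$params$ka, x$params$dh),
    std.error = c(x$n_se, x$ka_se, x$dh_se)
  )
}

#' @rdname fit_one_site
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(
    n = x$params$n, kd = x$kd, ka = x$params$ka,
    dh_kcal = x$params$dh / 1000, dg_kcal = x$dg / 1000, ds = x$ds,
    c_value = x$c_value, residual_norm = x$residual_norm,
    converged = x$converged
  )
}

#' @rdname fit_one_site
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  df <- object$fitted
  vol <- object$design$injection_volumes
  syr <- object$design$syringe_concentration
  df$observed_ndh <- df$observed_ucal / (syr * vol * 1e6) / 1000
  df$fitted_ndh <- df$fitted_ucal / (syr * vol * 1e6) / 1000
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_ndh)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_ndh), colour = "firebrick") +
    ggplot2::labs(
      x = "Molar ratio (ligand/macromolecule)",
      y = "kcal per mol of injectant"
    )
}

#' Read a titration table from delimited text
#'
#' Expects columns for injection volume and heat, in that order (extra
#' columns ignored; header optional).  Volumes may be in uL (values > 1e-3
#' are taken as uL, else L); heats are in ucal.
#'
#' @param path Delimited text file (whitespace, comma or tab separated).
#' @param design Optional [titration_design()] supplying concentrations; its
#'   injection schedule is replaced by the file's volumes.
#' @return A `titration_curve` tibble (with `design` attached when given).
#' @export
read_titration <- function(path, design = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read titration table: ", path),
      class = "cnbdkit_io_error"
    )
  }
  df <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
      stringsAsFactors = FALSE),
    error = function(e) {
      abort(paste0("failed to parse titration table ", path, ": ",
        conditionMessage(e)), class = "cnbdkit_parse_error")
    }
  )
  if (is.character(df[[1]][1]) && is.na(suppressWarnings(as.numeric(df[[1]][1])))) {
    df <- df[-1, , drop = FALSE] # header row
  }
  if (ncol(df) < 2 || nrow(df) < 2) {
    abort("titration table needs (volume, heat) columns and >= 2 injections",
      class = "cnbdkit_parse_error"
    )
  }
  vol <- suppressWarnings(as.numeric(df[[1]]))
  heat <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(vol)) || any(is.na(heat))) {
    abort("non-numeric entries in titration table",
      class = "cnbdkit_parse_error"
    )
  }
  if (any(vol > 1e-3)) vol <- vol * 1e-6 # uL -> L
  if (!is.null(design)) {
    design <- titration_design(
      cell_concentration = design$cell_concentration,
      syringe_concentration = design$syringe_concentration,
      cell_volume = design$cell_volume,
      injection_volumes = vol,
      temperature = design$temperature
    )
  }
  out <- tibble(
    injection = seq_along(vol),
    injection_volume = vol,
    molar_ratio = if (!is.null(design)) {
      totals <- itc_totals(design, cumsum(vol))
      totals$x_tot / totals$m_tot
    } else {
      NA_real_
    },
    heat_ucal = heat,
    ndh_kcal_mol = if (!is.null(design)) {
      heat * 1e-6 / (design$syringe_concentration * vol) / 1000
    } else {
      NA_real_
    }
  )
  attr(out, "design") <- design
  class(out) <- c("titration_curve", class(out))
  out
}
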