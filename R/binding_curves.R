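# Single-site binding model for fluorescence-anisotropy titrations and the
# Kd <-> free-energy conversions used throughout the package.

#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.9872e-3

#' Convert a dissociation constant to a dissociation free energy
#'
#' `dG = -R T ln(Kd)` with Kd in molar, so larger values mean tighter
#' binding (a tenfold drop in Kd adds R T ln(10) ~= 1.364 kcal/mol at
#' 298.15 K).
#'
#' @param kd dissociation constant(s), molar; must be > 0.
#' @param temperature_K absolute temperature (default 298.15).
#' @return free energy of dissociation in kcal/mol.
#' @export
kd_to_dg <- function(kd, temperature_K = 298.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop("Kd must be positive and finite", call. = FALSE)
  }
  -R_KCAL * temperature_K * log(kd)
}

#' Convert a dissociation free energy back to a dissociation constant
#'
#' Exact inverse of [kd_to_dg()].
#'
#' @param dg free energy of dissociation, kcal/mol.
#' @inheritParams kd_to_dg
#' @return Kd in molar.
#' @export
dg_to_kd <- function(dg, temperature_K = 298.15) {
  if (any(!is.finite(dg))) stop("dG must be finite", call. = FALSE)
  exp(-dg / (R_KCAL * temperature_K))
}

#' Construct a titration curve object
#'
#' @param concentration_M protein concentrations, molar (>= 5 points, > 0).
#' @param anisotropy measured anisotropy values, same length.
#' @param protein,re,replicate optional genotype/replicate annotation.
#' @param probe_conc_M labeled-probe concentration (default 5e-9 M).
#' @return object of class `titration_curve`.
#' @export
titration_curve <- function(concentration_M, anisotropy, protein = NA,
                            re = NA, replicate = NA, probe_conc_M = 5e-9) {
  if (length(concentration_M) != length(anisotropy)) {
    stop("concentration and anisotropy lengths differ", call. = FALSE)
  }
  if (any(concentration_M <= 0)) stop("concentrations must be positive", call. = FALSE)
  ord <- order(concentration_M)
  structure(list(
    concentration_M = concentration_M[ord],
    anisotropy = anisotropy[ord],
    protein = protein, re = re, replicate = replicate,
    probe_conc_M = probe_conc_M
  ), class = "titration_curve")
}

.hyperbola <- function(conc, baseline, plateau, kd) {
  baseline + (plateau - baseline) * conc / (kd + conc)
}

# ligand-depletion (quadratic) variant: fraction of probe bound when the
# probe concentration S is not negligible relative to Kd
.depletion <- function(conc, baseline, plateau, kd, S) {
  fb <- ((conc + S + kd) - sqrt((conc + S + kd)^2 - 4 * conc * S)) / (2 * S)
  baseline + (plateau - baseline) * fb
}

#' Fit the single-site binding model to a titration curve
#'
#' Nonlinear least squares of
#' `A([P]) = A_free + (A_bound - A_free) [P] / (Kd + [P])` using
#' Levenberg-Marquardt.  Starting values are the minimum and maximum
#' anisotropy and the concentration nearest the half-maximal signal; on
#' failure up to five restarts over log-spaced Kd initializations are
#' attempted.  Set `depletion = TRUE` to use the quadratic
#' probe-depletion-corrected model instead (probe concentration taken from
#' the curve).
#'
#' @param curve a [titration_curve()].
#' @param initial_guess optional named list with any of `baseline`,
#'   `plateau`, `kd`.
#' @param depletion logical; fit the depletion-corrected model.
#' @param temperature_K temperature for the free-energy conversion.
#' @return object of class `binding_estimate`: a list with `kd`, `k1`
#'   (= 1/kd), `dG` (kcal/mol), `baseline`, `plateau`, `rss`, `converged`,
#'   `in_range` (fitted Kd inside the titrated concentration range),
#'   `temperature_K`, `n_points`.
#' @export
fit_single_site <- function(curve, initial_guess = NULL, depletion = FALSE,
                            temperature_K = 298.15) {
  stopifnot(inherits(curve, "titration_curve"))
  conc <- curve$concentration_M
  A <- curve$anisotropy
  if (length(conc) < 4L) stop("insufficient data: fewer than 4 points", call. = FALSE)
  lo <- min(A); hi <- max(A)
  half <- (lo + hi) / 2
  kd0 <- conc[which.min(abs(A - half))]
  start <- list(baseline = lo, plateau = hi, kd = kd0)
  for (nm in names(initial_guess)) start[[nm]] <- initial_guess[[nm]]

  model_fun <- if (depletion) {
    S <- curve$probe_conc_M
    function(b, p, k) .depletion(conc, b, p, k, S)
  } else {
    function(b, p, k) .hyperbola(conc, b, p, k)
  }

  try_fit <- function(kd_init) {
    df <- data.frame(conc = conc, A = A)
    tryCatch(
      minpack.lm::nlsLM(
        A ~ model_fun(baseline, plateau, kd),
        data = df,
        start = list(baseline = start$baseline, plateau = start$plateau,
                     kd = kd_init),
        lower = c(-Inf, -Inf, .Machine$double.xmin),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  fit <- try_fit(start$kd)
  if (is.null(fit)) {
    for (kd_init in 10^seq(log10(min(conc)), log10(max(conc)), length.out = 5)) {
      fit <- try_fit(kd_init)
      if (!is.null(fit)) break
    }
  }

  if (is.null(fit)) {
    est <- list(kd = NA_real_, k1 = NA_real_, dG = NA_real_,
                baseline = NA_real_, plateau = NA_real_, rss = NA_real_,
                converged = FALSE, in_range = NA,
                temperature_K = temperature_K, n_points = length(conc),
                protein = curve$protein, re = curve$re,
                replicate = curve$replicate)
    return(structure(est, class = "binding_estimate"))
  }

  cf <- stats::coef(fit)
  kd <- unname(cf["kd"])
  est <- list(
    kd = kd,
    k1 = 1 / kd,
    dG = kd_to_dg(kd, temperature_K),
    baseline = unname(cf["baseline"]),
    plateau = unname(cf["plateau"]),
    rss = sum(stats::residuals(fit)^2),
    converged = TRUE,
    in_range = kd >= min(conc) && kd <= max(conc),
    temperature_K = temperature_K,
    n_points = length(conc),
    protein = curve$protein, re = curve$re, replicate = curve$replicate
  )
  structure(est, class = "binding_estimate")
}

#' @export
print.binding_estimate <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("binding_estimate: fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("binding_estimate: Kd = %.4g M, dG = %.3f kcal/mol (%s)\n",
              x$kd, x$dG,
              if (isTRUE(x$in_range)) "Kd in titrated range" else "Kd outside titrated range"))
  invisible(x)
}

#' Summarize replicate binding-energy estimates
#'
#' @param dG numeric vector of replicate dG values, or a list of
#'   `binding_estimate` objects (non-converged replicates dropped).
#' @return list with `mean_dG`, `sem` (sample sd / sqrt(n); NA with
#'   `sem_defined = FALSE` for a single replicate) and `n`.
#' @export
aggregate_replicates <- function(dG) {
  if (is.list(dG) && all(vapply(dG, inherits, TRUE, "binding_estimate"))) {
    dG <- vapply(Filter(function(e) isTRUE(e$converged), dG),
                 function(e) e$dG, numeric(1))
  }
  if (length(dG) == 0L) stop("no replicate estimates supplied", call. = FALSE)
  n <- length(dG)
  list(
    mean_dG = mean(dG),
    sem = if (n > 1L) stats::sd(dG) / sqrt(n) else NA_real_,
    sem_defined = n > 1L,
    n = n
  )
}
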