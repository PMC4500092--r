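# Nested encoded linear models of binding energy, effect extraction,
# variance partitioning and energy logos.

.response_column <- function(table) {
  for (nm in c("dG", "dG_kcal_mol", "mean_dG")) {
    if (nm %in% names(table)) return(nm)
  }
  stop("no binding-energy column found (expected one of dG, dG_kcal_mol, mean_dG)",
       call. = FALSE)
}

#' Fit an encoded linear model of binding energy
#'
#' Ordinary least squares of the dG observations on the design matrix
#' defined by `spec` and `encoding`.  The log-likelihood is computed under
#' Gaussian errors with the variance profiled at its maximum-likelihood
#' value (RSS/n).  With `abc_wyk` encoding the design must be full column
#' rank; rank deficiency raises an error naming the collinear terms.  With
#' `binary` encoding (one-hot indicators, rank-deficient by construction)
#' the minimum-norm least-squares solution is used; fitted values are the
#' unique projection either way.
#'
#' @param table data.frame with columns `protein`, `re` and a binding-energy
#'   column (`dG`, `dG_kcal_mol` or `mean_dG`); optional logical `censored`
#'   column marks rows to exclude.
#' @param spec a [model_spec()] (or character vector of group names).
#' @param encoding "abc_wyk" or "binary".
#' @return object of class `epistasis_fit` with elements `coefficients`
#'   (named by term), `model_spec`, `encoding`, `n`, `rank`, `rss`,
#'   `sigma2` (MLE), `logLik`, `r_squared`, `adj_r_squared`, `cells`
#'   (per-genotype fitted means) and, for full-rank fits, `cov_unscaled`.
#' @export
fit_model <- function(table, spec = model_spec(), encoding = c("abc_wyk", "binary")) {
  encoding <- match.arg(encoding)
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("empty measurement table", call. = FALSE)
  }
  if ("censored" %in% names(table)) {
    ncens <- sum(table$censored, na.rm = TRUE)
    if (ncens > 0L) {
      message("excluding ", ncens, " censored row(s)")
      table <- table[!isTRUE_vec(table$censored), , drop = FALSE]
    }
  }
  ycol <- .response_column(table)
  y <- table[[ycol]]
  if (any(!is.finite(y))) stop("non-finite binding energies in table", call. = FALSE)

  X <- build_design_matrix(table, spec, encoding)
  n <- nrow(X)
  p <- ncol(X)

  if (encoding == "abc_wyk") {
    qx <- qr(X)
    if (qx$rank < p) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
      stop("design matrix is rank deficient; collinear terms: ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qx, y)
    fitted <- drop(X %*% beta)
    rank <- qx$rank
    R <- qr.R(qx)
    cov_unscaled <- chol2inv(R)
    dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- stats::setNames(drop(beta), colnames(X))
    fitted <- drop(X %*% beta)
    rank <- sum(pos)
    cov_unscaled <- NULL
  }

  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else ifelse(rss < 1e-24, 1, 0)
  adj <- if (n > rank) 1 - (1 - r2) * (n - 1) / (n - rank) else r2
  sigma2 <- rss / n
  # a residual sd below ~1e-12 kcal/mol is numerically an exact fit; the
  # profiled Gaussian likelihood degenerates there
  ll <- if (sigma2 <= 1e-24 * max(1, tss / n)) Inf else
    -n / 2 * (log(2 * pi * sigma2) + 1)

  key <- joint_label(table$protein, table$re)
  cells <- data.frame(protein = table$protein, re = table$re,
                      label = key, fitted = fitted, stringsAsFactors = FALSE)
  cells <- unique(cells[order(cells$label), , drop = FALSE])
  rownames(cells) <- NULL

  structure(list(
    coefficients = beta, model_spec = spec, encoding = encoding,
    n = n, rank = rank, rss = rss, sigma2 = sigma2, logLik = ll,
    r_squared = r2, adj_r_squared = adj, tss = tss, y_mean = mean(y),
    cells = cells, cov_unscaled = cov_unscaled
  ), class = "epistasis_fit")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.epistasis_fit <- function(x, ...) {
  cat(sprintf(
    "epistasis_fit (%s): %s\n  n = %d, rank = %d, R^2 = %.4f, adj R^2 = %.4f, logLik = %.2f\n",
    x$encoding, paste(unclass(x$model_spec), collapse = " + "),
    x$n, x$rank, x$r_squared, x$adj_r_squared, x$logLik))
  invisible(x)
}

.has_group <- function(fit, group) group %in% unclass(fit$model_spec)

.require_group <- function(fit, group) {
  if (!.has_group(fit, group)) {
    stop("fit does not include term group ", group, call. = FALSE)
  }
}

# mean fitted value over cells selected by a predicate on (protein, re)
.cell_mean <- function(fit, keep) {
  cells <- fit$cells
  mean(cells$fitted[keep(cells$protein, cells$re)])
}

.re_state_of <- function(re, site) {
  if (site == 3 || site == "3") substr(re, 1, 1) else substr(re, 2, 2)
}

.protein_derived_at <- function(protein, site) {
  vapply(protein, function(p) .parse_protein(p)[[site]], TRUE, USE.NAMES = FALSE)
}

.site_letter <- c(site25 = "a", site26 = "b", site29 = "c")

#' Main effect of a nucleotide state at an RE site
#'
#' The dot product of the site's fitted (w, y, k) coefficients with the
#' state's WYK vector: the state's average deviation of binding energy from
#' the grand mean, in kcal/mol.  For instance C at site 3 is
#' `-w3 + y3 - k3`.  For binary-encoded fits the same contrast is computed
#' from the fitted cell means.
#'
#' @param fit an [fit_model()] result including that site's first-order group.
#' @param re_site 3 or 4.
#' @param nucleotide "A", "C", "G" or "T".
#' @param conf if TRUE (abc_wyk only), also return the standard error and a
#'   95 percent t confidence interval.
#' @return kcal/mol (numeric), or a list when `conf = TRUE`.
#' @export
state_effect <- function(fit, re_site, nucleotide, conf = FALSE) {
  group <- paste0("R1_", re_site)
  .require_group(fit, group)
  v <- wyk_encode(nucleotide)
  if (fit$encoding == "abc_wyk") {
    nm <- paste0(c("w", "y", "k"), re_site)
    contrast <- stats::setNames(numeric(length(fit$coefficients)),
                                names(fit$coefficients))
    contrast[nm] <- v
    val <- sum(fit$coefficients[nm] * v)
    if (conf) return(.contrast_conf(fit, contrast, val))
    val
  } else {
    .cell_mean(fit, function(p, r) .re_state_of(r, re_site) == nucleotide) -
      mean(fit$cells$fitted)
  }
}

.contrast_conf <- function(fit, contrast, value) {
  if (is.null(fit$cov_unscaled)) {
    stop("confidence intervals require an abc_wyk full-rank fit", call. = FALSE)
  }
  dfree <- fit$n - fit$rank
  if (dfree <= 0) stop("no residual degrees of freedom", call. = FALSE)
  s2 <- fit$rss / dfree
  se <- sqrt(drop(t(contrast) %*% fit$cov_unscaled %*% contrast) * s2)
  tq <- stats::qt(0.975, dfree)
  list(value = value, se = se, lower = value - tq * se, upper = value + tq * se)
}

#' Pairwise epistasis between nucleotide states at RE sites 3 and 4
#'
#' The excess effect of a state combination beyond the sum of its two main
#' effects: the dot product of the nine fitted pair coefficients with the
#' outer product of the two states' WYK vectors.  On a complete factorial
#' it equals `cellmean(s3, s4) - grandmean - effect(s3) - effect(s4)`.
#'
#' @inheritParams state_effect
#' @param state3,state4 nucleotides at sites 3 and 4.
#' @return kcal/mol.
#' @export
pair_epistasis <- function(fit, state3, state4) {
  .require_group(fit, "R2")
  v3 <- wyk_encode(state3)
  v4 <- wyk_encode(state4)
  if (fit$encoding == "abc_wyk") {
    weights <- as.vector(t(outer(v3, v4)))       # row-major: w3w4, w3y4, ...
    sum(fit$coefficients[.R2_NAMES] * weights)
  } else {
    gm <- mean(fit$cells$fitted)
    both <- .cell_mean(fit, function(p, r)
      .re_state_of(r, 3) == state3 & .re_state_of(r, 4) == state4)
    both - gm - state_effect(fit, 3, state3) - state_effect(fit, 4, state4)
  }
}

#' Average effect of an amino acid substitution on binding energy
#'
#' Twice the site's fitted coefficient: the difference between the mean
#' binding energy in the derived and ancestral backgrounds on a balanced
#' factorial.
#'
#' @inheritParams state_effect
#' @param protein_site "site25", "site26" or "site29".
#' @return kcal/mol.
#' @export
substitution_effect <- function(fit, protein_site, conf = FALSE) {
  .require_group(fit, "P1")
  protein_site <- match.arg(protein_site, PROTEIN_SITES)
  if (fit$encoding == "abc_wyk") {
    nm <- .site_letter[[protein_site]]
    val <- 2 * unname(fit$coefficients[nm])
    if (conf) {
      contrast <- stats::setNames(numeric(length(fit$coefficients)),
                                  names(fit$coefficients))
      contrast[nm] <- 2
      return(.contrast_conf(fit, contrast, val))
    }
    val
  } else {
    .cell_mean(fit, function(p, r) .protein_derived_at(p, protein_site)) -
      .cell_mean(fit, function(p, r) !.protein_derived_at(p, protein_site))
  }
}

#' Marginal epistatic interaction between two amino acid substitutions
#'
#' With the default `"marginal"` convention this is twice the fitted pair
#' coefficient: the effect of substitution i in the derived background at
#' site j minus its average effect across backgrounds.  The
#' double-mutant-cycle convention (`"cycle"`, four times the coefficient)
#' is also available.
#'
#' @inheritParams substitution_effect
#' @param site_i,site_j distinct protein sites.
#' @param convention "marginal" (default) or "cycle".
#' @return kcal/mol.
#' @export
protein_pair_epistasis <- function(fit, site_i, site_j,
                                   convention = c("marginal", "cycle")) {
  .require_group(fit, "P2")
  convention <- match.arg(convention)
  site_i <- match.arg(site_i, PROTEIN_SITES)
  site_j <- match.arg(site_j, PROTEIN_SITES)
  if (site_i == site_j) stop("site_i and site_j must differ", call. = FALSE)
  mult <- if (convention == "marginal") 2 else 4
  if (fit$encoding == "abc_wyk") {
    letters2 <- sort(c(.site_letter[[site_i]], .site_letter[[site_j]]))
    nm <- paste0(letters2[1], letters2[2])
    mult * unname(fit$coefficients[nm])
  } else {
    di <- function(p) .protein_derived_at(p, site_i)
    dj <- function(p) .protein_derived_at(p, site_j)
    eff_in_derived_j <-
      .cell_mean(fit, function(p, r) di(p) & dj(p)) -
      .cell_mean(fit, function(p, r) !di(p) & dj(p))
    avg_eff <-
      .cell_mean(fit, function(p, r) di(p)) -
      .cell_mean(fit, function(p, r) !di(p))
    (mult / 2) * (eff_in_derived_j - avg_eff)
  }
}

#' Cross-interface effect of a substitution on a nucleotide state effect
#'
#' The change an amino acid replacement causes in the main effect of a
#' nucleotide state: twice the dot product of the protein site's
#' cross-interface coefficients for that RE site with the state's WYK
#' vector, i.e. the state's effect in the derived background minus its
#' effect in the ancestral background.  `protein_site` may also be a pair
#' of sites (length 2), in which case the protein pairwise interaction's
#' modulation of the state effect is returned (requires X3).
#'
#' @inheritParams substitution_effect
#' @param re_site 3 or 4.
#' @param nucleotide the RE state.
#' @return kcal/mol.
#' @export
cross_interface_effect <- function(fit, protein_site, re_site, nucleotide) {
  v <- wyk_encode(nucleotide)
  if (length(protein_site) == 1L) {
    .require_group(fit, "X2")
    if (fit$encoding == "abc_wyk") {
      letter <- .site_letter[[match.arg(protein_site, PROTEIN_SITES)]]
      nm <- paste0(letter, c("w", "y", "k"), re_site)
      2 * sum(fit$coefficients[nm] * v)
    } else {
      ps <- match.arg(protein_site, PROTEIN_SITES)
      eff_in <- function(want) {
        sub <- fit$cells[.protein_derived_at(fit$cells$protein, ps) == want, ]
        mean(sub$fitted[.re_state_of(sub$re, re_site) == nucleotide]) -
          mean(sub$fitted)
      }
      eff_in(TRUE) - eff_in(FALSE)
    }
  } else if (length(protein_site) == 2L) {
    .require_group(fit, "X3")
    if (fit$encoding != "abc_wyk") {
      stop("pair x nucleotide cross effects require abc_wyk encoding", call. = FALSE)
    }
    l2 <- sort(vapply(protein_site, function(s) .site_letter[[match.arg(s, PROTEIN_SITES)]], ""))
    nm <- paste0(l2[1], l2[2], c("w", "y", "k"), re_site)
    2 * sum(fit$coefficients[nm] * v)
  } else {
    stop("protein_site must have length 1 or 2", call. = FALSE)
  }
}

#' Third-order cross-interface effect on an RE pair contrast
#'
#' The change a substitution causes in the site 3 x site 4 epistasis
#' contrast of a nucleotide combination: twice the dot product of the
#' protein site's 27 third-order coefficients with the outer product of the
#' two states' WYK vectors.
#'
#' @inheritParams cross_interface_effect
#' @param state3,state4 nucleotides at RE sites 3 and 4.
#' @return kcal/mol.
#' @export
cross_interface_pair_effect <- function(fit, protein_site, state3, state4) {
  .require_group(fit, "X3")
  v3 <- wyk_encode(state3)
  v4 <- wyk_encode(state4)
  weights <- as.vector(t(outer(v3, v4)))
  if (fit$encoding == "abc_wyk") {
    letter <- .site_letter[[match.arg(protein_site, PROTEIN_SITES)]]
    nm <- paste0(letter, .R2_NAMES)
    2 * sum(fit$coefficients[nm] * weights)
  } else {
    ps <- match.arg(protein_site, PROTEIN_SITES)
    contrast_in <- function(want) {
      sub <- fit$cells[.protein_derived_at(fit$cells$protein, ps) == want, ]
      gm <- mean(sub$fitted)
      e3 <- mean(sub$fitted[.re_state_of(sub$re, 3) == state3]) - gm
      e4 <- mean(sub$fitted[.re_state_of(sub$re, 4) == state4]) - gm
      both <- mean(sub$fitted[.re_state_of(sub$re, 3) == state3 &
                              .re_state_of(sub$re, 4) == state4])
      both - gm - e3 - e4
    }
    contrast_in(TRUE) - contrast_in(FALSE)
  }
}

#' Likelihood-ratio comparison of two nested fits
#'
#' `statistic = 2 (logL_complex - logL_simple)` referred to a chi-squared
#' distribution with df equal to the number of added columns (ranks for
#' binary fits); the Bonferroni-adjusted p is `min(1, p * family_size)`.
#' The adjusted-R-squared increment is reported as-is (it may be negative).
#'
#' @param fit_simple,fit_complex nested [fit_model()] results on the same
#'   observations (the simple spec's groups must be a subset of the
#'   complex's).
#' @param family_size Bonferroni family size (default 1).
#' @return one-row data.frame of class `nested_comparison` with columns
#'   `statistic`, `df`, `p`, `p_adj`, `adj_r2_increment`, `r2_increment`,
#'   `family_size`.
#' @export
compare_nested <- function(fit_simple, fit_complex, family_size = 1) {
  stopifnot(inherits(fit_simple, "epistasis_fit"),
            inherits(fit_complex, "epistasis_fit"))
  if (!all(unclass(fit_simple$model_spec) %in% unclass(fit_complex$model_spec))) {
    stop("models are not nested: simple spec is not a subset of complex spec",
         call. = FALSE)
  }
  if (fit_simple$n != fit_complex$n ||
      abs(fit_simple$y_mean - fit_complex$y_mean) > 1e-12 * (1 + abs(fit_simple$y_mean))) {
    stop("fits were not computed on the same observations", call. = FALSE)
  }
  df <- fit_complex$rank - fit_simple$rank
  if (identical(unclass(fit_simple$model_spec), unclass(fit_complex$model_spec))) {
    stat <- 0
    p <- 1
    df <- 0L
  } else {
    if (df <= 0L) stop("complex model adds no parameters", call. = FALSE)
    stat <- max(0, 2 * (fit_complex$logLik - fit_simple$logLik))
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  out <- data.frame(
    simple = paste(unclass(fit_simple$model_spec), collapse = "+"),
    complex = paste(unclass(fit_complex$model_spec), collapse = "+"),
    statistic = stat, df = df, p = p,
    p_adj = min(1, p * family_size),
    adj_r2_increment = fit_complex$adj_r_squared - fit_simple$adj_r_squared,
    r2_increment = fit_complex$r_squared - fit_simple$r_squared,
    family_size = family_size,
    stringsAsFactors = FALSE
  )
  class(out) <- c("nested_comparison", "data.frame")
  out
}

#' Partition variance in binding energy across term groups
#'
#' Adds the requested term groups in canonical order (INTERCEPT, P1, P2,
#' R1_3, R1_4, R2, X2, X3, P3) and reports, for each, the raw and
#' adjusted R-squared increments over the previous model.  Raw increments
#' telescope to the full model's R-squared; on a complete balanced
#' factorial with abc_wyk encoding they are order-invariant.
#'
#' @inheritParams fit_model
#' @return data.frame with one row per group: `group`, `columns`, `r2`,
#'   `adj_r2`, `r2_increment`, `adj_r2_increment`.  The list of cumulative
#'   fits is attached as attribute `fits`.
#' @export
variance_partition <- function(table, spec = model_spec(),
                               encoding = c("abc_wyk", "binary")) {
  encoding <- match.arg(encoding)
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  groups <- unclass(spec)
  fits <- vector("list", length(groups))
  rows <- vector("list", length(groups))
  prev_r2 <- 0; prev_adj <- 0
  for (i in seq_along(groups)) {
    f <- fit_model(table, model_spec(groups[seq_len(i)]), encoding)
    fits[[i]] <- f
    rows[[i]] <- data.frame(
      group = groups[i],
      columns = .GROUP_SIZES[[groups[i]]],
      r2 = f$r_squared, adj_r2 = f$adj_r_squared,
      r2_increment = f$r_squared - prev_r2,
      adj_r2_increment = f$adj_r_squared - prev_adj,
      stringsAsFactors = FALSE
    )
    prev_r2 <- f$r_squared
    prev_adj <- f$adj_r_squared
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(fits) <- groups
  attr(out, "fits") <- fits
  out
}

#' Build a numeric energy logo for one protein's RE preferences
#'
#' Fits the nested sequence INTERCEPT, +R1_3, +R1_4, +R2 to one protein's
#' measurements across the 16 REs and assembles the logo: three columns
#' (site-3 main effects, site-4 main effects, 3 x 4 epistasis) with state
#' heights in kcal/mol ranked by magnitude, column widths equal to the
#' adjusted-R-squared increment of the corresponding term group (floored at
#' 0 for display; signed values kept in the `width_signed` column), and a
#' significance star where the Bonferroni-adjusted likelihood-ratio p is
#' below `alpha`.  Stars require replicate-level data (the mean-level
#' per-protein model is saturated); without them widths are emitted and
#' stars are NA with a warning.
#'
#' @param table replicate-level measurement table (a single protein's rows,
#'   or pass `protein` to subset).
#' @param protein optional protein label to subset `table`.
#' @param encoding "abc_wyk" or "binary".
#' @param alpha significance level for stars (default 0.05).
#' @param family_size Bonferroni family (default: the 3 comparisons made).
#' @return data.frame of class `energy_logo` with columns `column`
#'   ("site3", "site4", "epistasis"), `state`, `height`, `width`,
#'   `width_signed`, `star`.
#' @export
build_energy_logo <- function(table, protein = NULL,
                              encoding = c("abc_wyk", "binary"),
                              alpha = 0.05, family_size = 3) {
  encoding <- match.arg(encoding)
  if (!is.null(protein)) table <- table[table$protein == protein, , drop = FALSE]
  if (nrow(table) == 0L) stop("no rows for requested protein", call. = FALSE)
  if (length(unique(table$protein)) != 1L) {
    stop("energy logos are per protein; table contains several", call. = FALSE)
  }
  seqs <- list(c(), "R1_3", c("R1_3", "R1_4"), c("R1_3", "R1_4", "R2"))
  fits <- lapply(seqs, function(g) fit_model(table, model_spec(g), encoding))
  cmp <- vector("list", 3L)
  have_reps <- all(vapply(fits, function(f) f$n > f$rank, TRUE)) &&
    all(is.finite(vapply(fits, function(f) f$logLik, 0)))
  if (have_reps) {
    for (i in 1:3) cmp[[i]] <- compare_nested(fits[[i]], fits[[i + 1]], family_size)
    stars <- vapply(cmp, function(cc) cc$p_adj < alpha, TRUE)
  } else {
    warning("saturated (replicate-free) fit: significance stars omitted")
    stars <- rep(NA, 3L)
  }
  widths <- vapply(2:4, function(i)
    fits[[i]]$adj_r_squared - fits[[i - 1]]$adj_r_squared, 0)
  final <- fits[[4]]

  main_col <- function(site, colname, w, st) {
    h <- vapply(NUCLEOTIDES, function(nn) state_effect(final, site, nn), 0)
    data.frame(column = colname, state = NUCLEOTIDES, height = unname(h),
               width = max(0, w), width_signed = w, star = st,
               stringsAsFactors = FALSE)
  }
  combos <- expand.grid(s3 = NUCLEOTIDES, s4 = NUCLEOTIDES,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  epi <- data.frame(
    column = "epistasis",
    state = paste0(combos$s3, combos$s4),
    height = mapply(function(a, b) pair_epistasis(final, a, b),
                    combos$s3, combos$s4),
    width = max(0, widths[3]), width_signed = widths[3], star = stars[3],
    stringsAsFactors = FALSE
  )
  logo <- rbind(main_col(3, "site3", widths[1], stars[1]),
                main_col(4, "site4", widths[2], stars[2]),
                epi)
  logo <- do.call(rbind, lapply(split(logo, factor(logo$column,
                  levels = c("site3", "site4", "epistasis"))),
                  function(d) d[order(-abs(d$height)), ]))
  rownames(logo) <- NULL
  attr(logo, "fits") <- fits
  attr(logo, "comparisons") <- cmp
  attr(logo, "protein") <- table$protein[1]
  class(logo) <- c("energy_logo", "data.frame")
  logo
}

#' Tabulate all state-level effects from a fitted model
#'
#' Collects, for whichever term groups the fit contains: RE state main
#' effects, RE pair epistasis contrasts, protein substitution effects,
#' protein pairwise marginals, and cross-interface shifts (second and
#' third order).
#'
#' @param fit an [fit_model()] result.
#' @return data.frame with columns `term_type`, `protein_site`, `re_site`,
#'   `state`, `value` (kcal/mol).
#' @export
effect_table <- function(fit) {
  rows <- list()
  add <- function(term_type, protein_site, re_site, state, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      term_type = term_type, protein_site = protein_site, re_site = re_site,
      state = state, value = value, stringsAsFactors = FALSE)
  }
  combos <- expand.grid(s3 = NUCLEOTIDES, s4 = NUCLEOTIDES,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (site in c(3, 4)) if (.has_group(fit, paste0("R1_", site))) {
    for (nn in NUCLEOTIDES)
      add("re_main", NA, as.character(site), nn, state_effect(fit, site, nn))
  }
  if (.has_group(fit, "R2")) {
    for (i in seq_len(nrow(combos)))
      add("re_pair", NA, "3x4", paste0(combos$s3[i], combos$s4[i]),
          pair_epistasis(fit, combos$s3[i], combos$s4[i]))
  }
  if (.has_group(fit, "P1")) {
    for (ps in PROTEIN_SITES)
      add("protein_main", ps, NA, "derived", substitution_effect(fit, ps))
  }
  if (.has_group(fit, "P2")) {
    prs <- list(c("site25", "site26"), c("site25", "site29"), c("site26", "site29"))
    for (pr in prs)
      add("protein_pair", paste(pr, collapse = ":"), NA, "derived:derived",
          protein_pair_epistasis(fit, pr[1], pr[2]))
  }
  if (.has_group(fit, "X2")) {
    for (ps in PROTEIN_SITES) for (site in c(3, 4)) for (nn in NUCLEOTIDES)
      add("cross_2", ps, as.character(site), nn,
          cross_interface_effect(fit, ps, site, nn))
  }
  if (.has_group(fit, "X3") && fit$encoding == "abc_wyk") {
    for (ps in PROTEIN_SITES) for (i in seq_len(nrow(combos)))
      add("cross_3_pair", ps, "3x4", paste0(combos$s3[i], combos$s4[i]),
          cross_interface_pair_effect(fit, ps, combos$s3[i], combos$s4[i]))
    prs <- list(c("site25", "site26"), c("site25", "site29"), c("site26", "site29"))
    for (pr in prs) for (site in c(3, 4)) for (nn in NUCLEOTIDES)
      add("cross_3_pp", paste(pr, collapse = ":"), as.character(site), nn,
          cross_interface_effect(fit, pr, site, nn))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
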