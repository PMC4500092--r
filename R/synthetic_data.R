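# Seeded generator for binding-energy landscapes, replicate measurement
# tables, titration curves and pathway fixtures.  Parameters are specified
# in interpretable state-effect space (zero-sum constrained, kcal/mol) and
# converted internally to the coefficient space the regression models use.

.zero_sum_ok <- function(x, tol = 1e-8) all(abs(x) < Inf) && abs(sum(x)) < tol

.check_centered_vec <- function(x, what) {
  if (!.zero_sum_ok(x)) stop(what, " must sum to zero", call. = FALSE)
}

.check_centered_mat <- function(m, what) {
  if (any(abs(rowSums(m)) > 1e-8) || any(abs(colSums(m)) > 1e-8)) {
    stop(what, " must have zero row and column sums", call. = FALSE)
  }
}

.zero_vec <- function() stats::setNames(numeric(4), NUCLEOTIDES)
.zero_mat <- function() matrix(0, 4, 4, dimnames = list(NUCLEOTIDES, NUCLEOTIDES))

.PP_NAMES <- c("site25:site26", "site25:site29", "site26:site29")

#' Specify the generative parameters of a binding-energy landscape
#'
#' Effects are given in state-effect space: the same mean-relative
#' quantities (kcal/mol) that [state_effect()], [pair_epistasis()],
#' [substitution_effect()] and friends recover from a fitted model, so a
#' noiseless generate-then-fit round trip returns exactly these numbers.
#'
#' @param grand_mean grand mean dG over the whole landscape, kcal/mol.
#' @param re3,re4 named 4-vectors (A, C, G, T) of nucleotide main effects at
#'   sites 3 and 4; each must sum to zero.
#' @param re_pair 4 x 4 matrix (rows = site-3 state, cols = site-4 state) of
#'   pair epistasis contrasts; zero row and column sums.
#' @param protein named 3-vector (site25, site26, site29) of substitution
#'   effects (derived-minus-ancestral background means).
#' @param protein_pair named 3-vector ("site25:site26", ...) of marginal
#'   pairwise interactions.
#' @param cross named list `cross[[protein_site]][[re_site]]` of zero-sum
#'   4-vectors: the shift each substitution causes in each nucleotide state
#'   effect.
#' @param cross_pair named list `cross_pair[[protein_site]]` of zero-margin
#'   4 x 4 matrices: third-order shifts of the RE pair contrasts.
#' @param cross_pp named list `cross_pp[["site25:site26"]][[re_site]]` of
#'   zero-sum 4-vectors: protein-pair x nucleotide third-order shifts.
#' @param noise_sd Gaussian replicate noise sd, kcal/mol (>= 0).
#' @param replicates replicates per cell (>= 1).
#' @param provenance named character vector tagging parameters as "paper"
#'   (printed in the source study's text) or "placeholder".
#' @return object of class `landscape_params`.
#' @export
landscape_params <- function(grand_mean = 10,
                             re3 = .zero_vec(), re4 = .zero_vec(),
                             re_pair = .zero_mat(),
                             protein = stats::setNames(numeric(3), PROTEIN_SITES),
                             protein_pair = stats::setNames(numeric(3), .PP_NAMES),
                             cross = list(), cross_pair = list(),
                             cross_pp = list(),
                             noise_sd = 0, replicates = 1,
                             provenance = character()) {
  re3 <- re3[NUCLEOTIDES]; re4 <- re4[NUCLEOTIDES]
  .check_centered_vec(re3, "re3 state effects")
  .check_centered_vec(re4, "re4 state effects")
  .check_centered_mat(re_pair, "re_pair contrasts")
  protein <- protein[PROTEIN_SITES]
  protein_pair <- protein_pair[.PP_NAMES]
  protein[is.na(protein)] <- 0
  protein_pair[is.na(protein_pair)] <- 0
  names(protein) <- PROTEIN_SITES
  names(protein_pair) <- .PP_NAMES
  for (ps in names(cross)) for (rs in names(cross[[ps]])) {
    cross[[ps]][[rs]] <- cross[[ps]][[rs]][NUCLEOTIDES]
    .check_centered_vec(cross[[ps]][[rs]],
                        paste0("cross[", ps, "][", rs, "] shifts"))
  }
  for (ps in names(cross_pair)) {
    .check_centered_mat(cross_pair[[ps]], paste0("cross_pair[", ps, "]"))
  }
  for (pp in names(cross_pp)) for (rs in names(cross_pp[[pp]])) {
    cross_pp[[pp]][[rs]] <- cross_pp[[pp]][[rs]][NUCLEOTIDES]
    .check_centered_vec(cross_pp[[pp]][[rs]],
                        paste0("cross_pp[", pp, "][", rs, "] shifts"))
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(
    grand_mean = grand_mean, re3 = re3, re4 = re4, re_pair = re_pair,
    protein = protein, protein_pair = protein_pair,
    cross = cross, cross_pair = cross_pair, cross_pp = cross_pp,
    noise_sd = noise_sd, replicates = as.integer(replicates),
    provenance = provenance
  ), class = "landscape_params")
}

#' Zero-margin RE pair-contrast matrix with fixed GT and GA entries
#'
#' Builds a 4 x 4 contrast matrix whose (G, T) and (G, A) entries are
#' exactly the requested values, with the remaining row-G entries splitting
#' the complement equally and every other row compensating its column, so
#' that all row and column sums are zero.
#'
#' @param GT,GA contrast values for the G3/T4 and G3/A4 combinations.
#' @return 4 x 4 matrix (rows = site 3, cols = site 4).
#' @export
re_pair_matrix <- function(GT = 0, GA = 0) {
  m <- .zero_mat()
  m["G", "T"] <- GT
  m["G", "A"] <- GA
  rest <- -(GT + GA) / 2
  m["G", "C"] <- rest
  m["G", "G"] <- rest
  for (cc in NUCLEOTIDES) {
    for (rr in setdiff(NUCLEOTIDES, "G")) m[rr, cc] <- -m["G", cc] / 3
  }
  m
}

# true (noise-free) cell means over the full 8 x 16 factorial
.cell_means <- function(params) {
  jg <- enumerate_joint_genotypes()
  U <- .base_wyk(jg$protein, jg$re)[, c("a", "b", "c")]
  n3 <- substr(jg$re, 1, 1)
  n4 <- substr(jg$re, 2, 2)
  mu <- rep(params$grand_mean, nrow(jg))
  mu <- mu + params$re3[n3] + params$re4[n4] + params$re_pair[cbind(n3, n4)]
  for (i in 1:3) mu <- mu + 0.5 * U[, i] * params$protein[[PROTEIN_SITES[i]]]
  pp_cols <- list(`site25:site26` = U[, "a"] * U[, "b"],
                  `site25:site29` = U[, "a"] * U[, "c"],
                  `site26:site29` = U[, "b"] * U[, "c"])
  for (pp in .PP_NAMES) mu <- mu + 0.5 * pp_cols[[pp]] * params$protein_pair[[pp]]
  for (ps in names(params$cross)) {
    u <- U[, .site_letter[[ps]]]
    for (rs in names(params$cross[[ps]])) {
      nuc <- if (rs == "3") n3 else n4
      mu <- mu + 0.5 * u * params$cross[[ps]][[rs]][nuc]
    }
  }
  for (ps in names(params$cross_pair)) {
    u <- U[, .site_letter[[ps]]]
    mu <- mu + 0.5 * u * params$cross_pair[[ps]][cbind(n3, n4)]
  }
  for (pp in names(params$cross_pp)) {
    u <- pp_cols[[pp]]
    for (rs in names(params$cross_pp[[pp]])) {
      nuc <- if (rs == "3") n3 else n4
      mu <- mu + 0.5 * u * params$cross_pp[[pp]][[rs]][nuc]
    }
  }
  data.frame(protein = jg$protein, re = jg$re, dG_true = unname(mu),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic landscape and replicate measurement table
#'
#' Each cell mean is the grand mean plus all applicable state effects
#' (built with the same encoding contracts the regression models use);
#' replicates add independent Gaussian noise.  Deterministic under `seed`.
#'
#' @param params a [landscape_params()].
#' @param seed optional integer seed.
#' @return list of class `synthetic_landscape` with `measurements`
#'   (protein, re, replicate, dG), `landscape` (replicate means: protein,
#'   re, mean_dG), `truth` (noise-free cell means) and `params`.
#' @export
generate_landscape <- function(params, seed = NULL) {
  stopifnot(inherits(params, "landscape_params"))
  if (!is.null(seed)) set.seed(seed)
  truth <- .cell_means(params)
  r <- params$replicates
  meas <- truth[rep(seq_len(nrow(truth)), each = r), c("protein", "re"), drop = FALSE]
  meas$replicate <- rep(seq_len(r), times = nrow(truth))
  mu <- rep(truth$dG_true, each = r)
  meas$dG <- mu + if (params$noise_sd > 0) {
    stats::rnorm(length(mu), 0, params$noise_sd)
  } else 0
  rownames(meas) <- NULL
  agg <- stats::aggregate(dG ~ protein + re, data = meas, FUN = mean)
  names(agg)[names(agg) == "dG"] <- "mean_dG"
  key <- joint_label(truth$protein, truth$re)
  agg <- agg[match(key, joint_label(agg$protein, agg$re)), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(measurements = meas, landscape = agg, truth = truth,
                 params = params), class = "synthetic_landscape")
}

#' Generative preset for the ancestral receptor's RE preferences
#'
#' Encodes the reported determinants of the ancestral protein's affinity
#' across RE space: a 1.0 kcal/mol preference for G at site 3, 0.5 kcal/mol
#' for T at site 4, an extra 0.8 kcal/mol for the G3/T4 combination, a
#' negative G3/A4 contrast (magnitude not reported; -0.5 placeholder), and
#' a 1.3 kcal/mol average-affinity gain from the site-25 substitution.
#' Quantities whose magnitudes are not printed in the source study's text
#' (state-effect splits among non-preferred nucleotides, the grand mean,
#' the other substitution effects) are documented placeholders; the
#' `provenance` field of the result tags each parameter as "paper" or
#' "placeholder".
#'
#' @param noise_sd,replicates forwarded to [landscape_params()].
#' @return a [landscape_params()] object.
#' @export
preset_ancsr1 <- function(noise_sd = 0, replicates = 3) {
  re3 <- stats::setNames(c(-1 / 3, -1 / 3, 1.0, -1 / 3), NUCLEOTIDES)
  re4 <- stats::setNames(c(-0.5 / 3, -0.5 / 3, -0.5 / 3, 0.5), NUCLEOTIDES)
  landscape_params(
    grand_mean = 10,
    re3 = re3, re4 = re4,
    re_pair = re_pair_matrix(GT = 0.8, GA = -0.5),
    protein = c(site25 = 1.3, site26 = -0.5, site29 = -0.4),
    noise_sd = noise_sd, replicates = replicates,
    provenance = c(
      re3_G = "paper", re3_other = "placeholder",
      re4_T = "paper", re4_other = "placeholder",
      re_pair_GT = "paper", re_pair_GA_sign = "paper",
      re_pair_GA_magnitude = "placeholder", re_pair_fill = "placeholder",
      protein_site25 = "paper",
      protein_site26_sign = "paper", protein_site26_magnitude = "placeholder",
      protein_site29_sign = "paper", protein_site29_magnitude = "placeholder",
      grand_mean = "placeholder"
    )
  )
}

.center_vec <- function(x) stats::setNames(x - mean(x), NUCLEOTIDES)
.center_mat <- function(m) {
  m <- sweep(m, 1, rowMeans(m))
  m <- sweep(m, 2, colMeans(m))
  dimnames(m) <- list(NUCLEOTIDES, NUCLEOTIDES)
  m
}

#' Draw a random valid parameter set
#'
#' All effect classes (main, pairwise, cross-interface, third-order) are
#' drawn from centered Gaussians of scale `sd`, so zero-sum constraints
#' hold exactly.  Useful for property-style round-trip tests.
#'
#' @param seed integer seed.
#' @param sd scale of the drawn effects (kcal/mol).
#' @param noise_sd,replicates forwarded to [landscape_params()].
#' @return a [landscape_params()] object.
#' @export
random_landscape_params <- function(seed = NULL, sd = 0.5, noise_sd = 0,
                                    replicates = 1) {
  if (!is.null(seed)) set.seed(seed)
  cross <- list(); cross_pair <- list(); cross_pp <- list()
  for (ps in PROTEIN_SITES) {
    cross[[ps]] <- list(`3` = .center_vec(stats::rnorm(4, 0, sd)),
                        `4` = .center_vec(stats::rnorm(4, 0, sd)))
    cross_pair[[ps]] <- .center_mat(matrix(stats::rnorm(16, 0, sd), 4, 4))
  }
  for (pp in .PP_NAMES) {
    cross_pp[[pp]] <- list(`3` = .center_vec(stats::rnorm(4, 0, sd)),
                           `4` = .center_vec(stats::rnorm(4, 0, sd)))
  }
  landscape_params(
    grand_mean = stats::rnorm(1, 10, 1),
    re3 = .center_vec(stats::rnorm(4, 0, sd)),
    re4 = .center_vec(stats::rnorm(4, 0, sd)),
    re_pair = .center_mat(matrix(stats::rnorm(16, 0, sd), 4, 4)),
    protein = stats::setNames(stats::rnorm(3, 0, sd), PROTEIN_SITES),
    protein_pair = stats::setNames(stats::rnorm(3, 0, sd), .PP_NAMES),
    cross = cross, cross_pair = cross_pair, cross_pp = cross_pp,
    noise_sd = noise_sd, replicates = replicates
  )
}

#' Simulate a fluorescence-anisotropy titration
#'
#' Hyperbolic single-site anisotropy values plus Gaussian noise;
#' deterministic under `seed`.
#'
#' @param kd dissociation constant, molar (> 0).
#' @param baseline,plateau free and bound anisotropy.
#' @param concentrations protein concentrations, molar (>= 5 values).
#' @param noise_sd Gaussian anisotropy noise sd.
#' @param seed optional integer seed.
#' @inheritParams titration_curve
#' @return a [titration_curve()].
#' @export
generate_titration <- function(kd, baseline = 0.05, plateau = 0.25,
                               concentrations = 10^seq(-9, -5, length.out = 12),
                               noise_sd = 0, seed = NULL,
                               protein = NA, re = NA, replicate = NA,
                               probe_conc_M = 5e-9) {
  if (!is.finite(kd) || kd <= 0) stop("Kd must be positive", call. = FALSE)
  if (length(concentrations) < 5L) {
    stop("at least 5 concentrations required", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  A <- .hyperbola(concentrations, baseline, plateau, kd)
  if (noise_sd > 0) A <- A + stats::rnorm(length(A), 0, noise_sd)
  titration_curve(concentrations, A, protein = protein, re = re,
                  replicate = replicate, probe_conc_M = probe_conc_M)
}

#' Named pathway-analysis fixtures
#'
#' Deterministic landscapes (and, where noted, functional-call objects)
#' with known accessibility structure, for exercising the pathway module:
#' \describe{
#'   \item{all_functional_calls}{a `functional_calls` object marking all
#'     128 complexes functional (the strict grand-mean criterion can never
#'     produce this itself), giving the full 576-edge joint graph.}
#'   \item{every_protein_functional}{landscape in which each protein's GT
#'     complex is boosted above the grand mean: all 6 protein orderings
#'     accessible.}
#'   \item{none_functional}{uniform landscape: no complex passes the strict
#'     grand-mean criterion.}
#'   \item{single_gateway}{only the site-25 replacement leads away from the
#'     all-ancestral protein to a functional TF, so every accessible
#'     ordering starts with it.}
#'   \item{separable}{functional set is a Cartesian product of a protein
#'     set and an RE set: no cross-molecule gating events exist.}
#'   \item{permissive_4node}{hand-built case in which the RE move GT -> TT
#'     is inadmissible from the all-ancestral protein but admissible after
#'     the site-25 replacement.}
#' }
#'
#' @return named list; each element has `landscape` and/or `calls` plus an
#'   `expect` note describing the known outcome.
#' @export
pathway_fixtures <- function() {
  jg <- enumerate_joint_genotypes()
  base <- function(value = 8) data.frame(protein = jg$protein, re = jg$re,
                                         mean_dG = value, stringsAsFactors = FALSE)
  set_cell <- function(ls, protein, re, value) {
    ls$mean_dG[ls$protein == protein & ls$re == re] <- value
    ls
  }
  pg <- enumerate_protein_genotypes()$label
  anc <- pg[1]
  fx <- list()

  calls_all <- data.frame(protein = jg$protein, re = jg$re,
                          mean_dG = 12, functional = TRUE,
                          stringsAsFactors = FALSE)
  class(calls_all) <- c("functional_calls", "data.frame")
  fx$all_functional_calls <- list(
    calls = calls_all,
    expect = "joint graph has 128 nodes and 576 edges")

  ls <- base()
  for (p in pg) ls <- set_cell(ls, p, "GT", 12)
  fx$every_protein_functional <- list(
    landscape = ls,
    expect = "all 6 protein orderings accessible")

  fx$none_functional <- list(
    landscape = base(10),
    expect = "uniform landscape: zero functional complexes")

  # single gateway: from the all-ancestral protein only the site25
  # replacement leads to a protein with a functional RE
  ls <- base()
  ls <- set_cell(ls, anc, "GT", 13)
  site25_der <- grepl("^GLY", pg)
  for (p in pg[site25_der]) ls <- set_cell(ls, p, "GT", 12.5)
  for (p in pg[site25_der]) ls <- set_cell(ls, p, "AA", 12.5)
  fx$single_gateway <- list(
    landscape = ls,
    expect = "accessible orderings all start with site25")

  # separable: functional set = {site25-derived proteins} x {GT, AA}
  ls <- base()
  for (p in pg) for (r in c("GT", "AA")) ls <- set_cell(ls, p, r, 12)
  fx$separable <- list(
    landscape = ls,
    expect = "functional set is a product set: no cross-molecule gating")

  # permissive 4-node case: anc:GT, GLY:GT, GLY:TT functional; anc:TT not
  ls <- base()
  gly <- "GLY-gly-ala"
  ls <- set_cell(ls, anc, "GT", 12)
  ls <- set_cell(ls, gly, "GT", 12)
  ls <- set_cell(ls, gly, "TT", 12)
  fx$permissive_4node <- list(
    landscape = ls,
    expect = "site25 replacement is permissive for the RE move GT -> TT at the ancestral complex")

  fx
}
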