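# Regression of structural summary features (hydrogen-bond counts,
# contact-pair counts from simulation) against measured binding energy.

#' Correlate a structural feature with binding energy
#'
#' Ordinary least squares of mean dG on the feature mean, either globally
#' over all complexes or separately per protein genotype (16 REs each).
#' Each regression is classified as `positive` (slope > 0 and p < alpha),
#' `negative` (slope < 0 and p < alpha) or `NS`; features with zero
#' variance within a group are `NS` with `zero_variance = TRUE`.  Replicate
#' SEMs in the feature table are carried through for display only; the fit
#' is unweighted.
#'
#' @param features data.frame with columns `protein`, `re`, `feature`,
#'   `mean` (and optionally `sem`, `n`).
#' @param landscape data.frame (protein, re, mean_dG) or
#'   `synthetic_landscape`.
#' @param grouping "global" or "per_protein".
#' @param feature optional feature name to select when `features` holds
#'   several.
#' @param alpha significance level (default 0.05, unadjusted).
#' @param bonferroni if TRUE, multiply p-values by the number of groups
#'   before classification.
#' @return data.frame of class `correlation_results`: one row per group
#'   with `group`, `feature`, `slope`, `intercept`, `p`, `r_squared`,
#'   `class`, `zero_variance`, `n`.
#' @export
regress_feature <- function(features, landscape,
                            grouping = c("global", "per_protein"),
                            feature = NULL, alpha = 0.05,
                            bonferroni = FALSE) {
  grouping <- match.arg(grouping)
  ls <- .as_landscape(landscape)
  if (!is.null(feature)) features <- features[features$feature == feature, , drop = FALSE]
  if (length(unique(features$feature)) != 1L) {
    stop("features table must contain exactly one feature (use `feature=`)",
         call. = FALSE)
  }
  key <- joint_label(features$protein, features$re)
  lkey <- joint_label(ls$protein, ls$re)
  if (!all(lkey %in% key)) {
    stop("feature table is missing genotypes present in the landscape: ",
         paste(utils::head(setdiff(lkey, key), 5), collapse = ", "),
         call. = FALSE)
  }
  merged <- data.frame(protein = ls$protein, re = ls$re, dG = ls$mean_dG,
                       x = features$mean[match(lkey, key)],
                       stringsAsFactors = FALSE)
  groups <- if (grouping == "global") list(global = merged) else
    split(merged, merged$protein)
  nfam <- if (bonferroni) length(groups) else 1L

  rows <- lapply(names(groups), function(gname) {
    d <- groups[[gname]]
    if (grouping == "per_protein" && nrow(d) != 16L) {
      stop("per-protein grouping requires all 16 REs for protein ", gname,
           call. = FALSE)
    }
    if (stats::var(d$x) < .Machine$double.eps) {
      return(data.frame(group = gname, slope = NA_real_, intercept = mean(d$dG),
                        p = NA_real_, r_squared = NA_real_, class = "NS",
                        zero_variance = TRUE, n = nrow(d),
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(dG ~ x, data = d)
    sm <- summary(fit)
    slope <- unname(stats::coef(fit)["x"])
    p <- min(1, sm$coefficients["x", "Pr(>|t|)"] * nfam)
    cls <- if (p < alpha && slope > 0) "positive"
           else if (p < alpha && slope < 0) "negative" else "NS"
    data.frame(group = gname, slope = slope,
               intercept = unname(stats::coef(fit)["(Intercept)"]),
               p = p, r_squared = sm$r.squared, class = cls,
               zero_variance = FALSE, n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$feature <- unique(features$feature)
  rownames(out) <- NULL
  class(out) <- c("correlation_results", "data.frame")
  out
}
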