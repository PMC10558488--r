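#' Depression slope: abundance-dependent fold-change decline
#'
#' OLS slope of log2 fold change on log10 molar concentration, reported in
#' permille (slope x 1000): the change in log2 FC per decade of protein
#' abundance, per mille. Negative values indicate that abundant proteins of
#' the group decline more.
#'
#' @param conc_mM Positive molar concentrations (one per protein).
#' @param log2fc Matching log2 fold changes.
#' @return List: `slope_permille`, `slope` (raw), `intercept`, `n`,
#'   `ci_permille` (95% CI on the permille scale), `definition` (the
#'   convention, emitted with every report).
#' @export
#' @examples
#' x <- c(1e-4, 1e-3, 1e-2, 1e-1, 1)
#' depression_slope(x, -0.1 * log10(x))$slope_permille  # -100
depression_slope <- function(conc_mM, log2fc) {
  stopifnot(length(conc_mM) == length(log2fc))
  ok <- !is.na(conc_mM) & !is.na(log2fc) & conc_mM > 0
  x <- log10(conc_mM[ok]); y <- log2fc[ok]
  if (length(x) < 3) stop("depression slope needs at least 3 proteins with positive concentration")
  if (stats::sd(x) == 0) stop("degenerate concentrations: all equal on the log scale")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  ci <- stats::confint(fit, "x", level = 0.95)
  list(slope_permille = 1000 * slope, slope = slope,
       intercept = unname(stats::coef(fit)[1]), n = length(x),
       ci_permille = 1000 * c(lower = ci[1], upper = ci[2]),
       definition = "OLS slope of log2 FC on log10 concentration (mM), x1000")
}

#' High/low by up/down classification with a Fisher enrichment test
#'
#' Proteins are split into high/low abundance and up/down fold change, and the
#' focal group's enrichment in the high-down cell is tested with Fisher's
#' exact test (two-sided). Two split rules:
#'
#' * `"mean"`: high iff log10 concentration exceeds the mean log10
#'   concentration of the analyzed set (the concentration axis is
#'   logarithmic throughout; `mean_scale = "linear"` switches to the linear
#'   mean).
#' * `"quartile"`: high iff the concentration exceeds the 75th percentile of
#'   an external reference proteome (`reference_conc`), mirroring the use of
#'   published abundance estimates.
#'
#' Ties at the threshold go to "low"; proteins with log2 FC exactly 0 are
#' excluded from up/down.
#'
#' @param conc Named positive concentrations for all analyzed proteins.
#' @param log2fc Named log2 fold changes (same ids).
#' @param focal_ids Ids of the focal group (e.g. NIA+B6+PA enzymes).
#' @param split `"mean"` or `"quartile"`.
#' @param reference_conc Reference proteome concentrations (required for the
#'   quartile rule).
#' @param mean_scale `"log"` (default) or `"linear"` for the mean split.
#' @return List: `counts` (2x2x2 tibble of group x abundance x direction),
#'   `table` (2x2 focal-membership x high-down), `fisher_p`, `threshold`,
#'   `split` (rule tag recorded in output), `n_excluded_zero_fc`.
#' @export
binary_classify <- function(conc, log2fc, focal_ids,
                            split = c("mean", "quartile"),
                            reference_conc = NULL,
                            mean_scale = c("log", "linear")) {
  split <- match.arg(split)
  mean_scale <- match.arg(mean_scale)
  ids <- intersect(names(conc), names(log2fc))
  if (any(conc[ids] <= 0)) stop("concentrations must be positive")
  focal_ids <- intersect(focal_ids, ids)
  if (length(focal_ids) == 0) stop("focal group is empty after matching ids")
  threshold <- switch(split,
    mean = if (mean_scale == "log") 10^mean(log10(conc[ids])) else mean(conc[ids]),
    quartile = {
      if (is.null(reference_conc)) stop("quartile split needs `reference_conc`")
      unname(stats::quantile(reference_conc, 0.75, type = 7))
    })
  high <- conc[ids] > threshold           # ties -> low
  dir_ok <- log2fc[ids] != 0              # exact 0 excluded from up/down
  down <- log2fc[ids] < 0
  focal <- ids %in% focal_ids
  keep <- dir_ok
  counts <- dplyr::count(
    tibble::tibble(group = factor(ifelse(focal[keep], "focal", "other"),
                                  c("focal", "other")),
                   abundance = factor(ifelse(high[keep], "high", "low"),
                                      c("high", "low")),
                   direction = factor(ifelse(down[keep], "down", "up"),
                                      c("down", "up"))),
    .data$group, .data$abundance, .data$direction, .drop = FALSE)
  high_down <- high[keep] & down[keep]
  tab <- table(factor(focal[keep], c(TRUE, FALSE), c("focal", "other")),
               factor(high_down, c(TRUE, FALSE), c("high_down", "rest")))
  p <- stats::fisher.test(tab)$p.value
  list(counts = counts, table = tab, fisher_p = p, threshold = threshold,
       split = paste0(split, if (split == "mean") paste0("_", mean_scale, "10")),
       n_excluded_zero_fc = sum(!dir_ok))
}

#' Abundance-weighted fraction of a member set
#'
#' Percentage of the summed concentration of the members relative to the
#' summed concentration of a specified denominator group.
#'
#' @param member_ids Members of the numerator set (must be a subset of
#'   `names(conc)`).
#' @param conc Named concentrations of the denominator group.
#' @return Percent in `[0, 100]`.
#' @export
abundance_weighted_fraction <- function(member_ids, conc) {
  member_ids <- unique(member_ids)
  missing_ids <- setdiff(member_ids, names(conc))
  if (length(missing_ids) > 0) {
    stop("member id(s) absent from the denominator group: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  denom <- sum(conc)
  if (denom <= 0) stop("denominator group has zero total abundance")
  100 * sum(conc[member_ids]) / denom
}

#' Cofactor-dummy multiple regression with collinearity diagnostics
#'
#' OLS of log2 fold change on a focal-group dummy (1 for e.g. NIA/B6/PA
#' enzymes, 0 for other enzymes) plus log10 molar concentration. Reports
#' partial two-sided p-values, non-adjusted multiple R-squared, and the
#' generalized variance-inflation factor per predictor, `GVIF_j =
#' 1 / (1 - R_j^2)` with `R_j^2` from regressing predictor j on the other.
#'
#' @param log2fc Response vector.
#' @param is_focal Logical or 0/1 dummy vector.
#' @param conc_mM Positive concentrations.
#' @return List of class `cofactor_regression`: `coefficients` tibble
#'   (term, estimate, p), `r_squared`, `gvif` (named), `n`, `fit` (the `lm`).
#' @export
cofactor_regression <- function(log2fc, is_focal, conc_mM) {
  stopifnot(length(log2fc) == length(is_focal), length(log2fc) == length(conc_mM))
  ok <- !is.na(log2fc) & !is.na(is_focal) & !is.na(conc_mM) & conc_mM > 0
  y <- log2fc[ok]; d <- as.numeric(is_focal[ok]); x <- log10(conc_mM[ok])
  if (length(y) < 10) stop("regression needs at least 10 enzymes")
  if (length(unique(d)) < 2) stop("both dummy levels must be present")
  if (stats::sd(x) == 0) stop("degenerate abundance predictor: all equal")
  r_dx <- stats::cor(d, x)
  if (abs(r_dx) >= 1 - 1e-12) {
    stop("perfect collinearity between predictors 'focal dummy' and 'log10 abundance'")
  }
  fit <- stats::lm(y ~ d + x)
  sm <- summary(fit)
  coefs <- tibble::tibble(
    term = c("intercept", "focal_dummy", "log10_abundance"),
    estimate = unname(stats::coef(fit)),
    p = unname(sm$coefficients[, "Pr(>|t|)"]))
  # with two predictors both R_j^2 equal the squared predictor correlation
  gvif <- 1 / (1 - r_dx^2)
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 gvif = c(focal_dummy = gvif, log10_abundance = gvif),
                 n = length(y), fit = fit),
            class = "cofactor_regression")
}

#' @export
print.cofactor_regression <- function(x, ...) {
  cat(sprintf("<cofactor_regression> n = %d, R^2 = %.4f\n", x$n, x$r_squared))
  print(x$coefficients)
  cat("GVIF:", paste(sprintf("%s %.4f", names(x$gvif), x$gvif), collapse = ", "), "\n")
  invisible(x)
}
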