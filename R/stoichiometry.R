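#' Log-log regression of paired molar concentrations
#'
#' Ordinary least squares on (log10 x, log10 y) with Pearson's correlation and
#' its two-sided p-value computed on the logged data. Pairs with a nonpositive
#' member are excluded (not offset-shifted) and counted.
#'
#' @param x_mM,y_mM Paired numeric vectors (e.g. metabolite and enzyme-pool
#'   molarities).
#' @return A list of class `loglog_fit`: `slope`, `intercept`, `pearson_r`,
#'   `p`, `n` (pairs used), `excluded` (nonpositive pairs dropped).
#' @export
#' @examples
#' f <- loglog_fit(c(1, 2, 4, 8, 16), 3 * c(1, 2, 4, 8, 16)^2)
#' c(f$slope, f$pearson_r)  # 2, 1
loglog_fit <- function(x_mM, y_mM) {
  stopifnot(length(x_mM) == length(y_mM))
  ok <- !is.na(x_mM) & !is.na(y_mM) & x_mM > 0 & y_mM > 0
  excluded <- sum(!ok)
  lx <- log10(x_mM[ok]); ly <- log10(y_mM[ok])
  if (length(lx) < 3) stop("log-log fit needs at least 3 usable pairs")
  fit <- stats::lm(ly ~ lx)
  sx <- stats::sd(lx)
  if (sx == 0) stop("degenerate x: all logged values equal")
  if (stats::sd(ly) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(lx, ly)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = r, p = p, n = length(lx), excluded = excluded),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("<loglog_fit> slope %.4g, intercept %.4g, r %.4g (p %.3g), n %d (%d excluded)\n",
              x$slope, x$intercept, x$pearson_r, x$p, x$n, x$excluded))
  invisible(x)
}

#' Metabolite:enzyme molar ratio with the gray-zone flag
#'
#' The ratio of an object's aggregate metabolite molarity to its aggregate
#' enzyme molarity, and whether it falls in the "gray zone" of near one-to-one
#' stoichiometry: `|log10 ratio| <= 1` (closed interval, i.e. ratio in
#' `[0.1, 10]`).
#'
#' @param objects Tibble from [build_cofactor_objects()], or any data frame
#'   with `object`, `metabolite_mM`, `enzyme_mM` columns.
#' @return The input with `ratio`, `log10_ratio`, `in_gray_zone` columns.
#' @export
molar_ratio <- function(objects) {
  objects <- tibble::as_tibble(objects)
  if (any(objects$enzyme_mM <= 0)) {
    stop("undefined molar ratio (enzyme_mM = 0) for object(s): ",
         paste(objects$object[objects$enzyme_mM <= 0], collapse = ", "))
  }
  dplyr::mutate(objects,
                ratio = .data$metabolite_mM / .data$enzyme_mM,
                log10_ratio = log10(.data$ratio),
                in_gray_zone = abs(.data$log10_ratio) <= 1)
}

#' Cross-species molar-ratio summary
#'
#' Per-species median ratio, plus per-vitamin cross-species means: the
#' geometric mean (mean of log10 ratios, back-transformed alongside) as the
#' primary "average", with the arithmetic mean of ratios also reported.
#'
#' @param ratios Tibble from [molar_ratio()] with an added `species` column.
#' @return List with tibbles `per_species` (median, n, fraction in gray zone)
#'   and `per_object` (mean log10 ratio across species, geometric and
#'   arithmetic mean ratios).
#' @export
species_ratio_summary <- function(ratios) {
  ratios <- tibble::as_tibble(ratios)
  if (!"species" %in% names(ratios)) stop("ratio table needs a 'species' column")
  per_species <- dplyr::summarise(
    dplyr::group_by(ratios, .data$species),
    median_ratio = stats::median(.data$ratio),
    n = dplyr::n(),
    gray_zone_fraction = mean(.data$in_gray_zone),
    .groups = "drop")
  per_object <- dplyr::summarise(
    dplyr::group_by(ratios, .data$object),
    mean_log10_ratio = mean(.data$log10_ratio),
    geometric_mean_ratio = 10^mean(.data$log10_ratio),
    arithmetic_mean_ratio = mean(.data$ratio),
    n_species = dplyr::n(),
    .groups = "drop")
  list(per_species = per_species, per_object = per_object)
}

#' Linear fit of enzyme fold-change response to metabolite fold change
#'
#' OLS of enzyme log2 fold change on metabolite log2 fold change across
#' experimental models, for one cofactor object. The starvation model can be
#' excluded to isolate the tumor-bearing response.
#'
#' @param metab_fc_by_model,enzyme_fc_by_model Named numeric vectors of linear
#'   fold changes, names = model labels; matched by name.
#' @param exclude Model labels to leave out (e.g. `"STRV"`); default none.
#' @return A `loglog_fit`-shaped list (slope/intercept/r/p/n on the log2
#'   scale); `pearson_r` is `NA` and the slope 0 when the response is constant.
#' @export
linear_response_fit <- function(metab_fc_by_model, enzyme_fc_by_model,
                                exclude = character()) {
  models <- setdiff(intersect(names(metab_fc_by_model), names(enzyme_fc_by_model)),
                    exclude)
  if (length(models) < 3) stop("response fit needs at least 3 models with both fold changes")
  x <- log2(metab_fc_by_model[models])
  y <- log2(enzyme_fc_by_model[models])
  if (stats::sd(x) == 0) stop("degenerate metabolite fold changes: all equal")
  if (stats::sd(y) == 0) {
    return(structure(list(slope = 0, intercept = unname(mean(y)),
                          pearson_r = NA_real_, p = NA_real_,
                          n = length(models), excluded = length(exclude)),
                     class = "loglog_fit"))
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = unname(ct$estimate), p = ct$p.value,
                 n = length(models), excluded = length(exclude)),
            class = "loglog_fit")
}
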