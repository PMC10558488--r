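#' Concentration matrix container
#'
#' A `conc_matrix` is a numeric entities-by-samples matrix carrying a unit tag
#' and an entity kind. Values are non-negative or `NA` (missing). Row names are
#' the entity ids, column names the sample ids; both must be unique.
#'
#' @param values Numeric matrix with unique rownames (entity ids) and unique
#'   colnames (sample ids). Present values must be non-negative.
#' @param unit One of `"umol_per_g"`, `"mM"`, `"share"`, `"ppm"`,
#'   `"mg_per_100g"`, `"intensity"`.
#' @param entity_kind One of `"metabolite"`, `"protein"`, `"transcript"`.
#' @return A `conc_matrix` object.
#' @export
#' @examples
#' m <- conc_matrix(matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
#'                  unit = "mM", entity_kind = "metabolite")
#' entity_ids(m)
conc_matrix <- function(values, unit, entity_kind) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  unit <- match.arg(unit, conc_units())
  entity_kind <- match.arg(entity_kind, c("metabolite", "protein", "transcript"))
  # a zero-extent dimension legitimately has no names (R normalizes them away)
  if ((is.null(rownames(values)) && nrow(values) > 0) ||
      (is.null(colnames(values)) && ncol(values) > 0)) {
    stop("`values` must carry entity ids as rownames and sample ids as colnames")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    stop("duplicate entity id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
  structure(values, unit = unit, entity_kind = entity_kind,
            class = c("conc_matrix", "matrix", "array"))
}

conc_units <- function() {
  c("umol_per_g", "mM", "share", "ppm", "mg_per_100g", "intensity")
}

#' @rdname conc_matrix
#' @param m A `conc_matrix`.
#' @export
entity_ids <- function(m) rownames(m)

#' @rdname conc_matrix
#' @export
sample_ids <- function(m) colnames(m)

#' @rdname conc_matrix
#' @export
conc_unit <- function(m) attr(m, "unit")

#' @rdname conc_matrix
#' @export
entity_kind <- function(m) attr(m, "entity_kind")

#' @export
print.conc_matrix <- function(x, ...) {
  cat(sprintf("<conc_matrix> %d %s(s) x %d sample(s), unit '%s', %d missing\n",
              nrow(x), attr(x, "entity_kind"), ncol(x), attr(x, "unit"),
              sum(is.na(x))))
  invisible(x)
}

# matrix-style subsetting keeps the class and tags; vector-style subsetting
# (single index) falls back to the plain values
#' @export
`[.conc_matrix` <- function(x, i, j, ...) {
  if (nargs() <= 2) return(unclass(x)[i])
  out <- unclass(x)[i, j, drop = FALSE]
  conc_matrix(out, unit = attr(x, "unit"), entity_kind = attr(x, "entity_kind"))
}

#' Read a delimited concentration table
#'
#' Reads a CSV/TSV file whose first column holds entity ids and whose remaining
#' columns are samples. Cells that do not parse as numbers (including empty
#' cells, `"NA"`, `"NaN"`) become missing values; negative values are rejected.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma) unless `delim` is given.
#' @param unit,entity_kind Tags for the resulting matrix (see [conc_matrix()]).
#' @param delim Optional delimiter override.
#' @return A [conc_matrix()].
#' @export
read_concentration_table <- function(path, unit, entity_kind, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  if (ncol(raw) < 2) stop("expected an id column plus at least one sample column")
  ids <- as.character(raw[[1]])
  vals <- vapply(raw[-1], function(col) {
    suppressWarnings(as.numeric(dplyr::na_if(trimws(col), "")))
  }, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, names(raw)[-1]))
  vals[is.nan(vals)] <- NA_real_
  if (any(vals < 0, na.rm = TRUE)) stop("negative concentration values in ", path)
  conc_matrix(vals, unit = unit, entity_kind = entity_kind)
}

#' Write a concentration table
#'
#' Inverse of [read_concentration_table()]: one `entity_id` column then one
#' column per sample. Missing values are written as `NA`. Full double precision
#' is kept so that a write/read round trip reproduces values bit-identically.
#'
#' @param m A [conc_matrix()].
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @export
write_concentration_table <- function(m, path) {
  df <- tibble::as_tibble(unclass(m), rownames = "entity_id")
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  # format() at 17 significant digits round-trips IEEE doubles exactly
  num <- dplyr::mutate(df, dplyr::across(
    -"entity_id", ~ ifelse(is.na(.x), "NA", format(.x, digits = 17, trim = TRUE,
                                                   scientific = TRUE))))
  readr::write_delim(num, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Missing-value rules for metabolome and proteome matrices
#'
#' Three small filters mirror standard CE-MS metabolomics / TMT proteomics
#' preprocessing: metabolite rows missing in every sample are dropped, the
#' remaining missing metabolite cells are imputed with half the global minimum
#' of all present values, and protein rows containing any missing value are
#' dropped outright (proteins are never imputed).
#'
#' @param m A [conc_matrix()].
#' @return A filtered/imputed [conc_matrix()].
#' @export
drop_all_missing_entities <- function(m) {
  keep <- rowSums(!is.na(m)) > 0
  m[keep, , drop = FALSE]
}

#' @rdname drop_all_missing_entities
#' @export
impute_half_minimum <- function(m) {
  out <- unclass(m)
  present <- !is.na(out)
  if (!any(present)) stop("cannot impute a matrix with no present values")
  fill <- 0.5 * min(out[present])
  out[!present] <- fill
  conc_matrix(out, unit = conc_unit(m), entity_kind = entity_kind(m))
}

#' @rdname drop_all_missing_entities
#' @export
drop_incomplete_proteins <- function(m) {
  keep <- rowSums(is.na(m)) == 0
  if (!any(keep)) warning("all proteins contain missing values; result is empty")
  m[keep, , drop = FALSE]
}

#' Median-ratio normalization against a reference sample
#'
#' Each sample is divided by its scale factor, the median over entities of the
#' per-entity ratio of that sample to the reference sample. Afterwards the
#' median per-entity ratio of every sample to the reference equals 1. Entities
#' whose reference value is 0 are excluded from the scale-factor median with a
#' warning.
#'
#' @param m A complete (no missing) [conc_matrix()].
#' @param reference_sample A sample id present in `m`.
#' @return The normalized matrix, with a `"scale_factors"` attribute.
#' @export
median_ratio_normalize <- function(m, reference_sample) {
  if (!reference_sample %in% sample_ids(m)) {
    stop("reference sample '", reference_sample, "' not in matrix")
  }
  if (anyNA(m)) stop("median-ratio normalization requires a complete matrix")
  ref <- unclass(m)[, reference_sample]
  usable <- ref > 0
  if (!all(usable)) {
    warning(sum(!usable), " entity(ies) with reference value 0 excluded from scale factors")
  }
  if (!any(usable)) stop("reference sample has no positive values")
  scales <- apply(unclass(m)[usable, , drop = FALSE], 2,
                  function(s) stats::median(s / ref[usable]))
  out <- sweep(unclass(m), 2, scales, "/")
  out <- conc_matrix(out, unit = conc_unit(m), entity_kind = entity_kind(m))
  attr(out, "scale_factors") <- scales
  out
}

#' Read a sample-design table
#'
#' @param path CSV with columns `sample_id`, `model`, `arm`
#'   (`experimental`/`control`) and optionally `tissue`, `sex`.
#' @return A tibble.
#' @export
read_sample_design <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_design(d)
}

validate_design <- function(design) {
  req <- c("sample_id", "model", "arm")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0) stop("design lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(design$arm), c("experimental", "control"))
  if (length(bad) > 0) stop("unknown arm label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  tibble::as_tibble(design)
}

design_samples <- function(m, design, model) {
  design <- validate_design(design)
  design <- design[design$model == model & design$sample_id %in% sample_ids(m), ]
  if (nrow(design) == 0) stop("model '", model, "' absent from design (or no samples in matrix)")
  list(exp = design$sample_id[design$arm == "experimental"],
       ctl = design$sample_id[design$arm == "control"])
}

#' Group fold changes for one model
#'
#' Fold change per entity is the ratio of the experimental-arm summary to the
#' control-arm summary on the linear scale. The default summary is the
#' arithmetic mean; `estimator = "median"` uses group medians instead.
#' Entities whose control summary is 0 are excluded and flagged in the
#' `"excluded"` attribute.
#'
#' @param m A [conc_matrix()].
#' @param design Sample design tibble (see [read_sample_design()]).
#' @param model Model label to compute fold changes for.
#' @param estimator `"mean"` (default) or `"median"`.
#' @return A tibble with columns `entity_id`, `model`, `fc`, `log2fc`,
#'   `n_exp`, `n_ctl`.
#' @export
group_fold_change <- function(m, design, model, estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  s <- design_samples(m, design, model)
  if (length(s$exp) < 1 || length(s$ctl) < 1) {
    stop("model '", model, "' needs at least one sample per arm")
  }
  f <- if (estimator == "mean") rowMeans else function(x) apply(x, 1, stats::median)
  me <- f(unclass(m)[, s$exp, drop = FALSE])
  mc <- f(unclass(m)[, s$ctl, drop = FALSE])
  ok <- !is.na(mc) & mc > 0 & !is.na(me)
  ratio <- unname(me[ok] / mc[ok])
  out <- tibble::tibble(entity_id = entity_ids(m)[ok], model = model,
                        fc = ratio, log2fc = log2(ratio),
                        n_exp = length(s$exp), n_ctl = length(s$ctl))
  attr(out, "excluded") <- entity_ids(m)[!ok]
  out
}

#' Volcano statistics: fold change plus Welch's t-test
#'
#' Attaches a per-entity two-sided Welch p-value (unequal-variance t-test on
#' the linear-scale values) to the group fold changes. Two exactly identical
#' groups yield p = 1; groups with zero pooled variance but different means
#' yield p = 0.
#'
#' @inheritParams group_fold_change
#' @return [group_fold_change()] output with a `p` column.
#' @export
welch_volcano <- function(m, design, model, estimator = c("mean", "median")) {
  s <- design_samples(m, design, model)
  if (length(s$exp) < 2 || length(s$ctl) < 2) {
    stop("Welch's test needs at least two samples per arm")
  }
  fc <- group_fold_change(m, design, model, estimator = match.arg(estimator))
  vals <- unclass(m)
  p <- vapply(fc$entity_id, function(id) {
    x <- vals[id, s$exp]
    y <- vals[id, s$ctl]
    welch_p(x, y)
  }, numeric(1))
  fc$p <- unname(p)
  fc
}

welch_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Write a fold-change table as TSV
#'
#' @param fc Tibble from [group_fold_change()] or [welch_volcano()].
#' @param path Output path.
#' @export
write_fold_change_table <- function(fc, path) {
  readr::write_tsv(fc, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_fold_change_table
#' @export
read_fold_change_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
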