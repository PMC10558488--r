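#' Compartment-matched subsampling of a proteome
#'
#' Draws protein id sets matched in compartment composition: within each
#' compartment (e.g. the NIA+B6+C1 enzymes, other enzymes, non-enzymes), the
#' requested number of ids is drawn without replacement. The default counts
#' mirror the muscle-proteome composition used when building adjusted liver
#' datasets: 96 + 292 + 669 = 1057 proteins.
#'
#' @param pools Named list: compartment -> character vector of candidate ids.
#' @param counts Named integer vector: compartment -> number to draw; names
#'   must match `pools`. Default `c(nia_b6_c1 = 96, other_enzymes = 292,
#'   non_enzymes = 669)`.
#' @param n_draws Number of independent draws.
#' @param seed Master seed; per-draw seeds are derived deterministically and
#'   returned, so any single draw can be regenerated.
#' @return List of class `matched_draws`: `draws` (list of character vectors),
#'   `counts`, `draw_seeds`.
#' @export
matched_subsample <- function(pools, counts = c(nia_b6_c1 = 96,
                                                other_enzymes = 292,
                                                non_enzymes = 669),
                              n_draws = 1000, seed = 1) {
  miss <- setdiff(names(counts), names(pools))
  if (length(miss) > 0) stop("no pool for compartment(s): ", paste(miss, collapse = ", "))
  too_small <- names(counts)[counts > lengths(pools)[names(counts)]]
  if (length(too_small) > 0) {
    stop("requested count exceeds pool size for compartment(s): ",
         paste(too_small, collapse = ", "))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  draws <- lapply(draw_seeds, function(s) {
    set.seed(s)
    unlist(lapply(names(counts), function(k) {
      sample(pools[[k]], counts[[k]], replace = FALSE)
    }), use.names = FALSE)
  })
  structure(list(draws = draws, counts = counts, draw_seeds = draw_seeds),
            class = "matched_draws")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' PCA scores with unit-variance scaling
#'
#' Centers and scales every variable to unit variance, then computes principal
#' components. Zero-variance variables are dropped with a warning.
#'
#' @param x Numeric matrix, observations in rows and variables in columns, or
#'   a [conc_matrix()] (transposed internally so samples become observations).
#' @return List: `scores` (observations x PCs), `loadings`,
#'   `contribution_pct` (percent variance per PC), `dropped` (zero-variance
#'   variable names).
#' @export
pca_scores <- function(x) {
  if (inherits(x, "conc_matrix")) x <- t(unclass(x))
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("PCA requires a complete matrix")
  if (nrow(x) < 3) stop("PCA needs at least 3 observations")
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped) > 0) {
    warning(length(dropped), " zero-variance variable(s) dropped before PCA")
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  contrib <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation,
       contribution_pct = stats::setNames(contrib, colnames(pc$x)),
       dropped = dropped)
}

#' Maximal margin of a linear SVM on 2-D scores
#'
#' Fits a linear soft-margin SVM (default cost 1) on the first two principal
#' component scores and reports the maximal-margin width, the shortest
#' Euclidean distance between the two margin lines: `2 / ||w||`. For
#' non-separable data the width is still reported, together with the number
#' of training points violating their margin.
#'
#' @param scores_2d Numeric matrix with 2 columns (e.g. PC1/PC2 scores).
#' @param labels Two-level factor/character vector, one per row.
#' @param cost Soft-margin cost parameter (default 1, the library default).
#' @param tolerance Optimizer termination tolerance passed to the solver.
#' @return List: `margin`, `w`, `b`, `separable`, `n_support_violations`,
#'   `labels_used`.
#' @export
svm_margin <- function(scores_2d, labels, cost = 1, tolerance = 0.001) {
  scores_2d <- as.matrix(scores_2d)
  stopifnot(ncol(scores_2d) == 2, nrow(scores_2d) == length(labels))
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("svm_margin needs exactly two classes")
  if (any(table(labels) < 1)) stop("each class needs at least one point")
  fit <- e1071::svm(scores_2d, labels, kernel = "linear", cost = cost,
                    scale = FALSE, type = "C-classification",
                    tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  f <- drop(scores_2d %*% w) + b
  # map internal +1 side to the class lying on the positive side
  y <- ifelse(labels == levels(labels)[which.max(
    tapply(f, labels, mean))], 1, -1)
  violations <- sum(y * f < 1 - 1e-6)
  list(margin = 2 / sqrt(sum(w^2)), w = w, b = b,
       separable = violations == 0, n_support_violations = violations,
       labels_used = levels(labels))
}

#' Compare resampled margins against a reference margin
#'
#' @param draw_margins Numeric vector of margins from resampled datasets
#'   (e.g. adjusted liver proteomes).
#' @param reference_margin Single margin to compare against (e.g. muscle).
#' @return List: `fraction_greater` (ties count as not greater),
#'   `median_ratio`, `summary` (median and IQR of draw margins), `margins`.
#' @export
margin_comparison <- function(draw_margins, reference_margin) {
  if (length(draw_margins) < 1) stop("need at least one draw margin")
  list(fraction_greater = mean(draw_margins > reference_margin),
       median_ratio = stats::median(draw_margins) / reference_margin,
       summary = c(median = stats::median(draw_margins),
                   q1 = unname(stats::quantile(draw_margins, 0.25)),
                   q3 = unname(stats::quantile(draw_margins, 0.75))),
       margins = draw_margins)
}

#' Margins over compartment-matched draws of a proteome matrix
#'
#' Convenience wrapper: for each matched draw, subsets the proteome matrix to
#' the drawn proteins, computes PCA scores over samples, and fits the linear
#' SVM between the two sample classes on PC1/PC2.
#'
#' @param m A complete protein [conc_matrix()] (or plain matrix, entities x
#'   samples).
#' @param sample_classes Named two-level vector: sample id -> class label
#'   (samples absent from it are excluded).
#' @param pools,counts,n_draws,seed Passed to [matched_subsample()].
#' @param cost SVM cost.
#' @return Tibble with one row per draw: `draw`, `margin`, `separable`,
#'   `n_support_violations`.
#' @export
resample_margins <- function(m, sample_classes, pools,
                             counts = c(nia_b6_c1 = 96, other_enzymes = 292,
                                        non_enzymes = 669),
                             n_draws = 1000, seed = 1, cost = 1) {
  vals <- if (inherits(m, "conc_matrix")) unclass(m) else m
  use <- intersect(colnames(vals), names(sample_classes))
  vals <- vals[, use, drop = FALSE]
  classes <- sample_classes[use]
  draws <- matched_subsample(pools, counts, n_draws, seed)
  rows <- purrr::imap(draws$draws, function(ids, i) {
    sub <- t(vals[ids, , drop = FALSE])
    pc <- suppressWarnings(pca_scores(sub))
    mg <- svm_margin(pc$scores[, 1:2, drop = FALSE], classes, cost = cost)
    tibble::tibble(draw = i, margin = mg$margin, separable = mg$separable,
                   n_support_violations = mg$n_support_violations)
  })
  dplyr::bind_rows(rows)
}
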