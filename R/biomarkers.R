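#' Permutation Jonckheere-Terpstra trend test over ordered groups
#'
#' The JT statistic is the sum over ordered group pairs (i < j) of
#' Mann-Whitney counts: pairs where the later group's value exceeds the
#' earlier group's, ties counted one half. The one-sided p-value is estimated
#' by permuting group membership, with the add-one estimator
#' `p = (1 + #extreme) / (1 + n_perm)` so p is never 0.
#'
#' @param groups List of numeric vectors in increasing group order (e.g. GPS
#'   0, 1, 2).
#' @param direction `"increasing"` (values rise with group order) or
#'   `"decreasing"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation draw (recorded in the output).
#' @return List of class `jt_trend`: `statistic`, `p`, `n_permutations`,
#'   `direction`, `seed`, `n` per group.
#' @export
#' @examples
#' jonckheere_trend(list(c(1, 2), c(3, 4), c(5, 6)), "increasing",
#'                  n_perm = 500, seed = 1)$p
jonckheere_trend <- function(groups, direction = c("increasing", "decreasing"),
                             n_perm = 10000, seed = 1) {
  direction <- match.arg(direction)
  if (length(groups) < 3) stop("trend test needs at least 3 ordered groups")
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop("every group needs at least one value")
  values <- unlist(groups, use.names = FALSE)
  idx <- rep(seq_along(groups), sizes)
  obs <- jt_statistic(values, idx, length(groups))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    jt_statistic(sample(values), idx, length(groups))
  }, numeric(1))
  extreme <- if (direction == "increasing") {
    sum(null_stats >= obs)
  } else {
    sum(null_stats <= obs)
  }
  structure(list(statistic = obs, p = (1 + extreme) / (1 + n_perm),
                 n_permutations = n_perm, direction = direction, seed = seed,
                 n = sizes),
            class = "jt_trend")
}

#' @export
print.jt_trend <- function(x, ...) {
  cat(sprintf("<jt_trend> JT = %.1f, one-sided (%s) p = %.4g [%d permutations]\n",
              x$statistic, x$direction, x$p, x$n_permutations))
  invisible(x)
}

jt_statistic <- function(values, idx, k) {
  by_group <- split(values, factor(idx, levels = seq_len(k)))
  s <- 0
  for (i in seq_len(k - 1)) {
    xi <- by_group[[i]]
    for (j in seq(i + 1, k)) {
      d <- outer(xi, by_group[[j]], function(a, b) (b > a) + 0.5 * (b == a))
      s <- s + sum(d)
    }
  }
  s
}

#' Repeated random-forest importance selection
#'
#' Runs repeated random-forest classifications (500 trees each by default) and
#' collects the scaled permutation importance ("mean decrease accuracy",
#' importance type 1 with z-scaling by its standard error across trees) per
#' feature and trial. Features whose mean MDA across trials exceeds the
#' threshold (default 1.5) are selected; a percentile 95% CI over trials is
#' attached. Trials use distinct seeds derived from the master seed so the
#' whole procedure is reproducible.
#'
#' @param x Numeric matrix or data frame, samples in rows, features in
#'   columns.
#' @param labels Two-level factor/character class labels, one per sample; the
#'   second level is treated as the case class for the direction of change.
#' @param n_trials Number of independent forests (>= 2 for a CI).
#' @param threshold Selection threshold on the mean MDA.
#' @param ntree Trees per forest.
#' @param seed Master seed.
#' @return Tibble: `feature`, `mda_mean`, `ci_lower`, `ci_upper`, `selected`,
#'   `direction` (`"up"`/`"down"`, case vs control feature means); attributes
#'   `"threshold"` and `"scaling"` record the conventions.
#' @export
rf_mda_select <- function(x, labels, n_trials = 2000, threshold = 1.5,
                          ntree = 500, seed = 1) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("labels must contain at least two classes")
  if (n_trials < 2) stop("n_trials must be >= 2 so the CI over trials is defined")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  mda <- vapply(trial_seeds, function(s) {
    set.seed(s)
    fit <- randomForest::randomForest(x, labels, ntree = ntree, importance = TRUE)
    randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  }, numeric(ncol(x)))
  mda <- matrix(mda, nrow = ncol(x),
                dimnames = list(colnames(x), NULL))
  case <- levels(labels)[2]
  dir_up <- colMeans(x[labels == case, , drop = FALSE]) >
    colMeans(x[labels != case, , drop = FALSE])
  out <- tibble::tibble(
    feature = rownames(mda),
    mda_mean = unname(rowMeans(mda)),
    ci_lower = unname(apply(mda, 1, stats::quantile, 0.025)),
    ci_upper = unname(apply(mda, 1, stats::quantile, 0.975)),
    selected = unname(rowMeans(mda) > threshold),
    direction = unname(ifelse(dir_up[rownames(mda)], "up", "down")))
  attr(out, "threshold") <- threshold
  attr(out, "scaling") <- "permutation importance z-scaled by its SE across trees (type 1, scale = TRUE)"
  out
}

#' Concordant overlap of feature selections from two models
#'
#' Intersects the selected features of two selection results, requiring the
#' same direction of change, and reports the Venn region counts.
#'
#' @param selected_a,selected_b Tibbles from [rf_mda_select()] (columns
#'   `feature`, `selected`, `direction`).
#' @return List: `overlap` (concordant selected features), `discordant`
#'   (selected in both, opposite direction), `venn` (counts: a_only, b_only,
#'   both_concordant, both_discordant).
#' @export
model_overlap <- function(selected_a, selected_b) {
  a <- selected_a[selected_a$selected, c("feature", "direction")]
  b <- selected_b[selected_b$selected, c("feature", "direction")]
  both <- intersect(a$feature, b$feature)
  dir_a <- stats::setNames(a$direction, a$feature)[both]
  dir_b <- stats::setNames(b$direction, b$feature)[both]
  concordant <- both[dir_a == dir_b]
  list(overlap = concordant,
       discordant = setdiff(both, concordant),
       venn = c(a_only = length(setdiff(a$feature, both)),
                b_only = length(setdiff(b$feature, both)),
                both_concordant = length(concordant),
                both_discordant = length(both) - length(concordant)))
}

#' ROC area under the curve
#'
#' `roc_auc()` computes the univariate AUC by the rank (Mann-Whitney)
#' statistic with ties counted one half. `roc_auc_logistic()` fits a
#' maximum-likelihood logistic regression on several features and returns the
#' AUC of the fitted linear score (resubstitution, as in standard multivariate
#' ROC analysis).
#'
#' @param scores Numeric vector of marker values.
#' @param labels Two-level vector; `positive` names the positive class
#'   (default: second factor level).
#' @param positive Positive class label.
#' @return For `roc_auc()`, the AUC as a scalar. For `roc_auc_logistic()`, a
#'   list with `auc`, `coefficients` and the fitted scores.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c("ctl", "ctl", "case", "case"), positive = "case")
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("AUC needs exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("one class is empty")
  r <- rank(scores)               # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @param x Numeric matrix/data frame of features (samples in rows).
#' @export
roc_auc_logistic <- function(x, labels, positive = NULL) {
  x <- as.data.frame(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("AUC needs exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  y <- as.numeric(labels == positive)
  fit <- stats::glm(y ~ ., data = cbind(y = y, x), family = stats::binomial())
  score <- stats::predict(fit, type = "link")
  list(auc = roc_auc(score, labels, positive = positive),
       coefficients = stats::coef(fit), scores = score)
}
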