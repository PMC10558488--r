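#' PTM site tables and shared acyl-lysine sites
#'
#' A PTM site table has one row per modified lysine: `accession`, `position`
#' (1-based residue index), `acyl` (`aceK`, `malK` or `sucK`), `fc` (> 0) and
#' optionally `adjusted_fc`. `(accession, position, acyl)` must be unique.
#'
#' @param x Data frame to validate.
#' @param acyl Expected acyl type; `NULL` accepts any.
#' @return The validated tibble.
#' @export
validate_ptm_table <- function(x, acyl = NULL) {
  x <- tibble::as_tibble(x)
  req <- c("accession", "position", "acyl", "fc")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) stop("PTM table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(x$position < 1)) stop("residue positions are 1-based and must be >= 1")
  if (any(x$fc <= 0)) stop("PTM fold changes must be positive")
  bad <- setdiff(unique(x$acyl), c("aceK", "malK", "sucK"))
  if (length(bad) > 0) stop("unknown acyl type(s): ", paste(bad, collapse = ", "))
  if (!is.null(acyl) && !all(x$acyl == acyl)) stop("table must contain only ", acyl, " sites")
  if (anyDuplicated(x[c("accession", "position", "acyl")])) {
    stop("duplicate (accession, position, acyl) key(s)")
  }
  x
}

#' Lysine sites shared by acetylation, malonylation and succinylation
#'
#' Exact triple intersection on `(accession, position)`: a site is shared iff
#' it occurs in all three tables. The result carries one row per shared site
#' and acyl type.
#'
#' @param ace,mal,suc PTM site tables (see [validate_ptm_table()]).
#' @return Tibble of the shared sites (long, one row per site x acyl) with a
#'   `"venn"` attribute giving the seven region counts of the three-set Venn
#'   diagram over `(accession, position)` keys.
#' @export
find_shared_sites <- function(ace, mal, suc) {
  ace <- validate_ptm_table(ace, "aceK")
  mal <- validate_ptm_table(mal, "malK")
  suc <- validate_ptm_table(suc, "sucK")
  key <- function(t) paste(t$accession, t$position, sep = "@")
  ka <- key(ace); km <- key(mal); ks <- key(suc)
  shared <- intersect(intersect(ka, km), ks)
  long <- dplyr::bind_rows(ace[ka %in% shared, ],
                           mal[km %in% shared, ],
                           suc[ks %in% shared, ])
  long <- dplyr::arrange(long, .data$accession, .data$position, .data$acyl)
  venn <- c(
    ace_only = sum(!(ka %in% km) & !(ka %in% ks)),
    mal_only = sum(!(km %in% ka) & !(km %in% ks)),
    suc_only = sum(!(ks %in% ka) & !(ks %in% km)),
    ace_mal = sum((ka %in% km) & !(ka %in% ks)),
    ace_suc = sum((ka %in% ks) & !(ka %in% km)),
    mal_suc = sum((km %in% ks) & !(km %in% ka)),
    all_three = length(shared))
  attr(long, "venn") <- venn
  long
}

#' Protein-level adjustment of PTM fold changes
#'
#' Divides each site's fold change by its parent protein's total-protein fold
#' change, isolating modification-level change from protein-level change.
#' Sites whose protein has no fold change are dropped; the count is attached.
#'
#' @param sites PTM site tibble.
#' @param protein_fc Named positive vector: accession -> protein fold change.
#' @return `sites` with an `adjusted_fc` column; attribute `"n_dropped"`
#'   counts sites without a protein fold change.
#' @export
adjust_fc <- function(sites, protein_fc) {
  sites <- tibble::as_tibble(sites)
  if (any(protein_fc <= 0, na.rm = TRUE)) stop("protein fold changes must be positive")
  have <- sites$accession %in% names(protein_fc) &
    !is.na(protein_fc[sites$accession])
  out <- sites[have, ]
  out$adjusted_fc <- out$fc / unname(protein_fc[out$accession])
  attr(out, "n_dropped") <- sum(!have)
  out
}

#' Extreme-ratio filter on adjusted fold changes
#'
#' Keeps sites whose adjusted fold change lies strictly inside (0.03, 32);
#' both bounds are excluded. Idempotent.
#'
#' @param sites Tibble with an `adjusted_fc` column.
#' @param lower,upper Open-interval bounds.
#' @return Filtered tibble.
#' @export
filter_adjusted <- function(sites, lower = 0.03, upper = 32) {
  if (!"adjusted_fc" %in% names(sites)) stop("sites lack an 'adjusted_fc' column")
  sites[!is.na(sites$adjusted_fc) &
          sites$adjusted_fc > lower & sites$adjusted_fc < upper, ]
}

#' Acyl-group comparison on shared lysine sites
#'
#' One-way ANOVA on log2 adjusted fold changes across the three acyl groups,
#' followed by many-to-one comparisons of aceK and sucK against malK as the
#' single control. The primary method is Dunnett's two-sided test via the
#' multivariate-t distribution; a permutation max-t alternative (with the seed
#' recorded) is available and is used as an independent cross-check in the
#' test-suite.
#'
#' @param shared Long tibble from [find_shared_sites()] with `adjusted_fc`.
#' @param method `"dunnett"` (multivariate-t) or `"permutation"` (max-t).
#' @param n_perm Permutations for the max-t method.
#' @param seed Seed for the permutation method (recorded in the output).
#' @return List: `anova_p`, `comparisons` tibble (`comparison`, `estimate` =
#'   difference in mean log2 adjusted FC vs malK, `p_adjusted`), `method`,
#'   `group_medians` (median adjusted FC per acyl), `n` per group.
#' @export
acyl_group_compare <- function(shared, method = c("dunnett", "permutation"),
                               n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  if (!"adjusted_fc" %in% names(shared)) stop("shared sites lack 'adjusted_fc'")
  n_by <- table(shared$acyl)
  if (length(n_by) < 3 || any(n_by < 2)) {
    stop("each acyl group needs at least 2 sites after filtering")
  }
  y <- log2(shared$adjusted_fc)
  g <- factor(shared$acyl, levels = c("malK", "aceK", "sucK"))
  fit <- stats::aov(y ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  means <- tapply(y, g, mean)
  est <- c(aceK = unname(means["aceK"] - means["malK"]),
           sucK = unname(means["sucK"] - means["malK"]))
  if (method == "dunnett") {
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(glht_fit)
    p_adj <- stats::setNames(as.numeric(sm$test$pvalues),
                             sub(" - malK$", "", names(sm$test$coefficients)))
    p_adj <- pmin(pmax(p_adj[c("aceK", "sucK")], 0), 1)
  } else {
    p_adj <- permutation_max_t(y, g, control = "malK", n_perm = n_perm,
                               seed = seed)[c("aceK", "sucK")]
  }
  list(anova_p = anova_p,
       comparisons = tibble::tibble(comparison = paste0(names(est), " - malK"),
                                    estimate = unname(est),
                                    p_adjusted = unname(p_adj)),
       method = if (method == "dunnett") "dunnett (multivariate t)"
                else sprintf("permutation max-t (%d permutations, seed %d)", n_perm, seed),
       group_medians = tapply(shared$adjusted_fc, g, stats::median),
       n = as.integer(n_by[levels(g)]))
}

# two-sided max-t permutation test for many-to-one comparisons: the null
# distribution of the maximum |t| over contrasts controls the family-wise rate
permutation_max_t <- function(y, g, control, n_perm, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  others <- setdiff(levels(g), control)
  t_stats <- function(yy) {
    vapply(others, function(lev) {
      a <- yy[g == lev]; b <- yy[g == control]
      se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
      if (se == 0) return(0)
      (mean(a) - mean(b)) / se
    }, numeric(1))
  }
  obs <- abs(t_stats(y))
  max_null <- vapply(seq_len(n_perm), function(i) {
    max(abs(t_stats(sample(y))))
  }, numeric(1))
  vapply(obs, function(t0) (1 + sum(max_null >= t0)) / (1 + n_perm), numeric(1))
}

#' Liver-origin tagging with abundance weighting
#'
#' Flags proteins present in a liver-origin reference list and computes the
#' abundance-weighted percentage of liver-derived protein mass.
#'
#' @param accessions Character vector of proteins to tag.
#' @param liver_reference Character vector of liver-origin accessions (e.g.
#'   read from a one-accession-per-line file).
#' @param abundance Named non-negative abundances for `accessions`.
#' @return List: `flags` (named logical), `weighted_percent`.
#' @export
tag_liver_origin <- function(accessions, liver_reference, abundance) {
  flags <- stats::setNames(accessions %in% liver_reference, accessions)
  ab <- abundance[accessions]
  if (anyNA(ab)) stop("abundance missing for some accession(s)")
  total <- sum(ab)
  pct <- if (total > 0) 100 * sum(ab[flags]) / total else NA_real_
  list(flags = flags, weighted_percent = pct)
}
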