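# Independent oracles and fixture builders used across the test files.
# Oracles are deliberately naive (enumeration, normal equations, nested
# loops) and share no code with the implementation paths they check.

toy_matrix <- function(values, unit = "mM", entity_kind = "metabolite",
                       entities = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- entities %||% rownames(values) %||%
    sprintf("e%d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  conc_matrix(values, unit = unit, entity_kind = entity_kind)
}

# OLS slope/intercept/r via explicit normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, intercept = intercept, r = r)
}

# closed-form Welch statistic and p
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t), df)
}

# exhaustive two-sided Fisher p for a 2x2 table via hypergeometric enumeration
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random annotation catalog over a tiny tag vocabulary
random_catalog <- function(n, seed) {
  set.seed(seed)
  kw_pool <- c("KW-0001", "KW-0002", "KW-0003")
  chebi_pool <- c("CHEBI:1", "CHEBI:2", "CHEBI:3", "CHEBI:4")
  pick <- function(pool) {
    paste(sample(pool, sample(0:2, 1)), collapse = ";")
  }
  tibble::tibble(
    accession = sprintf("A%03d", seq_len(n)),
    entry_name = sprintf("N%03d_MOUSE", seq_len(n)),
    ec_number = ifelse(runif(n) < 0.5,
                       sprintf("%d.%d.%d.%d", sample(1:6, n, TRUE),
                               sample(1:9, n, TRUE), sample(1:9, n, TRUE),
                               sample(1:99, n, TRUE)), ""),
    catalytic_activity = ifelse(runif(n) < 0.5, "a + NAD(+) = b + NADH", ""),
    nucleotide_binding = ifelse(runif(n) < 0.3, "NAD", ""),
    keyword_id = vapply(seq_len(n), function(i) pick(kw_pool), character(1)),
    chebi_id = vapply(seq_len(n), function(i) pick(chebi_pool), character(1)))
}

# per-record brute-force evaluation of a formula tree (no vectorization)
brute_force_match <- function(record, f) {
  if (f$op == "leaf") {
    colmap <- c(accession = "accession", entry_name = "entry_name",
                ec = "ec_number", catalytic = "catalytic_activity",
                nucleotide = "nucleotide_binding", keyword = "keyword_id",
                chebi = "chebi_id")
    cell <- record[[colmap[[f$field]]]]
    if (is.na(cell)) cell <- ""
    return(switch(f$mode,
      substring = grepl(tolower(f$pattern), tolower(cell), fixed = TRUE),
      regex = grepl(f$pattern, cell, ignore.case = TRUE, perl = TRUE),
      tag = f$pattern %in% trimws(strsplit(cell, ";", fixed = TRUE)[[1]])))
  }
  hits <- vapply(f$children, function(ch) brute_force_match(record, ch), logical(1))
  switch(f$op, and = all(hits), or = any(hits), not = !hits[1])
}

brute_force_eval <- function(catalog, f) {
  hit <- vapply(seq_len(nrow(catalog)), function(i) {
    brute_force_match(as.list(catalog[i, ]), f)
  }, logical(1))
  catalog$accession[hit]
}

random_formula <- function(depth = 2) {
  fields <- c("ec", "catalytic", "keyword", "chebi", "nucleotide")
  if (depth == 0 || runif(1) < 0.4) {
    field <- sample(fields, 1)
    if (field %in% c("keyword", "chebi") && runif(1) < 0.7) {
      pool <- if (field == "keyword") c("KW-0001", "KW-0002", "KW-0003")
              else c("CHEBI:1", "CHEBI:2", "CHEBI:3", "CHEBI:4")
      return(ff_leaf(field, sample(pool, 1), "tag"))
    }
    return(ff_leaf(field, sample(c("nad", "1.", "a +", "2"), 1), "substring"))
  }
  op <- sample(c("and", "or", "not"), 1)
  if (op == "not") return(ff_not(random_formula(depth - 1)))
  k <- sample(2:3, 1)
  kids <- lapply(seq_len(k), function(i) random_formula(depth - 1))
  if (op == "and") do.call(ff_and, kids) else do.call(ff_or, kids)
}

# exact distance between the convex hulls of two 2-D point sets:
# min over vertex-vertex and vertex-edge distances (exact in 2-D when the
# hulls are disjoint); this is the hard-margin maximal-margin width
hull_distance_oracle <- function(a, b) {
  seg_dist <- function(p, s1, s2) {
    v <- s2 - s1
    t <- if (sum(v^2) == 0) 0 else max(0, min(1, sum((p - s1) * v) / sum(v^2)))
    sqrt(sum((p - (s1 + t * v))^2))
  }
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  }
  pair_edges <- function(pts, others) {
    if (nrow(pts) < 2) return(Inf)
    best <- Inf
    for (i in seq_len(nrow(pts) - 1)) for (j in seq(i + 1, nrow(pts))) {
      for (k in seq_len(nrow(others))) {
        best <- min(best, seg_dist(others[k, ], pts[i, ], pts[j, ]))
      }
    }
    best
  }
  min(best, pair_edges(a, b), pair_edges(b, a))
}

# exhaustive Jonckheere-Terpstra null over all assignments of the pooled
# values to groups of the given sizes (one-sided, "increasing")
jt_stat_oracle <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    for (xv in groups[[i]]) for (yv in groups[[j]]) {
      s <- s + (yv > xv) + 0.5 * (yv == xv)
    }
  }
  s
}

jt_exhaustive_p <- function(groups) {
  sizes <- lengths(groups)
  values <- unlist(groups)
  obs <- jt_stat_oracle(groups)
  n <- length(values)
  idx_all <- seq_len(n)
  count <- 0; total <- 0
  g1 <- utils::combn(idx_all, sizes[1], simplify = FALSE)
  for (a in g1) {
    rest <- setdiff(idx_all, a)
    g2 <- utils::combn(rest, sizes[2], simplify = FALSE)
    for (b in g2) {
      cgrp <- setdiff(rest, b)
      gg <- list(values[a], values[b], values[cgrp])
      total <- total + 1
      if (jt_stat_oracle(gg) >= obs - 1e-9) count <- count + 1
    }
  }
  count / total
}

# AUC by explicit pair counting with half-credit ties
auc_pair_oracle <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
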