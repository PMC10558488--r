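random_ptm_table <- function(acyl, n, seed) {
  set.seed(seed)
  keys <- unique(data.frame(accession = sample(sprintf("P%02d", 1:8), n, TRUE),
                            position = sample(1:30, n, TRUE)))
  tibble::tibble(accession = keys$accession, position = keys$position,
                 acyl = acyl, fc = rlnorm(nrow(keys)))
}

test_that("shared sites are the exact triple intersection with Venn counts", {
  ace <- tibble::tibble(accession = c("P1", "P1", "P2"), position = c(57, 10, 5),
                        acyl = "aceK", fc = 1)
  mal <- tibble::tibble(accession = c("P1", "P2", "P3"), position = c(57, 5, 9),
                        acyl = "malK", fc = 1)
  suc <- tibble::tibble(accession = c("P1", "P2"), position = c(57, 99),
                        acyl = "sucK", fc = 1)
  out <- find_shared_sites(ace, mal, suc)
  expect_equal(unique(paste(out$accession, out$position)), "P1 57")
  expect_equal(nrow(out), 3)          # one record per acyl
  venn <- attr(out, "venn")
  expect_equal(unname(venn["all_three"]), 1)
  expect_equal(unname(venn["ace_mal"]), 1)   # P2@5 in ace+mal only
  expect_equal(unname(venn["ace_only"]), 1)  # P1@10
  expect_equal(unname(venn["mal_only"]), 1)  # P3@9
  expect_equal(unname(venn["suc_only"]), 1)  # P2@99
})

test_that("shared-site detection equals a brute-force nested-loop intersection", {
  for (s in 1:15) {
    ace <- random_ptm_table("aceK", 25, 3 * s)
    mal <- random_ptm_table("malK", 25, 3 * s + 1)
    suc <- random_ptm_table("sucK", 25, 3 * s + 2)
    got <- find_shared_sites(ace, mal, suc)
    got_keys <- unique(paste(got$accession, got$position))
    expected <- character()
    for (i in seq_len(nrow(ace))) {
      in_mal <- FALSE; in_suc <- FALSE
      for (j in seq_len(nrow(mal))) {
        if (ace$accession[i] == mal$accession[j] && ace$position[i] == mal$position[j]) in_mal <- TRUE
      }
      for (k in seq_len(nrow(suc))) {
        if (ace$accession[i] == suc$accession[k] && ace$position[i] == suc$position[k]) in_suc <- TRUE
      }
      if (in_mal && in_suc) expected <- c(expected, paste(ace$accession[i], ace$position[i]))
    }
    expect_setequal(got_keys, expected)
  }
})

test_that("shared-site detection is order-invariant in its inputs", {
  ace <- random_ptm_table("aceK", 30, 91)
  mal <- random_ptm_table("malK", 30, 92)
  suc <- random_ptm_table("sucK", 30, 93)
  a <- find_shared_sites(ace, mal, suc)
  b <- find_shared_sites(ace[sample(nrow(ace)), ], mal[sample(nrow(mal)), ],
                         suc[sample(nrow(suc)), ])
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("protein-level adjustment divides by the parent fold change", {
  sites <- tibble::tibble(accession = c("P1", "P2", "P3"), position = 1:3,
                          acyl = "aceK", fc = c(0.5, 2, 1))
  pfc <- c(P1 = 0.5, P2 = 0.5)
  out <- adjust_fc(sites, pfc)
  expect_equal(out$adjusted_fc, c(1, 4))
  expect_equal(attr(out, "n_dropped"), 1)
  expect_error(adjust_fc(sites, c(P1 = -1)), "positive")
})

test_that("common rescaling of PTM and protein fold changes cancels out", {
  sites <- random_ptm_table("aceK", 20, 55)
  pfc <- setNames(rlnorm(8), sprintf("P%02d", 1:8))
  a <- adjust_fc(sites, pfc)
  sites2 <- sites; sites2$fc <- sites2$fc * 7
  b <- adjust_fc(sites2, pfc * 7)
  expect_equal(b$adjusted_fc, a$adjusted_fc, tolerance = 1e-12)
})

test_that("the extreme-ratio filter is a strict open interval and idempotent", {
  sites <- tibble::tibble(accession = "P1", position = 1:5, acyl = "aceK",
                          fc = 1, adjusted_fc = c(0.03, 0.031, 1, 31.9, 32))
  out <- filter_adjusted(sites)
  expect_equal(out$adjusted_fc, c(0.031, 1, 31.9))
  expect_identical(filter_adjusted(out), out)
})

test_that("identical acyl groups yield a null comparison", {
  vals <- c(0.5, 1, 2, 0.8, 1.4)
  shared <- dplyr::bind_rows(lapply(c("aceK", "malK", "sucK"), function(a) {
    tibble::tibble(accession = "P1", position = 1:5, acyl = a, fc = 1,
                   adjusted_fc = vals)
  }))
  cmp <- suppressWarnings(acyl_group_compare(shared))
  expect_equal(cmp$anova_p, 1, tolerance = 1e-9)
  expect_true(all(cmp$comparisons$p_adjusted > 0.99))
  expect_equal(cmp$comparisons$estimate, c(0, 0), tolerance = 1e-12)
})

test_that("a planted malonylation decline is detected by both Dunnett routes", {
  set.seed(31)
  n <- 50
  shared <- dplyr::bind_rows(
    tibble::tibble(accession = "P1", position = 1:n, acyl = "aceK", fc = 1,
                   adjusted_fc = 2^rnorm(n, 0, 0.1)),
    tibble::tibble(accession = "P1", position = 1:n, acyl = "malK", fc = 1,
                   adjusted_fc = 2^rnorm(n, -1, 0.1)),
    tibble::tibble(accession = "P1", position = 1:n, acyl = "sucK", fc = 1,
                   adjusted_fc = 2^rnorm(n, 0, 0.1)))
  d <- acyl_group_compare(shared, method = "dunnett")
  expect_lt(d$anova_p, 1e-6)
  expect_true(all(d$comparisons$p_adjusted < 0.001))
  expect_true(all(d$comparisons$estimate > 0.8))     # malK sits ~1 log2 below
  p <- acyl_group_compare(shared, method = "permutation", n_perm = 2000, seed = 5)
  expect_true(all(p$comparisons$p_adjusted < 0.01))
  expect_match(p$method, "permutation")
})

test_that("the permutation max-t route matches exhaustive relabeling on a tiny toy", {
  # observed assignment: malK sits low, aceK and sucK near zero
  yy <- c(-1.2, -1.0, -1.4, 0.1, 0.2, 0.35, 0.05, 0.3, 0.15)
  gg <- factor(rep(c("malK", "aceK", "sucK"), each = 3),
               levels = c("malK", "aceK", "sucK"))
  t_stat <- function(vals, lev) {
    a <- vals[gg == lev]; b <- vals[gg == "malK"]
    (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  }
  obs <- sapply(c("aceK", "sucK"), function(l) abs(t_stat(yy, l)))
  # exhaustive enumeration of all 9!/(3!3!3!) = 1680 group relabelings
  combs_a <- utils::combn(9, 3, simplify = FALSE)
  max_ts <- c()
  for (a in combs_a) {
    rest <- setdiff(1:9, a)
    for (b in utils::combn(rest, 3, simplify = FALSE)) {
      cc <- setdiff(rest, b)
      perm <- numeric(9); perm[gg == "malK"] <- yy[a]
      perm[gg == "aceK"] <- yy[b]; perm[gg == "sucK"] <- yy[cc]
      max_ts <- c(max_ts, max(abs(t_stat(perm, "aceK")), abs(t_stat(perm, "sucK"))))
    }
  }
  p_exhaustive <- sapply(obs, function(t0) mean(max_ts >= t0))
  got <- cachexomics:::permutation_max_t(yy, gg, "malK", n_perm = 4000, seed = 11)
  expect_true(all(abs(unname(got[c("aceK", "sucK")]) - unname(p_exhaustive)) < 0.02))
})

test_that("liver-origin tagging computes abundance-weighted percentages", {
  out <- tag_liver_origin(c("P1", "P2"), c("P1"), c(P1 = 9, P2 = 1))
  expect_equal(out$weighted_percent, 90)
  expect_equal(unname(out$flags), c(TRUE, FALSE))
  all_liver <- tag_liver_origin(c("P1", "P2"), c("P1", "P2"), c(P1 = 1, P2 = 5))
  expect_equal(all_liver$weighted_percent, 100)
  # brute-force weighted sum on a random toy
  set.seed(33)
  acc <- sprintf("Q%02d", 1:12)
  ref <- sample(acc, 5)
  ab <- setNames(runif(12), acc)
  got <- tag_liver_origin(acc, ref, ab)
  expect_equal(got$weighted_percent, 100 * sum(ab[ref]) / sum(ab), tolerance = 1e-12)
})
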