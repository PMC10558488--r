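test_that("formula leaves match substrings, regexes and exact tags", {
  cat5 <- tibble::tibble(
    accession = paste0("A", 1:5),
    entry_name = paste0("N", 1:5),
    ec_number = c("1.1.1.27", "2.7.1.1", "", "1.1.1.1", ""),
    catalytic_activity = c("L-lactate + NAD(+) = pyruvate + NADH", "", "", "", ""),
    nucleotide_binding = "",
    keyword_id = c("KW-0000", "", "KW-0000;KW-0520", "", ""),
    chebi_id = c("CHEBI:57540", "CHEBI:57540;CHEBI:58349", "", "CHEBI:57540", ""))
  expect_setequal(evaluate_search_formula(cat5, ff_leaf("ec", "1.1.1.", "substring")),
                  c("A1", "A4"))
  # case-insensitive substring on free text
  expect_equal(evaluate_search_formula(cat5, ff_leaf("catalytic", "nad(+)", "substring")),
               "A1")
  # exact tags are not substring-matched
  expect_setequal(evaluate_search_formula(cat5, ff_leaf("keyword", "KW-0000", "tag")),
                  c("A1", "A3"))
  expect_length(evaluate_search_formula(cat5, ff_leaf("keyword", "KW-00", "tag")), 0)
  f <- ff_and(ff_leaf("chebi", "CHEBI:57540", "tag"),
              ff_not(ff_leaf("keyword", "KW-0000", "tag")))
  # brute-force per-record evaluation over the 5-record toy catalog
  expect_setequal(evaluate_search_formula(cat5, f), brute_force_eval(cat5, f))
  expect_setequal(evaluate_search_formula(cat5, f), c("A2", "A4"))
  # matching nothing is an empty set, not an error
  expect_length(evaluate_search_formula(cat5, ff_leaf("ec", "9.9.9.9", "substring")), 0)
  expect_error(ff_leaf("ec", "([", "regex"), "invalid regex")
  expect_error(ff_leaf("bogus_field", "x"), "unknown formula field")
})

test_that("parser round-trips formulas and agrees with constructed trees", {
  f <- ff_and(ff_leaf("ec", "1.1.1.", "substring"),
              ff_not(ff_leaf("keyword", "KW-0000", "tag")))
  expect_identical(parse_search_formula('ec:"1.1.1." AND NOT keyword="KW-0000"'), f)
  g <- ff_or(ff_leaf("chebi", "CHEBI:1", "tag"),
             ff_and(ff_leaf("catalytic", "nad", "substring"),
                    ff_leaf("ec", "^1\\.", "regex")))
  expect_identical(parse_search_formula(cachexomics:::deparse_formula(g)), g)
  expect_error(parse_search_formula('ec:"1." AND'), "ends unexpectedly")
  expect_error(parse_search_formula('(ec:"1."'), "unbalanced")
})

test_that("random formulas obey De Morgan identities against brute force", {
  for (s in 1:25) {
    catalog <- random_catalog(12, seed = s)
    set.seed(s + 1000)
    a <- random_formula(2); b <- random_formula(2)
    expect_setequal(evaluate_search_formula(catalog, ff_not(ff_and(a, b))),
                    brute_force_eval(catalog, ff_or(ff_not(a), ff_not(b))))
    expect_setequal(evaluate_search_formula(catalog, ff_not(ff_or(a, b))),
                    brute_force_eval(catalog, ff_and(ff_not(a), ff_not(b))))
  }
})

test_that("proteome partition is disjoint, covering, with B-vitamin precedence", {
  enzymes_f <- parse_search_formula('ec~"[0-9]"')
  bvit_f <- parse_search_formula('chebi="CHEBI:1" OR chebi="CHEBI:2"')
  for (s in 1:20) {
    catalog <- random_catalog(15, seed = 100 + s)
    p <- partition_proteome(catalog, enzymes_f, bvit_f)
    all_ids <- c(p$b_vitamin_enzymes, p$other_enzymes, p$non_enzymes)
    expect_equal(sort(all_ids), sort(catalog$accession))  # coverage, no overlap
    expect_length(intersect(p$b_vitamin_enzymes, p$other_enzymes), 0)
    expect_length(intersect(p$b_vitamin_enzymes, p$non_enzymes), 0)
    # b-vitamin members are enzymes
    expect_true(all(p$b_vitamin_enzymes %in% brute_force_eval(catalog, enzymes_f)))
  }
  # a record with an NAD ChEBI link and an EC number lands in the B-vitamin set
  cat1 <- tibble::tibble(accession = c("E1", "X1"), entry_name = c("a", "b"),
                         ec_number = c("1.1.1.1", ""), catalytic_activity = "",
                         nucleotide_binding = "", keyword_id = "",
                         chebi_id = c("CHEBI:1", ""))
  p <- partition_proteome(cat1, enzymes_f, bvit_f)
  expect_equal(p$b_vitamin_enzymes, "E1")
  expect_equal(p$non_enzymes, "X1")
})

test_that("aggregation is a once-per-id sum that skips unknown ids with a warning", {
  vals <- c(m1 = 0.3, m2 = 0.7, m3 = 1)
  expect_equal(aggregate_concentration(c("m1", "m2"), vals), 1.0)
  expect_equal(aggregate_concentration(c("m1", "m1", "m2"), vals), 1.0)
  expect_warning(out <- aggregate_concentration(c("m1", "nope"), vals), "skipped")
  expect_equal(out, 0.3)
  expect_warning(z <- aggregate_concentration(character(), vals), "empty")
  expect_equal(z, 0)
  # permutation invariance and additivity over disjoint sets
  set.seed(1)
  vv <- setNames(runif(10), paste0("x", 1:10))
  a <- paste0("x", 1:4); b <- paste0("x", 5:10)
  expect_equal(aggregate_concentration(sample(a), vv), aggregate_concentration(a, vv))
  expect_equal(aggregate_concentration(c(a, b), vv),
               aggregate_concentration(a, vv) + aggregate_concentration(b, vv))
})

test_that("unit conversions follow the molar unit algebra exactly", {
  expect_equal(tissue_to_molar(1), 1)
  expect_equal(tissue_to_molar(0), 0)
  expect_equal(tissue_to_molar(0.0025), 0.0025)   # 2.5 nmol/g in umol/g
  expect_error(tissue_to_molar(-1), "non-negative")

  expect_equal(proteome_share_to_molar(1), 5)
  expect_equal(proteome_share_to_molar(200, unit = "ppm"), 200e-6 * 5)
  expect_error(proteome_share_to_molar(2), "ppm")
  # conservation: a whole proteome of shares sums to exactly 5 mM
  set.seed(2)
  shares <- runif(100); shares <- shares / sum(shares)
  expect_equal(sum(proteome_share_to_molar(shares)), 5, tolerance = 1e-12)

  expect_equal(mass_to_molar(123.111, "NIA"), 10)
  expect_equal(mass_to_molar(0, "B6"), 0)
  expect_equal(mass_to_molar(1.355388, "B12"), 0.01, tolerance = 1e-12)
  expect_error(mass_to_molar(1, "B99"), "unknown vitamin")
  # linear and invertible
  expect_equal(mass_to_molar(7.3, "PA") * 219.23 / 10, 7.3, tolerance = 1e-12)
})

test_that("metabolite-enzyme linking equals an exhaustive bipartite scan", {
  catalog <- random_catalog(20, seed = 77)
  set.seed(78)
  mets <- setNames(lapply(1:6, function(i) {
    sample(c("CHEBI:1", "CHEBI:2", "CHEBI:3", "CHEBI:4"), sample(0:2, 1))
  }), paste0("met", 1:6))
  links <- suppressWarnings(link_metabolite_enzymes(catalog, mets))
  expect_warning(link_metabolite_enzymes(catalog, list(a = "CHEBI:1", b = character())),
                 "omitted")
  # brute-force nested scan
  for (m in names(mets)) {
    if (length(mets[[m]]) == 0) {
      expect_false(m %in% names(links))
      next
    }
    expected <- character()
    for (i in seq_len(nrow(catalog))) {
      tags <- trimws(strsplit(catalog$chebi_id[i], ";", fixed = TRUE)[[1]])
      if (any(mets[[m]] %in% tags)) expected <- c(expected, catalog$accession[i])
    }
    expect_setequal(links[[m]], expected)
  }
  # a metabolite whose id no enzyme carries keeps an empty set
  links2 <- link_metabolite_enzymes(catalog, list(orphan = "CHEBI:99999"))
  expect_length(links2$orphan, 0)
})

test_that("cofactor objects aggregate member molarities and may overlap", {
  catalog <- tibble::tibble(
    accession = c("E1", "E2", "E3"), entry_name = c("a", "b", "c"),
    ec_number = "1.1.1.1", catalytic_activity = "", nucleotide_binding = "",
    keyword_id = "", chebi_id = c("CHEBI:1", "CHEBI:1;CHEBI:2", "CHEBI:2"))
  formulas <- list(
    NIA = list(enzymes = parse_search_formula('chebi="CHEBI:1"'),
               metabolites = parse_search_formula('entry_name:"nad"')),
    B6 = list(enzymes = parse_search_formula('chebi="CHEBI:2"'),
              metabolites = parse_search_formula('entry_name:"plp"')))
  met <- c(NAD = 0.2, NADP = 0.3, PLP = 0.1)
  prot <- c(E1 = 0.1, E2 = 0.4, E3 = 0.2)
  obj <- build_cofactor_objects(catalog, formulas, met, prot)
  nia <- obj[obj$object == "NIA", ]
  expect_equal(nia$metabolite_mM, 0.5)
  expect_equal(nia$enzyme_mM, 0.5)
  # overlap allowed: E2 belongs to both objects
  expect_true("E2" %in% obj$enzyme_accessions[[1]])
  expect_true("E2" %in% obj$enzyme_accessions[[2]])
  # totals equal brute-force re-summation over the membership lists
  for (i in seq_len(nrow(obj))) {
    expect_equal(obj$enzyme_mM[i], sum(prot[obj$enzyme_accessions[[i]]]))
    expect_equal(obj$metabolite_mM[i], sum(met[obj$metabolite_ids[[i]]]))
  }
  # an object with no member enzymes is flagged
  formulas$empty <- list(enzymes = parse_search_formula('chebi="CHEBI:9"'),
                         metabolites = NULL)
  expect_warning(obj2 <- build_cofactor_objects(catalog, formulas, met, prot),
                 "without member enzymes")
  expect_equal(obj2$enzyme_mM[obj2$object == "empty"], 0)
})

test_that("shipped default formulas parse and drive the partition on synthetic catalogs", {
  forms <- read_formula_file(default_formula_file())
  expect_true(all(c("all_enzymes", "b_vitamin_enzymes", "NIA", "C1") %in% names(forms)))
  gen <- generate_catalog(n_proteins = 300, seed = 5)
  p <- partition_proteome(gen$catalog, forms$all_enzymes$enzymes,
                          forms$b_vitamin_enzymes$enzymes)
  expect_equal(sum(lengths(p)), 300)
  expect_setequal(p$non_enzymes, names(gen$classes)[gen$classes == "none"])
})

test_that("RLD summaries report percent lengths, count bins and medians", {
  rec <- tibble::tibble(
    enzyme_id = paste0("z", 1:5),
    chain_length_aa = c(400, 200, 300, 500, 600),
    rld_lengths_aa = list(c(100, 100), 100, c(120, 100), 235, c(100, 100, 100)))
  out <- rld_summary(rec)
  expect_equal(out$per_enzyme$percent_length[1], 50)   # 200 of 400 aa
  expect_equal(out$per_enzyme$n_rld, c(2, 1, 2, 1, 3))
  hist <- setNames(out$count_histogram$n, as.character(out$count_histogram$bin))
  expect_equal(hist[["1"]], 2); expect_equal(hist[["2"]], 2); expect_equal(hist[[">2"]], 1)
  # sort-and-pick median of {100, 220, 235, 200, 300}
  expect_equal(out$median_total_length$median_total_length,
               sort(c(200, 100, 220, 235, 300))[3])
  bad <- rec; bad$chain_length_aa[1] <- 0
  expect_error(rld_summary(bad), "positive")
  bad2 <- rec; bad2$rld_lengths_aa[[2]] <- c(150, 100)  # exceeds chain 200
  expect_error(rld_summary(bad2), "exceed")
})
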