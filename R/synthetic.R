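#' Synthetic-data generators with planted ground truth
#'
#' Every input the pipeline consumes can be generated here, with the planted
#' truth serialized alongside, so all stages are testable without downloads.
#' All generators are pure functions of their parameters and seed.
#'
#' @name synthetic_data
NULL

# canonical cofactor ChEBI ids used both by the generators and the default
# formula file; one id set per cofactor class
cofactor_chebi_ids <- function() {
  list(NIA = c("CHEBI:57540", "CHEBI:58349"),
       B6 = "CHEBI:597326",
       PA = "CHEBI:57287",
       B2 = c("CHEBI:57692", "CHEBI:58210"),
       B1 = "CHEBI:58937",
       ATP = "CHEBI:30616",
       SAM = "CHEBI:59789",
       Gly = "CHEBI:57305",
       C1 = "CHEBI:15636",
       Folate = "CHEBI:57453")
}

#' Generate an annotation catalog with log-normal abundances
#'
#' Proteins are assigned to cofactor classes (NIA, B6, PA, B2, B1, ATP, SAM,
#' Gly, C1), to a generic "other_enzyme" class, or to "none" (non-enzymes).
#' Enzymes receive an EC number, an enzyme-class keyword, and the ChEBI ids of
#' their cofactor class, so the shipped default search formulas recover the
#' planted classes. Abundances are log-normal (log10 mM around -3, sd 1,
#' spanning roughly six decades after normalizing shares to a 5 mM total);
#' B-vitamin classes get a configurable upward shift, emulating the high
#' hepatic expression of B-vitamin enzymes. Half of the C1 enzymes also carry
#' a folate tag (B-vitamin-dependent one-carbon enzymes), half do not.
#'
#' @param n_proteins Catalog size.
#' @param class_probs Named class probabilities (summing to <= 1; the
#'   remainder is "none").
#' @param bvit_shift_log10 Upward abundance shift (decades) for the B-vitamin
#'   classes NIA, B6, PA, B2, B1.
#' @param seed Seed.
#' @return List: `catalog` (annotation tibble), `abundance_mM` (named,
#'   sums to 5 mM), `classes` (named truth vector), `seed`.
#' @export
generate_catalog <- function(n_proteins = 2000,
                             class_probs = c(NIA = 0.05, B6 = 0.04, C1 = 0.04,
                                             PA = 0.03, B2 = 0.03, B1 = 0.02,
                                             ATP = 0.08, SAM = 0.03, Gly = 0.03,
                                             other_enzyme = 0.25),
                             bvit_shift_log10 = 0.5, seed = 1) {
  if (any(class_probs < 0) || sum(class_probs) > 1) {
    stop("class probabilities must be non-negative and sum to at most 1")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  probs <- c(class_probs, none = 1 - sum(class_probs))
  classes <- sample(names(probs), n_proteins, replace = TRUE, prob = probs)
  acc <- sprintf("P%05d", seq_len(n_proteins))
  chebi <- cofactor_chebi_ids()
  is_enzyme <- classes != "none"
  ec <- ifelse(is_enzyme,
               sprintf("%d.%d.%d.%d", sample(1:7, n_proteins, TRUE),
                       sample(1:20, n_proteins, TRUE),
                       sample(1:30, n_proteins, TRUE),
                       sample(1:99, n_proteins, TRUE)),
               "")
  folate_dependent <- classes == "C1" & (seq_len(n_proteins) %% 2 == 0)
  chebi_col <- vapply(seq_len(n_proteins), function(i) {
    cls <- classes[i]
    ids <- if (cls %in% names(chebi)) chebi[[cls]] else character()
    if (folate_dependent[i]) ids <- c(ids, chebi$Folate)
    paste(ids, collapse = ";")
  }, character(1))
  catalytic <- ifelse(is_enzyme & classes %in% names(chebi),
                      sprintf("substrate + %s cofactor = product", classes),
                      ifelse(is_enzyme, "substrate = product", ""))
  catalog <- tibble::tibble(
    accession = acc,
    entry_name = sprintf("%s_MOUSE", toupper(acc)),
    ec_number = ec,
    catalytic_activity = catalytic,
    nucleotide_binding = ifelse(classes %in% c("NIA", "ATP"), classes, ""),
    keyword_id = ifelse(is_enzyme, "KW-0560", ""),
    chebi_id = chebi_col)
  shift <- ifelse(classes %in% c("NIA", "B6", "PA", "B2", "B1"),
                  bvit_shift_log10, 0)
  raw <- 10^(stats::rnorm(n_proteins, mean = -3, sd = 1) + shift)
  abundance <- proteome_share_to_molar(raw / sum(raw), "share")
  names(abundance) <- acc
  list(catalog = catalog, abundance_mM = abundance,
       classes = stats::setNames(classes, acc), seed = seed)
}

#' Compartment pools from planted classes
#'
#' Groups a catalog's proteins into the three mutually exclusive compartments
#' used for matched resampling: NIA + B6 + C1 enzymes, other enzymes,
#' non-enzymes.
#'
#' @param classes Named class vector from [generate_catalog()].
#' @return Named list of accession pools.
#' @export
compartment_pools <- function(classes) {
  list(nia_b6_c1 = names(classes)[classes %in% c("NIA", "B6", "C1")],
       other_enzymes = names(classes)[!classes %in% c("NIA", "B6", "C1", "none")],
       non_enzymes = names(classes)[classes == "none"])
}

#' Generate a metabolome with planted metabolite:enzyme ratios
#'
#' Per cofactor class, the metabolite pool total is the enzyme pool total
#' times `10^Normal(ratio_mean, ratio_sd)`; the total is split randomly among
#' the class's member metabolites. Each metabolite carries its class's ChEBI
#' ids in the returned lookup so formula-based object construction recovers
#' the membership.
#'
#' @param cat_obj Output of [generate_catalog()].
#' @param ratio_mean,ratio_sd Planted Normal parameters of the log10
#'   metabolite:enzyme ratio.
#' @param n_met_per_class Metabolites per cofactor class.
#' @param seed Seed.
#' @return List: `metabolome_mM` (named vector), `chebi_map` (metabolite ->
#'   ChEBI ids), `log10_ratio` (planted truth, named by class), `seed`.
#' @export
generate_metabolome <- function(cat_obj, ratio_mean = 0, ratio_sd = 0.3,
                                n_met_per_class = 3, seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  chebi <- cofactor_chebi_ids()
  cofactor_classes <- intersect(names(chebi), unique(cat_obj$classes))
  met_mM <- numeric(0); chebi_map <- list(); ratios <- numeric(0)
  for (cls in cofactor_classes) {
    members <- names(cat_obj$classes)[cat_obj$classes == cls]
    enzyme_total <- sum(cat_obj$abundance_mM[members])
    lr <- stats::rnorm(1, ratio_mean, ratio_sd)
    total <- enzyme_total * 10^lr
    w <- stats::runif(n_met_per_class)
    vals <- total * w / sum(w)
    nm <- sprintf("%s_met%d", cls, seq_len(n_met_per_class))
    met_mM[nm] <- vals
    for (m in nm) chebi_map[[m]] <- chebi[[cls]]
    ratios[cls] <- lr
  }
  list(metabolome_mM = met_mM, chebi_map = chebi_map,
       log10_ratio = ratios, seed = seed)
}

#' Generate standalone cofactor objects with planted ratios
#'
#' Directly emits an objects table (as from [build_cofactor_objects()]) with
#' log-normal enzyme aggregates and metabolite aggregates planted at
#' `enzyme_mM x 10^Normal(ratio_mean, ratio_sd)`, optionally spread over
#' several species. Used for stoichiometry-recovery studies at large object
#' counts.
#'
#' @param n_objects Number of objects.
#' @param ratio_mean,ratio_sd Planted log10-ratio Normal parameters.
#' @param species Character vector of species labels cycled over objects.
#' @param seed Seed.
#' @return Tibble: `object`, `species`, `metabolite_mM`, `enzyme_mM`,
#'   `true_log10_ratio`.
#' @export
generate_stoich_objects <- function(n_objects = 500, ratio_mean = 0,
                                    ratio_sd = 0.3,
                                    species = c("M.musculus", "S.cerevisiae",
                                                "B.taurus", "A.thaliana"),
                                    seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  enzyme <- 10^stats::rnorm(n_objects, mean = -1, sd = 1)
  lr <- stats::rnorm(n_objects, ratio_mean, ratio_sd)
  tibble::tibble(object = sprintf("obj%04d", seq_len(n_objects)),
                 species = rep_len(species, n_objects),
                 metabolite_mM = enzyme * 10^lr,
                 enzyme_mM = enzyme,
                 true_log10_ratio = lr)
}

#' Generate a cachexia fold-change experiment
#'
#' Builds a complete protein concentration matrix plus sample design for the
#' five experimental models (MEWO, LNCA, SEKI, CRCA, STRV). Control samples
#' are log-normal around each protein's planted abundance; experimental
#' samples additionally apply a planted per-protein log2 fold change
#' `(slope/1000) * log10(abundance) + Normal(0, noise_sd)`, where the slope
#' depends on the protein's cofactor class and the model. The defaults plant
#' a severity gradient: the focal B-vitamin classes (NIA, B6, PA) decline
#' abundance-dependently at -100 permille in the severe models (SEKI, CRCA),
#' at -30 permille in LNCA, and not at all in MEWO or the starvation model.
#'
#' @param cat_obj Output of [generate_catalog()].
#' @param slopes_permille Named list model -> named vector class -> permille
#'   slope (classes absent from the vector get 0).
#' @param noise_sd SD of the protein-level Normal noise on log2 FC.
#' @param n_per_arm Samples per arm and model.
#' @param rep_sd_log10 Replicate-level log10 noise on concentrations.
#' @param seed Seed.
#' @return List: `matrix` (a complete mM [conc_matrix()]), `design` (tibble),
#'   `truth` (planted log2 FC per protein and model, plus the slope spec),
#'   `seed`.
#' @export
generate_cachexia_experiment <- function(cat_obj,
                                         slopes_permille = default_slopes(),
                                         noise_sd = 0.2, n_per_arm = 3,
                                         rep_sd_log10 = 0.05, seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  acc <- names(cat_obj$abundance_mM)
  ab <- cat_obj$abundance_mM
  models <- names(slopes_permille)
  cols <- list(); design <- list(); truth_fc <- list()
  for (mod in models) {
    s <- slopes_permille[[mod]]
    slope <- ifelse(cat_obj$classes[acc] %in% names(s),
                    s[cat_obj$classes[acc]], 0) / 1000
    log2fc <- slope * log10(ab) + stats::rnorm(length(acc), 0, noise_sd)
    truth_fc[[mod]] <- stats::setNames(log2fc, acc)
    for (arm in c("control", "experimental")) {
      base <- if (arm == "control") ab else ab * 2^log2fc
      for (r in seq_len(n_per_arm)) {
        id <- sprintf("%s_%s_%d", mod, substr(arm, 1, 3), r)
        cols[[id]] <- base * 10^stats::rnorm(length(acc), 0, rep_sd_log10)
        design[[id]] <- tibble::tibble(sample_id = id, model = mod, arm = arm,
                                       tissue = "liver", sex = "mixed")
      }
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- acc
  list(matrix = conc_matrix(vals, unit = "mM", entity_kind = "protein"),
       design = dplyr::bind_rows(design),
       truth = list(log2fc = truth_fc, slopes_permille = slopes_permille,
                    noise_sd = noise_sd),
       seed = seed)
}

#' @rdname generate_cachexia_experiment
#' @export
default_slopes <- function() {
  focal <- c(NIA = -100, B6 = -100, PA = -100)
  list(MEWO = c(NIA = 0),
       LNCA = focal * 0.3,
       SEKI = focal,
       CRCA = focal,
       STRV = c(NIA = 0))
}

#' Generate acyl-PTM site tables with a planted malonylation shift
#'
#' Builds three PTM site tables (aceK, malK, sucK) sharing `n_shared_sites`
#' lysine sites, plus per-table non-shared sites, and a protein fold-change
#' table. Shared sites carry log2 adjusted fold changes drawn from
#' `Normal(0, sigma)` for aceK and sucK and `Normal(-delta, sigma)` for malK;
#' raw site fold changes are the adjusted values times the parent protein's
#' fold change, so the protein-level adjustment recovers them.
#'
#' @param cat_obj Output of [generate_catalog()].
#' @param n_shared_sites Number of shared lysine sites.
#' @param delta_mal_log2 Planted malonylation-specific downward shift (log2).
#' @param sigma_log2 SD of the log2 adjusted fold changes.
#' @param n_extra_per_table Non-shared sites added to each table.
#' @param seed Seed.
#' @return List: `ace`, `mal`, `suc` (site tibbles), `protein_fc` (named
#'   vector), `truth`, `seed`.
#' @export
generate_ptm_tables <- function(cat_obj, n_shared_sites = 300,
                                delta_mal_log2 = 1, sigma_log2 = 0.3,
                                n_extra_per_table = 50, seed = 1) {
  stopifnot(n_shared_sites >= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  acc <- names(cat_obj$abundance_mM)
  n_needed <- n_shared_sites + 3 * n_extra_per_table
  site_acc <- sample(acc, n_needed, replace = TRUE)
  # unique (protein, position) keys: positions drawn without replacement per protein
  by_acc <- split(seq_len(n_needed), site_acc)
  accession <- rep(names(by_acc), lengths(by_acc))
  position <- unlist(lapply(lengths(by_acc), function(k) {
    sample(seq_len(50 * k + 500), k)
  }), use.names = FALSE)
  shared_idx <- seq_len(n_shared_sites)
  extra_idx <- split(n_shared_sites + seq_len(3 * n_extra_per_table),
                     rep(1:3, each = n_extra_per_table))
  protein_fc <- stats::setNames(2^stats::rnorm(length(acc), 0, 0.2), acc)
  make_table <- function(acyl, delta, idx_extra) {
    idx <- c(shared_idx, idx_extra)
    adj <- 2^stats::rnorm(length(idx), -delta, sigma_log2)
    site_accession <- accession[idx]
    tibble::tibble(accession = site_accession, position = position[idx],
                   acyl = acyl,
                   fc = adj * unname(protein_fc[site_accession]))
  }
  ace <- make_table("aceK", 0, extra_idx[[1]])
  mal <- make_table("malK", delta_mal_log2, extra_idx[[2]])
  suc <- make_table("sucK", 0, extra_idx[[3]])
  list(ace = ace, mal = mal, suc = suc, protein_fc = protein_fc,
       truth = list(n_shared_sites = n_shared_sites,
                    delta_mal_log2 = delta_mal_log2, sigma_log2 = sigma_log2),
       seed = seed)
}

#' Generate a patient metabolite panel with a planted GPS trend
#'
#' Six blood metabolites (betaine, Ser, Thr, choline, GAA, Trp) with a
#' monotone downward mean shift per Glasgow-Prognostic-Score level plus
#' Gaussian noise on the log2 scale, and a cachexia label whose probability
#' is driven by the planted choline and Trp signal.
#'
#' @param n_per_gps Integer vector of patients per GPS level 0, 1, 2.
#' @param trend_effects Named per-step downward shift (log2 units per GPS
#'   level) per metabolite.
#' @param noise_sd SD of the log2 noise.
#' @param seed Seed.
#' @return Tibble: `patient_id`, `gps` (0/1/2), `cachexia` (0/1) and one
#'   column per metabolite (linear fold-change scale); planted effects in the
#'   `"truth"` attribute.
#' @export
generate_patient_panel <- function(n_per_gps = c(20, 10, 27),
                                   trend_effects = c(betaine = 0.4, Ser = 0.3,
                                                     Thr = 0.3, choline = 0.5,
                                                     GAA = 0.4, Trp = 0.6),
                                   noise_sd = 0.3, seed = 1) {
  stopifnot(length(n_per_gps) == 3)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  gps <- rep(0:2, n_per_gps)
  n <- length(gps)
  vals <- vapply(names(trend_effects), function(m) {
    2^(-trend_effects[[m]] * gps + stats::rnorm(n, 0, noise_sd))
  }, numeric(n))
  colnames(vals) <- names(trend_effects)
  score <- -scale(log2(vals[, "choline"]))[, 1] - scale(log2(vals[, "Trp"]))[, 1]
  cachexia <- stats::rbinom(n, 1, stats::plogis(1.5 * score))
  out <- tibble::tibble(patient_id = sprintf("pt%03d", seq_len(n)),
                        gps = gps, cachexia = cachexia)
  out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
  attr(out, "truth") <- list(trend_effects = trend_effects,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Serialize planted truth next to generated data
#'
#' @param truth A list of planted parameters.
#' @param path JSON output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
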