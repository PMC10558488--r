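#' Read a UniProt-style annotation catalog
#'
#' TSV export with columns `accession`, `entry_name`, `ec_number`,
#' `catalytic_activity`, `nucleotide_binding`, `keyword_id`, `chebi_id`.
#' Multi-valued cells are semicolon-separated. Accessions must be unique.
#'
#' @param path TSV file path.
#' @return A tibble, one row per protein.
#' @export
read_annotation_catalog <- function(path) {
  cat <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_catalog(cat)
}

validate_catalog <- function(cat) {
  req <- unname(catalog_fields())
  miss <- setdiff(req, names(cat))
  if (length(miss) > 0) stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cat$accession)) {
    dup <- unique(cat$accession[duplicated(cat$accession)])
    stop("duplicate accession(s) in catalog: ", paste(dup, collapse = ", "))
  }
  tibble::as_tibble(cat)
}

#' Partition a proteome into three mutually exclusive groups
#'
#' Splits the catalog into B-vitamin-related enzymes, other enzymes, and
#' non-enzyme proteins. Enzyme status comes from the configured all-enzymes
#' formula; B-vitamin membership (intersected with enzyme status) takes
#' precedence over "other enzymes". The three sets are pairwise disjoint and
#' cover the catalog.
#'
#' @param catalog Annotation catalog tibble.
#' @param all_enzymes_formula,b_vitamin_formula `search_formula` objects or
#'   formula text.
#' @return List with character vectors `b_vitamin_enzymes`, `other_enzymes`,
#'   `non_enzymes`.
#' @export
partition_proteome <- function(catalog, all_enzymes_formula, b_vitamin_formula) {
  enz <- evaluate_search_formula(catalog, all_enzymes_formula)
  bvit <- intersect(evaluate_search_formula(catalog, b_vitamin_formula), enz)
  list(b_vitamin_enzymes = bvit,
       other_enzymes = setdiff(enz, bvit),
       non_enzymes = setdiff(catalog$accession, enz))
}

#' Sum molar concentrations over a member set
#'
#' Simple addition of member molarities with set semantics: each id counts
#' once even if repeated in the input. Ids absent from `molar_values` are
#' skipped with a warning carrying the skip count.
#'
#' @param ids Character vector of member ids.
#' @param molar_values Named numeric vector of concentrations (mM).
#' @return Scalar sum (mM).
#' @export
aggregate_concentration <- function(ids, molar_values) {
  ids <- unique(ids)
  if (length(ids) == 0) {
    warning("empty member set; aggregate is 0")
    return(0)
  }
  present <- ids %in% names(molar_values)
  if (!all(present)) {
    warning(sum(!present), " id(s) absent from concentration vector; skipped")
  }
  sum(molar_values[ids[present]])
}

#' Read a metabolite-to-ChEBI lookup table
#'
#' @param path Two-column TSV: `metabolite` name, `chebi_id`
#'   (semicolon-separated when a metabolite maps to several ids).
#' @return Named list metabolite -> character vector of ChEBI ids.
#' @export
read_chebi_map <- function(path) {
  d <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("metabolite", "chebi_id") %in% names(d))) {
    stop("ChEBI map needs columns 'metabolite' and 'chebi_id'")
  }
  stats::setNames(lapply(strsplit(d$chebi_id, ";", fixed = TRUE), trimws),
                  d$metabolite)
}

#' Link each metabolite to the enzymes annotated with its ChEBI ids
#'
#' A metabolite is linked to every catalog protein whose `chebi_id` tag set
#' intersects the metabolite's ChEBI ids. Metabolites without any ChEBI
#' mapping are omitted with a warning. Used for per-metabolite enzyme-pool
#' scatter analyses.
#'
#' @param catalog Annotation catalog tibble.
#' @param metabolite_chebi_map Named list metabolite -> ChEBI ids (see
#'   [read_chebi_map()]).
#' @return Named list metabolite -> character vector of accessions (possibly
#'   empty).
#' @export
link_metabolite_enzymes <- function(catalog, metabolite_chebi_map) {
  has_map <- lengths(metabolite_chebi_map) > 0
  if (!all(has_map)) {
    warning(sum(!has_map), " metabolite(s) without ChEBI mapping omitted")
  }
  chebi_sets <- lapply(strsplit(dplyr::coalesce(catalog$chebi_id, ""), ";",
                                fixed = TRUE), trimws)
  purrr::map(metabolite_chebi_map[has_map], function(ids) {
    hit <- vapply(chebi_sets, function(tags) any(ids %in% tags), logical(1))
    catalog$accession[hit]
  })
}

#' Build cofactor objects from formulas and molar data
#'
#' One object per named formula entry: the metabolite formula is evaluated
#' over the metabolite table (name and ChEBI columns), the enzyme formula over
#' the protein catalog, and both member lists are aggregated by simple
#' addition of molarities. Objects may overlap in membership; only the
#' three-way proteome partition is exclusive.
#'
#' @param catalog Annotation catalog tibble.
#' @param formulas Named list from [read_formula_file()]; entries with a
#'   `metabolites` formula get a metabolite aggregate, all entries get an
#'   enzyme aggregate.
#' @param metabolome_mM Named numeric vector: metabolite -> mM.
#' @param proteome_mM Named numeric vector: accession -> mM.
#' @param metabolite_chebi_map Named list metabolite -> ChEBI ids; used to
#'   evaluate metabolite formulas with `chebi=` leaves.
#' @return A tibble with one row per object: `object`, `n_metabolites`,
#'   `n_enzymes`, `metabolite_mM`, `enzyme_mM`, plus list-columns
#'   `metabolite_ids`, `enzyme_accessions`.
#' @export
build_cofactor_objects <- function(catalog, formulas, metabolome_mM, proteome_mM,
                                   metabolite_chebi_map = NULL) {
  if (anyDuplicated(names(formulas))) stop("formula names must be unique")
  met_catalog <- metabolite_pseudo_catalog(names(metabolome_mM), metabolite_chebi_map)
  rows <- purrr::imap(formulas, function(f, name) {
    enzymes <- if (!is.null(f$enzymes)) {
      evaluate_search_formula(catalog, f$enzymes)
    } else character()
    mets <- if (!is.null(f$metabolites)) {
      evaluate_search_formula(met_catalog, f$metabolites)
    } else character()
    enzyme_mM <- if (length(enzymes)) {
      suppressWarnings(aggregate_concentration(enzymes, proteome_mM))
    } else 0
    metabolite_mM <- if (length(mets)) {
      suppressWarnings(aggregate_concentration(mets, metabolome_mM))
    } else 0
    tibble::tibble(object = name,
                   n_metabolites = length(mets), n_enzymes = length(enzymes),
                   metabolite_mM = metabolite_mM, enzyme_mM = enzyme_mM,
                   metabolite_ids = list(mets), enzyme_accessions = list(enzymes))
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$n_enzymes == 0)) {
    warning("object(s) without member enzymes: ",
            paste(out$object[out$n_enzymes == 0], collapse = ", "))
  }
  out
}

# metabolite names reuse the catalog evaluator: names go in entry_name (and
# accession), ChEBI ids in chebi_id; other annotation fields stay empty
metabolite_pseudo_catalog <- function(met_names, chebi_map = NULL) {
  chebi <- if (is.null(chebi_map)) {
    rep("", length(met_names))
  } else {
    vapply(met_names, function(m) {
      paste(chebi_map[[m]] %||% character(), collapse = ";")
    }, character(1))
  }
  tibble::tibble(accession = met_names, entry_name = met_names,
                 ec_number = "", catalytic_activity = "",
                 nucleotide_binding = "", keyword_id = "", chebi_id = chebi)
}

#' Default (reconstructed) cofactor search formulas
#'
#' Returns the path of the formula file shipped with the package. The entries
#' are reconstructed, educated-guess formulas keyed on cofactor ChEBI ids and
#' EC presence; any catalog/formula pair can be supplied instead.
#'
#' @return Path to the installed YAML formula file.
#' @export
default_formula_file <- function() {
  system.file("extdata", "default_formulas.yml", package = "cachexomics",
              mustWork = TRUE)
}
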