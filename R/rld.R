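#' Summarize Rossmann-like-domain (RLD) tables
#'
#' RLDs are nucleotide-cofactor-binding folds; enzymes can carry one or more.
#' Input records arrive as a pre-computed table, one row per enzyme, with the
#' total chain length and the lengths of each RLD.
#'
#' @param records A data frame / tibble with columns `enzyme_id`,
#'   `chain_length_aa` (positive integer) and `rld_lengths_aa` (list-column of
#'   positive integer vectors), optionally a `species` column.
#' @return A list with:
#'   * `per_enzyme`: tibble with `percent_length` (100 x total RLD length /
#'     chain length) and `n_rld` per enzyme,
#'   * `count_histogram`: counts over the `1`, `2`, `>2` RLD-per-enzyme bins
#'     (per species when a `species` column is present),
#'   * `median_total_length`: median summed RLD length (per species likewise).
#' @export
rld_summary <- function(records) {
  records <- tibble::as_tibble(records)
  req <- c("enzyme_id", "chain_length_aa", "rld_lengths_aa")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) stop("RLD table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(records$chain_length_aa <= 0)) stop("chain_length_aa must be positive")
  if (any(lengths(records$rld_lengths_aa) == 0)) {
    stop("every record must list at least one RLD length")
  }
  total <- vapply(records$rld_lengths_aa, sum, numeric(1))
  if (any(total > records$chain_length_aa)) {
    stop("summed RLD lengths exceed chain length for some enzyme(s)")
  }
  per <- tibble::tibble(
    enzyme_id = records$enzyme_id,
    n_rld = lengths(records$rld_lengths_aa),
    total_rld_aa = total,
    percent_length = 100 * total / records$chain_length_aa
  )
  if ("species" %in% names(records)) per$species <- records$species
  bin <- cut(per$n_rld, breaks = c(0.5, 1.5, 2.5, Inf), labels = c("1", "2", ">2"))
  if ("species" %in% names(per)) {
    hist <- dplyr::count(tibble::tibble(species = per$species, bin = bin),
                         .data$species, .data$bin, .drop = FALSE)
    med <- dplyr::summarise(dplyr::group_by(per, .data$species),
                            median_total_length = stats::median(.data$total_rld_aa),
                            .groups = "drop")
  } else {
    hist <- dplyr::count(tibble::tibble(bin = bin), .data$bin, .drop = FALSE)
    med <- tibble::tibble(median_total_length = stats::median(per$total_rld_aa))
  }
  list(per_enzyme = per, count_histogram = hist, median_total_length = med)
}
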