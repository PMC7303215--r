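# Classification of variants along the three annotation axes (allele
# frequency, functionality, deleteriousness) and membership in the eight
# category combinations used by the burden analysis.

#' Classify variants along the three annotation axes
#'
#' Flags each variant as rare (reference-panel minor allele frequency below
#' `rare_af`; an absent frequency counts as rare, since a variant unobserved
#' in the panel is below any cutoff), functional (missense, splice site,
#' frameshift, stop gain/lost/retained, start lost, in-frame indel),
#' protein-truncating (the functional set minus missense and in-frame
#' indels), and deleterious (SIFT <= `sift_max` OR CADD >= `cadd_min`;
#' absent scores contribute false to their disjunct). Classification is
#' total: every variant gets all four flags.
#'
#' @param annotations Annotation tibble with columns `variant_id`,
#'   `consequence`, `sift`, `cadd`, `ref_panel_af`.
#' @param rare_af Rare-variant frequency cutoff (default 0.001; set 0.01 for
#'   the sensitivity re-analysis with a wider rare definition).
#' @param sift_max,cadd_min Deleteriousness cutoffs.
#' @param include_splice_region If `TRUE`, `splice_region` consequences are
#'   treated as functional (and protein-truncating) as well; off by default.
#' @return The input tibble with logical columns `is_rare`, `is_functional`,
#'   `is_ptv`, `is_deleterious` and one logical membership column per
#'   combination in [combo_names()].
#' @export
classify_variants <- function(annotations, rare_af = 0.001, sift_max = 0.05,
                              cadd_min = 15,
                              include_splice_region = FALSE) {
  if (rare_af <= 0 || sift_max <= 0 || cadd_min <= 0) {
    abort("classification thresholds must be positive")
  }
  fun_set <- functional_consequences(include_splice_region)
  ptv_set <- ptv_consequences()
  if (include_splice_region) ptv_set <- c(ptv_set, "splice_region")
  flags <- annotations |>
    dplyr::mutate(
      is_rare = is.na(.data$ref_panel_af) | .data$ref_panel_af < rare_af,
      is_functional = .data$consequence %in% fun_set,
      is_ptv = .data$consequence %in% ptv_set,
      is_deleterious = (!is.na(.data$sift) & .data$sift <= sift_max) |
        (!is.na(.data$cadd) & .data$cadd >= cadd_min))
  assign_combos(flags)
}

#' Assign membership in the eight category combinations
#'
#' Each combination is the conjunction of its named flags; e.g. membership
#' in rare-PTVs-deleterious requires `is_rare & is_ptv & is_deleterious`,
#' while plain `functional` requires only `is_functional`. The memberships
#' form a lattice: every rare-X set is a subset of X, every X-deleterious
#' set a subset of X, and every PTV set a subset of the matching functional
#' set (PTV consequences are functional by construction).
#'
#' @param flags Tibble with logical columns `is_rare`, `is_functional`,
#'   `is_ptv`, `is_deleterious`.
#' @return `flags` with one logical column per combination.
#' @export
assign_combos <- function(flags) {
  need <- c("is_rare", "is_functional", "is_ptv", "is_deleterious")
  if (!all(need %in% names(flags))) {
    abort("flags must contain is_rare, is_functional, is_ptv, is_deleterious")
  }
  flags |>
    dplyr::mutate(
      functional = .data$is_functional,
      rare_functional = .data$is_rare & .data$is_functional,
      functional_deleterious = .data$is_functional & .data$is_deleterious,
      rare_functional_deleterious = .data$is_rare & .data$is_functional &
        .data$is_deleterious,
      ptv = .data$is_ptv,
      rare_ptv = .data$is_rare & .data$is_ptv,
      ptv_deleterious = .data$is_ptv & .data$is_deleterious,
      rare_ptv_deleterious = .data$is_rare & .data$is_ptv &
        .data$is_deleterious)
}

#' Write the classification sidecar table
#'
#' @param categories Output of [classify_variants()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_category_table <- function(categories, path) {
  cols <- c("variant_id", "is_rare", "is_functional", "is_ptv",
            "is_deleterious", combo_names())
  readr::write_tsv(categories[, intersect(cols, names(categories))], path)
  invisible(path)
}
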