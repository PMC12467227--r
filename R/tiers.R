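## Confidence tiers: the bit-score rubric converting search hits into
## per-(species, component) H/M/L/P/ABS calls.

#' Scoring rubric for detection tiers
#'
#' Band boundaries follow the half-open convention: bits below
#' `absent_below` are not considered (ABS); `[absent_below, medium_min)` is
#' a low hit; `[medium_min, high_min)` a medium hit; `high_min` and above a
#' high hit. Defaults are the 100/150/300 rubric derived from inspecting
#' bit-score distributions of verified hits.
#'
#' @param absent_below Bits below which a hit is not considered (default 100).
#' @param medium_min Lower edge of the medium band (default 150).
#' @param high_min Lower edge of the high band (default 300).
#' @return A `rubric_config` list.
#' @export
rubric_config <- function(absent_below = 100, medium_min = 150, high_min = 300) {
  if (!(absent_below > 0 && absent_below <= medium_min && medium_min <= high_min))
    abort("rubric bands must satisfy 0 < absent_below <= medium_min <= high_min")
  structure(list(absent_below = absent_below, medium_min = medium_min,
                 high_min = high_min), class = "rubric_config")
}

#' Effective score of search hits: the max of overall and best-domain bits
#'
#' The maximum of the full-sequence and single-best-domain bit scores is
#' used to indicate presence, so a strong single domain is not penalized by
#' a fragmented overall alignment and vice versa.
#'
#' @param hits Hits tibble with `overall_bits` and `best_domain_bits`.
#' @return `hits` with an `effective_bits` column added.
#' @export
effective_score <- function(hits) {
  if (!all(c("overall_bits", "best_domain_bits") %in% names(hits)))
    abort("hits must carry `overall_bits` and `best_domain_bits`")
  if (any(is.na(hits$overall_bits) & is.na(hits$best_domain_bits)))
    abort("a hit has no computed score")
  hits |> mutate(effective_bits = pmax(.data$overall_bits,
                                       .data$best_domain_bits, na.rm = TRUE))
}

#' Assign detection tiers from bit scores
#'
#' @param bits Numeric vector of bit scores; `NA` means no hit.
#' @param rubric A [rubric_config()].
#' @return Character vector of tiers in `{H, M, L, ABS}`.
#' @export
assign_tier <- function(bits, rubric = rubric_config()) {
  if (any(is.nan(bits)) || any(bits < 0, na.rm = TRUE))
    abort("bit scores must be non-negative and not NaN")
  out <- rep("ABS", length(bits))
  out[!is.na(bits) & bits >= rubric$absent_below] <- "L"
  out[!is.na(bits) & bits >= rubric$medium_min] <- "M"
  out[!is.na(bits) & bits >= rubric$high_min] <- "H"
  out
}

#' Call one tier per (species, component) from search hits
#'
#' Keeps, per species and component, the hit maximizing the effective score
#' (ties broken by higher domain coverage, then lexicographically smallest
#' sequence id), assigns its tier, and completes the matrix: every
#' (species, component) pair gets exactly one row, ABS when no hit survives.
#'
#' @param hits Hits tibble; if `profiles` is supplied, domain coverage is
#'   (re)computed, otherwise an existing `coverage` column is used (0 if
#'   absent).
#' @param profiles Optional named list of `torc_profile`s for coverage.
#' @param rubric A [rubric_config()].
#' @param species Species to include (default: those present in `hits`).
#' @param components Components to include (default [TORC_COMPONENTS]).
#' @return Tier tibble: `species`, `component`, `tier`, `effective_bits`,
#'   `sequence_id`, `coverage`, `identity`, `source`, `flags`.
#' @export
call_tiers <- function(hits, profiles = NULL, rubric = rubric_config(),
                       species = NULL, components = TORC_COMPONENTS) {
  species <- species %||% unique(hits$species)
  if (!is.null(profiles)) hits <- domain_coverage(hits, profiles)
  if (!"coverage" %in% names(hits)) hits$coverage <- 0
  best <- hits |>
    filter(.data$component %in% components) |>
    effective_score() |>
    mutate(identity = purrr::map_dbl(
      .data$domains,
      function(d) if (!is.null(d) && nrow(d)) d$identity[which.max(d$bits)]
                  else NA_real_)) |>
    group_by(.data$species, .data$component) |>
    arrange(dplyr::desc(.data$effective_bits), dplyr::desc(.data$coverage),
            .data$sequence_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  grid <- tidyr::expand_grid(species = species, component = components)
  grid |>
    left_join(best |> select("species", "component", "effective_bits",
                             "sequence_id", "coverage", "identity"),
              by = c("species", "component")) |>
    mutate(
      tier = assign_tier(.data$effective_bits, rubric),
      source = "proteome",
      flags = "") |>
    select("species", "component", "tier", "effective_bits", "sequence_id",
           "coverage", "identity", "source", "flags")
}

add_flag <- function(flags, new) {
  ifelse(nzchar(flags), paste(flags, new, sep = ","), new)
}

has_flag <- function(flags, what) {
  vapply(strsplit(flags, ","), function(f) what %in% f, logical(1))
}

#' Screen tier calls for contaminant or misannotated hits
#'
#' A positive hit in a clade where every other member lacks the component is
#' suspect. It is demoted to ABS (keeping a `contaminant` flag for
#' reporting) when its domain coverage fails, or when reference identities
#' are supplied and its identity to an out-clade reference exceeds its
#' identity to in-clade references. A sole-positive hit that passes both
#' checks is kept and flagged `outlier_checked` — genuine phylogenetic
#' outliers must not be deleted silently.
#'
#' @param tiers Tier tibble from [call_tiers()].
#' @param clades Tibble with `species` and `clade`.
#' @param min_coverage Coverage pass threshold (default 0.25).
#' @param reference_identity Optional tibble `species`, `component`,
#'   `identity_in_clade`, `identity_out_clade` from a reference comparison.
#' @return `tiers` with demotions applied and `flags` updated.
#' @export
flag_contaminants <- function(tiers, clades, min_coverage = 0.25,
                              reference_identity = NULL) {
  x <- tiers |> left_join(clades, by = "species")
  if (any(is.na(x$clade))) abort("every species needs a clade label")
  x <- x |>
    group_by(.data$clade, .data$component) |>
    mutate(
      n_other_positive = sum(.data$tier != "ABS") - (.data$tier != "ABS"),
      n_other = dplyr::n() - 1L,
      sole_positive = .data$tier != "ABS" & .data$n_other > 0 &
        .data$n_other_positive == 0) |>
    ungroup()
  if (!is.null(reference_identity)) {
    x <- x |> left_join(reference_identity, by = c("species", "component"))
  } else {
    x$identity_in_clade <- NA_real_
    x$identity_out_clade <- NA_real_
  }
  cov_fail <- dplyr::coalesce(x$coverage, 0) < min_coverage
  ident_bad <- !is.na(x$identity_out_clade) & !is.na(x$identity_in_clade) &
    x$identity_out_clade > x$identity_in_clade
  demote <- x$sole_positive & (cov_fail | ident_bad)
  keep_checked <- x$sole_positive & !demote
  x |>
    mutate(
      flags = ifelse(demote, add_flag(.data$flags, "contaminant"), .data$flags),
      flags = ifelse(keep_checked, add_flag(.data$flags, "outlier_checked"),
                     .data$flags),
      tier = ifelse(demote, "ABS", .data$tier),
      effective_bits = ifelse(demote, NA_real_, .data$effective_bits)) |>
    select(-"clade", -"n_other_positive", -"n_other", -"sole_positive",
           -"identity_in_clade", -"identity_out_clade")
}
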