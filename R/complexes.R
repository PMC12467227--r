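## Complex-presence rules: RAPTOR implies TORC1; RICTOR (with or without
## SIN1) implies TORC2; SIN1 never affects the TORC2 call on its own.

#' Derive TORC1/TORC2 presence and architecture class per species
#'
#' TORC1 is called present when RAPTOR is detected at any positive tier
#' (H/M/L/P); TORC2 when RICTOR is. Read-rescued (P) detections count as
#' presence. SIN1 supports but never drives the TORC2 call.
#'
#' @param tiers Tier tibble with one row per (species, component); every
#'   species must carry all five components (ABS rows included).
#' @return Tibble: `species`, `torc1`, `torc2`, `architecture`, and the
#'   supporting per-component tiers as `tier_TOR` ... `tier_SIN1`.
#' @export
call_complexes <- function(tiers) {
  need <- TORC_COMPONENTS
  chk <- tiers |> count(.data$species) |> filter(.data$n < length(need))
  missing_any <- tiers |>
    group_by(.data$species) |>
    summarise(miss = paste(setdiff(need, .data$component), collapse = ","),
              .groups = "drop") |>
    filter(nzchar(.data$miss))
  if (nrow(missing_any) || nrow(chk))
    abort(sprintf("species missing component rows: %s",
                  paste(missing_any$species, collapse = ", ")))
  wide <- tiers |>
    select("species", "component", "tier") |>
    tidyr::pivot_wider(names_from = "component", values_from = "tier",
                       names_prefix = "tier_")
  positive <- function(t) t %in% c("H", "M", "L", "P")
  wide |>
    mutate(
      torc1 = positive(.data$tier_RAPTOR),
      torc2 = positive(.data$tier_RICTOR),
      architecture = dplyr::case_when(
        .data$torc1 & .data$torc2 ~ "both",
        .data$torc1 ~ "TORC1_only",
        .data$torc2 ~ "TORC2_only",
        TRUE ~ "neither")) |>
    select("species", "torc1", "torc2", "architecture",
           dplyr::all_of(paste0("tier_", need)))
}

#' Check dataset-wide component co-occurrence rules
#'
#' Three empirical constraints hold across well-annotated proteomes: SIN1 is
#' never found without RICTOR, and RAPTOR and/or RICTOR are always
#' accompanied by both TOR and LST8. Violations usually indicate annotation
#' or methodology problems and are reported for re-examination; the
#' pipeline keeps the rule-derived complex calls.
#'
#' @param tiers Tier tibble (complete species x component matrix).
#' @return Tibble of violations: `species`, `rule`, `components`; zero rows
#'   when all rules hold.
#' @export
check_consistency <- function(tiers) {
  wide <- tiers |>
    select("species", "component", "tier") |>
    tidyr::pivot_wider(names_from = "component", values_from = "tier")
  pos <- function(t) t %in% c("H", "M", "L", "P")
  out <- list(
    wide |>
      filter(pos(.data$SIN1) & !pos(.data$RICTOR)) |>
      mutate(rule = "SIN1_without_RICTOR", components = "SIN1,RICTOR"),
    wide |>
      filter((pos(.data$RAPTOR) | pos(.data$RICTOR)) & !pos(.data$TOR)) |>
      mutate(rule = "RAPTOR_or_RICTOR_without_TOR",
             components = "RAPTOR,RICTOR,TOR"),
    wide |>
      filter((pos(.data$RAPTOR) | pos(.data$RICTOR)) & !pos(.data$LST8)) |>
      mutate(rule = "RAPTOR_or_RICTOR_without_LST8",
             components = "RAPTOR,RICTOR,LST8"))
  bind_rows(out) |> select("species", "rule", "components") |>
    arrange(.data$species, .data$rule)
}
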