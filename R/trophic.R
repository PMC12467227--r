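## Composition summaries joining complex architecture to clade membership
## and trophic strategy (the machine twins of the pie-chart panels).

#' Trophic strategy categories recognised by the summaries
#' @format Character vector of the six categories plus `unknown`.
#' @export
TROPHIC_LEVELS <- c("autotroph", "mixotroph", "heterotroph",
                    "parasite_intracellular", "parasite_extracellular",
                    "endosymbiont")

summary_check <- function(tb, group_col) {
  s <- tb |> group_by(.data[[group_col]]) |> summarise(p = sum(.data$prop))
  stopifnot(all(abs(s$p - 1) < 1e-9))
  tb
}

#' Architecture-class proportions per clade
#'
#' @param complexes Complex-call tibble from [call_complexes()].
#' @param clades Tibble `species`, `clade` covering every species.
#' @return Tibble: `clade`, `architecture`, `n`, `n_clade`, `prop`; all
#'   four architecture classes appear for every clade and each clade's
#'   proportions sum to 1.
#' @export
architecture_proportions <- function(complexes, clades) {
  x <- complexes |> left_join(clades, by = "species")
  if (any(is.na(x$clade))) abort("every species needs a clade label")
  empty <- setdiff(unique(clades$clade), unique(x$clade))
  if (length(empty))
    abort(sprintf("clade with zero species: %s", paste(empty, collapse = ", ")))
  out <- x |>
    count(.data$clade, architecture = factor(.data$architecture,
                                             ARCHITECTURE_LEVELS),
          .drop = FALSE) |>
    group_by(.data$clade) |>
    mutate(n_clade = sum(.data$n), prop = .data$n / .data$n_clade) |>
    ungroup() |>
    mutate(architecture = as.character(.data$architecture))
  summary_check(out, "clade")
}

#' Trophic-strategy composition by architecture class (and transpose)
#'
#' Per architecture class, the fraction of species following each trophic
#' strategy — or, with `margin = "strategy"`, per strategy the fraction in
#' each architecture class. Species without a label are reported as
#' `unknown`.
#'
#' @param complexes Complex-call tibble.
#' @param trophic Tibble `species`, `strategy`.
#' @param margin `"architecture"` (rows are architecture classes, default)
#'   or `"strategy"` (the transposed table).
#' @return Tibble with `architecture`, `strategy`, `n`, the margin total
#'   and `prop`; proportions sum to 1 within each margin row.
#' @export
strategy_by_architecture <- function(complexes, trophic,
                                     margin = c("architecture", "strategy")) {
  margin <- match.arg(margin)
  x <- complexes |>
    left_join(trophic |> select("species", "strategy"), by = "species") |>
    mutate(strategy = dplyr::coalesce(.data$strategy, "unknown"))
  bad <- setdiff(unique(x$strategy), c(TROPHIC_LEVELS, "unknown"))
  if (length(bad))
    abort(sprintf("unrecognised strategy: %s", paste(bad, collapse = ", ")))
  tab <- x |> count(.data$architecture, .data$strategy)
  group_col <- margin
  out <- tab |>
    group_by(.data[[group_col]]) |>
    mutate(n_group = sum(.data$n), prop = .data$n / .data$n_group) |>
    ungroup()
  summary_check(out, group_col)
}
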