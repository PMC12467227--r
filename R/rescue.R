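## Phylogenetic-outlier rescue: absences that contradict close relatives in
## species with poor proteome completeness are re-examined against short
## peptide fragments (translated RNA-seq reads), yielding tier P.

#' Configuration for read-based rescue
#'
#' Acceptance gates for a read match: expectation value at most
#' `evalue_max`, bits above `bits_min`, and overlap with an annotated
#' domain region — except that matches shorter than `short_match_len`
#' residues (10 aa, the protein-level equivalent of a 30-nucleotide match,
#' where E-values and bit scores are unreliable) instead require percent
#' identity of at least `short_match_identity_min`.
#'
#' @param evalue_max Maximum E-value (default 1e-10).
#' @param bits_min Bit-score floor, exclusive (default 50).
#' @param short_match_len Matches shorter than this many residues use the
#'   identity gate (default 10).
#' @param short_match_identity_min Identity floor for short matches
#'   (default 0.70).
#' @param min_accepted_matches Accepted matches (at non-identical reference
#'   intervals) required to call tier P (default 2).
#' @param busco_low_threshold Completeness below which an absence is not
#'   trusted (default 0.70).
#' @param relative_radius Tip-to-tip distance in edges defining "close
#'   relatives" for outlier detection (default 3).
#' @param report_evalue_max Reporting threshold of the fragment aligner:
#'   alignments worse than this E-value are never reported as matches
#'   (default 1e-3, the usual aligner default).
#' @return A `rescue_config` list.
#' @export
rescue_config <- function(evalue_max = 1e-10, bits_min = 50,
                          short_match_len = 10,
                          short_match_identity_min = 0.70,
                          min_accepted_matches = 2,
                          busco_low_threshold = 0.70,
                          relative_radius = 3,
                          report_evalue_max = 1e-3) {
  if (!(short_match_identity_min > 0 && short_match_identity_min <= 1))
    abort("`short_match_identity_min` must lie in (0, 1]")
  if (bits_min <= 0) abort("`bits_min` must be positive")
  structure(list(evalue_max = evalue_max, bits_min = bits_min,
                 short_match_len = short_match_len,
                 short_match_identity_min = short_match_identity_min,
                 min_accepted_matches = min_accepted_matches,
                 busco_low_threshold = busco_low_threshold,
                 relative_radius = relative_radius,
                 report_evalue_max = report_evalue_max),
            class = "rescue_config")
}

#' Flag rescue candidates: absences contradicting close relatives
#'
#' A (species, component) pair is a rescue candidate when the component is
#' called ABS, the species' proteome completeness is below
#' `busco_low_threshold`, and either (a) at least half of the tip
#' neighbours within `relative_radius` edges carry the component at H/M/L
#' (with at least one such neighbour), or (b) every other member of the
#' species' clade carries it. Clade-consistent absence — all relatives also
#' lacking the component — is accepted as a real loss and never flagged;
#' absences in high-completeness proteomes are trusted.
#'
#' @param tiers Tier tibble.
#' @param tree Taxonomy tree (`phylo`) whose tips cover the matrix species.
#' @param metadata Tibble with `species`, `completeness` and (for the clade
#'   rule) `clade`.
#' @param config A [rescue_config()].
#' @return Tibble of candidates: `species`, `component`, `reason`.
#' @export
flag_outliers <- function(tiers, tree, metadata, config = rescue_config()) {
  miss <- setdiff(unique(tiers$species), tree$tip.label)
  if (length(miss))
    abort(sprintf("species not in tree: %s", paste(miss, collapse = ", ")))
  unit <- tree
  unit$edge.length <- rep(1, nrow(unit$edge))
  dmat <- ape::cophenetic.phylo(unit) # tip-to-tip distance in edges
  comp_df <- metadata |> select("species", "completeness")
  x <- tiers |>
    left_join(comp_df, by = "species") |>
    filter(.data$tier == "ABS",
           .data$completeness < config$busco_low_threshold)
  if (!nrow(x)) return(tibble(species = character(), component = character(),
                              reason = character()))
  pos_tiers <- c("H", "M", "L")
  tier_of <- tiers |> select("species", "component", "tier")

  radius_candidate <- function(sp, comp) {
    nb <- names(which(dmat[sp, ] > 0 & dmat[sp, ] <= config$relative_radius))
    if (!length(nb)) return(FALSE)
    st <- tier_of$tier[tier_of$component == comp & tier_of$species %in% nb]
    length(st) > 0 && sum(st %in% pos_tiers) >= length(st) / 2 &&
      any(st %in% pos_tiers)
  }
  clade_candidate <- function(sp, comp) {
    if (!"clade" %in% names(metadata)) return(FALSE)
    cl <- metadata$clade[match(sp, metadata$species)]
    members <- setdiff(metadata$species[metadata$clade %in% cl], sp)
    if (!length(members)) return(FALSE)
    st <- tier_of$tier[tier_of$component == comp & tier_of$species %in% members]
    length(st) > 0 && all(st %in% pos_tiers)
  }
  res <- purrr::pmap(list(x$species, x$component), function(sp, comp) {
    r <- radius_candidate(sp, comp)
    c_ <- clade_candidate(sp, comp)
    if (r || c_) tibble(species = sp, component = comp,
                        reason = if (r) "neighbour_majority" else "clade_uniform")
    else NULL
  })
  bind_rows(res)
}

#' Classify read matches against the match-acceptance gates
#'
#' @param matches Tibble of read matches with `bits`, `evalue`, `align_len`,
#'   `percent_identity` (fraction in [0,1]) and `overlaps_domain`.
#' @param config A [rescue_config()].
#' @return `matches` with `accept` (logical) and `reason` (first failed
#'   gate, or `"ok"`).
#' @export
classify_read_match <- function(matches, config = rescue_config()) {
  short <- matches$align_len < config$short_match_len
  reason <- rep("ok", nrow(matches))
  long_eval_fail <- !short & matches$evalue > config$evalue_max
  long_bits_fail <- !short & matches$bits <= config$bits_min
  short_id_fail <- short & matches$percent_identity < config$short_match_identity_min
  dom_fail <- !matches$overlaps_domain
  reason[dom_fail] <- "no_domain_overlap"
  reason[long_bits_fail] <- "bits"
  reason[long_eval_fail] <- "evalue"
  reason[short_id_fail] <- "short_identity"
  matches |> mutate(accept = reason == "ok", reason = reason)
}

#' Align peptide fragments to a component profile
#'
#' Uses the same position-specific local aligner as the proteome search
#' (gapped stage enabled for every reported fragment). Only alignments
#' within the aligner's reporting threshold (`report_evalue_max`) become
#' matches, as a real short-read aligner would only report such hits.
#'
#' @param profile A `torc_profile`.
#' @param fragments Named character vector of peptide fragments.
#' @param config A [rescue_config()].
#' @return Read-match tibble: `fragment_id`, `component`, `bits`, `evalue`,
#'   `align_len`, `percent_identity`, `ref_start`, `ref_end`,
#'   `overlaps_domain`.
#' @export
align_reads <- function(profile, fragments, config = rescue_config()) {
  empty <- tibble(fragment_id = character(), component = character(),
                  bits = double(), evalue = double(), align_len = integer(),
                  percent_identity = double(), ref_start = integer(),
                  ref_end = integer(), overlaps_domain = logical())
  if (!length(fragments)) return(empty)
  hits <- score_sequences(profile, fragments, domain_floor = 0,
                          prefilter_bits = 0, max_domains = 1L)
  if (!nrow(hits)) return(empty)
  dom <- hits |>
    tidyr::unnest("domains") |>
    mutate(
      evalue = nchar(unlist(fragments)[.data$sequence_id]) *
        profile$length * 2^(-.data$bits),
      overlaps_domain = purrr::map2_lgl(
        .data$prof_start, .data$prof_end,
        function(s, e) interval_overlap_length(s, e, profile$domain_regions) > 0)) |>
    filter(.data$evalue <= config$report_evalue_max)
  dom |>
    mutate(component = profile$component) |>
    select(fragment_id = "sequence_id", "component", "bits", "evalue",
           align_len = "naligned", percent_identity = "identity",
           ref_start = "prof_start", ref_end = "prof_end", "overlaps_domain")
}

#' Attempt rescue of one (species, component) candidate from fragments
#'
#' Fragments are aligned to the component profile; the call becomes P when
#' at least `min_accepted_matches` matches are accepted and their reference
#' intervals are not all identical (independent evidence along the
#' protein). Otherwise the ABS call is retained. Supplying no fragments is
#' itself informative (the negative-control situation) and returns ABS with
#' flag `no_reads`.
#'
#' @param fragments Named character vector of the species' peptide
#'   fragments (possibly empty).
#' @param profile The component's `torc_profile`.
#' @param config A [rescue_config()].
#' @return List: `tier` ("P" or "ABS"), `n_accepted`, `flag`, `matches`
#'   (classified read-match tibble).
#' @export
rescue_component <- function(fragments, profile, config = rescue_config()) {
  if (!length(fragments)) {
    return(list(tier = "ABS", n_accepted = 0L, flag = "no_reads",
                matches = classify_read_match(
                  align_reads(profile, character(), config), config)))
  }
  m <- align_reads(profile, fragments, config) |> classify_read_match(config)
  acc <- m |> filter(.data$accept)
  n_distinct_iv <- nrow(distinct(acc, .data$ref_start, .data$ref_end))
  ok <- nrow(acc) >= config$min_accepted_matches &&
    (config$min_accepted_matches < 2 || n_distinct_iv >= 2)
  list(tier = if (ok) "P" else "ABS",
       n_accepted = nrow(acc),
       flag = if (ok) "rescued" else "rescue_attempted",
       matches = m)
}

#' Run rescue over all flagged candidates and update the tier matrix
#'
#' Only ABS calls can change, and only to P (source `read_rescue`); H/M/L
#' calls are never altered.
#'
#' @param tiers Tier tibble.
#' @param candidates Candidate tibble from [flag_outliers()].
#' @param reads Named list (by species) of named character vectors of
#'   peptide fragments; a species absent from the list has no reads.
#' @param profiles Named list of `torc_profile`s.
#' @param config A [rescue_config()].
#' @return List: `tiers` (updated) and `report` (one row per candidate:
#'   `species`, `component`, `n_matches`, `n_accepted`, `outcome`, `flag`).
#' @export
rescue_components <- function(tiers, candidates, reads, profiles,
                              config = rescue_config()) {
  if (!nrow(candidates)) {
    return(list(tiers = tiers,
                report = tibble(species = character(), component = character(),
                                n_matches = integer(), n_accepted = integer(),
                                outcome = character(), flag = character())))
  }
  rep_rows <- purrr::pmap(list(candidates$species, candidates$component),
                          function(sp, comp) {
    frg <- reads[[sp]] %||% character()
    r <- rescue_component(frg, profiles[[comp]], config)
    tibble(species = sp, component = comp,
           n_matches = nrow(r$matches), n_accepted = r$n_accepted,
           outcome = r$tier, flag = r$flag)
  })
  report <- bind_rows(rep_rows)
  upd <- tiers
  for (k in seq_len(nrow(report))) {
    i <- which(upd$species == report$species[k] &
                 upd$component == report$component[k])
    if (length(i) != 1L || upd$tier[i] != "ABS") next
    upd$flags[i] <- add_flag(upd$flags[i], report$flag[k])
    if (report$outcome[k] == "P") {
      upd$tier[i] <- "P"
      upd$source[i] <- "read_rescue"
    }
  }
  list(tiers = upd, report = report)
}

#' Parse DIAMOND tabular output into a read-match tibble
#'
#' Expects the column layout `qseqid sseqid pident length evalue bitscore
#' sstart send` (subject = component reference). Subject coordinates are
#' converted from 1-based inclusive to half-open 0-based; `pident` from
#' percent to fraction.
#'
#' @param path Path to the tabular file.
#' @param profiles Optional named list of `torc_profile`s (keyed by the
#'   sseqid component) used to evaluate domain overlap; without profiles
#'   `overlaps_domain` is `NA`.
#' @return Read-match tibble as in [align_reads()].
#' @export
parse_diamond <- function(path, profiles = NULL) {
  cols <- c("fragment_id", "component", "pident", "length", "evalue",
            "bitscore", "sstart", "send")
  df <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                        comment = "#")
  out <- df |>
    mutate(ref_start = as.integer(pmin(.data$sstart, .data$send) - 1L),
           ref_end = as.integer(pmax(.data$sstart, .data$send)),
           percent_identity = .data$pident / 100,
           align_len = as.integer(.data$length),
           bits = .data$bitscore)
  ov <- if (is.null(profiles)) NA else purrr::pmap_lgl(
    list(out$component, out$ref_start, out$ref_end),
    function(comp, s, e) {
      pr <- profiles[[comp]]
      if (is.null(pr)) NA else
        interval_overlap_length(s, e, pr$domain_regions) > 0
    })
  out |>
    mutate(overlaps_domain = ov) |>
    select("fragment_id", "component", "bits", "evalue", "align_len",
           "percent_identity", "ref_start", "ref_end", "overlaps_domain")
}
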