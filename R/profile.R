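## Profile models: position-specific log2-odds score matrices built from
## reference alignments, standing in for the downloaded family HMMs used in
## real runs (where HMMER domtblout files are ingested instead).

#' Build a profile model from a reference multiple sequence alignment
#'
#' Alignment columns with at least `occupancy_min` residue occupancy become
#' match columns. Per-column residue frequencies receive +1/20 pseudocounts
#' against the background, so a column observed `n` times scores residue `a`
#' as `log2(((c_a + 1/20) / (n + 1)) / bg_a)` bits. A column whose residues
#' are background-distributed therefore scores near 0 for every residue.
#'
#' @param msa Named character vector of equal-length aligned amino-acid
#'   sequences (gaps `-` or `.`), or a `Biostrings::AAStringSet`.
#' @param component Component (family) name, e.g. `"RICTOR"`.
#' @param background Residue background frequencies (default uniform 1/20),
#'   in [aa_alphabet()] order; must sum to 1.
#' @param occupancy_min Minimum fraction of non-gap residues for a column to
#'   become a match column (default 0.5).
#' @param gap_open,gap_extend Affine gap penalties in bits used when scoring
#'   sequences against the profile.
#' @param domain_regions Optional list of half-open, 0-based `c(start, end)`
#'   intervals on the match columns marking diagnostic domains; defaults to
#'   the single full-length interval.
#' @return A `torc_profile` object.
#' @export
build_profile <- function(msa, component,
                          background = rep(1 / 20, 20),
                          occupancy_min = 0.5,
                          gap_open = 10, gap_extend = 1,
                          domain_regions = NULL) {
  if (inherits(msa, "XStringSet")) msa <- setNames(as.character(msa), names(msa))
  if (!length(msa)) abort("empty alignment")
  if (length(msa) < 2) abort("a profile needs at least 2 aligned sequences")
  if (length(unique(nchar(msa))) != 1L)
    abort("ragged alignment: aligned sequences differ in length")
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-8)
    abort("`background` must be 20 frequencies summing to 1")
  aa <- aa_alphabet()
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  mat[mat == "."] <- "-"
  occupancy <- colMeans(mat != "-")
  match_cols <- which(occupancy >= occupancy_min)
  if (!length(match_cols)) abort("no alignment column reaches the occupancy minimum")

  scores <- matrix(0, nrow = length(match_cols), ncol = 20,
                   dimnames = list(NULL, aa))
  for (k in seq_along(match_cols)) {
    col <- mat[, match_cols[k]]
    col <- col[col %in% aa]
    n <- length(col)
    cnt <- tabulate(match(col, aa), nbins = 20)
    freq <- (cnt + 1 / 20) / (n + 1)
    scores[k, ] <- log2(freq / background)
  }
  L <- length(match_cols)
  if (is.null(domain_regions)) domain_regions <- list(c(0L, L))
  dr <- do.call(rbind, lapply(domain_regions, function(x) as.integer(x[1:2])))
  if (any(dr[, 1] < 0) || any(dr[, 2] > L) || any(dr[, 1] >= dr[, 2]))
    abort("`domain_regions` must be half-open intervals within the profile")

  structure(list(
    component = component,
    length = L,
    scores = scores,
    consensus = max.col(scores, ties.method = "first") - 1L, # 0-based codes
    background = background,
    gap_open = gap_open,
    gap_extend = gap_extend,
    domain_regions = dr,
    alignment_columns = match_cols
  ), class = "torc_profile")
}

#' @export
print.torc_profile <- function(x, ...) {
  cat(sprintf("<torc_profile> %s: %d match columns, %d domain region(s)\n",
              x$component, x$length, nrow(x$domain_regions)))
  cat(sprintf("  consensus score %.1f bits; gap open/extend %.1f/%.1f bits\n",
              profile_max_bits(x), x$gap_open, x$gap_extend))
  invisible(x)
}

#' Maximum attainable bit score of a profile (its consensus scored exactly)
#' @param profile A `torc_profile`.
#' @return Bits.
#' @export
profile_max_bits <- function(profile) {
  sum(apply(profile$scores, 1, max))
}

#' Consensus sequence of a profile
#' @param profile A `torc_profile`.
#' @return Single amino-acid string of length `profile$length`.
#' @export
profile_consensus <- function(profile) {
  paste0(aa_alphabet()[profile$consensus + 1L], collapse = "")
}

## Core search --------------------------------------------------------------

#' Score sequences against one profile
#'
#' Local alignment of each sequence against the profile's position-specific
#' score matrix. An ungapped best-diagonal scan filters every sequence;
#' sequences reaching `prefilter_bits` get a full affine-gap alignment, and
#' further non-overlapping domains are extracted by masking until the next
#' domain falls below `domain_floor` bits. The hit's `overall_bits` is the
#' sum of accepted domain scores and `best_domain_bits` the best single
#' domain. A crude expectation value `evalue = m * n * 2^-bits` (query
#' length x profile length) accompanies each hit.
#'
#' @param profile A `torc_profile`.
#' @param seqs Named character vector of amino-acid sequences.
#' @param domain_floor Minimum bits for a domain to be reported (default 10).
#' @param prefilter_bits Ungapped score needed to trigger the full gapped
#'   stage and its multi-domain masking loop (default 40, calibrated above
#'   the ungapped null tail so background sequences never enter the gapped
#'   stage and cannot accumulate summed junk domains); below it the single
#'   best ungapped diagonal is reported as the hit's only domain.
#' @param max_domains Cap on domains per sequence.
#' @return Tibble with one row per sequence that produced at least one
#'   domain: `sequence_id`, `component`, `overall_bits`, `best_domain_bits`,
#'   `n_domains`, `evalue` and a `domains` list-column (per-domain tibbles
#'   with half-open 0-based `seq_start/seq_end`, `prof_start/prof_end`,
#'   `bits`, `naligned`, `identity`).
#' @export
score_sequences <- function(profile, seqs, domain_floor = 10,
                            prefilter_bits = 40, max_domains = 8L) {
  stopifnot(inherits(profile, "torc_profile"))
  seqs <- unlist(seqs)
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  ids <- names(seqs)
  dom <- .pssm_scan(profile$scores, profile$consensus, unname(seqs),
                    profile$gap_open, profile$gap_extend,
                    domain_floor, prefilter_bits, as.integer(max_domains))
  if (!length(dom$seq)) {
    return(tibble(sequence_id = character(), component = character(),
                  overall_bits = double(), best_domain_bits = double(),
                  n_domains = integer(), evalue = double(),
                  domains = list()))
  }
  # base-R aggregation: this sits in the pipeline's hot loop
  idx <- split(seq_along(dom$seq), dom$seq)
  which_seq <- as.integer(names(idx))
  overall <- vapply(idx, function(ix) sum(dom$bits[ix]), 0)
  bestd <- vapply(idx, function(ix) max(dom$bits[ix]), 0)
  domlist <- lapply(idx, function(ix) tibble::new_tibble(list(
    seq_start = dom$seq_start[ix], seq_end = dom$seq_end[ix],
    prof_start = dom$prof_start[ix], prof_end = dom$prof_end[ix],
    bits = dom$bits[ix], naligned = dom$naligned[ix],
    identity = dom$identity[ix]), nrow = length(ix)))
  lens <- nchar(seqs)
  tibble::new_tibble(list(
    sequence_id = ids[which_seq],
    component = rep(profile$component, length(idx)),
    overall_bits = unname(overall),
    best_domain_bits = unname(bestd),
    n_domains = unname(lengths(idx)),
    evalue = unname(as.numeric(lens[which_seq]) * profile$length * 2^(-bestd)),
    domains = unname(domlist)), nrow = length(idx))
}

#' Score one sequence against a profile
#'
#' Convenience wrapper around [score_sequences()] for a single sequence.
#' An empty sequence yields the defined no-hit row (`overall_bits = 0`,
#' no domains).
#'
#' @inheritParams score_sequences
#' @param seq A single amino-acid string.
#' @param sequence_id Identifier for the returned row.
#' @return One-row hit tibble (see [score_sequences()]).
#' @export
score_sequence <- function(profile, seq, sequence_id = "seq1", ...) {
  stopifnot(length(seq) == 1L)
  hit <- score_sequences(profile, setNames(seq, sequence_id), ...)
  if (!nrow(hit)) {
    hit <- tibble(sequence_id = sequence_id, component = profile$component,
                  overall_bits = 0, best_domain_bits = 0, n_domains = 0L,
                  evalue = NA_real_, domains = list(tibble(
                    seq_start = integer(), seq_end = integer(),
                    prof_start = integer(), prof_end = integer(),
                    bits = double(), naligned = integer(),
                    identity = double())))
  }
  hit
}

#' Score a whole proteome against a set of component profiles
#'
#' @param profiles Named list of `torc_profile` objects (one per component).
#' @param proteome Named character vector of protein sequences.
#' @param species Species identifier attached to every hit.
#' @param ... Passed to [score_sequences()].
#' @return Hits tibble with a leading `species` column.
#' @export
score_proteome <- function(profiles, proteome, species, ...) {
  hits <- purrr::map(profiles, score_sequences, seqs = proteome, ...) |>
    bind_rows()
  dplyr::bind_cols(tibble(species = rep(species, nrow(hits))), hits)
}

#' Fraction of a profile's diagnostic domain regions covered by a hit
#'
#' Coverage is the length of the profile's annotated domain regions that the
#' hit's aligned profile intervals overlap, divided by the regions' total
#' length. Hits with no aligned domain section (coverage 0) indicate
#' contamination or improper annotation and fail the check.
#'
#' @param hits Hits tibble (from [score_proteome()] or [parse_domtblout()]).
#' @param profiles Named list of `torc_profile`s keyed by component.
#' @param min_coverage Pass threshold (default 0.25).
#' @return `hits` with `coverage` and `coverage_pass` columns added.
#' @export
domain_coverage <- function(hits, profiles, min_coverage = 0.25) {
  cov <- purrr::map2_dbl(hits$component, hits$domains, function(comp, dom) {
    prof <- profiles[[comp]]
    if (is.null(prof)) abort(sprintf("no profile supplied for component %s", comp))
    tot <- interval_union_length(prof$domain_regions)
    if (tot == 0 || is.null(dom) || !nrow(dom)) return(0)
    hitsiv <- interval_merge(cbind(dom$prof_start, dom$prof_end))
    ov <- sum(vapply(seq_len(nrow(hitsiv)), function(r) {
      interval_overlap_length(hitsiv[r, 1], hitsiv[r, 2], prof$domain_regions)
    }, numeric(1)))
    ov / tot
  })
  hits |> mutate(coverage = cov, coverage_pass = cov >= min_coverage)
}
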