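## Ingest real HMMER3 per-domain tabular output so the pipeline can run on
## genuine hmmsearch results instead of the in-package scorer.

#' Parse a HMMER3 `--domtblout` file into a hits tibble
#'
#' Maps the full-sequence score column to `overall_bits`, per-domain scores
#' to domain bits, and the `ali from/to` (sequence) and `hmm from/to`
#' (profile) 1-based inclusive coordinates to half-open 0-based intervals.
#' Rows are grouped by (target sequence, query profile); the query name is
#' taken as the component.
#'
#' @param path Path to a whitespace-delimited domtblout file (`#` comment
#'   lines ignored).
#' @param species Optional species id attached to all hits (default: the
#'   file name without extension).
#' @return Hits tibble compatible with [score_proteome()] output.
#' @export
parse_domtblout <- function(path, species = NULL) {
  species <- species %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  rows <- which(keep)
  empty <- tibble(species = character(), sequence_id = character(),
                  component = character(), overall_bits = double(),
                  best_domain_bits = double(), n_domains = integer(),
                  evalue = double(), domains = list())
  if (!length(rows)) return(empty)

  parsed <- lapply(rows, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22)
      abort(sprintf("malformed domtblout row at line %d: %d fields (need >= 22)",
                    i, length(f)))
    num <- suppressWarnings(as.numeric(f[c(7, 8, 14, 16, 17, 18, 19)]))
    if (anyNA(num))
      abort(sprintf("malformed domtblout row at line %d: non-numeric score/coordinate",
                    i))
    tibble(
      sequence_id = f[1], component = f[4],
      seq_evalue = num[1], overall_bits = num[2], dom_bits = num[3],
      hmm_from = num[4], hmm_to = num[5], ali_from = num[6], ali_to = num[7])
  })
  df <- bind_rows(parsed)
  df |>
    group_by(.data$sequence_id, .data$component) |>
    summarise(
      overall_bits = .data$overall_bits[1],
      best_domain_bits = max(.data$dom_bits),
      n_domains = dplyr::n(),
      evalue = .data$seq_evalue[1],
      domains = list(tibble(
        seq_start = as.integer(ali_from - 1L),
        seq_end = as.integer(ali_to),
        prof_start = as.integer(hmm_from - 1L),
        prof_end = as.integer(hmm_to),
        bits = dom_bits,
        naligned = as.integer(ali_to - ali_from + 1L),
        identity = NA_real_)),
      .groups = "drop") |>
    mutate(species = species) |>
    select("species", "sequence_id", "component", "overall_bits",
           "best_domain_bits", "n_domains", "evalue", "domains")
}
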