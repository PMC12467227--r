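## End-to-end orchestration over files on disk: search -> tiers -> complex
## calls -> consistency -> rescue -> loss inference -> summaries, with a
## machine-readable run manifest.

#' Pipeline run configuration
#'
#' @param proteome_dir Directory of per-species proteome FASTAs (`.faa` /
#'   `.fa` / `.fasta`; file name = species id), or `NULL` when running from
#'   `domtblout_dir`.
#' @param msa_dir Directory of per-component reference alignments (file
#'   name = component), used to build profiles.
#' @param tree_file Newick taxonomy tree.
#' @param metadata_file TSV with `species`, `clade`, `completeness` (and
#'   optionally `strategy`).
#' @param reads_dir Optional directory of per-species fragment FASTAs.
#' @param out_dir Output directory.
#' @param domtblout_dir Optional directory of per-species HMMER domtblout
#'   files; when given, parsing replaces the in-package scorer.
#' @param rubric A [rubric_config()].
#' @param rescue A [rescue_config()].
#' @param unknown_policy Passed to [count_losses_per_trait()].
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the config is used to simulate).
#' @return A `run_config` list (validated: referenced paths must exist).
#' @export
run_config <- function(proteome_dir = NULL, msa_dir = NULL, tree_file,
                       metadata_file, reads_dir = NULL, out_dir,
                       domtblout_dir = NULL,
                       rubric = rubric_config(), rescue = rescue_config(),
                       unknown_policy = c("absent", "missing"), seed = 1) {
  unknown_policy <- match.arg(unknown_policy)
  for (p in c(proteome_dir, msa_dir, tree_file, metadata_file, reads_dir,
              domtblout_dir))
    if (!is.null(p) && !file.exists(p)) abort(sprintf("path not found: %s", p))
  if (is.null(proteome_dir) && is.null(domtblout_dir))
    abort("need `proteome_dir` (with `msa_dir`) or `domtblout_dir`")
  structure(list(proteome_dir = proteome_dir, msa_dir = msa_dir,
                 tree_file = tree_file, metadata_file = metadata_file,
                 reads_dir = reads_dir, out_dir = out_dir,
                 domtblout_dir = domtblout_dir, rubric = rubric,
                 rescue = rescue, unknown_policy = unknown_policy,
                 seed = as.integer(seed)),
            class = "run_config")
}

list_species_files <- function(dir, exts = c("faa", "fa", "fasta")) {
  f <- list.files(dir, full.names = TRUE)
  f <- f[tools::file_ext(f) %in% exts]
  setNames(f, tools::file_path_sans_ext(basename(f)))
}

load_profiles <- function(msa_dir) {
  files <- list_species_files(msa_dir, exts = c("afa", "faa", "fa", "fasta",
                                                "sto", "stk"))
  purrr::imap(as.list(files), function(p, comp) build_profile(read_msa(p), comp))
}

#' Search stage: score every proteome (or parse every domtblout file)
#'
#' A proteome that fails to read is logged, skipped, and recorded in the
#' returned attributes rather than aborting the run.
#'
#' @param config A [run_config()].
#' @return Hits tibble; attribute `skipped` lists failed inputs.
#' @export
run_search <- function(config) {
  skipped <- character(0)
  if (!is.null(config$domtblout_dir)) {
    files <- list_species_files(config$domtblout_dir,
                                exts = c("domtblout", "tbl", "txt", "tsv"))
    hits <- purrr::imap(as.list(files), function(p, sp) {
      tryCatch(parse_domtblout(p, species = sp), error = function(e) {
        message(sprintf("skipping %s: %s", p, conditionMessage(e)))
        skipped <<- c(skipped, p); NULL
      })
    }) |> bind_rows()
  } else {
    profiles <- load_profiles(config$msa_dir)
    files <- list_species_files(config$proteome_dir)
    hits <- purrr::imap(as.list(files), function(p, sp) {
      tryCatch(score_proteome(profiles, read_fasta(p), species = sp),
               error = function(e) {
                 message(sprintf("skipping %s: %s", p, conditionMessage(e)))
                 skipped <<- c(skipped, p); NULL
               })
    }) |> bind_rows()
  }
  attr(hits, "skipped") <- skipped
  hits
}

write_stage_tsv <- function(x, out_dir, name) {
  flat <- x |> select(!dplyr::where(is.list))
  readr::write_tsv(flat, file.path(out_dir, name))
  nrow(flat)
}

#' Run the full pipeline and write all outputs
#'
#' Executes search, tier calling (with contaminant screen), complex calls,
#' consistency checks, outlier rescue (when reads are available), Dollo
#' loss inference and the two composition summaries. Outputs under
#' `out_dir`: `hits.tsv`, `tiers.tsv`, `complexes.tsv`, `violations.tsv`,
#' `rescue.tsv`, `losses.tsv`, `summary_clade.tsv`, `summary_trophic.tsv`,
#' `annotated_<trait>.nwk` and `manifest.json`. Reruns on unchanged inputs
#' are byte-identical.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  metadata <- readr::read_tsv(config$metadata_file, show_col_types = FALSE)
  tree <- read_taxon_tree(config$tree_file)
  stage_rows <- list()
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    expr
  }

  hits <- stage("search", run_search(config))
  stage_rows$search <- write_stage_tsv(hits, config$out_dir, "hits.tsv")

  profiles <- if (!is.null(config$msa_dir)) load_profiles(config$msa_dir)
              else NULL
  tiers <- stage("tiers", {
    tr <- call_tiers(hits, profiles = profiles, rubric = config$rubric,
                     species = metadata$species)
    if ("clade" %in% names(metadata))
      tr <- flag_contaminants(tr, metadata |> select("species", "clade"))
    tr
  })
  stage_rows$tiers <- write_stage_tsv(tiers, config$out_dir, "tiers.tsv")

  complexes <- stage("complexes", call_complexes(tiers))
  stage_rows$complexes <- write_stage_tsv(complexes, config$out_dir,
                                          "complexes.tsv")

  violations <- stage("consistency", check_consistency(tiers))
  stage_rows$consistency <- write_stage_tsv(violations, config$out_dir,
                                            "violations.tsv")

  rescue_report <- tibble(species = character(), component = character(),
                          n_matches = integer(), n_accepted = integer(),
                          outcome = character(), flag = character())
  tiers2 <- tiers
  if (!is.null(config$reads_dir) && !is.null(profiles)) {
    cand <- flag_outliers(tiers, tree, metadata, config$rescue)
    reads <- purrr::map(as.list(list_species_files(config$reads_dir)),
                        read_fasta)
    res <- stage("rescue",
                 rescue_components(tiers, cand, reads, profiles, config$rescue))
    tiers2 <- res$tiers
    rescue_report <- res$report
    if (nrow(rescue_report)) {
      complexes <- call_complexes(tiers2)
      stage_rows$complexes <- write_stage_tsv(complexes, config$out_dir,
                                              "complexes.tsv")
      stage_rows$tiers <- write_stage_tsv(tiers2, config$out_dir, "tiers.tsv")
    }
  }
  stage_rows$rescue <- write_stage_tsv(rescue_report, config$out_dir,
                                       "rescue.tsv")

  losses <- stage("losses", count_losses_per_trait(
    tiers2, tree, unknown_policy = config$unknown_policy,
    metadata = metadata,
    busco_low_threshold = config$rescue$busco_low_threshold))
  stage_rows$losses <- write_stage_tsv(losses$summary, config$out_dir,
                                       "losses.tsv")
  for (nm in names(losses$reconstructions))
    write_annotated_newick(losses$reconstructions[[nm]],
                           file.path(config$out_dir,
                                     sprintf("annotated_%s.nwk", nm)))

  s_clade <- stage("summaries", architecture_proportions(
    complexes, metadata |> select("species", "clade")))
  n_clade <- write_stage_tsv(s_clade, config$out_dir, "summary_clade.tsv")
  trophic <- if ("strategy" %in% names(metadata))
    metadata |> select("species", "strategy") else
      tibble(species = metadata$species, strategy = NA_character_)
  s_troph <- strategy_by_architecture(complexes, trophic)
  n_troph <- write_stage_tsv(s_troph, config$out_dir, "summary_trophic.tsv")
  stage_rows$summaries <- list(clade = n_clade, trophic = n_troph)

  manifest <- list(
    package_version = as.character(utils::packageVersion("torcscan")),
    seed = config$seed,
    unknown_policy = config$unknown_policy,
    config_hash = config_hash(config),
    n_species = length(unique(metadata$species)),
    skipped_inputs = attr(hits, "skipped") %||% character(0),
    stages = stage_rows,
    n_stages = length(stage_rows),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest_out <- manifest
  manifest_out$elapsed_s <- NULL # keep reruns byte-identical
  jsonlite::write_json(manifest_out, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  x <- config
  class(x) <- NULL
  x$rubric <- unclass(x$rubric); x$rescue <- unclass(x$rescue)
  s <- jsonlite::toJSON(x, auto_unbox = TRUE)
  h <- 0
  for (k in utf8ToInt(as.character(s))) h <- (h * 131 + k) %% 2147483629
  sprintf("%08x", as.integer(h))
}
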