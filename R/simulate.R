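## Synthetic data: everything the pipeline consumes, generated with the
## statistical structure the analysis assumes — irreversible losses planted
## on a clade-structured taxonomy tree, homologs emitted at controlled
## divergence among background decoys, proteome degradation emulating poor
## completeness, translated short-read fragments, and trophic labels
## correlated with TORC2 retention.

#' Configuration of the synthetic-data generator
#'
#' Defaults encode the study conditions the pipeline targets: five
#' components all present at the root (both complexes in the last common
#' ancestor), near-universal retention of TOR/LST8 with losses concentrated
#' on the TORC2 side (RICTOR, and SIN1 at a slightly higher rate), moderate
#' sequence divergence, and a strong association between TORC2 loss and
#' autotrophy.
#'
#' @param n_tips Number of species (>= 3).
#' @param n_clades Number of named clades partitioning the tips.
#' @param seed Master seed; identical config => bit-identical outputs.
#' @param components Component names (default [TORC_COMPONENTS]).
#' @param loss_prob_per_edge Per-edge loss probability, recycled or named
#'   per component.
#' @param root_state Present at root? Recycled or named per component.
#' @param divergence Expected per-site substitution rate of emitted
#'   homologs relative to the profile consensus, in [0, 1.5] (capped at 1
#'   per site).
#' @param completeness Fraction of proteins retained per proteome.
#' @param fragmentation_prob Probability a retained protein is truncated.
#' @param read_length_aa Peptide fragment length in residues (>= 5).
#' @param read_error_rate Per-residue substitution probability on reads.
#' @param trophic_assoc Probability a TORC2-lacking tip is labeled
#'   autotroph (1/4 = no association).
#' @param n_decoys Background proteins per proteome.
#' @param decoy_length_range Length range (aa) of background proteins.
#' @param n_reads_per_component Fragments emitted per present component.
#' @param n_background_reads Background fragments per species.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tips = 30, n_clades = 4, seed = 1,
                       components = TORC_COMPONENTS,
                       loss_prob_per_edge = c(TOR = 0, LST8 = 0, RAPTOR = 0.02,
                                              RICTOR = 0.08, SIN1 = 0.10),
                       root_state = TRUE,
                       divergence = 0.05,
                       completeness = 1.0,
                       fragmentation_prob = 0.05,
                       read_length_aa = 33,
                       read_error_rate = 0.02,
                       trophic_assoc = 0.9,
                       n_decoys = 50,
                       decoy_length_range = c(200, 1500),
                       n_reads_per_component = 30,
                       n_background_reads = 20) {
  if (n_tips < 3) abort("`n_tips` must be >= 3 (no informative root split below)")
  if (divergence < 0 || divergence > 1.5)
    abort("`divergence` must lie in [0, 1.5]")
  if (read_length_aa < 5) abort("`read_length_aa` must be >= 5")
  assert_prob(completeness, "completeness")
  assert_prob(fragmentation_prob, "fragmentation_prob")
  assert_prob(read_error_rate, "read_error_rate")
  assert_prob(trophic_assoc, "trophic_assoc")
  lp <- expand_per_component(loss_prob_per_edge, components, "loss_prob_per_edge")
  assert_prob(lp, "loss_prob_per_edge")
  rs <- expand_per_component(root_state, components, "root_state")
  structure(list(
    n_tips = as.integer(n_tips), n_clades = as.integer(max(1, min(n_clades, n_tips))),
    seed = as.integer(seed), components = components,
    loss_prob_per_edge = lp, root_state = rs,
    divergence = divergence, completeness = completeness,
    fragmentation_prob = fragmentation_prob,
    read_length_aa = as.integer(read_length_aa),
    read_error_rate = read_error_rate, trophic_assoc = trophic_assoc,
    n_decoys = as.integer(n_decoys),
    decoy_length_range = as.integer(decoy_length_range),
    n_reads_per_component = as.integer(n_reads_per_component),
    n_background_reads = as.integer(n_background_reads)
  ), class = "sim_config")
}

expand_per_component <- function(x, components, name) {
  if (is.null(names(x))) {
    if (length(x) == 1L) return(setNames(rep(x, length(components)), components))
    if (length(x) == length(components)) return(setNames(x, components))
    abort(sprintf("`%s` must be length 1, one per component, or named", name))
  }
  out <- setNames(rep(if (is.logical(x)) TRUE else 0, length(components)),
                  components)
  extra <- setdiff(names(x), components)
  if (length(extra)) abort(sprintf("`%s` names unknown: %s", name,
                                   paste(extra, collapse = ", ")))
  out[names(x)] <- x
  out
}

#' Simulate a rooted, clade-structured taxonomy tree
#'
#' Tips (`sp01`, `sp02`, ...) are partitioned into `n_clades` labeled
#' clades; within each clade the topology is built by random agglomerative
#' merging joining 2-4 groups at a time, so taxonomy-style polytomies
#' arise naturally (and at least one is guaranteed whenever `n_tips >= 6`).
#' Internal nodes all carry labels (clade names at clade roots, `nXX`
#' elsewhere) so edges can be identified by their child label.
#'
#' @param config A [sim_config()].
#' @return A `phylo` tree with labeled internal nodes; clade membership is
#'   recoverable with [clade_map()].
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(str_seed(config$seed, "taxonomy"), {
    n <- config$n_tips
    k <- config$n_clades
    tips <- sprintf("sp%02d", seq_len(n))
    # near-even partition with >= 1 tip per clade
    sizes <- rep(n %/% k, k)
    if (n %% k) {
      idx <- sample.int(k, n %% k)
      sizes[idx] <- sizes[idx] + 1
    }
    groups <- split(tips, rep(seq_len(k), times = sizes))
    counter <- new.env(); counter$i <- 0L
    next_lab <- function() { counter$i <- counter$i + 1L; sprintf("n%02d", counter$i) }
    build <- function(items, top_label) {
      # items: character vector of newick fragments; merge until one remains
      while (length(items) > 1) {
        m <- min(length(items), sample(2:4, 1))
        pick <- sample.int(length(items), m)
        lab <- if (length(items) == m) top_label else next_lab()
        merged <- sprintf("(%s)%s", paste(items[pick], collapse = ","), lab)
        items <- c(items[-pick], merged)
      }
      items
    }
    clade_names <- sprintf("clade_%02d", seq_len(k))
    sub <- purrr::map2_chr(groups, clade_names, function(g, nm) {
      if (length(g) == 1) g else build(g, nm)
    })
    root_lab <- "root"
    nwk <- if (k == 1) {
      if (length(groups[[1]]) == 1) sprintf("(%s)%s;", sub, root_lab)
      else paste0(sub, ";") # clade root is the tree root
    } else sprintf("(%s)%s;", paste(sub, collapse = ","), root_lab)
    tr <- ape::read.tree(text = nwk)
    # taxonomy trees are multifurcating: guarantee a polytomy for n >= 6
    if (n >= 6 && !any(tabulate(tr$edge[, 1]) >= 3)) {
      ntip <- length(tr$tip.label)
      inner <- setdiff(unique(tr$edge[, 1]), root_of(tr))
      inner <- inner[inner > ntip]
      # keep clade-root labels intact
      labs <- node_labels_raw(tr, ntip)
      inner <- inner[!startsWith(labs[inner], "clade_")]
      if (length(inner)) tr <- collapse_node(tr, inner[1])
    }
    tr
  })
}

## collapse internal node v into its parent (unresolve one split)
collapse_node <- function(tree, v) {
  parent <- tree$edge[tree$edge[, 2] == v, 1]
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  keep <- tree$edge[, 2] != v & tree$edge[, 1] != v
  new_edges <- rbind(tree$edge[keep, , drop = FALSE],
                     cbind(rep(parent, length(kids)), kids))
  tree$edge <- new_edges
  tree$Nnode <- tree$Nnode - 1L
  # renumber via newick round-trip (simplest safe route)
  ntip <- length(tree$tip.label)
  # rebuild newick manually
  labs <- node_labels_raw(tree, ntip)
  ch <- list()
  for (k in seq_len(nrow(new_edges)))
    ch[[as.character(new_edges[k, 1])]] <- c(ch[[as.character(new_edges[k, 1])]],
                                             new_edges[k, 2])
  root <- setdiff(unique(new_edges[, 1]), new_edges[, 2])
  rec <- function(u) {
    kk <- ch[[as.character(u)]]
    if (is.null(kk)) return(labs[u])
    sprintf("(%s)%s", paste(vapply(kk, rec, ""), collapse = ","), labs[u])
  }
  ape::read.tree(text = paste0(rec(root), ";"))
}

node_labels_raw <- function(tree, ntip) {
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", tree$Nnode)
  c(tree$tip.label, nl)
}

#' Clade membership of a simulated (or labeled) taxonomy tree
#'
#' @param tree `phylo` with clade-labeled internal nodes (labels starting
#'   `clade_`); a tip not under any clade node falls back to the root clade
#'   name if the whole tree is one clade.
#' @return Tibble: `species`, `clade`.
#' @export
clade_map <- function(tree) {
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  ch <- children_of(tree)
  out <- setNames(rep(NA_character_, ntip), tree$tip.label)
  assign_below <- function(v, clade) {
    lab <- labs[v]
    if (v > ntip && startsWith(lab, "clade_")) clade <- lab
    if (v <= ntip) { if (!is.na(clade)) out[tree$tip.label[v]] <<- clade }
    else for (w in ch[[v]]) assign_below(w, clade)
  }
  assign_below(root_of(tree), NA_character_)
  if (anyNA(out)) out[is.na(out)] <- "clade_01"
  tibble(species = names(out), clade = unname(out))
}

#' Plant irreversible loss events on a tree
#'
#' For each component present at the root, every edge independently becomes
#' a loss edge with its per-edge probability, suppressed below an existing
#' loss (a proper single-gain, no-regain process). Two refinements keep the
#' planted sets identifiable: (a) at every still-present node the draw is
#' conditioned on at least one child lineage surviving (redrawn otherwise),
#' so each planted loss-edge set is exactly the minimal Dollo explanation
#' of the tip pattern — except at `loss_prob >= 1`, where all root-child
#' edges are lost; and (b) SIN1 losses are planted on top of RICTOR's (a
#' SIN1 subunit cannot outlive its complex), so SIN1's loss set contains
#' RICTOR's.
#'
#' @param tree Tree from [simulate_taxonomy()].
#' @param config A [sim_config()].
#' @return A `ground_truth` list: `tip_presence` (tibble species x
#'   component, logical), `loss_edges` (named list of child-node labels per
#'   component), `tree`.
#' @export
plant_losses <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  ch <- children_of(tree)
  root <- root_of(tree)

  plant_one <- function(p, forced_children) {
    # forced_children: node ids whose incoming edge is already a loss
    # (inherited from a parent trait); returns child-node ids of loss edges
    losses <- integer(0)
    walk <- function(v) {
      kids <- ch[[v]]
      if (!length(kids)) return()
      repeat {
        forced <- kids %in% forced_children
        drawn <- forced | (runif(length(kids)) < p)
        if (!all(drawn) || p >= 1 || all(forced)) break
      }
      losses <<- c(losses, kids[drawn])
      for (w in kids[!drawn]) walk(w)
    }
    walk(root)
    losses
  }

  with_seed(str_seed(config$seed, "losses"), {
    comps <- config$components
    loss_edges <- setNames(vector("list", length(comps)), comps)
    presence <- matrix(FALSE, nrow = ntip, ncol = length(comps),
                       dimnames = list(tree$tip.label, comps))
    rictor_losses <- integer(0)
    for (comp in comps) {
      if (!isTRUE(config$root_state[[comp]])) { loss_edges[[comp]] <- character(0); next }
      forced <- if (comp == "SIN1" && "RICTOR" %in% comps) rictor_losses
                else integer(0)
      le <- plant_one(config$loss_prob_per_edge[[comp]], forced)
      if (comp == "RICTOR") rictor_losses <- le
      loss_edges[[comp]] <- labs[le]
      # tips present unless a loss edge sits on the root-to-tip path
      lost_below <- logical(length(labs))
      mark <- function(v) {
        lost_below[v] <<- TRUE
        for (w in ch[[v]]) mark(w)
      }
      for (v in le) mark(v)
      presence[, comp] <- !lost_below[seq_len(ntip)]
    }
    structure(list(
      tip_presence = as_tibble(presence, rownames = "species"),
      loss_edges = loss_edges,
      tree = tree
    ), class = "ground_truth")
  })
}

#' Simulate reference alignments for the component families
#'
#' Each component gets a random consensus and `n_seqs` aligned copies with
#' per-site substitutions at `ref_divergence` — the ungapped seed
#' alignments from which profile models are built.
#'
#' @param components Component names.
#' @param seed Seed.
#' @param length_aa Alignment length (match columns).
#' @param n_seqs Sequences per alignment.
#' @param ref_divergence Within-family divergence.
#' @return Named list of named character vectors (alignments).
#' @export
simulate_reference_msas <- function(components = TORC_COMPONENTS, seed = 1,
                                    length_aa = 160, n_seqs = 6,
                                    ref_divergence = 0.02) {
  aa <- aa_alphabet()
  purrr::map(setNames(components, components), function(comp) {
    with_seed(str_seed(seed, "refmsa", comp), {
      cons <- sample(aa, length_aa, replace = TRUE)
      seqs <- vapply(seq_len(n_seqs), function(i)
        paste0(mutate_seq(cons, ref_divergence), collapse = ""), "")
      setNames(seqs, sprintf("%s_ref%02d", comp, seq_len(n_seqs)))
    })
  })
}

## substitute each site with prob `rate` to a uniformly chosen other residue
mutate_seq <- function(chars, rate) {
  aa <- aa_alphabet()
  hit <- runif(length(chars)) < min(rate, 1)
  if (any(hit)) {
    repl <- sample(aa, sum(hit), replace = TRUE)
    same <- repl == chars[hit]
    while (any(same)) {
      repl[same] <- sample(aa, sum(same), replace = TRUE)
      same <- repl == chars[hit]
    }
    chars[hit] <- repl
  }
  chars
}

random_background_seq <- function(len) {
  paste0(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

## deterministic planted homolog for (species, component)
planted_sequence <- function(profile, species, component, config) {
  cons <- strsplit(profile_consensus(profile), "")[[1]]
  with_seed(str_seed(config$seed, "homolog", species, component), {
    paste0(mutate_seq(cons, config$divergence), collapse = "")
  })
}

#' Emit degraded proteomes with planted homologs among decoys
#'
#' Every truly-present component contributes one sequence sampled from the
#' profile consensus with per-site substitutions at rate `divergence`,
#' embedded among `n_decoys` background sequences. The proteome is then
#' degraded: a `completeness` fraction of proteins is retained (uniformly
#' at random) and each retained protein is truncated to a uniform 20-80%
#' prefix or suffix with probability `fragmentation_prob`.
#'
#' @param truth A `ground_truth` from [plant_losses()].
#' @param profiles Named list of `torc_profile`s (one per component).
#' @param config A [sim_config()].
#' @return List: `proteomes` (named list of named character vectors) and
#'   `catalog` (tibble `species`, `sequence_id`, `component` (NA = decoy),
#'   `retained`, `truncated`).
#' @export
emit_proteomes <- function(truth, profiles, config) {
  if (config$divergence < 0) abort("`divergence` must be >= 0")
  missing_prof <- setdiff(config$components, names(profiles))
  if (length(missing_prof))
    abort(sprintf("no profile for component(s): %s",
                  paste(missing_prof, collapse = ", ")))
  pres <- truth$tip_presence
  species <- pres$species
  out <- vector("list", length(species)); names(out) <- species
  cat_rows <- vector("list", length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    present <- config$components[unlist(pres[i, config$components])]
    planted <- setNames(
      vapply(present, function(comp)
        planted_sequence(profiles[[comp]], sp, comp, config), ""),
      sprintf("%s_%s", sp, present))
    decoys <- with_seed(str_seed(config$seed, "decoys", sp), {
      lens <- sample(config$decoy_length_range[1]:config$decoy_length_range[2],
                     config$n_decoys, replace = TRUE)
      setNames(vapply(lens, random_background_seq, ""),
               sprintf("%s_g%04d", sp, seq_len(config$n_decoys)))
    })
    prot <- c(planted, decoys)
    comp_of <- c(present, rep(NA_character_, length(decoys)))
    with_seed(str_seed(config$seed, "degrade", sp), {
      n_keep <- round(config$completeness * length(prot))
      keep_idx <- sort(sample.int(length(prot), n_keep))
      retained <- seq_along(prot) %in% keep_idx
      truncated <- retained & runif(length(prot)) < config$fragmentation_prob
      for (j in which(truncated)) {
        len <- nchar(prot[j])
        frac <- runif(1, 0.2, 0.8)
        klen <- max(1L, floor(frac * len))
        prot[j] <- if (runif(1) < 0.5) substr(prot[j], 1L, klen)
                   else substr(prot[j], len - klen + 1L, len)
      }
      cat_rows[[i]] <- tibble(species = sp, sequence_id = names(prot),
                              component = comp_of, retained = retained,
                              truncated = truncated)
      out[[i]] <- prot[retained]
    })
  }
  list(proteomes = out, catalog = bind_rows(cat_rows))
}

#' Emit translated short-read peptide fragments per species
#'
#' For each truly-present component, fragments of `read_length_aa` residues
#' are sampled uniformly along that species' (undegraded) planted homolog,
#' with per-residue substitutions at `read_error_rate`. Every species also
#' receives `n_background_reads` background fragments; truly-absent
#' components contribute nothing beyond background.
#'
#' @inheritParams emit_proteomes
#' @return Named list (by species) of named character vectors of fragments.
#' @export
emit_reads <- function(truth, profiles, config) {
  if (config$read_length_aa < 5) abort("`read_length_aa` must be >= 5")
  pres <- truth$tip_presence
  rl <- config$read_length_aa
  out <- vector("list", nrow(pres)); names(out) <- pres$species
  for (i in seq_len(nrow(pres))) {
    sp <- pres$species[i]
    present <- config$components[unlist(pres[i, config$components])]
    frg <- character(0)
    for (comp in present) {
      src <- planted_sequence(profiles[[comp]], sp, comp, config)
      frg_c <- with_seed(str_seed(config$seed, "reads", sp, comp), {
        n <- config$n_reads_per_component
        len <- nchar(src)
        starts <- sample.int(max(1L, len - rl + 1L), n, replace = TRUE)
        vapply(starts, function(s) {
          piece <- strsplit(substr(src, s, min(len, s + rl - 1L)), "")[[1]]
          paste0(mutate_seq(piece, config$read_error_rate), collapse = "")
        }, "")
      })
      names(frg_c) <- sprintf("%s_%s_r%03d", sp, comp,
                              seq_len(config$n_reads_per_component))
      frg <- c(frg, frg_c)
    }
    bg <- with_seed(str_seed(config$seed, "bgreads", sp), {
      setNames(vapply(seq_len(config$n_background_reads),
                      function(k) random_background_seq(rl), ""),
               sprintf("%s_bg_r%03d", sp, seq_len(config$n_background_reads)))
    })
    out[[sp]] <- c(frg, bg)
  }
  out
}

#' Assign trophic-strategy labels correlated with TORC2 retention
#'
#' Tips lacking TORC2 (no RICTOR) are labeled autotroph with probability
#' `trophic_assoc`, otherwise uniformly one of mixotroph / heterotroph /
#' parasite_intracellular. Tips retaining TORC2 are autotroph with the
#' complementary rate `(1 - trophic_assoc)/3`, so `trophic_assoc = 1/4`
#' makes the label independent of TORC2 status. Plastid and free-living
#' annotations follow the strategy.
#'
#' @inheritParams emit_proteomes
#' @return Tibble: `species`, `strategy`, `plastid`, `free_living_stage`.
#' @export
assign_trophic_labels <- function(truth, config) {
  others <- c("mixotroph", "heterotroph", "parasite_intracellular")
  pres <- truth$tip_presence
  has_torc2 <- if ("RICTOR" %in% names(pres)) pres$RICTOR
               else rep(TRUE, nrow(pres))
  with_seed(str_seed(config$seed, "trophic"), {
    p_auto <- ifelse(has_torc2, (1 - config$trophic_assoc) / 3,
                     config$trophic_assoc)
    is_auto <- runif(nrow(pres)) < p_auto
    strat <- ifelse(is_auto, "autotroph",
                    sample(others, nrow(pres), replace = TRUE))
    tibble(
      species = pres$species,
      strategy = strat,
      plastid = ifelse(strat %in% c("autotroph", "mixotroph"), "yes", "no"),
      free_living_stage = ifelse(strat == "parasite_intracellular", "no", "yes"))
  })
}

#' Simulate a complete synthetic dataset
#'
#' One call producing every pipeline input: taxonomy tree, clade map,
#' planted ground truth, reference alignments and profiles, degraded
#' proteomes, read fragments, trophic labels and a per-species metadata
#' table (with the configured completeness as the quality score a BUSCO
#' run would have supplied).
#'
#' @param config A [sim_config()].
#' @return A `torc_sim` list with elements `config`, `tree`, `clades`,
#'   `truth`, `msas`, `profiles`, `proteomes`, `catalog`, `reads`,
#'   `trophic`, `metadata`.
#' @export
simulate_torc_dataset <- function(config = sim_config()) {
  tree <- simulate_taxonomy(config)
  clades <- clade_map(tree)
  truth <- plant_losses(tree, config)
  msas <- simulate_reference_msas(config$components, seed = config$seed)
  profiles <- purrr::imap(msas, function(m, comp) build_profile(m, comp))
  prot <- emit_proteomes(truth, profiles, config)
  reads <- emit_reads(truth, profiles, config)
  trophic <- assign_trophic_labels(truth, config)
  metadata <- clades |>
    mutate(completeness = unname(config$completeness)) |>
    left_join(trophic |> select("species", "strategy"), by = "species")
  structure(list(config = config, tree = tree, clades = clades,
                 truth = truth, msas = msas, profiles = profiles,
                 proteomes = prot$proteomes, catalog = prot$catalog,
                 reads = reads, trophic = trophic, metadata = metadata),
            class = "torc_sim")
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Proteome and read FASTAs per species, the tree as Newick, metadata /
#' truth / trophic tables as TSV, and the config echo as JSON.
#'
#' @param sim A `torc_sim` from [simulate_torc_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_inputs <- function(sim, dir) {
  for (d in file.path(dir, c("proteomes", "reads", "msas")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$proteomes))
    write_fasta(sim$proteomes[[sp]], file.path(dir, "proteomes",
                                               paste0(sp, ".faa")))
  for (sp in names(sim$reads))
    write_fasta(sim$reads[[sp]], file.path(dir, "reads", paste0(sp, ".faa")))
  for (comp in names(sim$msas))
    write_fasta(sim$msas[[comp]], file.path(dir, "msas", paste0(comp, ".afa")))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$truth$tip_presence, file.path(dir, "truth_presence.tsv"))
  readr::write_tsv(
    tibble(component = rep(names(sim$truth$loss_edges),
                           lengths(sim$truth$loss_edges)),
           loss_edge_child = unlist(sim$truth$loss_edges)),
    file.path(dir, "truth_losses.tsv"))
  readr::write_tsv(sim$trophic, file.path(dir, "trophic.tsv"))
  cfg <- sim$config; class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
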