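test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_tips = 2), "n_tips")
  expect_error(sim_config(divergence = -0.1), "divergence")
  expect_error(sim_config(read_length_aa = 4), "read_length_aa")
  expect_error(sim_config(completeness = 1.5), "completeness")
  expect_error(sim_config(loss_prob_per_edge = c(BADNAME = 0.1)), "unknown")
})

test_that("taxonomy simulation is seed-deterministic and structurally sound", {
  cfg <- sim_config(n_tips = 12, n_clades = 3, seed = 7)
  t1 <- simulate_taxonomy(cfg)
  t2 <- simulate_taxonomy(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  tmin <- simulate_taxonomy(sim_config(n_tips = 3, n_clades = 1, seed = 1))
  expect_equal(length(tmin$tip.label), 3L)
  expect_equal(nrow(clade_map(tmin)), 3L)
  expect_equal(length(unique(clade_map(tmin)$clade)), 1L)

  big <- simulate_taxonomy(sim_config(n_tips = 50, n_clades = 5, seed = 5))
  cm <- clade_map(big)
  expect_setequal(cm$species, big$tip.label)          # labels partition tips
  expect_equal(length(unique(cm$clade)), 5L)
  # every tip reachable from the root
  reach <- torcscan:::postorder_nodes(big)
  expect_true(all(seq_along(big$tip.label) %in% reach))
})

test_that("simulated taxonomy trees contain a polytomy once n_tips >= 6", {
  for (s in 1:10) {
    tr <- simulate_taxonomy(sim_config(n_tips = 6 + s, n_clades = 2, seed = s))
    expect_true(any(tabulate(tr$edge[, 1]) >= 3), info = sprintf("seed %d", s))
  }
})

test_that("loss planting honours the degenerate limits", {
  cfg0 <- sim_config(n_tips = 10, seed = 3, loss_prob_per_edge = 0)
  tr <- simulate_taxonomy(cfg0)
  gt0 <- plant_losses(tr, cfg0)
  expect_true(all(as.matrix(gt0$tip_presence[, -1])))
  expect_true(all(lengths(gt0$loss_edges) == 0))

  cfg1 <- sim_config(n_tips = 10, seed = 3, loss_prob_per_edge = 1)
  gt1 <- plant_losses(tr, cfg1)
  expect_false(any(as.matrix(gt1$tip_presence[, -1])))
  n_root_children <- length(torcscan:::children_of(tr)[[torcscan:::root_of(tr)]])
  expect_true(all(lengths(gt1$loss_edges) == n_root_children))
})

test_that("planted losses are irreversible and SIN1 never outlives RICTOR", {
  for (s in 1:10) {
    cfg <- sim_config(n_tips = 25, seed = s, loss_prob_per_edge = 0.15)
    tr <- simulate_taxonomy(cfg)
    gt <- plant_losses(tr, cfg)
    labs <- torcscan:::node_labels(tr)
    ch <- torcscan:::children_of(tr)
    for (comp in TORC_COMPONENTS) {
      lost_tips <- character(0)
      mark <- function(v) {
        if (v <= length(tr$tip.label))
          lost_tips <<- c(lost_tips, tr$tip.label[v])
        for (w in ch[[v]]) mark(w)
      }
      for (le in gt$loss_edges[[comp]]) mark(which(labs == le))
      # no tip below a loss edge may be present
      pres <- gt$tip_presence[[comp]][match(lost_tips,
                                            gt$tip_presence$species)]
      expect_false(any(pres))
      # every other tip is present (presence = no loss on the path)
      other <- setdiff(gt$tip_presence$species, lost_tips)
      expect_true(all(gt$tip_presence[[comp]][
        match(other, gt$tip_presence$species)]))
    }
    expect_true(all(gt$tip_presence$RICTOR | !gt$tip_presence$SIN1))
  }
})

test_that("zero-divergence undegraded proteomes carry exact consensus homologs", {
  cfg <- sim_config(n_tips = 4, n_clades = 1, seed = 9, divergence = 0,
                    completeness = 1, fragmentation_prob = 0, n_decoys = 3)
  tr <- simulate_taxonomy(cfg)
  gt <- plant_losses(tr, cfg)
  msas <- simulate_reference_msas(seed = 9)
  profiles <- purrr::imap(msas, function(m, comp) build_profile(m, comp))
  ep <- emit_proteomes(gt, profiles, cfg)
  for (sp in gt$tip_presence$species) {
    for (comp in TORC_COMPONENTS) {
      if (!gt$tip_presence[[comp]][gt$tip_presence$species == sp]) next
      id <- sprintf("%s_%s", sp, comp)
      expect_equal(unname(ep$proteomes[[sp]][id]),
                   profile_consensus(profiles[[comp]]))
    }
  }
})

test_that("zero completeness empties the proteome", {
  cfg <- sim_config(n_tips = 3, n_clades = 1, seed = 2, completeness = 0)
  tr <- simulate_taxonomy(cfg)
  gt <- plant_losses(tr, cfg)
  msas <- simulate_reference_msas(seed = 2)
  profiles <- purrr::imap(msas, function(m, comp) build_profile(m, comp))
  ep <- emit_proteomes(gt, profiles, cfg)
  expect_true(all(lengths(ep$proteomes) == 0))
})

test_that("error-free reads are exact substrings of their source protein", {
  cfg <- sim_config(n_tips = 3, n_clades = 1, seed = 4, read_error_rate = 0,
                    completeness = 1, fragmentation_prob = 0, n_decoys = 2,
                    n_reads_per_component = 5, n_background_reads = 2)
  tr <- simulate_taxonomy(cfg)
  gt <- plant_losses(tr, cfg)
  msas <- simulate_reference_msas(seed = 4)
  profiles <- purrr::imap(msas, function(m, comp) build_profile(m, comp))
  ep <- emit_proteomes(gt, profiles, cfg)
  reads <- emit_reads(gt, profiles, cfg)
  for (sp in names(reads)) {
    frg <- reads[[sp]]
    comp_frags <- frg[!grepl("_bg_", names(frg))]
    for (nm in names(comp_frags)) {
      comp <- sub(sprintf("^%s_([A-Z0-9]+)_r\\d+$", sp), "\\1", nm)
      src <- ep$proteomes[[sp]][sprintf("%s_%s", sp, comp)]
      expect_true(grepl(comp_frags[[nm]], src, fixed = TRUE))
    }
  }
})

test_that("absent components contribute no derived read fragments", {
  cfg <- sim_config(n_tips = 6, n_clades = 2, seed = 8,
                    loss_prob_per_edge = c(TOR = 0, LST8 = 0, RAPTOR = 0,
                                           RICTOR = 0.4, SIN1 = 0.4))
  tr <- simulate_taxonomy(cfg)
  gt <- plant_losses(tr, cfg)
  msas <- simulate_reference_msas(seed = 8)
  profiles <- purrr::imap(msas, function(m, comp) build_profile(m, comp))
  reads <- emit_reads(gt, profiles, cfg)
  for (i in seq_len(nrow(gt$tip_presence))) {
    sp <- gt$tip_presence$species[i]
    for (comp in TORC_COMPONENTS) {
      n_from <- sum(grepl(sprintf("^%s_%s_r", sp, comp), names(reads[[sp]])))
      if (gt$tip_presence[[comp]][i]) expect_gt(n_from, 0)
      else expect_equal(n_from, 0L)
    }
  }
})

test_that("full association makes every TORC2-lacking tip an autotroph", {
  cfg <- sim_config(n_tips = 20, seed = 12, trophic_assoc = 1,
                    loss_prob_per_edge = c(TOR = 0, LST8 = 0, RAPTOR = 0,
                                           RICTOR = 0.3, SIN1 = 0.3))
  tr <- simulate_taxonomy(cfg)
  gt <- plant_losses(tr, cfg)
  lab <- assign_trophic_labels(gt, cfg)
  lacking <- gt$tip_presence$species[!gt$tip_presence$RICTOR]
  expect_gt(length(lacking), 0)
  expect_true(all(lab$strategy[lab$species %in% lacking] == "autotroph"))
  # and the TORC2-retaining tips are never autotrophic at assoc = 1
  keeping <- setdiff(lab$species, lacking)
  expect_false(any(lab$strategy[lab$species %in% keeping] == "autotroph"))
})

test_that("the whole generator is bit-reproducible under one seed", {
  cfg <- sim_config(n_tips = 8, n_clades = 2, seed = 99, n_decoys = 4,
                    completeness = 0.8)
  s1 <- simulate_torc_dataset(cfg)
  s2 <- simulate_torc_dataset(cfg)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$truth$tip_presence, s2$truth$tip_presence)
  expect_identical(s1$truth$loss_edges, s2$truth$loss_edges)
  expect_identical(s1$proteomes, s2$proteomes)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$trophic, s2$trophic)
})

test_that("high-fidelity conditions give error-free high-tier detection", {
  cfg <- sim_config(n_tips = 15, seed = 23, divergence = 0.05,
                    completeness = 1, fragmentation_prob = 0, n_decoys = 10)
  sim <- simulate_torc_dataset(cfg)
  tiers <- sim_tiers(sim)
  expect_equal(tier_errors(tiers, sim$truth), 0)
  # planted sequences all land in the high-confidence band
  pres_long <- tidyr::pivot_longer(sim$truth$tip_presence, -species,
                                   names_to = "component",
                                   values_to = "present")
  joined <- dplyr::inner_join(tiers, pres_long, by = c("species", "component"))
  expect_true(all(joined$tier[joined$present] == "H"))
  expect_true(all(joined$tier[!joined$present] == "ABS"))
})
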