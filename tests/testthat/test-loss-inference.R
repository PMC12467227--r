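test_that("newick reading preserves topology, polytomies, and round-trips", {
  t1 <- read_taxon_tree("((A,B),C);")
  expect_equal(length(t1$tip.label), 3L)
  expect_equal(length(torcscan:::children_of(t1)[[torcscan:::root_of(t1)]]), 2L)

  t2 <- read_taxon_tree("(A,B,C,D);")
  expect_equal(length(torcscan:::children_of(t2)[[torcscan:::root_of(t2)]]), 4L)

  t3 <- read_taxon_tree("((A,B)ab,(C,D,E)cde)r;")
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(t3, f)
  t3b <- read_taxon_tree(f)
  expect_true(ape::all.equal.phylo(t3, t3b, use.edge.length = FALSE))

  expect_error(read_taxon_tree("((A,B),A);"), "duplicate")
})

test_that("basic Dollo reconstructions match hand-worked cases", {
  tr <- read_taxon_tree("((A,B)n1,C)r;")
  r <- dollo_reconstruct(tr, c(A = "absent", B = "present", C = "present"))
  expect_equal(r$n_losses, 1L)
  expect_equal(r$loss_edges, "A")
  expect_equal(r$root_state, "present_at_root")

  r0 <- dollo_reconstruct(tr, c(A = "present", B = "present", C = "present"))
  expect_equal(r0$n_losses, 0L)
  expect_true(all(r0$node_state == "present"))

  # no presence anywhere: absent everywhere, zero losses
  rn <- dollo_reconstruct(tr, c(A = "absent", B = "absent", C = "absent"))
  expect_equal(rn$n_losses, 0L)
  expect_true(all(rn$node_state == "absent"))
  expect_equal(rn$root_state, "absent")

  expect_error(dollo_reconstruct(tr, c(A = "present", B = "absent")), "C")
})

test_that("unknown-only subtrees inherit the parental state without losses", {
  tr <- read_taxon_tree("(((A,B)n1,(C,D)n2)n3,E)r;")
  st <- c(A = "unknown", B = "unknown", C = "present", D = "absent",
          E = "present")
  r <- dollo_reconstruct(tr, st)
  expect_equal(r$loss_edges, "D")
  expect_equal(unname(r$node_state[c("A", "B")]), c("present", "present"))
  expect_equal(r$tips_unknown, c("A", "B"))
  # flipping the unknowns to absent adds exactly one loss (the n1 subtree)
  st2 <- replace(st, c("A", "B"), "absent")
  expect_equal(dollo_reconstruct(tr, st2)$n_losses, 2L)
})

test_that("minimum loss counts equal exhaustive enumeration on random trees", {
  checked <- 0L
  for (s in 1:60) {
    n <- sample(3:10, 1)
    tr <- random_small_tree(n, seed = s)
    set.seed(s + 10000)
    st <- stats::setNames(sample(c(TRUE, FALSE), length(tr$tip.label),
                                 replace = TRUE), tr$tip.label)
    r <- dollo_reconstruct(tr, st)
    expect_equal(r$n_losses, dollo_min_oracle(tr, st),
                 info = sprintf("seed %d", s))
    checked <- checked + 1L
  }
  expect_equal(checked, 60L)
})

test_that("flipping one tip to absent increases the count by at most one", {
  for (s in 1:25) {
    tr <- random_small_tree(sample(4:10, 1), seed = s + 300)
    set.seed(s + 20000)
    st <- stats::setNames(sample(c(TRUE, FALSE), length(tr$tip.label),
                                 replace = TRUE, prob = c(0.7, 0.3)),
                          tr$tip.label)
    if (!any(st)) next
    base <- dollo_reconstruct(tr, st)$n_losses
    flip <- sample(names(st)[st], 1)
    st2 <- replace(st, flip, FALSE)
    expect_lte(dollo_reconstruct(tr, st2)$n_losses, base + 1L)
  }
})

test_that("root-state inference distinguishes root presence from later origin", {
  tr <- read_taxon_tree("((A,B)diphoda,(C,D)opimoda)leca;")
  expect_equal(infer_root_state(tr, c(A = "present", B = "absent",
                                      C = "present", D = "absent")),
               "present_at_root")
  expect_equal(infer_root_state(tr, c(A = "present", B = "present",
                                      C = "absent", D = "absent")),
               "origin_within_tree")
  expect_equal(infer_root_state(tr, c(A = "absent", B = "absent",
                                      C = "absent", D = "absent")),
               "absent")
})

test_that("the dinoflagellate pattern yields two independent losses per complex", {
  tr <- read_taxon_tree("((Polarella,Endosymbiont)Suessiales,Amoebophyra)Dinophyceae;")
  st <- c(Polarella = "present", Endosymbiont = "absent", Amoebophyra = "absent")
  r <- dollo_reconstruct(tr, st, trait = "TORC2")
  expect_equal(r$n_losses, 2L)
  expect_setequal(r$loss_edges, c("Endosymbiont", "Amoebophyra"))
})

test_that("the Ochrophyta pattern yields two TORC2 losses", {
  tr <- read_taxon_tree(
    "((Bacillariophyta,Parmales)nP,Pelagophyceae,Phaeophyceae)Ochrophyta;")
  st <- c(Bacillariophyta = "absent", Parmales = "present",
          Pelagophyceae = "absent", Phaeophyceae = "present")
  expect_equal(dollo_reconstruct(tr, st, trait = "TORC2")$n_losses, 2L)
})

test_that("per-trait counting covers components and complexes from a tier matrix", {
  tiers <- make_tiers(list(
    sp1 = c(TOR = "H", LST8 = "H", RAPTOR = "H", RICTOR = "H", SIN1 = "H"),
    sp2 = c(TOR = "H", LST8 = "H", RAPTOR = "H", RICTOR = "ABS", SIN1 = "ABS"),
    sp3 = c(TOR = "H", LST8 = "H", RAPTOR = "H", RICTOR = "ABS", SIN1 = "ABS")))
  tr <- read_taxon_tree("((sp1,sp2)n1,sp3)r;")
  out <- count_losses_per_trait(tiers, tr)
  expect_setequal(out$summary$trait, c(TORC_COMPONENTS, "TORC1", "TORC2"))
  s <- out$summary
  expect_equal(s$n_losses[s$trait == "TORC2"], 2L)
  expect_equal(s$n_losses[s$trait == "TORC1"], 0L)
  expect_equal(s$n_losses[s$trait == "RICTOR"], 2L)
})

test_that("planted loss edges are recovered exactly from true tip states", {
  for (s in c(3, 17, 29)) {
    cfg <- sim_config(n_tips = 30, seed = s, loss_prob_per_edge = 0.1)
    tree <- simulate_taxonomy(cfg)
    truth <- plant_losses(tree, cfg)
    for (comp in TORC_COMPONENTS) {
      st <- stats::setNames(
        ifelse(truth$tip_presence[[comp]], "present", "absent"),
        truth$tip_presence$species)
      r <- dollo_reconstruct(tree, st, trait = comp)
      expect_setequal(r$loss_edges, truth$loss_edges[[comp]])
    }
  }
})

test_that("the missing-data policy never inflates the planted loss count", {
  for (s in c(7, 19)) {
    cfg <- sim_config(n_tips = 30, seed = s, loss_prob_per_edge = 0.1,
                      completeness = 0.6, fragmentation_prob = 0)
    sim <- simulate_torc_dataset(cfg)
    tiers <- sim_tiers(sim)
    out <- count_losses_per_trait(tiers, sim$tree, unknown_policy = "missing",
                                  metadata = sim$metadata)
    for (comp in TORC_COMPONENTS) {
      planted <- length(sim$truth$loss_edges[[comp]])
      got <- out$summary$n_losses[out$summary$trait == comp]
      expect_lte(got, planted)
    }
  }
})

test_that("annotated newick output and tidiers expose the reconstruction", {
  tr <- read_taxon_tree("((A,B)n1,C)r;")
  r <- dollo_reconstruct(tr, c(A = "absent", B = "present", C = "present"),
                         trait = "RICTOR")
  td <- tidy(r)
  expect_equal(nrow(td), 5L)
  expect_equal(td$state[td$label == "A"], "absent")
  expect_true(td$loss_edge[td$label == "A"])
  g <- glance(r)
  expect_equal(g$n_losses, 1L)
  expect_equal(g$trait, "RICTOR")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_annotated_newick(r, f)
  txt <- readLines(f)
  expect_match(txt, "A\\|absent")
  expect_match(txt, "B\\|present")
})
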