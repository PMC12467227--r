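# Independent oracles and small fixture builders used across the suite.

# Brute-force minimum-loss count under irreversibility: enumerate every
# internal labeling in which no absent parent has a present child, keep
# those consistent with the tips, and count present -> absent edges.
# Exponential in internal nodes; only for trees of <= ~10 tips.
dollo_min_oracle <- function(tree, tip_present) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edges <- tree$edge
  base <- rep(NA, ntip + nint)
  base[seq_len(ntip)] <- as.logical(tip_present[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    st <- base
    st[ntip + seq_len(nint)] <- bitwAnd(bitwShiftR(mask, 0:(nint - 1)), 1) == 1
    if (any(!st[edges[, 1]] & st[edges[, 2]])) next # regain: invalid
    best <- min(best, sum(st[edges[, 1]] & !st[edges[, 2]]))
  }
  best
}

# random small multifurcating rooted tree (newick built by random grouping)
random_small_tree <- function(n_tips, seed) {
  set.seed(seed)
  items <- paste0("t", seq_len(n_tips))
  while (length(items) > 1) {
    m <- min(length(items), sample(2:3, 1))
    pick <- sample.int(length(items), m)
    items <- c(items[-pick], sprintf("(%s)", paste(items[pick], collapse = ",")))
  }
  ape::read.tree(text = paste0(items, ";"))
}

# a complete tier tibble from a named list species -> named tier vector
make_tiers <- function(per_species) {
  rows <- lapply(names(per_species), function(sp) {
    t <- per_species[[sp]]
    tibble::tibble(species = sp, component = names(t), tier = unname(t),
                   effective_bits = ifelse(t == "ABS", NA_real_, 350),
                   sequence_id = NA_character_, coverage = 1, identity = 1,
                   source = "proteome", flags = "")
  })
  dplyr::bind_rows(rows)
}

# uniform tiers for n species (helper for clade-pattern fixtures)
uniform_tiers <- function(species, tier_by_component) {
  make_tiers(stats::setNames(
    rep(list(tier_by_component), length(species)), species))
}

all_tiers_default <- function() {
  c(TOR = "H", LST8 = "H", RAPTOR = "H", RICTOR = "H", SIN1 = "H")
}

# The Alveolata presence/absence pattern and NCBI-style topology used by
# the worked loss-count examples.
alveolata_fixture <- function() {
  tree <- read_taxon_tree(paste0(
    "(Ciliophora,(((Polarella,Endosymbiont)Suessiales,Amoebophyra)Dinophyceae,",
    "Perkinsozoa)nodeA,((Vitrella,Chromera)Chromerida,Apicomplexa)nodeB)",
    "Myzozoa;"))
  torc1 <- c(Polarella = "present", Endosymbiont = "absent",
             Amoebophyra = "absent", Perkinsozoa = "present",
             Vitrella = "present", Chromera = "present",
             Apicomplexa = "absent", Ciliophora = "absent")
  torc2 <- c(Polarella = "present", Endosymbiont = "absent",
             Amoebophyra = "absent", Perkinsozoa = "present",
             Vitrella = "present", Chromera = "absent",
             Apicomplexa = "absent", Ciliophora = "present")
  list(tree = tree, torc1 = torc1, torc2 = torc2)
}

# score planted truth -> tiers for a simulated dataset (shared pipeline walk)
sim_tiers <- function(sim) {
  hits <- dplyr::bind_rows(lapply(names(sim$proteomes), function(sp)
    score_proteome(sim$profiles, sim$proteomes[[sp]], sp)))
  call_tiers(hits, profiles = sim$profiles, species = sim$metadata$species)
}

# count tier-call presence errors against planted truth
tier_errors <- function(tiers, truth) {
  pres <- tiers |>
    dplyr::mutate(present = tier %in% c("H", "M", "L", "P")) |>
    dplyr::select(species, component, present) |>
    tidyr::pivot_wider(names_from = component, values_from = present)
  m <- dplyr::inner_join(pres, truth$tip_presence, by = "species",
                         suffix = c(".call", ".true"))
  sum(vapply(TORC_COMPONENTS, function(comp)
    sum(m[[paste0(comp, ".call")]] != m[[paste0(comp, ".true")]]),
    numeric(1)))
}
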