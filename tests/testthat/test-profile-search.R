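test_that("profile construction follows the pseudocount closed form", {
  # column 1: all A; column 2: half A half G; column 3: all gaps (dropped)
  msa <- c(s1 = "AA-", s2 = "AA-", s3 = "AG-", s4 = "AG-")
  p <- build_profile(msa, "X")
  expect_equal(p$length, 2L)
  # n = 4 observations; freq_A = (2 + 1/20) / 5; background uniform 1/20
  expect_equal(unname(p$scores[2, "A"]), log2(((2 + 1 / 20) / 5) / 0.05))
  expect_equal(unname(p$scores[2, "G"]), log2(((2 + 1 / 20) / 5) / 0.05))
  expect_equal(unname(p$scores[2, "C"]), log2(((0 + 1 / 20) / 5) / 0.05))
  expect_equal(unname(p$scores[1, "A"]), log2(((4 + 1 / 20) / 5) / 0.05))
})

test_that("consensus residue maximizes every column of an identical-sequence MSA", {
  msa <- rep("ACDEFGHIKL", 3)
  names(msa) <- paste0("s", 1:3)
  p <- build_profile(msa, "X")
  expect_equal(p$length, 10L)
  expect_equal(profile_consensus(p), "ACDEFGHIKL")
  expect_true(all(apply(p$scores, 1, which.max) == p$consensus + 1L))
})

test_that("profile construction rejects degenerate alignments", {
  expect_error(build_profile(character(), "X"), "empty")
  expect_error(build_profile(c(a = "ACD", b = "AC"), "X"), "ragged")
  expect_error(build_profile(c(a = "ACD"), "X"), "at least 2")
})

test_that("a consensus sequence scores as one full-length high-scoring domain", {
  msas <- simulate_reference_msas("RICTOR", seed = 3)
  p <- build_profile(msas$RICTOR, "RICTOR")
  h <- score_sequence(p, profile_consensus(p))
  expect_equal(h$n_domains, 1L)
  expect_gt(h$overall_bits, 300)
  expect_equal(h$overall_bits, h$best_domain_bits)
  expect_equal(h$overall_bits, profile_max_bits(p), tolerance = 1e-6)
  d <- h$domains[[1]]
  expect_equal(c(d$prof_start, d$prof_end), c(0L, p$length))
  expect_equal(d$identity, 1)
})

test_that("an empty sequence yields the defined no-hit result", {
  msas <- simulate_reference_msas("TOR", seed = 3)
  p <- build_profile(msas$TOR, "TOR")
  h <- score_sequence(p, "")
  expect_equal(h$overall_bits, 0)
  expect_equal(h$n_domains, 0L)
})

test_that("background sequences stay deep in the no-hit regime", {
  msas <- simulate_reference_msas("RICTOR", seed = 3)
  p <- build_profile(msas$RICTOR, "RICTOR")
  set.seed(42)
  nulls <- replicate(200, paste0(sample(aa_alphabet(), 300, TRUE), collapse = ""))
  names(nulls) <- paste0("n", seq_along(nulls))
  nh <- score_sequences(p, nulls)
  ob <- stats::setNames(rep(0, 200), names(nulls))
  ob[nh$sequence_id] <- nh$overall_bits
  # null maximum concentrates near log2(K*m*n): far below the 100-bit
  # ABS threshold, with the 95th percentile at ~18 bits
  expect_gte(mean(ob <= 20), 0.95)
  expect_lt(max(ob), 40)
  expect_true(all(assign_tier(ob) == "ABS"))
})

test_that("two profile copies in one sequence give two additive domains", {
  msas <- simulate_reference_msas("LST8", seed = 3)
  p <- build_profile(msas$LST8, "LST8")
  cons <- profile_consensus(p)
  set.seed(7)
  spacer <- paste0(sample(aa_alphabet(), 100, TRUE), collapse = "")
  h <- score_sequence(p, paste0(cons, spacer, cons), domain_floor = 20)
  expect_equal(h$n_domains, 2L)
  single <- score_sequence(p, cons)$best_domain_bits
  expect_equal(h$overall_bits, 2 * single, tolerance = 2 / (2 * single))
  expect_lte(h$best_domain_bits, h$overall_bits + 1e-6)
})

test_that("scores are invariant to decoy order within a proteome", {
  msas <- simulate_reference_msas(c("TOR", "RAPTOR"), seed = 5)
  profiles <- purrr::imap(msas, function(m, comp) build_profile(m, comp))
  set.seed(11)
  prot <- c(
    stats::setNames(replicate(20, paste0(sample(aa_alphabet(),
                                                sample(200:600, 1), TRUE),
                                         collapse = "")), paste0("g", 1:20)),
    TORh = profile_consensus(profiles$TOR))
  h1 <- score_proteome(profiles, prot, "sp")
  h2 <- score_proteome(profiles, rev(prot), "sp")
  o1 <- h1 |> dplyr::arrange(component, sequence_id) |>
    dplyr::select(-domains)
  o2 <- h2 |> dplyr::arrange(component, sequence_id) |>
    dplyr::select(-domains)
  expect_equal(o1, o2)
})

test_that("mean homolog score decreases with divergence", {
  msas <- simulate_reference_msas("SIN1", seed = 9)
  p <- build_profile(msas$SIN1, "SIN1")
  cons <- strsplit(profile_consensus(p), "")[[1]]
  mean_bits <- function(rate, seeds) {
    seqs <- vapply(seeds, function(s) {
      set.seed(s)
      paste0(torcscan:::mutate_seq(cons, rate), collapse = "")
    }, "")
    mean(score_sequences(p, stats::setNames(seqs, paste0("s", seeds)))$best_domain_bits)
  }
  expect_gt(mean_bits(0.05, 1:20), mean_bits(0.30, 101:120))
})

test_that("domtblout parsing maps fields, groups domains, and flags bad rows", {
  row <- function(target, query, seqE, seqScore, domScore, hf, ht, af, at) {
    paste(target, "-", 1000, query, "-", 160, seqE, seqScore, 0.1,
          1, 1, 1e-20, 1e-18, domScore, 0.1, hf, ht, af, at, af, at, 0.9,
          "desc", sep = " ")
  }
  f <- withr::local_tempfile(fileext = ".domtblout")

  writeLines("# comment only", f)
  expect_equal(nrow(parse_domtblout(f)), 0L)

  writeLines(c("# h", row("seqA", "RICTOR", 1e-80, 312.0, 250.0, 1, 160, 10, 400)), f)
  h <- parse_domtblout(f, species = "sp1")
  expect_equal(h$overall_bits, 312)
  expect_equal(h$best_domain_bits, 250)
  d <- h$domains[[1]]
  expect_equal(c(d$seq_start, d$seq_end), c(9L, 400L))   # half-open 0-based
  expect_equal(c(d$prof_start, d$prof_end), c(0L, 160L))

  writeLines(c(row("seqA", "TOR", 1e-40, 130, 120, 1, 80, 5, 90),
               row("seqA", "TOR", 1e-40, 130, 95, 90, 160, 120, 200)), f)
  h2 <- parse_domtblout(f)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$n_domains, 2L)
  expect_equal(h2$best_domain_bits, 120)

  writeLines("seqA broken row", f)
  expect_error(parse_domtblout(f), "line 1")
})

test_that("domain coverage is the covered fraction of annotated regions", {
  msa <- rep(paste0(rep("A", 300), collapse = ""), 3)
  names(msa) <- paste0("s", 1:3)
  p <- build_profile(msa, "X", domain_regions = list(c(0, 100), c(200, 300)))
  fake_hit <- function(iv) tibble::tibble(
    species = "sp", sequence_id = "q", component = "X",
    overall_bits = 200, best_domain_bits = 200, n_domains = nrow(iv),
    evalue = 1e-30,
    domains = list(tibble::tibble(
      seq_start = iv[, 1], seq_end = iv[, 2],
      prof_start = iv[, 1], prof_end = iv[, 2],
      bits = 100, naligned = iv[, 2] - iv[, 1], identity = 0.9)))
  full <- domain_coverage(fake_hit(cbind(0, 300)), list(X = p))
  expect_equal(full$coverage, 1)
  expect_true(full$coverage_pass)
  none <- domain_coverage(fake_hit(cbind(100, 200)), list(X = p))
  expect_equal(none$coverage, 0)
  expect_false(none$coverage_pass)
  half <- domain_coverage(fake_hit(cbind(c(50, 200), c(100, 250))), list(X = p))
  expect_equal(half$coverage, 0.5)
})

test_that("parsed HMMER scores and in-package scores tier identically within a band", {
  # construct hits whose scores sit inside the same rubric band and check
  # the two routes (parser vs scorer) give identical tiers
  msas <- simulate_reference_msas("RAPTOR", seed = 13)
  p <- build_profile(msas$RAPTOR, "RAPTOR")
  cons <- strsplit(profile_consensus(p), "")[[1]]
  set.seed(3)
  seq_m <- paste0(torcscan:::mutate_seq(cons[1:60], 0.1), collapse = "") # ~M band
  own <- score_proteome(list(RAPTOR = p), c(q1 = seq_m), "sp1")
  own_tier <- call_tiers(own, species = "sp1")
  b <- own$overall_bits[1]
  row <- paste("q1 - 60 RAPTOR - 160", 1e-30, round(b, 1), 0.1,
               "1 1 1e-20 1e-18", round(b, 1), "0.1 1 60 1 60 1 60 0.9 d")
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(row, f)
  parsed_tier <- call_tiers(parse_domtblout(f, species = "sp1"), species = "sp1")
  own_r <- own_tier[own_tier$component == "RAPTOR", ]
  par_r <- parsed_tier[parsed_tier$component == "RAPTOR", ]
  expect_equal(own_r$tier, par_r$tier)
  expect_true(own_r$tier %in% c("M", "H", "L"))
})
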