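test_that("back-translation round-trips through frame-1 translation", {
  set.seed(42)
  for (seed in 1:5) {
    pep <- paste(sample(mcrapipe:::AA_ALPHABET, 157, TRUE),
                 collapse = "")
    nt <- back_translate(pep, seed = seed)
    expect_equal(nchar(nt), 471)
    expect_identical(mcrapipe:::translate_nt(nt), pep)
  }
  expect_identical(back_translate("M", 1), "ATG")
  expect_identical(back_translate("MW", 1), "ATGTGG")
  expect_error(back_translate("MXZ", 1), "residue")
})

test_that("panel generation respects the identity-separation contracts", {
  p <- two_clade_panel(seed = 7)
  tax <- p$taxonomy
  within_a <- tax$id[tax$clade_name == "a"]
  within_b <- tax$id[tax$clade_name == "b"]
  for (i in within_a) for (j in within_b)
    expect_lt(mcrapipe:::hamming_identity(p$peptides[[i]],
                                          p$peptides[[j]]), 0.97)
  # two clades at divergence 0.10 sit near 90% identity
  ident <- mcrapipe:::hamming_identity(p$peptides[[within_a[1]]],
                                       p$peptides[[within_b[1]]])
  expect_gt(ident, 0.80)
  expect_lt(ident, 0.97)
  # nucleotides translate exactly to peptides, no internal stops
  for (id in tax$id) {
    expect_identical(mcrapipe:::translate_nt(p$nucleotides[[id]]),
                     p$peptides[[id]])
    expect_false(grepl("*", p$peptides[[id]], fixed = TRUE))
  }
  # determinism
  p2 <- two_clade_panel(seed = 7)
  expect_identical(p$peptides, p2$peptides)
  expect_identical(p$nucleotides, p2$nucleotides)
})

test_that("a single clade with zero divergence gives identical members", {
  p <- generate_reference_panel(
    list(clade_spec("a", "F", "G", "C", 3, 0, 0)), seed = 3)
  expect_identical(unname(p$peptides[1]), unname(p$peptides[2]))
  expect_equal(mcrapipe:::hamming_identity(p$peptides[[1]],
                                           p$peptides[[3]]), 1.0)
})

test_that("unsatisfiable divergence settings raise a panel error", {
  expect_error(
    generate_reference_panel(
      list(clade_spec("a", "F", "G", "C", 3, 0.1, 0.2)), seed = 1),
    "panel not separable")
})

test_that("noise-free simulation reproduces templates exactly", {
  p <- two_clade_panel()
  prof <- uniform_profile(p)
  sim <- simulate_sample(p, prof, 200, seed = 5, sample_id = "S1")
  expect_equal(nrow(sim$pairs), 200)
  expect_equal(nrow(sim$truth), 200)
  m <- merge_simulated(sim)
  expect_true(all(m$seq %in% p$nucleotides))
  # every emitted read has exactly one truth record
  expect_identical(sim$truth$id, sim$pairs$id)
  # determinism: same seed, byte-identical output
  sim2 <- simulate_sample(p, prof, 200, seed = 5, sample_id = "S1")
  expect_identical(sim$pairs, sim2$pairs)
  expect_identical(sim$truth, sim2$truth)
})

test_that("empty simulation is valid and empty", {
  p <- two_clade_panel()
  sim <- simulate_sample(p, uniform_profile(p), 0, seed = 1)
  expect_equal(nrow(sim$pairs), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("template draws follow the profile within multinomial bounds", {
  p <- two_clade_panel()
  ids <- p$taxonomy$id
  prob <- c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05)
  prof <- community_profile(setNames(prob, ids), "R")
  n <- 20000
  sim <- simulate_sample(p, prof, n, seed = 9)
  freq <- table(factor(sim$truth$source, levels = ids)) / n
  se <- sqrt(prob * (1 - prob) / n)
  expect_true(all(abs(as.numeric(freq) - prob) <= 4 * se))
})

test_that("artefact flags appear at the configured rates", {
  p <- two_clade_panel()
  n <- 10000
  sim <- simulate_sample(p, uniform_profile(p), n, chimera_rate = 0.05,
                         offlength_rate = 0.03, frameshift_rate = 0.02,
                         seed = 13)
  nch <- sum(sim$truth$is_chimera)
  # binomial 99% interval around 500
  expect_true(abs(nch - 500) < 2.58 * sqrt(n * 0.05 * 0.95))
  expect_true(abs(sum(sim$truth$is_offlength) - 300) <
                2.58 * sqrt(n * 0.03 * 0.97))
  expect_true(abs(sum(sim$truth$is_frameshifted) - 200) <
                2.58 * sqrt(n * 0.02 * 0.98))
  # chimera truth rows carry parent ids and a crossover
  ch <- sim$truth[sim$truth$is_chimera, ]
  expect_true(all(!is.na(ch$parent_a) & !is.na(ch$parent_b) &
                    !is.na(ch$crossover)))
})

test_that("community fixture profiles match their printed values", {
  tab <- reference_profiles()
  expect_equal(nrow(tab), 25)
  expect_equal(tab$R[tab$cluster == "1"], 56.1)
  expect_equal(tab$A[tab$cluster == "3"], 34.7)
  # compositional closure within table rounding
  for (tr in c("R", "A", "RA", "AA"))
    expect_lt(abs(sum(tab[[tr]]) - 100), 0.5)
  profs <- treatment_profiles()
  for (tr in names(profs))
    expect_equal(sum(profs[[tr]]$proportions), 1, tolerance = 1e-12)
  # taxonomy structure: 12 Methanobrevibacter, 5 Methanosphaera,
  # 8 Methanomassiliicoccaceae clusters
  expect_equal(sum(tab$genus == "Methanobrevibacter"), 12)
  expect_equal(sum(tab$genus == "Methanosphaera"), 5)
  expect_equal(sum(tab$family == "Methanomassiliicoccaceae"), 8)
})

test_that("experiment layout matches the study design", {
  exp <- simulate_experiment(n_reads = 50L, seed = 2)
  expect_equal(nrow(exp$sheet), 54)
  expect_equal(as.vector(table(exp$sheet$treatment)[c("R", "A", "RA",
                                                      "AA")]),
               c(13, 12, 15, 14))
  expect_equal(nrow(exp$truth), 54 * 50)
})
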