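gln <- genetic_code("uar_to_gln")
std <- genetic_code("standard")

test_that("composition counts bases over all UTR windows", {
  lib <- utr_library("g1", "AAAATTTTGGGGCCCCAATT", gln)
  expect_equal(unclass(composition(lib)),
               c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  lib2 <- utr_library(c("g1", "g2"),
                      c(strrep("A", 20), strrep("T", 20)), gln)
  expect_equal(unclass(composition(lib2)),
               c(A = 0.5, C = 0, G = 0, T = 0.5))
})

test_that("composition matches an independent character tally", {
  set.seed(21)
  for (k in 1:10) {
    lib <- random_library(30, random_composition(), gln)
    chars <- unlist(strsplit(lib$utr, ""))
    manual <- table(factor(chars, levels = c("A", "C", "G", "T")))
    expect_equal(unclass(composition(lib)),
                 stats::setNames(as.numeric(manual) / length(chars),
                                 c("A", "C", "G", "T")))
  }
})

test_that("codon probability is the product of positional base frequencies", {
  comp <- composition_profile(c(A = 0.3, T = 0.3, G = 0.2, C = 0.2))
  expect_equal(codon_probability(comp, "TGA"), 0.018)
  expect_equal(codon_probability(comp, "UGA"), 0.018)  # RNA alphabet
  uniform <- composition_profile(c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(codon_probability(uniform, "ACG"), 0.25^3)
  # multinomial normalization: probabilities over all 64 codons sum to 1
  triplets <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                c("A","C","G","T")), 1, paste0, collapse = "")
  set.seed(4)
  comp2 <- random_composition()
  expect_equal(sum(codon_probability(comp2, triplets)), 1)
  expect_error(codon_probability(comp, "TG"), "invalid codon")
})

test_that("p_stop sums codon probabilities over the code's stop set", {
  comp <- composition_profile(c(A = 0.4, T = 0.4, G = 0.1, C = 0.1))
  expect_equal(stop_probability(comp, std), 0.064 + 0.016 + 0.016)
  expect_equal(stop_probability(comp, gln), 0.016)
  no_t <- composition_profile(c(A = 0.5, C = 0.25, G = 0.25, T = 0))
  expect_equal(stop_probability(no_t, std), 0)
})

test_that("the geometric law gives the first-occurrence null", {
  null <- expected_counts(0.018, 1000)
  expect_equal(null$q[1], 0.018)
  expect_equal(null$q[2], 0.018 * 0.982)
  expect_equal(null$exp, null$q * 1000)
  expect_true(all(diff(null$q) < 0))
  expect_equal(expected_counts(0, 10)$q, rep(0, 6))
})

test_that("geometric q matches simulated first-occurrence frequencies", {
  set.seed(99)
  n <- 1e5; p <- 0.1
  stops <- matrix(runif(n * 6) < p, nrow = n)
  has <- rowSums(stops) > 0
  first <- integer(n)
  first[has] <- max.col(stops[has, , drop = FALSE], ties.method = "first")
  q <- expected_counts(p, n)$q
  for (i in 1:6) {
    se <- sqrt(q[i] * (1 - q[i]) / n)
    expect_lt(abs(mean(first == i) - q[i]), 3 * se)
  }
})

test_that("only the first in-frame stop in each window is counted", {
  utrs <- c(paste0("TGA", strrep("A", 17)),
            paste0("AAATGA", strrep("A", 14)),
            strrep("A", 20),
            paste0("AAAAAATGATGA", strrep("A", 8)))
  lib <- utr_library(sprintf("g%d", 1:4), utrs, gln)
  counts <- observed_first_occurrence(lib)
  expect_equal(counts$obs, c(1, 1, 1, 0, 0, 0))
  expect_equal(counts$n_with_tsc, 3L)
  expect_equal(unname(counts$first_stop), c(1L, 2L, NA, 3L))

  # out-of-frame TGA (spanning nt 2-4) is not a stop
  lib2 <- utr_library("g1", paste0("ATGAA", strrep("A", 15)), gln)
  expect_equal(observed_first_occurrence(lib2)$obs, rep(0, 6))

  # position 7+ stops are outside the scanned window
  lib3 <- utr_library("g1", paste0(strrep("A", 18), "TG"), gln)
  expect_equal(observed_first_occurrence(lib3)$n_with_tsc, 0L)
})

test_that("observed counts match the brute-force character walk", {
  set.seed(31)
  for (k in 1:25) {
    code <- genetic_code(sample(c("standard", "uar_to_gln", "uga_to_trp"), 1))
    lib <- random_library(40, random_composition(), code)
    counts <- observed_first_occurrence(lib)
    expect_equal(counts$obs, brute_force_obs(lib$utr, code$stop_codons))
  }
})

test_that("SCOs are log observed-over-expected with sane edge handling", {
  counts <- structure(list(n_genes = 100L, obs = c(20L, 5L, 0L, 2L, 1L, 1L),
                           n_with_tsc = 29L,
                           first_stop = stats::setNames(integer(0), character(0))),
                      class = "tsc_counts")
  # null with exp_1 = 10 so sco_1 = ln 2
  null <- expected_counts(0.1, 100)
  prof <- sco_profile(counts, null)
  expect_equal(prof$sco[1], log(20 / null$exp[1]))
  expect_equal(prof$sco[1], log(2), tolerance = 1e-12)
  expect_true(is.na(prof$sco[3]))   # obs = 0 reported missing, not -Inf
  expect_equal(prof$combined_sco, log(29 / sum(null$exp)))
  expect_equal(prof$frac_obs, 0.29)
  expect_equal(prof$frac_exp, sum(null$q))

  # obs_i = exp_i everywhere -> all scores zero
  null2 <- expected_counts(0.05, 1000)
  counts2 <- structure(list(n_genes = 1000L, obs = null2$exp,
                            n_with_tsc = round(sum(null2$exp)),
                            first_stop = integer(0)),
                       class = "tsc_counts")
  prof2 <- sco_profile(counts2, null2)
  expect_equal(prof2$sco, rep(0, 6))
  expect_equal(prof2$combined_sco, 0, tolerance = 1e-3)

  # degenerate null: expected 0 but observed positive
  counts3 <- structure(list(n_genes = 10L, obs = c(1L, rep(0L, 5)),
                            n_with_tsc = 1L, first_stop = integer(0)),
                       class = "tsc_counts")
  expect_error(sco_profile(counts3, expected_counts(0, 10)), "degenerate")
  # n_genes mismatch between counts and null
  expect_error(sco_profile(counts, expected_counts(0.1, 50)), "n_genes")
})

test_that("libraries sampled from their own composition score near zero", {
  set.seed(12)
  reps <- 60
  scos <- vapply(seq_len(reps), function(r) {
    lib <- random_library(500, composition_preset("ciliate_like"), gln)
    comp <- composition(lib)
    null <- expected_counts(stop_probability(comp, gln), 500)
    sco_profile(observed_first_occurrence(lib), null)$combined_sco
  }, numeric(1))
  se <- sd(scos) / sqrt(reps)
  expect_lt(abs(mean(scos)), 3 * se + 0.01)
})

test_that("planting extra first-position stops strictly raises sco_1", {
  base <- synthetic_spec(n_genes = 2000, seed = 8)
  sco1_at <- function(f1) {
    spec <- synthetic_spec(n_genes = 2000, seed = 8,
                           enrichment = if (f1 > 0) c("1" = f1) else numeric(0))
    lib <- simulate_utr_library(spec)$library
    comp <- composition(lib)
    null <- expected_counts(stop_probability(comp, gln), 2000)
    sco_profile(observed_first_occurrence(lib), null)$sco[1]
  }
  scores <- vapply(c(0, 0.05, 0.15, 0.3), sco1_at, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("per-position TSVs round numbers but preserve structure", {
  sim <- simulate_utr_library(synthetic_spec(n_genes = 300, seed = 2))
  lib <- sim$library
  comp <- composition(lib)
  null <- expected_counts(stop_probability(comp, gln), 300)
  prof <- sco_profile(observed_first_occurrence(lib), null, "org1")
  dir <- withr::local_tempdir()
  write_sco_tsv(prof, file.path(dir, "sco.tsv"), file.path(dir, "sum.tsv"))
  tab <- read.delim(file.path(dir, "sco.tsv"))
  expect_equal(tab$position, 1:6)
  expect_equal(tab$obs, prof$obs)
  expect_equal(tab$sco, round(prof$sco, 3))
  smry <- read.delim(file.path(dir, "sum.tsv"))
  expect_equal(smry$combined_sco, round(prof$combined_sco, 3))
})
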