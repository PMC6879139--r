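std <- genetic_code("standard")
gln <- genetic_code("uar_to_gln")

test_that("relative adaptiveness scales by the family maximum", {
  # glycine family usage 90:10:0:0
  ref <- paste0("ATG", strrep("GGT", 90), strrep("GGC", 10))
  tab <- relative_adaptiveness(ref, std)
  expect_equal(unname(tab$w["GGT"]), 1)
  expect_equal(unname(tab$w["GGC"]), 10 / 90)
  # unused codons get the 0.5 pseudo-count before scaling
  expect_equal(unname(tab$w["GGA"]), 0.5 / 90)
  # one codon per family -> that codon has w = 1
  one_each <- paste0(vapply(std$synonym_families, `[`, character(1), 1),
                     collapse = "")
  tab2 <- relative_adaptiveness(one_each, std)
  used <- vapply(std$synonym_families, `[`, character(1), 1)
  expect_true(all(tab2$w[used] == 1))
  # scale invariance: duplicating the reference leaves every observed
  # codon's w unchanged (only the fixed pseudo-count for unused codons
  # scales relative to the doubled family maxima)
  tab3 <- relative_adaptiveness(c(ref, ref), std)
  observed <- names(tab$counts)[tab$counts >= 1]
  expect_equal(tab3$w[observed], tab$w[observed])
  expect_error(relative_adaptiveness(character(0), std), "empty")
})

test_that("reassigned stops are scored inside their new family", {
  # under UAR->Gln, TAA/TAG are glutamine codons and may dominate usage
  ref <- paste0("ATG", strrep("TAA", 30), strrep("CAA", 10))
  tab <- relative_adaptiveness(ref, gln)
  expect_equal(unname(tab$w["TAA"]), 1)
  expect_equal(unname(tab$w["CAA"]), 10 / 30)
  expect_true(all(c("TAA", "TAG") %in% tab$scoreable))
  # but a true stop codon inside a reference CDS is an error
  expect_error(relative_adaptiveness(paste0("ATG", "TGA", "CAA"), gln),
               "stop")
})

test_that("CAI is the geometric mean of w over scoreable codons", {
  # craft w(TTC) = 0.5 (Phe 8:4) and w(GGC) = 0.125 (Gly 8:1)
  ref <- paste0(strrep("TTT", 8), strrep("TTC", 4),
                strrep("GGT", 8), strrep("GGC", 1))
  tab <- relative_adaptiveness(ref, std)
  expect_equal(unname(tab$w["TTC"]), 0.5)
  expect_equal(unname(tab$w["GGC"]), 0.125)
  expect_equal(unname(cai("TTCGGC", tab)), 0.25)  # sqrt(0.0625)
  # all-preferred gene scores the maximum
  expect_equal(unname(cai("TTTGGT", tab)), 1)
  # a terminal stop codon is trimmed, single-codon families skipped
  expect_equal(unname(cai("TTTATGGGTTAA", tab)), 1)  # ATG (Met) skipped
  # monotonicity: swapping in a lower-w synonym strictly decreases CAI
  expect_lt(cai("TTCGGT", tab), cai("TTTGGT", tab))
  expect_lt(cai("TTCGGC", tab), cai("TTCGGT", tab))
  expect_error(cai("ATG", tab), "no scoreable")
  expect_error(cai("ATGC", tab), "divisible")
})

test_that("CAI of reference genes against their own table is at most 1", {
  spec <- synthetic_spec(n_genes = 10, seed = 23, code = "uar_to_gln")
  refs <- generate_reference_set(spec, n_ref = 50)
  tab <- relative_adaptiveness(refs, gln)
  vals <- cai(refs, tab)
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("quartile split reproduces the stated size patterns", {
  split_sizes <- function(n) {
    q <- quartile_split(sprintf("g%d", 1:n), seq_len(n))
    tabulate(q$quartile, 4)
  }
  expect_equal(split_sizes(26498), c(6625, 6624, 6624, 6625))
  expect_equal(split_sizes(8), c(2, 2, 2, 2))
  expect_equal(split_sizes(7), c(2, 2, 1, 2))
  expect_equal(sum(split_sizes(101)), 101)
  # quartile labels are monotone in CAI: quartile 4 holds the highest
  set.seed(5)
  vals <- runif(40)
  q <- quartile_split(sprintf("g%d", 1:40), vals)
  expect_true(min(vals[q$quartile == 4]) >= max(vals[q$quartile == 1]))
  expect_error(quartile_split("g1", 0.5), ">= 4")
})

test_that("subgroup chi-square matches hand arithmetic and the printed table", {
  # 30 TSC genes in a 100-gene subgroup, genome rate 0.2:
  # chi2 = 100/20 + 100/80 = 6.25
  res <- enrichment_chisq(30, 100, 200, 1000)
  expect_equal(res$statistic, 6.25)
  expect_equal(res$df, 1L)
  # top CAI quartile of a 26498-gene genome
  res2 <- enrichment_chisq(971, 6625, 3046, 26498)
  expect_equal(res2$statistic_rounded, 65)
  expect_equal(signif(res2$p_value, 2), 7.2e-16)
  # subgroup at exactly the genome rate scores zero
  expect_equal(enrichment_chisq(20, 100, 200, 1000)$statistic, 0)
  expect_error(enrichment_chisq(0, 10, 0, 100), "degenerate")
})

test_that("biased genes receive higher CAI than uniform genes", {
  spec <- synthetic_spec(n_genes = 500, seed = 77, codon_bias_gradient = 1)
  out <- generate_genome(spec, withr::local_tempdir())
  g <- read_genome(out$fasta, gln, organism = "sim")
  m <- read_gene_models(out$gff, g)
  refs <- generate_reference_set(spec, n_ref = 100)
  tab <- relative_adaptiveness(refs, gln)
  cds <- cds_sequences(m)
  vals <- cai(cds, tab)
  bias <- out$truth$bias[match(names(cds), out$truth$gene_id)]
  hi <- vals[bias > 0.75]; lo <- vals[bias < 0.25]
  expect_gt(median(hi), median(lo))
  expect_gt(cor(bias, vals, method = "spearman"), 0.5)
})

test_that("expression-coupled planting is detected by the quartile test", {
  # TSC presence coupled to the codon-bias quartile: 15% of top-quartile
  # genes planted vs 10% elsewhere, on top of the natural stop background
  reps <- 12
  rejected <- 0L
  for (r in seq_len(reps)) {
    spec <- synthetic_spec(
      n_genes = 20000, codon_bias_gradient = 1, seed = 500 + r,
      tsc_bias_by_expression = list(top_fraction = 0.15,
                                    other_fraction = 0.10, position = 1))
    sim <- simulate_utr_library(spec)
    has <- !is.na(observed_first_occurrence(sim$library)$first_stop)
    top <- sim$truth$bias >= quantile(sim$truth$bias, 0.75, type = 1)
    res <- enrichment_chisq(sum(has[top]), sum(top), sum(has),
                            length(has))
    if (res$p_value < 0.001) rejected <- rejected + 1L
  }
  expect_gte(rejected / reps, 0.9)
})

test_that("the CAI/TSC table assembles quartile summaries correctly", {
  set.seed(9)
  n <- 100
  qt <- quartile_split(sprintf("g%03d", 1:n), runif(n))
  has <- stats::setNames(runif(n) < 0.3, qt$gene_id)
  has[qt$gene_id[qt$quartile == 4]] <- runif(25) < 0.6
  tab <- cai_tsc_table(qt, has)
  expect_equal(sum(tab$summary$n_genes[1:4]), n)
  expect_equal(tab$summary$n_with_tsc[5], sum(has))
  expect_equal(tab$summary$pct_with_tsc[5],
               round(100 * sum(has) / n, 2))
  expect_equal(tab$top_quartile_test$df, 1L)
  expect_error(cai_tsc_table(qt, has[-1]), "missing for gene")
})
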