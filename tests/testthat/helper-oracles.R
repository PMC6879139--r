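# Independent oracles and toy-data builders shared across tests.

# Brute-force first-occurrence stop recount: plain character walk over the
# in-frame triplets, independent of the package's matrix scan.
brute_force_first_stop <- function(utr, stop_codons, n_positions = 6L) {
  for (i in seq_len(n_positions)) {
    tri <- substr(utr, 3L * i - 2L, 3L * i)
    if (tri %in% stop_codons) return(i)
  }
  NA_integer_
}

brute_force_obs <- function(utrs, stop_codons, n_positions = 6L) {
  firsts <- vapply(utrs, brute_force_first_stop, integer(1),
                   stop_codons = stop_codons, n_positions = n_positions)
  tabulate(firsts[!is.na(firsts)], nbins = n_positions)
}

# Exhaustive-permutation two-tailed Mann-Whitney oracle (no ties assumed):
# enumerates every assignment of the pooled values to the two groups.
mw_permutation_oracle <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  combos <- utils::combn(length(pool), n)
  u_all <- apply(combos, 2L, function(idx) u_of(pool[idx], pool[-idx]))
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Write a toy genome: FASTA from named contig strings, GFF3 from a data
# frame (gene_id, seq_id, strand, start, end), single-exon CDS per gene.
write_toy_genome <- function(contigs, genes,
                             dir = withr::local_tempdir(
                               .local_envir = parent.frame())) {
  fasta <- file.path(dir, "toy.fasta")
  writeLines(unlist(lapply(names(contigs), function(nm)
    c(paste0(">", nm), contigs[[nm]]))), fasta)
  gff_lines <- "##gff-version 3"
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    gff_lines <- c(gff_lines,
      sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$seq_id, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$seq_id, g$start, g$end, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c;Parent=%s.t1",
              g$seq_id, g$start, g$end, g$strand, g$gene_id, g$gene_id))
  }
  gff <- file.path(dir, "toy.gff3")
  writeLines(gff_lines, gff)
  list(fasta = fasta, gff = gff, dir = dir)
}

# random composition bounded away from degeneracy
random_composition <- function() {
  f <- stats::runif(4, 0.05, 1)
  composition_profile(stats::setNames(f / sum(f), c("A", "C", "G", "T")))
}

# i.i.d. random UTR library under a composition
random_library <- function(n, comp, code, window_nt = 20L) {
  bases <- sample(c("A", "C", "G", "T"), n * window_nt, replace = TRUE,
                  prob = unclass(comp))
  utrs <- apply(matrix(bases, nrow = n), 1L, paste0, collapse = "")
  utr_library(sprintf("g%04d", seq_len(n)), utrs, code,
              window_nt = window_nt)
}
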