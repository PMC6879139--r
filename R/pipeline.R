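#' Run the per-organism TSC pipeline
#'
#' Chains genome reading, gene-model resolution, UTR extraction, the
#' composition null and SCO scoring for one organism, optionally writing
#' the per-position table, summary row and exclusion log as TSVs.
#'
#' @param fasta_path genome FASTA.
#' @param gff_path GFF3 annotation.
#' @param code a [genetic_code()] or code label.
#' @param organism organism label used in outputs and error messages.
#' @param window_nt UTR window length (default 20).
#' @param out_dir optional output directory for TSVs
#'   (\code{<organism>_sco.tsv}, \code{<organism>_summary.tsv},
#'   \code{<organism>_exclusions.tsv}).
#' @return list with \code{profile} ([sco_profile()]), \code{counts},
#'   \code{null}, \code{composition}, \code{library} and \code{models}.
#' @export
run_organism <- function(fasta_path, gff_path, code,
                         organism = basename(fasta_path),
                         window_nt = 20L, out_dir = NULL) {
  if (is.character(code)) code <- genetic_code(code)
  res <- tryCatch({
    genome <- read_genome(fasta_path, code, organism = organism)
    models <- read_gene_models(gff_path, genome)
    lib <- extract_utrs(genome, models, window_nt = window_nt)
    comp <- composition(lib)
    null <- expected_counts(stop_probability(comp, code), length(lib$utr))
    counts <- observed_first_occurrence(lib)
    profile <- sco_profile(counts, null, organism = organism)
    list(profile = profile, counts = counts, null = null,
         composition = comp, library = lib, models = models)
  }, error = function(e) {
    stop("[", organism, "] ", conditionMessage(e), call. = FALSE)
  })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_sco_tsv(res$profile,
                  file.path(out_dir, paste0(organism, "_sco.tsv")),
                  file.path(out_dir, paste0(organism, "_summary.tsv")))
    write_exclusion_log(res$library,
                        file.path(out_dir, paste0(organism,
                                                  "_exclusions.tsv")))
  }
  res
}

#' Run group comparisons over per-organism SCO profiles
#'
#' Thin wrapper over [compare_groups()] that optionally collapses
#' configured sets of congeneric organisms into composites (via
#' [composite_average()]) before testing, and writes the comparison table
#' as TSV.
#'
#' @param profiles_by_group named list: group label -> list of
#'   [sco_profile()] objects.
#' @param alpha_family family-wise error rate (default 0.01).
#' @param composites optional named list: composite label -> character
#'   vector of organism labels to average into one pseudo-organism within
#'   their group.
#' @param out_path optional TSV output path.
#' @return a [compare_groups()] result.
#' @export
run_groups <- function(profiles_by_group, alpha_family = 0.01,
                       composites = NULL, out_path = NULL) {
  if (!is.null(composites)) {
    for (lab in names(composites)) {
      members <- composites[[lab]]
      for (g in names(profiles_by_group)) {
        grp <- profiles_by_group[[g]]
        orgs <- vapply(grp, `[[`, character(1), "organism")
        hit <- orgs %in% members
        if (any(hit)) {
          comp_prof <- composite_average(grp[hit], label = lab)
          profiles_by_group[[g]] <- c(grp[!hit], list(comp_prof))
        }
      }
    }
  }
  tab <- compare_groups(profiles_by_group, alpha_family = alpha_family)
  if (!is.null(out_path)) write_group_table(tab, out_path)
  tab
}

#' Run the CAI quartile TSC enrichment analysis
#'
#' Computes relative codon adaptiveness from a highly expressed reference
#' set, CAI for every gene, splits genes into CAI quartiles, flags genes
#' carrying a TSC within the scanned UTR window, and chi-square-tests the
#' top quartile against the genome-wide TSC rate.
#'
#' @param organism_run a [run_organism()] result (supplies gene CDS and
#'   per-gene first-stop positions).
#' @param reference_cds character vector of reference coding sequences,
#'   or a FASTA path.
#' @param out_dir optional output directory for per-gene and summary TSVs.
#' @return a [cai_tsc_table()] result.
#' @export
run_cai <- function(organism_run, reference_cds, out_dir = NULL) {
  code <- organism_run$library$code
  if (length(reference_cds) == 1L && file.exists(reference_cds)) {
    reference_cds <- as.character(
      Biostrings::readDNAStringSet(reference_cds))
  }
  adapt <- relative_adaptiveness(reference_cds, code)
  cds <- cds_sequences(organism_run$models)
  cds <- cds[names(cds) %in% organism_run$library$gene_id]
  cai_vals <- cai(cds, adapt)
  qt <- quartile_split(names(cds), unname(cai_vals))
  has_tsc <- !is.na(organism_run$counts$first_stop)
  res <- cai_tsc_table(qt, has_tsc)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    org <- organism_run$profile$organism
    write_cai_tsv(res, file.path(out_dir, paste0(org, "_cai_genes.tsv")),
                  file.path(out_dir, paste0(org, "_cai_summary.tsv")))
  }
  res
}
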