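# split CDS strings into codon triplets; validates length %% 3 == 0
.codons <- function(cds) {
  n <- nchar(cds)
  if (any(n %% 3L != 0L)) stop("CDS length(s) not divisible by 3")
  unlist(lapply(cds, function(s) {
    starts <- seq.int(1L, nchar(s), by = 3L)
    substring(s, starts, starts + 2L)
  }), use.names = FALSE)
}

# drop a terminal stop triplet, if present, from each CDS
.trim_stop <- function(cds, code) {
  n <- nchar(cds)
  term <- substr(cds, n - 2L, n)
  has_stop <- n >= 3L & !grepl("[^ACGT]", term) & term %in% code$stop_codons
  ifelse(has_stop, substr(cds, 1L, n - 3L), cds)
}

#' Relative adaptiveness of codons from a highly expressed reference set
#'
#' Counts codon usage over the reference coding sequences and scales each
#' codon by the most-used codon of its synonym family:
#' \code{w = count / max(count within family)}, so every family's
#' preferred codon has w = 1. Families are defined by the genetic code, so
#' reassigned former stops are scored inside their amino acid's family.
#' Codons absent from the reference receive a pseudo-count of 0.5 before
#' scaling, keeping w positive. Single-codon families carry w = 1 but are
#' flagged unscoreable and skipped by [cai()].
#'
#' @param reference_cds character vector of coding sequences (lengths
#'   divisible by 3; a terminal stop codon, if present, is trimmed).
#' @param code a [genetic_code()].
#' @param pseudo_count count assigned to unused codons (default 0.5).
#' @return An object of class \code{adaptiveness_table}: list with \code{w}
#'   (named over sense codons), \code{scoreable} (codons in families of
#'   size >= 2), \code{counts} and \code{code}.
#' @export
relative_adaptiveness <- function(reference_cds, code, pseudo_count = 0.5) {
  stopifnot(inherits(code, "genetic_code"))
  if (length(reference_cds) == 0L) stop("empty reference set")
  cod <- .codons(.trim_stop(toupper(reference_cds), code))
  cod <- cod[!grepl("[^ACGT]", cod)]
  if (any(cod %in% code$stop_codons)) {
    stop("internal stop codon(s) in reference CDS")
  }
  fams <- code$synonym_families
  sense <- unlist(fams, use.names = FALSE)
  counts <- table(factor(cod, levels = sense))
  counts <- stats::setNames(as.numeric(counts), sense)
  counts[counts == 0] <- pseudo_count
  w <- counts
  for (f in fams) w[f] <- counts[f] / max(counts[f])
  scoreable <- unlist(fams[lengths(fams) >= 2L], use.names = FALSE)
  structure(list(w = w, scoreable = scoreable, counts = counts, code = code),
            class = "adaptiveness_table")
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the relative adaptiveness values over the gene's
#' codons, skipping codons of single-codon synonym families (which carry
#' no usage-bias information) and any stop codon. Used as a proxy for
#' expression level.
#'
#' @param gene_cds a single coding sequence, or a character vector of them
#'   (lengths divisible by 3; terminal stops trimmed automatically).
#' @param table a [relative_adaptiveness()] result.
#' @return numeric CAI value(s) in (0, 1].
#' @export
cai <- function(gene_cds, table) {
  stopifnot(inherits(table, "adaptiveness_table"))
  vapply(toupper(gene_cds), function(s) {
    cod <- .codons(.trim_stop(s, table$code))
    cod <- cod[cod %in% table$scoreable]
    if (length(cod) == 0L) {
      stop("gene has no scoreable codons (only single-codon families/stops)")
    }
    exp(mean(log(table$w[cod])))
  }, numeric(1), USE.NAMES = !is.null(names(gene_cds)))
}

#' Split genes into CAI quartiles
#'
#' Genes are sorted ascending by CAI (quartile 1 = lowest, quartile 4 =
#' highest expression proxy) and cut into four contiguous blocks with
#' sizes as equal as possible; when n is not a multiple of 4 the spare
#' genes go to the outer quartiles first (order 1, 4, 2, 3), so e.g.
#' n = 26498 gives sizes 6625/6624/6624/6625. Ties in CAI keep input
#' (gene_id) order.
#'
#' @param gene_id character vector of gene identifiers.
#' @param cai_value numeric CAI per gene.
#' @return data frame (gene_id, cai, quartile) in the input order.
#' @export
quartile_split <- function(gene_id, cai_value) {
  n <- length(gene_id)
  stopifnot(n == length(cai_value), n >= 4L)
  base <- n %/% 4L
  sizes <- rep(base, 4L)
  extra_order <- c(1L, 4L, 2L, 3L)
  r <- n %% 4L
  if (r > 0L) sizes[extra_order[seq_len(r)]] <- base + 1L
  ord <- order(cai_value)          # stable: ties keep input order
  quartile <- integer(n)
  quartile[ord] <- rep(1:4, times = sizes)
  data.frame(gene_id = gene_id, cai = cai_value, quartile = quartile,
             stringsAsFactors = FALSE)
}

#' Chi-square test for TSC enrichment in a gene subgroup
#'
#' Goodness-of-fit (df = 1, no continuity correction) of the subgroup's
#' (TSC, no-TSC) gene counts against expectations from the genome-wide
#' TSC rate; the null hypothesis is that TSCs are as common in the
#' subgroup as in the whole genome. The subgroup is typically a CAI
#' quartile, or a partition by primary-stop identity.
#'
#' @param subgroup_tsc number of subgroup genes with a TSC.
#' @param subgroup_n subgroup size.
#' @param genome_tsc number of genes with a TSC genome-wide.
#' @param genome_n total genes genome-wide (subgroup included).
#' @return list with \code{statistic}, \code{df} (1), \code{p_value},
#'   \code{expected} (expected TSC count in the subgroup) and
#'   \code{statistic_rounded}.
#' @examples
#' enrichment_chisq(971, 6625, 3046, 26498)$statistic_rounded  # 65
#' @export
enrichment_chisq <- function(subgroup_tsc, subgroup_n, genome_tsc, genome_n) {
  stopifnot(subgroup_n <= genome_n, subgroup_tsc >= 0,
            subgroup_tsc <= subgroup_n, genome_tsc <= genome_n)
  if (genome_tsc == 0L || genome_tsc == genome_n) {
    stop("degenerate genome-wide TSC rate (0 or 1): chi-square undefined")
  }
  rate <- genome_tsc / genome_n
  ht <- suppressWarnings(stats::chisq.test(
    c(subgroup_tsc, subgroup_n - subgroup_tsc), p = c(rate, 1 - rate)))
  list(statistic = unname(ht$statistic), df = 1L,
       p_value = unname(ht$p.value),
       expected = subgroup_n * rate,
       statistic_rounded = round(unname(ht$statistic)))
}

#' CAI-quartile TSC enrichment table
#'
#' Combines per-gene CAI values with TSC presence flags into the
#' quartile-by-quartile summary (counts and percent of genes with a TSC)
#' and tests the top quartile against the whole genome with
#' [enrichment_chisq()].
#'
#' @param cai_table data frame from [quartile_split()].
#' @param has_tsc named logical vector (names = gene ids) or logical
#'   vector aligned with \code{cai_table$gene_id}.
#' @return An object of class \code{cai_tsc_table}: list with \code{genes}
#'   (gene_id, cai, quartile, has_tsc), \code{summary} (per-quartile and
#'   total counts/percentages) and \code{top_quartile_test}.
#' @export
cai_tsc_table <- function(cai_table, has_tsc) {
  stopifnot(is.data.frame(cai_table),
            all(c("gene_id", "cai", "quartile") %in% names(cai_table)))
  if (!is.null(names(has_tsc))) {
    miss <- setdiff(cai_table$gene_id, names(has_tsc))
    if (length(miss)) stop("has_tsc missing for gene(s): ",
                           paste(utils::head(miss, 3), collapse = ", "))
    flags <- as.logical(has_tsc[cai_table$gene_id])
  } else {
    stopifnot(length(has_tsc) == nrow(cai_table))
    flags <- as.logical(has_tsc)
  }
  genes <- cbind(cai_table, has_tsc = flags)
  n_q <- tabulate(genes$quartile, 4L)
  tsc_q <- vapply(1:4, function(q) sum(flags[genes$quartile == q]),
                  integer(1))
  summary <- data.frame(
    quartile = c(as.character(1:4), "total"),
    n_genes = c(n_q, sum(n_q)),
    n_with_tsc = c(tsc_q, sum(tsc_q)),
    pct_with_tsc = round(100 * c(tsc_q / n_q, sum(tsc_q) / sum(n_q)), 2))
  test <- enrichment_chisq(tsc_q[4], n_q[4], sum(tsc_q), sum(n_q))
  structure(list(genes = genes, summary = summary,
                 top_quartile_test = test),
            class = "cai_tsc_table")
}

#' @export
print.cai_tsc_table <- function(x, ...) {
  cat("TSC prevalence by CAI quartile (quartile 4 = highest CAI):\n")
  print(x$summary, row.names = FALSE)
  t <- x$top_quartile_test
  cat(sprintf(
    "4th quartile vs genome: chi-square = %.2f (df = 1), p = %.3g\n",
    t$statistic, t$p_value))
  invisible(x)
}

#' Write the CAI/TSC tables as TSV
#'
#' @param x a [cai_tsc_table()] result.
#' @param genes_path per-gene TSV (gene_id, cai, quartile, has_tsc).
#' @param summary_path per-quartile summary TSV.
#' @export
write_cai_tsv <- function(x, genes_path, summary_path = NULL) {
  stopifnot(inherits(x, "cai_tsc_table"))
  utils::write.table(x$genes, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.table(x$summary, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(genes_path)
}
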