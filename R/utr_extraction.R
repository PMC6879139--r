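#' Construct a UTR library object
#'
#' Low-level constructor used by [extract_utrs()] and the synthetic
#' generator. Validates window length, alphabet and gene-id uniqueness.
#'
#' @param gene_id character vector of gene identifiers.
#' @param utr character vector of UTR windows, same length as
#'   \code{gene_id}, each exactly \code{window_nt} long over \{A,C,G,T\}.
#' @param code the organism's [genetic_code()].
#' @param window_nt window length in nucleotides.
#' @param organism organism label.
#' @param excluded named integer vector of exclusion reason -> count.
#' @return An object of class \code{utr_library}.
#' @export
utr_library <- function(gene_id, utr, code, window_nt = 20L,
                        organism = "unknown", excluded = integer(0)) {
  stopifnot(inherits(code, "genetic_code"), length(gene_id) == length(utr))
  if (length(utr) == 0L) stop("empty UTR library: nothing to analyze")
  if (anyDuplicated(gene_id)) stop("duplicate gene_ids in UTR library")
  if (any(nchar(utr) != window_nt)) {
    stop("all UTR windows must have length window_nt = ", window_nt)
  }
  if (any(grepl("[^ACGT]", utr))) {
    stop("UTR windows must contain only A/C/G/T")
  }
  structure(list(organism = organism, code = code,
                 window_nt = as.integer(window_nt),
                 gene_id = as.character(gene_id), utr = as.character(utr),
                 excluded = excluded),
            class = "utr_library")
}

#' Extract fixed-length 3' UTR windows downstream of stop codons
#'
#' For a plus-strand gene the window is the \code{window_nt} nucleotides
#' immediately following the last base of the stop codon; for a
#' minus-strand gene, the reverse complement of the \code{window_nt}
#' nucleotides immediately preceding the stop codon's first (leftmost)
#' genomic base. Genes whose window runs off the contig end
#' (\code{"short_utr"}) or contains N (\code{"n_in_window"}) are excluded
#' and counted.
#'
#' @param genome a [read_genome()] result.
#' @param models a [read_gene_models()] result from the same genome.
#' @param window_nt window length, default 20 (>= 18 so that six full
#'   in-frame triplets can be scanned downstream).
#' @return An object of class \code{utr_library}; its \code{excluded}
#'   field also carries forward the gene-model exclusions.
#' @export
extract_utrs <- function(genome, models, window_nt = 20L) {
  stopifnot(inherits(genome, "genome"), inherits(models, "gene_models"))
  window_nt <- as.integer(window_nt)
  if (window_nt < 18L) stop("window_nt must be >= 18 (six in-frame triplets)")
  g <- models$genes
  if (!nrow(g)) stop("no gene models to extract UTRs from")

  contig_len <- nchar(genome$sequences)
  utrs <- character(nrow(g))
  reason <- character(nrow(g))  # "" = kept
  for (k in seq_len(nrow(g))) {
    contig <- genome$sequences[[g$seq_id[k]]]
    len <- contig_len[[g$seq_id[k]]]
    coord <- g$stop_coord[[k]]
    if (g$strand[k] == "+") {
      s <- max(coord) + 1L; e <- s + window_nt - 1L
      if (e > len) { reason[k] <- "short_utr"; next }
      w <- substr(contig, s, e)
    } else {
      e <- min(coord) - 1L; s <- e - window_nt + 1L
      if (s < 1L) { reason[k] <- "short_utr"; next }
      w <- reverse_complement(substr(contig, s, e))
    }
    if (grepl("N", w)) { reason[k] <- "n_in_window"; next }
    utrs[k] <- w
  }

  kept <- reason == ""
  excl <- table(reason[!kept])
  excl <- stats::setNames(as.integer(excl), names(excl))
  all_excl <- c(models$excluded, excl)
  if (!any(kept)) stop("empty UTR library: all genes excluded")
  utr_library(g$gene_id[kept], utrs[kept], genome$code,
              window_nt = window_nt, organism = genome$organism,
              excluded = all_excl)
}

#' @export
print.utr_library <- function(x, ...) {
  cat("UTR library for ", x$organism, ": ", length(x$utr), " windows of ",
      x$window_nt, " nt (code '", x$code$name, "'); ",
      sum(x$excluded), " genes excluded\n", sep = "")
  invisible(x)
}

#' Write a UTR library to a two-column TSV
#'
#' The companion [read_utr_library()] restores the library so downstream
#' stages can run without the genome.
#'
#' @param lib a \code{utr_library}.
#' @param path output path.
#' @export
write_utr_library <- function(lib, path) {
  stopifnot(inherits(lib, "utr_library"))
  utils::write.table(data.frame(gene_id = lib$gene_id, utr = lib$utr),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a UTR library from TSV
#'
#' @param path TSV written by [write_utr_library()].
#' @param code the organism's [genetic_code()].
#' @param organism organism label.
#' @return a \code{utr_library}.
#' @export
read_utr_library <- function(path, code, organism = basename(path)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "utr") %in% names(d))) {
    stop("expected columns gene_id, utr in ", path)
  }
  utr_library(d$gene_id, d$utr, code,
              window_nt = unique(nchar(d$utr))[1L], organism = organism)
}
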