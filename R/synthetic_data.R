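#' Named UTR composition presets
#'
#' \code{"ciliate_like"} mimics the extreme A/T richness of ciliate
#' genomes (A = T = 0.35, G = C = 0.15); \code{"balanced"} is uniform.
#'
#' @param name preset name.
#' @return a [composition_profile()].
#' @export
composition_preset <- function(name = c("ciliate_like", "balanced")) {
  name <- match.arg(name)
  switch(name,
    ciliate_like = composition_profile(c(A = 0.35, C = 0.15, G = 0.15,
                                         T = 0.35)),
    balanced = composition_profile(c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25)))
}

#' Specification for a synthetic genome
#'
#' Describes a multi-gene genome with known UTR composition, stop-codon
#' dictionary, planted tandem-stop enrichment, and codon-usage bias, so
#' every pipeline stage can be validated against ground truth.
#'
#' @param n_genes number of genes.
#' @param composition a [composition_profile()] or preset name
#'   ([composition_preset()]) for the UTR windows.
#' @param code a [genetic_code()] or code label.
#' @param enrichment named numeric: UTR position (as character "1".."6")
#'   -> fraction of genes whose first in-frame stop is forced at that
#'   position (earlier positions rejection-sampled stop-free). The
#'   remaining genes draw their windows i.i.d. from \code{composition}.
#' @param cds_length_range CDS length bounds in nt (inclusive of start and
#'   stop codons; rounded to multiples of 3; minimum 9).
#' @param codon_bias_gradient value in \[0,1\]: per-gene codon-usage bias
#'   levels run linearly from 0 up to this value across genes (0 = every
#'   gene uses synonymous codons uniformly).
#' @param tsc_bias_by_expression optional list
#'   \code{(top_fraction, other_fraction, position)}: instead of
#'   \code{enrichment}, plant a first stop at \code{position} with
#'   probability \code{top_fraction} for genes in the top quartile of
#'   codon bias and \code{other_fraction} for the rest (couples TSC
#'   presence to the expression proxy).
#' @param window_nt UTR window length (default 20).
#' @param seed integer seed driving all randomness.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           composition = "ciliate_like",
                           code = "uar_to_gln",
                           enrichment = numeric(0),
                           cds_length_range = c(150L, 600L),
                           codon_bias_gradient = 0,
                           tsc_bias_by_expression = NULL,
                           window_nt = 20L,
                           seed = 1L) {
  if (is.character(composition)) composition <- composition_preset(composition)
  stopifnot(inherits(composition, "composition_profile"))
  if (is.character(code)) code <- genetic_code(code)
  stopifnot(inherits(code, "genetic_code"))
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 1L, window_nt >= 18L,
            codon_bias_gradient >= 0, codon_bias_gradient <= 1,
            length(cds_length_range) == 2L,
            cds_length_range[1] >= 9L,
            cds_length_range[1] <= cds_length_range[2])
  if (length(enrichment)) {
    pos <- as.integer(names(enrichment))
    if (anyNA(pos) || any(pos < 1L) || any(3L * pos > window_nt)) {
      stop("enrichment must be named by UTR positions fitting the window")
    }
    if (any(enrichment < 0) || sum(enrichment) > 1) {
      stop("enrichment fractions must be nonnegative and sum to <= 1")
    }
  }
  p_stop <- stop_probability(composition, code)
  needs_stops <- length(enrichment) > 0 || !is.null(tsc_bias_by_expression)
  if (needs_stops && p_stop == 0) {
    stop("infeasible spec: composition gives zero probability to every ",
         "stop codon, cannot plant tandem stops")
  }
  if (!is.null(tsc_bias_by_expression)) {
    tb <- tsc_bias_by_expression
    stopifnot(is.list(tb),
              all(c("top_fraction", "other_fraction") %in% names(tb)))
    if (is.null(tb$position)) tb$position <- 1L
    tsc_bias_by_expression <- tb
  }
  structure(list(n_genes = n_genes, composition = composition, code = code,
                 enrichment = enrichment,
                 cds_length_range = as.integer(cds_length_range),
                 codon_bias_gradient = codon_bias_gradient,
                 tsc_bias_by_expression = tsc_bias_by_expression,
                 window_nt = as.integer(window_nt),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# i.i.d. base matrix -> character vector of strings
.random_strings <- function(n, width, comp) {
  if (n == 0L) return(character(0))
  bases <- sample(c("A", "C", "G", "T"), n * width, replace = TRUE,
                  prob = unclass(comp))
  m <- matrix(bases, nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# k stop-free triplets for each of n genes (rejection sampling)
.stop_free_block <- function(n, k, comp, code) {
  if (n == 0L || k == 0L) return(character(max(n, 0L)))
  tri <- matrix(.random_strings(n * k, 3L, comp), nrow = n)
  repeat {
    bad <- matrix(tri %in% code$stop_codons, nrow = n)
    if (!any(bad)) break
    tri[bad] <- .random_strings(sum(bad), 3L, comp)
  }
  apply(tri, 1L, paste0, collapse = "")
}

# planted positions per gene: 0 = not planted (i.i.d. null window)
.assign_planted <- function(spec, bias) {
  n <- spec$n_genes
  tb <- spec$tsc_bias_by_expression
  if (!is.null(tb)) {
    top <- bias >= stats::quantile(bias, 0.75, type = 1)
    f <- ifelse(top, tb$top_fraction, tb$other_fraction)
    ifelse(stats::runif(n) < f, as.integer(tb$position), 0L)
  } else if (length(spec$enrichment)) {
    pos <- as.integer(names(spec$enrichment))
    cum <- cumsum(spec$enrichment)
    u <- stats::runif(n)
    idx <- findInterval(u, c(0, cum), left.open = TRUE)
    out <- integer(n)
    planted <- idx >= 1L & idx <= length(pos) & u < cum[length(cum)]
    out[planted] <- pos[idx[planted]]
    out
  } else {
    integer(n)
  }
}

# UTR windows honoring planted first-stop positions (RNG NOT seeded here)
.sample_utrs <- function(spec, planted_pos) {
  comp <- spec$composition; code <- spec$code
  n <- spec$n_genes; w <- spec$window_nt
  utrs <- character(n)
  null_idx <- which(planted_pos == 0L)
  utrs[null_idx] <- .random_strings(length(null_idx), w, comp)
  stops <- code$stop_codons
  stop_p <- codon_probability(comp, stops)
  for (i in sort(unique(planted_pos[planted_pos > 0L]))) {
    idx <- which(planted_pos == i)
    pre <- .stop_free_block(length(idx), i - 1L, comp, code)
    stop_cd <- sample(stops, length(idx), replace = TRUE,
                      prob = stop_p / sum(stop_p))
    tail_nt <- .random_strings(length(idx), w - 3L * i, comp)
    utrs[idx] <- paste0(pre, stop_cd, tail_nt)
  }
  utrs
}

#' Simulate a UTR library directly (no genome round-trip)
#'
#' Draws the per-gene 20-nt UTR windows of a [synthetic_spec()] without
#' building the full genome: the fast path for calibration studies that
#' only need the library. [generate_genome()] embeds byte-identical logic
#' in full FASTA/GFF3 output.
#'
#' @param spec a [synthetic_spec()].
#' @param organism organism label.
#' @return list with \code{library} (a [utr_library()]) and \code{truth}
#'   (data frame: gene_id, planted_pos, bias, first_stop).
#' @export
simulate_utr_library <- function(spec, organism = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  bias <- if (n > 1L) {
    spec$codon_bias_gradient * (seq_len(n) - 1L) / (n - 1L)
  } else rep(0, n)
  planted <- .assign_planted(spec, bias)
  utrs <- .sample_utrs(spec, planted)
  ids <- sprintf("gene%05d", seq_len(n))
  lib <- utr_library(ids, utrs, spec$code, window_nt = spec$window_nt,
                     organism = organism)
  first <- observed_first_occurrence(lib)$first_stop
  list(library = lib,
       truth = data.frame(gene_id = ids, planted_pos = planted, bias = bias,
                          first_stop = unname(first),
                          stringsAsFactors = FALSE))
}

# sample n_codons sense codons at bias level b (preferred codon of each
# family drawn with probability b + (1-b)/family size)
.sample_codons <- function(n_codons, fams, b) {
  members <- unlist(fams, use.names = FALSE)
  sizes <- lengths(fams)
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  fam <- sample.int(length(fams), n_codons, replace = TRUE)
  preferred <- offsets[fam] + 1L                 # families stored sorted
  pick_pref <- stats::runif(n_codons) < b
  member <- offsets[fam] + ceiling(stats::runif(n_codons) * sizes[fam])
  members[ifelse(pick_pref, preferred, member)]
}

#' Generate a synthetic genome with annotation and truth table
#'
#' Builds a multi-contig genome in which every gene is ATG + a CDS drawn
#' from the codon model (no in-frame stops under the spec's code) + a stop
#' codon + a UTR window drawn per the spec's composition and planted
#' enrichment. Roughly 35\% of genes are placed on the minus strand.
#' Writes FASTA, GFF3 (gene/mRNA/CDS features, stop codon included in the
#' CDS) and a truth TSV recording each gene's strand, planted status,
#' bias level and realized first-stop position.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param genes_per_contig genes per contig (default 200).
#' @param minus_fraction fraction of minus-strand genes (default 0.35).
#' @return list with paths \code{fasta}, \code{gff}, \code{truth_path} and
#'   the in-memory \code{truth} data frame (which includes each gene's
#'   true UTR window).
#' @export
generate_genome <- function(spec, dir, prefix = "synthetic",
                            genes_per_contig = 200L,
                            minus_fraction = 0.35) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)
  n <- spec$n_genes
  comp <- spec$composition; code <- spec$code
  fams <- lapply(code$synonym_families, sort)

  bias <- if (n > 1L) {
    spec$codon_bias_gradient * (seq_len(n) - 1L) / (n - 1L)
  } else rep(0, n)
  planted <- .assign_planted(spec, bias)
  utrs <- .sample_utrs(spec, planted)
  strand <- sample(c("+", "-"), n, replace = TRUE,
                   prob = c(1 - minus_fraction, minus_fraction))
  lo <- spec$cds_length_range[1] %/% 3L
  hi <- spec$cds_length_range[2] %/% 3L
  n_codons_total <- sample(lo:hi, n, replace = TRUE)  # codons incl start/stop
  stops <- code$stop_codons
  stop_p <- codon_probability(comp, stops)
  stop_cd <- sample(stops, n, replace = TRUE, prob = stop_p / sum(stop_p))

  cds <- character(n)
  for (g in seq_len(n)) {
    body <- .sample_codons(n_codons_total[g] - 2L, fams, bias[g])
    cds[g] <- paste0("ATG", paste0(body, collapse = ""), stop_cd[g])
  }

  ids <- sprintf("gene%05d", seq_len(n))
  contig_of <- (seq_len(n) - 1L) %/% genes_per_contig + 1L
  n_contigs <- max(contig_of)
  contig_names <- sprintf("contig%03d", seq_len(n_contigs))

  gff <- c("##gff-version 3")
  contigs <- character(n_contigs)
  cds_start <- cds_end <- integer(n)
  for (ci in seq_len(n_contigs)) {
    idx <- which(contig_of == ci)
    parts <- character(0)
    offset <- 0L
    for (g in idx) {
      spacer <- .random_strings(1L, 30L, comp)
      full <- paste0(cds[g], utrs[g])
      L <- nchar(cds[g])
      block <- if (strand[g] == "+") full else reverse_complement(full)
      gstart <- offset + nchar(spacer) +
        (if (strand[g] == "+") 1L else spec$window_nt + 1L)
      gend <- gstart + L - 1L
      cds_start[g] <- gstart; cds_end[g] <- gend
      parts <- c(parts, spacer, block)
      offset <- offset + nchar(spacer) + nchar(block)
    }
    parts <- c(parts, .random_strings(1L, 30L, comp))
    contigs[ci] <- paste0(parts, collapse = "")
    for (g in idx) {
      att_gene <- sprintf("ID=%s", ids[g])
      att_mrna <- sprintf("ID=%s.t1;Parent=%s", ids[g], ids[g])
      att_cds <- sprintf("ID=%s.cds;Parent=%s.t1", ids[g], ids[g])
      gff <- c(gff,
        sprintf("%s\ttandemstop\tgene\t%d\t%d\t.\t%s\t.\t%s",
                contig_names[ci], cds_start[g], cds_end[g], strand[g],
                att_gene),
        sprintf("%s\ttandemstop\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
                contig_names[ci], cds_start[g], cds_end[g], strand[g],
                att_mrna),
        sprintf("%s\ttandemstop\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                contig_names[ci], cds_start[g], cds_end[g], strand[g],
                att_cds))
    }
  }

  fasta_path <- file.path(dir, paste0(prefix, ".fasta"))
  gff_path <- file.path(dir, paste0(prefix, ".gff3"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  seqs <- Biostrings::DNAStringSet(contigs)
  names(seqs) <- contig_names
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  writeLines(gff, gff_path)

  lib <- utr_library(ids, utrs, code, window_nt = spec$window_nt,
                     organism = prefix)
  first <- unname(observed_first_occurrence(lib)$first_stop)
  truth <- data.frame(gene_id = ids, contig = contig_names[contig_of],
                      strand = strand, planted_pos = planted, bias = bias,
                      first_stop = first, utr = utrs,
                      stringsAsFactors = FALSE)
  con <- file(truth_path, "w")
  writeLines(sprintf("# seed: %d", spec$seed), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  list(fasta = fasta_path, gff = gff_path, truth_path = truth_path,
       truth = truth)
}

#' Generate a highly expressed reference CDS set
#'
#' Coding sequences drawn entirely from the biased codon distribution
#' (bias level 1), standing in for an experimentally determined highly
#' expressed gene set when computing [relative_adaptiveness()].
#'
#' @param spec a [synthetic_spec()].
#' @param n_ref number of reference genes (default 225).
#' @param path optional FASTA output path.
#' @return named character vector of CDS (stop codons not included).
#' @export
generate_reference_set <- function(spec, n_ref = 225L, path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), n_ref >= 1L)
  set.seed(spec$seed + 1L)
  fams <- lapply(spec$code$synonym_families, sort)
  lo <- spec$cds_length_range[1] %/% 3L
  hi <- spec$cds_length_range[2] %/% 3L
  n_codons <- sample(lo:hi, n_ref, replace = TRUE)
  out <- vapply(seq_len(n_ref), function(g) {
    paste0("ATG", paste0(.sample_codons(n_codons[g] - 2L, fams, 1),
                         collapse = ""))
  }, character(1))
  names(out) <- sprintf("ref%04d", seq_len(n_ref))
  if (!is.null(path)) {
    x <- Biostrings::DNAStringSet(out)
    Biostrings::writeXStringSet(x, path, width = 80L)
  }
  out
}
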