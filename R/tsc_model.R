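#' Base composition of a UTR library
#'
#' Pooled mononucleotide frequencies over every character of every UTR
#' window in the library. All \code{window_nt} nucleotides enter the
#' estimate even though only the first 18 are scanned for stop codons.
#'
#' @param lib a [utr_library()], or a character vector of A/C/G/T strings.
#' @return An object of class \code{composition_profile}: named numeric
#'   (A, C, G, T) summing to 1.
#' @export
composition <- function(lib) {
  utrs <- if (inherits(lib, "utr_library")) lib$utr else lib
  if (length(utrs) == 0L) stop("empty UTR library")
  cnt <- colSums(Biostrings::letterFrequency(Biostrings::DNAStringSet(utrs),
                                             c("A", "C", "G", "T")))
  composition_profile(cnt / sum(cnt))
}

#' Construct a composition profile from base frequencies
#'
#' @param freq named numeric over A, C, G, T; must be nonnegative and sum
#'   to 1 (within 1e-9).
#' @return object of class \code{composition_profile}.
#' @examples
#' composition_profile(c(A = 0.3, T = 0.3, G = 0.2, C = 0.2))
#' @export
composition_profile <- function(freq) {
  if (is.null(names(freq)) || !setequal(names(freq), c("A", "C", "G", "T"))) {
    stop("freq must be named over exactly A, C, G, T")
  }
  freq <- freq[c("A", "C", "G", "T")]
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-9) {
    stop("frequencies must be nonnegative and sum to 1")
  }
  structure(freq, class = "composition_profile")
}

#' Expected probability of a codon under the composition null
#'
#' Product of the three positional base frequencies, treating UTR bases as
#' independent draws from the pooled composition. E.g. with 30% A, 30% T
#' and 20% G, p(TGA) = 0.3 x 0.2 x 0.3 = 0.018.
#'
#' @param comp a [composition_profile()].
#' @param codon a triplet (DNA or RNA alphabet).
#' @return probability.
#' @export
codon_probability <- function(comp, codon) {
  stopifnot(inherits(comp, "composition_profile"))
  codon <- normalize_codon(codon)
  vapply(strsplit(codon, ""), function(b) prod(unclass(comp)[b]), numeric(1))
}

#' Expected per-position stop codon probability
#'
#' Sum of [codon_probability()] over the code's stop codons: the chance
#' that a random in-frame triplet drawn from the composition is a stop.
#'
#' @param comp a [composition_profile()].
#' @param code a [genetic_code()].
#' @return probability \code{p_stop}.
#' @export
stop_probability <- function(comp, code) {
  stopifnot(inherits(code, "genetic_code"))
  sum(codon_probability(comp, code$stop_codons))
}

#' Geometric first-occurrence null model
#'
#' Under the null, each in-frame UTR triplet is an independent stop with
#' probability \code{p_stop}, so the first stop lands at position i with
#' probability \code{q_i = p_stop * (1 - p_stop)^(i-1)} (the geometric
#' first-success law; the second factor is the chance that every earlier
#' position was stop-free). Expected counts are \code{q_i * n_genes}.
#'
#' @param p_stop per-position stop probability in \[0,1\].
#' @param n_genes number of UTRs in the library.
#' @param n_positions number of in-frame positions modeled (default 6).
#' @return An object of class \code{null_model}: list with \code{p_stop},
#'   \code{q}, \code{exp}, \code{n_genes}.
#' @export
expected_counts <- function(p_stop, n_genes, n_positions = 6L) {
  stopifnot(p_stop >= 0, p_stop <= 1, n_genes > 0)
  i <- seq_len(n_positions)
  q <- p_stop * (1 - p_stop)^(i - 1)
  structure(list(p_stop = p_stop, q = q, exp = q * n_genes,
                 n_genes = as.integer(n_genes),
                 n_positions = as.integer(n_positions)),
            class = "null_model")
}

# triplet matrix: one row per UTR, one column per in-frame position
.utr_triplets <- function(utrs, n_positions = 6L) {
  starts <- 3L * (seq_len(n_positions) - 1L) + 1L
  vapply(starts, function(s) substr(utrs, s, s + 2L),
         character(length(utrs)))
}

#' Observed first-occurrence stop counts per UTR position
#'
#' Scans the in-frame triplets (nt 1-3, 4-6, ..., 16-18) of each UTR
#' window and records only the FIRST stop codon per gene; later stops in
#' the same window are not counted (the null model is the matching
#' geometric law).
#'
#' @param lib a [utr_library()].
#' @param n_positions number of positions scanned (default 6).
#' @return An object of class \code{tsc_counts}: list with \code{n_genes},
#'   \code{obs} (counts at positions 1..n), \code{n_with_tsc}, and
#'   \code{first_stop} (named per-gene first-stop position, NA if none).
#' @export
observed_first_occurrence <- function(lib, n_positions = 6L) {
  stopifnot(inherits(lib, "utr_library"))
  if (lib$window_nt < 3L * n_positions) {
    stop("window_nt too short for ", n_positions, " positions")
  }
  tri <- .utr_triplets(lib$utr, n_positions)
  if (is.null(dim(tri))) tri <- matrix(tri, nrow = length(lib$utr))
  hit <- matrix(tri %in% lib$code$stop_codons, nrow = nrow(tri))
  has <- rowSums(hit) > 0L
  first <- rep(NA_integer_, nrow(hit))
  first[has] <- max.col(hit[has, , drop = FALSE], ties.method = "first")
  obs <- tabulate(first[has], nbins = n_positions)
  structure(list(n_genes = length(lib$utr), obs = obs,
                 n_with_tsc = sum(has),
                 first_stop = stats::setNames(first, lib$gene_id)),
            class = "tsc_counts")
}

#' Stop codon overrepresentation scores (SCOs)
#'
#' Per-position SCO is the natural log of observed over expected
#' first-occurrence stop counts, \code{SCO_i = ln(obs_i / exp_i)}; scores
#' above zero indicate more tandem stop codons than the composition null
#' predicts. The combined SCO pools the first \code{n_positions}
#' positions: \code{ln(sum(obs) / sum(exp))}. Observed and expected
#' fractions of genes carrying a TSC in the window are reported alongside.
#'
#' @param counts a [observed_first_occurrence()] result.
#' @param null a [expected_counts()] result built with the same
#'   \code{n_genes}.
#' @param organism organism label.
#' @return An object of class \code{sco_profile}: list with \code{sco}
#'   (per position; NA where \code{obs_i} = 0), \code{combined_sco},
#'   \code{frac_obs}, \code{frac_exp}, plus the inputs' \code{obs},
#'   \code{exp}, \code{q} and \code{n_genes}.
#' @export
sco_profile <- function(counts, null, organism = "unknown") {
  stopifnot(inherits(counts, "tsc_counts"), inherits(null, "null_model"))
  if (counts$n_genes != null$n_genes) {
    stop("null model built for n_genes = ", null$n_genes,
         " but counts have n_genes = ", counts$n_genes)
  }
  obs <- counts$obs
  ex <- null$exp
  if (length(obs) != length(ex)) stop("position count mismatch")
  if (any(ex == 0 & obs > 0)) {
    stop("degenerate null: expected count 0 with observed > 0")
  }
  sco <- ifelse(obs > 0, log(obs / ex), NA_real_)
  combined <- log(sum(obs) / sum(ex))
  structure(list(organism = organism, sco = sco, combined_sco = combined,
                 frac_obs = counts$n_with_tsc / counts$n_genes,
                 frac_exp = sum(null$q),
                 obs = obs, exp = ex, q = null$q,
                 p_stop = null$p_stop, n_genes = counts$n_genes,
                 n_with_tsc = counts$n_with_tsc),
            class = "sco_profile")
}

#' @export
print.sco_profile <- function(x, digits = 3, ...) {
  cat("SCO profile for ", x$organism, " (", x$n_genes, " UTRs, p_stop = ",
      signif(x$p_stop, 4), ")\n", sep = "")
  print(data.frame(position = seq_along(x$sco), obs = x$obs,
                   exp = round(x$exp, digits), sco = round(x$sco, digits)))
  cat("combined SCO = ", round(x$combined_sco, digits),
      "; genes with TSC: ", sprintf("%.2f%%", 100 * x$frac_obs),
      " observed vs ", sprintf("%.2f%%", 100 * x$frac_exp),
      " expected\n", sep = "")
  invisible(x)
}

#' Write per-position SCO results as TSV
#'
#' One row per UTR position (position, obs, exp, q, sco) followed by a
#' summary file row layout mirroring per-organism result tables.
#'
#' @param profile a [sco_profile()].
#' @param path output TSV for the per-position table.
#' @param summary_path optional TSV for the one-row summary
#'   (combined_sco, frac_obs, frac_exp).
#' @export
write_sco_tsv <- function(profile, path, summary_path = NULL) {
  stopifnot(inherits(profile, "sco_profile"))
  utils::write.table(
    data.frame(position = seq_along(profile$sco), obs = profile$obs,
               exp = profile$exp, q = profile$q,
               sco = round(profile$sco, 3)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.table(
      data.frame(organism = profile$organism,
                 n_genes = profile$n_genes,
                 combined_sco = round(profile$combined_sco, 3),
                 frac_obs = profile$frac_obs,
                 frac_exp = profile$frac_exp),
      summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
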