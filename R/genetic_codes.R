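#' Supported genetic-code labels
#'
#' Named variants of the nuclear genetic code that differ in which of the
#' three canonical stop triplets actually terminate translation:
#' \describe{
#'   \item{standard}{TAA, TAG and TGA all terminate.}
#'   \item{uar_to_gln}{TAA/TAG (the "UAR" pair) reassigned to glutamine, as
#'     in most ciliates and the diplomonad \emph{Spironucleus salmonicida};
#'     TGA is the sole stop.}
#'   \item{uga_to_trp}{TGA reassigned to tryptophan, as in
#'     \emph{Euplotes octocarinatus}; TAA/TAG terminate.}
#'   \item{uga_to_cys}{TGA reassigned to cysteine (the
#'     \emph{Pseudocohnilembus persalinus} variant); same stop set as
#'     \code{uga_to_trp}, the reassigned TGA simply joins the cysteine
#'     synonym family instead.}
#' }
#' @keywords internal
#' @name code-labels
NULL

.code_labels <- c("standard", "uar_to_gln", "uga_to_trp", "uga_to_cys")

.reassignments <- list(
  standard   = character(0),
  uar_to_gln = c(TAA = "Q", TAG = "Q"),
  uga_to_trp = c(TGA = "W"),
  uga_to_cys = c(TGA = "C")
)

#' Normalize codons to the internal DNA alphabet
#'
#' Uppercases and converts U to T. Errors on anything that is not a triplet
#' over \{A,C,G,T,U\}.
#'
#' @param codon character vector of triplets.
#' @return character vector of DNA triplets over \{A,C,G,T\}.
#' @keywords internal
normalize_codon <- function(codon) {
  if (!is.character(codon) || length(codon) == 0L) {
    stop("codon must be a non-empty character vector")
  }
  out <- chartr("u", "T", chartr("U", "T", toupper(codon)))
  bad <- nchar(out) != 3L | grepl("[^ACGT]", out)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(codon[bad], collapse = ", "),
         " (expected triplets over A/C/G/T/U)")
  }
  out
}

#' Construct a genetic code as a stop-codon dictionary
#'
#' A genetic code here is defined by which of TAA/TAG/TGA terminate
#' translation. Former stop codons that were reassigned to a sense codon
#' join that amino acid's synonym family, which matters for codon adaptation
#' index calculations (e.g. TAA and TAG join the glutamine family under
#' \code{"uar_to_gln"}).
#'
#' @param name one of \code{"standard"}, \code{"uar_to_gln"},
#'   \code{"uga_to_trp"}, \code{"uga_to_cys"}, or an arbitrary label when
#'   \code{stop_codons} is supplied explicitly.
#' @param stop_codons optional explicit stop set (triplets, DNA or RNA
#'   alphabet), a nonempty subset of TAA/TAG/TGA, defining a custom code.
#'   Former stops not in the set are treated as unassigned single-codon
#'   families (they never terminate and never enter CAI scoring).
#' @return An object of class \code{genetic_code} with fields \code{name},
#'   \code{stop_codons}, \code{reassigned} (former stop -> one-letter amino
#'   acid) and \code{synonym_families} (amino acid -> codons).
#' @examples
#' genetic_code("uar_to_gln")$stop_codons  # "TGA"
#' @export
genetic_code <- function(name = "standard", stop_codons = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  canonical <- c("TAA", "TAG", "TGA")
  if (is.null(stop_codons)) {
    if (!name %in% .code_labels) {
      stop("unknown genetic code '", name, "'; supported codes: ",
           paste(.code_labels, collapse = ", "),
           " (or supply stop_codons= for a custom code)")
    }
    reassigned <- .reassignments[[name]]
    stops <- setdiff(canonical, names(reassigned))
  } else {
    stops <- unique(normalize_codon(stop_codons))
    if (!all(stops %in% canonical) || length(stops) == 0L) {
      stop("stop_codons must be a nonempty subset of TAA/TAG/TGA")
    }
    former <- setdiff(canonical, stops)
    # custom codes: unknown amino-acid assignment, flagged "X"
    reassigned <- stats::setNames(rep("X", length(former)), former)
  }

  tab <- Biostrings::GENETIC_CODE
  assign <- tab
  assign[names(reassigned)] <- reassigned
  assign[stops] <- "*"
  sense <- assign[assign != "*"]
  families <- split(names(sense), sense)
  # custom "X" reassignments: each former stop is its own family
  if (!is.null(stop_codons) && length(reassigned)) {
    families[["X"]] <- NULL
    for (cd in names(reassigned)) families[[cd]] <- cd
  }

  structure(
    list(name = name,
         stop_codons = sort(stops),
         reassigned = reassigned,
         synonym_families = families),
    class = "genetic_code"
  )
}

#' Test whether codons are stop codons under a genetic code
#'
#' Case-insensitive; U and T interchangeable on input.
#'
#' @param codon character vector of triplets.
#' @param code a [genetic_code()].
#' @return logical vector.
#' @examples
#' is_stop("UGA", genetic_code("uar_to_gln"))  # TRUE
#' is_stop("TAA", genetic_code("uar_to_gln"))  # FALSE
#' @export
is_stop <- function(codon, code) {
  stopifnot(inherits(code, "genetic_code"))
  normalize_codon(codon) %in% code$stop_codons
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code '", x$name, "': stops {",
      paste(x$stop_codons, collapse = ", "), "}", sep = "")
  if (length(x$reassigned)) {
    cat("; reassigned ",
        paste(names(x$reassigned), "->", x$reassigned, collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}
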