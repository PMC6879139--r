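#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased and validated against the \{A,C,G,T,N\}
#' alphabet. The contig label is the first whitespace-delimited token of
#' each FASTA header.
#'
#' @param fasta_path path to a (multi-record) FASTA file.
#' @param code the organism's [genetic_code()].
#' @param organism organism label carried through to downstream outputs.
#' @return An object of class \code{genome}: list with \code{organism},
#'   \code{code} and \code{sequences} (named character vector of contigs).
#' @export
read_genome <- function(fasta_path, code, organism = basename(fasta_path)) {
  stopifnot(inherits(code, "genetic_code"))
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", fasta_path)
  labels <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(labels)) {
    stop("duplicate contig labels in ", fasta_path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  chars <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("contig(s) with characters outside A/C/G/T/N: ",
         paste(labels[bad], collapse = ", "))
  }
  names(chars) <- labels
  structure(list(organism = organism, code = code, sequences = chars),
            class = "genome")
}

#' Reverse complement of DNA sequences
#'
#' @param seq character vector over \{A,C,G,T,N\} (empty strings allowed).
#' @return character vector of reverse complements; N maps to N.
#' @examples
#' reverse_complement("TGA")  # "TCA"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("seq must be character")
  if (any(grepl("[^ACGTN]", seq))) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

# Spliced CDS sequence in transcript orientation from sorted genomic intervals.
.spliced_seq <- function(contig_seq, starts, ends, strand) {
  pieces <- substring(contig_seq, starts, ends)
  s <- paste(pieces, collapse = "")
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Read gene models from GFF3 and resolve stop-codon coordinates
#'
#' Parses CDS features (grouped per transcript via \code{Parent}
#' attributes), keeps one representative isoform per gene (the one with the
#' longest total CDS; ties broken by file order), and resolves each gene's
#' stop codon genomically. GFF dialects that exclude the stop codon from
#' the CDS are handled by testing the 3 nt immediately downstream of the
#' CDS end when the CDS-terminal triplet is not a stop. Genes without an
#' ATG at the CDS start (transcript orientation), without a resolvable stop
#' codon, with Ns in either terminal triplet, or with coordinates off the
#' contig are excluded and tallied by reason.
#'
#' @param gff_path path to a GFF3 file with gene/mRNA/CDS features.
#' @param genome a [read_genome()] result; supplies sequence and the code
#'   used to validate stop codons.
#' @return An object of class \code{gene_models}: list with
#'   \describe{
#'     \item{genes}{data frame: \code{gene_id}, \code{seq_id},
#'       \code{strand}, \code{cds_start}, \code{cds_end}, list-columns
#'       \code{cds_starts}/\code{cds_ends} (per-exon intervals),
#'       \code{stop_coord} (list of 3 genomic positions), \code{stop_codon}
#'       (triplet in transcript orientation), \code{stop_in_cds},
#'       \code{cds_seq} (spliced CDS, stop codon trimmed).}
#'     \item{excluded}{named integer vector, exclusion reason -> count.}
#'     \item{n_annotated}{total genes seen in the GFF.}
#'   }
#' @export
read_gene_models <- function(gff_path, genome) {
  stopifnot(inherits(genome, "genome"))
  if (!file.exists(gff_path)) stop("GFF file not found: ", gff_path)
  gff <- tryCatch(
    rtracklayer::import(gff_path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in ", gff_path, ": ",
                             conditionMessage(e))
  )
  df <- as.data.frame(gff, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no features in GFF3 file: ", gff_path)
  if (is.null(df$ID)) df$ID <- NA_character_
  if (is.null(df$Parent)) df$Parent <- replicate(nrow(df), character(0))
  df$Parent1 <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))

  is_tx <- df$type %in% c("mRNA", "transcript")
  tx2gene <- stats::setNames(
    ifelse(is.na(df$Parent1[is_tx]), df$ID[is_tx], df$Parent1[is_tx]),
    df$ID[is_tx])

  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features in GFF3 file: ", gff_path)
  cds$tx <- ifelse(is.na(cds$Parent1), cds$ID, cds$Parent1)
  if (anyNA(cds$tx)) stop("CDS feature without ID/Parent in ", gff_path)
  cds$gene <- ifelse(cds$tx %in% names(tx2gene), tx2gene[cds$tx], cds$tx)
  cds$row0 <- seq_len(nrow(cds))

  gene_ids <- unique(c(df$ID[df$type == "gene" & !is.na(df$ID)], cds$gene))
  n_annotated <- length(gene_ids)

  excl <- c(no_cds = 0L, unknown_contig = 0L, inconsistent_annotation = 0L,
            cds_out_of_bounds = 0L, cds_too_short = 0L,
            ambiguous_terminus = 0L, no_start_codon = 0L, no_stop_codon = 0L)
  keep <- vector("list", n_annotated)

  by_gene <- split(cds, cds$gene)
  for (gid in gene_ids) {
    g <- by_gene[[gid]]
    if (is.null(g)) { excl["no_cds"] <- excl["no_cds"] + 1L; next }
    # representative isoform: longest total CDS, ties by file order
    widths <- tapply(g$end - g$start + 1L, g$tx, sum)
    first_row <- tapply(g$row0, g$tx, min)
    best <- names(widths)[order(-widths, first_row)][1L]
    g <- g[g$tx == best, , drop = FALSE]

    seq_id <- as.character(g$seqnames[1L])
    strand <- as.character(g$strand[1L])
    if (length(unique(as.character(g$seqnames))) > 1L ||
        length(unique(as.character(g$strand))) > 1L ||
        !strand %in% c("+", "-")) {
      excl["inconsistent_annotation"] <- excl["inconsistent_annotation"] + 1L
      next
    }
    if (!seq_id %in% names(genome$sequences)) {
      excl["unknown_contig"] <- excl["unknown_contig"] + 1L
      next
    }
    contig <- genome$sequences[[seq_id]]
    ord <- order(g$start)
    starts <- g$start[ord]; ends <- g$end[ord]
    if (any(ends[-length(ends)] >= starts[-1L])) {
      excl["inconsistent_annotation"] <- excl["inconsistent_annotation"] + 1L
      next
    }
    if (starts[1L] < 1L || ends[length(ends)] > nchar(contig)) {
      excl["cds_out_of_bounds"] <- excl["cds_out_of_bounds"] + 1L
      next
    }
    cds_seq <- .spliced_seq(contig, starts, ends, strand)
    L <- nchar(cds_seq)
    if (L < 6L) { excl["cds_too_short"] <- excl["cds_too_short"] + 1L; next }

    start_tri <- substr(cds_seq, 1L, 3L)
    if (grepl("N", start_tri)) {
      excl["ambiguous_terminus"] <- excl["ambiguous_terminus"] + 1L; next
    }
    if (start_tri != "ATG") {
      excl["no_start_codon"] <- excl["no_start_codon"] + 1L; next
    }

    term_tri <- substr(cds_seq, L - 2L, L)
    stop_in_cds <- !grepl("N", term_tri) && is_stop(term_tri, genome$code)
    if (stop_in_cds) {
      # genomic coordinates of the last 3 spliced positions
      pos <- unlist(Map(seq.int, starts, ends), use.names = FALSE)
      tri_pos <- if (strand == "+") utils::tail(pos, 3L) else pos[1:3]
      stop_codon <- term_tri
      cds_trim <- substr(cds_seq, 1L, L - 3L)
    } else {
      # dialect fallback: stop codon immediately downstream of the CDS
      if (strand == "+") {
        s <- ends[length(ends)] + 1L; e <- s + 2L
        if (e > nchar(contig)) {
          excl["no_stop_codon"] <- excl["no_stop_codon"] + 1L; next
        }
        down <- substr(contig, s, e)
      } else {
        e <- starts[1L] - 1L; s <- e - 2L
        if (s < 1L) { excl["no_stop_codon"] <- excl["no_stop_codon"] + 1L; next }
        down <- reverse_complement(substr(contig, s, e))
      }
      if (grepl("N", down)) {
        excl["ambiguous_terminus"] <- excl["ambiguous_terminus"] + 1L; next
      }
      if (!is_stop(down, genome$code)) {
        excl["no_stop_codon"] <- excl["no_stop_codon"] + 1L; next
      }
      tri_pos <- s:e
      stop_codon <- down
      cds_trim <- cds_seq
    }

    keep[[match(gid, gene_ids)]] <- data.frame(
      gene_id = gid, seq_id = seq_id, strand = strand,
      cds_start = starts[1L], cds_end = ends[length(ends)],
      cds_starts = I(list(starts)), cds_ends = I(list(ends)),
      stop_coord = I(list(sort(tri_pos))),
      stop_codon = stop_codon, stop_in_cds = stop_in_cds,
      cds_seq = cds_trim, stringsAsFactors = FALSE)
  }

  genes <- do.call(rbind, keep[!vapply(keep, is.null, logical(1))])
  if (is.null(genes)) genes <- data.frame(gene_id = character(0))
  rownames(genes) <- NULL
  structure(list(genes = genes, excluded = excl[excl > 0L],
                 n_annotated = n_annotated),
            class = "gene_models")
}

#' Extract spliced CDS sequences from gene models
#'
#' @param models a [read_gene_models()] result.
#' @return named character vector of CDS sequences in transcript
#'   orientation, stop codons trimmed, ready for [cai()].
#' @export
cds_sequences <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  stats::setNames(models$genes$cds_seq, models$genes$gene_id)
}

#' Write a per-gene exclusion log
#'
#' @param models a [read_gene_models()] result (or any object with an
#'   \code{excluded} count vector).
#' @param path output TSV path (columns: reason, n_genes).
#' @export
write_exclusion_log <- function(models, path) {
  ex <- models$excluded
  utils::write.table(
    data.frame(reason = names(ex), n_genes = as.integer(ex)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
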