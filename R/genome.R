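#' Read a genome FASTA into a named set of contig sequences
#'
#' Loads a (possibly multi-contig) FASTA file and validates that every
#' sequence is non-empty, that contig names are unique, and that only IUPAC
#' nucleotide characters occur. Sequences are held as a
#' [Biostrings::DNAStringSet] so slicing and reverse complement use the
#' standard machinery.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_sequence` object (a `DNAStringSet` with unique names).
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  as_genome(seqs)
}

#' Build a genome object from named character sequences
#'
#' @param x Named character vector of nucleotide strings, or a
#'   `DNAStringSet`.
#' @return A `genome_sequence` object.
#' @export
as_genome <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      stop("all contigs must be named")
    }
    x <- Biostrings::DNAStringSet(x)  # rejects non-IUPAC characters
  }
  if (!methods::is(x, "DNAStringSet")) stop("expected a DNAStringSet or named character vector")
  nm <- names(x)
  # strip FASTA description after first whitespace, as samtools faidx does
  names(x) <- sub("\\s.*$", "", nm)
  if (anyDuplicated(names(x))) stop("duplicate contig names in genome")
  if (any(Biostrings::width(x) == 0L)) stop("empty contig sequence in genome")
  x  # a validated DNAStringSet; referred to as a genome_sequence throughout
}

#' Fetch a strand-aware subsequence from the genome
#'
#' Coordinates are 0-based half-open (BED convention). On the minus strand
#' the reverse complement of the slice is returned, so the result always
#' reads 5' to 3' in transcript orientation.
#'
#' @param genome A `genome_sequence`.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @return A nucleotide string of length `end - start`.
#' @export
fetch_sequence <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) {
    stop(sprintf("unknown contig '%s'", contig))
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  len <- length(genome[[contig]])
  if (start < 0L || end > len || end < start) {
    stop(sprintf("interval [%d,%d) out of bounds for contig '%s' (length %d)",
                 start, end, contig, len))
  }
  s <- Biostrings::subseq(genome[[contig]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Translate a coding nucleotide sequence codon by codon
#'
#' Uses the standard genetic code. Codons containing `N` (or any
#' non-ACGT base) translate to `X`; stop codons translate to `*`. The
#' caller decides how to treat internal or terminal stops.
#'
#' @param nt Nucleotide string; its length need not be a multiple of 3 --
#'   a trailing partial codon is dropped.
#' @return Amino-acid string (with `*` for stops).
#' @keywords internal
translate_codons <- function(nt) {
  n <- nchar(nt)
  n3 <- n - n %% 3L
  if (n3 < 3L) return("")
  codons <- substring(nt, seq(1L, n3 - 2L, by = 3L), seq(3L, n3, by = 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# plain-string reverse complement for short windows (keeps helpers cheap)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
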