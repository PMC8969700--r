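#' @importFrom stats kmeans median rnorm rlnorm runif setNames
#' @importFrom utils head tail read.table write.table modifyList
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors, which is how sequences travel through this package.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence
#'
#' @param n length in bp.
#' @return a single DNA string drawn uniformly over A/C/G/T from the current
#'   RNG state.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

## Terminus bookkeeping: a terminus is (contig_id, side) with side head/tail;
## head is the 5' end of the stored strand.
TERMINUS_SIDES <- c("head", "tail")

terminus_key <- function(contig_id, side) paste(contig_id, side, sep = ":")

other_side <- function(side) ifelse(side == "head", "tail", "head")

## Exit terminus of a contig traversed with the given orientation, and the
## orientation implied by entering a contig at a given terminus.
exit_side <- function(orientation) ifelse(orientation == "+", "tail", "head")
entry_side <- function(orientation) ifelse(orientation == "+", "head", "tail")
orientation_from_entry <- function(side) ifelse(side == "head", "+", "-")

flip_orientation <- function(o) ifelse(o == "+", "-", "+")

## round() half away from zero -- print conventions for shares (integer
## percent) and usage factors (1 decimal) depend on it.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA strings.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}
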