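#' Bundled assay sequences
#'
#' Accessors for the sequences that define the spacer-agnostic sgRNA qPCR
#' assay and the HiBiT motif scan: the scaffold-specific qPCR primer pair,
#' the three standard oligonucleotides used to build absolute standard
#' curves, the four sgRNA spacers, and the 11-residue HiBiT query peptide.
#'
#' The standard oligonucleotides correspond to the cDNA sequence of a full
#' sgRNA (spacer plus scaffold); the primers bind the invariant scaffold, so
#' the same primer pair amplifies a product of identical length from each
#' oligo regardless of spacer.
#'
#' @return `scaffold_primers()` returns a [primer_pair]; the others return a
#'   named character vector of sequences (DNA, or for `hibit_query()` a
#'   single amino-acid string).
#' @examples
#' scaffold_primers()
#' nchar(sgrna_spacers())  # all 20 nt
#' hibit_query()
#' @name fixtures
NULL

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "evlptiter")
  if (!nzchar(path)) stop("bundled fixture not found: ", file)
  path
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that returns plain
#' uppercase character sequences named by the first word of each description
#' line (full descriptions kept in the `"description"` attribute).
#'
#' @param file path to a FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(file) {
  set <- Biostrings::readDNAStringSet(file)
  desc <- names(set)
  ids <- vapply(strsplit(desc, "[ \t]+"), `[[`, character(1), 1L)
  out <- toupper(as.character(set))
  names(out) <- ids
  attr(out, "description") <- desc
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences
#' @param file output path
#' @param width line width for wrapping
#' @return `file`, invisibly
#' @export
write_fasta <- function(seqs, file, width = 60L) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, file, width = width)
  invisible(file)
}

#' @rdname fixtures
#' @export
scaffold_primers <- function() {
  p <- read_fasta(fixture_path("scaffold_qpcr_primers.fasta"))
  primer_pair(forward = unname(p[["qPCR_sgRNA_fw"]]),
              reverse = unname(p[["qPCR_sgRNA_rv"]]))
}

#' @rdname fixtures
#' @export
standard_oligos <- function() {
  read_fasta(fixture_path("scaffold_standard_oligos.fasta"))
}

#' @rdname fixtures
#' @export
sgrna_spacers <- function() {
  read_fasta(fixture_path("sgrna_spacers.fasta"))
}

#' @rdname fixtures
#' @export
hibit_query <- function() "VSGWRLFKKIS"
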