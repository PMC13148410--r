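# Codon-aware back-translation: threads unaligned, in-frame CDS onto a
# protein multiple alignment so that every residue gap becomes the gap codon
# "---" and removing gap codons reconstructs the CDS exactly.

#' Back-translate a protein alignment to a codon alignment
#'
#' For each taxon the ungapped coding sequence is translated under the
#' standard nuclear code and checked residue-by-residue against the ungapped
#' protein row (a terminal stop codon is allowed and stripped; an internal
#' stop is an error). Codons are then laid onto the alignment, with `---`
#' at every residue gap.
#'
#' @param protein_alignment Named [Biostrings::AAStringSet] (or named
#'   character vector) of aligned protein sequences; `-` marks gaps.
#' @param cds Named [Biostrings::DNAStringSet] (or named character vector)
#'   of unaligned, in-frame coding sequences covering the same taxa.
#' @return A [CodonAlignment-class].
#' @examples
#' backTranslateAlignment(c(t1 = "M-A", t2 = "MKA"),
#'                        c(t1 = "ATGGCT", t2 = "ATGAAAGCT"))
#' @export
backTranslateAlignment <- function(protein_alignment, cds) {
  if (is(protein_alignment, "AAStringSet"))
    protein_alignment <- as.character(protein_alignment)
  if (is(cds, "DNAStringSet")) cds <- as.character(cds)
  protein_alignment <- toupper(protein_alignment)
  cds <- toupper(cds)
  taxa <- names(protein_alignment)
  if (is.null(taxa) || anyDuplicated(taxa))
    stop("protein alignment rows must carry unique taxon names", call. = FALSE)
  missing <- setdiff(taxa, names(cds))
  if (length(missing))
    stop("CDS missing for taxon/taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  widths <- nchar(protein_alignment)
  if (length(unique(widths)) != 1L)
    stop("protein alignment rows differ in width", call. = FALSE)

  rows <- vapply(taxa, function(tx) {
    prot <- strsplit(protein_alignment[[tx]], "")[[1]]
    codons <- .splitCodons(cds[[tx]])
    stops <- which(codons %in% .STOP_CODONS)
    if (length(stops)) {
      if (length(stops) > 1L || stops[1] != length(codons))
        stop("internal stop codon in CDS of taxon '", tx, "' at codon ",
             stops[1], call. = FALSE)
      codons <- codons[-length(codons)]  # strip terminal stop
    }
    residues <- prot[prot != "-"]
    if (length(residues) != length(codons))
      stop("taxon '", tx, "': ungapped protein has ", length(residues),
           " residues but CDS encodes ", length(codons), " codons",
           call. = FALSE)
    aa <- unname(.GC[codons])
    mismatch <- which(aa != residues & residues != "X")
    if (length(mismatch))
      stop("taxon '", tx, "': translation mismatch at residue ",
           mismatch[1], " (codon ", codons[mismatch[1]], " encodes ",
           aa[mismatch[1]], ", alignment has ", residues[mismatch[1]], ")",
           call. = FALSE)
    out <- rep("---", length(prot))
    out[prot != "-"] <- codons
    paste(out, collapse = "")
  }, character(1))

  codonAlignment(stats::setNames(rows, taxa))
}

#' Remove gap codons from one alignment row
#'
#' Inverse check for back-translation: stripping `---` codons from a row of
#' the codon alignment reconstructs the original CDS (minus any terminal
#' stop).
#'
#' @param alignment A [CodonAlignment-class].
#' @param taxon Taxon name.
#' @return Ungapped coding sequence as a character scalar.
#' @export
ungappedCds <- function(alignment, taxon) {
  stopifnot(is(alignment, "CodonAlignment"))
  codons <- .splitCodons(alignment@seqs[[taxon]])
  paste(codons[codons != "---"], collapse = "")
}
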