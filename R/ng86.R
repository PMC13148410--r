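# Nei-Gojobori (1986) counting estimator of dN/dS with Jukes-Cantor
# correction. Sites: per codon, the fraction of single-base changes at each
# position that are synonymous (changes to stops count as nonsynonymous, so
# S + N = 3 per codon), averaged between the two sequences. Differences:
# equal-weight average over all minimal mutational pathways between differing
# codons, excluding pathways through stop codons.

.codonPair <- function(row_a, row_b) {
  ca <- .splitCodons(row_a)
  cb <- .splitCodons(row_b)
  if (length(ca) != length(cb))
    stop("sequences differ in codon length (", length(ca), " vs ",
         length(cb), ")", call. = FALSE)
  plain_a <- ca %in% names(.GC)
  plain_b <- cb %in% names(.GC)
  if (any(ca[plain_a] %in% .STOP_CODONS))
    stop("stop codon in first sequence", call. = FALSE)
  if (any(cb[plain_b] %in% .STOP_CODONS))
    stop("stop codon in second sequence", call. = FALSE)
  # pairwise deletion: drop columns where either member has a gap or
  # any ambiguous base
  use <- ca %in% .SENSE_CODONS & cb %in% .SENSE_CODONS
  list(a = ca[use], b = cb[use], n_used = sum(use))
}

.jcCorrect <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 pairwise dN/dS
#'
#' Counting estimator on two equal-length, in-frame coding sequences.
#' Columns in which either sequence has a gap codon or an ambiguous base are
#' excluded from all counts (pairwise deletion). `omega` is reported as
#' undefined (`status = "dS_zero"`) rather than infinite when there are no
#' synonymous differences, and `status = "saturated"` when a difference
#' proportion reaches the Jukes-Cantor ceiling of 3/4.
#'
#' @param row_a,row_b Nucleotide sequences (character scalars or
#'   [Biostrings::DNAString]) of equal length, in frame.
#' @return An [OmegaEstimate-class] with `method = "NG86"`.
#' @examples
#' ng86Pairwise("TTTAAAGGG", "TTCAAAGGG")  # one synonymous change
#' @export
ng86Pairwise <- function(row_a, row_b) {
  pair <- .codonPair(as.character(row_a), as.character(row_b))
  a <- pair$a
  b <- pair$b
  n <- pair$n_used
  if (n == 0L)
    stop("no comparable codon columns after pairwise deletion", call. = FALSE)
  S <- (sum(.SYN_SITES[a]) + sum(.SYN_SITES[b])) / 2
  N <- 3 * n - S
  ia <- .codonIndex[a]
  ib <- .codonIndex[b]
  Sd <- sum(.SD_TAB[cbind(ia, ib)])
  Nd <- sum(.ND_TAB[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- .jcCorrect(pS)
  dN <- .jcCorrect(pN)
  status <- "ok"
  om <- NA_real_
  if (Sd == 0) {
    status <- "dS_zero"
  } else if (pS >= 0.75 || pN >= 0.75) {
    status <- "saturated"
  } else {
    om <- dN / dS
  }
  new("OmegaEstimate", method = "NG86", n_codons = n,
      S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
      dS = dS, dN = dN, omega = om, status = status)
}
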