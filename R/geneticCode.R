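# Standard nuclear genetic code machinery shared by the NG86 counter, the
# GY94/M0 likelihood, and the codon-evolution simulator. Stop codons are never
# valid inside coding rows; all 61 sense codons are indexed in the fixed order
# of Biostrings::GENETIC_CODE.

.GC <- Biostrings::GENETIC_CODE
.STOP_CODONS <- names(.GC)[.GC == "*"]
.SENSE_CODONS <- names(.GC)[.GC != "*"]
.N_SENSE <- length(.SENSE_CODONS)
.NUC <- c("A", "C", "G", "T")

.codonIndex <- stats::setNames(seq_len(.N_SENSE), .SENSE_CODONS)

.isTransitionPair <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Per-codon synonymous site count: at each of the 3 positions the fraction of
# the 3 possible single-base changes that preserve the amino acid; changes to
# stop codons count as nonsynonymous so that S + N = 3 per codon.
.synSitesOne <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(.NUC, bases[pos])) {
      mut <- bases
      mut[pos] <- alt
      mutc <- paste(mut, collapse = "")
      if (.GC[[mutc]] != "*" && .GC[[mutc]] == .GC[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

.SYN_SITES <- vapply(.SENSE_CODONS, .synSitesOne, numeric(1))

.PERMS <- list(
  matrix(1L, 1, 1),
  rbind(1:2, 2:1),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Average synonymous / nonsynonymous difference counts between two sense
# codons, enumerating all minimal mutational pathways with equal weights and
# excluding pathways that pass through a stop codon (if every pathway is
# blocked, all pathways are used, so counts are always defined).
.pathwayCountsOne <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  d <- length(pos)
  if (d == 0L) return(c(Sd = 0, Nd = 0))
  perms <- .PERMS[[d]]
  res <- matrix(NA_real_, nrow(perms), 2)
  blocked <- logical(nrow(perms))
  for (p in seq_len(nrow(perms))) {
    cur <- b1
    sd <- nd <- 0
    for (step in perms[p, ]) {
      nxt <- cur
      nxt[pos[step]] <- b2[pos[step]]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (.GC[[to]] == "*") blocked[p] <- TRUE
      if (.GC[[from]] == .GC[[to]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[p, ] <- c(sd, nd)
  }
  keep <- !blocked
  if (!any(keep)) keep <- rep(TRUE, nrow(perms))
  c(Sd = mean(res[keep, 1]), Nd = mean(res[keep, 2]))
}

.pairwiseCountTables <- local({
  Sd <- Nd <- matrix(0, .N_SENSE, .N_SENSE,
                     dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  for (i in seq_len(.N_SENSE)) {
    for (j in seq_len(.N_SENSE)) {
      if (i < j) {
        cnt <- .pathwayCountsOne(.SENSE_CODONS[i], .SENSE_CODONS[j])
        Sd[i, j] <- Sd[j, i] <- cnt[["Sd"]]
        Nd[i, j] <- Nd[j, i] <- cnt[["Nd"]]
      }
    }
  }
  list(Sd = Sd, Nd = Nd)
})

.SD_TAB <- .pairwiseCountTables$Sd
.ND_TAB <- .pairwiseCountTables$Nd

# Single-nucleotide neighbour structure among sense codons, used to build the
# GY94 generator: which pairs differ at exactly one position, whether that
# change is a transition, and whether it is synonymous.
.neighbourStructure <- local({
  one <- ts <- syn <- matrix(FALSE, .N_SENSE, .N_SENSE,
                             dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  split_mat <- do.call(rbind, strsplit(.SENSE_CODONS, ""))
  for (i in seq_len(.N_SENSE)) {
    for (j in seq_len(.N_SENSE)) {
      if (i == j) next
      diffpos <- which(split_mat[i, ] != split_mat[j, ])
      if (length(diffpos) == 1L) {
        one[i, j] <- TRUE
        ts[i, j] <- .isTransitionPair(split_mat[i, diffpos], split_mat[j, diffpos])
        syn[i, j] <- .GC[[.SENSE_CODONS[i]]] == .GC[[.SENSE_CODONS[j]]]
      }
    }
  }
  list(one = one, ts = ts, syn = syn)
})

.ONE_STEP <- .neighbourStructure$one
.IS_TS <- .neighbourStructure$ts
.IS_SYN <- .neighbourStructure$syn

.splitCodons <- function(x) {
  x <- toupper(as.character(x))
  n <- nchar(x)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Uniform codon frequencies over the 61 sense codons
#'
#' Convenience stationary distribution for simulations and as a neutral
#' default for the one-ratio codon model.
#'
#' @return Named numeric vector of length 61 summing to one.
#' @export
uniformCodonFrequencies <- function() {
  stats::setNames(rep(1 / .N_SENSE, .N_SENSE), .SENSE_CODONS)
}

#' Sense codons of the standard nuclear genetic code
#'
#' @return Character vector of the 61 stop-free codons in the fixed order used
#'   by all codon-indexed structures in the package.
#' @export
senseCodons <- function() .SENSE_CODONS
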