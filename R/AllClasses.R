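#' @import methods
#' @importClassesFrom Biostrings DNAStringSet AAStringSet XStringSet
#' @importFrom S4Vectors isSingleNumber
NULL

.CONDITIONS <- c("testis", "male_carcass", "ovary", "female_carcass")

#' Tissue conditions required of every expression matrix
#'
#' The pipeline works on RPKM matrices over exactly four adult tissue
#' conditions: the male reproductive tract (`testis`), the male carcass
#' without the reproductive tract, the whole ovary, and the female carcass
#' without the ovary.
#'
#' @return Character vector of the four fixed condition identifiers.
#' @export
snbpConditions <- function() .CONDITIONS

setClass("PipelineConfig",
  representation(
    min_target_rpkm = "numeric",
    max_other_rpkm = "numeric",
    min_pi = "numeric",
    pka_table_name = "character",
    window_min = "integer",
    window_max = "integer",
    min_basic_fraction = "numeric",
    go_exclude_terms = "character",
    go_include_terms = "character",
    prot_min_length = "integer",
    prot_max_length = "integer",
    prot_min_arg_fraction = "numeric",
    arcsine_transform = "logical",
    random_seed = "integer"
  ),
  prototype(
    min_target_rpkm = 100,
    max_other_rpkm = 5,
    min_pi = 8.0,
    pka_table_name = "IPC_protein",
    window_min = 30L,
    window_max = 50L,
    min_basic_fraction = 0.35,
    go_exclude_terms = c("electron transport chain", "mitochondri",
                         "microtubule", "kinase"),
    go_include_terms = c("DNA", "histone", "chromatin", "nucleosome",
                         "uncharacterized"),
    prot_min_length = 50L,
    prot_max_length = 110L,
    prot_min_arg_fraction = 0.30,
    arcsine_transform = FALSE,
    random_seed = 1L
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character(0)
  if (!(object@min_target_rpkm > object@max_other_rpkm))
    msg <- c(msg, "min_target_rpkm must exceed max_other_rpkm")
  if (object@max_other_rpkm < 0)
    msg <- c(msg, "max_other_rpkm must be >= 0")
  if (object@window_min > object@window_max)
    msg <- c(msg, "window_min must be <= window_max")
  if (object@min_basic_fraction < 0 || object@min_basic_fraction > 1)
    msg <- c(msg, "min_basic_fraction must be in [0, 1]")
  if (object@prot_min_arg_fraction < 0 || object@prot_min_arg_fraction > 1)
    msg <- c(msg, "prot_min_arg_fraction must be in [0, 1]")
  if (object@prot_min_length > object@prot_max_length)
    msg <- c(msg, "prot_min_length must be <= prot_max_length")
  if (object@min_pi <= 0 || object@min_pi >= 14)
    msg <- c(msg, "min_pi must be in (0, 14)")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the SNBP discovery pipeline. The
#' defaults encode the published operating points: testis RPKM at least 100
#' with no more than 5 RPKM in any other condition, an isoelectric point of
#' at least 8.0, a 30-50 residue arginine/lysine-rich window, and a 50-110
#' residue length range for protamines. The basic-window fraction (0.35) and
#' the protamine arginine fraction (0.30) are package operating points and
#' are deliberately exposed here.
#'
#' @param ... Named slot overrides, e.g. `min_pi = 7.5`.
#' @return A validated `PipelineConfig` object.
#' @examples
#' cfg <- pipelineConfig(min_basic_fraction = 0.4)
#' cfg
#' @aliases PipelineConfig PipelineConfig-class
#' @export
#' @exportClass PipelineConfig
pipelineConfig <- function(...) {
  args <- list(...)
  ints <- c("window_min", "window_max", "prot_min_length", "prot_max_length",
            "random_seed")
  for (nm in intersect(names(args), ints)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("PipelineConfig"), args))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  expression : testis >= %g RPKM, others <= %g RPKM\n",
              object@min_target_rpkm, object@max_other_rpkm))
  cat(sprintf("  basicity   : pI >= %g (pKa table '%s')\n",
              object@min_pi, object@pka_table_name))
  cat(sprintf("  windows    : %d-%d aa, R+K fraction >= %g\n",
              object@window_min, object@window_max, object@min_basic_fraction))
  cat(sprintf("  protamine  : %d-%d aa, R fraction >= %g\n",
              object@prot_min_length, object@prot_max_length,
              object@prot_min_arg_fraction))
  cat(sprintf("  GO exclude : %s\n",
              paste(object@go_exclude_terms, collapse = ", ")))
  cat(sprintf("  GO include : %s\n",
              paste(object@go_include_terms, collapse = ", ")))
})

#' In-frame codon alignment
#'
#' Thin S4 wrapper around an aligned [Biostrings::DNAStringSet]: all rows have
#' equal width divisible by three, every codon is either the gap codon `---`
#' or three unambiguous bases, and no row contains a stop codon. Build one
#' directly from aligned coding sequences with [codonAlignment()] or from a
#' protein alignment plus unaligned CDS with [backTranslateAlignment()].
#'
#' @aliases CodonAlignment CodonAlignment-class
#' @exportClass CodonAlignment
setClass("CodonAlignment", representation(seqs = "DNAStringSet"))

setValidity("CodonAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(w) == 0L) return("alignment must contain at least one row")
  if (length(unique(w)) != 1L) return("all rows must have equal width")
  if (w[1] %% 3L != 0L) return("alignment width must be a multiple of 3")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    return("rows must carry unique taxon names")
  for (i in seq_along(object@seqs)) {
    cod <- .splitCodons(object@seqs[[i]])
    bad <- !(cod %in% .SENSE_CODONS | cod == "---")
    if (any(bad)) {
      offender <- cod[bad][1]
      if (offender %in% .STOP_CODONS)
        return(sprintf("row '%s' contains stop codon %s",
                       names(object@seqs)[i], offender))
      return(sprintf("row '%s' contains invalid codon '%s' (partial gap or ambiguity)",
                     names(object@seqs)[i], offender))
    }
  }
  TRUE
})

#' Construct a codon alignment
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of aligned,
#'   in-frame coding sequences (gap codon `---`).
#' @return A [CodonAlignment-class] object.
#' @examples
#' codonAlignment(c(a = "ATGAAA---", b = "ATGAAGCGT"))
#' @export
codonAlignment <- function(seqs) {
  if (!is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  new("CodonAlignment", seqs = seqs)
}

#' @describeIn CodonAlignment-class number of codon columns
#' @param x,object A `CodonAlignment`.
#' @export
nCodons <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  Biostrings::width(x@seqs)[1] %/% 3L
}

#' @describeIn CodonAlignment-class taxon names
#' @export
taxa <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  names(x@seqs)
}

#' @describeIn CodonAlignment-class underlying aligned DNAStringSet
#' @export
alignedSeqs <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  x@seqs
}

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d taxa x %d codon columns\n",
              length(object@seqs), nCodons(object)))
  shown <- utils::head(names(object@seqs), 5)
  for (nm in shown) {
    s <- as.character(object@seqs[[nm]])
    cat(sprintf("  %-15s %s%s\n", nm, substr(s, 1, 45),
                if (nchar(s) > 45) "..." else ""))
  }
  if (length(object@seqs) > 5) cat(sprintf("  ... %d more rows\n",
                                           length(object@seqs) - 5))
})

#' Omega (dN/dS) estimate
#'
#' Result container shared by the NG86 counting estimator and the pairwise
#' one-ratio (M0) maximum-likelihood estimator. Counting slots (`S_sites`,
#' `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`) are `NA` for the ML method;
#' ML slots (`kappa`, `t`, `logLik`, `codon_freqs`) are `NA`/empty for NG86.
#' `status` is one of `ok`, `dS_zero` (no synonymous differences; omega
#' undefined rather than infinite), `saturated` (a difference proportion at or
#' beyond the Jukes-Cantor ceiling of 3/4), or `boundary` (an ML estimate at a
#' box bound).
#'
#' @aliases OmegaEstimate OmegaEstimate-class
#' @exportClass OmegaEstimate
setClass("OmegaEstimate",
  representation(
    method = "character",
    n_codons = "numeric",
    S_sites = "numeric", N_sites = "numeric",
    Sd = "numeric", Nd = "numeric",
    pS = "numeric", pN = "numeric",
    dS = "numeric", dN = "numeric",
    omega = "numeric",
    kappa = "numeric", t = "numeric", logLik = "numeric",
    codon_freqs = "numeric",
    status = "character"
  ),
  prototype(method = "NG86", n_codons = 0,
            S_sites = NA_real_, N_sites = NA_real_, Sd = NA_real_,
            Nd = NA_real_, pS = NA_real_, pN = NA_real_, dS = NA_real_,
            dN = NA_real_, omega = NA_real_, kappa = NA_real_, t = NA_real_,
            logLik = NA_real_, codon_freqs = numeric(0), status = "ok")
)

setValidity("OmegaEstimate", function(object) {
  if (!object@method %in% c("NG86", "M0_ML"))
    return("method must be 'NG86' or 'M0_ML'")
  if (!object@status %in% c("ok", "dS_zero", "saturated", "boundary"))
    return("unknown status")
  if (identical(object@status, "ok") &&
      (is.na(object@omega) || object@omega < 0))
    return("omega must be >= 0 when status is 'ok'")
  if (length(object@codon_freqs) &&
      abs(sum(object@codon_freqs) - 1) > 1e-6)
    return("codon_freqs must sum to 1")
  TRUE
})

#' @describeIn OmegaEstimate-class extract the omega point estimate
#' @param x,object An `OmegaEstimate`.
#' @export
omega <- function(x) {
  stopifnot(is(x, "OmegaEstimate"))
  x@omega
}

#' @describeIn OmegaEstimate-class estimation status flag
#' @export
estimateStatus <- function(x) {
  stopifnot(is(x, "OmegaEstimate"))
  x@status
}

setMethod("show", "OmegaEstimate", function(object) {
  cat(sprintf("OmegaEstimate [%s] over %d codon columns (status: %s)\n",
              object@method, as.integer(object@n_codons), object@status))
  if (object@method == "NG86") {
    cat(sprintf("  S = %.2f, N = %.2f sites; Sd = %.2f, Nd = %.2f\n",
                object@S_sites, object@N_sites, object@Sd, object@Nd))
    cat(sprintf("  dS = %.4f, dN = %.4f, omega = %.4f\n",
                object@dS, object@dN, object@omega))
  } else {
    cat(sprintf("  t = %.4f, kappa = %.3f, omega = %.4f, logLik = %.3f\n",
                object@t, object@kappa, object@omega, object@logLik))
  }
})
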