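# GO-term triage and SNBP-class decision rules, and the orchestration that
# strings all filters into the candidate table.

.SNBP_CLASSES <- c("Prot", "PL", "TS_histone", "HMG_box", "non_SNBP")

.matchesAnyTerm <- function(terms, patterns) {
  if (length(terms) == 0L) return(FALSE)
  lt <- tolower(terms)
  for (p in tolower(patterns)) {
    if (any(grepl(p, lt, fixed = TRUE))) return(TRUE)
  }
  FALSE
}

#' GO-term triage
#'
#' A gene is removed when any of its GO term strings contains any exclude
#' term (case-insensitive substring match); of the remainder, a gene is kept
#' when any term contains an include term, or when it has no GO annotation
#' at all (annotation-free genes count as "uncharacterized", an include
#' category). Exclusion is evaluated before inclusion.
#'
#' @param genes Character vector of gene identifiers to triage.
#' @param go GO annotation `data.frame` with columns `gene`, `category`,
#'   `term` (see [readGoTable()]).
#' @param exclude_terms,include_terms Character vectors of informal term
#'   fragments; matching is case-insensitive substring on the term strings.
#' @return Character vector of surviving gene identifiers (a subset of
#'   `genes`, original order preserved).
#' @export
filterByGO <- function(genes, go,
                       exclude_terms = pipelineConfig()@go_exclude_terms,
                       include_terms = pipelineConfig()@go_include_terms) {
  if (length(exclude_terms) == 0L || length(include_terms) == 0L)
    stop("exclude and include term lists must be non-empty", call. = FALSE)
  terms_by_gene <- split(go$term, go$gene)
  keep <- vapply(genes, function(g) {
    terms <- terms_by_gene[[g]]
    if (is.null(terms)) return(TRUE)  # uncharacterized
    if (.matchesAnyTerm(terms, exclude_terms)) return(FALSE)
    .matchesAnyTerm(terms, include_terms)
  }, logical(1))
  genes[keep]
}

.checkDomains <- function(domains, len, gene) {
  if (nrow(domains) == 0L) return(invisible(NULL))
  if (any(domains$start < 1 | domains$end > len | domains$end < domains$start))
    stop("domain interval outside protein length for gene '", gene, "'",
         call. = FALSE)
  invisible(NULL)
}

#' Assign an SNBP class from sequence features and domain calls
#'
#' Decision rules, first match wins:
#' 1. **Prot** (protamine): length within the protamine range and arginine
#'    fraction at or above `prot_min_arg_fraction`.
#' 2. **PL** (protamine-like): a winged-helix (`WH`) domain lying entirely in
#'    the N-terminal half (domain end at or before `ceiling(length / 2)`)
#'    and at least one Arg/Lys-rich window starting in the C-terminal half.
#' 3. **HMG_box**: an `HMG_box` domain present.
#' 4. **TS_histone**: a `histone_fold` domain present and pI at or above
#'    `min_pi`.
#' 5. Otherwise **non_SNBP**.
#'
#' Domain calls are inputs produced by upstream annotators, not computed
#' here.
#'
#' @param length Protein length (residues).
#' @param arg_fraction Arginine fraction of the protein.
#' @param pI Predicted isoelectric point.
#' @param basic_windows [IRanges::IRanges] of merged Arg/Lys-rich windows
#'   (1-based, closed), as from [detectBasicWindows()].
#' @param domains `data.frame` of domain calls for this gene with columns
#'   `type`, `start`, `end` (may have zero rows).
#' @param config A [pipelineConfig()].
#' @param gene Gene identifier used in error messages.
#' @return One of `"Prot"`, `"PL"`, `"HMG_box"`, `"TS_histone"`,
#'   `"non_SNBP"`.
#' @export
classifySNBP <- function(length, arg_fraction, pI, basic_windows, domains,
                         config = pipelineConfig(), gene = "?") {
  .checkDomains(domains, length, gene)
  half <- ceiling(length / 2)
  if (length >= config@prot_min_length && length <= config@prot_max_length &&
      arg_fraction >= config@prot_min_arg_fraction)
    return("Prot")
  wh <- domains[domains$type == "WH", , drop = FALSE]
  wh_nterm <- nrow(wh) > 0L && any(wh$end <= half)
  win_cterm <- length(basic_windows) > 0L &&
    any(IRanges::start(basic_windows) > half)
  if (wh_nterm && win_cterm) return("PL")
  if (any(domains$type == "HMG_box")) return("HMG_box")
  if (any(domains$type == "histone_fold") && pI >= config@min_pi)
    return("TS_histone")
  "non_SNBP"
}

#' Run the full candidate pipeline and build the report
#'
#' Applies, in order, the tissue-exclusivity filter, the isoelectric-point
#' filter, and the GO triage, then classifies every survivor into an SNBP
#' class and ranks survivors by target-tissue RPKM. Per-stage gene counts
#' (the filtering funnel) are reported on standard error.
#'
#' @param matrix RPKM matrix (see [readExpressionTable()]).
#' @param proteins Named [Biostrings::AAStringSet] covering the matrix genes.
#' @param go GO annotation `data.frame` ([readGoTable()]).
#' @param domains Domain annotation `data.frame` ([readDomainTable()]).
#' @param config A [pipelineConfig()].
#' @param target Target condition identifier.
#' @return `data.frame` with one row per gene: `gene`, `rpkm_testis`, `pI`,
#'   `go_summary`, pass flags `passed_expression` / `passed_pi` /
#'   `passed_go`, `snbp_class` (`NA` unless all three flags are true) and
#'   `rank` (`NA` for non-survivors). The per-stage funnel is attached as
#'   `attr(, "funnel")`. Rows are ordered survivors first (by rank), then
#'   the remaining genes by descending RPKM.
#' @export
buildCandidateTable <- function(matrix, proteins, go, domains,
                                config = pipelineConfig(),
                                target = "testis") {
  .checkExpressionMatrix(matrix)
  genes <- rownames(matrix)
  missing <- setdiff(genes, names(proteins))
  if (length(missing))
    stop("protein sequence missing for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)

  pass_expr <- filterTissueExclusive(matrix, target,
                                     config@min_target_rpkm,
                                     config@max_other_rpkm)
  expr_genes <- names(which(pass_expr))
  message(sprintf("[funnel] expression filter: %d -> %d genes",
                  length(genes), length(expr_genes)))

  # Features are only needed for genes that survived stage 1.
  feats <- if (length(expr_genes))
    featureTable(proteins[expr_genes], config) else
    featureTable(proteins[0], config)
  pi_genes <- filterByPI(feats, config@min_pi)
  message(sprintf("[funnel] pI filter: %d -> %d genes",
                  length(expr_genes), length(pi_genes)))

  go_genes <- filterByGO(pi_genes, go, config@go_exclude_terms,
                         config@go_include_terms)
  message(sprintf("[funnel] GO triage: %d -> %d genes",
                  length(pi_genes), length(go_genes)))

  classes <- vapply(go_genes, function(g) {
    row <- feats[feats$gene == g, , drop = FALSE]
    dom <- domains[domains$gene == g, , drop = FALSE]
    classifySNBP(row$length, row$frac_R, row$pI,
                 decodeWindows(row$basic_windows), dom, config, gene = g)
  }, character(1))

  ranked <- rankByExpression(matrix, go_genes, target)
  terms_by_gene <- split(go$term, go$gene)
  summarize_go <- function(g) {
    t <- terms_by_gene[[g]]
    if (is.null(t)) "uncharacterized" else paste(unique(t), collapse = "; ")
  }

  report <- data.frame(
    gene = genes,
    rpkm_testis = matrix[genes, target],
    pI = NA_real_,
    go_summary = vapply(genes, summarize_go, character(1)),
    passed_expression = unname(pass_expr[genes]),
    passed_pi = genes %in% pi_genes,
    passed_go = genes %in% pi_genes & genes %in% go_genes,
    snbp_class = NA_character_,
    rank = NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  report$pI[match(feats$gene, report$gene)] <- feats$pI
  report$snbp_class[match(go_genes, report$gene)] <- unname(classes[go_genes])
  report$rank[match(ranked, report$gene)] <- seq_along(ranked)

  ord <- order(is.na(report$rank), report$rank, -report$rpkm_testis,
               report$gene)
  report <- report[ord, , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "funnel") <- c(input = length(genes),
                              expression = length(expr_genes),
                              pI = length(pi_genes),
                              GO = length(go_genes))
  report
}
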