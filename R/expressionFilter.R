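# Stage 1 of the pipeline: genes expressed exclusively in the target tissue.
# Both thresholds are inclusive: a gene is testis-exclusive when its testis
# RPKM is at least min_target AND no other condition exceeds max_other.

.checkExpressionMatrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(matrix)))
    stop("expression matrix must have gene identifiers as rownames",
         call. = FALSE)
  missing <- setdiff(.CONDITIONS, colnames(matrix))
  if (length(missing))
    stop("expression matrix lacks condition column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyNA(matrix))
    stop("expression matrix contains missing values; complete rows are required",
         call. = FALSE)
  if (any(matrix < 0))
    stop("expression matrix contains negative RPKM values", call. = FALSE)
  invisible(matrix)
}

#' Identify tissue-exclusive genes
#'
#' A gene passes when its RPKM in the target condition is at least
#' `min_target` and its RPKM in every other condition is at most
#' `max_other`; both comparisons are inclusive. With the defaults this is
#' the testis-exclusivity rule: at least 100 RPKM in the male reproductive
#' tract and no more than 5 RPKM elsewhere.
#'
#' @param matrix Numeric gene x condition RPKM matrix with gene rownames and
#'   the four condition columns of [snbpConditions()].
#' @param target Target condition identifier.
#' @param min_target Minimum RPKM in the target condition (inclusive).
#' @param max_other Maximum RPKM tolerated in every other condition
#'   (inclusive).
#' @return Named logical vector (one element per gene) of pass flags.
#'   `names(which(...))` gives the surviving gene set.
#' @examples
#' m <- matrix(c(150, 4, 0, 2, 99, 0, 0, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), snbpConditions()))
#' filterTissueExclusive(m)
#' @export
filterTissueExclusive <- function(matrix, target = "testis",
                                  min_target = 100, max_other = 5) {
  .checkExpressionMatrix(matrix)
  if (!target %in% colnames(matrix))
    stop("unknown target condition '", target, "'", call. = FALSE)
  if (!(min_target > max_other))
    stop("min_target must exceed max_other", call. = FALSE)
  others <- setdiff(colnames(matrix), target)
  pass <- matrix[, target] >= min_target &
    apply(matrix[, others, drop = FALSE] <= max_other, 1L, all)
  stats::setNames(as.logical(pass), rownames(matrix))
}

#' Rank genes by target-tissue expression
#'
#' Descending by target RPKM; ties broken lexicographically by gene
#' identifier, so the order is total and stable.
#'
#' @inheritParams filterTissueExclusive
#' @param genes Character vector of gene identifiers (a subset of the matrix
#'   rows).
#' @return Character vector: `genes` reordered.
#' @export
rankByExpression <- function(matrix, genes, target = "testis") {
  .checkExpressionMatrix(matrix)
  if (!target %in% colnames(matrix))
    stop("unknown target condition '", target, "'", call. = FALSE)
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(genes) == 0L) return(character(0))
  vals <- matrix[genes, target]
  genes[order(-vals, genes)]
}
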