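# Readers and writers for the plain-text formats the pipeline consumes and
# emits: FASTA (via Biostrings), tab-separated expression / GO / domain /
# brood tables, flat key=value configuration files, and the candidate report.

.readFasta <- function(path, reader, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- reader(path)
  if (length(set) == 0L)
    stop("no records in ", what, " FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(Biostrings::width(set) == 0L)) {
    empty <- ids[Biostrings::width(set) == 0L][1]
    stop("empty sequence for record '", empty, "' in ", path, call. = FALSE)
  }
  names(set) <- ids
  set
}

#' Read a protein FASTA file
#'
#' Records are returned in file order with residues upper-cased; duplicate
#' identifiers (the first whitespace-delimited token of each header) and
#' empty sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::AAStringSet].
#' @export
readProteinFasta <- function(path) {
  set <- .readFasta(path, Biostrings::readAAStringSet, "protein")
  Biostrings::AAStringSet(toupper(as.character(set)))
}

#' Read a coding-sequence (or aligned protein) FASTA file
#'
#' @rdname readProteinFasta
#' @export
readCdsFasta <- function(path) {
  set <- .readFasta(path, Biostrings::readDNAStringSet, "CDS")
  Biostrings::DNAStringSet(toupper(as.character(set)))
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param seqs A named [Biostrings::XStringSet].
#' @param path Output path.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a gene x condition RPKM table
#'
#' Tab-separated with a header row; the first column holds gene identifiers
#' and the remaining columns are RPKM values for the four tissue conditions.
#' Column headers may be remapped to the fixed condition identifiers of
#' [snbpConditions()] via `condition_map`.
#'
#' @param path Path to the TSV file.
#' @param condition_map Optional named character vector mapping file column
#'   headers to condition identifiers, e.g.
#'   `c(MRT = "testis", MC = "male_carcass")`.
#' @return Numeric matrix (genes x 4 conditions) with gene rownames.
#' @export
readExpressionTable <- function(path, condition_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5L)
    stop("expression table must have a gene column plus 4 condition columns",
         call. = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id(s) in expression table: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  tab <- tab[, -1, drop = FALSE]
  if (!is.null(condition_map)) {
    hit <- names(condition_map)[names(condition_map) %in% colnames(tab)]
    colnames(tab)[match(hit, colnames(tab))] <- condition_map[hit]
  }
  missing <- setdiff(.CONDITIONS, colnames(tab))
  if (length(missing))
    stop("expression table lacks condition column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- tab[, .CONDITIONS, drop = FALSE]
  for (cn in .CONDITIONS) {
    vals <- suppressWarnings(as.numeric(tab[[cn]]))
    bad <- which(is.na(vals) & !is.na(tab[[cn]]))
    if (anyNA(tab[[cn]]) || length(bad)) {
      row <- if (length(bad)) bad[1] else which(is.na(tab[[cn]]))[1]
      stop("non-numeric or missing value in expression table at row ", row,
           ", column '", cn, "'", call. = FALSE)
    }
    neg <- which(vals < 0)
    if (length(neg))
      stop("negative RPKM in expression table at row ", neg[1],
           ", column '", cn, "'", call. = FALSE)
    tab[[cn]] <- vals
  }
  m <- as.matrix(tab)
  rownames(m) <- genes
  m
}

#' Write an RPKM matrix as TSV
#'
#' @param matrix Gene x condition matrix as from [readExpressionTable()].
#' @param path Output path.
#' @export
writeExpressionTable <- function(matrix, path) {
  .checkExpressionMatrix(matrix)
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GO and domain annotation tables
#'
#' The GO table is tab-separated with columns `gene`, `category` (one of
#' `C`, `F`, `P`) and `term`; the domain table has columns `gene`, `type`
#' (`WH`, `HMG_box`, `histone_fold`, or `other`) and 1-based inclusive
#' `start`, `end` residue coordinates. Both come from upstream annotators
#' and are consumed as plain tables.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with validated columns.
#' @export
readGoTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read everything as character: category codes "F"/"T" must not become logicals
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene", "category", "term")
  if (!all(need %in% colnames(tab)))
    stop("GO table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$category), c("C", "F", "P"))
  if (length(bad))
    stop("invalid GO category code(s): ", paste(bad, collapse = ", "),
         " (expected C, F or P)", call. = FALSE)
  tab[, need]
}

#' @rdname readGoTable
#' @export
readDomainTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "type", "start", "end")
  if (!all(need %in% colnames(tab)))
    stop("domain table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$type), c("WH", "HMG_box", "histone_fold", "other"))
  if (length(bad))
    stop("invalid domain type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  swapped <- which(tab$end < tab$start | tab$start < 1)
  if (length(swapped))
    stop("invalid domain interval at row ", swapped[1],
         " (need 1 <= start <= end)", call. = FALSE)
  tab[, need]
}

#' Read a brood table
#'
#' Tab-separated with columns `group` (treatment group), `brood` (brood
#' identifier) and non-negative integer counts `females` and `males`, at
#' least one progeny per brood.
#'
#' @param path Path to the TSV file.
#' @return Validated `data.frame`.
#' @export
readBroodTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "brood", "females", "males")
  if (!all(need %in% colnames(tab)))
    stop("brood table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (cn in c("females", "males")) {
    v <- tab[[cn]]
    if (!is.numeric(v) || any(v < 0) || any(v != round(v)))
      stop("column '", cn, "' must hold non-negative integer counts",
           call. = FALSE)
  }
  if (any(tab$females + tab$males < 1))
    stop("every brood needs at least one scored individual", call. = FALSE)
  tab[, need]
}

#' Read a flat key=value configuration file
#'
#' One `key = value` (or `key<TAB>value`) pair per line; `#` starts a
#' comment. List-valued keys (`go_exclude_terms`, `go_include_terms`) are
#' comma-separated. Keys not set in the file keep their
#' [pipelineConfig()] defaults.
#'
#' @param path Path to the configuration file.
#' @return A [PipelineConfig-class] object.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=\t]", perl = TRUE)[[1]]
    if (length(kv) < 2L)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (key %in% c("go_exclude_terms", "go_include_terms")) {
      args[[key]] <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (key %in% c("pka_table_name")) {
      args[[key]] <- val
    } else if (key %in% c("arcsine_transform")) {
      args[[key]] <- toupper(val) %in% c("TRUE", "T", "1", "YES")
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop("config key '", key, "' has non-numeric value '", val, "'",
             call. = FALSE)
      args[[key]] <- num
    }
  }
  unknown <- setdiff(names(args), slotNames("PipelineConfig"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipelineConfig, args)
}

#' Write the candidate report
#'
#' Tab-separated table of per-gene pipeline verdicts, sorted by descending
#' target-tissue RPKM with ties broken lexicographically by gene id.
#'
#' @param report `data.frame` from [buildCandidateTable()].
#' @param path Output path.
#' @export
writeCandidateReport <- function(report, path) {
  cols <- c("gene", "go_summary", "rpkm_testis", "pI", "snbp_class",
            "passed_expression", "passed_pi", "passed_go", "rank")
  missing <- setdiff(cols, colnames(report))
  if (length(missing))
    stop("report lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  report <- report[order(-report$rpkm_testis, report$gene), cols, drop = FALSE]
  report$pI <- round(report$pI, 1)  # display precision only
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published Nasonia vitripennis SNBP candidate table
#'
#' The 13-gene candidate table produced by running this pipeline's filtering
#' strategy on the published *N. vitripennis* tissue transcriptomes:
#' male-reproductive-tract RPKM, predicted isoelectric point and a GO
#' summary per gene, with the two protamine-like genes Nv-PL1 and Nv-PL2 at
#' the top. Shipped as a plain-text reference so downstream summaries (for
#' example the Nv-PL1 / Nv-PL2 expression fold ratio) can be recomputed
#' without any download.
#'
#' @return `data.frame` with columns `gene`, `label`, `go_summary`,
#'   `rpkm_testis`, `pI`, sorted by descending `rpkm_testis`.
#' @export
publishedCandidateTable <- function() {
  path <- system.file("extdata", "nasonia_snbp_candidates.tsv",
                      package = "SNBPscan", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab[order(-tab$rpkm_testis, tab$gene), , drop = FALSE]
}
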