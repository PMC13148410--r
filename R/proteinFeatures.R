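# Basicity and architecture features computed from primary sequence alone:
# charge-balance isoelectric point, amino-acid composition, arginine
# placement, and detection of arginine/lysine-rich windows of protamine-like
# peptide size.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_ALLOWED <- c(.AA20, "X")
.POSITIVE_AA <- c("K", "R", "H")
.NEGATIVE_AA <- c("D", "E", "C", "Y")

.aaChars <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (nchar(s) == 0L) stop("sequence must be non-empty", call. = FALSE)
  ch <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(ch), .AA_ALLOWED)
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         " (only the 20 standard amino acids plus X are accepted)",
         call. = FALSE)
  ch
}

.aaCounts <- function(sequence) {
  ch <- .aaChars(sequence)
  tab <- table(factor(ch, levels = .AA_ALLOWED))
  stats::setNames(as.integer(tab), .AA_ALLOWED)
}

#' Load a named pKa table
#'
#' Two published scales ship with the package, transcribed from their
#' sources: `IPC_protein` (the protein-optimized scale of the Isoelectric
#' Point Calculator; the default) and `EMBOSS` (the scale of the EMBOSS
#' `iep` tool). Tables live in a plain-text data file so further scales can
#' be added without touching code.
#'
#' @param name Scale identifier.
#' @param path Optional path to an alternative table file with columns
#'   `table`, `group`, `pKa`.
#' @return Named numeric vector with elements `NH2`, `COOH`, `C`, `D`, `E`,
#'   `H`, `K`, `R`, `Y`.
#' @examples
#' pkaTable()["R"]
#' @export
pkaTable <- function(name = "IPC_protein", path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pka_tables.tsv", package = "SNBPscan",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$table == name, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no pKa table named '", name, "' in ", path, call. = FALSE)
  pka <- stats::setNames(tab$pKa, tab$group)
  needed <- c("NH2", "COOH", "K", "R", "H", "D", "E", "C", "Y")
  missing <- setdiff(needed, names(pka))
  if (length(missing))
    stop("pKa table '", name, "' lacks groups: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(pka <= 0 | pka >= 14))
    stop("all pKa values must lie in (0, 14)", call. = FALSE)
  pka[needed]
}

#' Net protein charge at a given pH
#'
#' Standard Henderson-Hasselbalch charge balance over the protein termini and
#' the ionizable side chains (K, R, H positive; D, E, C, Y negative). `X`
#' residues contribute no ionizable group. The function is strictly
#' decreasing in pH, which guarantees a unique isoelectric point.
#'
#' @param sequence Protein sequence (character or [Biostrings::AAString]).
#' @param pH Numeric vector of pH values.
#' @param pka pKa table from [pkaTable()].
#' @return Numeric vector of net charges, one per pH value.
#' @examples
#' netCharge("KRDE", c(2, 7, 12))
#' @export
netCharge <- function(sequence, pH, pka = pkaTable()) {
  counts <- .aaCounts(sequence)
  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - pka[["NH2"]]))
    for (r in c("K", "R", "H"))
      pos <- pos + counts[[r]] / (1 + 10^(p - pka[[r]]))
    neg <- 1 / (1 + 10^(pka[["COOH"]] - p))
    for (r in c("D", "E", "C", "Y"))
      neg <- neg + counts[[r]] / (1 + 10^(pka[[r]] - p))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the unique root of [netCharge()] on pH 0-14 by bisection. The
#' result is reported at full precision; rounding to one decimal is a
#' display-time choice of the candidate report.
#'
#' @inheritParams netCharge
#' @param tolerance Bisection stops when the bracketing interval is narrower
#'   than this (pH units).
#' @return The isoelectric point (pH units).
#' @examples
#' isoelectricPoint("RKRKRK")   # strongly basic
#' isoelectricPoint("DDEE")     # acidic
#' @export
isoelectricPoint <- function(sequence, pka = pkaTable(), tolerance = 1e-4) {
  counts <- .aaCounts(sequence)  # validates alphabet up front
  lo <- 0
  hi <- 14
  qlo <- netCharge(sequence, lo, pka)
  qhi <- netCharge(sequence, hi, pka)
  if (qlo <= 0) return(lo)
  if (qhi >= 0) return(hi)
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (netCharge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Amino-acid composition profile
#'
#' Exact residue counts and per-residue fractions (denominator = full
#' sequence length, `X` included as its own category so fractions sum to
#' one). The basic fraction is arginine plus lysine; histidine is reported
#' separately because protamine-like peptides are defined by Arg/Lys
#' richness.
#'
#' @inheritParams netCharge
#' @return List with `length`, named `fractions` (20 amino acids plus `X`),
#'   `basic_fraction` (R + K), `histidine_fraction`, and `cysteine_count`.
#' @examples
#' compositionProfile("RKRK")$basic_fraction
#' @export
compositionProfile <- function(sequence) {
  counts <- .aaCounts(sequence)
  len <- sum(counts)
  fr <- counts / len
  list(
    length = len,
    fractions = fr,
    basic_fraction = unname(fr[["R"]] + fr[["K"]]),
    histidine_fraction = unname(fr[["H"]]),
    cysteine_count = unname(counts[["C"]])
  )
}

#' Arginine placement statistics
#'
#' @inheritParams netCharge
#' @return List with `positions` (1-based indices of R residues),
#'   `max_run` (longest run of consecutive arginines), `mean_gap` (mean
#'   distance between successive arginines; `NA` with `gap_defined = FALSE`
#'   when fewer than two arginines are present).
#' @examples
#' argininePlacement("RARRA")
#' @export
argininePlacement <- function(sequence) {
  ch <- .aaChars(sequence)
  pos <- which(ch == "R")
  if (length(pos) == 0L) {
    return(list(positions = integer(0), max_run = 0L,
                mean_gap = NA_real_, gap_defined = FALSE))
  }
  runs <- rle(ch == "R")
  max_run <- max(runs$lengths[runs$values])
  if (length(pos) < 2L) {
    mean_gap <- NA_real_
    defined <- FALSE
  } else {
    mean_gap <- mean(diff(pos))
    defined <- TRUE
  }
  list(positions = pos, max_run = as.integer(max_run),
       mean_gap = mean_gap, gap_defined = defined)
}

#' Detect arginine/lysine-rich windows
#'
#' Scans every window of every length between `window_min` and `window_max`
#' residues; a window qualifies when its combined arginine + lysine fraction
#' reaches `min_basic_fraction`. Overlapping or adjacent qualifying windows
#' are merged into maximal intervals. This is the detector for
#' protamine-like peptide candidates, which are 30-50 residue Arg/Lys-rich
#' stretches in the disordered half of a protamine-like protein.
#'
#' @inheritParams netCharge
#' @param window_min,window_max Window length bounds (residues).
#' @param min_basic_fraction Minimum R+K fraction for a window to qualify.
#' @return An [IRanges::IRanges] of merged intervals (1-based, closed),
#'   sorted by start. When the sequence is shorter than `window_min` an empty
#'   result is returned with a warning.
#' @examples
#' s <- paste0(strrep("A", 40), strrep("RK", 15), strrep("A", 30))
#' detectBasicWindows(s)
#' @export
detectBasicWindows <- function(sequence, window_min = 30L, window_max = 50L,
                               min_basic_fraction = 0.35) {
  ch <- .aaChars(sequence)
  n <- length(ch)
  window_min <- as.integer(window_min)
  window_max <- as.integer(window_max)
  if (window_min > window_max)
    stop("window_min must be <= window_max", call. = FALSE)
  if (n < window_min) {
    warning("sequence (", n, " aa) shorter than window_min (", window_min,
            "); no windows can be evaluated")
    return(IRanges::IRanges())
  }
  window_max <- min(window_max, n)
  cs <- c(0L, cumsum(ch %in% c("R", "K")))
  starts <- integer(0)
  ends <- integer(0)
  for (w in window_min:window_max) {
    st <- seq_len(n - w + 1L)
    basic <- cs[st + w] - cs[st]
    ok <- basic / w >= min_basic_fraction
    if (any(ok)) {
      starts <- c(starts, st[ok])
      ends <- c(ends, st[ok] + w - 1L)
    }
  }
  if (length(starts) == 0L) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
}

#' Feature table for a set of proteins
#'
#' Computes the full per-protein feature profile used downstream: length,
#' isoelectric point, composition, arginine placement, and merged basic
#' windows.
#'
#' @param proteins Named [Biostrings::AAStringSet] (or named character
#'   vector) of protein sequences.
#' @param config A [pipelineConfig()].
#' @param pka Optional pKa table; defaults to the table named in `config`.
#' @return `data.frame` with one row per protein: `gene`, `length`, `pI`,
#'   one `frac_<aa>` column per residue, `basic_fraction`,
#'   `histidine_fraction`, `cysteine_count`, `n_arg`, `arg_max_run`,
#'   `arg_mean_gap`, and `basic_windows` (intervals encoded
#'   `start-end;start-end`, 1-based closed; empty string when none).
#' @export
featureTable <- function(proteins, config = pipelineConfig(), pka = NULL) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must carry unique names", call. = FALSE)
  if (is.null(pka)) pka <- pkaTable(config@pka_table_name)
  if (length(proteins) == 0L) {
    empty <- data.frame(gene = character(0), length = integer(0),
                        pI = numeric(0), stringsAsFactors = FALSE)
    for (a in c(.AA_ALLOWED)) empty[[paste0("frac_", a)]] <- numeric(0)
    empty$basic_fraction <- numeric(0)
    empty$histidine_fraction <- numeric(0)
    empty$cysteine_count <- integer(0)
    empty$n_arg <- integer(0)
    empty$arg_max_run <- integer(0)
    empty$arg_mean_gap <- numeric(0)
    empty$basic_windows <- character(0)
    return(empty)
  }
  rows <- lapply(names(proteins), function(g) {
    s <- as.character(proteins[[g]])
    comp <- compositionProfile(s)
    arg <- argininePlacement(s)
    win <- suppressWarnings(
      detectBasicWindows(s, config@window_min, config@window_max,
                         config@min_basic_fraction))
    enc <- if (length(win) == 0L) "" else
      paste(sprintf("%d-%d", IRanges::start(win), IRanges::end(win)),
            collapse = ";")
    out <- data.frame(gene = g, length = comp$length,
                      pI = isoelectricPoint(s, pka),
                      stringsAsFactors = FALSE)
    fr <- as.list(comp$fractions)
    names(fr) <- paste0("frac_", names(comp$fractions))
    cbind(out, as.data.frame(fr),
          data.frame(basic_fraction = comp$basic_fraction,
                     histidine_fraction = comp$histidine_fraction,
                     cysteine_count = comp$cysteine_count,
                     n_arg = length(arg$positions),
                     arg_max_run = arg$max_run,
                     arg_mean_gap = arg$mean_gap,
                     basic_windows = enc,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Decode a basic-windows string back into an IRanges
#'
#' @param encoded String of the form `"start-end;start-end"` as written by
#'   [featureTable()]; empty string gives an empty range set.
#' @return An [IRanges::IRanges].
#' @export
decodeWindows <- function(encoded) {
  if (is.na(encoded) || !nzchar(encoded)) return(IRanges::IRanges())
  parts <- strsplit(strsplit(encoded, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  IRanges::IRanges(start = as.integer(vapply(parts, `[`, "", 1)),
                   end = as.integer(vapply(parts, `[`, "", 2)))
}

#' Retain proteins at or above a minimum isoelectric point
#'
#' The basicity filter of the pipeline: proteins with predicted pI below the
#' threshold are removed; a pI exactly at the threshold is kept.
#'
#' @param profiles Feature table from [featureTable()], or a named numeric
#'   vector of pI values.
#' @param min_pi Minimum isoelectric point (pH units).
#' @return Character vector of surviving gene identifiers.
#' @export
filterByPI <- function(profiles, min_pi = 8.0) {
  if (is.data.frame(profiles)) {
    as.character(profiles$gene[profiles$pI >= min_pi])
  } else if (length(profiles) == 0L) {
    character(0)
  } else {
    names(profiles)[profiles >= min_pi]
  }
}
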