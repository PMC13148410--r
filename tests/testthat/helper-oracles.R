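# Independent oracles used across the suite. Each is written from the
# definition, separately from the package's implementation path.

# --- dense-grid isoelectric point oracle -----------------------------------
# Evaluate the charge balance on a 0.001-pH grid and take the sign change.
gridPI <- function(sequence, pka = pkaTable(), step = 0.001) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  cnt <- function(a) sum(ch == a)
  pH <- seq(0, 14, by = step)
  q <- 1 / (1 + 10^(pH - pka[["NH2"]])) - 1 / (1 + 10^(pka[["COOH"]] - pH))
  for (r in c("K", "R", "H")) q <- q + cnt(r) / (1 + 10^(pH - pka[[r]]))
  for (r in c("D", "E", "C", "Y")) q <- q - cnt(r) / (1 + 10^(pka[[r]] - pH))
  i <- which(q <= 0)[1]
  if (is.na(i)) return(14)
  if (i == 1L) return(0)
  mean(pH[c(i - 1L, i)])
}

randomProtein <- function(len, probs = NULL) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (is.null(probs)) probs <- rep(1, 20)
  paste(sample(aa, len, replace = TRUE, prob = probs), collapse = "")
}

# --- brute-force NG86 oracle ------------------------------------------------
# Recursive pathway enumeration; written independently of the package's
# permutation tables.
.GCO <- Biostrings::GENETIC_CODE
oracleSenseCodons <- names(.GCO)[.GCO != "*"]

oracleSynSites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      m <- b
      m[pos] <- nt
      mc <- paste(m, collapse = "")
      if (.GCO[[mc]] != "*" && .GCO[[mc]] == .GCO[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

oraclePathCounts <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  if (length(pos) == 0L) return(c(Sd = 0, Nd = 0))
  walk <- function(cur, remaining) {
    if (length(remaining) == 0L)
      return(list(c(sd = 0, nd = 0, blocked = 0)))
    paths <- list()
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- b2[p]
      to <- paste(nxt, collapse = "")
      from <- paste(cur, collapse = "")
      syn <- as.numeric(.GCO[[from]] == .GCO[[to]])
      hit_stop <- as.numeric(.GCO[[to]] == "*" && length(remaining) > 1L)
      for (tail in walk(nxt, setdiff(remaining, p))) {
        paths[[length(paths) + 1L]] <-
          c(sd = syn + tail[["sd"]], nd = (1 - syn) + tail[["nd"]],
            blocked = max(hit_stop, tail[["blocked"]]))
      }
    }
    paths
  }
  paths <- do.call(rbind, walk(b1, pos))
  keep <- paths[, "blocked"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(paths))
  c(Sd = mean(paths[keep, "sd"]), Nd = mean(paths[keep, "nd"]))
}

oracleNG86Counts <- function(seq_a, seq_b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(seq_a)
  cb <- split3(seq_b)
  S <- (sum(vapply(ca, oracleSynSites, 0)) +
        sum(vapply(cb, oracleSynSites, 0))) / 2
  diffs <- t(mapply(oraclePathCounts, ca, cb))
  c(S = S, N = 3 * length(ca) - S, Sd = sum(diffs[, "Sd"]),
    Nd = sum(diffs[, "Nd"]))
}

randomCodonSeq <- function(n_codons) {
  paste(sample(oracleSenseCodons, n_codons, replace = TRUE), collapse = "")
}

# --- brute-force basic-window oracle ---------------------------------------
oracleBasicWindows <- function(sequence, wmin, wmax, thr) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(ch)
  ivs <- NULL
  for (w in wmin:min(wmax, n)) {
    if (w > n) next
    for (st in seq_len(n - w + 1L)) {
      frac <- sum(ch[st:(st + w - 1L)] %in% c("R", "K")) / w
      if (frac >= thr) ivs <- rbind(ivs, c(st, st + w - 1L))
    }
  }
  if (is.null(ivs)) return(data.frame(start = integer(0), end = integer(0)))
  ivs <- ivs[order(ivs[, 1], ivs[, 2]), , drop = FALSE]
  merged <- ivs[1, , drop = FALSE]
  for (i in seq_len(nrow(ivs))[-1]) {
    last <- nrow(merged)
    if (ivs[i, 1] <= merged[last, 2] + 1L) {
      merged[last, 2] <- max(merged[last, 2], ivs[i, 2])
    } else {
      merged <- rbind(merged, ivs[i, ])
    }
  }
  data.frame(start = merged[, 1], end = merged[, 2])
}

# --- Monte-Carlo studentized-range oracle (balanced designs) ----------------
mcTukeyP <- function(proportions, groups, B = 10000, seed = 1) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- unique(table(g))
  stopifnot(length(n) == 1L)  # balanced only
  N <- k * n
  df <- N - k
  means <- tapply(proportions, g, mean)
  s2 <- sum(tapply(proportions, g, function(x) sum((x - mean(x))^2))) / df
  se <- sqrt(s2 / n)
  set.seed(seed)
  z <- matrix(stats::rnorm(B * k), B, k)
  s <- sqrt(stats::rchisq(B, df) / df)
  qsim <- (apply(z, 1, max) - apply(z, 1, min)) / s
  pairs <- utils::combn(levels(g), 2)
  res <- apply(pairs, 2, function(pr) {
    qobs <- abs(means[[pr[1]]] - means[[pr[2]]]) / se
    mean(qsim >= qobs)
  })
  # name pairs "second-first" to line up with stats::TukeyHSD rownames
  stats::setNames(res, apply(pairs, 2, function(pr)
    paste(pr[2], pr[1], sep = "-")))
}
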