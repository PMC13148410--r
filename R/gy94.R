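# One-ratio (M0) Goldman-Yang codon model, pairwise maximum likelihood.
# Rate matrix: single-nucleotide changes only; target-codon frequency pi_j
# times kappa for transitions and omega for nonsynonymous changes;
# normalized to one expected substitution per codon per unit time at
# stationarity. Transition probabilities come from eigendecomposition of the
# reversible generator in the pi-symmetrized basis.

.ML_BOUNDS <- list(t = c(1e-4, 50), kappa = c(1e-2, 100), omega = c(1e-4, 10))

.checkCodonFreqs <- function(freqs) {
  if (length(freqs) != .N_SENSE)
    stop("codon frequency vector must have ", .N_SENSE, " entries",
         call. = FALSE)
  if (!is.null(names(freqs))) {
    if (!identical(sort(names(freqs)), sort(.SENSE_CODONS)))
      stop("codon frequency names must be the 61 sense codons", call. = FALSE)
    freqs <- freqs[.SENSE_CODONS]
  } else {
    names(freqs) <- .SENSE_CODONS
  }
  if (any(freqs <= 0))
    stop("all codon frequencies must be strictly positive for the M0 model",
         call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-8) freqs <- freqs / sum(freqs)
  freqs
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies (codon positions 1-3, add-one
#' smoothing on the counts so no frequency is zero) multiplied per codon,
#' stop codons removed, renormalized to sum to one over the 61 sense codons.
#' Gap codons are ignored in the counts.
#'
#' @param alignment A [CodonAlignment-class].
#' @return Named numeric vector of 61 sense-codon frequencies.
#' @export
f3x4Frequencies <- function(alignment) {
  stopifnot(is(alignment, "CodonAlignment"))
  counts <- matrix(1, nrow = 3, ncol = 4, dimnames = list(NULL, .NUC))
  for (i in seq_along(alignment@seqs)) {
    codons <- .splitCodons(alignment@seqs[[i]])
    codons <- codons[codons != "---"]
    if (length(codons) == 0L) next
    for (pos in 1:3) {
      tab <- table(factor(substr(codons, pos, pos), levels = .NUC))
      counts[pos, ] <- counts[pos, ] + as.integer(tab)
    }
  }
  posfreq <- counts / rowSums(counts)
  f <- vapply(.SENSE_CODONS, function(cod) {
    b <- strsplit(cod, "")[[1]]
    posfreq[1, b[1]] * posfreq[2, b[2]] * posfreq[3, b[3]]
  }, numeric(1))
  f / sum(f)
}

# Normalized GY94 generator (61 x 61), mean rate 1 at stationarity.
.gy94Generator <- function(kappa, omega, freqs) {
  Q <- matrix(0, .N_SENSE, .N_SENSE,
              dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  Q[.ONE_STEP] <- freqs[col(Q)[.ONE_STEP]]
  Q[.ONE_STEP & .IS_TS] <- Q[.ONE_STEP & .IS_TS] * kappa
  ns <- .ONE_STEP & !.IS_SYN
  Q[ns] <- Q[ns] * omega
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  if (scale <= 0) stop("degenerate generator (zero total rate)", call. = FALSE)
  Q / scale
}

# P(t) = exp(Qt) by eigendecomposition in the pi-symmetrized basis.
.transitionProbs <- function(Q, freqs, t) {
  sp <- sqrt(freqs)
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  core <- e$vectors %*% (t(e$vectors) * exp(e$values * t))
  P <- core * ((1 / sp) %o% sp)
  P[P < 0] <- 0
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8))
    warning("transition probability row sums deviate from 1 by up to ",
            signif(max(abs(rs - 1)), 3))
  P / rs
}

#' Pairwise one-ratio (M0) maximum-likelihood omega
#'
#' Fits the GY94 codon model with a single omega to a two-sequence
#' alignment: the log-likelihood is the sum over codon columns of
#' `log(pi_i * P_ij(t))`, maximized over divergence `t`, the
#' transition/transversion ratio `kappa`, and `omega` within box bounds
#' (`t` in (1e-4, 50], `kappa` in (0.01, 100], `omega` in (1e-4, 10]),
#' starting from `(t, kappa, omega) = (0.5, 2, 1)`. By reversibility the
#' likelihood is invariant under swapping the two sequences. Columns with
#' gaps or ambiguity are dropped (pairwise deletion). `status = "boundary"`
#' flags an estimate at a bound (identical sequences, for instance, drive
#' `t` to its lower bound).
#'
#' @inheritParams ng86Pairwise
#' @param freqs Codon frequency vector (61 sense codons), e.g. from
#'   [f3x4Frequencies()] or [uniformCodonFrequencies()].
#' @param tol Convergence tolerance on the log-likelihood.
#' @return An [OmegaEstimate-class] with `method = "M0_ML"`.
#' @export
m0PairwiseML <- function(row_a, row_b, freqs = uniformCodonFrequencies(),
                         tol = 1e-6) {
  freqs <- .checkCodonFreqs(freqs)
  pair <- .codonPair(as.character(row_a), as.character(row_b))
  if (pair$n_used == 0L)
    stop("no comparable codon columns after pairwise deletion", call. = FALSE)
  ia <- .codonIndex[pair$a]
  ib <- .codonIndex[pair$b]
  pat <- stats::aggregate(list(n = rep(1L, length(ia))),
                          by = list(i = ia, j = ib), FUN = sum)
  logpi <- log(freqs)

  nll <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2]); om <- exp(par[3])
    Q <- .gy94Generator(kappa, om, freqs)
    P <- suppressWarnings(.transitionProbs(Q, freqs, t))
    ll <- sum(pat$n * (logpi[pat$i] + log(pmax(P[cbind(pat$i, pat$j)],
                                               1e-300))))
    -ll
  }

  lower <- log(c(.ML_BOUNDS$t[1], .ML_BOUNDS$kappa[1], .ML_BOUNDS$omega[1]))
  upper <- log(c(.ML_BOUNDS$t[2], .ML_BOUNDS$kappa[2], .ML_BOUNDS$omega[2]))
  start <- log(c(0.5, 2, 1))
  fit <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = tol / .Machine$double.eps,
                                     maxit = 500))
  est <- exp(fit$par)
  at_bound <- any(fit$par <= lower + 1e-7) || any(fit$par >= upper - 1e-7)
  new("OmegaEstimate", method = "M0_ML", n_codons = pair$n_used,
      omega = est[3], kappa = est[2], t = est[1], logLik = -fit$value,
      codon_freqs = freqs,
      status = if (at_bound) "boundary" else "ok")
}

#' M0 log-likelihood at fixed parameters
#'
#' Utility for optimization contracts and reversibility checks: evaluates
#' the pairwise M0 log-likelihood at a given `(t, kappa, omega)` without
#' optimizing.
#'
#' @inheritParams m0PairwiseML
#' @param t,kappa,omega Model parameters.
#' @return Log-likelihood (numeric scalar).
#' @export
m0LogLik <- function(row_a, row_b, t, kappa, omega,
                     freqs = uniformCodonFrequencies()) {
  freqs <- .checkCodonFreqs(freqs)
  pair <- .codonPair(as.character(row_a), as.character(row_b))
  ia <- .codonIndex[pair$a]
  ib <- .codonIndex[pair$b]
  Q <- .gy94Generator(kappa, omega, freqs)
  P <- .transitionProbs(Q, freqs, t)
  sum(log(freqs[ia]) + log(pmax(P[cbind(ia, ib)], 1e-300)))
}

#' Omega for a restricted region of an alignment
#'
#' Applies either estimator to a slice of codon columns only — the workflow
#' used to score a conserved winged-helix domain separately from the rest of
#' the protein. With `pairs = "reference"` only the first two rows are
#' compared; with `pairs = "all"` every pair is estimated and the across-pair
#' median omega (over pairs with `status = "ok"`) is reported.
#'
#' @param alignment A [CodonAlignment-class].
#' @param region Integer vector `c(start, end)` of codon columns (1-based,
#'   inclusive), or `NULL` for the whole alignment.
#' @param method `"NG86"` or `"M0"`.
#' @param pairs `"all"` or `"reference"`.
#' @param freqs Codon frequencies for the M0 method; defaults to F3x4
#'   frequencies of the full alignment.
#' @return List with `estimates` (list of [OmegaEstimate-class], named
#'   `taxonA|taxonB`), `table` (per-pair `data.frame` of omega, status and
#'   column count) and `median_omega`.
#' @export
regionOmega <- function(alignment, region = NULL,
                        method = c("NG86", "M0"), pairs = c("all", "reference"),
                        freqs = NULL) {
  stopifnot(is(alignment, "CodonAlignment"))
  method <- match.arg(method)
  pairs <- match.arg(pairs)
  nc <- nCodons(alignment)
  if (is.null(region)) region <- c(1L, nc)
  region <- as.integer(region)
  if (length(region) != 2L || region[1] < 1L || region[2] > nc ||
      region[1] > region[2])
    stop("region must be c(start, end) within 1..", nc,
         " codon columns with start <= end", call. = FALSE)
  if (method == "M0" && is.null(freqs)) freqs <- f3x4Frequencies(alignment)

  sub <- Biostrings::subseq(alignment@seqs, start = (region[1] - 1L) * 3L + 1L,
                            end = region[2] * 3L)
  tx <- taxa(alignment)
  idx <- if (pairs == "reference") {
    if (length(tx) < 2L) stop("need at least two taxa", call. = FALSE)
    matrix(c(1L, 2L), ncol = 2)
  } else {
    t(utils::combn(length(tx), 2L))
  }
  estimates <- vector("list", nrow(idx))
  names(estimates) <- paste(tx[idx[, 1]], tx[idx[, 2]], sep = "|")
  for (k in seq_len(nrow(idx))) {
    a <- as.character(sub[[idx[k, 1]]])
    b <- as.character(sub[[idx[k, 2]]])
    estimates[[k]] <- if (method == "NG86") ng86Pairwise(a, b) else
      m0PairwiseML(a, b, freqs)
  }
  tab <- data.frame(
    pair = names(estimates),
    omega = vapply(estimates, function(e) e@omega, numeric(1)),
    status = vapply(estimates, function(e) e@status, character(1)),
    n_codons = vapply(estimates, function(e) e@n_codons, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ok <- tab$omega[tab$status == "ok" & !is.na(tab$omega)]
  list(estimates = estimates, table = tab,
       median_omega = if (length(ok)) stats::median(ok) else NA_real_)
}
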