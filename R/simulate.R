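# Truth-labelled synthetic inputs with the statistical structure the
# analysis assumes. All generators are pure functions of (parameters, seed):
# the caller's RNG state is saved and restored. Planted objects enforce
# margins on every decision threshold so the deterministic stages have exact
# expected outputs; decoys are re-drawn whenever a random draw would land on
# or near a decision boundary.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a four-condition RPKM matrix with planted testis-exclusive genes
#'
#' Background genes draw log-normal RPKM (meanlog `log(10)`, sdlog 1.5) in
#' all four conditions; any background draw that would pass the exclusivity
#' rule — or come within `margin` of passing — is re-drawn, so the planted
#' set is exactly the set of true positives. Planted genes get a testis
#' RPKM at least `margin` above `min_target_rpkm` and other-condition RPKM
#' at least `margin` below `max_other_rpkm` (clipped at 0).
#'
#' @param n_genes Total number of genes.
#' @param n_exclusive Number of planted testis-exclusive genes.
#' @param margin RPKM margin planted on both sides of the thresholds.
#' @param seed Integer seed.
#' @param config A [pipelineConfig()] supplying the thresholds.
#' @param gene_ids Optional gene identifiers (length `n_genes`).
#' @param exclusive_ids Optional identifiers of the genes to plant;
#'   defaults to a random subset.
#' @return List with `matrix` (genes x 4 conditions) and `truth`
#'   (`data.frame` of `gene`, `exclusive` flag).
#' @export
simulateExpressionMatrix <- function(n_genes, n_exclusive, margin = 10,
                                     seed = 1, config = pipelineConfig(),
                                     gene_ids = NULL, exclusive_ids = NULL) {
  if (n_exclusive > n_genes || n_genes < 1L || n_exclusive < 0L)
    stop("need 0 <= n_exclusive <= n_genes and n_genes >= 1", call. = FALSE)
  if (margin <= 0) stop("margin must be > 0", call. = FALSE)
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids))
    stop("gene_ids must be ", n_genes, " unique identifiers", call. = FALSE)
  lo <- config@min_target_rpkm
  hi <- config@max_other_rpkm
  .withSeed(seed, {
    if (is.null(exclusive_ids)) {
      exclusive_ids <- if (n_exclusive > 0)
        sort(sample(gene_ids, n_exclusive)) else character(0)
    }
    stopifnot(all(exclusive_ids %in% gene_ids),
              length(exclusive_ids) == n_exclusive)
    m <- matrix(stats::rlnorm(n_genes * 4L, meanlog = log(10), sdlog = 1.5),
                nrow = n_genes, dimnames = list(gene_ids, .CONDITIONS))
    is_planted <- gene_ids %in% exclusive_ids
    # re-draw background rows that pass, or nearly pass, the rule
    repeat {
      near <- !is_planted &
        m[, "testis"] >= lo - margin &
        apply(m[, setdiff(.CONDITIONS, "testis"), drop = FALSE] <= hi + margin,
              1L, all)
      if (!any(near)) break
      m[near, ] <- stats::rlnorm(sum(near) * 4L, meanlog = log(10),
                                 sdlog = 1.5)
    }
    k <- sum(is_planted)
    if (k > 0) {
      m[is_planted, "testis"] <- lo + margin +
        stats::rlnorm(k, meanlog = log(100), sdlog = 1)
      for (cond in setdiff(.CONDITIONS, "testis"))
        m[is_planted, cond] <- stats::runif(k, 0, max(0, hi - margin))
    }
    list(matrix = m,
         truth = data.frame(gene = gene_ids, exclusive = is_planted,
                            stringsAsFactors = FALSE))
  })
}

.BG_MILD_BASIC <- c(A = 0.10, G = 0.08, S = 0.09, P = 0.07, T = 0.06,
                    V = 0.05, L = 0.05, I = 0.03, K = 0.07, R = 0.06,
                    N = 0.04, Q = 0.04, H = 0.03, F = 0.02, Y = 0.02,
                    W = 0.01, M = 0.02, C = 0.02, D = 0.02, E = 0.02)

.sampleAA <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

.plantPL <- function(config, pka) {
  for (try in 1:50) {
    L <- sample(200:250, 1)
    half <- ceiling(L / 2)
    wh_start <- sample(5:15, 1)
    wh_end <- wh_start + sample(55:70, 1) - 1L
    win_len <- sample(config@window_min:config@window_max, 1)
    # keep the planted window deep in the C-terminal half so that merged
    # windows extended leftwards by background R/K still start past midpoint
    win_start <- sample((half + 40L):(L - win_len + 1L), 1)
    win_end <- win_start + win_len - 1L
    ch <- strsplit(.sampleAA(L, .BG_MILD_BASIC), "")[[1]]
    f_basic <- config@min_basic_fraction + 0.15
    n_basic <- ceiling(f_basic * win_len)
    win_pos <- win_start:win_end
    basic_pos <- sample(win_pos, n_basic)
    ch[basic_pos] <- sample(c("R", "K"), n_basic, replace = TRUE,
                            prob = c(0.6, 0.4))
    rest <- setdiff(win_pos, basic_pos)
    ch[rest] <- sample(c("A", "G", "S", "P", "T"), length(rest),
                       replace = TRUE)
    # PL peptides carry scattered cysteines
    if (length(rest) >= 2) ch[sample(rest, 2)] <- "C"
    s <- paste(ch, collapse = "")
    if (isoelectricPoint(s, pka) >= config@min_pi + 0.2)
      return(list(seq = s, wh = c(wh_start, wh_end),
                  win = c(win_start, win_end), basic_fraction = f_basic))
  }
  stop("failed to generate a planted PL protein meeting the pI margin")
}

.plantProt <- function(config, pka) {
  lo <- config@prot_min_length
  hi <- config@prot_max_length
  L <- sample((lo + 5L):(hi - 5L), 1)
  f_arg <- stats::runif(1, 0.4, 0.7)
  n_arg <- ceiling(f_arg * L)
  ch <- sample(c("A", "G", "S", "K", "P", "T", "V"), L, replace = TRUE)
  ch[sample(L, n_arg)] <- "R"
  list(seq = paste(ch, collapse = ""), arg_fraction = n_arg / L)
}

.plantHMG <- function(config, pka) {
  for (try in 1:50) {
    L <- sample(150:250, 1)
    s <- .sampleAA(L, .BG_MILD_BASIC)
    if (isoelectricPoint(s, pka) >= config@min_pi + 0.2)
      return(list(seq = s, dom = c(L - 70L, L - 10L)))
  }
  stop("failed to generate a planted HMG-box protein meeting the pI margin")
}

.plantTSHistone <- function(config, pka) {
  probs <- .BG_MILD_BASIC
  probs[["K"]] <- 0.14
  probs[["R"]] <- 0.08
  for (try in 1:50) {
    L <- sample(100:140, 1)
    s <- .sampleAA(L, probs)
    if (isoelectricPoint(s, pka) >= config@min_pi + 0.2)
      return(list(seq = s, dom = c(20L, min(90L, L - 5L))))
  }
  stop("failed to generate a planted TS histone meeting the pI margin")
}

.decoyProtein <- function(config) {
  repeat {
    L <- sample(60:400, 1)
    probs <- stats::rgamma(20, 1)
    names(probs) <- .AA20
    s <- .sampleAA(L, probs)
    fr <- compositionProfile(s)$fractions
    # keep decoys clear of the protamine arginine cutoff
    if (fr[["R"]] < config@prot_min_arg_fraction - 0.03) return(s)
  }
}

#' Simulate a proteome with planted SNBP architectures
#'
#' Planted protamine-like (PL) proteins are 200-250 aa with a winged-helix
#' domain in the N-terminal half and a 30-50 aa Arg/Lys-rich window (basic
#' fraction 0.15 above the detection threshold) deep in the C-terminal
#' half, with scattered cysteines; planted protamines are 55-105 aa with
#' arginine fraction 0.4-0.7; planted HMG-box and testis-specific-histone
#' proteins carry the corresponding domain call. Decoys draw their
#' composition from a flat Dirichlet and are re-drawn if they approach the
#' protamine arginine cutoff. Domain rows are emitted only for planted
#' domains. Planted PL and TS-histone proteins are guaranteed a pI above
#' the basicity threshold under the configured pKa table.
#'
#' @param n_decoys Number of background proteins.
#' @param planted Character vector of classes to plant, from
#'   `c("PL", "Prot", "HMG_box", "TS_histone")`.
#' @param seed Integer seed.
#' @param config A [pipelineConfig()].
#' @return List with `proteins` ([Biostrings::AAStringSet]), `domains`
#'   (`data.frame`: `gene`, `type`, `start`, `end`) and `truth`
#'   (`data.frame`: `gene`, `class`, planted intervals; decoys carry class
#'   `"non_SNBP"`).
#' @export
simulateSnbpProteome <- function(n_decoys, planted = c("PL", "PL", "Prot"),
                                 seed = 1, config = pipelineConfig()) {
  bad <- setdiff(planted, c("PL", "Prot", "HMG_box", "TS_histone"))
  if (length(bad))
    stop("unknown planted class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pka <- pkaTable(config@pka_table_name)
  .withSeed(seed, {
    seqs <- character(0)
    doms <- list()
    truth <- list()
    for (i in seq_along(planted)) {
      cls <- planted[i]
      id <- sprintf("planted_%02d_%s", i, tolower(cls))
      rec <- switch(cls,
        PL = .plantPL(config, pka),
        Prot = .plantProt(config, pka),
        HMG_box = .plantHMG(config, pka),
        TS_histone = .plantTSHistone(config, pka))
      seqs[id] <- rec$seq
      if (cls == "PL") {
        doms[[id]] <- data.frame(gene = id, type = "WH",
                                 start = rec$wh[1], end = rec$wh[2])
        truth[[id]] <- data.frame(gene = id, class = cls,
                                  wh_start = rec$wh[1], wh_end = rec$wh[2],
                                  win_start = rec$win[1], win_end = rec$win[2])
      } else if (cls == "HMG_box") {
        doms[[id]] <- data.frame(gene = id, type = "HMG_box",
                                 start = rec$dom[1], end = rec$dom[2])
        truth[[id]] <- data.frame(gene = id, class = cls, wh_start = NA,
                                  wh_end = NA, win_start = NA, win_end = NA)
      } else if (cls == "TS_histone") {
        doms[[id]] <- data.frame(gene = id, type = "histone_fold",
                                 start = rec$dom[1], end = rec$dom[2])
        truth[[id]] <- data.frame(gene = id, class = cls, wh_start = NA,
                                  wh_end = NA, win_start = NA, win_end = NA)
      } else {
        truth[[id]] <- data.frame(gene = id, class = cls, wh_start = NA,
                                  wh_end = NA, win_start = NA, win_end = NA)
      }
    }
    for (i in seq_len(n_decoys)) {
      id <- sprintf("decoy_%03d", i)
      seqs[id] <- .decoyProtein(config)
      truth[[id]] <- data.frame(gene = id, class = "non_SNBP", wh_start = NA,
                                wh_end = NA, win_start = NA, win_end = NA)
    }
    domains <- if (length(doms)) do.call(rbind, doms) else
      data.frame(gene = character(0), type = character(0),
                 start = integer(0), end = integer(0))
    rownames(domains) <- NULL
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(proteins = Biostrings::AAStringSet(seqs), domains = domains,
         truth = truth)
  })
}

#' Simulate codon-sequence evolution under the GY94 model
#'
#' Each taxon descends independently from a common ancestor (codons sampled
#' from `freqs`) along a branch of length `t / 2`, so every pair is
#' separated by total divergence `t`. Evolution is exact stochastic
#' (Gillespie) simulation under the normalized GY94 generator — deliberately
#' independent of the matrix-exponential machinery used by the estimator —
#' and can never produce a stop codon because rates into stops are zero.
#'
#' @param omega dN/dS ratio (`omega = 0` forbids nonsynonymous change).
#' @param kappa Transition/transversion rate ratio.
#' @param t Total pairwise divergence (expected substitutions per codon).
#' @param n_codons Number of codon sites.
#' @param freqs Stationary codon frequencies (61 sense codons).
#' @param n_taxa Number of taxa (tips of a star tree).
#' @param seed Integer seed.
#' @return List with `alignment` ([CodonAlignment-class]) and `truth`
#'   (the parameters plus the ancestral codon sequence).
#' @export
simulateCodonEvolution <- function(omega, kappa, t, n_codons,
                                   freqs = uniformCodonFrequencies(),
                                   n_taxa = 2, seed = 1) {
  if (omega < 0 || kappa <= 0 || t < 0 || n_codons < 1 || n_taxa < 2)
    stop("invalid simulation parameters", call. = FALSE)
  freqs <- .checkCodonFreqs(freqs)
  .withSeed(seed, {
    anc <- sample.int(.N_SENSE, n_codons, replace = TRUE, prob = freqs)
    branch <- t / 2
    Q <- if (branch > 0) .gy94Generator(kappa, omega, freqs) else NULL
    evolve <- function(states) {
      if (branch == 0) return(states)
      for (k in seq_along(states)) {
        s <- states[k]
        remaining <- branch
        repeat {
          rate <- -Q[s, s]
          if (rate <= 0) break
          w <- stats::rexp(1, rate)
          if (w > remaining) break
          remaining <- remaining - w
          jump <- Q[s, ]
          jump[s] <- 0
          s <- sample.int(.N_SENSE, 1, prob = jump)
        }
        states[k] <- s
      }
      states
    }
    rows <- vapply(seq_len(n_taxa), function(i)
      paste(.SENSE_CODONS[evolve(anc)], collapse = ""), character(1))
    names(rows) <- sprintf("t%d", seq_len(n_taxa))
    list(alignment = codonAlignment(rows),
         truth = list(omega = omega, kappa = kappa, t = t,
                      n_codons = n_codons,
                      ancestor = paste(.SENSE_CODONS[anc], collapse = "")))
  })
}

#' Simulate brood sex-ratio tables
#'
#' Brood sizes are Poisson around `brood_size_mean` (minimum one
#' individual); female counts are binomial with the group's planted
#' probability.
#'
#' @param group_probs Named (or unnamed) vector of per-group female
#'   probabilities in `[0, 1]`.
#' @param broods_per_group Number of broods per treatment group.
#' @param brood_size_mean Mean brood size.
#' @param seed Integer seed.
#' @return List with `broods` (`data.frame`: `group`, `brood`, `females`,
#'   `males`) and `truth` (the planted probabilities).
#' @export
simulateBroods <- function(group_probs, broods_per_group = 21,
                           brood_size_mean = 30, seed = 1) {
  if (any(group_probs < 0 | group_probs > 1))
    stop("group probabilities must lie in [0, 1]", call. = FALSE)
  if (is.null(names(group_probs)))
    names(group_probs) <- sprintf("group%d", seq_along(group_probs))
  .withSeed(seed, {
    rows <- lapply(names(group_probs), function(g) {
      size <- pmax(1L, stats::rpois(broods_per_group, brood_size_mean))
      fem <- stats::rbinom(broods_per_group, size, group_probs[[g]])
      data.frame(group = g, brood = sprintf("%s_b%02d", g,
                                            seq_len(broods_per_group)),
                 females = fem, males = size - fem,
                 stringsAsFactors = FALSE)
    })
    list(broods = do.call(rbind, rows), truth = group_probs)
  })
}

.GO_PLANTED_TERMS <- data.frame(
  category = c("C", "F", "P"),
  term = c("nucleosome", "DNA binding", "nucleosome assembly"),
  stringsAsFactors = FALSE
)

.GO_DECOY_POOL <- c("electron transport chain", "mitochondrial matrix",
                    "microtubule-associated complex",
                    "protein kinase activity", "calcium channel activity",
                    "odorant binding", "structural constituent of cuticle",
                    "proteolysis", "carbohydrate metabolic process")

#' Simulate a complete synthetic study
#'
#' Bundles the per-stage generators into one coherent fixture over a shared
#' gene universe: a proteome with planted SNBP architectures, an RPKM
#' matrix in which exactly the planted genes are testis-exclusive, GO
#' annotations (planted genes carry chromatin-related terms; decoys draw
#' from a pool that includes excluded categories, and a third of them are
#' left unannotated), and the planted-domain table.
#'
#' @inheritParams simulateSnbpProteome
#' @param margin RPKM margin for the expression generator.
#' @return List with `matrix`, `proteins`, `go`, `domains`, `truth`
#'   (per-gene class and exclusivity labels) and `config`.
#' @export
simulateStudy <- function(n_decoys = 97, planted = c("PL", "PL", "Prot"),
                          margin = 10, seed = 1, config = pipelineConfig()) {
  prot <- simulateSnbpProteome(n_decoys, planted, seed = seed,
                               config = config)
  ids <- names(prot$proteins)
  planted_ids <- prot$truth$gene[prot$truth$class != "non_SNBP"]
  expr <- simulateExpressionMatrix(length(ids), length(planted_ids),
                                   margin = margin, seed = seed + 1L,
                                   config = config, gene_ids = ids,
                                   exclusive_ids = planted_ids)
  go <- .withSeed(seed + 2L, {
    rows <- lapply(ids, function(g) {
      if (g %in% planted_ids) {
        cbind(data.frame(gene = g, stringsAsFactors = FALSE),
              .GO_PLANTED_TERMS)
      } else if (stats::runif(1) < 1 / 3) {
        NULL  # uncharacterized decoy
      } else {
        data.frame(gene = g, category = "F",
                   term = sample(.GO_DECOY_POOL, 1),
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })
  truth <- merge(prot$truth, expr$truth, by = "gene", sort = FALSE)
  list(matrix = expr$matrix, proteins = prot$proteins, go = go,
       domains = prot$domains, truth = truth, config = config)
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Emits the expression TSV, protein FASTA, GO and domain tables, and the
#' truth table into a directory.
#'
#' @param study Result of [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
writeSyntheticStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    proteins = file.path(dir, "proteins.fasta"),
    go = file.path(dir, "go.tsv"),
    domains = file.path(dir, "domains.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  writeExpressionTable(study$matrix, paths["expression"])
  writeFasta(study$proteins, paths["proteins"])
  utils::write.table(study$go, paths["go"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$domains, paths["domains"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
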