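test_that("back-translation threads codons onto the protein alignment", {
  aln <- backTranslateAlignment(c(t1 = "M-A", t2 = "MKA"),
                                c(t1 = "ATGGCT", t2 = "ATGAAAGCT"))
  expect_identical(as.character(alignedSeqs(aln)[["t1"]]), "ATG---GCT")
  expect_identical(as.character(alignedSeqs(aln)[["t2"]]), "ATGAAAGCT")

  # terminal stop codons are stripped
  aln2 <- backTranslateAlignment(c(t1 = "MA"), c(t1 = "ATGGCTTAA"))
  expect_identical(as.character(alignedSeqs(aln2)[["t1"]]), "ATGGCT")
})

test_that("back-translation rejects invalid CDS with informative errors", {
  expect_error(backTranslateAlignment(c(t1 = "M-A"), c(t1 = "ATGTAAGCT")),
               "internal stop.*t1")
  expect_error(backTranslateAlignment(c(t1 = "MA"), c(t1 = "ATGGC")),
               "not a multiple of 3")
  expect_error(backTranslateAlignment(c(t1 = "MW"), c(t1 = "ATGGCT")),
               "t1.*residue 2")
  expect_error(backTranslateAlignment(c(t1 = "MA"), c(t2 = "ATGGCT")),
               "CDS missing")
})

test_that("stripping gap codons is the identity on every CDS", {
  set.seed(201)
  for (i in 1:5) {
    n <- sample(10:30, 1)
    cds <- vapply(1:3, function(j) randomCodonSeq(n), character(1))
    names(cds) <- paste0("t", 1:3)
    prots <- vapply(cds, function(x) {
      as.character(Biostrings::translate(Biostrings::DNAString(x),
                                         no.init.codon = TRUE))
    }, character(1))
    # plant a shared gap column pattern
    gapped <- vapply(prots, function(p) {
      ch <- strsplit(p, "")[[1]]
      paste(append(ch, "-", after = 3), collapse = "")
    }, character(1))
    aln <- backTranslateAlignment(gapped, cds)
    for (tx in names(cds))
      expect_identical(ungappedCds(aln, tx), unname(cds[[tx]]))
  }
})

test_that("codon alignment validity catches stops, ragged rows and partial gaps", {
  expect_error(codonAlignment(c(a = "ATGAAA", b = "ATG")), "equal width")
  expect_error(codonAlignment(c(a = "ATGTAA", b = "ATGAAA")), "stop codon")
  expect_error(codonAlignment(c(a = "ATGA--", b = "ATGAAA")),
               "partial gap|invalid codon")
  expect_error(codonAlignment(c("ATGAAA", "ATGAAA")), "taxon names")
})

test_that("NG86 handles identical sequences and the single synonymous change", {
  s <- randomCodonSeq(20)
  e <- ng86Pairwise(s, s)
  expect_equal(e@Sd, 0)
  expect_equal(e@Nd, 0)
  expect_identical(e@status, "dS_zero")

  e <- ng86Pairwise("TTTAAAGGGCCC", "TTCAAAGGGCCC")  # Phe TTT -> TTC
  expect_equal(e@Sd, 1)
  expect_equal(e@Nd, 0)

  expect_error(ng86Pairwise("TTT", "TTTAAA"), "differ in codon length")
  expect_error(ng86Pairwise("TAA", "TTT"), "stop codon")
})

test_that("NG86 site and difference counts equal the brute-force enumerator", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    a <- randomCodonSeq(n)
    b <- randomCodonSeq(n)
    got <- ng86Pairwise(a, b)
    want <- oracleNG86Counts(a, b)
    expect_equal(got@S_sites, unname(want[["S"]]), tolerance = 1e-12)
    expect_equal(got@N_sites, unname(want[["N"]]), tolerance = 1e-12)
    expect_equal(got@Sd, unname(want[["Sd"]]), tolerance = 1e-12)
    expect_equal(got@Nd, unname(want[["Nd"]]), tolerance = 1e-12)
    expect_equal(got@S_sites + got@N_sites, 3 * n)
  }
})

test_that("gap and ambiguous columns are excluded pairwise", {
  e <- ng86Pairwise("TTT---AAA", "TTCAAAAAA")
  expect_equal(e@n_codons, 2)   # middle column dropped
  expect_equal(e@Sd, 1)
  e2 <- ng86Pairwise("TTTNNTAAA", "TTCAAAAAA")
  expect_equal(e2@n_codons, 2)
})

test_that("F3x4 frequencies are smoothed, stop-free and normalized", {
  aln <- codonAlignment(c(a = "ATGATG", b = "ATGATG"))
  f <- f3x4Frequencies(aln)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_true(all(f > 0))  # add-one smoothing leaves no zeros

  # hand computation: 4 ATG codons counted, +1 smoothing per nucleotide,
  # so each position has 5/8 mass on the observed base and 1/8 elsewhere
  posfreq <- function(pos, base) {
    obs <- c("A", "T", "G")[pos]
    if (base == obs) 5 / 8 else 1 / 8
  }
  raw <- vapply(oracleSenseCodons, function(cod) {
    b <- strsplit(cod, "")[[1]]
    posfreq(1, b[1]) * posfreq(2, b[2]) * posfreq(3, b[3])
  }, numeric(1))
  expect_equal(unname(f), unname(raw / sum(raw)), tolerance = 1e-12)
  expect_gt(f[["ATG"]], max(f[setdiff(names(f), "ATG")]))

  # large uniform alignment approaches the uniform distribution
  set.seed(203)
  rows <- vapply(1:6, function(i) randomCodonSeq(400), character(1))
  names(rows) <- paste0("t", 1:6)
  f2 <- f3x4Frequencies(codonAlignment(rows))
  expect_lt(max(abs(f2 - 1 / 61)), 0.02)
})

test_that("M0 pairwise ML behaves at the optimization contract level", {
  s <- randomCodonSeq(60)
  fit <- m0PairwiseML(s, s)
  expect_identical(fit@status, "boundary")       # identical rows: t at bound
  expect_equal(fit@t, 1e-4, tolerance = 1e-6)

  sim <- simulateCodonEvolution(0.3, 2, 0.5, 200, seed = 204)
  a <- as.character(alignedSeqs(sim$alignment)[[1]])
  b <- as.character(alignedSeqs(sim$alignment)[[2]])
  fit <- m0PairwiseML(a, b)
  expect_gte(fit@logLik, m0LogLik(a, b, 0.5, 2, 1))  # beats the start point
  # reversibility: likelihood invariant under swapping the sequences
  expect_equal(m0LogLik(a, b, 0.4, 2, 0.3), m0LogLik(b, a, 0.4, 2, 0.3),
               tolerance = 1e-8)
  expect_equal(m0PairwiseML(b, a)@omega, fit@omega, tolerance = 1e-4)
})

test_that("M0 recovers omega from data simulated at known parameters", {
  sim <- simulateCodonEvolution(0.2, 2, 0.4, 1000, seed = 205)
  a <- as.character(alignedSeqs(sim$alignment)[[1]])
  b <- as.character(alignedSeqs(sim$alignment)[[2]])
  fit <- m0PairwiseML(a, b, f3x4Frequencies(sim$alignment))
  expect_true(fit@omega >= 0.12 && fit@omega <= 0.30)
})

test_that("region slicing is consistent and degenerate slices are flagged", {
  sim <- simulateCodonEvolution(0.5, 2, 0.3, 60, n_taxa = 3, seed = 206)
  aln <- sim$alignment

  whole <- regionOmega(aln, method = "NG86", pairs = "reference")
  sliced <- regionOmega(aln, region = c(1, nCodons(aln)), method = "NG86",
                        pairs = "reference")
  expect_equal(sliced$estimates[[1]]@omega, whole$estimates[[1]]@omega)
  expect_equal(sliced$estimates[[1]]@Sd, whole$estimates[[1]]@Sd)

  one <- regionOmega(aln, region = c(1, 1), method = "NG86")
  expect_true(all(vapply(one$estimates, estimateStatus, "") %in%
                    c("dS_zero", "saturated")))

  expect_error(regionOmega(aln, region = c(5, 4)), "start <= end")
  expect_error(regionOmega(aln, region = c(0, 10)), "within")

  allp <- regionOmega(aln, method = "NG86", pairs = "all")
  expect_equal(nrow(allp$table), 3L)  # 3 taxa -> 3 pairs
  ok <- allp$table$omega[allp$table$status == "ok"]
  if (length(ok)) expect_equal(allp$median_omega, median(ok))
})
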