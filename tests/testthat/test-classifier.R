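no_domains <- data.frame(gene = character(0), type = character(0),
                         start = integer(0), end = integer(0))

test_that("GO triage removes excluded terms and keeps included or unannotated genes", {
  go <- data.frame(
    gene = c("kin", "kin", "dna", "chan"),
    category = c("F", "P", "F", "F"),
    term = c("Protein Kinase activity", "phosphorylation",
             "DNA binding", "calcium channel activity"),
    stringsAsFactors = FALSE)
  kept <- filterByGO(c("kin", "dna", "chan", "nogo"), go)
  expect_false("kin" %in% kept)    # exclude term, case-insensitive
  expect_true("dna" %in% kept)     # include term
  expect_false("chan" %in% kept)   # no include match
  expect_true("nogo" %in% kept)    # annotation-free = uncharacterized

  # exclusion wins over inclusion
  go2 <- data.frame(gene = "both", category = "F",
                    term = c("DNA binding", "kinase regulator"))
  expect_length(filterByGO("both", go2), 0L)

  expect_error(filterByGO("x", go, exclude_terms = character(0)),
               "non-empty")
})

test_that("SNBP classes follow the ordered decision rules", {
  cfg <- pipelineConfig()
  # protamine: short and arginine-rich
  expect_identical(
    classifySNBP(80, 0.5, 12, IRanges::IRanges(), no_domains, cfg), "Prot")
  # protamine-like: N-terminal WH + C-terminal basic window
  wh <- data.frame(gene = "g", type = "WH", start = 16, end = 90)
  win <- IRanges::IRanges(start = 141, end = 175)
  expect_identical(classifySNBP(216, 0.1, 10.7, win, wh, cfg), "PL")
  # WH too far C-terminal: not a PL
  wh_c <- data.frame(gene = "g", type = "WH", start = 120, end = 200)
  expect_identical(classifySNBP(216, 0.1, 10.7, win, wh_c, cfg), "non_SNBP")
  # window starting in the N-terminal half does not qualify
  win_n <- IRanges::IRanges(start = 20, end = 55)
  expect_identical(classifySNBP(216, 0.1, 10.7, win_n, wh, cfg), "non_SNBP")
  # HMG box
  hmg <- data.frame(gene = "g", type = "HMG_box", start = 150, end = 200)
  expect_identical(classifySNBP(216, 0.1, 9, IRanges::IRanges(), hmg, cfg),
                   "HMG_box")
  # TS histone requires the basicity floor
  hf <- data.frame(gene = "g", type = "histone_fold", start = 20, end = 90)
  expect_identical(classifySNBP(130, 0.1, 10, IRanges::IRanges(), hf, cfg),
                   "TS_histone")
  expect_identical(classifySNBP(130, 0.1, 7, IRanges::IRanges(), hf, cfg),
                   "non_SNBP")
  # fall-through
  expect_identical(
    classifySNBP(300, 0.05, 7.2, IRanges::IRanges(), no_domains, cfg),
    "non_SNBP")
  # domain interval outside the protein
  bad <- data.frame(gene = "g", type = "WH", start = 10, end = 400)
  expect_error(classifySNBP(216, 0.1, 10, win, bad, cfg), "outside protein")
})

test_that("protamine rule beats later rules and respects its bounds", {
  cfg <- pipelineConfig()
  hmg <- data.frame(gene = "g", type = "HMG_box", start = 50, end = 100)
  # in-range and arginine-rich: Prot even with an HMG box present
  expect_identical(classifySNBP(110, 0.30, 12, IRanges::IRanges(), hmg, cfg),
                   "Prot")
  # one residue too long falls through to HMG_box
  expect_identical(classifySNBP(111, 0.30, 12, IRanges::IRanges(), hmg, cfg),
                   "HMG_box")
  # arginine fraction below the cutoff
  expect_identical(
    classifySNBP(80, 0.29, 12, IRanges::IRanges(), no_domains, cfg),
    "non_SNBP")
})

test_that("candidate table recovers exactly the planted genes with their classes", {
  st <- simulateStudy(n_decoys = 60,
                      planted = c("PL", "PL", "Prot", "HMG_box", "TS_histone"),
                      seed = 42)
  rep <- suppressMessages(
    buildCandidateTable(st$matrix, st$proteins, st$go, st$domains, st$config))
  survivors <- rep$gene[!is.na(rep$snbp_class)]
  planted <- st$truth$gene[st$truth$class != "non_SNBP"]
  expect_setequal(survivors, planted)
  called <- setNames(rep$snbp_class[!is.na(rep$snbp_class)], survivors)
  truth <- setNames(st$truth$class, st$truth$gene)
  expect_identical(unname(called[planted]), unname(truth[planted]))

  # survivor with the highest testis RPKM holds rank 1
  top <- survivors[which.max(st$matrix[survivors, "testis"])]
  expect_equal(rep$rank[rep$gene == top], 1L)

  funnel <- attr(rep, "funnel")
  expect_equal(unname(funnel["input"]), 65L)
  expect_true(all(diff(funnel) <= 0))
})

test_that("all-decoy input yields an empty candidate set", {
  st <- simulateStudy(n_decoys = 30, planted = character(0), seed = 7)
  rep <- suppressMessages(
    buildCandidateTable(st$matrix, st$proteins, st$go, st$domains, st$config))
  expect_true(all(is.na(rep$snbp_class)))
  expect_equal(unname(attr(rep, "funnel")["GO"]), 0L)
})

test_that("pI and GO filters commute (independent predicates)", {
  st <- simulateStudy(n_decoys = 40, planted = c("PL", "Prot"), seed = 13)
  expr_pass <- names(which(filterTissueExclusive(st$matrix)))
  feats <- featureTable(st$proteins[expr_pass], st$config)

  pi_then_go <- filterByGO(filterByPI(feats, 8), st$go)
  go_then_pi <- intersect(filterByGO(feats$gene, st$go), filterByPI(feats, 8))
  expect_setequal(pi_then_go, go_then_pi)
})
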