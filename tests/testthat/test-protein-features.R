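test_that("net charge has the right limits and Henderson-Hasselbalch midpoint", {
  set.seed(101)
  for (i in 1:10) {
    s <- randomProtein(sample(10:80, 1))
    expect_gt(netCharge(s, 0), 0)    # all basic groups protonated
    expect_lt(netCharge(s, 14), 0)   # all acidic groups deprotonated
  }

  # lysine side chain contributes exactly 1/2 at its own pKa
  pka <- pkaTable()
  q <- netCharge("K", pka[["K"]], pka)
  termini <- 1 / (1 + 10^(pka[["K"]] - pka[["NH2"]])) -
    1 / (1 + 10^(pka[["COOH"]] - pka[["K"]]))
  expect_equal(q - termini, 0.5, tolerance = 1e-12)

  expect_error(netCharge("MKB", 7), "unknown residue")
})

test_that("net charge is strictly decreasing in pH", {
  set.seed(102)
  for (i in 1:20) {
    s <- randomProtein(sample(5:100, 1))
    ph <- sort(runif(2, 0, 14))
    expect_gt(netCharge(s, ph[1]), netCharge(s, ph[2]))
  }
})

test_that("bisection pI matches the dense-grid sign-change oracle", {
  pka <- pkaTable()
  # termini-only and acidic edge cases called out explicitly
  expect_lt(isoelectricPoint("DDDD", pka), 7)
  expect_equal(isoelectricPoint("DDDD", pka), gridPI("DDDD", pka),
               tolerance = 0.01)
  expect_equal(isoelectricPoint("GG", pka), gridPI("GG", pka),
               tolerance = 0.01)

  set.seed(103)
  for (i in 1:30) {
    s <- randomProtein(sample(20:200, 1))
    expect_equal(isoelectricPoint(s, pka), gridPI(s, pka), tolerance = 0.01)
  }
})

test_that("appending a basic residue never decreases the pI", {
  set.seed(104)
  for (i in 1:15) {
    s <- randomProtein(sample(10:100, 1))
    base <- isoelectricPoint(s)
    expect_gte(isoelectricPoint(paste0(s, "K")), base - 1e-6)
    expect_gte(isoelectricPoint(paste0(s, "R")), base - 1e-6)
  }
})

test_that("X residues count toward length but not charge", {
  expect_equal(isoelectricPoint("GXG"), isoelectricPoint("GG"),
               tolerance = 1e-6)
  comp <- compositionProfile("GXG")
  expect_equal(comp$length, 3L)
  expect_equal(unname(comp$fractions[["X"]]), 1 / 3)
  expect_error(compositionProfile("GZ"), "unknown residue")
})

test_that("composition profile is exact and normalized", {
  comp <- compositionProfile("RKRK")
  expect_equal(unname(comp$fractions[["R"]]), 0.5)
  expect_equal(unname(comp$fractions[["K"]]), 0.5)
  expect_equal(comp$basic_fraction, 1.0)

  expect_equal(compositionProfile("ACDC")$cysteine_count, 2L)

  set.seed(105)
  for (i in 1:5) {
    s <- randomProtein(sample(5:60, 1))
    expect_equal(sum(compositionProfile(s)$fractions), 1, tolerance = 1e-9)
  }

  # histidine reported separately, not in the basic fraction
  comp <- compositionProfile("HHRK")
  expect_equal(comp$basic_fraction, 0.5)
  expect_equal(comp$histidine_fraction, 0.5)
})

test_that("arginine placement reports positions, runs and gaps", {
  ap <- argininePlacement("RARRA")
  expect_identical(ap$positions, c(1L, 3L, 4L))
  expect_equal(ap$max_run, 2L)

  ap <- argininePlacement("AAAA")
  expect_identical(ap$positions, integer(0))
  expect_equal(ap$max_run, 0L)
  expect_false(ap$gap_defined)

  ap <- argininePlacement("RRRR")
  expect_equal(ap$max_run, 4L)
  expect_equal(ap$mean_gap, 1)

  expect_false(argininePlacement("ARA")$gap_defined)  # single arginine
})

test_that("basic-window detection matches the brute-force scan oracle", {
  # constructed string: poly-A with a 30-residue RK stretch
  s <- paste0(strrep("A", 40), strrep("RK", 15), strrep("A", 30))
  got <- as.data.frame(detectBasicWindows(s))[, c("start", "end")]
  want <- oracleBasicWindows(s, 30, 50, 0.35)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(nrow(got), 1L)                 # merged into one interval
  expect_true(got$start[1] <= 41 && got$end[1] >= 70)

  set.seed(106)
  for (i in 1:10) {
    s <- randomProtein(sample(60:150, 1),
                       probs = c(2, 1, 1, 1, 1, 2, 1, 1, 6, 1,
                                 1, 1, 1, 1, 6, 2, 1, 1, 1, 1))
    got <- as.data.frame(detectBasicWindows(s, 20, 35, 0.4))
    want <- oracleBasicWindows(s, 20, 35, 0.4)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("windows handle degenerate inputs", {
  expect_length(detectBasicWindows(strrep("A", 100)), 0L)
  expect_warning(res <- detectBasicWindows("RKRK", window_min = 30),
                 "shorter than window_min")
  expect_length(res, 0L)
})

test_that("every reported interval contains a qualifying admissible window", {
  set.seed(107)
  for (i in 1:5) {
    s <- randomProtein(120, probs = c(2, 1, 1, 1, 1, 2, 1, 1, 5, 1,
                                      1, 1, 1, 1, 5, 2, 1, 1, 1, 1))
    win <- detectBasicWindows(s, 25, 40, 0.4)
    ch <- strsplit(s, "")[[1]]
    for (k in seq_along(win)) {
      st <- IRanges::start(win)[k]
      en <- IRanges::end(win)[k]
      found <- FALSE
      for (w in 25:40) {
        for (a in st:max(st, en - w + 1L)) {
          if (a + w - 1L > en) next
          if (sum(ch[a:(a + w - 1L)] %in% c("R", "K")) / w >= 0.4)
            found <- TRUE
        }
      }
      expect_true(found)
    }
  }
})

test_that("pI filter keeps the boundary value and drops below it", {
  pis <- c(keep_hi = 10.7, keep_edge = 8.0, drop = 7.99)
  expect_identical(filterByPI(pis, 8.0), c("keep_hi", "keep_edge"))
  expect_identical(filterByPI(numeric(0), 8.0), character(0))

  ft <- data.frame(gene = c("a", "b"), pI = c(8.0, 7.5))
  expect_identical(filterByPI(ft, 8.0), "a")
})

test_that("feature table encodes windows round-trippably", {
  prot <- Biostrings::AAStringSet(c(
    pl = paste0(strrep("A", 100), strrep("RK", 20), strrep("A", 40)),
    plain = strrep("ACDEG", 30)))
  ft <- featureTable(prot)
  expect_equal(nrow(ft), 2L)
  win <- decodeWindows(ft$basic_windows[ft$gene == "pl"])
  expect_gt(length(win), 0L)
  expect_length(decodeWindows(ft$basic_windows[ft$gene == "plain"]), 0L)
  expect_equal(ft$length, c(180L, 150L))
})
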