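# Sequential rule mining: precedence support, confidence, thresholds

test_that("sequential support counts precedence once per sequence", {
  ds <- makeDataset(list(c(1L, 2L, 3L), c(1L, 3L), c(2L, 1L)))
  expect_equal(sequenceSupport(ds, 1L, 2L), 1L)   # only the first sequence
  expect_equal(sequenceSupport(ds, 2L, 1L), 1L)   # only the third
  expect_equal(sequenceSupport(ds, 1L, 3L), 2L)
  expect_error(sequenceSupport(ds, 1L, 99L), "unknown concept")

  # repeats: x before x needs two occurrences
  ds2 <- makeDataset(list(c(1L, 2L, 1L)))
  expect_equal(sequenceSupport(ds2, 1L, 1L), 1L)
  expect_equal(sequenceSupport(makeDataset(list(c(1L, 2L))), 2L, 2L), 0L)

  # y never occurring in any sequence
  ds3 <- makeDataset(list(c(1L, 2L)), extraIds = 7L)
  expect_equal(sequenceSupport(ds3, 1L, 7L), 0L)
})

test_that("mined rules reproduce the worked threshold example", {
  ds <- makeDataset(list(c(1L, 2L), c(1L, 2L), c(1L, 3L)))  # A=1,B=2,C=3
  g <- mineTemporalRules(ds, minSeqSup = 0.5, minSeqConf = 0.5)
  ed <- ruleEdges(g)
  ab <- ed[ed$antecedent == 1 & ed$consequent == 2, ]
  expect_equal(ab$seq_sup, 2 / 3)
  expect_equal(ab$seq_conf, 2 / 3)
  expect_equal(ab$weight, 2 / 3)
  expect_false(any(ed$antecedent == 1 & ed$consequent == 3))  # seqSup 1/3
})

test_that("vacuous thresholds emit every supported pair", {
  ds <- makeDataset(list(c(1L, 2L), c(2L, 3L)))
  g <- mineTemporalRules(ds, 0, 0)
  oracle <- bruteMineRules(ds, 0, 0)
  expect_equal(nrow(ruleEdges(g)), nrow(oracle))
})

test_that("thresholds (1,1) keep only pairs present in every sequence", {
  ds <- makeDataset(list(c(1L, 2L), c(1L, 3L), c(1L, 2L, 3L)))
  ed <- ruleEdges(mineTemporalRules(ds, 1, 1))
  # START->STOP, START->1, 1->STOP hold in all three sequences
  expect_true(any(ed$antecedent == START_ID & ed$consequent == STOP_ID))
  expect_true(any(ed$antecedent == 1 & ed$consequent == STOP_ID))
  expect_false(any(ed$antecedent == 1 & ed$consequent == 2))
})

test_that("mining matches exhaustive enumeration on random datasets", {
  set.seed(41)
  for (rep in 1:10) {
    ds <- randomSmallDataset(nseq = sample(3:15, 1),
                             nconcepts = sample(2:6, 1))
    thr <- runif(2, 0, 0.7)
    got <- ruleEdges(mineTemporalRules(ds, thr[1], thr[2]))
    want <- bruteMineRules(ds, thr[1], thr[2])
    expect_equal(got$antecedent, want$antecedent)
    expect_equal(got$consequent, want$consequent)
    expect_equal(got$seq_sup, want$seq_sup)
    expect_equal(got$seq_conf, want$seq_conf)
  }
})

test_that("raising a threshold never adds a rule", {
  set.seed(51)
  ds <- randomSmallDataset(nseq = 15, nconcepts = 5)
  grid <- seq(0, 1, by = 0.25)
  key <- function(g) paste(ruleEdges(g)$antecedent, ruleEdges(g)$consequent)
  for (s in grid) {
    for (cc in grid) {
      base <- key(mineTemporalRules(ds, s, cc))
      if (s < 1)
        expect_true(all(key(mineTemporalRules(ds, s + 0.25, cc)) %in% base))
      if (cc < 1)
        expect_true(all(key(mineTemporalRules(ds, s, cc + 0.25)) %in% base))
    }
  }
})

test_that("confidence dominates support on every emitted rule", {
  set.seed(61)
  for (rep in 1:5) {
    ed <- ruleEdges(mineTemporalRules(randomSmallDataset(12, 5), 0, 0))
    expect_true(all(ed$seq_conf >= ed$seq_sup - 1e-12))
  }
})

test_that("a planted x-then-y pattern is recovered at (0.5, 0.5)", {
  set.seed(71)
  bodies <- lapply(1:50, function(i) {
    filler <- sample(3:6, 2, replace = TRUE)
    if (i <= 40) c(1L, filler[1], 2L) else c(filler, sample(3:6, 1))
  })
  ed <- ruleEdges(mineTemporalRules(makeDataset(bodies), 0.5, 0.5))
  expect_true(any(ed$antecedent == 1 & ed$consequent == 2))
})
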