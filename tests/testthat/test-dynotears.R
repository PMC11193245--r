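# SVAR structure learning: encoding, acyclicity function, augmented
# Lagrangian fit, rule extraction

test_that("panel encoding pools windows without crossing patients", {
  ds <- makeDataset(list(1L))  # [START, A, STOP]
  dm <- encodeBinaryPanel(ds, p = 1)
  expect_equal(nrow(dm@X), 2L)  # START->A, A->STOP

  ds3 <- makeDataset(list(c(1L, 2L), c(2L, 1L), 1L))  # T = 4, 4, 3
  dm3 <- encodeBinaryPanel(ds3, p = 1)
  expect_equal(nrow(dm3@X), 8L)  # (4-1) + (4-1) + (3-1)
  expect_true(all(rowSums(dm3@X) == 1))
  expect_true(all(rowSums(dm3@Y) == 1))
  expect_true(all(dm3@X %in% c(0, 1)))
  # lag alignment: Y row equals the X row one step earlier within a patient
  expect_equal(dm3@Y[2, ], dm3@X[1, ])
})

test_that("too-short sequences are skipped and topK caps the vocabulary", {
  ds <- makeDataset(list(c(1L, 1L, 1L, 2L), c(1L, 3L)))
  dm <- encodeBinaryPanel(ds, topK = 2, p = 1)
  expect_equal(dm@concepts, c(START_ID, 1L, 2L, STOP_ID))
  expect_warning(encodeBinaryPanel(makeDataset(list(1L)), p = 3), "skipped")
})

test_that("acyclicity function matches closed forms", {
  expect_equal(hAcyclicity(matrix(0, 4, 4)), 0)
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(hAcyclicity(W2), 2 * cosh(1) - 2, tolerance = 1e-12)
  Wu <- matrix(c(0, 0, 0, 2, 0, 0, 1, 3, 0), 3, 3)  # strictly lower-tri cols
  expect_lt(hAcyclicity(Wu), 1e-10)
  expect_error(hAcyclicity(matrix(0, 2, 3)), "square")
})

test_that("acyclicity gradient matches finite differences", {
  set.seed(81)
  W <- matrix(rnorm(16, sd = 0.5), 4, 4)
  g <- hAcyclicity(W, gradient = TRUE)$gradient
  eps <- 1e-6
  for (k in sample(16, 5)) {
    Wp <- W; Wp[k] <- Wp[k] + eps
    Wm <- W; Wm[k] <- Wm[k] - eps
    num <- (hAcyclicity(Wp) - hAcyclicity(Wm)) / (2 * eps)
    expect_equal(g[k], num, tolerance = 1e-4)
  }
})

test_that("pure-noise data yields an empty thresholded graph", {
  sim <- simulateSVAR(d = 5, p = 1, edgeProb = 0, noiseSd = 0.1, M = 1000,
                      seed = 42)
  fit <- fitDynotears(sim$panel)
  expect_equal(sum(abs(intraSlice(fit)) > 0.3), 0L)
  expect_equal(sum(abs(interSlice(fit)) > 0.3), 0L)
  expect_true(fit@converged)
})

test_that("a known sparse SVAR structure is recovered", {
  sim <- simulateSVAR(d = 5, p = 1, edgeProb = 0.3, coefRange = c(0.5, 1),
                      noiseSd = 0.1, M = 2000, seed = 7)
  fit <- fitDynotears(sim$panel)
  shd <- structuralHammingDistance(intraSlice(sim$truth), intraSlice(fit),
                                   interSlice(sim$truth), interSlice(fit),
                                   threshold = 0.3)
  expect_lte(shd, 1L)
  expect_lte(fit@h, 1e-8)
})

test_that("overwhelming L1 penalties drive all coefficients to zero", {
  sim <- simulateSVAR(d = 4, p = 1, edgeProb = 0.4, noiseSd = 0.1, M = 500,
                      seed = 9)
  fit <- fitDynotears(sim$panel, lambdaW = 50, lambdaA = 50)
  expect_true(all(intraSlice(fit) == 0))
  expect_true(all(interSlice(fit) == 0))
})

test_that("each inner solve does not increase its objective", {
  sim <- simulateSVAR(d = 4, p = 1, edgeProb = 0.4, noiseSd = 0.1, M = 500,
                      seed = 10)
  fit <- fitDynotears(sim$panel)
  tr <- fit@trace
  expect_true(all(tr$objective_end <= tr$objective_start + 1e-9))
})

test_that("fitting is equivariant under coordinate permutation", {
  sim <- simulateSVAR(d = 4, p = 1, edgeProb = 0.4, noiseSd = 0.1, M = 800,
                      seed = 12)
  fit <- fitDynotears(sim$panel)
  perm <- c(3L, 1L, 4L, 2L)
  pm <- sim$panel
  dmp <- new("DesignMatrices", X = pm@X[, perm], Y = pm@Y[, perm],
             p = 1L, concepts = pm@concepts[perm], labels = pm@labels[perm])
  fitp <- fitDynotears(dmp)
  expect_equal(intraSlice(fitp), intraSlice(fit)[perm, perm],
               tolerance = 1e-2)
  expect_equal(interSlice(fitp), interSlice(fit)[perm, perm],
               tolerance = 1e-2)
  expect_identical(abs(intraSlice(fitp)) > 0.3,
                   abs(intraSlice(fit)[perm, perm]) > 0.3)
})

test_that("rule extraction thresholds and collapses lags as stated", {
  d <- 3
  A <- matrix(0, d, d); A[1, 2] <- 0.9
  m <- new("SVARModel", W = matrix(0, d, d), A = A, p = 1L,
           concepts = 1:3, labels = paste0("c", 1:3),
           lambdaW = 0, lambdaA = 0, threshold = 0.3, converged = TRUE,
           h = 0, trace = data.frame())
  ed <- ruleEdges(svarToRules(m))
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$antecedent, 1L)
  expect_equal(ed$consequent, 2L)
  expect_equal(ed$weight, 0.9)
  expect_equal(ed$provenance, "dynotears-inter")

  m0 <- new("SVARModel", W = matrix(0.1, d, d) - diag(0.1, d),
            A = matrix(0.2, d, d), p = 1L, concepts = 1:3,
            labels = paste0("c", 1:3), lambdaW = 0, lambdaA = 0,
            threshold = 0.3, converged = TRUE, h = 0, trace = data.frame())
  expect_equal(nrow(ruleEdges(svarToRules(m0))), 0L)

  A2 <- matrix(0, 2 * d, d)
  A2[1, 2] <- 0.5            # lag 1: 1 -> 2
  A2[d + 1, 2] <- -0.7       # lag 2: 1 -> 2
  m2 <- new("SVARModel", W = matrix(0, d, d), A = A2, p = 2L,
            concepts = 1:3, labels = paste0("c", 1:3),
            lambdaW = 0, lambdaA = 0, threshold = 0.3, converged = TRUE,
            h = 0, trace = data.frame())
  ed2 <- ruleEdges(svarToRules(m2))
  expect_equal(nrow(ed2), 1L)
  expect_equal(ed2$weight, 0.7)
})

test_that("intra-slice edges carry their own provenance", {
  d <- 3
  W <- matrix(0, d, d); W[2, 3] <- 0.8
  m <- new("SVARModel", W = W, A = matrix(0, d, d), p = 1L,
           concepts = 1:3, labels = paste0("c", 1:3),
           lambdaW = 0, lambdaA = 0, threshold = 0.3, converged = TRUE,
           h = 0, trace = data.frame())
  ed <- ruleEdges(svarToRules(m))
  expect_equal(ed$provenance, "dynotears-intra")
})

test_that("structural Hamming distance counts reversals once", {
  W1 <- matrix(0, 3, 3); W1[1, 2] <- 1
  W2 <- matrix(0, 3, 3); W2[2, 1] <- 1
  expect_equal(structuralHammingDistance(W1, W1), 0L)
  expect_equal(structuralHammingDistance(W1, W2), 1L)
  W3 <- matrix(0, 3, 3)
  expect_equal(structuralHammingDistance(W1, W3), 1L)
})
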