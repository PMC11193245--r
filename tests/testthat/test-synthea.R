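# Rule graph -> Synthea module mapping, validation, and sampling

test_that("rule weights normalize into distributed transitions", {
  g <- edgeListGraph(
    antecedent = c(START_ID, 1L, 1L, 2L, 3L),
    consequent = c(1L, 2L, 3L, STOP_ID, STOP_ID),
    weight = c(1.0, 0.4, 0.2, 1.0, 1.0))
  mod <- rulesToModule(g, "toy")
  expect_length(validateModule(mod), 0L)
  st <- moduleStates(mod)
  init <- st$Initial$distributed_transition
  expect_equal(init[[1]]$distribution, 1)
  a <- st[["c1"]]$distributed_transition
  probs <- sapply(a, `[[`, "distribution")
  targets <- sapply(a, `[[`, "transition")
  expect_equal(sort(probs), sort(c(0.4 / 0.6, 0.2 / 0.6)), tolerance = 1e-6)
  expect_setequal(targets, c("c2", "c3"))
})

test_that("unreachable states are pruned with a warning", {
  g <- edgeListGraph(
    antecedent = c(START_ID, 1L, 4L),
    consequent = c(1L, STOP_ID, 5L),
    weight = c(1, 1, 1))
  expect_warning(mod <- rulesToModule(g, "pruned"), "unreachable")
  expect_false("c4" %in% names(moduleStates(mod)))
  expect_length(validateModule(mod), 0L)
})

test_that("a single entry rule yields the minimal valid module", {
  g <- edgeListGraph(START_ID, 1L, 1)
  mod <- rulesToModule(g, "minimal")
  expect_setequal(names(moduleStates(mod)), c("Initial", "c1", "Terminal"))
  for (nm in setdiff(names(moduleStates(mod)), "Terminal")) {
    p <- sapply(moduleStates(mod)[[nm]]$distributed_transition,
                `[[`, "distribution")
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("graphs without an entry distribution or with bad weights error", {
  g <- edgeListGraph(1L, 2L, 1)
  expect_error(rulesToModule(g), "no entry distribution")
  gneg <- edgeListGraph(c(START_ID, 1L), c(1L, 2L), c(1, -0.5))
  expect_error(rulesToModule(gneg), "negative")
})

test_that("validation pinpoints corrupted distributions and ghost targets", {
  g <- edgeListGraph(c(START_ID, 1L), c(1L, STOP_ID), c(1, 1))
  doc <- list(name = "x", states = moduleStates(rulesToModule(g, "x")))
  doc$states$c1$distributed_transition[[1]]$distribution <- 0.9
  v <- validateModule(doc)
  expect_length(v, 1L)
  expect_match(v, "c1")
  doc2 <- list(name = "x", states = moduleStates(rulesToModule(g, "x")))
  doc2$states$c1$distributed_transition[[1]]$transition <- "Ghost"
  v2 <- validateModule(doc2)
  expect_length(v2, 1L)
  expect_match(v2, "Ghost")
  expect_error(validateModule(list(a = 1)), "parseable")
})

test_that("duplicate labels and reserved names are deduplicated", {
  edges <- data.frame(
    antecedent = c(START_ID, 1L, 2L),
    consequent = c(1L, 2L, STOP_ID),
    weight = 1, seq_sup = NA_real_, seq_conf = NA_real_,
    provenance = "fixture", self_loop = FALSE, stringsAsFactors = FALSE)
  nodes <- data.frame(concept_id = c(START_ID, 1L, 2L, STOP_ID),
                      label = c("START", "Terminal", "Terminal", "STOP"),
                      stringsAsFactors = FALSE)
  g <- new("RuleGraph", nodes = nodes, edges = edges,
           algorithm = "fixture", datasetTag = "")
  mod <- rulesToModule(g, "dedup")
  expect_length(validateModule(mod), 0L)
  expect_setequal(names(moduleStates(mod)),
                  c("Initial", "Terminal_1", "Terminal_2", "Terminal"))
})

test_that("sampling a deterministic chain always yields the same walk", {
  g <- edgeListGraph(c(START_ID, 1L), c(1L, STOP_ID), c(1, 1))
  mod <- rulesToModule(g, "chain")
  ds <- sampleModule(mod, 20, seed = 1)
  expect_true(all(vapply(sequences(ds), identical,
                         logical(1), c(START_ID, 1L, STOP_ID))))
})

test_that("sampled branch frequencies match the distribution", {
  g <- edgeListGraph(
    antecedent = c(START_ID, 1L, 1L, 2L, 3L),
    consequent = c(1L, 2L, 3L, STOP_ID, STOP_ID),
    weight = c(1, 0.75, 0.25, 1, 1))
  mod <- rulesToModule(g, "branch")
  ds <- sampleModule(mod, 10000, seed = 99)
  frac_b <- mean(vapply(sequences(ds), function(s) 2L %in% s, logical(1)))
  expect_lt(abs(frac_b - 0.75), 0.02)
  ds2 <- sampleModule(mod, 10000, seed = 99)
  expect_identical(sequences(ds2), sequences(ds))
})

test_that("sampling refuses invalid modules", {
  g <- edgeListGraph(c(START_ID, 1L), c(1L, STOP_ID), c(1, 1))
  mod <- rulesToModule(g, "x")
  broken <- moduleStates(mod)
  broken$c1$distributed_transition[[1]]$distribution <- 0.5
  fake <- mod
  fake@states <- broken
  expect_error(sampleModule(fake, 5, seed = 1), "invalid module")
})

test_that("module JSON round-trips through write/read", {
  g <- edgeListGraph(
    antecedent = c(START_ID, 1L, 1L, 2L, 3L),
    consequent = c(1L, 2L, 3L, STOP_ID, STOP_ID),
    weight = c(1, 0.6, 0.4, 1, 1))
  mod <- rulesToModule(g, "roundtrip")
  f <- tempfile(fileext = ".json")
  writeSyntheaModule(mod, f)
  mod2 <- readSyntheaModule(f)
  expect_equal(moduleName(mod2), "roundtrip")
  expect_length(validateModule(mod2), 0L)
  expect_equal(names(moduleStates(mod2)), names(moduleStates(mod)))
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(doc$states$Initial$type, "Initial")
})
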