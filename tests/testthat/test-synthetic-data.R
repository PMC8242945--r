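test_that("design emulates the clone structure and dropout cells", {
  d23 <- simulateDesign(6, data.frame(individual_id = "LPS_01",
                                      treatment = "LPS",
                                      timepoint = "t6h"))
  expect_equal(nrow(d23), 23)
  expect_equal(sum(d23$treatment == "LPS" & d23$timepoint == "t6h"), 5)

  expect_equal(nrow(simulateDesign(2)), 8)

  d24 <- simulateDesign(6)
  expect_equal(nrow(d24), 24)
  expect_true(all(table(d24$individual_id) == 2))
  # individuals never appear in both treatments
  expect_true(all(table(d24$individual_id,
                        d24$treatment) %in% c(0L, 2L)))
  # uniqueness of (individual, treatment, timepoint)
  expect_false(anyDuplicated(
    d24[, c("individual_id", "treatment", "timepoint")]) > 0)
})

test_that("design errors when dropout empties a treatment x timepoint cell", {
  drop <- data.frame(individual_id = c("LPS_01", "LPS_02"),
                     treatment = "LPS", timepoint = "t6h")
  expect_error(simulateDesign(2, drop), "LPS x t6h")
  expect_error(simulateDesign(6, data.frame(individual_id = "nope",
                                            treatment = "LPS",
                                            timepoint = "t6h")),
               "not in design")
})

test_that("config validity enforces the stated invariants", {
  expect_error(SimulationConfig(fracConstitutive = 0.5,
                                fracIndividualSpecific = 0.5,
                                fracNeverExpressed = 0.1),
               "sum to 1")
  expect_error(SimulationConfig(dispersion = -1), "dispersion")
  expect_error(SimulationConfig(nGenes = 100, nResponsive = 200),
               "nResponsive")
  expect_error(SimulationConfig(responderPenetrance = 1.5), "\\[0, 1\\]")
  # penetrance vector must match nResponsive
  expect_error(SimulationConfig(nResponsive = 4,
                                responderPenetrance = c(0.5, 1, 0.5)),
               "length")
  expect_s4_class(SimulationConfig(nResponsive = 4,
                                   responderPenetrance = c(.5, 1, .5, 1)),
                  "SimulationConfig")
})

test_that("planted structure is realized in the counts", {
  cfg <- SimulationConfig(nGenes = 1000, nResponsive = 50, seed = 1,
                          dispersion = 0, effectLog2FC = 0)
  ex <- simulateCounts(cfg)
  counts <- countsMatrix(ex)
  truth <- truthTable(ex)

  # silent genes are exact all-zero rows
  never <- truth$layer == "not_expressed"
  expect_true(all(counts[never, ] == 0))

  # Poisson limit: sample mean of a constitutive gene within 3 SE of mu
  cIdx <- which(truth$layer == "constitutive")[1:50]
  mu <- truth$baseline_mu[cIdx]
  se <- sqrt(mu / ncol(counts))
  expect_true(mean(abs(rowMeans(counts[cIdx, ]) - mu) <= 3 * se) > 0.95)

  # all-positive-row fraction near the planted constitutive fraction,
  # and exactly consistent with the truth table by brute-force scan
  allPos <- rownames(counts)[rowSums(counts > 0) == ncol(counts)]
  expect_equal(length(allPos) / nrow(counts), 0.4, tolerance = 0.05)
  expect_true(all(truth$layer[match(allPos, truth$gene_id)] ==
                    "constitutive"))

  # structural zeros: non-carrier individuals have zero counts
  des <- designTable(ex)
  isIdx <- which(truth$layer == "individual_specific")[1:100]
  for (g in isIdx) {
    carriers <- strsplit(truth$carrier_individuals[g], ",")[[1]]
    out <- des$sample_id[!des$individual_id %in% carriers]
    expect_true(all(counts[g, out] == 0))
  }

  # responder sets are LPS individuals only
  resp <- truth[truth$is_responsive, ]
  lpsInd <- unique(des$individual_id[des$treatment == "LPS"])
  responders <- unlist(strsplit(resp$responder_individuals, ","))
  expect_true(all(responders %in% lpsInd))
})

test_that("planted fold change shifts LPS responder means", {
  cfg <- SimulationConfig(nGenes = 400, nResponsive = 40, seed = 5,
                          dispersion = 0, effectLog2FC = 3,
                          fracDown = 0)
  ex <- simulateCounts(cfg)
  truth <- truthTable(ex)
  des <- designTable(ex)
  counts <- countsMatrix(ex)
  g <- which(truth$is_responsive)
  responders <- strsplit(truth$responder_individuals[g], ",")
  lps <- vapply(seq_along(g), function(i)
    mean(counts[g[i], des$sample_id[des$individual_id %in%
                                      responders[[i]]]]), 0)
  ctl <- rowMeans(counts[g, des$sample_id[des$treatment == "control"],
                         drop = FALSE])
  expect_equal(median(log2(lps / ctl)), 3, tolerance = 0.2)
})

test_that("identical config and seed give byte-identical output", {
  cfg <- SimulationConfig(nGenes = 300, nResponsive = 20, seed = 9)
  a <- simulateCounts(cfg)
  b <- simulateCounts(cfg)
  expect_identical(countsMatrix(a), countsMatrix(b))
  expect_identical(truthTable(a), truthTable(b))
  ann1 <- simulateAnnotations(10L, seed = 3)
  ann2 <- simulateAnnotations(10L, seed = 3)
  expect_identical(ann1, ann2)
})

test_that("planted annotations round-trip through the rule engine", {
  ann <- simulateAnnotations(50L, seed = 7)
  scr <- screenTranscriptome(ann$domains, ann$flags)
  called <- scr$calls$family[match(ann$truth$transcript_id,
                                   scr$calls$transcript_id)]
  expect_identical(called, ann$truth$family)
  expect_true(all(scr$tally[setdiff(names(scr$tally), "none")] == 50))
})

test_that("config YAML round-trips including penetrance vectors", {
  cfg <- SimulationConfig(nGenes = 100, nResponsive = 4,
                          responderPenetrance = c(1/3, 1, 1/3, 1),
                          dropoutSamples = NULL)
  path <- tempfile(fileext = ".yaml")
  writeSimulationConfig(cfg, path)
  back <- readSimulationConfig(path)
  for (s in slotNames("SimulationConfig"))
    expect_equal(slot(back, s), slot(cfg, s), info = s)
})
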