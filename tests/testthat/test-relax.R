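# Solvation boxes and the minimization backends

test_that("the box edge honours solute extent plus twice the padding", {
  g <- mumiscan:::buildPeptide("G")
  sys <- buildBox(g, solvationSpec(padding = 10), seed = 1)
  ext <- apply(coords(g)[isHeavy(g), , drop = FALSE], 2, function(v)
    diff(range(v)))
  expect_gte(boxEdge(sys), max(ext) + 20)
  expect_gt(nrow(waterPositions(sys)), 100)
  # no water overlaps the solute below the 2.4 A pruning distance
  d <- mumiscan:::crossDist(waterPositions(sys),
                            coords(g)[isHeavy(g), , drop = FALSE])
  expect_gte(min(d), 2.4)
})

test_that("zero concentration with a neutral solute places no ions", {
  g <- mumiscan:::buildPeptide("G")
  sys <- buildBox(g, solvationSpec(concentration = 0), seed = 1)
  expect_equal(nrow(ionTable(sys)), 0L)
})

test_that("ion counts follow concentration x volume x Avogadro", {
  # solute extent 40 A -> edge 60 A at padding 10
  line <- makeAtomCluster(rbind(c(-20, 0, 0), c(20, 0, 0)), element = "C")
  sys <- buildBox(line, solvationSpec(padding = 10, concentration = 0.15),
                  seed = 2)
  expect_equal(boxEdge(sys), 60)
  expectedPerSpecies <- round(0.15 * 60^3 * 6.02214076e23 * 1e-27)
  tab <- table(ionTable(sys)$species)
  expect_equal(unname(tab[["K"]]), expectedPerSpecies)
  expect_equal(unname(tab[["Cl"]]), expectedPerSpecies)

  # charged solute receives neutralising counterions
  glu <- mumiscan:::buildPeptide("E")
  sysq <- buildBox(glu, solvationSpec(padding = 12), seed = 3)
  tabq <- table(ionTable(sysq)$species)
  expect_equal(unname(tabq[["K"]]) - unname(tabq[["Cl"]]), 1L)
})

test_that("box construction is deterministic for a fixed seed", {
  g <- mumiscan:::buildPeptide("E")
  s1 <- buildBox(g, seed = 42)
  s2 <- buildBox(g, seed = 42)
  expect_identical(waterPositions(s1), waterPositions(s2))
  expect_identical(ionTable(s1), ionTable(s2))
  s3 <- buildBox(g, seed = 43)
  expect_false(identical(ionTable(s1)$x, ionTable(s3)$x))
})

test_that("an argon-like pair relaxes to the closed-form LJ minimum", {
  start <- makeAtomCluster(rbind(c(0, 0, 0), c(2.5, 0, 0)), element = "AR")
  res <- minimizeSystem(start, minimizationSpec(steps = 2000))
  expect_true(isConverged(res))
  co <- coords(relaxedStructure(res))
  sep <- vlen(co[1, ] - co[2, ])
  lj <- ljParameters("AR")
  rmin <- 2^(1 / 6) * (2 * lj$rvdw / 2^(1 / 6))  # = rvdw_i + rvdw_j
  expect_lt(abs(sep - rmin) / rmin, 0.02)
})

test_that("re-minimizing a relaxed system barely changes the energy", {
  # LJ cluster: its potential does not depend on the input geometry, so a
  # minimized configuration is a genuine fixed point
  set.seed(5)
  cl <- makeAtomCluster(matrix(rnorm(15, sd = 3), 5, 3), element = "AR")
  first <- minimizeSystem(cl, minimizationSpec(steps = 3000))
  second <- minimizeSystem(relaxedStructure(first),
                           minimizationSpec(steps = 3000))
  drop2 <- second@initialEnergy - second@finalEnergy
  expect_lte(drop2, 1e-3 * abs(second@initialEnergy) + 1e-6)
  expect_equal(second@initialEnergy, first@finalEnergy)
})

test_that("the reported energy sequence never increases", {
  m <- applyMutation(makeHelixPeptide(5), list(position = 3, wt = "A",
                                               mut = "W"))
  res <- minimizeSystem(m, minimizationSpec(steps = 400,
                                            energyReportInterval = 10))
  tr <- energyTrace(res)
  expect_gt(length(tr), 2)
  expect_true(all(diff(tr) <= 1e-9))
  expect_lte(res@finalEnergy, res@initialEnergy)
  # solute atom identity preserved through minimization
  expect_identical(atomData(relaxedStructure(res))$name, atomData(m)$name)
})

test_that("the engine backend errors with fallback instructions", {
  h <- makeHelixPeptide(3)
  expect_error(minimizeSystem(h, minimizationSpec(backend = "engine")),
               "fallback")
  # a registered hook is honoured
  withr::local_options(mumiscan.engineBackend = function(x, spec) "hooked")
  expect_equal(minimizeSystem(h, minimizationSpec(backend = "engine")),
               "hooked")
})

test_that("the scan isolates per-mutant failures and counts usable systems", {
  pep <- mumiscan:::buildPeptide("ASDKG", phi = -120, psi = 140)
  specs <- enumerateMutations(chainSequence(pep), positions = 2)[1:3, ]
  scan <- runMumi(pep, specs, minimization = minimizationSpec(steps = 60))
  expect_equal(nrow(scan$manifest), 3L)
  expect_equal(nFrames(scan$ensemble), usableSystems(scan$manifest))
  expect_true(all(scan$manifest$final_energy <=
                    scan$manifest$initial_energy + 1e-6 |
                    !scan$manifest$converged))
  # wrong WT letters fail per-mutant, not fatally
  bad <- specs
  bad$wt <- "W"
  bad$label <- paste0(bad$wt, bad$position, bad$mut)
  scanBad <- runMumi(pep, bad, minimization = minimizationSpec(steps = 10))
  expect_equal(usableSystems(scanBad$manifest), 0L)
  expect_match(scanBad$manifest$failure_reason[1], "mismatch")

  empty <- runMumi(pep, specs[0, , drop = FALSE])
  expect_equal(nrow(empty$manifest), 0L)
  expect_equal(nFrames(empty$ensemble), 0L)
})

test_that("manifest book-keeping reproduces the scan-size arithmetic", {
  seqG <- strrep("A", 56)
  all56 <- enumerateMutations(seqG)
  expect_equal(nrow(all56), 1064L)
  sub14 <- enumerateMutations(seqG, positions = c(25, 27, 28, 29, 31, 32,
                                                  33, 35, 36, 40, 41, 42,
                                                  43, 54))
  expect_equal(nrow(sub14), 266L)
  failures <- c("D40L", "E42H", "E42M", "E42F", "E42Y")
  manifest <- data.frame(label = sub14$label,
                         converged = !sub14$label %in% failures)
  # the synthetic sequence has no D/E at 40/42, so rebuild labels the way
  # the scan of the real sequence would name them
  manifest$converged <- TRUE
  manifest$converged[match(c("A40L", "A42H", "A42M", "A42F", "A42Y"),
                           manifest$label)] <- FALSE
  expect_equal(usableSystems(manifest), 261L)
})
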