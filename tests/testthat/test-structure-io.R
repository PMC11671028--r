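# PDB reading/writing, complex splitting and heavy-atom RMSD

test_that("write/read round trip is coordinate-stable to 0.001 A", {
  h <- makeHelixPeptide(5, sequence = "ASDKW")
  path <- withr::local_tempfile(fileext = ".pdb")
  writePdb(h, path)
  back <- readPdb(path)
  expect_equal(nAtoms(back), nAtoms(h))
  expect_equal(atomData(back)$name, atomData(h)$name)
  expect_equal(atomData(back)$chain, atomData(h)$chain)
  expect_lt(max(abs(coords(back) - coords(h))), 1e-3 + 1e-9)
  expect_equal(nrow(residueTable(back)), 5L)
})

test_that("chain ordering and het flags survive a round trip", {
  td <- standard_toy_dimer()$structure
  path <- withr::local_tempfile(fileext = ".pdb")
  writePdb(td, path)
  back <- readPdb(path)
  expect_equal(chains(back), c("A", "B"))
  expect_equal(atomData(back)$resname, atomData(td)$resname)
})

test_that("multi-model ensembles write as MODEL blocks and reparse", {
  h <- makeHelixPeptide(4)
  ens <- makeJitterEnsemble(h, sigma = 0.2, nFrames = 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  writePdb(ens, path)
  back <- readPdbEnsemble(path)
  expect_equal(nFrames(back), 3L)
  expect_s4_class(back, "StructureEnsemble")
  expect_equal(ensembleSource(back), "multi-model-pdb")
  # model selection picks the right coordinates
  m2 <- readPdb(path, model = 2)
  expect_lt(max(abs(coords(m2) - coords(frames(ens)[[2]]))), 1e-3 + 1e-9)
  expect_error(readPdb(path, model = 7), "model")
})

test_that("alternate locations resolve to highest occupancy, ties first", {
  lines <- c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   SER A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   SER A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB ASER A   1       2.000  -1.000   1.000  0.60  0.00           C",
    "ATOM      6  CB BSER A   1       2.000  -1.000  -1.000  0.40  0.00           C",
    "ATOM      7  OG ASER A   1       3.000  -2.000   1.000  0.50  0.00           O",
    "ATOM      8  OG BSER A   1       3.000  -2.000  -1.000  0.50  0.00           O",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- readPdb(path)
  a <- atomData(s)
  expect_equal(sum(a$name == "CB"), 1L)
  expect_equal(coords(s)[a$name == "CB", 3], 1.0)   # occupancy 0.6 wins
  expect_equal(coords(s)[a$name == "OG", 3], 1.0)   # tie -> first listed
})

test_that("insertion codes are rejected and missing backbone flagged", {
  ins <- c(
    "ATOM      1  N   ALA A   1A      0.000   0.000   0.000  1.00  0.00           N",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(ins, path)
  expect_error(readPdb(path), "insertion codes")

  frag <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(frag, path)
  expect_warning(s <- readPdb(path), "incomplete backbone")
  expect_true(all(atomData(s)$flag))
})

test_that("splitComplex partitions solute atoms and validates chains", {
  td <- standard_toy_dimer()$structure
  parts <- splitComplex(td, "A")
  expect_equal(nAtoms(parts$focal) + nAtoms(parts$partner), nAtoms(td))
  expect_equal(chains(parts$focal), "A")
  expect_equal(chains(parts$partner), "B")
  expect_error(splitComplex(td, c("A", "B")), "partner is empty")
  expect_error(splitComplex(td, "Q"), "available chains")
})

test_that("splitComplex reproduces the 56/206-residue partition shape", {
  # synthetic stand-in with the residue counts of a small binder bound to
  # a larger partner domain
  big <- mumiscan:::.rbindStructures(
    makeHelixPeptide(56, chain = "G"),
    rigid_move(makeHelixPeptide(206, chain = "F"), t = c(60, 0, 0)))
  parts <- splitComplex(big, "G")
  expect_equal(nrow(residueTable(parts$focal)), 56L)
  expect_equal(nrow(residueTable(parts$partner)), 206L)
})

test_that("rmsdHeavy handles identity, translation and symmetry", {
  h <- makeHelixPeptide(6, sequence = "ADSKWA")
  expect_equal(rmsdHeavy(h, h), 0)
  h2 <- rigid_move(h, t = c(3, 0, 0))
  expect_equal(rmsdHeavy(h, h2), 3, tolerance = 1e-10)
  expect_equal(rmsdHeavy(h, h2), rmsdHeavy(h2, h))
  expect_lte(rmsdHeavy(h, h2, superpose = TRUE), rmsdHeavy(h, h2))
  expect_lt(rmsdHeavy(h, h2, superpose = TRUE), 1e-8)
})

test_that("superposed RMSD matches a brute-force rotation-sampling oracle", {
  set.seed(42)
  co <- matrix(rnorm(30, sd = 3), 10, 3)
  a <- makeAtomCluster(co)
  b <- makeAtomCluster(co %*% t(random_rotation()) +
                         matrix(rnorm(30, sd = 0.3), 10, 3))
  fitted <- rmsdHeavy(a, b, superpose = TRUE)
  # oracle: centered coordinates, sampled quaternion rotations with a
  # local random-restart refinement around the incumbent
  ca <- sweep(co, 2, colMeans(co))
  cb0 <- sweep(coords(b), 2, colMeans(coords(b)))
  score <- function(R) sqrt(mean(rowSums((ca - cb0 %*% t(R))^2)))
  best <- Inf
  bestR <- diag(3)
  for (k in 1:2000) {
    R <- random_rotation()
    s <- score(R)
    if (s < best) {
      best <- s
      bestR <- R
    }
  }
  for (step in c(0.2, 0.05, 0.01)) {
    for (k in 1:800) {
      ax <- rnorm(3)
      R <- mumiscan:::rotationMatrix(ax, step * 57.3 * rnorm(1)) %*% bestR
      s <- score(R)
      if (s < best) {
        best <- s
        bestR <- R
      }
    }
  }
  expect_lte(fitted, best + 1e-9)        # optimal fit beats any sample
  expect_lt(abs(fitted - best), 0.02)    # and the refined search gets close
})

test_that("rmsdHeavy names the first unpaired atom on mismatch", {
  h <- makeHelixPeptide(4)
  m <- applyMutation(h, list(position = 2, wt = "A", mut = "V"))
  expect_error(rmsdHeavy(h, m), "no counterpart")
})

test_that("atom-count limit of the PDB format is enforced", {
  big <- makeAtomCluster(matrix(seq_len(3e5), ncol = 3))
  expect_error(writePdb(big, withr::local_tempfile(fileext = ".pdb")),
               "format limit")
})
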