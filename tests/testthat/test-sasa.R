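# Shrake-Rupley SASA, RSA normalisation and ensemble statistics

test_that("an isolated sphere matches the analytic area within 1 percent", {
  one <- makeAtomCluster(rbind(c(0, 0, 0)), element = "C")
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(sasaTotal(one), analytic, tolerance = 0.01)
  # additivity at infinity
  two <- makeAtomCluster(rbind(c(0, 0, 0), c(100, 0, 0)), element = "C")
  expect_equal(sasaTotal(two), 2 * analytic, tolerance = 0.01)
})

test_that("a caged atom has zero accessible area", {
  # 26 neighbours on the unit-cube directions at 2.0 A
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  cage <- 2.0 * dirs / sqrt(rowSums(dirs^2))
  cl <- makeAtomCluster(rbind(c(0, 0, 0), cage), element = "C")
  areas <- sasaAtoms(cl)
  expect_equal(areas[1], 0)
  # dense-point brute-force oracle for the caged atom: every direction on
  # a fine independent grid is inside some neighbour's expanded sphere
  nphi <- 60
  free <- 0L
  for (i in seq_len(nphi)) {
    for (j in seq_len(nphi)) {
      th <- pi * (i - 0.5) / nphi
      ph <- 2 * pi * (j - 0.5) / nphi
      p <- 3.1 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      buried <- FALSE
      for (k in seq_len(nrow(cage))) {
        if (vlen(p - cage[k, ]) < 3.1) {
          buried <- TRUE
          break
        }
      }
      if (!buried) free <- free + 1L
    }
  }
  expect_equal(free, 0L)
})

test_that("doubling the point count changes the total by < 0.5 percent", {
  h <- makeHelixPeptide(8, sequence = "AKWDESTA")
  t1 <- sasaTotal(h, sasaSpec(nSpherePoints = 960))
  t2 <- sasaTotal(h, sasaSpec(nSpherePoints = 1920))
  expect_lt(abs(t2 - t1) / t1, 0.005)
})

test_that("total SASA is invariant under rigid motion", {
  set.seed(31)
  h <- makeHelixPeptide(6, sequence = "AKWDES")
  t0 <- sasaTotal(h)
  # translation: exact (the point set moves with each atom)
  shifted <- rigid_move(h, t = c(13, -4, 7))
  expect_equal(sasaTotal(shifted), t0, tolerance = 1e-9)
  # rotation: within the point-set discretization error
  rotated <- rigid_move(h, random_rotation())
  expect_lt(abs(sasaTotal(rotated) - t0) / t0, 0.005)
})

test_that("complex SASA is bounded by the sum of its parts", {
  td <- standard_toy_dimer()$structure
  parts <- splitComplex(td, "A")
  whole <- sasaTotal(td)
  apart <- sasaTotal(parts$focal) + sasaTotal(parts$partner)
  expect_lte(whole, apart + 1e-6)
  # with real interface contact, strictly less
  expect_lt(whole, apart)
  # and with chains far apart, equality
  far <- td
  a <- atomData(far)
  co <- coords(far)
  co[a$chain == "B", ] <- co[a$chain == "B", ] + 200
  coords(far) <- co
  expect_equal(sasaTotal(far), apart, tolerance = 1e-6)
})

test_that("unknown elements are rejected by name", {
  bad <- makeAtomCluster(rbind(c(0, 0, 0)), element = "XX")
  expect_error(sasaAtoms(bad), "XX")
})

test_that("RSA is near its reference maximum for an exposed residue and tiny in a core", {
  # extended tripeptide, central alanine close to the reference state
  ext <- mumiscan:::buildPeptide("GAG", phi = -120, psi = 140)
  prof <- rsa(ext)
  expect_gt(prof$rsa[prof$resname == "ALA"], 60)
  expect_true(all(prof$rsa >= 0))

  # bury a single alanine inside a tight pseudo-atom shell
  ala <- mumiscan:::buildPeptide("A")
  center <- colMeans(coords(ala))
  dirs <- mumiscan:::goldenSpiralPoints(80) * 4.5
  shell <- makeAtomCluster(sweep(dirs, 2, center, "+"), element = "C")
  buried <- mumiscan:::.rbindStructures(ala, shell)
  bprof <- rsa(buried)
  expect_lt(bprof$rsa[1], 5)
  # nonstandard shell residues are excluded from the profile
  expect_equal(nrow(bprof), 1L)
})

test_that("deltaRsa signs distinguish interface from distal residues", {
  prof <- rsa(makeHelixPeptide(6, sequence = "AKDEST"))
  zero <- deltaRsa(prof, prof)
  expect_true(all(zero$delta == 0))

  td <- standard_toy_dimer()$structure
  parts <- splitComplex(td, "A")
  bound <- rsa(td)
  bound <- bound[bound$chain == "A", ]
  unbound <- rsa(parts$focal)
  d <- deltaRsa(unbound, bound)
  expect_true(all(d$delta <= 1e-9))   # burial only upon binding
  expect_true(any(d$delta < -1))      # interface residues lose exposure
  expect_error(deltaRsa(unbound, bound[-1, ]), "mismatch")
})

test_that("ensemble RSA statistics match hand calculations", {
  h <- makeHelixPeptide(4)
  same <- newEnsemble(list(h, h, h), source = "trajectory")
  st <- ensembleRsaStats(same)
  expect_true(all(st$sd_rsa == 0))

  f1 <- h
  f2 <- rigid_move(h, t = c(50, 0, 0))  # same RSA, sanity of pairing
  two <- newEnsemble(list(f1, f2), source = "trajectory")
  st2 <- ensembleRsaStats(two)
  p1 <- rsa(f1)$rsa
  expect_equal(st2$mean_rsa, p1, tolerance = 1e-9)

  expect_error(ensembleRsaStats(newEnsemble(list(h), "trajectory")),
               "at least 2")
})

test_that("jittered-ensemble mean RSA stays near the base value", {
  h <- makeHelixPeptide(5)
  ens <- makeJitterEnsemble(h, sigma = 0.05, nFrames = 12, seed = 9)
  st <- ensembleRsaStats(ens)
  base <- rsa(h)$rsa
  tol <- 3 * pmax(st$sd_rsa, 1) / sqrt(st$n)
  expect_true(all(abs(st$mean_rsa - base) < tol + 2))
})

test_that("RSA-statistics comparison reports R-squared correctly", {
  h <- makeHelixPeptide(8, sequence = "AKWDESTA")
  ens <- makeJitterEnsemble(h, sigma = 0.15, nFrames = 6, seed = 21)
  st <- ensembleRsaStats(ens)
  self <- compareRsaStats(st, st, allosteric = c(2, 5), binding = 3)
  expect_equal(self$r2_mean, 1)
  expect_equal(self$r2_sd, 1)
  expect_equal(self$table$annotation[self$table$resno == 2], "allosteric")
  expect_equal(self$table$annotation[self$table$resno == 3], "binding")

  # noiseless linear relation has R^2 = 1
  stb <- st
  stb$mean_rsa <- 2 * st$mean_rsa + 5
  expect_equal(compareRsaStats(st, stb)$r2_mean, 1)

  # permutation destroys pairing (large n, random values)
  set.seed(77)
  big <- data.frame(chain = "A", resno = 1:200, mean_rsa = runif(200, 0, 100),
                    sd_rsa = runif(200, 0, 10), n = 5)
  perm <- big
  perm$mean_rsa <- sample(big$mean_rsa)
  perm$sd_rsa <- sample(big$sd_rsa)
  expect_lt(compareRsaStats(big, perm)$r2_mean, 0.05)
})
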