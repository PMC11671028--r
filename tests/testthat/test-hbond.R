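# Polar-hydrogen construction and geometric hydrogen-bond analysis

test_that("backbone amide hydrogen sits 1.01 A from N in the C-N-CA plane", {
  h <- addPolarHydrogens(makeHelixPeptide(4))
  a <- atomData(h)
  co <- coords(h)
  g <- function(r, nm) co[which(a$resno == r & a$name == nm)[1], ]
  H <- g(2, "H")
  N <- g(2, "N")
  expect_equal(vlen(H - N), 1.01, tolerance = 1e-6)
  # coplanarity with C(prev), N, CA
  v1 <- g(1, "C") - N
  v2 <- g(2, "CA") - N
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  expect_lt(abs(sum((H - N) * nrm / vlen(nrm))), 1e-6)
})

test_that("protonation is idempotent and skips nonstandard residues", {
  h <- addPolarHydrogens(makeHelixPeptide(5, sequence = "SKNQW"))
  again <- addPolarHydrogens(h)
  expect_equal(nAtoms(again), nAtoms(h))
  expect_identical(coords(again), coords(h))
  odd <- rigid_move(mumiscan:::buildPeptide("A", chain = "Z"),
                    t = c(30, 0, 0))
  odd@atoms$resname <- "UNK"
  mix <- mumiscan:::.rbindStructures(makeHelixPeptide(3), odd)
  expect_warning(addPolarHydrogens(mix), "nonstandard")
})

test_that("serine hydroxyl hydrogen points toward the nearest acceptor", {
  # serine flanked by two carboxylates at different distances
  td <- makeToyDimer(data.frame(donor = c("S"), acceptor = c("D"),
                                distance = 2.8, angle = 0))
  a <- atomData(td$structure)
  co <- coords(td$structure)
  OG <- co[which(a$name == "OG")[1], ]
  HG <- co[which(a$name == "HG")[1], ]
  OD1 <- co[which(a$name == "OD1" & a$chain == "B")[1], ]
  OD2 <- co[which(a$name == "OD2" & a$chain == "B")[1], ]
  nearest <- if (vlen(OG - OD1) < vlen(OG - OD2)) OD1 else OD2
  # H on the acceptor side of the cone: closer to the nearest acceptor
  # than any alternative dihedral placement by construction
  expect_lt(vlen(HG - nearest), vlen(OG - nearest))
  expect_equal(vlen(HG - OG), 0.96, tolerance = 1e-6)
})

test_that("single-geometry detection respects both cutoffs", {
  inb <- makeToyDimer(data.frame(donor = "N", acceptor = "E",
                                 distance = 2.9, angle = 0))
  expect_equal(nrow(detectHBonds(inb$structure, between = list("A", "B"))),
               1L)
  outd <- makeToyDimer(data.frame(donor = "N", acceptor = "E",
                                  distance = 3.05, angle = 0))
  expect_equal(nrow(detectHBonds(outd$structure, between = list("A", "B"))),
               0L)
  outa <- makeToyDimer(data.frame(donor = "N", acceptor = "E",
                                  distance = 2.9, angle = 25))
  expect_equal(nrow(detectHBonds(outa$structure, between = list("A", "B"))),
               0L)
})

test_that("detection equals the brute-force oracle on random fixtures", {
  set.seed(101)
  mism <- 0L
  for (rep in 1:100) {
    s <- random_polar_structure(nres = 5, box = 8)
    if (!identical(detect_hbond_keys(s), oracle_hbond_keys(s)))
      mism <- mism + 1L
  }
  expect_equal(mism, 0L)
})

test_that("detection is invariant under rigid rotation and translation", {
  set.seed(55)
  s <- random_polar_structure(nres = 6, box = 8)
  ref <- detectHBonds(s)
  for (k in 1:5) {
    moved <- rigid_move(s, random_rotation(), rnorm(3, sd = 20))
    got <- detectHBonds(moved)
    expect_equal(got[, 1:11], ref[, 1:11])
    expect_equal(got$distance, ref$distance, tolerance = 1e-9)
    expect_equal(got$angle, ref$angle, tolerance = 1e-6)
  }
})

test_that("occupancy counts frames containing each pair", {
  td <- standard_toy_dimer()
  base <- td$structure
  # break bond 1 (Ser OG donor) in 3 of 10 frames by displacing chain B
  # residue 1 far away
  a <- atomData(base)
  idxB1 <- which(a$chain == "B" & a$resno == 1)
  fr <- lapply(1:10, function(i) {
    s <- base
    if (i <= 3) {
      co <- coords(s)
      co[idxB1, ] <- co[idxB1, ] + 50
      coords(s) <- co
    }
    s
  })
  ens <- newEnsemble(fr, source = "trajectory")
  occ <- hbondOccupancy(ens, between = list("A", "B"))
  expect_true(all(occ$occupancy >= 0 & occ$occupancy <= 1))
  expect_true(all(occ$frames_present <= occ$frames_total))
  o1 <- occ[occ$focal_resno == 1, ]
  expect_equal(o1$occupancy, 0.7)
  expect_equal(o1$frames_present, 7L)
  expect_equal(occ$occupancy[occ$focal_resno == 2], 1)
  expect_error(hbondOccupancy(newEnsemble(list(), "trajectory")), "empty")
})

test_that("occupancy recovers the generator-known bond frequency", {
  td <- makeToyDimer(data.frame(donor = "S", acceptor = "D",
                                distance = 2.75, angle = 8))
  sigma <- 0.25
  n <- 200
  ens <- makeJitterEnsemble(td$structure, sigma = sigma, nFrames = n,
                            seed = 17)
  # generator-side estimate of p: direct Monte-Carlo on the jittered
  # donor/hydrogen/acceptor triplet geometry, independent of detection
  a <- atomData(td$structure)
  co <- coords(td$structure)
  D <- co[which(a$name == "OG")[1], ]
  H <- co[which(a$name == "HG")[1], ]
  A1 <- co[which(a$name == "OD1" & a$chain == "B")[1], ]
  A2 <- co[which(a$name == "OD2" & a$chain == "B")[1], ]
  set.seed(999)
  hitsMC <- 0L
  M <- 20000
  for (k in seq_len(M)) {
    d <- D + rnorm(3, sd = sigma)
    h <- H + rnorm(3, sd = sigma)
    hit <- FALSE
    for (acc in list(A1, A2)) {
      aj <- acc + rnorm(3, sd = sigma)
      if (vlen(d - aj) <= 3.0 && angle_at(h, d, aj) <= 20) hit <- TRUE
    }
    if (hit) hitsMC <- hitsMC + 1L
  }
  p <- hitsMC / M
  occ <- hbondOccupancy(ens, between = list("A", "B"))
  side <- occ[occ$focal_moiety == "side-chain" &
                occ$partner_moiety == "side-chain", ]
  est <- if (nrow(side)) side$occupancy[1] else 0
  expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
})

test_that("dominant-bond filtering applies a strict threshold", {
  occ <- data.frame(occupancy = c(0.39, 0.74, 0.43, 0.59, 0.54, 0.23,
                                  0.38, 0.37, 0.44, 0.12))
  kept <- dominantBonds(occ, 0.20)
  expect_equal(nrow(kept), 9L)
  expect_false(is.unsorted(rev(kept$occupancy)))
  expect_equal(nrow(dominantBonds(occ, 0)), 10L)
  expect_equal(nrow(dominantBonds(data.frame(occupancy = c(1, 0.5)), 1.0)),
               0L)
})

test_that("maintained-bond counting tracks constructed interface bonds", {
  td <- standard_toy_dimer()
  wt <- toy_wt_bonds(td)
  expect_equal(countWtBonds(td$structure, wt, between = toy_between), 3L)

  # breaking exactly one bond by mutating its donor to alanine
  broken <- applyMutation(td$structure,
                          list(position = 1, wt = "S", mut = "A"),
                          chain = "A")
  expect_equal(countWtBonds(broken, wt, between = toy_between), 2L)

  # deleting every donor-side polar atom zeroes the count
  a <- atomData(td$structure)
  keep <- !(a$chain == "A" & a$name %in% c("OG", "HG", "ND2", "HD21",
                                           "HD22", "NE1", "HE1"))
  gutted <- mumiscan:::subsetStructure(td$structure, which(keep))
  expect_equal(countWtBonds(gutted, wt, between = toy_between), 0L)
})

test_that("maintained-bond count is monotone under polar-atom deletion", {
  td <- standard_toy_dimer()
  wt <- toy_wt_bonds(td)
  a <- atomData(td$structure)
  polar <- which(a$chain == "A" &
                   a$name %in% c("OG", "ND2", "NE1"))
  prev <- countWtBonds(td$structure, wt, between = toy_between)
  drop <- integer()
  for (p in polar) {
    drop <- c(drop, p)
    hkill <- which(a$chain == "A" & toupper(a$element) == "H" &
                     a$resno %in% a$resno[drop])
    s <- mumiscan:::subsetStructure(td$structure,
                                    setdiff(seq_len(nrow(a)),
                                            c(drop, hkill)))
    cur <- countWtBonds(s, wt, between = toy_between)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("salt-bridge distances use the side-chain charge-center geometry", {
  # constructed glutamate/lysine pair: carboxylate-O midpoint 3.0 A from NZ
  glu <- mumiscan:::buildPeptide("E", chain = "A")
  a <- atomData(glu)
  co <- coords(glu)
  mid <- (co[a$name == "OE1", ] + co[a$name == "OE2", ]) / 2
  lys <- mumiscan:::buildPeptide("K", chain = "B")
  al <- atomData(lys)
  cl <- coords(lys)
  shift <- (mid + c(3, 0, 0)) - cl[al$name == "NZ", ]
  coords(lys) <- sweep(cl, 2, shift, "+")
  s <- mumiscan:::.rbindStructures(glu, lys)
  expect_equal(saltBridgeDistance(s, list("A", 1), list("B", 1)), 3.0,
               tolerance = 1e-9)

  # swapping the two carboxylate oxygens leaves the distance unchanged
  sw <- s
  asw <- atomData(sw)
  i1 <- which(asw$name == "OE1")
  i2 <- which(asw$name == "OE2")
  cs <- coords(sw)
  cs[c(i1, i2), ] <- cs[c(i2, i1), ]
  coords(sw) <- cs
  expect_equal(saltBridgeDistance(sw, list("A", 1), list("B", 1)),
               saltBridgeDistance(s, list("A", 1), list("B", 1)))

  # arginine: mass centre over NE/NH1/NH2 agrees with a hand calculation
  arg <- rigid_move(mumiscan:::buildPeptide("R", chain = "B"),
                    t = c(8, 0, 0))
  s2 <- mumiscan:::.rbindStructures(glu, arg)
  a2 <- atomData(s2)
  c2 <- coords(s2)
  comA <- colMeans(c2[a2$name %in% c("OE1", "OE2"), ])
  comB <- colMeans(c2[a2$name %in% c("NE", "NH1", "NH2"), ])
  expect_equal(saltBridgeDistance(s2, list("A", 1), list("B", 1)),
               vlen(comA - comB), tolerance = 1e-9)

  expect_error(saltBridgeDistance(s, list("B", 1), list("A", 1)),
               "not an acidic")
})
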