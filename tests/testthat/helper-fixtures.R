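# Shared helpers: geometry primitives independent of the package
# internals, brute-force oracles, and random-structure generators.

vlen <- function(v) sqrt(sum(v^2))

angle_at <- function(a, b, c) {
  u <- a - b
  v <- c - b
  acos(max(-1, min(1, sum(u * v) / (vlen(u) * vlen(v))))) * 180 / pi
}

random_rotation <- function() {
  # quaternion-uniform rotation
  q <- rnorm(4)
  q <- q / vlen(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_move <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  coords(structure) <- coords(structure) %*% t(R) +
    matrix(t, nAtoms(structure), 3, byrow = TRUE)
  structure
}

# Random cloud of small polar residues (Ser donors / Asp acceptors and
# friends), protonated; used for oracle-equivalence property tests.
random_polar_structure <- function(nres = 6, box = 9) {
  letters_pool <- c("S", "D", "N", "T", "E", "A")
  parts <- lapply(seq_len(nres), function(i) {
    r <- mumiscan:::buildPeptide(sample(letters_pool, 1), chain = "A",
                                 startResno = i)
    co <- coords(r)
    co <- co %*% t(random_rotation())
    co <- co + matrix(runif(3, 0, box), nrow(co), 3, byrow = TRUE)
    coords(r) <- co
    r
  })
  s <- do.call(mumiscan:::.rbindStructures, parts)
  suppressWarnings(addPolarHydrogens(s))
}

# Independent O(N^2) hydrogen-bond oracle: plain double loop over polar
# atoms with its own donor/acceptor determination and trigonometry.
# Returns a character set of "donorIdx-acceptorIdx" atom-index keys.
oracle_hbond_keys <- function(structure, dmax = 3.0, amax = 20) {
  a <- atomData(structure)
  co <- coords(structure)
  chem <- hbondChemistry()
  n <- nrow(a)
  isH <- toupper(a$element) == "H"
  # donors: N/O/S with attached H in the same residue
  donors <- list()
  for (i in which(toupper(a$element) %in% c("N", "O", "S") & !a$het)) {
    hs <- integer()
    for (j in which(isH)) {
      if (a$chain[j] == a$chain[i] && a$resno[j] == a$resno[i] &&
          vlen(co[i, ] - co[j, ]) < 1.45) hs <- c(hs, j)
    }
    if (length(hs)) donors[[length(donors) + 1]] <- list(d = i, h = hs)
  }
  # acceptors: backbone O/OXT + side-chain table; N only when H-free
  accs <- integer()
  for (i in seq_len(n)) {
    if (a$het[i] || isH[i]) next
    ok <- a$name[i] %in% c("O", "OXT") ||
      a$name[i] %in% chem$acceptors[[a$resname[i]]]
    if (ok && substr(a$name[i], 1, 1) == "N") {
      hn <- chem$donors[[a$resname[i]]][[a$name[i]]]
      same <- a$chain == a$chain[i] & a$resno == a$resno[i]
      if (!is.null(hn) && any(a$name[same] %in% hn)) ok <- FALSE
    }
    if (ok) accs <- c(accs, i)
  }
  # covalent adjacency for 1-2/1-3 exclusion (distance rule, non-het)
  bonded <- vector("list", n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (a$het[i] || a$het[j]) next
    lim <- mumiscan:::covalentRadius(a$element[i]) +
      mumiscan:::covalentRadius(a$element[j]) + 0.4
    if (vlen(co[i, ] - co[j, ]) < lim) {
      bonded[[i]] <- c(bonded[[i]], j)
      bonded[[j]] <- c(bonded[[j]], i)
    }
  }
  excluded <- function(i, j) {
    if (j %in% bonded[[i]]) return(TRUE)
    length(intersect(bonded[[i]], bonded[[j]])) > 0
  }
  moiety <- function(nm) {
    if (nm %in% c("N", "C", "O", "CA", "OXT", "H", "H1", "H2", "H3"))
      "backbone" else "side-chain"
  }
  keys <- character()
  for (d in donors) for (acc in accs) {
    i <- d$d
    if (acc == i) next
    if (a$chain[acc] == a$chain[i] && a$resno[acc] == a$resno[i] &&
        moiety(a$name[acc]) == moiety(a$name[i])) next
    if (excluded(i, acc)) next
    if (vlen(co[i, ] - co[acc, ]) > dmax) next
    ang <- min(vapply(d$h, function(h) angle_at(co[h, ], co[i, ], co[acc, ]),
                      numeric(1)))
    if (ang <= amax) keys <- c(keys, paste0(i, "-", acc))
  }
  sort(unique(keys))
}

detect_hbond_keys <- function(structure, dmax = 3.0, amax = 20) {
  a <- atomData(structure)
  hb <- detectHBonds(structure, hbondCriterion(dmax, amax))
  if (!nrow(hb)) return(character())
  idx <- function(ch, rn, nm) {
    vapply(seq_along(ch), function(k)
      which(a$chain == ch[k] & a$resno == rn[k] & a$name == nm[k])[1],
      integer(1))
  }
  sort(unique(paste0(idx(hb$donor_chain, hb$donor_resno, hb$donor_atom), "-",
                     idx(hb$acceptor_chain, hb$acceptor_resno,
                         hb$acceptor_atom))))
}

# Brute-force all-pairs binding-region oracle
oracle_binding_region <- function(focal, partner, cutoff = 5.0) {
  af <- atomData(focal)
  ap <- atomData(partner)
  cf <- coords(focal)
  cp <- coords(partner)
  fi <- which(toupper(af$element) != "H" & !af$het)
  pidx <- which(toupper(ap$element) != "H" & !ap$het)
  hits <- integer()
  for (i in fi) {
    for (j in pidx) {
      if (vlen(cf[i, ] - cp[j, ]) <= cutoff) {
        hits <- c(hits, af$resno[i])
        break
      }
    }
  }
  sort(unique(hits))
}

# standard 3-bond toy dimer used across modules
standard_toy_dimer <- function() {
  makeToyDimer(data.frame(donor = c("S", "N", "W"),
                          acceptor = c("D", "E", "Q"),
                          distance = c(2.9, 2.8, 2.95),
                          angle = c(10, 5, 15)))
}

toy_between <- list("A", "B")

toy_wt_bonds <- function(td) {
  data.frame(focal_resno = td$manifest$donor_resno,
             focal_moiety = ifelse(td$manifest$donor_atom == "N",
                                   "backbone", "side-chain"),
             partner_resno = td$manifest$acceptor_resno,
             partner_moiety = ifelse(td$manifest$acceptor_atom == "O",
                                     "backbone", "side-chain"),
             stringsAsFactors = FALSE)
}
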