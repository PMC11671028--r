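# Amino-acid chemistry tables: name maps, side-chain build templates
# (internal coordinates), hydrogen-bond donor/acceptor chemistry,
# reference maximum ASA scales, van der Waals and covalent radii,
# Lennard-Jones parameters and formal charges for the reduced potential.

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.AA1 <- structure(names(.AA3), names = .AA3)

#' Amino-acid code conversion
#'
#' Convert between 1-letter and 3-letter amino-acid codes. Unknown codes
#' map to `NA` (3-to-1 additionally maps any nonstandard residue to "X"
#' when `strict = FALSE`).
#'
#' @param x character vector of codes.
#' @param strict logical; if `FALSE`, `aa321` returns "X" for unknown codes.
#' @return character vector of converted codes.
#' @examples
#' aa123("E")    # "GLU"
#' aa321("TRP")  # "W"
#' @export
aa123 <- function(x) unname(.AA3[toupper(x)])

#' @rdname aa123
#' @export
aa321 <- function(x, strict = FALSE) {
  out <- unname(.AA1[toupper(x)])
  if (!strict) out[is.na(out)] <- "X"
  out
}

## ---------------------------------------------------------------------------
## Side-chain templates.
##
## Each heavy atom beyond the backbone is placed by the natural-extension
## construction from three previously placed atoms: `rb` (bonded), `ra`
## (angle reference) and `rd` (dihedral reference). `chi` > 0 marks the
## dihedral as the chi-th torsion: its value is chi default + `off`; chi = 0
## dihedrals are rigid (`off` is the literal dihedral). Bond lengths in
## Angstrom, angles/dihedrals in degrees; single conformer per residue type
## (the most common rotamer of standard surveys), strain is relieved by the
## downstream minimization stage.
## ---------------------------------------------------------------------------

.tplRow <- function(name, el, rb, ra, rd, b, ang, chi, off) {
  data.frame(name = name, element = el, rb = rb, ra = ra, rd = rd,
             bond = b, angle = ang, chi = chi, off = off,
             stringsAsFactors = FALSE)
}

## CB is common to all non-glycine residues; +123.5 improper gives L chirality
.CB <- .tplRow("CB", "C", "CA", "N", "C", 1.530, 110.5, 0L, 123.5)

.SIDECHAIN_TEMPLATES <- list(
  ALA = .CB,
  GLY = .tplRow(character(), character(), character(), character(),
                character(), numeric(), numeric(), integer(), numeric()),
  SER = rbind(.CB, .tplRow("OG", "O", "CB", "CA", "N", 1.417, 110.8, 1L, 0)),
  CYS = rbind(.CB, .tplRow("SG", "S", "CB", "CA", "N", 1.808, 113.8, 1L, 0)),
  THR = rbind(.CB,
              .tplRow("OG1", "O", "CB", "CA", "N", 1.433, 109.6, 1L, 0),
              .tplRow("CG2", "C", "CB", "CA", "N", 1.521, 110.5, 1L, 123)),
  VAL = rbind(.CB,
              .tplRow("CG1", "C", "CB", "CA", "N", 1.527, 110.7, 1L, 0),
              .tplRow("CG2", "C", "CB", "CA", "N", 1.527, 110.7, 1L, -119)),
  LEU = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.530, 116.3, 1L, 0),
              .tplRow("CD1", "C", "CG", "CB", "CA", 1.524, 110.7, 2L, 0),
              .tplRow("CD2", "C", "CG", "CB", "CA", 1.524, 110.7, 2L, 122)),
  ILE = rbind(.CB,
              .tplRow("CG1", "C", "CB", "CA", "N", 1.530, 110.4, 1L, 0),
              .tplRow("CG2", "C", "CB", "CA", "N", 1.521, 110.5, 1L, 132),
              .tplRow("CD1", "C", "CG1", "CB", "CA", 1.513, 113.8, 2L, 0)),
  PRO = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.492, 104.5, 1L, 0),
              .tplRow("CD", "C", "CG", "CB", "CA", 1.503, 106.1, 2L, 0)),
  MET = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.520, 114.1, 1L, 0),
              .tplRow("SD", "S", "CG", "CB", "CA", 1.803, 112.7, 2L, 0),
              .tplRow("CE", "C", "SD", "CG", "CB", 1.791, 100.9, 3L, 0)),
  PHE = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.502, 113.8, 1L, 0),
              .tplRow("CD1", "C", "CG", "CB", "CA", 1.384, 120.8, 2L, 0),
              .tplRow("CD2", "C", "CG", "CB", "CA", 1.384, 120.8, 2L, 180),
              .tplRow("CE1", "C", "CD1", "CG", "CB", 1.384, 120.8, 0L, 180),
              .tplRow("CE2", "C", "CD2", "CG", "CB", 1.384, 120.8, 0L, 180),
              .tplRow("CZ", "C", "CE1", "CD1", "CG", 1.384, 120.0, 0L, 0)),
  TYR = NULL,  # filled below from PHE
  TRP = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.498, 113.6, 1L, 0),
              .tplRow("CD1", "C", "CG", "CB", "CA", 1.365, 126.9, 2L, 0),
              .tplRow("CD2", "C", "CG", "CB", "CA", 1.433, 126.7, 2L, 180),
              .tplRow("NE1", "N", "CD1", "CG", "CB", 1.374, 110.2, 0L, 180),
              .tplRow("CE2", "C", "CD2", "CG", "CB", 1.409, 107.2, 0L, 180),
              .tplRow("CE3", "C", "CD2", "CG", "CD1", 1.398, 133.9, 0L, 180),
              .tplRow("CZ2", "C", "CE2", "CD2", "CG", 1.394, 122.4, 0L, 180),
              .tplRow("CZ3", "C", "CE3", "CD2", "CG", 1.392, 118.6, 0L, 180),
              .tplRow("CH2", "C", "CZ2", "CE2", "CD2", 1.368, 117.5, 0L, 180)),
  ASP = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.516, 112.6, 1L, 0),
              .tplRow("OD1", "O", "CG", "CB", "CA", 1.249, 118.4, 2L, 0),
              .tplRow("OD2", "O", "CG", "CB", "CA", 1.249, 118.4, 2L, 180)),
  ASN = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.516, 112.6, 1L, 0),
              .tplRow("OD1", "O", "CG", "CB", "CA", 1.231, 120.8, 2L, 0),
              .tplRow("ND2", "N", "CG", "CB", "CA", 1.328, 116.4, 2L, 180)),
  GLU = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.530, 114.1, 1L, 0),
              .tplRow("CD", "C", "CG", "CB", "CA", 1.516, 112.6, 2L, 0),
              .tplRow("OE1", "O", "CD", "CG", "CB", 1.249, 118.4, 3L, 0),
              .tplRow("OE2", "O", "CD", "CG", "CB", 1.249, 118.4, 3L, 180)),
  GLN = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.530, 114.1, 1L, 0),
              .tplRow("CD", "C", "CG", "CB", "CA", 1.516, 112.6, 2L, 0),
              .tplRow("OE1", "O", "CD", "CG", "CB", 1.231, 120.8, 3L, 0),
              .tplRow("NE2", "N", "CD", "CG", "CB", 1.328, 116.4, 3L, 180)),
  LYS = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.520, 114.1, 1L, 0),
              .tplRow("CD", "C", "CG", "CB", "CA", 1.520, 111.3, 2L, 0),
              .tplRow("CE", "C", "CD", "CG", "CB", 1.520, 111.3, 3L, 0),
              .tplRow("NZ", "N", "CE", "CD", "CG", 1.489, 111.9, 4L, 0)),
  ARG = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.520, 114.1, 1L, 0),
              .tplRow("CD", "C", "CG", "CB", "CA", 1.520, 111.3, 2L, 0),
              .tplRow("NE", "N", "CD", "CG", "CB", 1.461, 112.0, 3L, 0),
              .tplRow("CZ", "C", "NE", "CD", "CG", 1.329, 124.2, 4L, 0),
              .tplRow("NH1", "N", "CZ", "NE", "CD", 1.326, 120.0, 0L, 0),
              .tplRow("NH2", "N", "CZ", "NE", "CD", 1.326, 120.0, 0L, 180)),
  HIS = rbind(.CB,
              .tplRow("CG", "C", "CB", "CA", "N", 1.497, 113.8, 1L, 0),
              .tplRow("ND1", "N", "CG", "CB", "CA", 1.378, 122.7, 2L, 0),
              .tplRow("CD2", "C", "CG", "CB", "CA", 1.354, 131.0, 2L, 180),
              .tplRow("CE1", "C", "ND1", "CG", "CB", 1.321, 109.2, 0L, 180),
              .tplRow("NE2", "N", "CD2", "CG", "CB", 1.374, 107.2, 0L, 180))
)
.SIDECHAIN_TEMPLATES$TYR <- rbind(
  .SIDECHAIN_TEMPLATES$PHE,
  .tplRow("OH", "O", "CZ", "CE1", "CD1", 1.376, 119.9, 0L, 180))

## most-common-rotamer chi defaults, degrees
.CHI_DEFAULTS <- list(
  ALA = numeric(), GLY = numeric(),
  SER = 62, CYS = -65, THR = 62, VAL = 175,
  LEU = c(-65, 175), ILE = c(-65, 170), PRO = c(-26, 38),
  MET = c(-65, 180, 75), PHE = c(-65, 85), TYR = c(-65, 85),
  TRP = c(-65, 95), ASP = c(-70, -15), ASN = c(-65, -58),
  GLU = c(-67, 180, -10), GLN = c(-67, 180, -25),
  LYS = c(-67, 180, 180, 180), ARG = c(-67, 180, 180, 180),
  HIS = c(-65, -75))

#' Side-chain build template for a residue type
#'
#' Returns the internal-coordinate template (bond lengths, angles,
#' dihedrals and their reference atoms) used to construct side-chain heavy
#' atoms beyond the backbone, plus the default chi angles (the most common
#' rotamer of standard surveys).
#'
#' @param resname 3-letter residue code.
#' @return list with elements `atoms` (data.frame of internal coordinates)
#'   and `chi` (numeric vector of default chi angles, degrees).
#' @examples
#' sideChainTemplate("VAL")
#' @export
sideChainTemplate <- function(resname) {
  resname <- toupper(resname)
  if (!resname %in% names(.SIDECHAIN_TEMPLATES))
    stop("no side-chain template for residue '", resname, "'")
  list(atoms = .SIDECHAIN_TEMPLATES[[resname]],
       chi = .CHI_DEFAULTS[[resname]])
}

## ---------------------------------------------------------------------------
## Hydrogen-bond chemistry: donor heavy atoms (with the hydrogens they
## carry once protonated) and acceptor heavy atoms per canonical residue.
## Backbone: N-H donor (except proline), carbonyl O (and OXT) acceptor.
## ---------------------------------------------------------------------------

.SC_DONORS <- list(
  SER = list(OG = "HG"), THR = list(OG1 = "HG1"), TYR = list(OH = "HH"),
  CYS = list(SG = "HG"), LYS = list(NZ = c("HZ1", "HZ2", "HZ3")),
  ARG = list(NE = "HE", NH1 = c("HH11", "HH12"), NH2 = c("HH21", "HH22")),
  ASN = list(ND2 = c("HD21", "HD22")), GLN = list(NE2 = c("HE21", "HE22")),
  TRP = list(NE1 = "HE1"),
  HIS = list(ND1 = "HD1", NE2 = "HE2"))  # one of the two per tautomer

.SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"))  # N acceptors only when unprotonated

#' Hydrogen-bond donor/acceptor chemistry tables
#'
#' The residue chemistry used by [detectHBonds()]: side-chain donor heavy
#' atoms with their hydrogen names, and side-chain acceptor heavy atoms.
#' Backbone amide N (except proline) is always a donor and backbone
#' carbonyl O (and OXT) always an acceptor. Histidine ND1/NE2 act as donor
#' or acceptor according to the protonation actually present in the
#' structure.
#'
#' @return list with elements `donors` and `acceptors`.
#' @export
hbondChemistry <- function() list(donors = .SC_DONORS, acceptors = .SC_ACCEPTORS)

## ---------------------------------------------------------------------------
## Reference maximum ASA per residue (A^2): theoretical and empirical
## scales of Tien et al. (2013). Theoretical is the default.
## ---------------------------------------------------------------------------

.MAX_ASA <- list(
  theoretical = c(
    ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0),
  empirical = c(
    ALA = 121.0, ARG = 265.0, ASN = 187.0, ASP = 187.0, CYS = 148.0,
    GLN = 214.0, GLU = 214.0, GLY = 97.0, HIS = 216.0, ILE = 195.0,
    LEU = 191.0, LYS = 230.0, MET = 203.0, PHE = 228.0, PRO = 154.0,
    SER = 143.0, THR = 163.0, TRP = 264.0, TYR = 255.0, VAL = 165.0))

#' Reference maximum accessible surface areas
#'
#' Per-residue maximum ASA values (A^2) used to normalise residue SASA
#' into relative solvent accessibility (RSA, percent).
#'
#' @param scale `"theoretical"` (default) or `"empirical"`.
#' @return named numeric vector, one value per standard residue.
#' @export
maxASA <- function(scale = c("theoretical", "empirical")) {
  .MAX_ASA[[match.arg(scale)]]
}

## per-element van der Waals radii (A); monovalent ions included for boxes
.VDW_RADII <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                K = 2.75, `NA` = 2.27, AR = 1.88, FE = 2.00, ZN = 1.39,
                MG = 1.73, CA = 2.31)

#' Van der Waals radius lookup
#' @param element character vector of element symbols.
#' @return numeric vector of radii (A); errors on unknown elements.
#' @export
vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(toupper(element)[is.na(r)])
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

## covalent radii (A) for distance-based bond inference
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                SE = 1.20, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
                K = 2.03, `NA` = 1.66, AR = 1.06, FE = 1.32, ZN = 1.22,
                MG = 1.41, CA = 1.76)

covalentRadius <- function(element) {
  r <- .COV_RADII[toupper(element)]
  r[is.na(r)] <- 0.77  # carbon-like default
  unname(r)
}

.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, SE = 78.971, K = 39.098, `NA` = 22.990,
                  CL = 35.45, AR = 39.948, F = 18.998, FE = 55.845,
                  ZN = 65.38, MG = 24.305, CA = 40.078)

atomicMass <- function(element) {
  m <- .ATOMIC_MASS[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

## Lennard-Jones well depths (kcal/mol); pair minimum r_min = rvdw_i + rvdw_j
.LJ_EPS <- c(H = 0.03, C = 0.10, N = 0.17, O = 0.21, S = 0.25, P = 0.20,
             SE = 0.25, K = 0.087, `NA` = 0.047, CL = 0.15, AR = 0.238,
             F = 0.061, FE = 0.10, ZN = 0.10, MG = 0.10, CA = 0.10)

#' Lennard-Jones parameters of the reduced fallback potential
#'
#' Per-element parameters used by the built-in vacuum minimizer. For a pair
#' of elements the potential minimum lies at `rmin = vdwRadius(a) +
#' vdwRadius(b)` with depth `sqrt(eps_a * eps_b)`; the equivalent
#' 12-6 sigma is `rmin / 2^(1/6)`.
#'
#' @param element character vector of element symbols.
#' @return data.frame with columns `element`, `rvdw` (A), `eps` (kcal/mol),
#'   `sigma` (A, single-element 12-6 sigma for the homo pair).
#' @export
ljParameters <- function(element) {
  el <- toupper(element)
  eps <- .LJ_EPS[el]
  if (anyNA(eps)) stop("no LJ parameters for element(s): ",
                       paste(unique(el[is.na(eps)]), collapse = ", "))
  rv <- vdwRadius(el)
  data.frame(element = el, rvdw = rv, eps = unname(eps),
             sigma = 2 * rv / 2^(1 / 6), stringsAsFactors = FALSE)
}

## simplified formal charges for the reduced potential, by (resname, atom)
.FORMAL_CHARGES <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5), GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1.0), ARG = c(NH1 = 0.5, NH2 = 0.5))

formalCharge <- function(resname, atomname) {
  q <- numeric(length(resname))
  for (rn in names(.FORMAL_CHARGES)) {
    tab <- .FORMAL_CHARGES[[rn]]
    hit <- resname == rn & atomname %in% names(tab)
    q[hit] <- tab[atomname[hit]]
  }
  q
}

.WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "SOL", "H2O", "TIP", "SPC")
.ION_RESNAMES <- c("K", "CL", "NA", "MG", "CA", "ZN", "POT", "CLA", "SOD")

isWaterRes <- function(resname) toupper(resname) %in% .WATER_RESNAMES
isIonRes <- function(resname) toupper(resname) %in% .ION_RESNAMES
isStandardRes <- function(resname) toupper(resname) %in% names(.AA1)
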