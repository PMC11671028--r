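# Shrake-Rupley solvent-accessible surface area, relative solvent
# accessibility (RSA, percent of a reference maximum ASA), unbound/bound
# RSA differences and per-residue ensemble statistics.

#' SASA computation parameters
#'
#' @param probeRadius solvent probe radius, A (default 1.4, water).
#' @param nSpherePoints number of test points per atom (default 960),
#'   generated on a deterministic generalized spiral.
#' @param maxAsaScale reference maximum-ASA scale for RSA, see [maxASA()].
#' @return list of class `SasaSpec`.
#' @export
sasaSpec <- function(probeRadius = 1.4, nSpherePoints = 960L,
                     maxAsaScale = "theoretical") {
  stopifnot(probeRadius >= 0, nSpherePoints >= 32L)
  structure(list(probeRadius = probeRadius,
                 nSpherePoints = as.integer(nSpherePoints),
                 maxAsaScale = maxAsaScale), class = "SasaSpec")
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic spiral point set: for each heavy
#' atom, test points on the solvent-expanded sphere are marked buried when
#' inside any neighbour's expanded sphere. Hydrogens are excluded
#' (crystal-structure convention) but waters' oxygens participate unless
#' excluded. Deterministic for a fixed spec.
#'
#' @param structure a [Structure-class].
#' @param spec a [sasaSpec()].
#' @param includeWater include water molecules as occluders/targets
#'   (default `FALSE`).
#' @return numeric vector of per-atom areas (A^2), one entry per atom of
#'   the structure; hydrogens (and excluded waters) get 0.
#' @export
sasaAtoms <- function(structure, spec = sasaSpec(), includeWater = FALSE) {
  a <- atomData(structure)
  co <- coords(structure)
  use <- isHeavy(structure) & (includeWater | !isWaterRes(a$resname))
  out <- numeric(nrow(a))
  idx <- which(use)
  if (!length(idx)) return(out)
  el <- toupper(a$element[idx])
  radii <- vdwRadius(el) + spec$probeRadius
  pts <- goldenSpiralPoints(spec$nSpherePoints)
  cx <- co[idx, , drop = FALSE]
  n <- length(idx)
  ## neighbour lists from pairwise distances (desk-scale sizes)
  dm <- crossDist(cx, cx)
  lim <- outer(radii, radii, "+")
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] < lim[i, ] & seq_len(n) != i)
    Ri <- radii[i]
    if (!length(nb)) {
      out[idx[i]] <- 4 * pi * Ri^2
      next
    }
    sp <- pts * Ri
    sp <- sweep(sp, 2L, cx[i, ], "+")
    free <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(free)) break
      d2 <- distSqTo(cx[j, ], sp[free, , drop = FALSE])
      free[free] <- d2 >= radii[j]^2
    }
    out[idx[i]] <- 4 * pi * Ri^2 * sum(free) / spec$nSpherePoints
  }
  out
}

#' Total SASA of a structure
#' @inheritParams sasaAtoms
#' @return total area (A^2).
#' @export
sasaTotal <- function(structure, spec = sasaSpec(), includeWater = FALSE) {
  sum(sasaAtoms(structure, spec, includeWater))
}

#' Per-residue relative solvent accessibility
#'
#' Residue SASA normalised by the reference maximum ASA of its amino-acid
#' type, in percent. Values above 100 are possible for extended
#' conformations and are flagged.
#'
#' @inheritParams sasaAtoms
#' @return data.frame with columns `chain`, `resno`, `resname`, `sasa`
#'   (A^2), `rsa` (percent) and `flag` (RSA > 100). Nonstandard residues
#'   are excluded.
#' @export
rsa <- function(structure, spec = sasaSpec()) {
  areas <- sasaAtoms(structure, spec)
  a <- atomData(structure)
  std <- !a$het & isStandardRes(a$resname)
  rt <- residueTable(structure)
  rt <- rt[isStandardRes(rt$resname), , drop = FALSE]
  ref <- maxASA(spec$maxAsaScale)
  key <- paste(a$chain, a$resno)
  sasaRes <- vapply(seq_len(nrow(rt)), function(r)
    sum(areas[std & key == paste(rt$chain[r], rt$resno[r])]), numeric(1))
  out <- data.frame(chain = rt$chain, resno = rt$resno,
                    resname = rt$resname, sasa = sasaRes,
                    rsa = 100 * sasaRes / ref[rt$resname],
                    stringsAsFactors = FALSE)
  out$flag <- out$rsa > 100
  rownames(out) <- NULL
  out
}

#' RSA difference between two states of the same residues
#'
#' Bound minus unbound RSA per residue; negative values mark residues
#' buried upon binding.
#'
#' @param unbound,bound outputs of [rsa()] over the same residue set
#'   (matched by residue number; chains may differ between crystal forms).
#' @return data.frame with columns `resno`, `resname`, `rsa_unbound`,
#'   `rsa_bound`, `delta` (percent points).
#' @export
deltaRsa <- function(unbound, bound) {
  m <- match(unbound$resno, bound$resno)
  if (anyNA(m) || nrow(unbound) != nrow(bound))
    stop("residue mismatch between the two profiles")
  data.frame(resno = unbound$resno, resname = unbound$resname,
             rsa_unbound = unbound$rsa, rsa_bound = bound$rsa[m],
             delta = bound$rsa[m] - unbound$rsa,
             stringsAsFactors = FALSE)
}

#' Per-residue RSA statistics over an ensemble
#'
#' Mean and population standard deviation of RSA per residue over the
#' frames of an ensemble. For mutant-collection ensembles the statistics
#' run over the mutants (each frame is one relaxed mutant).
#'
#' @param ensemble a [StructureEnsemble-class] with at least 2 frames.
#' @param spec a [sasaSpec()].
#' @return data.frame with columns `chain`, `resno`, `mean_rsa`,
#'   `sd_rsa`, `n`.
#' @export
ensembleRsaStats <- function(ensemble, spec = sasaSpec()) {
  if (nFrames(ensemble) < 2L)
    stop("ensemble statistics need at least 2 frames")
  profs <- lapply(frames(ensemble), rsa, spec = spec)
  key <- paste(profs[[1L]]$chain, profs[[1L]]$resno)
  vals <- vapply(profs, function(p) {
    p$rsa[match(key, paste(p$chain, p$resno))]
  }, numeric(length(key)))
  mu <- rowMeans(vals)
  sdpop <- sqrt(rowMeans((vals - mu)^2))
  data.frame(chain = profs[[1L]]$chain, resno = profs[[1L]]$resno,
             mean_rsa = mu, sd_rsa = sdpop, n = length(profs),
             stringsAsFactors = FALSE)
}

#' Compare per-residue RSA statistics of two ensembles
#'
#' Pairs the per-residue means and standard deviations of two
#' [ensembleRsaStats()] outputs and reports least-squares coefficients of
#' determination (R^2) for both, with optional residue annotation.
#'
#' @param a,b outputs of [ensembleRsaStats()] over the same residues.
#' @param allosteric,binding optional integer vectors of residue numbers
#'   used to annotate the paired table.
#' @return list with `table` (per-residue paired values and annotation),
#'   `r2_mean` and `r2_sd`.
#' @export
compareRsaStats <- function(a, b, allosteric = integer(), binding = integer()) {
  m <- match(paste(a$chain, a$resno), paste(b$chain, b$resno))
  if (anyNA(m)) stop("residue mismatch between the two statistics tables")
  tab <- data.frame(
    chain = a$chain, resno = a$resno,
    mean_a = a$mean_rsa, mean_b = b$mean_rsa[m],
    sd_a = a$sd_rsa, sd_b = b$sd_rsa[m],
    annotation = ifelse(a$resno %in% allosteric, "allosteric",
                        ifelse(a$resno %in% binding, "binding", "")),
    stringsAsFactors = FALSE)
  r2 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }
  list(table = tab, r2_mean = r2(tab$mean_a, tab$mean_b),
       r2_sd = r2(tab$sd_a, tab$sd_b))
}
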