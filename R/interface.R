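# Binding-region membership by heavy-atom proximity and per-residue
# binding-region probabilities over ensembles. Membership follows the
# heavy-atom definition: a focal residue belongs to the binding region
# when any of its heavy atoms lies within the cutoff (default 5 A) of any
# partner heavy atom. The accelerated path uses a cell list with cell
# size equal to the cutoff; it is exactly equivalent to the all-pairs scan.

## heavy, non-solvent atom indices
.contactAtoms <- function(structure) {
  a <- atomData(structure)
  which(isHeavy(structure) & !isWaterRes(a$resname) & !isIonRes(a$resname))
}

## cell-list membership test: for each focal atom, is any partner atom
## within cutoff? Returns logical per focal atom.
.withinCutoff <- function(focalCo, partnerCo, cutoff) {
  cell <- function(m) {
    k <- floor(m / cutoff)
    paste(k[, 1L], k[, 2L], k[, 3L])
  }
  pc <- split(seq_len(nrow(partnerCo)), cell(partnerCo))
  fk <- floor(focalCo / cutoff)
  out <- logical(nrow(focalCo))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cut2 <- cutoff^2
  for (i in seq_len(nrow(focalCo))) {
    keys <- paste(fk[i, 1L] + offs[, 1L], fk[i, 2L] + offs[, 2L],
                  fk[i, 3L] + offs[, 3L])
    cand <- unlist(pc[keys], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    out[i] <- min(distSqTo(focalCo[i, ], partnerCo[cand, , drop = FALSE])) <=
      cut2
  }
  out
}

#' Binding-region residues of a focal structure
#'
#' Focal residues having at least one heavy atom within `cutoff` of any
#' partner heavy atom (hydrogens, waters and ions excluded).
#'
#' @param focal,partner [Structure-class] objects.
#' @param cutoff distance cutoff in A (default 5.0).
#' @return data.frame of binding-region residues: `chain`, `resno`,
#'   `resname`, ordered by chain then residue number.
#' @export
bindingRegion <- function(focal, partner, cutoff = 5.0) {
  if (!nAtoms(focal) || !nAtoms(partner))
    stop("both structures must be nonempty")
  fi <- .contactAtoms(focal)
  pi_ <- .contactAtoms(partner)
  af <- atomData(focal)[fi, , drop = FALSE]
  hit <- .withinCutoff(coords(focal)[fi, , drop = FALSE],
                       coords(partner)[pi_, , drop = FALSE], cutoff)
  res <- af[hit, c("chain", "resno", "resname"), drop = FALSE]
  res <- res[!duplicated(paste(res$chain, res$resno)), , drop = FALSE]
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-residue binding-region probability over an ensemble
#'
#' Fraction of frames (or mutants, for mutant-collection ensembles) in
#' which each focal residue is in the binding region. For
#' mutant-collection ensembles the denominator is the number of usable
#' mutants across all positions, so a residue's probability aggregates
#' over every substitution everywhere.
#'
#' @param ensemble a [StructureEnsemble-class] of complexes.
#' @param focalChains chain identifiers of the focal molecule.
#' @param cutoff distance cutoff in A (default 5.0).
#' @return data.frame with columns `chain`, `resno`, `resname` (first
#'   frame), `probability`, `n_obs`; attribute `cutoff`.
#' @export
bindingProbability <- function(ensemble, focalChains, cutoff = 5.0) {
  if (!nFrames(ensemble)) stop("empty ensemble")
  fr <- frames(ensemble)
  split1 <- splitComplex(fr[[1L]], focalChains)
  rt <- residueTable(split1$focal)
  counts <- integer(nrow(rt))
  key <- paste(rt$chain, rt$resno)
  for (f in fr) {
    parts <- splitComplex(f, focalChains)
    reg <- bindingRegion(parts$focal, parts$partner, cutoff)
    counts <- counts + (key %in% paste(reg$chain, reg$resno))
  }
  out <- data.frame(chain = rt$chain, resno = rt$resno,
                    resname = rt$resname,
                    probability = counts / length(fr),
                    n_obs = length(fr), stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

#' Rank positions by excess binding-region probability
#'
#' Positions whose binding-region probability exceeds the reference
#' profile (typically the wild-type indicator), sorted by probability
#' descending with deterministic residue-number tie-breaks.
#'
#' @param profile,reference outputs of [bindingProbability()] over the
#'   same residues.
#' @return data.frame of the exceeding positions with `probability` and
#'   `reference` columns.
#' @export
rankInterfacePositions <- function(profile, reference) {
  m <- match(paste(profile$chain, profile$resno),
             paste(reference$chain, reference$resno))
  if (anyNA(m)) stop("profile and reference cover different residues")
  ref <- reference$probability[m]
  keep <- profile$probability > ref
  out <- profile[keep, c("chain", "resno", "resname", "probability"),
                 drop = FALSE]
  out$reference <- ref[keep]
  out <- out[order(-out$probability, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}
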