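# Binding-fitness proxy: assemble the positions x substitutions matrix of
# maintained wild-type dominant interface hydrogen bonds and compare it
# with experimental deep-mutational-scanning binding energies.

#' Assemble the fitness-proxy matrix from a mutant scan
#'
#' For every usable mutant of a [runMumi()] scan, counts how many of the
#' wild-type dominant interface bonds are maintained
#' ([countWtBonds()]). Failed mutants are `NA` and listed as missing.
#'
#' @param scan list from [runMumi()] (`ensemble` + `manifest`), or a list
#'   with those two elements.
#' @param wtBonds reference WT bond pair table (see [countWtBonds()]).
#' @param criterion an [hbondCriterion()].
#' @param between list of two chain-id sets (focal, partner).
#' @return a [FitnessMatrix-class].
#' @export
buildFitnessMatrix <- function(scan, wtBonds,
                               criterion = hbondCriterion(), between) {
  manifest <- scan$manifest
  ens <- scan$ensemble
  if (sum(manifest$converged) != nFrames(ens))
    stop("manifest/ensemble mismatch: ", sum(manifest$converged),
         " converged entries vs ", nFrames(ens), " frames")
  positions <- sort(unique(manifest$position))
  wtLetters <- manifest$wt[match(positions, manifest$position)]
  letters20 <- sort(names(.AA3))
  vals <- matrix(NA_real_, length(positions), length(letters20),
                 dimnames = list(paste0(wtLetters, positions), letters20))
  fr <- frames(ens)
  ui <- 0L
  for (k in seq_len(nrow(manifest))) {
    if (!manifest$converged[k]) next
    ui <- ui + 1L
    vals[match(manifest$position[k], positions), manifest$mut[k]] <-
      countWtBonds(fr[[ui]], wtBonds, criterion, between)
  }
  new("FitnessMatrix", values = vals, positions = as.integer(positions),
      wt = wtLetters, wtBonds = as.data.frame(wtBonds),
      missing = manifest$label[!manifest$converged])
}

#' Cap experimental destabilization energies
#'
#' Destabilization values above the cap are reported through the cap
#' (default 9 kcal/mol). Idempotent.
#'
#' @param x numeric vector, or a data.frame with a `ddg` column.
#' @param cap ceiling, kcal/mol.
#' @return same shape as `x` with values capped.
#' @export
capEnergies <- function(x, cap = 9) {
  if (is.data.frame(x)) {
    if (!is.numeric(x$ddg)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(x$ddg))))[1L]
      stop("non-numeric energy in row ", bad)
    }
    x$ddg <- pmin(x$ddg, cap)
    return(x)
  }
  if (!is.numeric(x)) stop("non-numeric energy values")
  pmin(x, cap)
}

#' Read an experimental fitness table
#'
#' Delimited text with header `position,wt,mut,ddg` (destabilization
#' binding energies, kcal/mol).
#'
#' @param path file path.
#' @param cap passed to [capEnergies()]; use `Inf` to skip capping.
#' @return data.frame with a `label` column added.
#' @export
readExperimentTable <- function(path, cap = 9) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "wt", "mut", "ddg")
  if (!all(need %in% names(tab)))
    stop("experiment table needs columns: ", paste(need, collapse = ", "))
  suppressWarnings(num <- as.numeric(tab$ddg))
  if (anyNA(num))
    stop("non-numeric energy in row ", which(is.na(num))[1L])
  tab$ddg <- num
  tab <- capEnergies(tab, cap)
  tab$label <- paste0(toupper(tab$wt), tab$position, toupper(tab$mut))
  tab
}

#' Synthetic experimental table (fixture generator)
#'
#' A stand-in for external deep-mutational-scanning data: a monotone
#' decreasing map of the maintained-bond count plus Gaussian noise, so
#' that more maintained bonds mean less destabilization.
#'
#' @param fm a [FitnessMatrix-class].
#' @param intercept,slope linear map `ddg = intercept - slope * n_hb`.
#' @param noiseSd Gaussian noise standard deviation (kcal/mol).
#' @param seed integer seed.
#' @return data.frame with columns `position`, `wt`, `mut`, `ddg`,
#'   `label`.
#' @export
syntheticExperimentTable <- function(fm, intercept = 9, slope = 2,
                                     noiseSd = 0, seed = 1L) {
  long <- as.data.frame(fm)
  long <- long[!is.na(long$n_hb), , drop = FALSE]
  set.seed(seed)
  long$ddg <- intercept - slope * long$n_hb +
    stats::rnorm(nrow(long), sd = noiseSd)
  long[, c("position", "wt", "mut", "ddg", "label")]
}

#' Correlate the fitness proxy with experimental energies
#'
#' Joins the maintained-bond counts with an experiment table by mutation
#' label and reports Pearson and Spearman statistics. Experimental values
#' are destabilization energies (larger = worse binding), so the expected
#' association is negative; the sign is reported, not folded into a
#' score. Mutants missing on either side are excluded pairwise and
#' counted.
#'
#' @param fm a [FitnessMatrix-class].
#' @param table experiment data.frame with `label` and `ddg` columns.
#' @return list with `records` (joined per-mutation data), `pearson`,
#'   `spearman` (each with `estimate`, `p.value`), `n`, `n_missing`.
#' @export
correlateFitness <- function(fm, table) {
  long <- as.data.frame(fm)
  m <- match(long$label, table$label)
  rec <- data.frame(label = long$label, n_hb = long$n_hb,
                    ddg = table$ddg[m], stringsAsFactors = FALSE)
  ok <- stats::complete.cases(rec)
  if (!any(ok)) stop("no overlapping mutation labels between inputs")
  rec <- rec[order(rec$label), , drop = FALSE]
  rownames(rec) <- NULL
  use <- rec[stats::complete.cases(rec), ]
  pe <- suppressWarnings(stats::cor.test(use$n_hb, use$ddg,
                                         method = "pearson"))
  sp <- suppressWarnings(stats::cor.test(use$n_hb, use$ddg,
                                         method = "spearman", exact = FALSE))
  list(records = rec,
       pearson = list(estimate = unname(pe$estimate), p.value = pe$p.value),
       spearman = list(estimate = unname(sp$estimate), p.value = sp$p.value),
       n = nrow(use), n_missing = nrow(rec) - nrow(use))
}

#' Export a fitness matrix as CSV
#'
#' @param fm a [FitnessMatrix-class].
#' @param path output path; `paste0(path, "_long.csv")` additionally gets
#'   the long form when `long = TRUE`.
#' @param long also write the long-form table.
#' @return `path`, invisibly.
#' @export
writeFitnessMatrix <- function(fm, path, long = FALSE) {
  utils::write.csv(fitnessValues(fm), path, na = "")
  if (long)
    utils::write.csv(as.data.frame(fm),
                     sub("\\.csv$", "_long.csv", path), row.names = FALSE)
  invisible(path)
}

#' Desk-scale computational deep-mutational-scanning pipeline
#'
#' The end-to-end scan on a bound complex: determine the wild-type
#' interface bonds (dominant bonds of the reference ensemble, or the
#' single-structure interface bonds when no ensemble is given), mutate
#' every requested position of the focal chain, relax each mutant, and
#' assemble the maintained-bond [FitnessMatrix-class].
#'
#' @param complex wild-type bound complex ([Structure-class]).
#' @param focalChains chain id(s) of the mutated molecule.
#' @param positions positions to scan (default: all focal residues).
#' @param reference optional [StructureEnsemble-class] of the wild-type
#'   bound dynamics for occupancy-based dominant bonds.
#' @param criterion an [hbondCriterion()].
#' @param dominantThreshold occupancy threshold for [dominantBonds()].
#' @param minimization a [minimizationSpec()].
#' @return list with `wtBonds`, `scan` (from [runMumi()]), `fitness`
#'   (a [FitnessMatrix-class]) and `wtCount` (maintained bonds in the
#'   relaxed WT control).
#' @export
scanComplex <- function(complex, focalChains, positions = NULL,
                        reference = NULL, criterion = hbondCriterion(),
                        dominantThreshold = 0.20,
                        minimization = minimizationSpec(steps = 200L)) {
  partnerChains <- setdiff(chains(complex), focalChains)
  between <- list(focalChains, partnerChains)
  prot <- if (any(toupper(atomData(complex)$element) == "H")) complex else
    suppressWarnings(addPolarHydrogens(complex))
  wtBonds <- if (!is.null(reference)) {
    dominantBonds(hbondOccupancy(reference, criterion, between),
                  dominantThreshold)
  } else {
    .bondPairs(detectHBonds(prot, criterion, between), between)
  }
  focalChain <- focalChains[1L]
  seq1 <- chainSequence(complex, focalChain)
  rt <- residueTable(complex)
  focalRes <- rt$resno[rt$chain == focalChain]
  if (is.null(positions)) positions <- focalRes
  seqPos <- match(positions, focalRes)
  specs <- enumerateMutations(seq1, positions = seqPos)
  specs$position <- focalRes[specs$position]  # back to author numbering
  specs$label <- paste0(specs$wt, specs$position, specs$mut)
  scan <- runMumi(prot, specs, chain = focalChain,
                  minimization = minimization)
  fm <- buildFitnessMatrix(scan, wtBonds, criterion, between)
  wtRelax <- minimizeSystem(prot, minimization)
  wtCount <- countWtBonds(relaxedStructure(wtRelax), wtBonds, criterion,
                          between)
  list(wtBonds = wtBonds, scan = scan, fitness = fm, wtCount = wtCount)
}
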