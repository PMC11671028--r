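#' @import methods
NULL

## ---------------------------------------------------------------------------
## Structure
## ---------------------------------------------------------------------------

#' Structure: an ordered collection of atoms
#'
#' The universal coordinate container passed between pipeline stages:
#' ordered chains of residues of atoms, with element symbols and Cartesian
#' coordinates in Angstrom. Waters and other hetero groups are retained
#' but flagged in the `het` column of the atom table.
#'
#' @slot atoms data.frame with columns `serial` (integer), `name` (PDB
#'   atom name), `element` (symbol), `resno` (author residue numbering,
#'   integer), `resname` (3-letter code), `chain` (single character),
#'   `het` (logical), `flag` (logical; residues with incomplete backbone).
#' @slot coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @slot label character, free-text identifier.
#' @export
setClass("Structure",
         slots = c(atoms = "data.frame", coords = "matrix",
                   label = "character"))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resno", "resname", "chain",
            "het", "flag")
  if (!all(need %in% names(a)))
    return(paste("atom table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) != nrow(object@coords))
    return("atom table and coordinate matrix differ in length")
  if (nrow(object@coords) && ncol(object@coords) != 3L)
    return("coordinates must be an n x 3 matrix")
  if (nrow(object@coords) && !all(is.finite(object@coords)))
    return("coordinates must be finite")
  if (anyDuplicated(a$serial))
    return("atom serial numbers must be unique within a model")
  TRUE
})

#' Construct a Structure from an atom table and coordinates
#'
#' @param atoms data.frame as described in [Structure-class]. Missing
#'   `serial`/`het`/`flag` columns are filled with defaults.
#' @param coords numeric n x 3 matrix (Angstrom).
#' @param label optional identifier.
#' @return a [Structure-class] object.
#' @export
newStructure <- function(atoms, coords, label = "") {
  coords <- as.matrix(coords)
  if (nrow(coords)) {
    dimnames(coords) <- NULL
    storage.mode(coords) <- "double"
  }
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$flag)) atoms$flag <- FALSE
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, coords = coords, label = as.character(label))
}

#' @rdname atomData
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Accessors for Structure objects
#'
#' `atomData` returns the atom table; `coords` the coordinate matrix;
#' `chains` the ordered distinct chain identifiers; `nAtoms` the atom
#' count; `chainSequence` the 1-letter sequence of one chain (nonstandard
#' residues become "X"); `isHeavy` a logical vector marking non-hydrogen
#' atoms.
#'
#' @param x a [Structure-class] object.
#' @param value replacement coordinate matrix.
#' @param chain chain identifier (default: first chain).
#' @name atomData
#' @aliases atomData,Structure-method
#' @export
setMethod("atomData", "Structure", function(x) x@atoms)

#' @rdname atomData
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname atomData
#' @export
setMethod("coords", "Structure", function(x) x@coords)

#' @rdname atomData
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname atomData
#' @export
setMethod("coords<-", "Structure", function(x, value) {
  value <- as.matrix(value)
  dimnames(value) <- NULL
  x@coords <- value
  validObject(x)
  x
})

#' @rdname atomData
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname atomData
#' @export
setMethod("chains", "Structure", function(x) unique(x@atoms$chain))

#' @rdname atomData
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname atomData
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname atomData
#' @export
isHeavy <- function(x) {
  a <- if (is(x, "Structure")) x@atoms else x
  toupper(a$element) != "H"
}

#' @rdname atomData
#' @export
setGeneric("chainSequence", function(x, chain) standardGeneric("chainSequence"))

#' @rdname atomData
#' @export
setMethod("chainSequence", "Structure", function(x, chain) {
  a <- x@atoms
  if (missing(chain)) chain <- a$chain[!a$het][1L]
  a <- a[a$chain == chain & !a$het, , drop = FALSE]
  if (!nrow(a)) return("")
  res <- a[!duplicated(a$resno), , drop = FALSE]
  paste(aa321(res$resname), collapse = "")
})

#' Residue table of a Structure
#'
#' One row per residue in atom order: chain, author residue number,
#' residue name and het flag.
#'
#' @param x a [Structure-class] object.
#' @param het include hetero residues (default `FALSE`).
#' @return data.frame with columns `chain`, `resno`, `resname`, `het`.
#' @export
residueTable <- function(x, het = FALSE) {
  a <- atomData(x)
  if (!het) a <- a[!a$het, , drop = FALSE]
  key <- paste(a$chain, a$resno)
  r <- a[!duplicated(key), c("chain", "resno", "resname", "het")]
  rownames(r) <- NULL
  r
}

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  rt <- residueTable(object)
  cat("Structure", if (nzchar(object@label)) paste0("'", object@label, "'"),
      "\n  ", nrow(a), " atoms (", sum(isHeavy(object)), " heavy), ",
      nrow(rt), " residues, chains: ",
      paste(unique(a$chain), collapse = ", "), "\n", sep = "")
  if (any(a$het)) cat("  ", sum(a$het), " hetero atoms (flagged)\n", sep = "")
})

## subset a Structure by atom index, renumbering serials
subsetStructure <- function(x, idx, label = x@label) {
  a <- x@atoms[idx, , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  newStructure(a, x@coords[idx, , drop = FALSE], label = label)
}

## ---------------------------------------------------------------------------
## StructureEnsemble
## ---------------------------------------------------------------------------

#' StructureEnsemble: ordered frames sharing a topology
#'
#' A list of [Structure-class] frames. For `"multi-model-pdb"` and
#' `"trajectory"` sources all frames share one topology (identical atom
#' count and names, varying coordinates); `"mutant-collection"` ensembles
#' instead guarantee an identical residue count per chain.
#'
#' @slot frames list of [Structure-class] objects.
#' @slot source one of `"multi-model-pdb"`, `"trajectory"`,
#'   `"mutant-collection"`.
#' @export
setClass("StructureEnsemble",
         slots = c(frames = "list", source = "character"))

setValidity("StructureEnsemble", function(object) {
  if (!object@source %in% c("multi-model-pdb", "trajectory",
                            "mutant-collection"))
    return("source must be multi-model-pdb, trajectory or mutant-collection")
  if (!all(vapply(object@frames, is, logical(1), "Structure")))
    return("all frames must be Structure objects")
  if (length(object@frames) >= 2L) {
    if (object@source == "mutant-collection") {
      nres <- lapply(object@frames, function(f) {
        rt <- residueTable(f)
        table(rt$chain)
      })
      if (!all(vapply(nres[-1L], identical, logical(1), nres[[1L]])))
        return("mutant-collection frames must have identical residue counts per chain")
    } else {
      nat <- vapply(object@frames, nAtoms, integer(1))
      if (length(unique(nat)) != 1L)
        return("fixed-topology ensemble frames must have identical atom counts")
    }
  }
  TRUE
})

#' Construct a StructureEnsemble
#' @param frames list of [Structure-class] frames.
#' @param source ensemble provenance; see [StructureEnsemble-class].
#' @return a [StructureEnsemble-class] object.
#' @export
newEnsemble <- function(frames, source = c("trajectory", "multi-model-pdb",
                                           "mutant-collection")) {
  new("StructureEnsemble", frames = frames, source = match.arg(source))
}

#' @rdname frames
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Accessors for StructureEnsemble objects
#' @param x a [StructureEnsemble-class] object.
#' @name frames
#' @export
setMethod("frames", "StructureEnsemble", function(x) x@frames)

#' @rdname frames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname frames
#' @export
setMethod("nFrames", "StructureEnsemble", function(x) length(x@frames))

#' @rdname frames
#' @export
ensembleSource <- function(x) x@source

setMethod("show", "StructureEnsemble", function(object) {
  cat("StructureEnsemble: ", length(object@frames), " frames, source: ",
      object@source, "\n", sep = "")
  if (length(object@frames)) {
    cat("  first frame: ")
    show(object@frames[[1L]])
  }
})

## ---------------------------------------------------------------------------
## RelaxResult
## ---------------------------------------------------------------------------

#' RelaxResult: outcome of one relaxation
#'
#' @slot structure relaxed solute [Structure-class] (water/ions stripped).
#' @slot initialEnergy,finalEnergy backend energy units (kcal/mol for the
#'   fallback backend).
#' @slot converged logical.
#' @slot failureReason character ("" when converged).
#' @slot trace numeric vector of energies at each report interval.
#' @export
setClass("RelaxResult",
         slots = c(structure = "Structure", initialEnergy = "numeric",
                   finalEnergy = "numeric", converged = "logical",
                   failureReason = "character", trace = "numeric"))

setValidity("RelaxResult", function(object) {
  if (object@converged && is.finite(object@finalEnergy) &&
      is.finite(object@initialEnergy) &&
      object@finalEnergy > object@initialEnergy + 1e-6)
    return("a converged result cannot raise the energy")
  TRUE
})

setMethod("show", "RelaxResult", function(object) {
  cat("RelaxResult: E ", format(object@initialEnergy, digits = 6), " -> ",
      format(object@finalEnergy, digits = 6),
      if (object@converged) "  [converged]" else
        paste0("  [FAILED: ", object@failureReason, "]"), "\n", sep = "")
})

#' @rdname RelaxResult-class
#' @param x a RelaxResult.
#' @export
relaxedStructure <- function(x) x@structure

#' @rdname RelaxResult-class
#' @export
energyTrace <- function(x) x@trace

#' @rdname RelaxResult-class
#' @export
isConverged <- function(x) x@converged

## ---------------------------------------------------------------------------
## SolvatedSystem
## ---------------------------------------------------------------------------

#' SolvatedSystem: a solute in a cubic water box with ions
#'
#' @slot solute the solute [Structure-class].
#' @slot waters numeric matrix of water oxygen positions (n x 3, A).
#' @slot ions data.frame with columns `species`, `x`, `y`, `z`.
#' @slot boxEdge cubic box edge length (A).
#' @slot origin numeric length-3, lower box corner.
#' @export
setClass("SolvatedSystem",
         slots = c(solute = "Structure", waters = "matrix",
                   ions = "data.frame", boxEdge = "numeric",
                   origin = "numeric"))

setMethod("show", "SolvatedSystem", function(object) {
  cat("SolvatedSystem: box edge ", round(object@boxEdge, 2), " A, ",
      nrow(object@waters), " waters, ", nrow(object@ions), " ions (",
      paste(names(table(object@ions$species)), table(object@ions$species),
            collapse = ", "), ")\n", sep = "")
})

#' @rdname SolvatedSystem-class
#' @param x a SolvatedSystem.
#' @export
solute <- function(x) x@solute

#' @rdname SolvatedSystem-class
#' @export
boxEdge <- function(x) x@boxEdge

#' @rdname SolvatedSystem-class
#' @export
ionTable <- function(x) x@ions

#' @rdname SolvatedSystem-class
#' @export
waterPositions <- function(x) x@waters

## ---------------------------------------------------------------------------
## FitnessMatrix
## ---------------------------------------------------------------------------

#' FitnessMatrix: maintained WT hydrogen bonds per mutant
#'
#' Positions x substitutions matrix of the binding-fitness proxy: the
#' number of wild-type dominant interface hydrogen bonds maintained in
#' each relaxed mutant complex. Rows are scanned positions (named by WT
#' letter + author residue number, e.g. "E27"), columns the 20 amino-acid
#' letters; the WT identity cell and failed mutants are `NA` (failures are
#' additionally listed in `missing`).
#'
#' @slot values numeric matrix.
#' @slot positions integer vector of author residue numbers.
#' @slot wt character vector of WT 1-letter codes, one per position.
#' @slot wtBonds data.frame of the reference WT bond pairs.
#' @slot missing character vector of failed mutant labels.
#' @export
setClass("FitnessMatrix",
         slots = c(values = "matrix", positions = "integer",
                   wt = "character", wtBonds = "data.frame",
                   missing = "character"))

setValidity("FitnessMatrix", function(object) {
  if (nrow(object@values) != length(object@positions))
    return("one matrix row per position required")
  if (length(object@wt) != length(object@positions))
    return("one WT letter per position required")
  v <- object@values[!is.na(object@values)]
  if (length(v) && (any(v < 0) || any(v > max(1L, nrow(object@wtBonds)))))
    return("values must lie in [0, number of WT bonds]")
  TRUE
})

#' @rdname FitnessMatrix-class
#' @param x a FitnessMatrix.
#' @export
fitnessValues <- function(x) x@values

#' @rdname FitnessMatrix-class
#' @export
missingMutants <- function(x) x@missing

#' @rdname FitnessMatrix-class
#' @export
scanPositions <- function(x) x@positions

setMethod("show", "FitnessMatrix", function(object) {
  cat("FitnessMatrix: ", nrow(object@values), " positions x ",
      ncol(object@values), " substitutions, reference set of ",
      nrow(object@wtBonds), " WT bonds\n", sep = "")
  if (length(object@missing))
    cat("  missing (failed) mutants: ",
        paste(object@missing, collapse = ", "), "\n", sep = "")
})

#' Long-form view of a FitnessMatrix
#'
#' @param x a [FitnessMatrix-class] object.
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @return data.frame with columns `label`, `position`, `wt`, `mut`, `n_hb`.
#' @export
setMethod("as.data.frame", "FitnessMatrix",
          function(x, row.names = NULL, optional = FALSE, ...) {
  v <- x@values
  out <- data.frame(
    position = rep(x@positions, times = ncol(v)),
    wt = rep(x@wt, times = ncol(v)),
    mut = rep(colnames(v), each = nrow(v)),
    n_hb = as.vector(v), stringsAsFactors = FALSE)
  out <- out[out$wt != out$mut, , drop = FALSE]
  out$label <- paste0(out$wt, out$position, out$mut)
  out <- out[order(out$position, out$mut), c("label", "position", "wt",
                                             "mut", "n_hb")]
  rownames(out) <- NULL
  out
})
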