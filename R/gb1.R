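# Reference inputs for the GB1 / IgG-Fc study system: the 56-residue B1
# domain sequence (author numbering) and the wild-type dominant interface
# hydrogen-bond occupancy table from long bound-state dynamics.

.GB1_SEQ <- "MTYKLILNGKTLKGETTTEAVDAATAEKVFKQYANDNGVDGEWTYDDATKTFTVTE"

#' GB1 reference sequence
#'
#' The 56-residue B1 immunoglobulin-binding domain of streptococcal
#' protein G in author numbering, the focal molecule of the saturation
#' scan (56 x 19 = 1064 single mutants). Key interface positions resolve
#' through this numbering: E27, K28, K31, N35, D40, E42, W43.
#'
#' @return a 1-letter amino-acid string of length 56.
#' @examples
#' nrow(enumerateMutations(gb1Sequence()))  # 1064
#' @export
gb1Sequence <- function() .GB1_SEQ

#' Wild-type GB1/IgG-Fc interface hydrogen-bond occupancies
#'
#' The reference residue-moiety occupancy table of the wild-type bound
#' complex, measured over long equilibrium dynamics of the bound state
#' (microsecond scale): nine interface pairs, all with occupancy above
#' 20 percent. Shipped as package data; the dominant subset of this table
#' is the maintained-bond reference set of the fitness proxy.
#'
#' @return data.frame with columns `focal_resno`, `focal_moiety`,
#'   `partner_resno`, `partner_moiety`, `occupancy` (fraction).
#' @seealso [dominantBonds()], [countWtBonds()]
#' @export
gb1InterfaceOccupancies <- function() {
  path <- system.file("extdata", "gb1_wt_interface_occupancies.csv",
                      package = "mumiscan", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Candidate positions for post-scan dynamics
#'
#' The binding-proximal position subset used for short-dynamics follow-up
#' (14 positions x 19 = 266 mutants). The set is derived from the
#' interface-probability ranking of a full mutant scan
#' ([rankInterfacePositions()]); this accessor records the candidate set
#' used with the default study conditions.
#'
#' @return integer vector of 14 author-numbered positions.
#' @export
mumiDynPositions <- function() {
  c(25L, 27L, 28L, 29L, 31L, 32L, 33L, 35L, 36L, 40L, 41L, 42L, 43L, 54L)
}

#' Mutants failing the excess-energy screen
#'
#' Labels of the five mutants whose post-graft relaxation showed excess
#' energy in the reference study conditions, excluded from the
#' short-dynamics follow-up (266 - 5 = 261 usable systems).
#'
#' @return character vector of mutation labels.
#' @export
knownFailedMutants <- function() c("D40L", "E42H", "E42M", "E42F", "E42Y")

#' Allosteric residue annotation for GB1
#'
#' Residues described as allosteric for GB1 in prior work, used as an
#' annotation category in RSA comparisons.
#'
#' @return integer vector of author-numbered positions.
#' @export
gb1AllostericResidues <- function() c(9L, 12L, 14L, 30L, 33L, 37L, 39L, 56L)
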