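#!/usr/bin/env Rscript
# OPTIONAL full-scale reproduction workflow (not desk scale).
#
# Reproducing the published crystal-structure analysis requires (a)
# network access to fetch the 1PGA (unbound GB1) and 1FCC (GB1 bound to
# the IgG-Fc domain) entries from the PDB, and (b) an explicit-solvent
# molecular-dynamics engine registered as the "engine" minimization
# backend for the solvated 10,000-step minimizations (the built-in
# fallback potential is a reduced model; interface hydrogen-bond counts
# and RSA profiles computed with it are qualitative only). Occupancy
# tables additionally require microsecond-scale bound-state trajectories
# and are reproducible only within sampling error at reduced length.
#
# Expected outcomes at full scale, for orientation:
#   - minimized WT complex: 9 dominant interface hydrogen bonds, two each
#     at GB1 positions 27 and 28, one each at 35/39/40/42/43;
#   - bound GB1: 33 residues with RSA > 25 (surface residues);
#   - heavy-atom RMSD of E27V / K31L / W43K relaxation near
#     1.15 / 1.07 / 1.11 A (backend-dependent, +-0.3 A).
#
# Usage: Rscript scripts/reproduce_full.R [--workdir DIR]

suppressPackageStartupMessages({
  library(optparse)
  library(mumiscan)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--workdir", default = "reproduction"))))
dir.create(opts$workdir, showWarnings = FALSE, recursive = TRUE)

fetch <- function(id) {
  path <- file.path(opts$workdir, paste0(id, ".pdb"))
  if (!file.exists(path))
    download.file(sprintf("https://files.rcsb.org/download/%s.pdb", id),
                  path, quiet = TRUE)
  path
}

message("fetching crystal structures (network required) ...")
unboundPath <- fetch("1pga")
boundPath <- fetch("1fcc")

unbound <- readPdb(unboundPath, label = "GB1_unbound")
bound <- readPdb(boundPath, label = "GB1_IgGFc")

## 1FCC: GB1 is the short chain
rt <- residueTable(bound)
counts <- table(rt$chain)
gb1Chain <- names(counts)[which.min(counts)]
parts <- splitComplex(bound, gb1Chain)
message("GB1 chain: ", gb1Chain, " (", min(counts), " residues); partner: ",
        max(counts), " residues")

backend <- if (is.function(getOption("mumiscan.engineBackend")))
  "engine" else "fallback"
if (backend == "fallback")
  message("NOTE: no engine backend registered; using the reduced fallback ",
          "potential - results are qualitative")

minim <- minimizationSpec(steps = 10000L, backend = backend)

message("relaxing the WT complex ...")
prot <- addPolarHydrogens(bound)
wtRelax <- minimizeSystem(
  if (backend == "engine") buildBox(prot, solvationSpec(), seed = 1) else
    prot, minim)
wtMin <- relaxedStructure(wtRelax)

partnerChains <- setdiff(chains(bound), gb1Chain)
wtBonds <- detectHBonds(wtMin, between = list(gb1Chain, partnerChains))
message("WT interface hydrogen bonds after minimization: ", nrow(wtBonds))
print(table(wtBonds$donor_resno))

message("RSA of bound GB1 ...")
boundRsa <- rsa(wtMin)
gb1Rsa <- boundRsa[boundRsa$chain == gb1Chain, ]
message("surface residues (RSA > 25): ", sum(gb1Rsa$rsa > 25), " of ",
        nrow(gb1Rsa))

message("example mutant relaxations (E27V, K31L, W43K) ...")
for (lbl in c("E27V", "K31L", "W43K")) {
  spec <- list(position = as.integer(gsub("\\D", "", lbl)),
               wt = substr(lbl, 1, 1), mut = substr(lbl, nchar(lbl),
                                                    nchar(lbl)))
  mut <- applyMutation(prot, spec, chain = gb1Chain)
  res <- minimizeSystem(
    if (backend == "engine") buildBox(mut, solvationSpec(), seed = 2) else
      mut, minim)
  message(lbl, ": heavy-atom RMSD initial->final = ",
          round(rmsdHeavy(mut, relaxedStructure(res)), 2), " A")
}

message("full saturation scan (1064 mutants) - uncomment to run:")
message("  sc <- scanComplex(prot, gb1Chain, minimization = minim)")
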