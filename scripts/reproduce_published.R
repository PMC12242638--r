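#!/usr/bin/env Rscript
# Reproduce the two published data-dependent checks, given network access or
# pre-downloaded inputs in a local directory:
#
#   1. Hierarchical clustering of the deposited ROCK1/ROCK2 active SMILES at
#      Tanimoto-distance threshold 0.5 (expected 45 and 67 clusters), swept
#      over linkage criteria since the published linkage is unstated.
#   2. ATP-site comparison of ROCK1 (PDB 6EW9) vs ROCK2 (PDB 6ED6) with
#      10-Angstrom ligand-radius sites: residue identity (expected 100%) and
#      Kabsch RMSD (expected ~0.885 A) under Calpha/backbone/heavy-atom
#      selections.
#
# Usage: Rscript scripts/reproduce_published.R [--data-dir dir]
# Inputs expected (downloaded if absent and a network is available):
#   <data-dir>/rock1_actives.csv, rock2_actives.csv  (column: smiles)
#   <data-dir>/6EW9.pdb, 6ED6.pdb

suppressMessages(library(phorescreen))

args <- commandArgs(trailingOnly = TRUE)
i <- which(args == "--data-dir")
data_dir <- if (length(i) && i < length(args)) args[i + 1] else "data_published"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

fetch <- function(url, dest) {
  if (file.exists(dest)) return(TRUE)
  ok <- tryCatch({
    utils::download.file(url, dest, quiet = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  ok && file.exists(dest)
}

base <- "https://raw.githubusercontent.com/pedrosenamp/ROCK_virtual_screening/main"
for (f in c("rock1_actives.csv", "rock2_actives.csv")) {
  fetch(file.path(base, f), file.path(data_dir, f))
}
for (p in c("6EW9", "6ED6")) {
  fetch(sprintf("https://files.rcsb.org/download/%s.pdb", p),
        file.path(data_dir, paste0(p, ".pdb")))
}

for (tgt in c("rock1", "rock2")) {
  path <- file.path(data_dir, paste0(tgt, "_actives.csv"))
  if (!file.exists(path)) {
    message(tgt, " actives not available (", path, " missing); skipping")
    next
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  smi_col <- intersect(c("smiles", "canonical_smiles", "SMILES"), names(tab))[1]
  cmp <- data.frame(compound_id = sprintf("%s_%04d", tgt, seq_len(nrow(tab))),
                    smiles = tab[[smi_col]], stringsAsFactors = FALSE)
  filt <- apply_structural_filters(cmp)
  fps <- fingerprint_matrix(filt$kept$canonical_smiles,
                            ids = filt$kept$compound_id)
  for (linkage in c("average", "complete", "single", "ward.D2")) {
    div <- diversity_select(
      data.frame(compound_id = filt$kept$compound_id,
                 smiles = filt$kept$canonical_smiles),
      distance_threshold = 0.5, linkage = linkage, fps = fps)
    cat(sprintf("%s actives, %s linkage: %d clusters\n",
                toupper(tgt), linkage, div$n_clusters))
  }
}

pa <- file.path(data_dir, "6EW9.pdb")
pb <- file.path(data_dir, "6ED6.pdb")
if (file.exists(pa) && file.exists(pb)) {
  sa <- read_structure(pa)
  sb <- read_structure(pb)
  lig_a <- sa$ligand_resnames[1]
  lig_b <- sb$ligand_resnames[1]
  site_a <- extract_site(sa, lig_a, 10)
  site_b <- extract_site(sb, lig_b, 10)
  for (mode in c("ca", "backbone", "heavy")) {
    cmp <- compare_sites(site_a, site_b, atoms = mode, sasa = (mode == "heavy"))
    cat(sprintf("6EW9 vs 6ED6 (%s): identity %.1f%%, RMSD %.3f A\n",
                mode, cmp$identity, cmp$rmsd))
    if (!is.null(cmp$sasa_a)) {
      cat(sprintf("  site SASA: %.0f vs %.0f A^2\n", cmp$sasa_a, cmp$sasa_b))
    }
  }
} else {
  message("PDB entries 6EW9/6ED6 not available; skipping site comparison")
}
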