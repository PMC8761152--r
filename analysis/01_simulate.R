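#!/usr/bin/env Rscript

## Step 1: build the synthetic study set.
##
## Generates a small "proteome" of membrane-protein-like C-alpha models with
## known ground truth: 40 correct helix bundles (mixed helix counts, mild
## coordinate noise), 6 collapse decoys and 4 inverted-helix decoys whose
## topology annotations deliberately describe the *correct* structure, plus
## a fabricated hmmsearch domain table for the fold-survey step.  Everything
## downstream (02-04) reads only what this script writes.

suppressMessages(library(memqa))

out <- "results/sim"
dir.create(file.path(out, "structures"), recursive = TRUE, showWarnings = FALSE)

annotations <- list()
manifest <- data.frame()

put <- function(s, topo, truth_thickness, kind) {
  id <- attr(s, "id")
  write_structure(s, file.path(out, "structures", paste0(id, ".pdb")))
  topo$protein_id <- id
  annotations[[length(annotations) + 1]] <<- topo
  manifest <<- rbind(manifest, data.frame(protein_id = id, kind = kind,
                                          true_thickness = truth_thickness))
}

for (i in 1:40) {
  spec <- bundle_spec(n_helices = c(2, 4, 6)[1 + i %% 3], radius = 6 + 2 * (i %% 3),
                      target_thickness = 30, noise_sigma = 0.3, seed = i)
  b <- generate_bundle(spec)
  put(b$structure, b$topology, 30, "correct")
}
for (i in 1:6) {
  b <- generate_bundle(bundle_spec(noise_sigma = 0.3, seed = 200 + i))
  put(make_decoy(b$structure, b$topology, "collapse"), b$topology, 12, "collapse_decoy")
}
for (i in 1:4) {
  b <- generate_bundle(bundle_spec(noise_sigma = 0.3, seed = 300 + i))
  put(make_decoy(b$structure, b$topology, "invert_helix"), b$topology, NA, "inverted_decoy")
}

write_topology_xml(annotations, file.path(out, "topology.xml"))
write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## hmmsearch table: every correct/decoy structure hits a fabricated ABC
## profile; three extra targets are constructed to fail the PFAM filter
## (high E-value or short profile coverage).
hits <- data.frame(target_id = manifest$protein_id, hmm_name = "ABC_membrane",
                   hmm_length = 100L, e_value = 1e-6, hmm_from = 1L,
                   hmm_to = 100L, stringsAsFactors = FALSE)
hits <- rbind(hits,
              data.frame(target_id = c("reject_high_e", "reject_short", "reject_both"),
                         hmm_name = "ABC_membrane", hmm_length = 100L,
                         e_value = c(0.05, 1e-6, 0.2), hmm_from = 1L,
                         hmm_to = c(100L, 80L, 70L), stringsAsFactors = FALSE))
write_fixture_domtbl(hits, file.path(out, "hits.domtbl"))

cat(sprintf("simulated %d structures (%d correct, %d decoys) -> %s\n",
            nrow(manifest), sum(manifest$kind == "correct"),
            sum(manifest$kind != "correct"), out))
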