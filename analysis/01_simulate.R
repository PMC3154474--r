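#!/usr/bin/env Rscript
# Step 1: generate the synthetic study ensembles.
#
# Stand-ins for the study's MD trajectories (five runs per adduct with
# hydrogen-bond classes planted at the published per-class fractions, plus
# an undamaged control) and for its NMR families (14-model platinated
# and undamaged duplexes). Writes the ground-truth bookkeeping and the
# NMR-family coordinates under results/ensembles/.

source("analysis/00_common.R")
dir.create("results/ensembles", recursive = TRUE, showWarnings = FALSE)

for (label in names(CLASS_FRACTIONS)) {
  runs <- adduct_runs(label)
  truth <- do.call(rbind, lapply(seq_along(runs), function(r) {
    tt <- runs[[r]]$truth
    tt$run <- r
    tt$class <- runs[[r]]$class_labels
    tt
  }))
  slug <- gsub("[^A-Za-z0-9]", "_", label)
  write_tsv(truth, sprintf("results/ensembles/%s_ground_truth.tsv", slug))
  planted <- table(truth$class)
  cat(sprintf("[%s] %d frames over %d runs; planted classes: %s\n",
              label, nrow(truth), length(runs),
              paste(names(planted), planted, collapse = ", ")))
}

und <- cached("undamaged_runs", lapply(seq_len(N_RUNS), function(r) {
  sample_ensemble(undamaged_spec(FRAMES_PER_RUN, BASE_SEED + 5000 + r))
}))
cat(sprintf("[undamaged] %d frames over %d runs (no Pt moiety)\n",
            N_RUNS * FRAMES_PER_RUN, N_RUNS))

fam_ox <- cached("family_ox", sample_ensemble(
  nmr_family_spec(platinated = TRUE, seed = BASE_SEED + 21)))
fam_und <- cached("family_und", sample_ensemble(
  nmr_family_spec(platinated = FALSE, seed = BASE_SEED + 22)))
write_pdb_ensemble(fam_ox$ensemble, "results/ensembles/family_ptgg.pdb")
write_pdb_ensemble(fam_und$ensemble, "results/ensembles/family_undamaged.pdb")
cat("[families] wrote 14-model platinated and undamaged families\n")
cat("done: ensembles cached under scratch/, bookkeeping under results/ensembles/\n")
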