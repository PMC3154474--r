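#!/usr/bin/env Rscript
# Step 5: superposition statistics. Family RMSD to the iterative mean
# (all atoms and heavy atoms) for the two 14-model families, the
# centroid frame of each MD stand-in and its distance to the family
# mean, and a smoothed per-frame RMSD series (running average over a
# centered window, the trajectory-stability diagnostic).

source("analysis/00_common.R")
dir.create("results/superpose", recursive = TRUE, showWarnings = FALSE)

fam_ox <- cached("family_ox", stop("run analysis/01_simulate.R first"))
fam_und <- cached("family_und", stop("run analysis/01_simulate.R first"))

fam_stats <- NULL
families <- list("Pt-GG" = fam_ox, "undamaged" = fam_und)
for (label in names(families)) {
  fam <- families[[label]]
  r_all <- family_rmsd(fam$ensemble, selection_tag = "all atoms")
  r_heavy <- family_rmsd(fam$ensemble, selection = sel_heavy,
                         selection_tag = "non-H")
  cat(sprintf("[%s family] RMSD to mean: %.2f +/- %.2f (all), %.2f +/- %.2f (non-H)\n",
              label, r_all$mean, r_all$sd, r_heavy$mean, r_heavy$sd))
  fam_stats <- rbind(fam_stats, data.frame(
    family = label,
    all_atoms = sprintf("%.2f +/- %.2f", r_all$mean, r_all$sd),
    non_h = sprintf("%.2f +/- %.2f", r_heavy$mean, r_heavy$sd)))
}
write_tsv(fam_stats, "results/superpose/family_rmsd.tsv")

for (label in names(CLASS_FRACTIONS)) {
  runs <- adduct_runs(label)
  ens <- runs[[1]]$ensemble  # one run suffices for the series diagnostic
  mu <- mean_structure(ens)
  ci <- centroid_model(ens)
  cat(sprintf("[%s run 1] centroid frame %d; RMSD(centroid, mean) = %.2f A\n",
              label, ci,
              kabsch(ptggdyn:::model_xyz(ensemble_model(ens, ci)),
                     ptggdyn:::model_xyz(mu))$rmsd))
  w <- atomic_mass(ens$atoms$element)
  series <- rmsd_series(ens, mu, window = 25, weights = w)
  slug <- gsub("[^A-Za-z0-9]", "_", label)
  write_tsv(data.frame(frame = seq_along(series), rmsd = series),
            sprintf("results/superpose/%s_rmsd_series.tsv", slug))
  cat(sprintf("[%s run 1] smoothed mass-weighted RMSD to mean: %.2f-%.2f A\n",
              label, min(series), max(series)))
}

cat("done: superposition reports under results/superpose/\n")
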