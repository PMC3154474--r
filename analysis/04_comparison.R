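#!/usr/bin/env Rscript
# Step 4: ensemble comparison heat maps. Z-score matrices compare the
# small 14-model families (platinated vs undamaged); KS-ratio matrices
# compare the hydrogen-bond classes within each adduct's MD stand-in
# (a ratio above 1 marks a parameter whose class-conditional
# distributions differ at the 0.05 level).

source("analysis/00_common.R")
dir.create("results/comparison", recursive = TRUE, showWarnings = FALSE)

## Z-scores between the two 14-model families
fam_ox <- cached("family_ox", stop("run analysis/01_simulate.R first"))
fam_und <- cached("family_und", stop("run analysis/01_simulate.R first"))
zt <- comparison_matrix(
  list("Pt-GG" = compute_param_table(fam_ox$ensemble, gg_dihedral = FALSE),
       "undamaged" = compute_param_table(fam_und$ensemble,
                                         gg_dihedral = FALSE)),
  statistic = "z")
write_comparison_matrix(zt, "results/comparison/families_zscore.tsv")
top <- order(abs(zt[, 1]), decreasing = TRUE)[1:4]
cat("[families] largest |Z| parameters (Pt-GG vs undamaged):\n")
for (i in top) cat(sprintf("  %-22s Z = %6.2f\n", rownames(zt)[i], zt[i, 1]))

## KS ratios between hydrogen-bond classes within each adduct
for (label in names(CLASS_FRACTIONS)) {
  runs <- adduct_runs(label)
  tab <- do.call(rbind, lapply(seq_along(runs), function(r) {
    tt <- compute_param_table(runs[[r]]$ensemble, gg_dihedral = FALSE)
    tt$run <- r
    tt$class <- runs[[r]]$class_labels
    tt
  }))
  class(tab) <- c("param_table", "data.frame")
  tab <- trim_equilibration(tab, BURN_IN)
  by_class <- split(tab, tab$class)
  keep <- c("None", "G7-O6", "T8-O4")
  tables <- lapply(by_class[keep], function(d) {
    d <- d[, !(colnames(d) %in% c("run", "class"))]
    class(d) <- c("param_table", "data.frame")
    d
  })
  mat <- comparison_matrix(tables,
                           comparisons = list(c("G7-O6", "None"),
                                              c("T8-O4", "None"),
                                              c("T8-O4", "G7-O6")),
                           statistic = "ks_ratio", alpha = 0.05)
  slug <- gsub("[^A-Za-z0-9]", "_", label)
  write_comparison_matrix(mat, sprintf(
    "results/comparison/%s_class_ks_ratio.tsv", slug))
  cat(sprintf("[%s] parameters above the KS significance boundary:\n",
              label))
  for (cmp in colnames(mat)) {
    sig <- rownames(mat)[mat[, cmp] > 1]
    top1 <- rownames(mat)[which.max(mat[, cmp])]
    cat(sprintf("  %-18s %2d of %d (max: %s, ratio %.1f)\n", cmp,
                length(sig), nrow(mat), top1, max(mat[, cmp])))
  }
}

cat("done: heat-map matrices under results/comparison/\n")
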