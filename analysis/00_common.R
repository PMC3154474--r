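# Shared setup for the analysis scripts: study ensemble definitions and
# a scratch cache so later steps do not regenerate earlier ensembles.
# All sizes are desk-scale stand-ins for the study conditions: five
# independent runs per ensemble (the study used five 10 ns simulations
# per starting structure), 400 frames per run here, with the first 40
# percent of each run discarded as equilibration.

library(ptggdyn)

N_RUNS <- 5
FRAMES_PER_RUN <- 400
BURN_IN <- 0.4
BASE_SEED <- 20260927

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

# Planted per-class fractions mirroring the published per-class frequency rows
# (order: None, G-O6, T-O4, both).
CLASS_FRACTIONS <- list(
  "CP-TGGT" = c(0.29, 0.20, 0.37, 0.12),
  "OX-TGGT" = c(0.20, 0.59, 0.06, 0.13)
)

# One MD-emulating ensemble: N_RUNS planted runs concatenated, with a
# run column on the truth/label bookkeeping.
simulate_adduct_runs <- function(label, seed_base) {
  fr <- CLASS_FRACTIONS[[label]]
  runs <- lapply(seq_len(N_RUNS), function(r) {
    plant_hbond_classes(fr, n_frames = FRAMES_PER_RUN,
                        seed = seed_base + r)
  })
  runs
}

cached <- function(name, expr) {
  path <- file.path("scratch", paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- expr
  saveRDS(val, path)
  val
}

adduct_runs <- function(label) {
  seed_base <- BASE_SEED + 1000 * match(label, names(CLASS_FRACTIONS))
  cached(paste0("runs_", gsub("[^A-Za-z0-9]", "_", label)),
         simulate_adduct_runs(label, seed_base))
}

# NMR-family stand-ins: 14 conformers with tighter spread than the MD
# stand-ins (a refined family is more homogeneous than a trajectory).
nmr_family_spec <- function(platinated, seed) {
  generator_spec(n_frames = 14, seed = seed,
                 pair_sd = c(0.08, 0.06, 0.12, 4, 4, 2),
                 step_sd = c(0.2, 0.2, 0.12, 1.5, 2.5, 2.5),
                 pt = platinated)
}

undamaged_spec <- function(n_frames, seed) {
  generator_spec(n_frames = n_frames, seed = seed)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
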