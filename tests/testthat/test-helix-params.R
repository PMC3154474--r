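# Helical-parameter engine: frame fitting, mid-frame decomposition and
# its exact inverse, plane dihedral, bend, and per-ensemble tables.

test_that("mid-frame decomposition and its inverse round-trip exactly", {
  set.seed(101)
  worst <- 0
  for (i in 1:300) {
    par <- c(stats::runif(3, -3, 3), stats::runif(3, -60, 60))
    R1 <- rand_rotation(); o1 <- stats::rnorm(3, sd = 5)
    f2 <- ptggdyn:::midframe_compose(R1, o1, par)
    out <- ptggdyn:::midframe_params(R1, o1, f2$R, f2$origin)
    worst <- max(worst, max(abs(out$par - par)))
  }
  expect_lt(worst, 1e-9)
})

test_that("swapping the two frames inverts the step as the rebuild oracle dictates", {
  set.seed(102)
  for (i in 1:20) {
    par <- c(stats::runif(3, -3, 3), stats::runif(3, -50, 50))
    R1 <- rand_rotation(); o1 <- stats::rnorm(3)
    f2 <- ptggdyn:::midframe_compose(R1, o1, par)
    sw <- ptggdyn:::midframe_params(f2$R, f2$origin, R1, o1)
    # rebuild: composing the swapped parameters from frame 2 recovers
    # frame 1 exactly
    back <- ptggdyn:::midframe_compose(f2$R, f2$origin, sw$par)
    expect_all_close(back$R, R1, 1e-8)
    expect_all_close(back$origin, o1, 1e-8)
    # twist-like and translational components are antisymmetric
    expect_all_close(sw$par[c(1, 2, 3, 6)], -par[c(1, 2, 3, 6)], 1e-8)
  }
})

test_that("fit_base_frame recovers an exact rigid placement and its residual matches Kabsch", {
  set.seed(103)
  m0 <- build_duplex()
  R <- rand_rotation(); t <- c(3, -2, 7)
  m <- transform_model(m0, R, t)
  f0 <- fit_base_frame(m0, 6)
  f <- fit_base_frame(m, 6)
  expect_all_close(f$R, R %*% f0$R, 1e-9)          # equivariance
  expect_all_close(f$origin, R %*% f0$origin + t, 1e-9)
  expect_lt(f$rmsd, 1e-9)                          # exact standard geometry
  # perturb ring atoms in-plane and compare the residual with a directly
  # coded Kabsch superposition of the standard base
  ring <- ring_atom_names("G")
  idx <- which(m0$resno == 6 & m0$name %in% ring)
  m2 <- m0
  m2[idx, c("x", "y", "z")] <- m2[idx, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * length(idx), sd = 0.01), ncol = 3)
  f2 <- fit_base_frame(m2, 6)
  obs <- as.matrix(m2[m2$resno == 6, c("x", "y", "z")])[
    match(ring, m2$name[m2$resno == 6]), ]
  std <- std_base_atoms("G", hydrogens = FALSE)[ring, ]
  expect_equal(f2$rmsd, kabsch(std, obs)$rmsd, tolerance = 1e-9)
})

test_that("missing ring atoms are frame errors naming the atom", {
  m <- build_duplex()
  m2 <- m[!(m$resno == 6 & m$name == "N7"), ]
  expect_error(fit_base_frame(m2, 6), "N7")
})

test_that("pair parameters read axis-aligned constructions literally", {
  f_w <- list(R = diag(3), origin = c(0, 2, 0))
  f_c <- list(R = diag(3) %*% ptggdyn:::flip_x(), origin = c(0, 0, 0))
  par <- base_pair_params(f_w, f_c)
  expect_equal(unname(par["stretch"]), 2)
  expect_all_close(par[c("shear", "stagger", "buckle", "propeller",
                         "opening")], rep(0, 5), 1e-12)
  # coincident frames (after the flip) give exactly zero
  par0 <- base_pair_params(list(R = diag(3), origin = c(0, 0, 0)), f_c)
  expect_all_close(as.numeric(par0), rep(0, 6), 1e-12)
})

test_that("anti-aligned pair frames raise an orientation error", {
  f_w <- list(R = diag(3), origin = c(0, 0, 0))
  f_c <- list(R = diag(3), origin = c(0, 0, 0)) # not flipped
  expect_error(base_pair_params(f_w, f_c), "orientation|anti-aligned")
})

test_that("builder/analyzer round-trip recovers every parameter to 1e-6", {
  set.seed(104)
  worst <- 0
  topo <- fixture_topology(platinated_residues = NULL)
  for (rep in 1:25) {
    p <- random_params(12)
    e <- fixture_ensemble(build_duplex(p))
    tab <- compute_param_table(e, pairs = 1:12, steps = 1:11,
                               gg_dihedral = FALSE)
    for (i in 1:12) {
      got <- as.numeric(tab[1, paste0("pair_", i, "_", 25 - i, "_",
                                      ptggdyn:::PAIR_PARAM_NAMES)])
      worst <- max(worst, max(abs(got - p$pair[i, ])))
    }
    for (s in 1:11) {
      got <- as.numeric(tab[1, paste0("step_", s, "_", s + 1, "_",
                                      ptggdyn:::STEP_PARAM_NAMES)])
      worst <- max(worst, max(abs(got - p$step[s, ])))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("all parameters are invariant under a global rigid transform", {
  set.seed(105)
  p <- random_params(12, angle_max = 40, trans_max = 1.5)
  m <- build_duplex(p)
  tab1 <- compute_param_table(fixture_ensemble(m), gg_dihedral = FALSE,
                              bend = TRUE)
  m2 <- transform_model(m, rand_rotation(), stats::rnorm(3, sd = 20))
  tab2 <- compute_param_table(fixture_ensemble(m2), gg_dihedral = FALSE,
                              bend = TRUE)
  expect_all_close(as.matrix(tab1[, -1]), as.matrix(tab2[, -1]), 1e-9)
})

test_that("the GG plane dihedral matches an independent SVD plane fit", {
  m <- build_duplex()
  expect_lt(gg_plane_dihedral(m, 6, 7), 36 + 1e-6) # some twist-induced angle
  # coplanar: same residue against itself is zero by construction
  expect_equal(gg_plane_dihedral(m, 6, 6), 0, tolerance = 1e-9)
  # a pure central-step roll of 30 deg with zero twist tilts the two
  # guanine planes by exactly 30 deg
  p <- bform_params(12); p$step[, "twist"] <- 0
  p$step[6, "roll"] <- 30
  m30 <- build_duplex(p)
  expect_equal(gg_plane_dihedral(m30, 6, 7), 30, tolerance = 1e-6)
  # independent SVD oracle on noisy bases
  set.seed(106)
  mn <- m
  pert <- which(mn$resno %in% c(6, 7))
  mn[pert, c("x", "y", "z")] <- mn[pert, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * length(pert), sd = 0.02), ncol = 3)
  svd_normal <- function(model, resno) {
    ring <- ring_atom_names("G")
    rows <- model[model$resno == resno & model$name %in% ring, ]
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    sv <- svd(sweep(xyz, 2, colMeans(xyz)))
    sv$v[, 3]
  }
  n1 <- svd_normal(mn, 6); n2 <- svd_normal(mn, 7)
  ang <- acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
  expect_equal(gg_plane_dihedral(mn, 6, 7), ang, tolerance = 1e-9)
})

test_that("bend angle sees a straight duplex as straight and a planted kink as its angle", {
  topo <- fixture_topology(platinated_residues = NULL)
  m <- build_duplex()
  expect_lt(bend_angle(m, topo), 0.5)
  p <- bform_params(12)
  p$step[6, "roll"] <- 40
  mk <- build_duplex(p)
  expect_lt(abs(bend_angle(mk, topo) - 40), 5)
  mk2 <- transform_model(mk, rand_rotation(), c(5, 5, 5))
  expect_equal(bend_angle(mk, topo), bend_angle(mk2, topo),
               tolerance = 1e-9)
})

test_that("param tables are per-frame deterministic with fixed designation", {
  m <- build_duplex()
  e <- duplex_ensemble(rep(list(m), 4),
                       topology = fixture_topology(platinated_residues = NULL))
  tab <- compute_param_table(e)
  expect_equal(nrow(tab), 4)
  expect_equal(nrow(unique(tab[, -1])), 1)  # identical rows
  # ideal B-form values
  expect_all_close(as.numeric(tab[1, grep("twist", names(tab))]),
                   rep(36, 3), 1e-9)
  expect_all_close(as.numeric(tab[1, grep("rise", names(tab))]),
                   rep(3.38, 3), 1e-9)
  expect_all_close(as.numeric(tab[1, grep("pair", names(tab))]),
                   rep(0, 24), 1e-9)
})

test_that("a planted central-step roll distribution is recovered", {
  spec <- generator_spec(n_frames = 100, seed = 42)
  spec$step_mean[6, "roll"] <- 25
  spec$step_sd <- c(0.2, 0.2, 0.2, 3, 5, 4)
  be <- sample_ensemble(spec)
  tab <- compute_param_table(be$ensemble, gg_dihedral = FALSE)
  got <- tab$step_6_7_roll
  expect_lt(abs(mean(got) - 25), 3 * 5 / sqrt(100))
  # and the analyzed values equal the generator's ground truth
  expect_all_close(got, be$truth$step_6_7_roll, 1e-6)
})
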