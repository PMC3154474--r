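# Geometric hydrogen-bond detection, frame classification, frequency
# tables and bond-occupancy aggregation.

# Minimal donor/H/acceptor model with prescribed D-A distance and
# D-H-A angle (donor a guanine N1 so the enumerator picks it up).
planted_triple <- function(distance, angle) {
  h_for <- function(beta) c(1.01 * cos(beta), 1.01 * sin(beta), 0)
  ang_at <- function(beta) {
    h <- h_for(beta)
    u <- -h; v <- c(distance, 0, 0) - h
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  beta <- if (abs(ang_at(0) - angle) < 1e-9) 0 else
    stats::uniroot(function(b) ang_at(b) - angle, c(0, pi * 0.999),
                   tol = 1e-12)$root
  structure_model(
    name = c("N1", "H1", "O6"),
    resname = c("DG", "DG", "DG"),
    resno = c(1, 1, 2),
    xyz = rbind(c(0, 0, 0), h_for(beta), c(distance, 0, 0)),
    chain = "A")
}

test_that("detection applies both cut-offs inclusively", {
  crit <- hbond_criteria()
  hits <- function(d, a) nrow(detect_hbonds(planted_triple(d, a),
                                            criteria = crit))
  expect_equal(hits(3.4, 170), 1)
  expect_equal(hits(3.6, 180), 0)   # distance fail
  expect_equal(hits(3.0, 134.9), 0) # angle just under
  expect_equal(hits(3.0, 135.0), 1) # boundary inclusive
  expect_equal(hits(3.5, 160), 1)   # boundary inclusive
  rec <- detect_hbonds(planted_triple(3.2, 150))
  expect_equal(rec$distance, 3.2, tolerance = 1e-9)
  expect_equal(rec$angle, 150, tolerance = 1e-6)
})

test_that("detection is invariant under rigid motion", {
  set.seed(301)
  spec <- generator_spec(pt = TRUE, n_frames = 1)
  m <- attach_platinum(build_duplex(list(pair = spec$pair_mean,
                                         step = spec$step_mean)))
  r1 <- detect_hbonds(m)
  m2 <- transform_model(m, rand_rotation(), stats::rnorm(3, sd = 8))
  r2 <- detect_hbonds(m2)
  expect_equal(r1$donor, r2$donor)
  expect_equal(r1$acceptor, r2$acceptor)
  expect_all_close(r1$distance, r2$distance, 1e-9)
  expect_all_close(r1$angle, r2$angle, 1e-7)
})

test_that("donor/acceptor enumeration follows base chemistry", {
  m <- build_duplex()
  sites <- enumerate_donors_acceptors(m)
  acc6 <- sites$acceptors$label[grepl("^G6-", sites$acceptors$label)]
  expect_setequal(acc6, c("G6-O6", "G6-N7", "G6-N3"))
  don6 <- unique(sites$donors$label[grepl("^G6-", sites$donors$label)])
  expect_setequal(don6, c("G6-N1", "G6-N2"))
  acc5 <- sites$acceptors$label[grepl("^T5-", sites$acceptors$label)]
  expect_setequal(acc5, c("T5-O4", "T5-O2"))
  # no platinum moiety, no amine donors
  expect_false(any(grepl("^Pt-", sites$donors$label)))
})

test_that("the Watson-Crick bonds of an ideal duplex are detected", {
  m <- build_duplex()
  recs <- detect_hbonds(m)
  # every G-C pair shows the G-N1..N3 and C-N4..O6 contacts
  expect_true(any(recs$donor == "G6-N1" & recs$acceptor == "C19-N3"))
  expect_true(any(recs$donor == "T5-N3" & recs$acceptor == "A20-N1"))
})

test_that("classification matches planted classes and is deterministic", {
  be <- plant_hbond_classes(c(0.25, 0.25, 0.25, 0.25), n_frames = 48,
                            seed = 13)
  cls <- classify_frames(be$ensemble)
  expect_equal(cls$class, be$class_labels)
  expect_identical(cls, classify_frames(be$ensemble))
  # every label family appears
  expect_setequal(unique(cls$class),
                  c("None", "G7-O6", "T8-O4", "T8-O4+G7-O6"))
})

test_that("a platinum-free ensemble is all None and an always-both plant all combination", {
  m <- build_duplex()
  e <- duplex_ensemble(rep(list(m), 3),
                       topology = fixture_topology())
  expect_true(all(classify_frames(e)$class == "None"))
  be <- plant_hbond_classes(c(0, 0, 0, 1), n_frames = 10, seed = 5)
  expect_true(all(classify_frames(be$ensemble)$class == "T8-O4+G7-O6"))
})

test_that("frequencies sum to ~100 and recover planted fractions", {
  planted <- c(0.29, 0.20, 0.37, 0.12)  # None, G-O6, T-O4, both
  be <- plant_hbond_classes(planted, n_frames = 2000, seed = 17)
  fq <- frequency_table(classify_frames(be$ensemble), digits = 2)
  expect_lt(abs(sum(fq$percent) - 100), 0.5)
  got <- stats::setNames(fq$percent, fq$class)
  want <- c("None" = 29, "G7-O6" = 20, "T8-O4" = 37, "T8-O4+G7-O6" = 12)
  for (cl in names(want)) {
    p <- want[[cl]] / 100
    bound <- 3 * sqrt(p * (1 - p) / 2000) * 100
    expect_lt(abs(got[[cl]] - want[[cl]]), bound)
  }
  # single frame: one class at 100 percent
  one <- frequency_table(classify_frames(
    duplex_ensemble(list(ensemble_model(be$ensemble, 1)),
                    topology = be$ensemble$topology)))
  expect_equal(one$percent, 100)
})

test_that("bond occupancies aggregate classes containing the bond", {
  tabs <- read_frequency_tsv(system.file("extdata",
                                         "table1_hbond_frequencies.tsv",
                                         package = "ptggdyn"))
  expect_equal(aggregate_bond_occupancy(tabs[["OX-TGGT"]], "G7-O6"), 72)
  expect_equal(aggregate_bond_occupancy(tabs[["CP-TGGT"]], "T8-O4"), 49)
  none_only <- frequency_table_from_percent(c("None" = 100, "G7-O6" = 0,
                                              "T8-O4" = 0))
  expect_equal(aggregate_bond_occupancy(none_only, "G7-O6"), 0)
  expect_error(aggregate_bond_occupancy(none_only, "X9-O2"), "lookup")
})
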