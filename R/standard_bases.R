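# Standard reference geometries for the four DNA bases, expressed in the
# standard base reference frame (origin between the Watson-Crick edges,
# x toward the major groove, y along the base long axis toward the
# attached sugar, z normal to the base plane). Bases are treated as ideal
# rigid planar bodies (z = 0); the glycosidic C1' is carried so that
# C1'-C1' distances across a pair are meaningful for topology checks.
# Polar (nitrogen-bound) hydrogens are derived from the heavy-atom
# geometry at load time with an N-H length of 1.01 A and ideal sp2
# in-plane placement; carbon-bound hydrogens are not modelled.

NH_BOND <- 1.01

.std_base_coords <- list(
  A = matrix(c(
    -2.479, 5.346,
    -1.291, 4.498,
     0.024, 4.897,
     0.877, 3.902,
     0.071, 2.771,
     0.369, 1.398,
     1.611, 0.909,
    -0.668, 0.532,
    -1.912, 1.023,
    -2.320, 2.290,
    -1.267, 3.124), ncol = 2, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "N6",
                      "N1", "C2", "N3", "C4"), NULL)),
  G = matrix(c(
    -2.477, 5.399,
    -1.289, 4.551,
     0.023, 4.962,
     0.870, 3.969,
     0.071, 2.833,
     0.424, 1.460,
     1.554, 0.955,
    -0.700, 0.641,
    -1.999, 1.087,
    -2.949, 0.139,
    -2.342, 2.364,
    -1.265, 3.177), ncol = 2, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "O6",
                      "N1", "C2", "N2", "N3", "C4"), NULL)),
  C = matrix(c(
    -2.477, 5.402,
    -1.285, 4.542,
    -1.472, 3.158,
    -2.628, 2.709,
    -0.391, 2.344,
     0.837, 2.868,
     1.875, 2.027,
     1.056, 4.275,
    -0.023, 5.068), ncol = 2, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "N4",
                      "C5", "C6"), NULL)),
  T = matrix(c(
    -2.481, 5.354,
    -1.284, 4.500,
    -1.462, 3.135,
    -2.562, 2.608,
    -0.298, 2.407,
     0.994, 2.897,
     1.944, 2.119,
     1.106, 4.338,
     2.466, 4.961,
    -0.024, 5.057), ncol = 2, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "O4",
                      "C5", "C7", "C6"), NULL))
)

# Ring atoms used for base-frame fitting.
PURINE_RING <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

# Nitrogen donors and the heavy atoms that define hydrogen placement.
# type "amine": N bonded to one in-base heavy atom, two in-plane H.
# type "imino": ring N between two heavy atoms, one bisector H.
.base_donor_defs <- list(
  A = list(N6 = list(type = "amine", anchor = "C6", h = c("H61", "H62"))),
  G = list(N1 = list(type = "imino", anchor = c("C2", "C6"), h = "H1"),
           N2 = list(type = "amine", anchor = "C2", h = c("H21", "H22"))),
  C = list(N4 = list(type = "amine", anchor = "C4", h = c("H41", "H42"))),
  T = list(N3 = list(type = "imino", anchor = c("C2", "C4"), h = "H3"))
)

# Base acceptor atoms (lone-pair sites on the Watson-Crick and major/minor
# groove edges).
.base_acceptor_atoms <- list(
  A = c("N7", "N1", "N3"),
  G = c("O6", "N7", "N3"),
  C = c("O2", "N3"),
  T = c("O2", "O4")
)

.rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

.place_base_hydrogens <- function(base) {
  heavy <- .std_base_coords[[base]]
  defs <- .base_donor_defs[[base]]
  out <- NULL
  for (nname in names(defs)) {
    d <- defs[[nname]]
    N <- heavy[nname, ]
    if (d$type == "imino") {
      u1 <- (heavy[d$anchor[1], ] - N); u1 <- u1 / sqrt(sum(u1^2))
      u2 <- (heavy[d$anchor[2], ] - N); u2 <- u2 / sqrt(sum(u2^2))
      dir <- -(u1 + u2); dir <- dir / sqrt(sum(dir^2))
      h <- rbind(N + NH_BOND * dir)
      rownames(h) <- d$h
    } else {
      u <- N - heavy[d$anchor, ]; u <- u / sqrt(sum(u^2))
      h <- rbind(N + NH_BOND * drop(.rot2(pi / 3) %*% u),
                 N + NH_BOND * drop(.rot2(-pi / 3) %*% u))
      rownames(h) <- d$h
    }
    out <- rbind(out, h)
  }
  out
}

# Full standard atom set (heavy + polar H) in frame coordinates, 3 columns.
std_base_atoms <- function(base, hydrogens = TRUE) {
  base <- toupper(base)
  if (!base %in% names(.std_base_coords)) {
    stop("unknown base letter: ", base)
  }
  xy <- .std_base_coords[[base]]
  if (hydrogens) xy <- rbind(xy, .place_base_hydrogens(base))
  cbind(xy, z = 0)
}

ring_atom_names <- function(base) {
  if (toupper(base) %in% c("A", "G")) PURINE_RING else PYRIMIDINE_RING
}

is_purine <- function(base) toupper(base) %in% c("A", "G")

complement_base <- function(base) {
  c(A = "T", T = "A", G = "C", C = "G")[toupper(base)]
}

element_from_name <- function(name) {
  ifelse(toupper(name) == "PT", "Pt",
         toupper(substr(gsub("^[0-9]", "", name), 1, 1)))
}
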