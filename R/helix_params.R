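# Helical-parameter engine: base frames fitted against the standard
# reference geometry, intra-base-pair and base-pair-step parameters from
# the shared mid-frame decomposition, the guanine-guanine plane dihedral,
# and a two-segment global bend estimate.

PAIR_PARAM_NAMES <- c("shear", "stretch", "stagger",
                      "buckle", "propeller", "opening")
STEP_PARAM_NAMES <- c("shift", "slide", "rise", "tilt", "roll", "twist")

base_letter <- function(resname) {
  substr(resname, nchar(resname), nchar(resname))
}

#' Fit the standard reference frame to a base
#'
#' The frame is the least-squares rigid superposition (Kabsch) of the
#' standard-geometry base ring atoms onto the observed ring atoms: x
#' toward the major-groove edge, y along the base long axis, z the base
#' normal. The fit residual is reported.
#'
#' @param model a `structure_model`.
#' @param resno residue number of the base.
#' @return list with `R` (3 x 3 axes as columns), `origin`, `rmsd`, and
#'   the base letter.
#' @export
fit_base_frame <- function(model, resno) {
  rows <- model[model$resno == resno & model$type == "ATOM", ]
  if (nrow(rows) == 0) stop("frame error: no residue ", resno)
  base <- base_letter(rows$resname[1])
  ring <- ring_atom_names(base)
  idx <- match(ring, rows$name)
  if (any(is.na(idx))) {
    stop("frame error: residue ", resno, " missing ring atom ",
         ring[which(is.na(idx))[1]])
  }
  obs <- model_xyz(rows)[idx, , drop = FALSE]
  std <- std_base_atoms(base, hydrogens = FALSE)[ring, , drop = FALSE]
  sup <- kabsch(std, obs)
  list(R = sup$rotation, origin = sup$translation, rmsd = sup$rmsd,
       base = base)
}

#' Intra-base-pair parameters from two base frames
#'
#' The complementary-base frame is flipped 180 degrees about its x axis
#' and the mid-frame decomposition applied, giving shear/stretch/stagger
#' (Angstrom) and buckle/propeller/opening (degrees).
#'
#' @param frame_W frame of the strand-I (Watson) base from
#'   [fit_base_frame()].
#' @param frame_C frame of its complementary base.
#' @return named numeric vector of the six pair parameters, with the pair
#'   mid-frame attached as attribute `"mid"` (used for step parameters).
#' @export
base_pair_params <- function(frame_W, frame_C) {
  Rcf <- frame_C$R %*% flip_x()
  if (sum(Rcf[, 3] * frame_W$R[, 3]) < 0) {
    stop("orientation error: pair z axes anti-aligned after flipping")
  }
  out <- midframe_params(Rcf, frame_C$origin, frame_W$R, frame_W$origin)
  par <- out$par
  names(par) <- PAIR_PARAM_NAMES
  attr(par, "mid") <- out$mid
  par
}

#' Pair reference frame
#'
#' Mid-frame of a base pair (the frame whose sequence along the duplex
#' defines the step parameters).
#' @inheritParams base_pair_params
#' @export
pair_frame <- function(frame_W, frame_C) {
  attr(base_pair_params(frame_W, frame_C), "mid")
}

#' Base-pair-step parameters from two consecutive pair frames
#'
#' Same mid-frame decomposition as [base_pair_params()], read as
#' shift/slide/rise (Angstrom) and tilt/roll/twist (degrees).
#'
#' @param pf1,pf2 pair frames of two consecutive pairs (5' to 3' along
#'   strand I), as returned by [pair_frame()].
#' @export
step_params <- function(pf1, pf2) {
  out <- midframe_params(pf1$R, pf1$origin, pf2$R, pf2$origin)
  par <- out$par
  names(par) <- STEP_PARAM_NAMES
  attr(par, "mid") <- out$mid
  par
}

ls_plane_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  M <- sweep(xyz, 2, ctr)
  e <- eigen(crossprod(M), symmetric = TRUE)
  if (e$values[2] < 1e-9) stop("degenerate-plane error: collinear atoms")
  unitv(e$vectors[, 3])
}

#' Angle between the least-squares planes of two bases
#'
#' The dihedral-type distortion of the platinated GG step: the angle in
#' [0, 90] degrees between the least-squares base-plane normals of the
#' two (purine) residues.
#'
#' @param model a `structure_model`.
#' @param resno_a,resno_b residue numbers of the two bases.
#' @export
gg_plane_dihedral <- function(model, resno_a, resno_b) {
  norm_of <- function(resno) {
    rows <- model[model$resno == resno & model$type == "ATOM", ]
    if (nrow(rows) == 0) stop("frame error: no residue ", resno)
    ring <- ring_atom_names(base_letter(rows$resname[1]))
    idx <- match(ring, rows$name)
    if (any(is.na(idx))) {
      stop("frame error: residue ", resno, " missing ring atom ",
           ring[which(is.na(idx))[1]])
    }
    ls_plane_normal(model_xyz(rows)[idx, , drop = FALSE])
  }
  ang <- vec_angle(norm_of(resno_a), norm_of(resno_b))
  if (ang > 90) ang <- 180 - ang
  ang
}

segment_axis <- function(frames) {
  origins <- t(vapply(frames, function(f) f$origin, numeric(3)))
  zbar <- unitv(Reduce(`+`, lapply(frames, function(f) f$R[, 3])))
  ctr <- colMeans(origins)
  M <- sweep(origins, 2, ctr)
  e <- eigen(crossprod(M), symmetric = TRUE)
  if (e$values[1] > 1e-6) {
    u <- e$vectors[, 1]
    if (sum(u * zbar) < 0) u <- -u
    unitv(u + zbar)
  } else {
    zbar
  }
}

#' Global bend angle of a duplex
#'
#' Angle (degrees) between the best-fit helix axes of the first and last
#' `n_end` base pairs; each segment axis blends the principal direction of
#' the pair origins with the mean pair normal.
#'
#' @param model a `structure_model`.
#' @param topology a `duplex_topology`.
#' @param n_end pairs per terminal segment (>= 4 pairs required).
#' @export
bend_angle <- function(model, topology, n_end = 4) {
  np <- nrow(topology$pairs)
  if (np < 2 * n_end) stop("length error: need at least ", 2 * n_end, " pairs")
  pf <- lapply(seq_len(np), function(i) {
    fw <- fit_base_frame(model, topology$pairs[i, 1])
    fc <- fit_base_frame(model, topology$pairs[i, 2])
    pair_frame(fw, fc)
  })
  a1 <- segment_axis(pf[seq_len(n_end)])
  a2 <- segment_axis(pf[(np - n_end + 1):np])
  vec_angle(a1, a2)
}

#' Default designation: the central four pairs and the steps they span
#' @param topology a `duplex_topology`.
#' @export
central_designation <- function(topology) {
  np <- nrow(topology$pairs)
  mid <- np / 2
  pairs <- (mid - 1):(mid + 2)
  list(pairs = pairs, steps = pairs[-length(pairs)])
}

#' Per-frame helical parameter table for an ensemble
#'
#' One row per model; columns are the six pair parameters for every
#' designated pair (named like `pair_7_18_propeller`) and the six step
#' parameters for every designated step (named like `step_6_7_roll`,
#' strand-I residue numbers), plus optionally the platinated-GG plane
#' dihedral and the global bend.
#'
#' @param ensemble a `duplex_ensemble` whose topology is set.
#' @param pairs,steps indices into the topology pair/step lists; default
#'   the central four pairs and the steps among them.
#' @param gg_dihedral include the G-G plane dihedral (requires
#'   `platinated_pair_indices` on the topology).
#' @param bend include the global bend angle (slower).
#' @return A data.frame of class `param_table` with a `frame_index`
#'   column; the designation is attached as an attribute.
#' @export
compute_param_table <- function(ensemble, pairs = NULL, steps = NULL,
                                gg_dihedral = NULL, bend = FALSE) {
  topo <- ensemble$topology
  if (is.null(topo)) stop("ensemble has no topology; run infer_duplex_topology")
  des <- central_designation(topo)
  if (is.null(pairs)) pairs <- des$pairs
  if (is.null(steps)) steps <- des$steps
  stopifnot(all(pairs >= 1), all(pairs <= nrow(topo$pairs)),
            all(steps >= 1), all(steps <= nrow(topo$steps)))
  if (is.null(gg_dihedral)) {
    gg_dihedral <- !is.null(topo$platinated_pair_indices)
  }
  pair_cols <- as.vector(vapply(pairs, function(i) {
    paste0("pair_", topo$pairs[i, 1], "_", topo$pairs[i, 2], "_",
           PAIR_PARAM_NAMES)
  }, character(6)))
  step_cols <- as.vector(vapply(steps, function(s) {
    i <- topo$steps[s, 1]; j <- topo$steps[s, 2]
    paste0("step_", topo$pairs[i, 1], "_", topo$pairs[j, 1], "_",
           STEP_PARAM_NAMES)
  }, character(6)))
  cols <- c(pair_cols, step_cols,
            if (gg_dihedral) "gg_dihedral", if (bend) "bend")
  nm <- n_models(ensemble)
  out <- matrix(NA_real_, nm, length(cols), dimnames = list(NULL, cols))
  need_pairs <- sort(unique(c(pairs, as.vector(topo$steps[steps, ]))))
  for (f in seq_len(nm)) {
    model <- ensemble_model(ensemble, f)
    pf <- list()
    ppar <- list()
    for (i in need_pairs) {
      fw <- tryCatch(fit_base_frame(model, topo$pairs[i, 1]),
                     error = function(e) stop("frame ", f, ": ",
                                              conditionMessage(e)))
      fc <- fit_base_frame(model, topo$pairs[i, 2])
      p <- base_pair_params(fw, fc)
      ppar[[as.character(i)]] <- p
      pf[[as.character(i)]] <- attr(p, "mid")
    }
    for (i in pairs) {
      nm6 <- paste0("pair_", topo$pairs[i, 1], "_", topo$pairs[i, 2], "_",
                    PAIR_PARAM_NAMES)
      out[f, nm6] <- as.numeric(ppar[[as.character(i)]])
    }
    for (s in steps) {
      i <- topo$steps[s, 1]; j <- topo$steps[s, 2]
      sp <- step_params(pf[[as.character(i)]], pf[[as.character(j)]])
      nm6 <- paste0("step_", topo$pairs[i, 1], "_", topo$pairs[j, 1], "_",
                    STEP_PARAM_NAMES)
      out[f, nm6] <- as.numeric(sp)
    }
    if (gg_dihedral) {
      gi <- topo$platinated_pair_indices
      if (is.null(gi)) stop("gg_dihedral requested but no platinated pairs")
      out[f, "gg_dihedral"] <- gg_plane_dihedral(
        model, topo$pairs[gi[1], 1], topo$pairs[gi[2], 1])
    }
    if (bend) out[f, "bend"] <- bend_angle(model, topo)
  }
  df <- data.frame(frame_index = seq_len(nm), out, check.names = FALSE)
  attr(df, "designation") <- list(pairs = pairs, steps = steps)
  class(df) <- c("param_table", "data.frame")
  df
}

#' Write / read a parameter table as tab-separated text
#' @param table a `param_table`.
#' @param path file path.
#' @export
write_param_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_param_table
#' @export
read_param_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  class(df) <- c("param_table", "data.frame")
  df
}
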