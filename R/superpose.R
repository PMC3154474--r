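# Rigid-body superposition and ensemble RMSD statistics.

#' Kabsch superposition
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `target` (reflections excluded), with optional per-point weights
#' (e.g. atomic masses).
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3.
#' @param weights optional non-negative weights of length n.
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3; transformed points are `mobile %*% t(rotation) +
#'   translation`), and the weighted `rmsd` (Angstrom).
#' @export
kabsch <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  n <- nrow(mobile)
  stopifnot(n == nrow(target), n >= 3, ncol(mobile) == 3, ncol(target) == 3)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cm <- drop(crossprod(mobile, w)); ct <- drop(crossprod(target, w))
  M <- sweep(mobile, 2, cm); T <- sweep(target, 2, ct)
  S <- crossprod(M * w, T)  # weighted cross-covariance
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    warning("near-degenerate (collinear) point set in kabsch")
  }
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- M %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((moved - T)^2)))
  list(rotation = R, translation = drop(ct - R %*% cm), rmsd = rmsd)
}

apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' Weighted RMSD between two coordinate sets (no fitting)
#' @inheritParams kabsch
#' @export
rmsd_plain <- function(a, b, weights = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  w <- if (is.null(weights)) rep(1, nrow(a)) else as.numeric(weights)
  w <- w / sum(w)
  sqrt(sum(w * rowSums((a - b)^2)))
}

ensemble_coords <- function(ensemble, i) {
  matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Iterative mean structure of an ensemble
#'
#' Starting from model 1, all models are superposed onto the current mean
#' and the coordinate average is recomputed, until the mean moves by less
#' than `tol` (Angstrom). Deterministic given model order.
#'
#' @param ensemble a `duplex_ensemble`.
#' @param selection optional atom predicate (see [select_atoms()]) used
#'   for the fit; the mean is reported over the selected atoms.
#' @param tol convergence threshold on the mean coordinate shift.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return A `structure_model` holding the converged mean coordinates.
#' @export
mean_structure <- function(ensemble, selection = NULL, tol = 1e-6,
                           max_iter = 100) {
  if (!is.null(selection)) ensemble <- select_atoms(ensemble, selection)
  nm <- n_models(ensemble)
  stopifnot(nm >= 2)
  mean_xyz <- ensemble_coords(ensemble, 1)
  for (it in seq_len(max_iter)) {
    acc <- matrix(0, nrow(mean_xyz), 3)
    for (i in seq_len(nm)) {
      xi <- ensemble_coords(ensemble, i)
      acc <- acc + apply_superposition(xi, kabsch(xi, mean_xyz))
    }
    new_mean <- acc / nm
    shift <- max(sqrt(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tol) {
      m <- ensemble$atoms
      m$x <- mean_xyz[, 1]; m$y <- mean_xyz[, 2]; m$z <- mean_xyz[, 3]
      return(new_structure_model(m[MODEL_COLS]))
    }
  }
  stop("mean_structure did not converge in ", max_iter, " iterations")
}

#' Per-model RMSD of a family to its mean structure
#'
#' Each model is superposed onto the converged iterative mean over the
#' selection and its RMSD recorded; the report carries the per-model
#' values and their mean and standard deviation, the family-spread
#' statistic quoted for NMR ensembles.
#'
#' @inheritParams mean_structure
#' @param selection_tag label stored on the report (e.g. "non-H").
#' @return list with `per_model`, `mean`, `sd`, `selection_tag`, class
#'   `family_rmsd_report`.
#' @export
family_rmsd <- function(ensemble, selection = NULL,
                        selection_tag = if (is.null(selection)) "all atoms"
                        else "selection") {
  if (!is.null(selection)) ensemble <- select_atoms(ensemble, selection)
  mean_mod <- mean_structure(ensemble)
  mxyz <- model_xyz(mean_mod)
  per <- vapply(seq_len(n_models(ensemble)), function(i) {
    kabsch(ensemble_coords(ensemble, i), mxyz)$rmsd
  }, 0)
  structure(list(per_model = per, mean = mean(per), sd = stats::sd(per),
                 selection_tag = selection_tag),
            class = "family_rmsd_report")
}

#' @export
print.family_rmsd_report <- function(x, ...) {
  cat(sprintf("family RMSD to mean (%s): %.2f +/- %.2f A over %d models\n",
              x$selection_tag, x$mean, x$sd, length(x$per_model)))
  invisible(x)
}

#' Centroid model of an ensemble
#'
#' Index of the model minimizing the mean pairwise (superposed) RMSD to
#' all other models; ties resolve to the lowest index.
#'
#' @inheritParams mean_structure
#' @return integer model index.
#' @export
centroid_model <- function(ensemble, selection = NULL) {
  if (!is.null(selection)) ensemble <- select_atoms(ensemble, selection)
  nm <- n_models(ensemble)
  stopifnot(nm >= 2)
  coords <- lapply(seq_len(nm), function(i) ensemble_coords(ensemble, i))
  d <- matrix(0, nm, nm)
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      d[i, j] <- d[j, i] <- kabsch(coords[[i]], coords[[j]])$rmsd
    }
  }
  which.min(rowSums(d) / (nm - 1))
}

#' Smoothed per-frame RMSD to a reference structure
#'
#' Mass-weighted (or unweighted) RMSD of every frame to `reference` after
#' superposition, smoothed by a centered moving average of `window`
#' frames; truncated windows at the edges.
#'
#' @param ensemble a `duplex_ensemble` (frames in time order).
#' @param reference a `structure_model` with the same atoms.
#' @param window odd window length in frames; 1 gives the raw series.
#' @param weights optional per-atom weights (e.g. masses).
#' @return numeric vector, one value per frame.
#' @export
rmsd_series <- function(ensemble, reference, window = 1, weights = NULL) {
  nm <- n_models(ensemble)
  if (window > nm) stop("window larger than number of frames")
  if (window %% 2 != 1) stop("window must be odd")
  ref <- model_xyz(reference)
  raw <- vapply(seq_len(nm), function(i) {
    kabsch(ensemble_coords(ensemble, i), ref, weights)$rmsd
  }, 0)
  if (window == 1) return(raw)
  half <- (window - 1) / 2
  vapply(seq_len(nm), function(i) {
    mean(raw[max(1, i - half):min(nm, i + half)])
  }, 0)
}

#' Standard atomic masses for the elements in these structures
#' @param element character vector of element symbols.
#' @export
atomic_mass <- function(element) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
         Pt = 195.084)
  out <- m[element]
  if (any(is.na(out))) stop("unknown element: ",
                            element[which(is.na(out))[1]])
  unname(out)
}
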