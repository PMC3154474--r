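#' @importFrom bio3d read.pdb write.pdb
NULL

# A structure model is a data.frame with one row per atom and columns
# serial, name, resname, chain, resno, x, y, z, element, plus a "type"
# column (ATOM/HETATM). A duplex ensemble stores the shared atom table
# once and an n_models x (3 * n_atoms) coordinate matrix (bio3d layout).

MODEL_COLS <- c("serial", "name", "resname", "chain", "resno",
                "x", "y", "z", "element", "type")

new_structure_model <- function(df) {
  stopifnot(all(MODEL_COLS %in% names(df)))
  if (!all(is.finite(c(df$x, df$y, df$z)))) {
    stop("non-finite coordinates in structure model")
  }
  class(df) <- c("structure_model", "data.frame")
  df
}

#' Build a structure model from an atom table
#'
#' @param name,resname,chain,resno,element,type per-atom vectors; `element`
#'   and `type` are derived from `name`/`resname` when omitted.
#' @param xyz numeric matrix with 3 columns (Angstrom).
#' @return A `structure_model` data.frame.
#' @export
structure_model <- function(name, resname, resno, xyz, chain = "A",
                            element = NULL, type = NULL) {
  n <- length(name)
  xyz <- matrix(xyz, ncol = 3)
  stopifnot(nrow(xyz) == n)
  if (is.null(element)) element <- element_from_name(name)
  if (is.null(type)) {
    type <- ifelse(resname %in% c("DA", "DC", "DG", "DT", "A", "C", "G", "T"),
                   "ATOM", "HETATM")
  }
  new_structure_model(data.frame(
    serial = seq_len(n), name = name, resname = resname,
    chain = rep_len(chain, n), resno = resno,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = element, type = rep_len(type, n),
    stringsAsFactors = FALSE))
}

model_xyz <- function(model) cbind(model$x, model$y, model$z)

atom_key <- function(df) paste(df$chain, df$resno, df$name, sep = "|")

#' Assemble an ensemble from a list of structure models
#'
#' All models must share one atom ordering (chain, residue number, atom
#' name); a mismatch is a topology error naming the first offending atom.
#'
#' @param models list of `structure_model` objects (>= 1).
#' @param topology optional [duplex_topology()].
#' @param source_tag free-text provenance label.
#' @return A `duplex_ensemble`.
#' @export
duplex_ensemble <- function(models, topology = NULL, source_tag = "") {
  stopifnot(length(models) >= 1)
  ref <- models[[1]]
  keys <- atom_key(ref)
  if (anyDuplicated(keys)) {
    stop("duplicate (chain, residue, atom) triple: ",
         keys[duplicated(keys)][1])
  }
  xyz <- matrix(0, length(models), 3 * nrow(ref))
  for (i in seq_along(models)) {
    m <- models[[i]]
    ki <- atom_key(m)
    if (length(ki) != length(keys) || any(ki != keys)) {
      bad <- if (length(ki) != length(keys)) {
        setdiff(union(keys, ki), intersect(keys, ki))[1]
      } else ki[which(ki != keys)[1]]
      stop("topology error: model ", i, " atom set differs from model 1 ",
           "(first mismatch: ", bad, ")")
    }
    xyz[i, ] <- as.vector(t(model_xyz(m)))
  }
  atoms <- ref
  atoms$x <- atoms$y <- atoms$z <- NULL
  structure(list(atoms = atoms, xyz = xyz, topology = topology,
                 source_tag = source_tag),
            class = "duplex_ensemble")
}

#' @export
n_models <- function(ensemble) nrow(ensemble$xyz)

#' Extract one conformer of an ensemble as a structure model
#' @param ensemble a `duplex_ensemble`
#' @param i model index (1-based)
#' @export
ensemble_model <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_models(ensemble))
  m <- ensemble$atoms
  xyz <- matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE)
  m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
  new_structure_model(m[MODEL_COLS])
}

#' @export
print.duplex_ensemble <- function(x, ...) {
  cat("duplex_ensemble:", n_models(x), "model(s),",
      nrow(x$atoms), "atoms/model")
  if (nzchar(x$source_tag)) cat(" [", x$source_tag, "]", sep = "")
  cat("\n")
  if (!is.null(x$topology)) {
    cat("  topology:", x$topology$sequence_I, "/",
        x$topology$sequence_II, "\n")
  }
  invisible(x)
}

# Normalize legacy asterisk sugar-atom names (C1* -> C1') on read.
normalize_atom_names <- function(name) gsub("\\*", "'", name)

#' Read a multi-model PDB file as a duplex ensemble
#'
#' Models must share an identical atom set and ordering; coordinates are
#' in Angstrom. A file without MODEL records is read as a single model.
#' Asterisk-dialect sugar atom names are normalized to primes.
#'
#' @param path PDB file path.
#' @param source_tag provenance label stored on the ensemble.
#' @return A `duplex_ensemble` (topology not yet assigned; see
#'   [infer_duplex_topology()]).
#' @export
read_pdb_ensemble <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_pdb_models(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_at <- nrow(at)
  nm <- normalize_atom_names(at$elety)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- element_from_name(nm)
  } else {
    elem[is.na(elem) | elem == ""] <- element_from_name(nm[is.na(elem) | elem == ""])
  }
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  models <- lapply(seq_len(nrow(pdb$xyz)), function(i) {
    xyz <- matrix(pdb$xyz[i, seq_len(3 * n_at)], ncol = 3, byrow = TRUE)
    new_structure_model(data.frame(
      serial = at$eleno, name = nm, resname = at$resid, chain = chain,
      resno = at$resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = elem, type = at$type, stringsAsFactors = FALSE))
  })
  duplex_ensemble(models, source_tag = source_tag)
}

# Pre-scan MODEL blocks so atom-set mismatches are reported per atom and
# malformed coordinate fields are reported with their line number.
validate_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  coords <- lapply(which(is_atom), function(i) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    v <- suppressWarnings(as.numeric(fields))
    if (any(is.na(v))) {
      stop("parse error: unreadable coordinates at line ", i)
    }
    invisible(NULL)
  })
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) < 2) return(invisible(TRUE))
  model_ends <- which(rec == "ENDMDL")
  keys <- lapply(seq_along(model_starts), function(k) {
    idx <- seq(model_starts[k], model_ends[k])
    idx <- idx[is_atom[idx]]
    paste(substr(lines[idx], 22, 22), trimws(substr(lines[idx], 23, 26)),
          normalize_atom_names(trimws(substr(lines[idx], 13, 16))), sep = "|")
  })
  for (k in seq_along(keys)[-1]) {
    if (length(keys[[k]]) != length(keys[[1]]) ||
        any(keys[[k]] != keys[[1]])) {
      bad <- if (length(keys[[k]]) != length(keys[[1]])) {
        setdiff(union(keys[[1]], keys[[k]]),
                intersect(keys[[1]], keys[[k]]))[1]
      } else keys[[k]][which(keys[[k]] != keys[[1]])[1]]
      stop("topology error: model ", k,
           " atom set differs from model 1 (first mismatch: ", bad, ")")
    }
  }
  invisible(TRUE)
}

#' Write a duplex ensemble as a (multi-model) PDB file
#'
#' Coordinates are written on the standard 3-decimal PDB grid; atom names
#' use the prime dialect. Inverse of [read_pdb_ensemble()] at that
#' precision.
#'
#' @param ensemble a `duplex_ensemble`.
#' @param path output file path.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  a <- ensemble$atoms
  bio3d::write.pdb(
    file = path, xyz = ensemble$xyz, type = a$type, eleno = a$serial,
    elety = a$name, resid = a$resname, chain = a$chain, resno = a$resno,
    elesy = a$element)
  invisible(path)
}

#' Duplex topology constructor
#'
#' @param sequence_I,sequence_II strand base strings, both 5'->3'.
#' @param pairs two-column matrix of paired residue numbers (strand I,
#'   strand II); antiparallel order.
#' @param platinated_pair_indices optional indices (into `pairs`) of the
#'   two platinated guanine pairs.
#' @export
duplex_topology <- function(sequence_I, sequence_II, pairs,
                            platinated_pair_indices = NULL) {
  n <- nchar(sequence_I)
  stopifnot(nchar(sequence_II) == n, nrow(pairs) == n)
  sI <- strsplit(sequence_I, "")[[1]]
  sII <- strsplit(sequence_II, "")[[1]]
  # strand II runs antiparallel: pair i of strand I meets strand II
  # position n + 1 - i when sequence_II is given 5'->3'
  for (i in seq_len(n)) {
    if (complement_base(sI[i]) != sII[n + 1 - i]) {
      stop("topology error: position ", i, " (", sI[i],
           ") not complementary to strand II position ", n + 1 - i,
           " (", sII[n + 1 - i], ")")
    }
  }
  structure(list(sequence_I = sequence_I, sequence_II = sequence_II,
                 pairs = pairs, steps = cbind(seq_len(n - 1), 2:n),
                 platinated_pair_indices = platinated_pair_indices),
            class = "duplex_topology")
}

#' Infer duplex topology from one structure model
#'
#' Strands are taken from the two chains, or from a single chain split in
#' half by residue numbering (the continuous 1..2n convention, strand I =
#' 1..n). Pairing is antiparallel by sequence complementarity and
#' confirmed geometrically through C1'-C1' distances (8.5--12.5 Angstrom);
#' failures on more than 20 percent of pairs produce a warning but keep
#' the sequence-based pairing.
#'
#' @param model a `structure_model`.
#' @param platinated_residues optional length-2 vector of platinated
#'   residue numbers on strand I.
#' @return A `duplex_topology` whose `pairs` hold residue numbers.
#' @export
infer_duplex_topology <- function(model, platinated_residues = NULL) {
  nuc <- model[model$resname %in% c("DA", "DC", "DG", "DT", "A", "C", "G", "T"), ]
  chains <- unique(nuc$chain)
  if (length(chains) == 2) {
    resI <- unique(nuc$resno[nuc$chain == chains[1]])
    resII <- unique(nuc$resno[nuc$chain == chains[2]])
  } else if (length(chains) == 1) {
    res <- sort(unique(nuc$resno))
    if (length(res) %% 2 != 0 || length(res) < 4) {
      stop("topology error: single strand (cannot split ",
           length(res), " residues into two strands)")
    }
    half <- length(res) / 2
    resI <- res[seq_len(half)]
    resII <- res[half + seq_len(half)]
  } else {
    stop("topology error: expected 1 or 2 nucleic chains, found ",
         length(chains))
  }
  if (length(resI) != length(resII)) {
    stop("topology error: strands of unequal length")
  }
  base_of <- function(r) {
    rn <- nuc$resname[match(r, nuc$resno)]
    substr(rn, nchar(rn), nchar(rn))
  }
  sI <- vapply(resI, base_of, "")
  sII <- vapply(resII, base_of, "")
  n <- length(resI)
  pairs <- cbind(resI, rev(resII))
  topo <- duplex_topology(paste(sI, collapse = ""), paste(sII, collapse = ""),
                          pairs)
  # geometric confirmation via C1'-C1' distances
  c1 <- nuc[nuc$name == "C1'", ]
  bad <- 0L
  for (i in seq_len(n)) {
    pa <- c1[match(pairs[i, 1], c1$resno), ]
    pb <- c1[match(pairs[i, 2], c1$resno), ]
    d <- sqrt(sum((c(pa$x, pa$y, pa$z) - c(pb$x, pb$y, pb$z))^2))
    if (!is.finite(d) || d < 8.5 || d > 12.5) bad <- bad + 1L
  }
  if (bad > 0.2 * n) {
    warning("geometric pairing check failed for ", bad, " of ", n,
            " pairs; keeping sequence-based pairing")
  }
  if (!is.null(platinated_residues)) {
    idx <- match(platinated_residues, pairs[, 1])
    if (any(is.na(idx))) stop("platinated residues not on strand I")
    topo$platinated_pair_indices <- idx
  }
  topo
}

#' Restrict an ensemble to atoms matching a predicate
#'
#' @param ensemble a `duplex_ensemble`.
#' @param pred function taking the atom table and returning a logical
#'   vector, e.g. `function(a) a$element != "H"`.
#' @return A `duplex_ensemble` over the matching atoms (ordering
#'   preserved; topology and tag carried over).
#' @export
select_atoms <- function(ensemble, pred) {
  keep <- pred(ensemble$atoms)
  if (!any(keep)) stop("selection error: no atoms match")
  idx <- which(keep)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  structure(list(atoms = ensemble$atoms[idx, , drop = FALSE],
                 xyz = ensemble$xyz[, cols, drop = FALSE],
                 topology = ensemble$topology,
                 source_tag = ensemble$source_tag),
            class = "duplex_ensemble")
}

#' Convenience atom predicates
#'
#' `sel_heavy` keeps non-hydrogen atoms (the platinum moiety included);
#' `sel_residues` keeps the listed residue numbers; `sel_central4` keeps
#' the paper-numbered central four base pairs of a 12-mer duplex
#' (residues 5--8 and 17--20).
#' @param resno residue numbers to keep.
#' @export
sel_heavy <- function(a) a$element != "H"

#' @rdname sel_heavy
#' @export
sel_residues <- function(resno) {
  force(resno)
  function(a) a$resno %in% resno
}

#' @rdname sel_heavy
#' @export
sel_central4 <- function(a) a$resno %in% c(5:8, 17:20)
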