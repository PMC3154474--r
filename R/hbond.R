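# Geometric hydrogen-bond detection and per-frame classification of
# platinum-amine contacts.

#' Hydrogen-bond acceptance criteria
#'
#' A donor-hydrogen-acceptor triple is a hydrogen bond when the
#' donor-acceptor distance is at most `max_distance` (Angstrom) and the
#' donor-hydrogen-acceptor angle is at least `min_angle` (degrees); both
#' cut-offs inclusive.
#'
#' @param max_distance donor-acceptor distance cut-off, Angstrom.
#' @param min_angle donor-H-acceptor angular cut-off, degrees.
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = 135) {
  stopifnot(max_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

residue_label <- function(resname, resno) {
  ifelse(resname == "PTN", paste0("Pt", resno),
         paste0(base_letter(resname), resno))
}

# Map each amine/imino hydrogen to its donor nitrogen by name.
.donor_h_map <- list(
  H1 = "N1", H21 = "N2", H22 = "N2", H61 = "N6", H62 = "N6",
  H41 = "N4", H42 = "N4", H3 = "N3",
  H11 = "N1", H12 = "N1"  # PTN amine 1; H21/H22 map to N2 as above
)

#' Enumerate donor and acceptor sites of a model
#'
#' Donors are nucleobase N-H groups (with their explicit hydrogens) plus
#' platinum-amine N-H groups when a `PTN` moiety is present; acceptors
#' are the base lone-pair sites (G O6/N7/N3, A N7/N1/N3, T O4/O2,
#' C O2/N3). Donors lacking an explicit hydrogen are dropped with
#' `hydrogens = "require"`, or idealized hydrogens must already have
#' been placed (the builder always places polar hydrogens).
#'
#' @param model a `structure_model`.
#' @param hydrogens `"require"` (error on H-less donor) or `"skip"`.
#' @return list of data.frames `donors` (donor_idx, h_idx, label) and
#'   `acceptors` (idx, label); indices are row numbers into the model.
#' @export
enumerate_donors_acceptors <- function(model, hydrogens = "require") {
  don <- list(); acc <- list()
  for (r in unique(model$resno)) {
    rows <- which(model$resno == r)
    rn <- model$resname[rows[1]]
    if (rn == "PTN") {
      for (h in rows[grepl("^H", model$name[rows])]) {
        nn <- .donor_h_map[[model$name[h]]]
        ni <- rows[model$name[rows] == nn]
        don[[length(don) + 1]] <- data.frame(
          donor_idx = ni, h_idx = h,
          label = paste0("Pt-", nn), stringsAsFactors = FALSE)
      }
      next
    }
    b <- base_letter(rn)
    if (!b %in% c("A", "C", "G", "T")) next
    for (aa in .base_acceptor_atoms[[b]]) {
      ai <- rows[model$name[rows] == aa]
      if (length(ai) == 1) {
        acc[[length(acc) + 1]] <- data.frame(
          idx = ai, label = paste0(b, r, "-", aa), stringsAsFactors = FALSE)
      }
    }
    for (dn in names(.base_donor_defs[[b]])) {
      def <- .base_donor_defs[[b]][[dn]]
      ni <- rows[model$name[rows] == dn]
      if (length(ni) != 1) next
      hi <- rows[model$name[rows] %in% def$h]
      if (length(hi) == 0) {
        if (hydrogens == "require") {
          stop("enumeration error: donor ", b, r, "-", dn,
               " has no hydrogen")
        }
        next
      }
      for (h in hi) {
        don[[length(don) + 1]] <- data.frame(
          donor_idx = ni, h_idx = h, label = paste0(b, r, "-", dn),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(donors = do.call(rbind, don), acceptors = do.call(rbind, acc))
}

#' Detect hydrogen bonds in one model
#'
#' Every (donor, hydrogen, acceptor) triple with donor-acceptor distance
#' within and donor-H-acceptor angle above the criteria (both inclusive)
#' is reported; intra-residue pairs are excluded. Watson-Crick partner
#' bonds are reported here and filtered only downstream.
#'
#' @param model a `structure_model`.
#' @param sites donor/acceptor lists from [enumerate_donors_acceptors()];
#'   recomputed when NULL.
#' @param criteria an [hbond_criteria()].
#' @return data.frame with donor/hydrogen/acceptor serials and labels,
#'   distance (Angstrom) and angle (degrees).
#' @export
detect_hbonds <- function(model, sites = NULL, criteria = hbond_criteria()) {
  if (is.null(sites)) sites <- enumerate_donors_acceptors(model)
  xyz <- model_xyz(model)
  don <- sites$donors; acc <- sites$acceptors
  if (is.null(don) || is.null(acc)) {
    return(empty_hbond_records())
  }
  D <- xyz[don$donor_idx, , drop = FALSE]
  A <- xyz[acc$idx, , drop = FALSE]
  d2 <- outer(rowSums(D^2), rowSums(A^2), `+`) - 2 * (D %*% t(A))
  dist <- sqrt(pmax(d2, 0))
  same_res <- outer(model$resno[don$donor_idx], model$resno[acc$idx], `==`)
  cand <- which(dist <= criteria$max_distance & !same_res, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_hbond_records())
  i <- cand[, 1]; j <- cand[, 2]
  H <- xyz[don$h_idx[i], , drop = FALSE]
  u <- xyz[don$donor_idx[i], , drop = FALSE] - H
  v <- xyz[acc$idx[j], , drop = FALSE] - H
  ang <- acos(clamp1(rowSums(u * v) /
                       sqrt(rowSums(u^2) * rowSums(v^2)))) * DEG
  keep <- ang >= criteria$min_angle
  if (!any(keep)) return(empty_hbond_records())
  i <- i[keep]; j <- j[keep]
  data.frame(donor_serial = model$serial[don$donor_idx[i]],
             hydrogen_serial = model$serial[don$h_idx[i]],
             acceptor_serial = model$serial[acc$idx[j]],
             donor = don$label[i], acceptor = acc$label[j],
             distance = dist[cbind(i, j)], angle = ang[keep],
             stringsAsFactors = FALSE)
}

empty_hbond_records <- function() {
  data.frame(donor_serial = integer(), hydrogen_serial = integer(),
             acceptor_serial = integer(), donor = character(),
             acceptor = character(), distance = numeric(),
             angle = numeric(), stringsAsFactors = FALSE)
}

#' Hydrogen-bond species definition
#'
#' A species is present in a frame when at least one detected bond has a
#' donor label matching `donor_pattern` and acceptor label matching
#' `acceptor_pattern` (regular expressions).
#'
#' @param name species label used in class tables.
#' @param donor_pattern,acceptor_pattern regular expressions on the
#'   donor/acceptor labels (e.g. `"^Pt-"`, `"^G7-O6$"`).
#' @export
species_definition <- function(name, donor_pattern, acceptor_pattern) {
  structure(list(name = name, donor_pattern = donor_pattern,
                 acceptor_pattern = acceptor_pattern),
            class = "species_definition")
}

#' Default platinum-amine species for a platinated topology
#'
#' The two contacts on the 3' side of the adduct: the amine hydrogen
#' bond to the O6 of the 3' platinated guanine, and to the O4 of the
#' thymine flanking it on the 3' side (when that flank is a T).
#'
#' @param topology a `duplex_topology` with `platinated_pair_indices`.
#' @export
default_pt_species <- function(topology) {
  gi <- topology$platinated_pair_indices
  if (is.null(gi)) stop("definition error: topology has no platinated pairs")
  g3 <- topology$pairs[gi[2], 1]
  flank <- g3 + 1
  fb <- substr(topology$sequence_I, flank, flank)
  sp <- list(species_definition(paste0("G", g3, "-O6"), "^Pt-",
                                paste0("^G", g3, "-O6$")))
  if (identical(fb, "T")) {
    sp <- c(sp, list(species_definition(paste0("T", flank, "-O4"), "^Pt-",
                                        paste0("^T", flank, "-O4$"))))
  }
  sp
}

#' Classify every frame of an ensemble by hydrogen-bond species
#'
#' Only platinum-amine bonds enter the classification (Watson-Crick and
#' other base-base bonds are detected but filtered). A frame's label is
#' "None", the single species present, or the combination label (species
#' names joined "+" in reverse species order, matching the conventional
#' table layout).
#'
#' @param ensemble a `duplex_ensemble` with a platinated topology.
#' @param species list of [species_definition()]s; default from
#'   [default_pt_species()] when the topology is platinated, else empty.
#' @param criteria an [hbond_criteria()].
#' @return data.frame (class `frame_class_table`) with `frame_index` and
#'   `class`; all per-frame bond records are attached as attribute
#'   `"records"`.
#' @export
classify_frames <- function(ensemble, species = NULL,
                            criteria = hbond_criteria()) {
  if (is.null(species)) {
    species <- if (!is.null(ensemble$topology) &&
                   !is.null(ensemble$topology$platinated_pair_indices)) {
      default_pt_species(ensemble$topology)
    } else list()
  }
  nm <- n_models(ensemble)
  sites <- enumerate_donors_acceptors(ensemble_model(ensemble, 1),
                                      hydrogens = "skip")
  labels <- character(nm)
  all_recs <- vector("list", nm)
  for (f in seq_len(nm)) {
    recs <- detect_hbonds(ensemble_model(ensemble, f), sites, criteria)
    recs$frame_index <- if (nrow(recs)) f else integer(0)
    all_recs[[f]] <- recs
    present <- vapply(species, function(sp) {
      any(grepl(sp$donor_pattern, recs$donor) &
            grepl(sp$acceptor_pattern, recs$acceptor))
    }, FALSE)
    labels[f] <- if (!any(present)) "None" else {
      nms <- vapply(species[present], `[[`, "", "name")
      paste(rev(nms), collapse = "+")
    }
  }
  out <- data.frame(frame_index = seq_len(nm), class = labels,
                    stringsAsFactors = FALSE)
  attr(out, "records") <- do.call(rbind, all_recs)
  attr(out, "species") <- vapply(species, `[[`, "", "name")
  class(out) <- c("frame_class_table", "data.frame")
  out
}

#' Class frequency table
#'
#' Percentage of frames per hydrogen-bond class, in the conventional row
#' order (single species, combinations, then None).
#'
#' @param classes a `frame_class_table` (or the result of
#'   [frequency_table_from_percent()] for printed tables).
#' @param digits rounding for the reported percentage (default integer
#'   percent).
#' @return data.frame (class `frequency_table`) with class, count,
#'   percent.
#' @export
frequency_table <- function(classes, digits = 0) {
  stopifnot(nrow(classes) >= 1)
  tab <- table(classes$class)
  lab <- names(tab)
  singles <- attr(classes, "species")
  ord <- order(match(lab, c(singles,
                            setdiff(lab, c(singles, "None")), "None")))
  lab <- lab[ord]
  cnt <- as.integer(tab[lab])
  out <- data.frame(class = lab, count = cnt,
                    percent = round(100 * cnt / sum(cnt), digits),
                    stringsAsFactors = FALSE)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Frequency table from printed percentages
#' @param percents named numeric vector (names are class labels).
#' @export
frequency_table_from_percent <- function(percents) {
  out <- data.frame(class = names(percents), count = NA_integer_,
                    percent = as.numeric(percents),
                    stringsAsFactors = FALSE)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Occupancy of one bond across all classes containing it
#'
#' The occupancy of a bond (e.g. the 3'-guanine O6 contact) is the sum
#' of the frequencies of every class whose label contains that bond.
#'
#' @param freq a `frequency_table`.
#' @param bond bond name as it appears in class labels (e.g. `"G7-O6"`).
#' @return percentage.
#' @export
aggregate_bond_occupancy <- function(freq, bond) {
  parts <- strsplit(freq$class, "+", fixed = TRUE)
  known <- unique(unlist(parts))
  if (!bond %in% known) stop("lookup error: unknown bond '", bond, "'")
  sum(freq$percent[vapply(parts, function(p) bond %in% p, FALSE)])
}
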