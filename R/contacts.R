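# Fractional contact maps, interface contact counting, minimum-distance
# series, and salt-bridge tracking.
#
# A contact exists in a frame when the distance between two non-hydrogen
# atoms from different residues is strictly less than the cutoff (default
# 3.6 Angstrom); occupancy is the fraction of window frames in contact.

#' Contact specification
#' @param cutoff distance cutoff in Angstrom (strict less-than).
#' @param atom_class `"heavy"` (default) or `"all"`.
#' @export
contact_spec <- function(cutoff = 3.6, atom_class = c("heavy", "all")) {
  stopifnot(cutoff > 0)
  structure(list(cutoff = cutoff, atom_class = match.arg(atom_class),
                 comparison = "strict-less-than"),
            class = "ContactSpec")
}

#' Salt-bridge specification
#'
#' Default head-group atoms: Lys NZ and Arg NH1/NH2/NE as donors, Asp OD1/OD2
#' and Glu OE1/OE2 as acceptors, with a 4.0 Angstrom cutoff.  The
#' charge-center variant measures Arg CZ to Glu CD instead.
#'
#' @param cutoff Angstrom (default 4.0).
#' @param charge_center use the CZ/CD charge-center atom definition.
#' @export
salt_bridge_spec <- function(cutoff = 4.0, charge_center = FALSE) {
  stopifnot(cutoff > 0)
  donors <- if (charge_center) {
    list(ARG = "CZ", LYS = "NZ", HIS = "NE2")
  } else {
    list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ", HIS = c("ND1", "NE2"))
  }
  acceptors <- if (charge_center) {
    list(GLU = "CD", ASP = "CG")
  } else {
    list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))
  }
  structure(list(cutoff = cutoff, donors = donors, acceptors = acceptors,
                 charge_center = charge_center),
            class = "SaltBridgeSpec")
}

# residue table for a residue-set selection: list of (key, chain, resnum,
# atom indices) honouring the spec's atom class.
.residue_groups <- function(system, selection, spec) {
  groups <- selection$groups
  if (spec$atom_class == "heavy") {
    heavy <- which(!is_hydrogen(system$atoms$element))
    groups <- lapply(groups, intersect, heavy)
    groups <- Filter(length, groups)
  }
  groups
}

# Minimum inter-atom distance per residue pair in one frame, via a single
# atom-level distance matrix aggregated over the residue index of each atom.
.pair_min_matrix <- function(fr, groupsA, groupsB) {
  atomsA <- unlist(groupsA, use.names = FALSE)
  atomsB <- unlist(groupsB, use.names = FALSE)
  A <- fr[atomsA, , drop = FALSE]
  B <- fr[atomsB, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  ra <- rep.int(seq_along(groupsA), lengths(groupsA))
  rb <- rep.int(seq_along(groupsB), lengths(groupsB))
  nA <- length(groupsA); nB <- length(groupsB)
  m <- matrix(Inf, nA, nB)
  for (i in seq_len(nA)) {
    di <- d2[ra == i, , drop = FALSE]
    cmin <- apply(di, 2L, min)
    m[i, ] <- vapply(seq_len(nB), function(j) min(cmin[rb == j]), numeric(1))
  }
  sqrt(m)
}

.check_disjoint_residues <- function(groupsA, groupsB) {
  if (length(intersect(unlist(groupsA), unlist(groupsB)))) {
    stop("residue groups overlap; contact analysis needs disjoint sets")
  }
}

#' Fractional contact map between two residue sets
#'
#' A residue pair is in contact in a frame iff its minimum heavy-atom
#' distance is strictly below the cutoff; the fraction is the number of
#' contact frames over the window frames.  Pairs never in contact are
#' omitted from the table (`n_pairs_total` retains the count).
#'
#' @param traj a `TrajectorySegment`.
#' @param system the owning `MolecularSystem`.
#' @param groupA,groupB per-residue `SiteSelection`s (disjoint).
#' @param spec a [contact_spec()].
#' @return object of class `ContactMap`: data.frame `pairs` (resA, resB,
#'   fraction, min_distance_A), `n_frames`, `spec`.
#' @export
contact_map <- function(traj, system, groupA, groupB, spec = contact_spec()) {
  gA <- .residue_groups(system, groupA, spec)
  gB <- .residue_groups(system, groupB, spec)
  .check_disjoint_residues(gA, gB)
  wf <- window_frames(traj)
  nA <- length(gA); nB <- length(gB)
  counts <- matrix(0L, nA, nB)
  mind <- matrix(Inf, nA, nB)
  for (f in wf) {
    dm <- .pair_min_matrix(traj$coords[f, , , drop = TRUE], gA, gB)
    counts <- counts + (dm < spec$cutoff)
    mind <- pmin(mind, dm)
  }
  frac <- counts / length(wf)
  keep <- which(frac > 0, arr.ind = TRUE)
  pairs <- data.frame(
    resA = names(gA)[keep[, 1]], resB = names(gB)[keep[, 2]],
    fraction = frac[keep], min_distance_A = mind[keep],
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(-pairs$fraction), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_frames = length(wf), spec = spec,
                 n_pairs_total = nA * nB,
                 labelA = groupA$label, labelB = groupB$label),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("<ContactMap> %s vs %s: %d pair(s) with fraction > 0 over %d frames (cutoff %.2f A)\n",
              x$labelA, x$labelB, nrow(x$pairs), x$n_frames, x$spec$cutoff))
  invisible(x)
}

#' Per-frame interface contact counts
#'
#' Number of residue pairs in contact in each window frame, with a histogram
#' and mean — the interface-strength comparison of the dimerization
#' interfaces.
#'
#' @inheritParams contact_map
#' @return list with `counts` (per window frame), `histogram` (table),
#'   `mean`.
#' @export
interface_contact_count <- function(traj, system, groupA, groupB,
                                    spec = contact_spec()) {
  gA <- .residue_groups(system, groupA, spec)
  gB <- .residue_groups(system, groupB, spec)
  .check_disjoint_residues(gA, gB)
  wf <- window_frames(traj)
  counts <- vapply(wf, function(f) {
    dm <- .pair_min_matrix(traj$coords[f, , , drop = TRUE], gA, gB)
    sum(dm < spec$cutoff)
  }, integer(1))
  list(counts = counts, histogram = table(counts), mean = mean(counts))
}

# atom indices of one residue identified as "chain:resnum"
.residue_atoms <- function(system, residue, atom_names = NULL,
                           heavy_only = TRUE) {
  parts <- strsplit(residue, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("residue must be 'chain:resnum', got ", residue)
  a <- system$atoms
  keep <- a$chain_id == parts[1] & a$residue_number == as.integer(parts[2])
  if (!any(keep)) stop("residue not found: ", residue)
  if (heavy_only) keep <- keep & !is_hydrogen(a$element)
  if (!is.null(atom_names)) keep <- keep & trimws(a$atom_name) %in% atom_names
  idx <- which(keep)
  if (!length(idx)) stop("no matching atoms in residue ", residue)
  idx
}

#' Minimum-distance series between two residues (or residue/basepair sites)
#'
#' @param traj a `TrajectorySegment`.
#' @param system the owning `MolecularSystem`.
#' @param residueA,residueB `"chain:resnum"` strings, explicit atom index
#'   vectors, or (with `annotation`) `"bp:+k"` basepair references.
#' @param annotation optional `NucleosomeAnnotation`, required for `bp:`
#'   references.
#' @param atom_class `"heavy"` (default) or `"all"`.
#' @return a `DistanceSeries` of per-frame minimum distances; attributes
#'   `min` and `argmin_frame` give the window minimum.
#' @export
min_distance_series <- function(traj, system, residueA, residueB,
                                annotation = NULL,
                                atom_class = c("heavy", "all")) {
  atom_class <- match.arg(atom_class)
  resolve <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    if (startsWith(x, "bp:")) {
      if (is.null(annotation)) stop("basepair reference needs an annotation")
      b <- as.integer(sub("^bp:", "", x))
      sel <- select_sites(system, annotation, atom_class = "basepair",
                          bp_range = b)
      return(sel$groups[[1]])
    }
    .residue_atoms(system, x, heavy_only = (atom_class == "heavy"))
  }
  ia <- resolve(residueA); ib <- resolve(residueB)
  wf <- window_frames(traj)
  vals <- vapply(wf, function(f) {
    fr <- traj$coords[f, , , drop = TRUE]
    A <- fr[ia, , drop = FALSE]; B <- fr[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  lab <- paste(if (is.character(residueA)) residueA else "siteA",
               if (is.character(residueB)) residueB else "siteB",
               sep = " <-> ")
  ds <- distance_series(vals, traj$times[wf], lab)
  attr(ds, "min") <- min(vals)
  attr(ds, "argmin_frame") <- wf[which.min(vals)]
  ds
}

#' Salt-bridge occupancy and distance series
#'
#' Tracks a basic/acidic residue pair under the salt-bridge criterion: formed
#' in a frame when the minimum distance between the spec's donor and acceptor
#' atoms is below the cutoff (default 4.0 Angstrom; charge-center variant
#' measures Arg CZ to Glu CD).
#'
#' @param traj a `TrajectorySegment`.
#' @param system the owning `MolecularSystem`.
#' @param residueA `"chain:resnum"` of the basic residue (Arg/Lys/His).
#' @param residueB `"chain:resnum"` of the acidic residue (Asp/Glu).
#' @param spec a [salt_bridge_spec()].
#' @return list with `occupancy`, `formed` (per-frame logical) and `series`
#'   (a `DistanceSeries`).
#' @export
salt_bridge_series <- function(traj, system, residueA, residueB,
                               spec = salt_bridge_spec()) {
  resname <- function(residue) {
    idx <- .residue_atoms(system, residue, heavy_only = FALSE)
    toupper(system$atoms$residue_name[idx[1]])
  }
  rnA <- resname(residueA); rnB <- resname(residueB)
  if (!rnA %in% names(spec$donors)) {
    stop("residueA must be basic (", paste(names(spec$donors), collapse = "/"),
         "), got ", rnA)
  }
  if (!rnB %in% names(spec$acceptors)) {
    stop("residueB must be acidic (",
         paste(names(spec$acceptors), collapse = "/"), "), got ", rnB)
  }
  ia <- .residue_atoms(system, residueA, atom_names = spec$donors[[rnA]])
  ib <- .residue_atoms(system, residueB, atom_names = spec$acceptors[[rnB]])
  series <- min_distance_series(traj, system, ia, ib)
  series$label <- paste(residueA, residueB, sep = " <-> ")
  formed <- series$values < spec$cutoff
  list(occupancy = mean(formed), formed = formed, series = series,
       spec = spec)
}

#' Compare two contact maps (kept / lost / weakened / gained)
#'
#' Classifies each residue pair by occupancy change from system A to B:
#' `lost` when fraction >= `present` in A and < `absent` in B, `gained` for
#' the reverse, `weakened` when the fraction drops by at least `drop` while
#' still present, `kept` otherwise.  The thresholds are declared conventions
#' (the qualitative "lost"/"weakened" language has no published cutoffs) and
#' are surfaced in the output.
#'
#' @param mapA,mapB `ContactMap`s over comparable residue labels.
#' @param pair_map optional 2-column matrix mapping A pair labels to B pair
#'   labels (`"resA|resB"`); default identical labels.
#' @param present,absent,drop classification thresholds.
#' @return data.frame with fraction_A, fraction_B and status.
#' @export
compare_contact_maps <- function(mapA, mapB, pair_map = NULL,
                                 present = 0.5, absent = 0.05, drop = 0.25) {
  keyA <- paste(mapA$pairs$resA, mapA$pairs$resB, sep = "|")
  keyB <- paste(mapB$pairs$resA, mapB$pairs$resB, sep = "|")
  if (is.null(pair_map)) {
    keys <- union(keyA, keyB)
    pair_map <- cbind(keys, keys)
  }
  fa <- mapA$pairs$fraction[match(pair_map[, 1], keyA)]
  fb <- mapB$pairs$fraction[match(pair_map[, 2], keyB)]
  fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
  status <- rep("kept", nrow(pair_map))
  status[fa >= present & fb < absent] <- "lost"
  status[fb >= present & fa < absent] <- "gained"
  status[status == "kept" & fb >= absent & (fa - fb) >= drop] <- "weakened"
  out <- data.frame(pair = pair_map[, 1], fraction_A = fa, fraction_B = fb,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(present = present, absent = absent, drop = drop)
  out
}

#' Write a contact map as TSV
#' @param map a `ContactMap`.
#' @param path output path.
#' @export
write_contact_map_tsv <- function(map, path) {
  utils::write.table(map$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
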