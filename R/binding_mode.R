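#' Construct a docked ligand pose
#'
#' A pose is a set of ligand atoms plus the interaction metadata the
#' binding-mode classifier needs: which atoms carry the positive charge
#' (protonated amines) and which atom index sets form aromatic rings.
#' Perception of charges and rings is input metadata by design; no chemical
#' perception engine is involved.
#'
#' @param atoms Tibble with columns `atom_name`, `element`, `x`, `y`, `z`.
#' @param cation_atoms Character vector of atom names declared as cationic.
#' @param rings List of integer vectors (row indices into `atoms`) or
#'   character vectors (atom names), each with >= 5 members.
#' @param pose_id Identifier.
#' @return A list of class `ligand_pose`.
#' @export
ligand_pose <- function(atoms, cation_atoms = character(), rings = list(),
                        pose_id = "pose") {
  atoms <- tibble::as_tibble(atoms)
  required <- c("atom_name", "element", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("pose atoms missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cation_atoms <- as.character(cation_atoms)
  unknown <- setdiff(cation_atoms, atoms$atom_name)
  if (length(unknown) > 0) {
    stop("cation atom(s) not present in pose: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rings <- purrr::map(rings, function(r) {
    if (is.character(r)) r <- match(r, atoms$atom_name)
    r <- as.integer(r)
    if (any(is.na(r)) || any(r < 1 | r > nrow(atoms))) {
      stop("ring refers to atoms not present in the pose", call. = FALSE)
    }
    if (length(r) < 5) stop("aromatic rings need >= 5 atoms", call. = FALSE)
    r
  })
  structure(list(atoms = atoms, cation_atoms = cation_atoms, rings = rings,
                 pose_id = pose_id),
            class = "ligand_pose")
}

#' Binding-site anchors for binding-mode classification
#'
#' The two geometric anchors of the conserved aminergic binding mode: the
#' carboxylate oxygens of the anchor aspartate (Asp 3.32 in BW numbering)
#' and a set of receptor heavy atoms on the TM5/TM6 face of the pocket
#' toward which a well-posed ligand extends an aromatic moiety.
#'
#' @param structure Receptor structure tibble.
#' @param asp_resno Residue number of the anchor Asp (author numbering, or a
#'   BW label resolved through `numbering_map`).
#' @param tm56_resno Residue numbers (or BW labels) of the TM5/6 anchor
#'   residues; all their heavy side-chain atoms are used.
#' @param chain Chain id.
#' @param numbering_map Optional named map from BW labels to residue numbers.
#' @return A list of class `site_anchors` with `carboxylate` and
#'   `tm56_atoms` coordinate tibbles.
#' @export
site_anchors <- function(structure, asp_resno, tm56_resno, chain = "A",
                         numbering_map = NULL) {
  structure <- validate_structure(structure)
  if (!is.null(numbering_map)) {
    asp_resno <- region_definition(asp_resno, numbering_map = numbering_map)$resno
    tm56_resno <- region_definition(tm56_resno, numbering_map = numbering_map)$resno
  }
  asp <- structure[structure$chain == chain &
                     structure$resno == asp_resno, , drop = FALSE]
  if (nrow(asp) == 0 || asp$resid[1] != "ASP") {
    stop("anchor residue ", asp_resno, " is not an Asp in the structure",
         call. = FALSE)
  }
  carboxylate <- asp[asp$elety %in% c("OD1", "OD2"), , drop = FALSE]
  if (nrow(carboxylate) == 0) {
    stop("anchor Asp has no carboxylate oxygens (OD1/OD2)", call. = FALSE)
  }
  tm56 <- structure[structure$chain == chain &
                      structure$resno %in% tm56_resno &
                      !(structure$elety %in% c(backbone_atoms, "OXT")), ,
                    drop = FALSE]
  if (nrow(tm56) == 0) {
    stop("no heavy side-chain atoms found for the TM5/6 anchor residues",
         call. = FALSE)
  }
  structure(list(carboxylate = carboxylate, tm56_atoms = tm56),
            class = "site_anchors")
}

min_cross_distance <- function(a, b) {
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Detect the salt bridge to the anchor aspartate
#'
#' True when the minimum distance between any declared cationic nitrogen of
#' the pose and either carboxylate oxygen of the anchor Asp is within the
#' cutoff. The distance is reported regardless of the verdict.
#'
#' @param pose A [ligand_pose()] with at least one declared cation atom.
#' @param anchors A [site_anchors()].
#' @param cutoff Distance cutoff in Angstrom; default 4.0.
#' @return A list with `detected` (logical) and `distance` (Angstrom).
#' @export
detect_salt_bridge <- function(pose, anchors, cutoff = 4.0) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(anchors, "site_anchors"))
  if (length(pose$cation_atoms) == 0) {
    stop("criterion inapplicable: pose declares no cation atoms",
         call. = FALSE)
  }
  cations <- pose$atoms[pose$atoms$atom_name %in% pose$cation_atoms, ,
                        drop = FALSE]
  d <- min_cross_distance(cations, anchors$carboxylate)
  list(detected = d <= cutoff, distance = d)
}

#' Detect aromatic engagement toward the TM5/6 face
#'
#' True when the centroid of any declared aromatic ring lies within the
#' cutoff of any TM5/6 anchor heavy atom.
#'
#' @param pose A [ligand_pose()] with at least one declared ring.
#' @inheritParams detect_salt_bridge
#' @param cutoff Distance cutoff in Angstrom; default 6.0.
#' @return A list with `detected` and `distance` (minimum centroid-anchor
#'   distance).
#' @export
detect_aromatic_engagement <- function(pose, anchors, cutoff = 6.0) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(anchors, "site_anchors"))
  if (length(pose$rings) == 0) {
    stop("criterion inapplicable: pose declares no aromatic rings",
         call. = FALSE)
  }
  centroids <- purrr::map_dfr(pose$rings, function(r) {
    ring <- pose$atoms[r, , drop = FALSE]
    tibble::tibble(x = mean(ring$x), y = mean(ring$y), z = mean(ring$z))
  })
  d <- min_cross_distance(centroids, anchors$tm56_atoms)
  list(detected = d <= cutoff, distance = d)
}

#' Classify a docked pose as Good or Bad
#'
#' A pose is "Good" when it both forms the salt bridge to the anchor Asp and
#' engages the TM5/6 face with an aromatic moiety -- the binding-mode
#' features conserved across experimentally determined aminergic receptor
#' complexes. Failing either criterion gives "Bad".
#'
#' @inheritParams detect_salt_bridge
#' @param salt_bridge_cutoff,aromatic_cutoff Distance cutoffs in Angstrom
#'   (defaults 4.0 and 6.0).
#' @return A one-row tibble: `pose_id`, `salt_bridge`,
#'   `salt_bridge_distance`, `aromatic`, `aromatic_distance`, `verdict`
#'   (`"Good"`/`"Bad"`).
#' @export
classify_pose <- function(pose, anchors, salt_bridge_cutoff = 4.0,
                          aromatic_cutoff = 6.0) {
  sb <- detect_salt_bridge(pose, anchors, salt_bridge_cutoff)
  ar <- detect_aromatic_engagement(pose, anchors, aromatic_cutoff)
  tibble::tibble(
    pose_id = pose$pose_id,
    salt_bridge = sb$detected,
    salt_bridge_distance = sb$distance,
    aromatic = ar$detected,
    aromatic_distance = ar$distance,
    verdict = ifelse(sb$detected && ar$detected, "Good", "Bad")
  )
}

#' @rdname classify_pose
#' @param poses A list of [ligand_pose()]s.
#' @return `classify_poses()` returns one row per pose.
#' @export
classify_poses <- function(poses, anchors, salt_bridge_cutoff = 4.0,
                           aromatic_cutoff = 6.0) {
  purrr::map_dfr(poses, classify_pose, anchors = anchors,
                 salt_bridge_cutoff = salt_bridge_cutoff,
                 aromatic_cutoff = aromatic_cutoff)
}

#' Read a ligand pose from PDB/Mol2 plus a side-car annotation file
#'
#' The coordinate file supplies atoms; the YAML side-car supplies the
#' interaction metadata with keys `cation_atoms` (atom names) and `rings`
#' (list of atom-name lists).
#'
#' @param path Coordinate file (`.pdb` or `.mol2`).
#' @param annotation_path YAML annotation file; defaults to `path` with the
#'   extension replaced by `.yml`.
#' @param pose_id Identifier; defaults to the file name.
#' @return A [ligand_pose()].
#' @export
read_pose <- function(path, annotation_path = NULL, pose_id = NULL) {
  if (is.null(pose_id)) pose_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(annotation_path)) {
    annotation_path <- paste0(sub("\\.[^.]*$", "", path), ".yml")
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "mol2") {
    mol <- bio3d::read.mol2(path)
    atoms <- tibble::tibble(
      atom_name = mol$atom$elena,
      element = sub("\\..*$", "", mol$atom$elety),
      x = mol$atom$x, y = mol$atom$y, z = mol$atom$z
    )
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                            verbose = FALSE))
    atoms <- tibble::tibble(
      atom_name = pdb$atom$elety,
      element = trimws(ifelse(is.na(pdb$atom$elesy),
                              substr(pdb$atom$elety, 1, 1), pdb$atom$elesy)),
      x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z
    )
  }
  ann <- yaml::read_yaml(annotation_path)
  ligand_pose(atoms,
              cation_atoms = unlist(ann$cation_atoms),
              rings = purrr::map(ann$rings, unlist),
              pose_id = pose_id)
}
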