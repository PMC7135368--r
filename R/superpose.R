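backbone_atoms <- c("N", "CA", "C", "O")

pair_atoms <- function(mobile, reference, region = NULL,
                       atom_class = c("backbone", "sidechain_heavy", "all")) {
  atom_class <- match.arg(atom_class)
  pick <- function(s) {
    s <- validate_structure(s)
    s <- s[in_region(s, region), , drop = FALSE]
    if (atom_class == "backbone") {
      s <- s[s$elety %in% backbone_atoms, , drop = FALSE]
    } else if (atom_class == "sidechain_heavy") {
      s <- s[!(s$elety %in% c(backbone_atoms, "OXT")), , drop = FALSE]
    }
    s
  }
  m <- pick(mobile)
  r <- pick(reference)
  dplyr::inner_join(m, r, by = c("chain", "resno", "elety"),
                    suffix = c("_m", "_r"))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the optimal rotation and translation mapping the mobile
#' structure's fit-region backbone atoms onto the reference, pairing atoms by
#' `(chain, residue number, atom name)`; atoms missing from either structure
#' are skipped symmetrically. The rotation is the standard SVD solution with
#' a reflection guard, so the transform is always a proper rotation.
#'
#' @param mobile,reference Structure tibbles (see [read_structure()]).
#' @param fit_region A [region_definition()] restricting the fit (typically
#'   the TM backbone); `NULL` fits on all shared backbone atoms.
#' @return An object of class `rigid_transform`: list with `rotation` (3x3),
#'   `translation` (length 3), `fit_rmsd` (Angstrom, on the fitted atoms) and
#'   `n_atoms`.
#' @export
superpose <- function(mobile, reference, fit_region = NULL) {
  pairs <- pair_atoms(mobile, reference, fit_region, "backbone")
  if (nrow(pairs) < 3) {
    stop("insufficient overlap: need at least 3 paired backbone atoms, got ",
         nrow(pairs), call. = FALSE)
  }
  P <- as.matrix(pairs[, c("x_m", "y_m", "z_m")])   # mobile
  Q <- as.matrix(pairs[, c("x_r", "y_r", "z_r")])   # reference
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- cq - as.numeric(R %*% cp)
  fitted <- Pc %*% t(R)
  fit_rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = translation,
                 fit_rmsd = fit_rmsd, n_atoms = nrow(pairs)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a structure
#'
#' @param structure A structure tibble.
#' @param transform A `rigid_transform` from [superpose()].
#' @return The structure with transformed coordinates.
#' @export
apply_transform <- function(structure, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  structure <- validate_structure(structure)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  moved <- xyz %*% t(transform$rotation)
  moved <- sweep(moved, 2, transform$translation, "+")
  structure$x <- moved[, 1]
  structure$y <- moved[, 2]
  structure$z <- moved[, 3]
  structure
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform fitted on", x$n_atoms, "backbone atom pairs\n")
  cat(sprintf("fit RMSD: %.3f Angstrom\n", x$fit_rmsd))
  invisible(x)
}
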