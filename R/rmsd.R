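## Chemically equivalent side-chain atom labelings. A 180-degree flip of the
## terminal group makes these labelings indistinguishable, so an RMSD that
## ignores them penalizes pure renaming: for each residue the labeling with
## the smaller squared deviation is chosen.
symmetric_swaps <- list(
  ASP = c(OD1 = "OD2", OD2 = "OD1"),
  GLU = c(OE1 = "OE2", OE2 = "OE1"),
  PHE = c(CD1 = "CD2", CD2 = "CD1", CE1 = "CE2", CE2 = "CE1"),
  TYR = c(CD1 = "CD2", CD2 = "CD1", CE1 = "CE2", CE2 = "CE1"),
  ARG = c(NH1 = "NH2", NH2 = "NH1"),
  LEU = c(CD1 = "CD2", CD2 = "CD1"),
  VAL = c(CG1 = "CG2", CG2 = "CG1")
)

swap_symmetric_labels <- function(structure, resno = NULL) {
  structure <- validate_structure(structure)
  rows <- structure$resid %in% names(symmetric_swaps)
  if (!is.null(resno)) rows <- rows & structure$resno %in% resno
  idx <- which(rows)
  if (length(idx) > 0) {
    new <- vapply(idx, function(i) {
      map <- symmetric_swaps[[structure$resid[i]]]
      nm <- structure$elety[i]
      if (nm %in% names(map)) unname(map[nm]) else nm
    }, character(1))
    structure$elety[idx] <- new
  }
  structure
}

residue_ssd <- function(pairs) {
  pairs |>
    dplyr::mutate(sq = (.data$x_m - .data$x_r)^2 +
                       (.data$y_m - .data$y_r)^2 +
                       (.data$z_m - .data$z_r)^2) |>
    dplyr::group_by(.data$chain, .data$resno) |>
    dplyr::summarise(ssd = sum(.data$sq), n = dplyr::n(),
                     resid = .data$resid_r[1], .groups = "drop")
}

#' Region RMSD between two superposed structures
#'
#' Root-mean-square deviation over paired atoms of one atom class within a
#' region. Structures are compared in the frame they are given (no refit
#' here); pair them beforehand with [superpose()] and [apply_transform()].
#' With `symmetry = TRUE` (the default for side chains), residues carrying
#' chemically equivalent atom pairs -- Asp (OD1/OD2), Glu (OE1/OE2), Phe/Tyr
#' (CD1/CD2 + CE1/CE2), Arg (NH1/NH2), Leu (CD1/CD2), Val (CG1/CG2) -- use
#' whichever labeling gives the smaller squared deviation, resolved per
#' residue independently.
#'
#' @param mobile,reference Structure tibbles in a common frame.
#' @param region A [region_definition()], or `NULL` for all residues.
#' @param atom_class `"backbone"` (N, CA, C, O), `"sidechain_heavy"` (heavy
#'   atoms beyond the backbone, CB included; OXT and hydrogens never used),
#'   or `"all"` (both classes).
#' @param symmetry Apply the side-chain symmetry correction?
#' @return RMSD in Angstrom (numeric scalar) with an `n_atoms` attribute.
#' @export
region_rmsd <- function(mobile, reference, region = NULL,
                        atom_class = c("backbone", "sidechain_heavy", "all"),
                        symmetry = TRUE) {
  atom_class <- match.arg(atom_class)
  pairs <- pair_atoms(mobile, reference, region, atom_class)
  if (nrow(pairs) == 0) {
    stop("empty region: no paired ", atom_class, " atoms", call. = FALSE)
  }
  per_res <- residue_ssd(pairs)
  if (symmetry && atom_class != "backbone") {
    swapped <- swap_symmetric_labels(mobile)
    pairs_sw <- pair_atoms(swapped, reference, region, atom_class)
    per_res_sw <- residue_ssd(pairs_sw)
    joined <- dplyr::left_join(
      per_res, per_res_sw,
      by = c("chain", "resno"), suffix = c("", "_sw")
    )
    # only adopt the alternative labeling when it pairs the same atoms
    better <- !is.na(joined$ssd_sw) & joined$n_sw == joined$n &
      joined$ssd_sw < joined$ssd
    total_ssd <- sum(ifelse(better, joined$ssd_sw, joined$ssd))
  } else {
    total_ssd <- sum(per_res$ssd)
  }
  n <- sum(per_res$n)
  structure(sqrt(total_ssd / n), n_atoms = n)
}

#' Region-wise structural accuracy report for a model
#'
#' The standard accuracy triple for a receptor model against a reference
#' (crystal) structure: TM backbone RMSD, binding-site backbone RMSD and
#' symmetry-corrected binding-site side-chain RMSD. The model is first
#' superposed on the reference with a single least-squares fit over the TM
#' backbone; both binding-site metrics are then computed in that frame
#' without refitting.
#'
#' @param mobile,reference Structure tibbles.
#' @param tm_region,bs_region [region_definition()]s for the TM bundle and
#'   binding site (the BS is conventionally restricted to TM residues).
#' @param symmetry Symmetry-correct the side-chain RMSD? Default `TRUE`.
#' @return A one-row tibble: `model_id`, `rmsd_tmbb`, `rmsd_bsbb`,
#'   `rmsd_bssc`, the atom counts behind each metric, and
#'   `symmetry_corrected`.
#' @export
rmsd_report <- function(mobile, reference, tm_region, bs_region,
                        symmetry = TRUE) {
  mobile <- validate_structure(mobile)
  xf <- superpose(mobile, reference, tm_region)
  fitted <- apply_transform(mobile, xf)
  tmbb <- region_rmsd(fitted, reference, tm_region, "backbone")
  bsbb <- region_rmsd(fitted, reference, bs_region, "backbone")
  bssc <- region_rmsd(fitted, reference, bs_region, "sidechain_heavy",
                      symmetry = symmetry)
  tibble::tibble(
    model_id = mobile$model_id[1],
    rmsd_tmbb = as.numeric(tmbb),
    rmsd_bsbb = as.numeric(bsbb),
    rmsd_bssc = as.numeric(bssc),
    n_tmbb = attr(tmbb, "n_atoms"),
    n_bsbb = attr(bsbb, "n_atoms"),
    n_bssc = attr(bssc, "n_atoms"),
    symmetry_corrected = symmetry
  )
}

#' Pairwise structural diversity of a set of models
#'
#' Every pair of models is superposed on the fit region (TM backbone) and the
#' region RMSD of the requested atom class is computed, giving the symmetric
#' diversity matrix whose off-diagonal mean summarizes how much a template's
#' models differ from one another (e.g. binding-site side-chain diversity).
#'
#' @param models A list of structure tibbles sharing residue numbering.
#' @param region Region over which the RMSD is taken.
#' @param atom_class `"backbone"` or `"sidechain_heavy"`.
#' @param fit_region Region for the superposition fit; defaults to `region`.
#' @param symmetry Symmetry-correct side-chain comparisons? Default `TRUE`.
#' @return A list of class `pairwise_diversity`: `matrix` (symmetric, zero
#'   diagonal, dimnames = model ids) and `mean` (off-diagonal mean, Angstrom).
#' @export
pairwise_diversity <- function(models, region = NULL,
                               atom_class = "sidechain_heavy",
                               fit_region = NULL, symmetry = TRUE) {
  if (length(models) < 2) stop("need at least two models", call. = FALSE)
  if (is.null(fit_region)) fit_region <- region
  models <- purrr::map(models, validate_structure)
  ids <- purrr::map_chr(models, ~ .x$model_id[1])
  if (anyDuplicated(ids)) ids <- paste0(ids, "#", seq_along(ids))
  k <- length(models)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xf <- superpose(models[[j]], models[[i]], fit_region)
      fitted <- apply_transform(models[[j]], xf)
      m[i, j] <- m[j, i] <- as.numeric(
        region_rmsd(fitted, models[[i]], region, atom_class,
                    symmetry = symmetry)
      )
    }
  }
  structure(list(matrix = m, mean = mean(m[upper.tri(m)])),
            class = "pairwise_diversity")
}

#' @export
print.pairwise_diversity <- function(x, ...) {
  cat("Pairwise diversity over", nrow(x$matrix), "models; mean",
      sprintf("%.3f Angstrom\n", x$mean))
  invisible(x)
}

#' Fraction of candidate structures improving on a baseline
#'
#' For refinement protocols (e.g. MD snapshots of a homology model) this is
#' the fraction of candidates whose region RMSD to the reference is strictly
#' lower than the baseline model's; each structure is superposed on the
#' reference over `fit_region` before measuring.
#'
#' @param candidates List of structure tibbles (e.g. refined snapshots).
#' @param reference Reference (crystal) structure.
#' @param baseline The unrefined starting model.
#' @inheritParams pairwise_diversity
#' @return A fraction in \[0, 1\], with attributes `baseline_rmsd` and
#'   `candidate_rmsd`.
#' @export
improvement_fraction <- function(candidates, reference, baseline,
                                 region = NULL, atom_class = "backbone",
                                 fit_region = NULL, symmetry = TRUE) {
  if (length(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  if (is.null(fit_region)) fit_region <- region
  one_rmsd <- function(s) {
    xf <- superpose(s, reference, fit_region)
    as.numeric(region_rmsd(apply_transform(s, xf), reference, region,
                           atom_class, symmetry = symmetry))
  }
  base <- one_rmsd(baseline)
  vals <- purrr::map_dbl(candidates, one_rmsd)
  structure(mean(vals < base), baseline_rmsd = base, candidate_rmsd = vals)
}
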