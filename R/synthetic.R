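## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a ligand/decoy docking score table
#'
#' Scores follow the binormal model: ligand scores are
#' `Normal(mu_ligand, sigma)` and decoy scores `Normal(mu_decoy, sigma)`
#' (lower = more favorable energy), the minimal family with a closed-form
#' ROC curve so simulated screens can be checked against
#' [binormal_logauc_oracle()]. Each compound independently fails to dock
#' with probability `dock_failure_rate`, in which case its score is `NA`.
#' Defaults mirror a large retrospective aminergic-receptor benchmark: 822
#' ligands against ~55k property-matched decoys, docking energies around
#' -35 kcal/mol with spread 5, and a one-sigma ligand/decoy separation.
#'
#' @param n_ligands,n_decoys Compound counts (>= 1).
#' @param mu_ligand,mu_decoy Mean scores of the two classes.
#' @param sigma Common score standard deviation (> 0).
#' @param dock_failure_rate Probability a compound fails to dock, in
#'   \[0, 1).
#' @param seed Integer seed; the generator is fully reproducible from it and
#'   leaves the caller's RNG stream untouched.
#' @param model_id Model id of the simulated screen.
#' @return A screen table (see [screen_table()]).
#' @examples
#' gen_screen(n_ligands = 10, n_decoys = 100, seed = 7)
#' @export
gen_screen <- function(n_ligands = 822, n_decoys = 55146,
                       mu_ligand = -40, mu_decoy = -35, sigma = 5,
                       dock_failure_rate = 0, seed = NULL,
                       model_id = "model") {
  check_sim_params(n_ligands, n_decoys, sigma, dock_failure_rate)
  with_seed(seed, {
    n <- n_ligands + n_decoys
    is_ligand <- c(rep(TRUE, n_ligands), rep(FALSE, n_decoys))
    score <- stats::rnorm(n, mean = ifelse(is_ligand, mu_ligand, mu_decoy),
                          sd = sigma)
    docked <- stats::runif(n) >= dock_failure_rate
    score[!docked] <- NA_real_
    screen_table(
      compound_id = c(sprintf("L%05d", seq_len(n_ligands)),
                      sprintf("D%05d", seq_len(n_decoys))),
      is_ligand = is_ligand, score = score,
      model_id = model_id, docked = docked
    )
  })
}

check_sim_params <- function(n_ligands, n_decoys, sigma, dock_failure_rate) {
  if (n_ligands < 1 || n_decoys < 1) {
    stop("n_ligands and n_decoys must be >= 1", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (dock_failure_rate < 0 || dock_failure_rate >= 1) {
    stop("dock_failure_rate must be in [0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Expected semi-log AUC of the binormal score model
#'
#' For ligand and decoy scores drawn from normal distributions with common
#' `sigma`, the population ROC curve is
#' `TPR(x) = Phi(Phi^-1(x) + (mu_decoy - mu_ligand) / sigma)`. This oracle
#' integrates that analytic curve against `log10(x)` over `[lambda, 1]` by
#' trapezoidal quadrature on the log axis; it shares no code with the
#' empirical ROC path, so it serves as an independent expectation for
#' [gen_screen()] + [screen_enrichment()].
#'
#' @inheritParams gen_screen
#' @inheritParams log_auc
#' @param n_grid Number of quadrature nodes on the log axis (default 20001;
#'   halving the step changes the value by < 1e-4).
#' @return Expected logAUC in percent.
#' @export
binormal_logauc_oracle <- function(mu_ligand = -40, mu_decoy = -35, sigma = 5,
                                   lambda = 0.001, n_grid = 20001) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  check_lambda(lambda)
  d <- (mu_decoy - mu_ligand) / sigma
  u <- seq(log10(lambda), 0, length.out = n_grid)
  tpr <- stats::pnorm(stats::qnorm(10^u) + d)
  tpr[n_grid] <- 1
  h <- u[2] - u[1]
  area <- h * (sum(tpr) - (tpr[1] + tpr[n_grid]) / 2)
  100 * area / log10(1 / lambda)
}

#' @rdname binormal_logauc_oracle
#' @return `binormal_alogauc_oracle()` returns the expected aLogAUC
#'   (percentage points over random selection).
#' @export
binormal_alogauc_oracle <- function(mu_ligand = -40, mu_decoy = -35,
                                    sigma = 5, lambda = 0.001,
                                    n_grid = 20001) {
  binormal_logauc_oracle(mu_ligand, mu_decoy, sigma, lambda, n_grid) -
    random_log_auc(lambda)
}

#' Simulate a correlated ensemble of screens
#'
#' Emulates docking one compound library against many models built from the
#' same template: each compound has a latent score (its class-dependent
#' docking propensity), each model a global bias, and each compound-model
#' pair independent noise. The implied inter-model score correlation is
#' `sigma^2 / (sigma^2 + within_model_noise_sd^2)`. The default of 50 models
#' matches the convention of evaluating 50 models per template.
#'
#' @inheritParams gen_screen
#' @param n_models Number of member models (>= 1).
#' @param model_bias_sd SD of the per-model additive score bias.
#' @param within_model_noise_sd SD of the compound-by-model noise.
#' @return A list of `n_models` screen tables sharing one compound universe,
#'   with model ids `M01`, `M02`, ...
#' @export
gen_ensemble <- function(n_models = 50, n_ligands = 822, n_decoys = 55146,
                         mu_ligand = -40, mu_decoy = -35, sigma = 5,
                         model_bias_sd = 2, within_model_noise_sd = 5,
                         dock_failure_rate = 0, seed = NULL) {
  check_sim_params(n_ligands, n_decoys, sigma, dock_failure_rate)
  if (n_models < 1) stop("n_models must be >= 1", call. = FALSE)
  if (model_bias_sd < 0 || within_model_noise_sd < 0) {
    stop("bias and noise SDs must be >= 0", call. = FALSE)
  }
  with_seed(seed, {
    n <- n_ligands + n_decoys
    is_ligand <- c(rep(TRUE, n_ligands), rep(FALSE, n_decoys))
    ids <- c(sprintf("L%05d", seq_len(n_ligands)),
             sprintf("D%05d", seq_len(n_decoys)))
    latent <- stats::rnorm(n, mean = ifelse(is_ligand, mu_ligand, mu_decoy),
                           sd = sigma)
    bias <- stats::rnorm(n_models, 0, model_bias_sd)
    purrr::map(seq_len(n_models), function(m) {
      score <- latent + bias[m] + stats::rnorm(n, 0, within_model_noise_sd)
      docked <- stats::runif(n) >= dock_failure_rate
      score[!docked] <- NA_real_
      screen_table(ids, is_ligand, score,
                   model_id = sprintf("M%02d", m), docked = docked)
    })
  })
}

## residue templates for the toy receptor: atom name -> local offset from CA
toy_residue_atoms <- list(
  ALA = c("CB"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  VAL = c("CB", "CG1", "CG2"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  SER = c("CB", "OG"),
  LYS = c("CB", "CG", "CD", "CE", "NZ")
)

#' Generate a deterministic toy receptor structure
#'
#' An idealized helical peptide cycling through ten residue types (including
#' every side chain carrying a symmetric atom pair), with backbone and
#' heavy side-chain atoms at fixed geometric offsets. The geometry is not
#' chemically refined; it provides named, uniquely placed atoms for testing
#' superposition, RMSD and perturbation machinery.
#'
#' @param n_residues Number of residues (default 60, about 560 heavy atoms).
#' @param chain Chain id.
#' @param model_id Model id.
#' @return A structure tibble as from [read_structure()].
#' @export
gen_toy_structure <- function(n_residues = 60, chain = "A",
                              model_id = "toy") {
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  resids <- rep_len(names(toy_residue_atoms), n_residues)
  rows <- purrr::map_dfr(seq_len(n_residues), function(i) {
    phi <- i * 100 * pi / 180
    ca <- c(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * i)
    out <- c(cos(phi), sin(phi), 0)  # radial outward direction
    side <- toy_residue_atoms[[resids[i]]]
    atoms <- c("N", "CA", "C", "O", side)
    offs <- rbind(
      c(-0.8, -0.9, -0.6), c(0, 0, 0), c(0.9, 0.8, 0.5), c(1.3, 0.0, 1.2)
    )
    side_offs <- t(vapply(seq_along(side), function(k) {
      ang <- 0.5 * k
      (1.2 + 0.5 * k) * out + 0.7 * c(cos(ang), sin(ang), 0.3 * sin(ang + 1))
    }, numeric(3)))
    offs <- rbind(offs, side_offs)
    tibble::tibble(
      chain = chain, resno = i, resid = resids[i], elety = atoms,
      x = ca[1] + offs[, 1], y = ca[2] + offs[, 2], z = ca[3] + offs[, 3]
    )
  })
  validate_structure(dplyr::mutate(rows, model_id = model_id))
}

#' Standard regions of the toy receptor
#'
#' @param n_residues Residue count of the structure the regions refer to.
#' @param chain Chain id.
#' @return List with `tm` (all residues) and `bs` (middle third)
#'   [region_definition()]s.
#' @export
toy_regions <- function(n_residues = 60, chain = "A") {
  bs <- seq(max(1, floor(n_residues / 3)),
            min(n_residues, ceiling(2 * n_residues / 3)))
  list(tm = region_definition(seq_len(n_residues), chain, name = "TM"),
       bs = region_definition(bs, chain, name = "BS"))
}

#' Perturb and/or symmetry-relabel a structure
#'
#' Adds iid Gaussian displacement (`sigma` per coordinate) to every heavy
#' atom, so the expected RMSD to the base structure is `sqrt(3) * sigma`.
#' With `relabel_symmetric = TRUE`, a random subset of residues with
#' chemically equivalent atom pairs additionally has those labels swapped
#' without moving any coordinate -- a probe that should be invisible to a
#' symmetry-corrected RMSD and visible to a naive one.
#'
#' @param base Structure tibble.
#' @param sigma Displacement SD in Angstrom (>= 0).
#' @param relabel_symmetric Swap symmetric atom labels in a random subset of
#'   eligible residues?
#' @param relabel_fraction Fraction of eligible residues to relabel.
#' @param seed Integer seed.
#' @param model_id Model id of the perturbed copy.
#' @return A structure tibble.
#' @export
gen_perturbed_structure <- function(base, sigma = 0.5,
                                    relabel_symmetric = FALSE,
                                    relabel_fraction = 0.5, seed = NULL,
                                    model_id = NULL) {
  base <- validate_structure(base)
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  with_seed(seed, {
    out <- base
    if (sigma > 0) {
      n <- nrow(out)
      out$x <- out$x + stats::rnorm(n, 0, sigma)
      out$y <- out$y + stats::rnorm(n, 0, sigma)
      out$z <- out$z + stats::rnorm(n, 0, sigma)
    }
    if (relabel_symmetric) {
      eligible <- unique(out$resno[out$resid %in% names(symmetric_swaps)])
      if (length(eligible) > 0) {
        k <- max(1, round(relabel_fraction * length(eligible)))
        chosen <- sample(eligible, k)
        out <- swap_symmetric_labels(out, resno = chosen)
      }
    }
    if (!is.null(model_id)) out$model_id <- model_id
    out
  })
}

#' Generate a toy receptor-ligand complex with prescribed geometry
#'
#' Places an anchor aspartate carboxylate, a TM5/6-style aromatic anchor
#' residue, a ligand cation and a planar six-membered ring such that the
#' minimum cation-carboxylate distance is exactly `salt_bridge_distance` and
#' the minimum ring-centroid-to-anchor distance is exactly
#' `aromatic_distance`. Useful for exercising the binding-mode classifier at
#' known distances.
#'
#' @param salt_bridge_distance Requested N+ to carboxylate-O distance
#'   (Angstrom, >= 0).
#' @param aromatic_distance Requested ring-centroid to anchor-atom distance
#'   (Angstrom, >= 0).
#' @return A list with `receptor` (structure tibble), `pose`
#'   ([ligand_pose()]), `anchors` ([site_anchors()]), `asp_resno` (114) and
#'   `tm56_resno` (193).
#' @export
gen_toy_complex <- function(salt_bridge_distance = 3.0,
                            aromatic_distance = 5.0) {
  if (salt_bridge_distance < 0 || aromatic_distance < 0) {
    stop("infeasible geometry: requested distances must be >= 0",
         call. = FALSE)
  }
  asp <- tibble::tibble(
    chain = "A", resno = 114L, resid = "ASP",
    elety = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    x = c(-3.0, -2.2, -2.5, -3.5, -1.0, -0.6, 0.0, -1.2),
    y = c(-1.0, -0.5, 0.9, 1.3, -1.2, -0.4, 0.0, 1.8),
    z = c(0, 0, 0, 0.2, 0, 0.6, 0, 0)
  )
  phe <- tibble::tibble(
    chain = "A", resno = 193L, resid = "PHE",
    elety = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    x = c(-1.0, -0.5, -1.2, -2.2, 0.0, 0.0, 0.7, -0.7, 0.7, -0.7, 0.0),
    y = c(1.0, 0.2, -0.8, -0.9, 0.4, 0.2, 0.7, -0.7, 0.7, -0.7, 0.0),
    z = c(14.5, 13.8, 13.6, 13.9, 13.0, 12.2, 11.6, 11.6, 10.7, 10.7, 10.0)
  )
  receptor <- validate_structure(
    dplyr::mutate(dplyr::bind_rows(asp, phe), model_id = "toy_site")
  )
  centroid_z <- 10.0 - aromatic_distance
  theta <- 2 * pi * (0:5) / 6
  ring <- tibble::tibble(
    atom_name = sprintf("C%d", 2:7), element = "C",
    x = 1.39 * cos(theta), y = 1.39 * sin(theta), z = centroid_z
  )
  cation <- tibble::tibble(atom_name = "N1", element = "N",
                           x = salt_bridge_distance, y = 0, z = 0)
  pose <- ligand_pose(dplyr::bind_rows(cation, ring),
                      cation_atoms = "N1",
                      rings = list(sprintf("C%d", 2:7)),
                      pose_id = "toy_pose")
  anchors <- site_anchors(receptor, asp_resno = 114, tm56_resno = 193)
  ## the geometric anchor used for the aromatic criterion is the PHE CZ at
  ## (0, 0, 10); all other side-chain atoms of the anchor residue sit higher
  ## in z, so the requested distance is the realized minimum
  list(receptor = receptor, pose = pose, anchors = anchors,
       asp_resno = 114L, tm56_resno = 193L)
}

#' Generate a toy pairwise alignment with known region identity
#'
#' Builds an alignment whose region identity is exactly
#' `100 * n_matches / region_size` by construction: `n_matches` region
#' positions agree between target and template, `n_gap_columns` of the
#' mismatching positions align the target residue to a template gap (a gap
#' counts as mismatch), and the remaining mismatches use a different
#' residue. Flanking matched columns pad both ends.
#'
#' @param region_size Number of target positions in the region.
#' @param n_matches Number of identical columns within the region
#'   (`n_matches + n_gap_columns <= region_size`).
#' @param n_gap_columns Region positions aligned to a template gap.
#' @param seed Optional seed shuffling which positions match.
#' @param flank Matched columns added on each side of the region.
#' @return A list with `alignment` ([pairwise_alignment()]) and `region`
#'   (integer vector of target residue numbers).
#' @export
gen_toy_alignment <- function(region_size, n_matches, n_gap_columns = 0,
                              seed = NULL, flank = 5) {
  if (n_matches < 0 || n_gap_columns < 0 ||
      n_matches + n_gap_columns > region_size) {
    stop("need n_matches + n_gap_columns <= region_size", call. = FALSE)
  }
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  with_seed(seed, {
    target_region <- sample(aa, region_size, replace = TRUE)
    status <- sample(c(rep("match", n_matches), rep("gap", n_gap_columns),
                       rep("mismatch", region_size - n_matches - n_gap_columns)))
    template_region <- vapply(seq_len(region_size), function(i) {
      switch(status[i],
             match = target_region[i],
             gap = "-",
             mismatch = setdiff(aa, target_region[i])[1])
    }, character(1))
    flank_seq <- sample(aa, flank, replace = TRUE)
    flank_seq2 <- sample(aa, flank, replace = TRUE)
    target <- paste(c(flank_seq, target_region, flank_seq2), collapse = "")
    template <- paste(c(flank_seq, template_region, flank_seq2), collapse = "")
    list(
      alignment = pairwise_alignment(target, template,
                                     target_name = "target",
                                     template_name = "template"),
      region = seq(flank + 1L, flank + region_size)
    )
  })
}
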