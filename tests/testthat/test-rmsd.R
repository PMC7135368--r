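test_that("region RMSD is zero on self and exact for uniform displacement", {
  s <- gen_toy_structure(n_residues = 10)
  regions <- toy_regions(10)
  expect_equal(as.numeric(region_rmsd(s, s, regions$bs, "backbone")), 0)
  expect_equal(as.numeric(region_rmsd(s, s, regions$bs, "sidechain_heavy")), 0)

  shifted <- dplyr::mutate(s, x = .data$x + 1)
  expect_equal(as.numeric(region_rmsd(shifted, s, regions$tm, "backbone")), 1,
               tolerance = 1e-12)
  expect_equal(
    as.numeric(region_rmsd(shifted, s, regions$tm, "sidechain_heavy")), 1,
    tolerance = 1e-12
  )
})

test_that("a ring flip is invisible to the symmetry-aware RMSD only", {
  s <- gen_toy_structure(n_residues = 20)
  flipped <- gen_perturbed_structure(s, sigma = 0, relabel_symmetric = TRUE,
                                     relabel_fraction = 1, seed = 2)
  naive <- as.numeric(region_rmsd(flipped, s, NULL, "sidechain_heavy",
                                  symmetry = FALSE))
  sym <- as.numeric(region_rmsd(flipped, s, NULL, "sidechain_heavy",
                                symmetry = TRUE))
  expect_gt(naive, 0)
  expect_equal(sym, 0, tolerance = 1e-12)
})

test_that("symmetry-aware RMSD never exceeds the naive RMSD", {
  s <- gen_toy_structure(n_residues = 25)
  for (seed in 1:10) {
    pert <- gen_perturbed_structure(s, sigma = 0.6,
                                    relabel_symmetric = seed %% 2 == 0,
                                    seed = seed)
    naive <- as.numeric(region_rmsd(pert, s, NULL, "sidechain_heavy",
                                    symmetry = FALSE))
    sym <- as.numeric(region_rmsd(pert, s, NULL, "sidechain_heavy",
                                  symmetry = TRUE))
    expect_lte(sym, naive + 1e-12)
  }
  # equality when no symmetric residues are present
  plain <- s[s$resid %in% c("ALA", "SER", "LYS"), ]
  pert <- gen_perturbed_structure(plain, sigma = 0.4, seed = 3)
  expect_equal(
    as.numeric(region_rmsd(pert, plain, NULL, "sidechain_heavy", TRUE)),
    as.numeric(region_rmsd(pert, plain, NULL, "sidechain_heavy", FALSE))
  )
})

test_that("RMSD is symmetric in its arguments and invariant to joint rigid motion", {
  s <- gen_toy_structure(n_residues = 15)
  pert <- gen_perturbed_structure(s, sigma = 0.5, seed = 7)
  ab <- as.numeric(region_rmsd(pert, s, NULL, "sidechain_heavy"))
  ba <- as.numeric(region_rmsd(s, pert, NULL, "sidechain_heavy"))
  expect_equal(ab, ba, tolerance = 1e-12)

  expect_equal(
    as.numeric(region_rmsd(move_structure(pert), move_structure(s),
                           NULL, "sidechain_heavy")),
    ab, tolerance = 1e-9
  )
})

test_that("Gaussian perturbation concentrates the RMSD on sqrt(3) * sigma", {
  s <- gen_toy_structure(n_residues = 60)
  expect_gte(nrow(s), 500)
  pert <- gen_perturbed_structure(s, sigma = 0.5, seed = 11)
  rmsd <- as.numeric(region_rmsd(pert, s, NULL, "all"))
  expect_equal(rmsd, sqrt(3) * 0.5, tolerance = 0.1)
})

test_that("rmsd_report computes the accuracy triple in a single TM-fit frame", {
  ref <- gen_toy_structure(n_residues = 30, model_id = "xtal")
  regions <- toy_regions(30)
  model <- gen_perturbed_structure(move_structure(ref), sigma = 0.4, seed = 5,
                                   model_id = "hm1")
  rep <- rmsd_report(model, ref, regions$tm, regions$bs)
  expect_equal(rep$model_id, "hm1")
  expect_true(all(c(rep$rmsd_tmbb, rep$rmsd_bsbb, rep$rmsd_bssc) > 0))
  expect_true(rep$symmetry_corrected)

  # manual recomputation through the same public pieces
  xf <- superpose(model, ref, regions$tm)
  fitted <- apply_transform(model, xf)
  expect_equal(rep$rmsd_bssc,
               as.numeric(region_rmsd(fitted, ref, regions$bs,
                                      "sidechain_heavy")))
  # self-comparison is identically zero
  self <- rmsd_report(ref, ref, regions$tm, regions$bs)
  expect_equal(self$rmsd_tmbb + self$rmsd_bsbb + self$rmsd_bssc, 0,
               tolerance = 1e-9)
})

test_that("pairwise diversity matches per-pair recomputation and noise expectation", {
  base <- gen_toy_structure(n_residues = 20)
  regions <- toy_regions(20)
  models <- purrr::map(1:3, function(i) {
    gen_perturbed_structure(base, sigma = 0.5, seed = i,
                            model_id = paste0("m", i))
  })
  div <- pairwise_diversity(models, regions$bs, "sidechain_heavy",
                            fit_region = regions$tm, symmetry = FALSE)
  expect_equal(div$matrix, t(div$matrix))
  expect_equal(diag(div$matrix), c(m1 = 0, m2 = 0, m3 = 0))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      xf <- superpose(models[[j]], models[[i]], regions$tm)
      expect_equal(
        div$matrix[i, j],
        as.numeric(region_rmsd(apply_transform(models[[j]], xf), models[[i]],
                               regions$bs, "sidechain_heavy",
                               symmetry = FALSE))
      )
    }
  }
  # duplicates give an all-zero matrix
  dup <- pairwise_diversity(list(base, base), regions$bs, "sidechain_heavy",
                            fit_region = regions$tm)
  expect_equal(max(abs(dup$matrix)), 0, tolerance = 1e-9)

  # independent sigma-noise on both members: expect sqrt(2) * sqrt(3) * sigma
  big <- gen_toy_structure(n_residues = 60)
  big_regions <- toy_regions(60)
  pair <- purrr::map(1:4, function(i) {
    gen_perturbed_structure(big, sigma = 0.5, seed = 100 + i,
                            model_id = paste0("p", i))
  })
  div2 <- pairwise_diversity(pair, big_regions$tm, "sidechain_heavy",
                             fit_region = big_regions$tm, symmetry = FALSE)
  expect_equal(div2$mean, sqrt(2) * sqrt(3) * 0.5, tolerance = 0.2)
})

test_that("improvement fraction counts strict improvements only", {
  ref <- gen_toy_structure(n_residues = 15, model_id = "xtal")
  regions <- toy_regions(15)
  baseline <- gen_perturbed_structure(ref, sigma = 0.8, seed = 1,
                                      model_id = "hm")

  copies <- purrr::map(1:4, ~ baseline)
  expect_equal(as.numeric(
    improvement_fraction(copies, ref, baseline, regions$tm, "backbone")
  ), 0)

  perfect <- purrr::map(1:4, ~ ref)
  expect_equal(as.numeric(
    improvement_fraction(perfect, ref, baseline, regions$tm, "backbone")
  ), 1)

  # mixed set: candidates closer and farther than the baseline, hand-counted
  candidates <- purrr::map(c(0.1, 0.2, 1.6, 2.0), function(sg) {
    gen_perturbed_structure(ref, sigma = sg, seed = round(sg * 10))
  })
  frac <- improvement_fraction(candidates, ref, baseline, regions$tm,
                               "backbone")
  base_rmsd <- attr(frac, "baseline_rmsd")
  hand <- mean(attr(frac, "candidate_rmsd") < base_rmsd)
  expect_equal(as.numeric(frac), hand)
  expect_equal(as.numeric(frac), 0.5)
})
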