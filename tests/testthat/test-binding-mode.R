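make_pose <- function(cation_xyz = list(c(2.8, 0, 0)),
                      ring_centroids = list(c(0, 0, 6))) {
  cations <- purrr::imap_dfr(cation_xyz, function(p, i) {
    tibble::tibble(atom_name = paste0("N", i), element = "N",
                   x = p[1], y = p[2], z = p[3])
  })
  theta <- 2 * pi * (0:5) / 6
  rings <- purrr::imap_dfr(ring_centroids, function(c0, i) {
    tibble::tibble(atom_name = sprintf("C%d_%d", 1:6, i), element = "C",
                   x = c0[1] + 1.39 * cos(theta),
                   y = c0[2] + 1.39 * sin(theta), z = c0[3])
  })
  ligand_pose(dplyr::bind_rows(cations, rings),
              cation_atoms = cations$atom_name,
              rings = purrr::map(seq_along(ring_centroids),
                                 ~ sprintf("C%d_%d", 1:6, .x)))
}

toy_anchors <- function() gen_toy_complex(3.0, 5.0)$anchors

test_that("salt-bridge detection takes the minimum over cation-carboxylate pairs", {
  anchors <- toy_anchors()  # OD1 at the origin

  near <- detect_salt_bridge(make_pose(list(c(2.8, 0, 0))), anchors, 4.0)
  expect_true(near$detected)
  expect_equal(near$distance, 2.8, tolerance = 1e-9)

  far <- detect_salt_bridge(make_pose(list(c(6.5, 0, 0))), anchors, 4.0)
  expect_false(far$detected)
  expect_equal(far$distance, 6.5, tolerance = 1e-9)

  two <- detect_salt_bridge(make_pose(list(c(4.5, 0, 0), c(0, 0, 3.9))),
                            anchors, 4.0)
  expect_true(two$detected)
  expect_equal(two$distance, 3.9, tolerance = 1e-9)
})

test_that("aromatic engagement takes the minimum over ring centroids", {
  anchors <- toy_anchors()  # anchor CZ at (0, 0, 10)

  near <- detect_aromatic_engagement(make_pose(ring_centroids = list(c(0, 0, 6))),
                                     anchors, 6.0)
  expect_true(near$detected)
  expect_equal(near$distance, 4.0, tolerance = 1e-9)

  far <- detect_aromatic_engagement(
    make_pose(ring_centroids = list(c(0, 0, -5), c(20, 0, 10))), anchors, 6.0
  )
  expect_false(far$detected)
  expect_equal(far$distance, 15, tolerance = 1e-9)

  two <- detect_aromatic_engagement(
    make_pose(ring_centroids = list(c(0, 0, 2), c(0, 0, 5.5))), anchors, 6.0
  )
  expect_equal(two$distance, 4.5, tolerance = 1e-9)
})

test_that("verdicts are the conjunction of the two criteria", {
  anchors <- toy_anchors()
  good <- classify_pose(make_pose(list(c(2.8, 0, 0)), list(c(0, 0, 6))),
                        anchors)
  expect_equal(good$verdict, "Good")

  salt_only <- classify_pose(make_pose(list(c(2.8, 0, 0)), list(c(0, 0, -9))),
                             anchors)
  expect_equal(salt_only$verdict, "Bad")
  expect_true(salt_only$salt_bridge)
  expect_false(salt_only$aromatic)

  aromatic_only <- classify_pose(make_pose(list(c(9, 0, 0)), list(c(0, 0, 6))),
                                 anchors)
  expect_equal(aromatic_only$verdict, "Bad")
})

test_that("missing interaction metadata raises criterion-inapplicable errors", {
  anchors <- toy_anchors()
  no_cation <- ligand_pose(
    tibble::tibble(atom_name = sprintf("C%d", 1:6), element = "C",
                   x = 1.39 * cos(2 * pi * (0:5) / 6),
                   y = 1.39 * sin(2 * pi * (0:5) / 6), z = 6),
    rings = list(sprintf("C%d", 1:6))
  )
  expect_error(detect_salt_bridge(no_cation, anchors), "inapplicable")
  no_ring <- ligand_pose(
    tibble::tibble(atom_name = "N1", element = "N", x = 2, y = 0, z = 0),
    cation_atoms = "N1"
  )
  expect_error(detect_aromatic_engagement(no_ring, anchors), "inapplicable")
})

test_that("a batch of synthetic poses reproduces the hand enumeration", {
  anchors <- toy_anchors()
  set.seed(42)
  sb_d <- round(stats::runif(50, 2, 8), 2)
  ar_d <- round(stats::runif(50, 2, 10), 2)
  poses <- purrr::map(1:50, function(i) {
    p <- make_pose(list(c(sb_d[i], 0, 0)), list(c(0, 0, 10 - ar_d[i])))
    p$pose_id <- sprintf("pose%02d", i)
    p
  })
  res <- classify_poses(poses, anchors)
  hand_good <- sum(sb_d <= 4.0 & ar_d <= 6.0)
  expect_equal(sum(res$verdict == "Good"), hand_good)
  # count conservation
  expect_equal(sum(res$verdict == "Good") + sum(res$verdict == "Bad"), 50)

  # enlarging either cutoff never flips Good to Bad
  wider <- classify_poses(poses, anchors, salt_bridge_cutoff = 5.0,
                          aromatic_cutoff = 7.5)
  expect_true(all(!(res$verdict == "Good" & wider$verdict == "Bad")))
})

test_that("verdicts are invariant under joint rigid motion of pose and receptor", {
  cx <- gen_toy_complex(3.5, 5.5)
  before <- classify_pose(cx$pose, cx$anchors)

  moved_receptor <- move_structure(cx$receptor)
  moved_atoms <- cx$pose$atoms
  xyz <- rigid_motion(as.matrix(moved_atoms[, c("x", "y", "z")]))
  moved_atoms$x <- xyz[, 1]; moved_atoms$y <- xyz[, 2]; moved_atoms$z <- xyz[, 3]
  moved_pose <- ligand_pose(moved_atoms, cx$pose$cation_atoms,
                            list(sprintf("C%d", 2:7)))
  moved_anchors <- site_anchors(moved_receptor, cx$asp_resno, cx$tm56_resno)
  after <- classify_pose(moved_pose, moved_anchors)
  expect_equal(after$verdict, before$verdict)
  expect_equal(after$salt_bridge_distance, before$salt_bridge_distance,
               tolerance = 1e-9)
  expect_equal(after$aromatic_distance, before$aromatic_distance,
               tolerance = 1e-9)
})

test_that("poses round-trip from PDB plus YAML annotations", {
  cx <- gen_toy_complex(3.0, 5.0)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  atoms <- cx$pose$atoms
  lines <- sprintf(
    "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), atoms$atom_name, atoms$x, atoms$y, atoms$z,
    atoms$element
  )
  writeLines(c(lines, "END"), pdb)
  yml <- sub("\\.pdb$", ".yml", pdb)
  yaml::write_yaml(list(cation_atoms = list("N1"),
                        rings = list(as.list(sprintf("C%d", 2:7)))), yml)
  pose <- read_pose(pdb)
  res <- classify_pose(pose, cx$anchors)
  expect_equal(res$verdict, "Good")
  expect_equal(res$salt_bridge_distance, 3.0, tolerance = 1e-3)
  expect_equal(res$aromatic_distance, 5.0, tolerance = 1e-3)
})
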