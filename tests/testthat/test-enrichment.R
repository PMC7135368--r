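test_that("ROC construction handles separation, ties and undocked compounds", {
  # perfect separation: ligand retrieved before any decoy
  perfect <- roc_curve(screen_table(c("L", "D"), c(TRUE, FALSE), c(-10, -5)))
  expect_equal(perfect$fpr, c(0, 0, 1))
  expect_equal(perfect$tpr, c(0, 1, 1))

  # a ligand/decoy tie advances both fractions in one block
  tied <- roc_curve(screen_table(c("L", "D"), c(TRUE, FALSE), c(-7, -7)))
  expect_equal(tied$fpr, c(0, 1))
  expect_equal(tied$tpr, c(0, 1))

  # undocked compounds enter as one final tied block
  tbl <- screen_table(c("L1", "L2", "D1", "D2"), c(TRUE, TRUE, FALSE, FALSE),
                      c(-9, NA, -5, NA))
  curve <- roc_curve(tbl)
  expect_equal(curve$fpr, c(0, 0, 0.5, 1))
  expect_equal(curve$tpr, c(0, 0.5, 0.5, 1))
})

test_that("ROC curve equals the brute-force rank walk on structured and random tables", {
  # 2 ligands at ranks 1 and 3 among 8 decoys
  scores <- c(-12, -10, -11, -9, -8, -7, -6, -5, -4, -3)
  tbl <- screen_table(sprintf("C%02d", 1:10),
                      c(TRUE, TRUE, rep(FALSE, 8)), scores)
  curve <- roc_curve(tbl)
  expect_equal(plain_roc(curve), plain_roc(brute_roc(tbl)))

  for (seed in 1:25) {
    tbl <- random_small_screen(seed)
    expect_equal(plain_roc(roc_curve(tbl)), plain_roc(brute_roc(tbl)))
  }
})

test_that("ROC construction rejects invalid tables", {
  expect_error(roc_curve(screen_table("L", TRUE, -5)), "decoy")
  expect_error(
    screen_table(c("L", "D"), c(TRUE, FALSE), c(Inf, -5)),
    "non-finite"
  )
  expect_error(
    screen_table(c("L", "L"), c(TRUE, FALSE), c(-9, -5)),
    "duplicated"
  )
})

test_that("logAUC matches closed forms on the diagonal and the perfect screen", {
  diagonal <- tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))
  for (lam in c(0.001, 0.01, 0.1, 0.3)) {
    expect_equal(log_auc(diagonal, lam), 100 * (1 - lam) / log(1 / lam),
                 tolerance = 1e-12)
  }
  perfect <- tibble::tibble(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  for (lam in c(0.001, 0.05, 0.5)) {
    expect_equal(log_auc(perfect, lam), 100, tolerance = 1e-12)
  }
  expect_error(log_auc(diagonal, 0), "lambda")
  expect_error(log_auc(diagonal, 1), "lambda")
})

test_that("logAUC agrees with independent fine-grid quadrature", {
  # fixed 10-compound table
  tbl <- screen_table(sprintf("C%02d", 1:10),
                      c(TRUE, FALSE, TRUE, FALSE, FALSE,
                        TRUE, FALSE, FALSE, FALSE, TRUE),
                      c(-12, -11.5, -11, -10, -9.5, -9, -8, -7, -6, -5))
  curve <- roc_curve(tbl)
  expect_equal(log_auc(curve), quad_log_auc(curve), tolerance = 1e-8)

  for (seed in 1:100) {
    curve <- roc_curve(random_small_screen(seed))
    expect_equal(log_auc(curve), quad_log_auc(curve), tolerance = 1e-6)
  }
})

test_that("aLogAUC is zero for random selection and complements the perfect screen", {
  diagonal <- tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))
  for (lam in c(0.001, 0.02, 0.2, 0.9)) {
    expect_equal(adjusted_log_auc(diagonal, lam), 0, tolerance = 1e-12)
  }
  perfect <- tibble::tibble(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  expect_equal(adjusted_log_auc(perfect, 0.001),
               100 - random_log_auc(0.001), tolerance = 1e-12)
})

test_that("the doubling curve scores close to 10 aLogAUC units", {
  # TPR(x) = min(2x, 1): twice the random retrieval at every early fraction
  doubling <- tibble::tibble(fpr = c(0, 0.5, 1), tpr = c(0, 1, 1))
  expect_equal(adjusted_log_auc(doubling, 0.001), 10, tolerance = 0.05)
})

test_that("enrichment categories follow the band table with inclusive upper edges", {
  expect_equal(
    as.character(classify_enrichment(c(9.0, 10, 15, 15.1, 20, 20.1, 25, 26.6))),
    c("poor", "fair", "fair", "good", "good", "very good", "very good",
      "excellent")
  )
  expect_equal(as.character(classify_enrichment(18.1)), "good")
  expect_equal(as.character(classify_enrichment(-3)), "poor")
  expect_true(is.ordered(classify_enrichment(5)))
  expect_error(classify_enrichment(NA_real_), "finite")
})

test_that("curve and scores are invariant to record order", {
  set.seed(11)
  tbl <- random_small_screen(42)
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(plain_roc(roc_curve(tbl)), plain_roc(roc_curve(shuffled)))
  expect_equal(screen_enrichment(tbl)$alogauc,
               screen_enrichment(shuffled)$alogauc)
})

test_that("improving a ligand's rank never decreases aLogAUC", {
  for (seed in 1:20) {
    tbl <- random_small_screen(seed)
    before <- adjusted_log_auc(roc_curve(tbl))
    lig_idx <- which(tbl$is_ligand & tbl$docked)
    if (length(lig_idx) == 0) next
    i <- lig_idx[length(lig_idx)]
    improved <- tbl
    improved$score[i] <- min(tbl$score, na.rm = TRUE) - 1
    after <- adjusted_log_auc(roc_curve(improved))
    expect_gte(after, before - 1e-10)
  }
})

test_that("logAUC and aLogAUC respect their bounds on random tables", {
  lam <- 0.001
  for (seed in 101:140) {
    curve <- roc_curve(random_small_screen(seed))
    la <- log_auc(curve, lam)
    expect_gte(la, 0)
    expect_lte(la, 100)
    aa <- adjusted_log_auc(curve, lam)
    expect_gte(aa, -random_log_auc(lam))
    expect_lte(aa, 100 - random_log_auc(lam))
  }
})

test_that("screen_enrichment reports one consistent row per model", {
  s1 <- gen_screen(n_ligands = 15, n_decoys = 200, seed = 1, model_id = "A")
  s2 <- gen_screen(n_ligands = 15, n_decoys = 200, seed = 2, model_id = "B")
  res <- screen_enrichment(dplyr::bind_rows(s1, s2))
  expect_equal(nrow(res), 2)
  expect_equal(res$model_id, c("A", "B"))
  expect_equal(res$alogauc, res$logauc - random_log_auc(0.001))
  expect_equal(as.character(res$category),
               as.character(classify_enrichment(res$alogauc)))
})

test_that("screen tables round-trip through delimited text", {
  tbl <- gen_screen(n_ligands = 8, n_decoys = 30, seed = 3,
                    dock_failure_rate = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(tbl, path)
  back <- read_screen_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})
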