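# Independent oracles used across the suite. These deliberately share no
# code with the package's computation paths.

# Fine-grid numeric quadrature of the interpolated ROC curve against
# log10(x): composite Simpson on the log axis within each linear segment,
# with nodes aligned to the curve's kinks.
quad_log_auc <- function(curve, lambda = 0.001, n = 200) {
  x <- curve$fpr
  y <- curve$tpr
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    x0 <- x[i]; x1 <- x[i + 1]
    y0 <- y[i]; y1 <- y[i + 1]
    if (x1 <= lambda || x1 <= x0) next
    if (x0 < lambda) {
      y0 <- y0 + (y1 - y0) * (lambda - x0) / (x1 - x0)
      x0 <- lambda
    }
    u <- seq(log10(x0), log10(x1), length.out = 2 * n + 1)
    xx <- 10^u
    tt <- y0 + (y1 - y0) * (xx - x0) / (x1 - x0)
    h <- u[2] - u[1]
    w <- c(1, rep(c(4, 2), n - 1), 4, 1)
    total <- total + h / 3 * sum(w * tt)
  }
  100 * total / log10(1 / lambda)
}

# Strip class/attributes so curves compare by their points only.
plain_roc <- function(curve) {
  data.frame(fpr = as.numeric(curve$fpr), tpr = as.numeric(curve$tpr))
}

# Brute-force rank walk: retrieval fractions at every distinct score
# threshold, computed by direct counting over the full record vectors.
brute_roc <- function(tbl) {
  n_lig <- sum(tbl$is_ligand)
  n_dec <- sum(!tbl$is_ligand)
  th <- sort(unique(tbl$score[tbl$docked]))
  fpr <- c(0, vapply(th, function(s) {
    sum(!tbl$is_ligand & tbl$docked & tbl$score <= s) / n_dec
  }, numeric(1)))
  tpr <- c(0, vapply(th, function(s) {
    sum(tbl$is_ligand & tbl$docked & tbl$score <= s) / n_lig
  }, numeric(1)))
  if (any(!tbl$docked)) {
    fpr <- c(fpr, 1)
    tpr <- c(tpr, 1)
  }
  tibble::tibble(fpr = fpr, tpr = tpr)
}

# Small random screen with ties and optional docking failures, for
# property-style loops.
random_small_screen <- function(seed, max_compounds = 50) {
  set.seed(seed)
  n <- sample(4:max_compounds, 1)
  n_lig <- sample(seq_len(n - 1), 1)
  scores <- round(stats::rnorm(n, -30, 4), sample(0:2, 1))  # induces ties
  docked <- stats::runif(n) > 0.1
  if (!any(docked)) docked[1] <- TRUE
  scores[!docked] <- NA
  screen_table(
    compound_id = sprintf("C%03d", seq_len(n)),
    is_ligand = c(rep(TRUE, n_lig), rep(FALSE, n - n_lig)),
    score = scores,
    docked = docked
  )
}

rigid_motion <- function(xyz, angle = 0.7, axis = c(1, 2, 2) / 3,
                         shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(xyz %*% t(R), 2, shift, "+")
}

move_structure <- function(s, ...) {
  xyz <- rigid_motion(as.matrix(s[, c("x", "y", "z")]), ...)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}
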