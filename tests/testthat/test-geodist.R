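# Ancestry coordinate system: MDS, Procrustes, PC projection, genetic
# distance and binned accuracy profiles.

make_freq_points <- function(coords, pad_to = 5, pad_value = 0.5) {
  # embed explicit low-dimensional points as frequency rows
  out <- cbind(coords, matrix(pad_value, nrow(coords), pad_to - ncol(coords)))
  rownames(out) <- paste0("P", seq_len(nrow(out)))
  colnames(out) <- paste0("v", seq_len(ncol(out)))
  out
}

test_that("classical MDS reproduces exact low-dimensional configurations", {
  set.seed(61)
  pts <- matrix(runif(12, 0.2, 0.8), 4, 3)
  ft <- make_freq_points(pts)
  cfg <- mds_from_freqs(ft, k = 3)
  expect_equal(as.matrix(dist(cfg)), as.matrix(dist(ft)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # identical rows embed at distance zero
  ft2 <- make_freq_points(rbind(pts, pts[1, , drop = FALSE]))
  cfg2 <- mds_from_freqs(ft2, k = 3)
  expect_lt(sqrt(sum((cfg2[1, ] - cfg2[5, ])^2)), 1e-10)
  expect_error(mds_from_freqs(ft, k = 4), "k \\+ 1")
})

test_that("MDS matches the double-centering spectral oracle", {
  set.seed(62)
  ft <- matrix(runif(600, 0.05, 0.95), 6, 100)
  rownames(ft) <- paste0("P", 1:6)
  k <- 2
  cfg <- mds_from_freqs(ft, k = k)
  # oracle: eigendecomposition of the double-centered squared distances
  D2 <- as.matrix(dist(ft))^2
  J <- diag(6) - matrix(1 / 6, 6, 6)
  B <- -0.5 * J %*% D2 %*% J
  eg <- eigen(B, symmetric = TRUE)
  oracle <- eg$vectors[, 1:k] %*% diag(sqrt(eg$values[1:k]))
  for (j in 1:k) {
    pivot <- which.max(abs(oracle[, j]))
    if (oracle[pivot, j] < 0) oracle[, j] <- -oracle[, j]
  }
  expect_equal(unname(cfg), unname(oracle), tolerance = 1e-8)
})

test_that("Procrustes recovers identity and known transforms", {
  set.seed(63)
  X <- matrix(rnorm(40), 8, 5)
  fit0 <- procrustes_fit(X, X)
  expect_equal(fit0$s, 1, tolerance = 1e-12)
  expect_equal(fit0$R, diag(5), tolerance = 1e-10)
  expect_equal(fit0$t, rep(0, 5), tolerance = 1e-10)
  expect_lt(fit0$rss, 1e-18)

  qrR <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  if (det(qrR) < 0) qrR[, 1] <- -qrR[, 1]
  s_true <- 2.3
  t_true <- c(1, -2, 0.5, 3, -1)
  Y <- s_true * X %*% qrR + matrix(t_true, 8, 5, byrow = TRUE)
  fit <- procrustes_fit(X, Y)
  expect_equal(fit$s, s_true, tolerance = 1e-8)
  expect_equal(fit$R, qrR, tolerance = 1e-8)
  expect_equal(fit$t, t_true, tolerance = 1e-8)
  expect_equal(procrustes_apply(fit, X), Y, tolerance = 1e-8)

  expect_error(procrustes_fit(matrix(1, 4, 2), matrix(rnorm(8), 4, 2)),
               "degenerate")
})

test_that("reflections are allowed and beat a randomized rotation search", {
  set.seed(64)
  X <- matrix(rnorm(30), 6, 5)
  Rref <- diag(c(-1, 1, 1, 1, 1))  # reflection
  Y <- X %*% Rref
  fit <- procrustes_fit(X, Y)
  expect_equal(det(fit$R), -1, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
  # no orthogonal matrix from a random search does better
  rand_rss <- replicate(200, {
    Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
    sum((X %*% Q - Y)^2)
  })
  expect_true(all(fit$rss <= rand_rss + 1e-12))
  # constrained to proper rotations the fit is worse
  fit_rot <- procrustes_fit(X, Y, allow_reflection = FALSE)
  expect_gt(fit_rot$rss, fit$rss)
  expect_equal(det(fit_rot$R), 1, tolerance = 1e-8)
})

test_that("genetic distance is plain Euclidean distance", {
  pc <- rbind(c(0, 0, 0, 0, 0), c(3, 4, 0, 0, 0))
  gw <- c(0, 0, 0, 0, 0)
  expect_equal(unname(genetic_distance(pc, gw)), c(0, 5))
  set.seed(65)
  pc2 <- matrix(rnorm(50), 10, 5)
  gw2 <- rnorm(5)
  oracle <- numeric(10)
  for (i in 1:10) {
    acc <- 0
    for (d in 1:5) acc <- acc + (pc2[i, d] - gw2[d])^2
    oracle[i] <- sqrt(acc)
  }
  expect_equal(unname(genetic_distance(pc2, gw2)), oracle)
  expect_error(genetic_distance(pc2, c(0, 0)), "dimension")
})

make_three_pop_reference <- function(m = 400, n_per = 80, seed = 71) {
  set.seed(seed)
  base <- runif(m, 0.3, 0.7)
  clamp <- function(x) pmin(pmax(x, 0.05), 0.95)
  specs <- lapply(1:3, function(i) {
    population_spec(LETTERS[i], n_per, rep(1, m),
                    clamp(base + runif(m, -0.25, 0.25)))
  })
  panels <- Map(simulate_genotypes, specs, seed + 1:3)
  ref <- genotype_panel(do.call(rbind, lapply(panels, `[[`, "dosage")),
                        panels[[1]]$variants,
                        do.call(rbind, lapply(panels, `[[`, "samples")))
  list(ref = ref, specs = specs)
}

test_that("study samples duplicated from the reference project onto their PC positions", {
  tp <- make_three_pop_reference()
  ref <- tp$ref
  idx <- c(1:5, 81:85, 161:165)
  study <- ref[idx, ]
  # naive projection of a duplicate is exact
  pn <- project_pcs(study, ref, k = 2, method = "naive")
  expect_equal(unname(pn$study_scores), unname(pn$ref_scores[idx, ]),
               tolerance = 1e-8)
  # adjusted projection lands within a small fraction of the coordinate
  # scale, and always nearest its own population centroid
  po <- project_pcs(study, ref, k = 2, method = "oadp")
  scale0 <- mean(sqrt(rowSums(po$ref_scores^2)))
  rel <- sqrt(rowSums((po$study_scores - po$ref_scores[idx, ])^2)) / scale0
  expect_lt(max(rel), 0.15)
  cent <- t(sapply(c("A", "B", "C"), function(p) {
    colMeans(po$ref_scores[ref$samples$population == p, ])
  }))
  own <- rep(1:3, each = 5)
  for (i in seq_along(idx)) {
    d <- sqrt(rowSums(sweep(cent, 2, po$study_scores[i, ])^2))
    expect_equal(which.min(d), own[i], ignore_attr = TRUE)
  }
})

test_that("naive projection shrinks new samples relative to the adjusted one", {
  tp <- make_three_pop_reference(seed = 72)
  specs <- tp$specs
  specs[[1]]$n_samples <- 40L
  new_study <- simulate_genotypes(specs[[1]], 99)
  pn <- project_pcs(new_study, tp$ref, k = 2, method = "naive")
  pa <- project_pcs(new_study, tp$ref, k = 2, method = "oadp")
  ratio <- mean(sqrt(rowSums(pn$study_scores^2)) /
                  sqrt(rowSums(pa$study_scores^2)))
  expect_lt(ratio, 1)
  expect_error(project_pcs(new_study, tp$ref, k = 500), "rank")
})

test_that("PC1 of an admixture gradient tracks the admixture fraction", {
  ex <- experiment_gd_gradient(n_study = 600, n_ref_per_pop = 100,
                               n_snps = 400, n_bins = 10, seed = 73)
  expect_gt(abs(ex$cor_alpha_pc1), 0.9)
})

test_that("mapped GWAS points duplicate reference behavior and report residuals", {
  tp <- make_three_pop_reference(seed = 74)
  ref <- tp$ref
  study <- ref[c(10, 100, 200), ]
  pops <- c("A", "B", "C")
  ref_freqs <- t(sapply(pops, function(p) {
    colMeans(ref$dosage[ref$samples$population == p, ]) / 2
  }))
  colnames(ref_freqs) <- ref$variants$id
  gwas_freqs <- ref_freqs[2, , drop = FALSE]  # duplicates population B
  rownames(gwas_freqs) <- "GWAS"
  space <- build_ancestry_space(study, ref, ref_freqs, gwas_freqs, k = 2)
  expect_equal(space$mapped["GWAS", ], space$mapped["B", ],
               tolerance = 1e-10, ignore_attr = TRUE)
  mapped <- map_gwas_points(space)
  expect_equal(attr(mapped, "residual"), space$procrustes$rss)
  # mapping preserves distance ratios up to the single scale s
  d_mds <- as.matrix(dist(space$mds_coords))
  d_map <- as.matrix(dist(space$mapped))
  off <- upper.tri(d_mds) & d_mds > 1e-8  # skip the duplicated-row pair
  expect_equal(d_map[off] / d_mds[off],
               rep(space$procrustes$s, sum(off)), tolerance = 1e-8)
  # orthogonality of the fitted rotation
  RtR <- t(space$procrustes$R) %*% space$procrustes$R
  expect_equal(RtR, diag(2), tolerance = 1e-8)
})

test_that("genetic distances are invariant to a global rotation of PC space", {
  set.seed(75)
  pc <- matrix(rnorm(60), 30, 2)
  cent <- matrix(rnorm(6), 3, 2)
  mds <- matrix(rnorm(8), 4, 2)
  rownames(mds) <- c("A", "B", "C", "GWAS")
  fit1 <- procrustes_fit(mds[1:3, ], cent)
  gd1 <- genetic_distance(pc, procrustes_apply(fit1, mds)["GWAS", ])
  Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  fit2 <- procrustes_fit(mds[1:3, ], cent %*% Q)
  gd2 <- genetic_distance(pc %*% Q, procrustes_apply(fit2, mds)["GWAS", ])
  expect_equal(gd1, gd2, tolerance = 1e-8)
})

test_that("binned profiles partition evenly and handle degenerate bins", {
  set.seed(76)
  n <- 207
  gd <- runif(n)
  y <- rnorm(n)
  s <- 0.5 * y + rnorm(n)
  prof <- binned_accuracy_profile(gd, y, s, n_bins = 9)
  expect_true(all(abs(prof$table$n - n / 9) <= 1))
  expect_true(all(diff(prof$table$mean_gd) > 0))
  expect_error(binned_accuracy_profile(gd, y, s, n_bins = n), "bins")
  expect_error(binned_accuracy_profile(gd, y, s, n_bins = 2), ">= 3")
})

test_that("a homogeneous population yields a null distance-accuracy correlation", {
  ex <- experiment_gd_gradient(n_study = 800, n_ref_per_pop = 100,
                               n_snps = 300, n_bins = 10, seed = 77,
                               null = TRUE)
  expect_gt(ex$profile$p_value, 0.05)
})

test_that("the Procrustes solution agrees with an independent implementation", {
  set.seed(78)
  X <- matrix(rnorm(36), 12, 3)
  Y <- 1.7 * X %*% qr.Q(qr(matrix(rnorm(9), 3, 3))) +
    matrix(rnorm(3), 12, 3, byrow = TRUE) + matrix(rnorm(36, 0, 0.05), 12, 3)
  fit <- procrustes_fit(X, Y)
  mine <- procrustes_apply(fit, X)
  vg <- vegan::procrustes(Y, X, scale = TRUE, symmetric = FALSE)
  vg_full <- sweep(vg$Yrot, 2, colMeans(Y), `+`)  # Yrot is target-centered
  expect_equal(unname(mine), unname(vg_full), tolerance = 1e-8)
  expect_equal(fit$s, vg$scale, tolerance = 1e-8)
})
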