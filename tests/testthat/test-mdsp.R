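test_that("mode scatter with an identity co-projection reproduces the 2-D scatters exactly", {
  set.seed(301)
  ts <- rand_matrix_set(5, 2, 4, 7)
  sc2d <- scatter_matrices(ts)
  scmk <- mode_scatter(ts, list(NULL, diag(7)), 1)
  expect_identical(scmk$Sw, sc2d$Sw)
  expect_identical(scmk$Sb, sc2d$Sb)
})

test_that("within scatter vanishes for every mode when trials equal their class means", {
  set.seed(302)
  A <- rand_tensor(c(3, 4, 2))
  B <- rand_tensor(c(3, 4, 2))
  ts <- trial_set(list(A, A, B, B), c(1, 1, 2, 2))
  U <- list(matrix(rnorm(6), 3, 2), matrix(rnorm(8), 4, 2), matrix(rnorm(4), 2, 2))
  for (k in 1:3) {
    expect_equal(mode_scatter(ts, U, k)$Sw, matrix(0, dim(A)[k], dim(A)[k]))
  }
})

test_that("trace forms through mode scatter equal the Frobenius forms of the criterion", {
  set.seed(303)
  sp <- planted_spec(shape = c(4, 5, 3), ranks = c(2, 2, 2),
                     trials_per_class = 6, noise_sd = 0.5, seed = 303)
  pd <- planted_dataset(sp)
  ts <- pd$data
  cm <- class_means(ts)
  U <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(10), 5, 2), matrix(rnorm(6), 3, 2))
  for (k in 1:3) {
    sc <- mode_scatter(ts, U, k)
    Uk <- U[[k]]
    num_tr <- sum(diag(crossprod(Uk, sc$Sb %*% Uk)))
    den_tr <- sum(diag(crossprod(Uk, sc$Sw %*% Uk)))
    num_fro <- 0
    for (j in seq_along(cm$class_means)) {
      B <- multi_mode_product(cm$class_means[[j]] - cm$grand_mean, U)
      num_fro <- num_fro + cm$counts[[j]] * sum(B^2)
    }
    den_fro <- 0
    for (i in seq_len(ts$n)) {
      W <- multi_mode_product(
        ts$trials[[i]] - cm$class_means[[as.character(ts$labels[i])]], U)
      den_fro <- den_fro + sum(W^2)
    }
    expect_equal(num_tr, num_fro, tolerance = 1e-10)
    expect_equal(den_tr, den_fro, tolerance = 1e-10)
  }
})

test_that("update_mode reduces to fit_dsp for 2-D trials with identity co-projection", {
  set.seed(304)
  for (r in 1:5) {
    ts <- rand_matrix_set(6, 2, 4, 8)
    dm <- fit_dsp(ts, d = 2)
    up <- update_mode(ts, list(NULL, diag(8)), 1, ndim = 2)
    expect_equal(up$vectors, dm$U, tolerance = 1e-9)
    expect_equal(up$values, dm$eigenvalues, tolerance = 1e-9)
  }
})

test_that("update_mode warns on a zero between scatter", {
  set.seed(305)
  A <- rand_tensor(c(3, 4))
  B <- rand_tensor(c(3, 4))
  # both classes share the same mean: Sb = 0
  ts <- trial_set(list(A, B, A, B), c(1, 1, 2, 2))
  expect_warning(update_mode(ts, list(NULL, diag(4)), 1, ndim = 2), "degenerate")
})

test_that("update_mode is conditionally optimal against random orthonormal bases", {
  set.seed(306)
  sp <- planted_spec(shape = c(5, 6, 4), ranks = c(2, 2, 2),
                     trials_per_class = 8, noise_sd = 0.4, seed = 306)
  ts <- planted_dataset(sp)$data
  U <- list(matrix(rnorm(10), 5, 2), matrix(rnorm(12), 6, 2), matrix(rnorm(8), 4, 2))
  k <- 2
  sc <- mode_scatter(ts, U, k)
  up <- update_mode(ts, U, k, ndim = 2)
  ratio <- function(Uk) {
    sum(diag(crossprod(Uk, sc$Sb %*% Uk))) / sum(diag(crossprod(Uk, sc$Sw %*% Uk)))
  }
  best <- ratio(up$vectors)
  for (r in 1:100) {
    Q <- qr.Q(qr(matrix(rnorm(12), 6)))[, 1:2]
    expect_lte(ratio(Q), best * (1 + 1e-8))
  }
})

test_that("convergence error follows the relative-change formula", {
  expect_equal(convergence_error(diag(2), diag(2)), 0)
  # closed form: ||2I - I||_F / ||I||_F^2 = sqrt(2)/2
  expect_equal(convergence_error(diag(2), 2 * diag(2)), sqrt(2) / 2)
  set.seed(307)
  A <- matrix(rnorm(12), 4)
  B <- matrix(rnorm(12), 4)
  Ac <- mdsp:::canonicalize_signs(A)
  Bc <- mdsp:::canonicalize_signs(B)
  expect_equal(convergence_error(A, B),
               norm(Bc - Ac, "F") / norm(Ac, "F")^2, tolerance = 1e-12)
  expect_error(convergence_error(diag(2), diag(3)), "identical shape")
})

test_that("one MDSP sweep with the trailing mode kept full recovers the DSP subspace", {
  set.seed(308)
  for (r in 1:20) {
    ts <- rand_matrix_set(6, 2, 4, 6)
    dm <- fit_dsp(ts, d = 2)
    mf <- fit_mdsp(ts, dims = c(2, 6), t_max = 1, epsilon = 1e-12)
    expect_lt(max_principal_angle(mf$projections[[1]], dm$U), 1e-8)
  }
})

test_that("noiseless planted structure is recovered exactly and quickly", {
  sp <- planted_spec(shape = c(6, 8, 5), ranks = c(2, 2, 2),
                     trials_per_class = 5, noise_sd = 0, seed = 309,
                     holdout_per_class = 3)
  pd <- planted_dataset(sp)
  fit <- fit_mdsp(pd$data, dims = c(2, 2, 2))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 5)
  expect_lt(max(subspace_recovery_score(fit$projections, pd$bases)), 1e-6)
  expect_equal(mean(predict(fit, pd$holdout) == pd$holdout$labels), 1)
})

test_that("t_max caps the sweep count and flags non-convergence", {
  set.seed(310)
  ts <- rand_matrix_set(6, 2, 4, 5)
  fit <- fit_mdsp(ts, dims = c(2, 2), t_max = 1, epsilon = 1e-12)
  expect_identical(fit$iterations, 1L)
  expect_false(fit$converged)
  expect_identical(nrow(fit$trace), 1L)
  # shipped defaults of the convergence rule
  expect_equal(formals(fit_mdsp)$epsilon, 0.01)
  expect_equal(formals(fit_mdsp)$t_max, 50)
})

test_that("fit_mdsp validates dims and class structure", {
  set.seed(311)
  ts <- rand_matrix_set(3, 2, 4, 5)
  expect_error(fit_mdsp(ts, dims = c(5, 2)), "outside 1..4")
  expect_error(fit_mdsp(ts, dims = c(2, 2, 2)), "one filter count per mode")
  one <- trial_set(ts$trials[1:3], rep(1, 3))
  expect_error(fit_mdsp(one, dims = c(2, 2)), "at least 2 classes")
})

test_that("fitted model is invariant to trial order and equivariant to relabeling", {
  sp <- planted_spec(shape = c(5, 6, 4), ranks = c(2, 2, 2),
                     trials_per_class = 8, noise_sd = 0.2, seed = 312)
  ts <- planted_dataset(sp)$data
  fit <- fit_mdsp(ts, dims = c(2, 2, 2))
  set.seed(312)
  perm <- sample(ts$n)
  fit_p <- fit_mdsp(trial_set(ts$trials[perm], ts$labels[perm]), dims = c(2, 2, 2))
  for (k in 1:3) expect_equal(fit$projections[[k]], fit_p$projections[[k]],
                              tolerance = 1e-6)
  # relabeling permutes class means but leaves the projections unchanged
  fit_r <- fit_mdsp(trial_set(ts$trials, 3 - ts$labels), dims = c(2, 2, 2))
  for (k in 1:3) expect_equal(fit$projections[[k]], fit_r$projections[[k]],
                              tolerance = 1e-6)
  expect_equal(fit_r$class_means[["1"]], fit$class_means[["2"]])
})

test_that("projecting input-space class means equals averaging projected trials", {
  sp <- planted_spec(shape = c(4, 5, 3), ranks = c(2, 2, 2),
                     trials_per_class = 6, noise_sd = 0.3, seed = 313)
  ts <- planted_dataset(sp)$data
  fit <- fit_mdsp(ts, dims = c(2, 2, 2))
  protos <- fit_prototypes(fit)
  for (j in seq_along(fit$classes)) {
    idx <- which(ts$labels == fit$classes[j])
    avg <- Reduce(`+`, lapply(ts$trials[idx],
                              function(X) project_trial(fit, X))) / length(idx)
    expect_equal(protos$prototypes[[j]], avg, tolerance = 1e-8)
  }
})

test_that("project_trial chains the mode products and checks shape", {
  set.seed(314)
  ts <- rand_matrix_set(4, 2, 4, 6)
  fit <- fit_mdsp(ts, dims = c(2, 3), t_max = 3)
  X <- matrix(rnorm(24), 4)
  expect_equal(project_trial(fit, X),
               t(fit$projections[[1]]) %*% X %*% fit$projections[[2]],
               tolerance = 1e-12)
  expect_error(project_trial(fit, matrix(0, 5, 6)), "input shape")
})
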