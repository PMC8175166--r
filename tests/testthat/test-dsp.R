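test_that("class means reduce to the trials themselves in degenerate cases", {
  t1 <- matrix(1:6, 2)
  t2 <- matrix(7:12, 2)
  ts <- trial_set(list(t1, t2), c(1, 2))
  cm <- class_means(ts)
  expect_equal(cm$class_means[["1"]], t1)
  expect_equal(cm$class_means[["2"]], t2)
  expect_equal(cm$grand_mean, (t1 + t2) / 2)
  # all trials identical: every mean equals that trial
  ts2 <- trial_set(list(t1, t1, t1, t1), c(1, 1, 2, 2))
  cm2 <- class_means(ts2)
  expect_equal(cm2$class_means[["1"]], t1)
  expect_equal(cm2$grand_mean, t1)
})

test_that("class means match a loop-summation oracle on a random 3-class set", {
  set.seed(201)
  ts <- rand_matrix_set(4, 3, 3, 5)
  cm <- class_means(ts)
  om <- oracle_class_means(ts$trials, ts$labels)
  for (j in 1:3) expect_equal(cm$class_means[[j]], om$class_means[[j]])
  expect_equal(cm$grand_mean, om$grand_mean, tolerance = 1e-12)
})

test_that("scatter matrices vanish in the degenerate cases and match the oracle", {
  set.seed(202)
  # trials equal to class means -> zero within scatter
  A <- matrix(rnorm(8), 2)
  B <- matrix(rnorm(8), 2)
  ts <- trial_set(list(A, A, B, B), c(1, 1, 2, 2))
  sc <- scatter_matrices(ts)
  expect_equal(sc$Sw, matrix(0, 2, 2))
  # single class -> zero between scatter
  ts1 <- trial_set(list(A, B), c(1, 1))
  expect_equal(scatter_matrices(ts1)$Sb, matrix(0, 2, 2), tolerance = 1e-14)
  # random 2-class set matches the double-loop oracle elementwise
  ts2 <- rand_matrix_set(5, 2, 4, 6)
  sc2 <- scatter_matrices(ts2)
  osc <- oracle_scatters(ts2$trials, ts2$labels)
  expect_equal(sc2$Sw, osc$Sw, tolerance = 1e-12)
  expect_equal(sc2$Sb, osc$Sb, tolerance = 1e-12)
})

test_that("within plus between scatter traces equal the total scatter", {
  set.seed(203)
  for (r in 1:5) {
    ts <- rand_matrix_set(sample(3:6, 1), sample(2:3, 1), 4, 7)
    sc <- scatter_matrices(ts)
    cm <- class_means(ts)
    total <- sum(vapply(ts$trials,
                        function(X) sum((X - cm$grand_mean)^2), numeric(1)))
    expect_equal(sum(diag(sc$Sw)) + sum(diag(sc$Sb)), total, tolerance = 1e-10)
  }
})

test_that("eigenvalues beyond the between-class rank are numerically zero", {
  set.seed(204)
  # classes share the same within-class trials, shifted along one channel
  # direction each, so the sample between space has rank exactly p - 1
  p <- 3
  Z <- replicate(6, matrix(rnorm(40), 5), simplify = FALSE)
  trials <- list()
  labels <- integer(0)
  for (j in seq_len(p)) {
    shift <- matrix(0, 5, 8)
    shift[j, ] <- 2
    for (i in 1:6) {
      trials[[length(trials) + 1]] <- Z[[i]] + shift
      labels <- c(labels, j)
    }
  }
  fit <- fit_dsp(trial_set(trials, labels), d = 5)
  expect_lt(max(abs(fit$eigenvalues[p:5])), 1e-8 * fit$eigenvalues[1])
})

test_that("the leading filter recovers a planted channel direction", {
  set.seed(205)
  c_ <- 6
  t_ <- 40
  trials <- list()
  labels <- integer(0)
  for (j in 1:2) {
    for (i in 1:30) {
      X <- matrix(rnorm(c_ * t_, sd = 1e-3), c_)
      X[1, ] <- X[1, ] + (if (j == 1) 2 else -2)
      trials[[length(trials) + 1]] <- X
      labels <- c(labels, j)
    }
  }
  fit <- fit_dsp(trial_set(trials, labels), d = 1)
  u <- fit$U[, 1]
  expect_gt(abs(u[1]) / sqrt(sum(u^2)), 0.999)
})

test_that("fit_dsp matches a dense generalized-eigensolver oracle", {
  set.seed(206)
  ts <- rand_matrix_set(8, 2, 4, 9)
  reg <- 1e-8
  fit <- fit_dsp(ts, d = 3, reg = reg)
  sc <- oracle_scatters(ts$trials, ts$labels)
  ridge <- reg * sum(diag(sc$Sw)) / 4 +
    .Machine$double.eps * (sum(diag(sc$Sw)) + sum(diag(sc$Sb))) / 4
  Swr <- sc$Sw + diag(ridge, 4)
  e <- eigen(solve(Swr) %*% sc$Sb)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values[ord])[1:3]
  expect_equal(fit$eigenvalues, vals, tolerance = 1e-8)
  for (j in 1:3) {
    v <- Re(e$vectors[, ord[j]])
    v <- v / sqrt(sum(v^2))
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_equal(fit$U[, j], v, tolerance = 1e-6)
  }
  # ratio-trace objective equals the sum of the returned eigenvalues
  U <- fit$U
  obj <- sum(diag(solve(crossprod(U, Swr %*% U)) %*% crossprod(U, sc$Sb %*% U)))
  expect_equal(obj, sum(fit$eigenvalues), tolerance = 1e-8)
})

test_that("fit_dsp is invariant to trial order and class relabeling", {
  set.seed(207)
  ts <- rand_matrix_set(6, 2, 4, 7, sep = 1)
  fit <- fit_dsp(ts, d = 2)
  perm <- sample(ts$n)
  fit_p <- fit_dsp(trial_set(ts$trials[perm], ts$labels[perm]), d = 2)
  expect_equal(fit$U, fit_p$U, tolerance = 1e-8)
  # swap class labels 1 <-> 2
  fit_r <- fit_dsp(trial_set(ts$trials, 3 - ts$labels), d = 2)
  expect_equal(fit$U, fit_r$U, tolerance = 1e-8)
})

test_that("the leading filter beats random directions on the Fisher ratio", {
  set.seed(208)
  ts <- rand_matrix_set(6, 2, 5, 8, sep = 1)
  sc <- scatter_matrices(ts)
  fit <- fit_dsp(ts, d = 1)
  ratio <- function(u) c(crossprod(u, sc$Sb %*% u)) / c(crossprod(u, sc$Sw %*% u))
  best <- ratio(fit$U[, 1])
  for (r in 1:50) {
    u <- rnorm(5)
    expect_lte(ratio(u / sqrt(sum(u^2))), best * (1 + 1e-10))
  }
})

test_that("dsp_features computes the centered projection", {
  set.seed(209)
  ts <- rand_matrix_set(5, 2, 4, 6)
  fit <- fit_dsp(ts, d = 2)
  # the grand mean itself maps to zero
  expect_equal(dsp_features(fit, fit$grand_mean), matrix(0, 2, 6))
  # random trial: explicit product oracle
  X <- matrix(rnorm(24), 4)
  expect_equal(dsp_features(fit, X), t(fit$U) %*% (X - fit$grand_mean),
               tolerance = 1e-12)
  expect_error(dsp_features(fit, matrix(0, 3, 6)), "does not match")
})

test_that("singular within scatter without regularization asks for a ridge", {
  # n < c + p makes Sw rank deficient
  set.seed(210)
  trials <- list(matrix(rnorm(40), 10), matrix(rnorm(40), 10),
                 matrix(rnorm(40), 10), matrix(rnorm(40), 10))
  ts <- trial_set(trials, c(1, 1, 2, 2))
  expect_error(fit_dsp(ts, d = 2, reg = 0), "reg > 0")
  expect_s3_class(fit_dsp(ts, d = 2, reg = 1e-8), "dsp_model")
  expect_error(fit_dsp(ts, d = 11), "`d` must be in 1..10")
})
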