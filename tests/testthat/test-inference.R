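test_that("fit_control validates its arguments", {
  expect_error(fit_control(k = 0), "positive")
  expect_error(fit_control(step_size = 0), "step_size")
  expect_error(fit_control(step_size = 1.5), "step_size")
  expect_error(fit_control(prec_min = 1, prec_max = 0.1), "prec_min")
  expect_equal(fit_control()$step_size, 0.1)
  expect_equal(fit_control()$k, 10L)
})

test_that("update_B is a damped exact Newton step", {
  model <- make_random_model(31)
  # null step leaves B unchanged
  expect_equal(update_B(model, step_size = 0)$B, model$B)

  # full step zeroes the B-gradient (exact minimizer of a quadratic)
  m1 <- update_B(model, step_size = 1)
  expect_lt(max(abs(model_gradients(m1)$G_B)), 1e-9)

  # matches generic Newton with the dense Kronecker Hessian
  small <- make_random_model(32, p = 4, k = 2, n = 3)
  h <- model_hessians(small)
  dense <- kronecker(diag(3), h$A_B)  # column-stacked vec(B)
  g <- as.numeric(model_gradients(small)$G_B)
  b_dense <- as.numeric(small$B) - 0.4 * solve(dense, g)
  expect_equal(as.numeric(update_B(small, 0.4)$B), b_dense)
})

test_that("update_U takes a projected Newton step", {
  model <- make_random_model(33)
  # negative entries produced by the step are clamped to exactly zero
  m1 <- update_U(model, step_size = 1)
  expect_true(all(m1$U >= 0))
  raw <- as.numeric(model$U) -
    solve(model_hessians(model)$H_U, as.numeric(model_gradients(model)$G_U))
  expect_true(any(raw < 0))
  expect_equal(which(as.numeric(m1$U) == 0), which(raw < 0))

  # unclamped coordinates agree with the brute-force linear solve
  keep <- raw >= 0
  expect_equal(as.numeric(m1$U)[keep], raw[keep])

  # an entry at zero with its precision at the clamp stays pinned
  model2 <- make_random_model(34)
  model2$U[1, 1] <- 0
  model2$Lambda[1, 1] <- 1e12
  m2 <- update_U(model2, step_size = 1)
  expect_lt(m2$U[1, 1], 1e-8)
})

test_that("ALS updates never increase the objective at fixed hyperparameters", {
  for (seed in 1:2) {
    for (gamma in c(0.1, 1.0)) {
      model <- make_random_model(40 + seed, bimodal = seed == 2,
                                 m = 15, m2 = 10, p = 4, k = 3, n = 6)
      obj <- neg_log_joint(model)
      for (t in 1:30) {
        model <- if (t %% 2 == 0) update_B(model, gamma) else
          update_U(model, gamma)
        obj_new <- neg_log_joint(model)
        expect_lte(obj_new, obj + 1e-8 * max(1, abs(obj)))
        obj <- obj_new
      }
    }
  }
})

test_that("hyperparameter fixed points match dense-inverse reference evaluations", {
  model <- make_random_model(51, p = 5, k = 3, n = 7)
  h <- model_hessians(model)
  up <- update_hyperparameters(model, h)

  # reference: direct dense inverses, scalar formulas
  Hinv <- solve(h$H_U)
  Ainv <- solve(h$A_B)
  p <- nrow(model$U); k <- ncol(model$U); n <- ncol(model$B)
  Lam_ref <- matrix(NA_real_, p, k)
  for (i in seq_len(p)) for (j in seq_len(k)) {
    idx <- (j - 1) * p + i
    Lam_ref[i, j] <- (1 - model$Lambda[i, j] * Hinv[idx, idx]) / model$U[i, j]^2
  }
  Lam_ref <- pmin(pmax(Lam_ref, 1e-6), 1e12)
  Lam_ref[model$U == 0] <- 1e12
  expect_equal(unname(up$Lambda), Lam_ref, tolerance = 1e-8)

  delta_ref <- sapply(seq_len(k), function(j) {
    n * (1 - model$delta[j] * Ainv[j, j]) / sum(model$B[j, ]^2)
  })
  expect_equal(unname(up$delta), pmin(pmax(delta_ref, 1e-6), 1e12),
               tolerance = 1e-8)

  md <- model$modalities$rna
  R <- md$Y - md$scale * (md$mask$matrix %*% up$U %*% up$B)
  d <- max(n - k + sum(up$delta * diag(Ainv)), 1)
  expect_equal(up$modalities$rna$sigma, sqrt(pmax(rowSums(R^2) / d, 1e-8)),
               tolerance = 1e-6)

  # zero entries are pruned to the precision ceiling
  model0 <- model
  model0$U[2, 2] <- 0
  up0 <- update_hyperparameters(model0, model_hessians(model0))
  expect_equal(up0$Lambda[2, 2], 1e12)
})

test_that("noise variances stay positive under both dof modes when p > n", {
  # adversarial shape: more pathways than samples
  model <- make_random_model(52, m = 12, p = 10, k = 2, n = 4)
  for (mode in c("sbl", "as_printed")) {
    up <- update_hyperparameters(model, model_hessians(model), dof_mode = mode)
    expect_true(all(up$modalities$rna$sigma > 0))
    expect_true(all(is.finite(up$modalities$rna$sigma)))
  }
})

test_that("scale updates solve the weighted least-squares scalar", {
  model <- make_random_model(53)
  md <- model$modalities$rna
  R0 <- md$mask$matrix %*% model$U %*% model$B

  # exact self-match and pure scaling
  model$modalities$rna$Y <- R0
  expect_equal(update_scales(model)$modalities$rna$scale, 1)
  model$modalities$rna$Y <- 2 * R0
  expect_equal(update_scales(model)$modalities$rna$scale, 2)

  # random instance: matches a 1-D numeric minimization of the objective
  model2 <- make_random_model(54)
  c_hat <- update_scales(model2)$modalities$rna$scale
  f <- function(cc) {
    m <- model2
    m$modalities$rna$scale <- cc
    neg_log_joint(m)
  }
  c_opt <- optimize(f, c(-5, 5), tol = 1e-10)$minimum
  expect_equal(c_hat, c_opt, tolerance = 1e-6)

  # an identically-zero reconstruction leaves the scale untouched
  model3 <- model2
  model3$U[] <- 0
  expect_equal(update_scales(model3)$modalities$rna$scale,
               model3$modalities$rna$scale)
})

test_that("fit initialization follows the documented contract", {
  set.seed(60)
  md <- make_modality(m = 20, p = 5, k = 3, n = 6)
  fit0 <- pathfact(list(rna = md), fit_control(k = 3, n_iter = 0))
  m0 <- fit0$model
  expect_true(all(m0$U == 0))
  expect_equal(m0$delta, 10^seq(-4, 4, length.out = 3))
  expect_equal(unname(m0$Lambda),
               matrix(10^seq(-4, 4, length.out = 3), 5, 3, byrow = TRUE))
  expect_equal(m0$modalities$rna$sigma, rep(1, 20))
  # B rows are the singular-value-scaled right singular vectors, each
  # oriented so the implied pathway-weight direction has nonnegative mass
  sv <- svd(md$Y, nu = 0, nv = 3)
  B_ref <- sv$d[1:3] * t(sv$v)
  expect_equal(abs(unname(m0$B)), abs(B_ref))
  CtY <- crossprod(md$mask$matrix, md$Y)
  for (j in 1:3) expect_gte(sum(CtY %*% m0$B[j, ]), 0)
})

test_that("fitting is reproducible and shares Hessians with the ARD updates", {
  set.seed(61)
  md <- make_modality(m = 25, p = 5, k = 3, n = 8)
  ctrl <- fit_control(k = 3, n_iter = 12, seed = 99)
  f1 <- pathfact(list(rna = md), ctrl)
  f2 <- pathfact(list(rna = md), ctrl)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$report$objective_trace, f2$report$objective_trace)

  # each Hessian factor is computed exactly once per iteration even though
  # both the Newton and the hyperparameter updates consume it
  expect_equal(unname(f1$report$hessian_evals), c(12L, 12L))

  # traces are finite and the evidence is defined from iteration one
  expect_true(all(is.finite(f1$report$objective_trace)))
  expect_true(all(is.finite(f1$report$evidence_trace)))
})

test_that("the fit recovers a noiseless synthetic factorization", {
  set.seed(62)
  p <- 10; k <- 3; m <- 200; n <- 50
  ids <- sprintf("g%03d", 1:m)
  C <- matrix(rbinom(m * p, 1, 0.2), m, p,
              dimnames = list(ids, sprintf("pw%02d", 1:p)))
  mask <- structure(list(matrix = C, marker_ids = ids,
                         pathway_names = colnames(C)), class = "pathway_mask")
  U_true <- matrix(abs(rnorm(p * k)), p, k)
  B_true <- matrix(rnorm(k * n), k, n)
  Y <- C %*% U_true %*% B_true
  colnames(Y) <- sprintf("s%02d", 1:n)
  md <- modality_data(Y, mask, label = "rna")
  fit <- pathfact(list(rna = md), fit_control(k = 3, n_iter = 200))
  Y_hat <- fit$model$modalities$rna$scale *
    (C %*% fit$model$U %*% fit$model$B)
  # exactly noiseless data stiffens the reweighted least-squares
  # landscape (learned noise variances span many decades) and the fit
  # plateaus at a moderate reconstruction error while the pathway
  # activities stay well recovered; thresholds fixed by pilot runs
  expect_lt(norm(Y_hat - Y, "F") / norm(Y, "F"), 0.25)
  expect_gt(cor(as.numeric(U_true %*% B_true),
                as.numeric(fit$model$U %*% fit$model$B)), 0.9)
})

test_that("held-out loading inference is the frozen-model ridge solution", {
  model <- make_random_model(63, bimodal = TRUE, m = 20, m2 = 14,
                             p = 5, k = 3, n = 6)

  # all-zero observations map to the prior mean
  zero_data <- lapply(model$modalities, function(md) {
    md$Y[] <- 0
    md
  })
  expect_equal(unname(infer_loadings(model, zero_data)),
               matrix(0, 3, 6))

  # equals one exact update_B step started from zero loadings
  new_data <- lapply(model$modalities, function(md) {
    md$Y <- md$Y + 0.5
    md
  })
  B_inf <- infer_loadings(model, new_data)
  model_zero <- model
  model_zero$B[] <- 0
  for (lab in names(new_data)) model_zero$modalities[[lab]]$Y <- new_data[[lab]]$Y
  expect_equal(unname(B_inf), unname(update_B(model_zero, step_size = 1)$B))

  # in the flat-prior, low-noise limit the true loadings are recovered
  model2 <- make_random_model(64, m = 40, p = 5, k = 3, n = 6)
  model2$delta[] <- 1e-6
  model2$modalities$rna$sigma[] <- 1e-4
  b_true <- matrix(rnorm(3 * 4), 3, 4)
  md_new <- model2$modalities$rna
  md_new$Y <- md_new$scale * (md_new$mask$matrix %*% model2$U %*% b_true)
  b_hat <- infer_loadings(model2, list(rna = md_new))
  expect_lt(max(abs(b_hat - b_true)) / max(abs(b_true)), 1e-6)

  # marker mismatch is rejected
  md_bad <- model$modalities$rna
  md_bad$mask$marker_ids <- rev(md_bad$mask$marker_ids)
  expect_error(infer_loadings(model, list(rna = md_bad)), "marker mismatch")
})

test_that("degenerate fits are handled explicitly", {
  set.seed(65)
  md <- make_modality(m = 10, p = 4, k = 2, n = 3)
  expect_warning(pathfact(list(rna = md), fit_control(k = 5, n_iter = 2)),
                 "ARD pruning")
  expect_error(pathfact(list(), fit_control()), "length")
})
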