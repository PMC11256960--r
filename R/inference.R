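# Bayesian alternating least-squares: exact (damped) Newton updates for U
# and B alternate with closed-form evidence-based fixed-point updates for
# all hyperparameters. Because the hyperparameter updates reuse the same
# Hessian factors as the Newton steps, automatic relevance determination
# comes at no extra asymptotic cost.

#' Fitting configuration
#'
#' @param k Number of latent dimensions (default 10; surplus latents are
#'   pruned by ARD).
#' @param n_iter Maximum number of outer iterations.
#' @param step_size Newton damping factor gamma in (0, 1]; 0.1 is a
#'   robust default, 1 gives the exact blockwise minimizer.
#' @param seed Optional integer seed set at the start of [pathfact()]
#'   (the fit itself is deterministic; the seed is recorded for
#'   provenance).
#' @param diagonal_U Use only the diagonal of the U-Hessian (cheap
#'   approximation when p * k is large).
#' @param prec_min,prec_max Clamping bounds for the ARD precisions Lambda
#'   and delta; `prec_max` marks pruned entries/latents.
#' @param sigma_floor Lower bound on the per-marker noise variances.
#' @param init_precision_log_range Length-2 exponent range; initial
#'   precisions are log-spaced as `10^seq(lo, hi, length.out = k)` along
#'   the latents.
#' @param rel_tol Relative objective change below which the fit is
#'   declared converged.
#' @param dof_mode Denominator of the noise-variance update: `"sbl"`
#'   (default) uses the effective degrees of freedom
#'   `n - k + tr(diag(delta) A_B^-1)`; `"as_printed"` uses
#'   `n - p + tr(diag(delta) A_B^-1)`. Both are clamped to >= 1 so the
#'   variances stay positive.
#' @param update_hypers,update_scales Logical switches for the
#'   hyperparameter and scale-factor updates (disable to run plain ALS at
#'   fixed hyperparameters).
#' @param verbose Print per-iteration progress lines.
#' @return An object of class `fit_control`.
#' @export
fit_control <- function(k = 10L, n_iter = 500L, step_size = 0.1, seed = NULL,
                        diagonal_U = FALSE, prec_min = 1e-6, prec_max = 1e12,
                        sigma_floor = 1e-8,
                        init_precision_log_range = c(-4, 4),
                        rel_tol = 1e-6, dof_mode = c("sbl", "as_printed"),
                        update_hypers = TRUE, update_scales = TRUE,
                        verbose = FALSE) {
  dof_mode <- match.arg(dof_mode)
  k <- as.integer(k); n_iter <- as.integer(n_iter)
  if (k <= 0L) stop("k must be a positive integer")
  if (n_iter < 0L) stop("n_iter must be >= 0")
  if (!(step_size > 0 && step_size <= 1)) stop("step_size must be in (0, 1]")
  if (!(prec_min < prec_max) || prec_min <= 0) stop("need 0 < prec_min < prec_max")
  if (sigma_floor <= 0) stop("sigma_floor must be positive")
  stopifnot(length(init_precision_log_range) == 2L)
  structure(list(k = k, n_iter = n_iter, step_size = step_size, seed = seed,
                 diagonal_U = diagonal_U, prec_min = prec_min,
                 prec_max = prec_max, sigma_floor = sigma_floor,
                 init_precision_log_range = as.numeric(init_precision_log_range),
                 rel_tol = rel_tol, dof_mode = dof_mode,
                 update_hypers = isTRUE(update_hypers),
                 update_scales = isTRUE(update_scales),
                 verbose = isTRUE(verbose)),
            class = "fit_control")
}

#' Damped Newton update of the loadings B
#'
#' `B <- B - gamma * A_B^-1 G_B`, applied columnwise via the Kronecker
#' factor of the B-Hessian. With `step_size = 1` this is the exact ridge
#' minimizer of the objective in B at fixed U.
#'
#' @param model A [factor_model()].
#' @param step_size Damping factor gamma in (0, 1].
#' @param hessians Optional precomputed `hessian_pair` containing `A_B`.
#' @return The model with B updated.
#' @export
update_B <- function(model, step_size = 1, hessians = NULL) {
  stopifnot(inherits(model, "factor_model"))
  if (is.null(hessians)) hessians <- model_hessians(model, components = "B")
  G_B <- model_gradients(model)$G_B
  R <- .hp_chol(hessians, "A_B")
  step <- backsolve(R, backsolve(R, G_B, transpose = TRUE))
  model$B <- model$B - step_size * step
  model
}

#' Damped projected Newton update of the pathway weights U
#'
#' Takes the Newton step `vec(U) <- vec(U) - gamma * H_U^-1 vec(G_U)` and
#' clamps every negative entry to zero (projection onto the
#' non-negativity constraint). Two safeguards keep the step a descent
#' step, which a naively clamped joint Newton step is not when the
#' constraint is active: entries sitting at zero whose gradient points
#' into the constraint are frozen and the Newton system is solved on the
#' remaining free coordinates (two-metric projection), and the step
#' length is halved, down to a null step, while the clamped candidate
#' would increase the objective. When no entry is clamped or frozen this
#' is exactly the plain damped Newton update.
#'
#' @param model A [factor_model()].
#' @param step_size Damping factor gamma in (0, 1].
#' @param diagonal_U Use the diagonal U-Hessian approximation.
#' @param hessians Optional precomputed `hessian_pair` containing `H_U`.
#' @return The model with U updated.
#' @export
update_U <- function(model, step_size = 1, diagonal_U = FALSE, hessians = NULL) {
  stopifnot(inherits(model, "factor_model"))
  if (is.null(hessians)) {
    hessians <- model_hessians(model, diagonal_U = diagonal_U, components = "U")
  }
  u0 <- as.numeric(model$U)
  g <- as.numeric(model_gradients(model)$G_U)
  # coordinates at the bound with an inward (or flat) gradient stay put
  pinned <- u0 <= 0 & g >= 0
  free <- which(!pinned)
  step <- numeric(length(u0))
  if (hessians$diagonal_U) {
    if (any(hessians$H_U <= 0)) stop("singular diagonal U-Hessian")
    step[free] <- g[free] / hessians$H_U[free]
  } else if (length(free) == length(u0)) {
    R <- .hp_chol(hessians, "H_U")
    step <- backsolve(R, backsolve(R, g, transpose = TRUE))
  } else if (length(free)) {
    Rf <- .chol_pd(hessians$H_U[free, free, drop = FALSE], "H_U")
    step[free] <- backsolve(Rf, backsolve(Rf, g[free], transpose = TRUE))
  }
  obj0 <- neg_log_joint(model)
  gamma <- step_size
  cand <- model
  for (halving in seq_len(30L)) {
    u_new <- u0 - gamma * step
    u_new[u_new < 0] <- 0
    cand$U <- matrix(u_new, nrow(model$U), ncol(model$U),
                     dimnames = dimnames(model$U))
    if (neg_log_joint(cand) <= obj0 + 1e-10 * max(1, abs(obj0))) {
      return(cand)
    }
    gamma <- gamma / 2
  }
  model
}

# diagonal of H_U^-1 (full inverse via Cholesky, or reciprocal in the
# diagonal approximation)
.diag_inv_HU <- function(hessians) {
  if (hessians$diagonal_U) 1 / hessians$H_U
  else diag(chol2inv(.hp_chol(hessians, "H_U")))
}

#' Closed-form evidence fixed-point updates of the hyperparameters
#'
#' Updates, in closed form derived from the Laplace evidence: the ARD
#' precisions `Lambda[p,k] <- (1 - Lambda[p,k] [H_U^-1]_(pk,pk)) /
#' U[p,k]^2` and `delta[k] <- n (1 - delta[k] [A_B^-1]_kk) / sum_n
#' B[k,n]^2`, both clamped to `[prec_min, prec_max]`; and the per-marker
#' noise variances `sigma_m^2 <- sum_n residual^2 / d` with the
#' denominator chosen by `dof_mode` (see [fit_control()]), floored at
#' `sigma_floor`. Entries with `U[p,k] = 0` (and latents with zero
#' loading energy, or non-positive update numerators) are pruned to
#' `prec_max`.
#'
#' @param model A [factor_model()] after its parameter updates.
#' @param hessians A `hessian_pair` with both components, current for the
#'   model.
#' @param dof_mode,prec_min,prec_max,sigma_floor See [fit_control()].
#' @return The model with `Lambda`, `delta` and per-modality `sigma`
#'   updated.
#' @export
update_hyperparameters <- function(model, hessians = model_hessians(model),
                                   dof_mode = c("sbl", "as_printed"),
                                   prec_min = 1e-6, prec_max = 1e12,
                                   sigma_floor = 1e-8) {
  stopifnot(inherits(model, "factor_model"), inherits(hessians, "hessian_pair"))
  dof_mode <- match.arg(dof_mode)
  p <- nrow(model$U); k <- ncol(model$U); n <- ncol(model$B)

  clamp <- function(x) pmin(pmax(x, prec_min), prec_max)

  d_HU <- matrix(.diag_inv_HU(hessians), p, k)
  num_L <- 1 - model$Lambda * d_HU
  Lam <- clamp(num_L / model$U^2)
  Lam[model$U == 0 | num_L <= 0 | !is.finite(Lam)] <- prec_max
  model$Lambda <- Lam

  A_inv <- chol2inv(.hp_chol(hessians, "A_B"))
  bsq <- rowSums(model$B^2)
  num_d <- n * (1 - model$delta * diag(A_inv))
  delta <- clamp(num_d / bsq)
  delta[bsq == 0 | num_d <= 0 | !is.finite(delta)] <- prec_max
  model$delta <- delta

  tr_term <- sum(model$delta * diag(A_inv))
  for (i in seq_along(model$modalities)) {
    md <- model$modalities[[i]]
    if (is.null(md$Y)) next
    R <- md$Y - .recon(md, model$U, model$B)
    d <- switch(dof_mode,
                sbl = n - k + tr_term,
                as_printed = n - p + tr_term)
    d <- max(d, 1)
    s2 <- pmax(rowSums(R^2) / d, sigma_floor)
    model$modalities[[i]]$sigma <- sqrt(s2)
  }
  model
}

#' Closed-form update of the modality scale factors
#'
#' Sets each modality's scalar to the noise-weighted least-squares fit of
#' the observations on the unscaled reconstruction `R_x = C_x U B`:
#' `c_x <- <Y_x, R_x>_w / <R_x, R_x>_w` with weights `sigma_x,m^-2`. A
#' modality whose reconstruction is identically zero keeps its current
#' scale.
#'
#' @param model A [factor_model()].
#' @return The model with updated scale factors.
#' @export
update_scales <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  for (i in seq_along(model$modalities)) {
    md <- model$modalities[[i]]
    if (is.null(md$Y)) next
    R0 <- (md$mask$matrix %*% model$U) %*% model$B
    w <- 1 / md$sigma^2
    den <- sum(w * rowSums(R0^2))
    if (den == 0) next
    num <- sum(w * rowSums(md$Y * R0))
    model$modalities[[i]]$scale <- num / den
  }
  model
}

# initialization: U = 0, B from the k-truncated SVD of the first
# modality's observations (singular values times right singular vectors),
# noise at 1, precisions log-spaced along the latents
.init_model <- function(data, control) {
  md1 <- data[[1L]]
  Y <- md1$Y
  k <- control$k
  n <- ncol(Y)
  p <- ncol(md1$mask$matrix)
  if (k > min(dim(Y)) || k > p) {
    warning("k = ", k, " exceeds a data dimension; surplus latents are left ",
            "to ARD pruning")
  }
  kk <- min(k, nrow(Y), n)
  sv <- svd(Y, nu = 0L, nv = kk)
  B <- matrix(0, k, n)
  B[seq_len(kk), ] <- sv$d[seq_len(kk)] * t(sv$v)
  # the SVD sign is arbitrary; orient each loading row so the implied
  # pathway-weight direction carries non-negative net mass, otherwise the
  # first projected U update clamps the whole column and ARD permanently
  # prunes the latent
  CtY <- crossprod(md1$mask$matrix, Y)
  for (j in seq_len(kk)) {
    if (sum(CtY %*% B[j, ]) < 0) B[j, ] <- -B[j, ]
  }
  rownames(B) <- paste0("latent_", seq_len(k))
  colnames(B) <- colnames(Y)
  U <- matrix(0, p, k, dimnames = list(md1$mask$pathway_names, rownames(B)))
  lr <- control$init_precision_log_range
  r <- 10^seq(lr[1L], lr[2L], length.out = k)
  delta <- r
  Lambda <- matrix(r, p, k, byrow = TRUE, dimnames = dimnames(U))
  data <- lapply(data, function(md) {
    md$sigma <- rep(1, length(md$sigma))
    md$scale <- 1
    md
  })
  factor_model(U, B, Lambda, delta, data)
}

#' Fit the pathway factor model
#'
#' Runs the full Bayesian alternating least-squares loop: B is updated on
#' even iterations and U (with non-negativity projection) on odd ones,
#' each by a damped Newton step; every iteration then applies the
#' closed-form hyperparameter updates (ARD precisions and per-marker
#' noise, reusing the Hessian factors already computed) and the
#' weighted-least-squares scale-factor update. The loop stops after
#' `n_iter` iterations or when the relative objective change drops below
#' `rel_tol`.
#'
#' @param data A `modality_data` or a list of them (e.g. RNA and
#'   proteomics); all must share the sample count and pathway set.
#' @param control A [fit_control()].
#' @return Object of class `pathfact_fit`: a list with `model` (the
#'   fitted [factor_model()]) and `report` (per-iteration objective and
#'   evidence traces, pruned latents, Hessian evaluation counts,
#'   convergence flag, control echo).
#' @export
pathfact <- function(data, control = fit_control()) {
  if (inherits(data, "modality_data")) data <- list(data)
  stopifnot(is.list(data), length(data) >= 1L, inherits(control, "fit_control"))
  lapply(data, function(md) {
    stopifnot(inherits(md, "modality_data"))
    if (is.null(md$Y)) stop("all modalities must carry observations for fitting")
  })
  n <- ncol(data[[1L]]$Y)
  if (n < 1L) stop("need at least one sample")
  if (!is.null(control$seed)) set.seed(control$seed)

  model <- .init_model(data, control)
  objective <- numeric(0L)
  evidence <- numeric(0L)
  hess_before <- hessian_eval_counts()
  converged <- FALSE
  iters <- 0L

  for (t in seq_len(control$n_iter)) {
    iters <- t
    if (t %% 2L == 0L) {
      hB <- model_hessians(model, components = "B")
      model <- update_B(model, control$step_size, hessians = hB)
      hU <- model_hessians(model, diagonal_U = control$diagonal_U,
                           components = "U")
    } else {
      hU <- model_hessians(model, diagonal_U = control$diagonal_U,
                           components = "U")
      model <- update_U(model, control$step_size,
                        diagonal_U = control$diagonal_U, hessians = hU)
      hB <- model_hessians(model, components = "B")
    }
    cache <- new.env(parent = emptyenv())
    if (!is.null(hU$cache$chol_H_U)) cache$chol_H_U <- hU$cache$chol_H_U
    if (!is.null(hB$cache$chol_A_B)) cache$chol_A_B <- hB$cache$chol_A_B
    hess <- structure(list(H_U = hU$H_U, A_B = hB$A_B,
                           diagonal_U = hU$diagonal_U, cache = cache),
                      class = "hessian_pair")
    obj <- neg_log_joint(model)
    ev <- tryCatch(log_evidence(model, hess), error = function(e) NA_real_)
    objective <- c(objective, obj)
    evidence <- c(evidence, ev)
    if (control$verbose) {
      message(sprintf("iter %4d  objective %.6g  evidence %.6g  pruned %d",
                      t, obj, ev, sum(model$delta >= control$prec_max)))
    }
    if (control$update_hypers) {
      model <- update_hyperparameters(model, hess,
                                      dof_mode = control$dof_mode,
                                      prec_min = control$prec_min,
                                      prec_max = control$prec_max,
                                      sigma_floor = control$sigma_floor)
    }
    if (control$update_scales) model <- update_scales(model)
    if (t >= 2L) {
      rel <- abs(objective[t] - objective[t - 1L]) /
        max(1, abs(objective[t - 1L]))
      if (rel < control$rel_tol) {
        converged <- TRUE
        break
      }
    }
  }

  hess_after <- hessian_eval_counts()
  report <- list(
    objective_trace = objective,
    evidence_trace = evidence,
    pruned_latents = which(model$delta >= control$prec_max),
    iterations_run = iters,
    converged = converged,
    hessian_evals = hess_after - hess_before,
    control = unclass(control)
  )
  structure(list(model = model, report = report), class = "pathfact_fit")
}

#' @export
print.pathfact_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("pathfact fit: %d iterations (%s), objective %.6g, ",
                     "%d of %d latents pruned\n"),
              r$iterations_run,
              if (r$converged) "converged" else "max iterations",
              utils::tail(r$objective_trace, 1L),
              length(r$pruned_latents), ncol(x$model$U)))
  invisible(x)
}

#' Infer loadings for held-out samples under a frozen model
#'
#' With U, the ARD precisions, noise and scale factors fixed, the
#' objective is quadratic in the new loading columns and the exact
#' minimizer is the ridge solution
#' `b_n = A_B^-1 sum_x c_x U' Cw_x' y_x,n` (equivalently one exact
#' [update_B()] step started from zero).
#'
#' @param object A `pathfact_fit` or [factor_model()].
#' @param new_data A `modality_data` or list of them, using the same masks
#'   and marker order as the fitted model (matched by label).
#' @return A k x n_test loading matrix.
#' @export
infer_loadings <- function(object, new_data) {
  model <- if (inherits(object, "pathfact_fit")) object$model else object
  stopifnot(inherits(model, "factor_model"))
  if (inherits(new_data, "modality_data")) new_data <- list(new_data)
  names(new_data) <- vapply(new_data, `[[`, character(1L), "label")
  k <- ncol(model$U)
  n_test <- ncol(new_data[[1L]]$Y)
  rhs <- matrix(0, k, n_test)
  A_B <- diag(model$delta, k, k)
  for (md_new in new_data) {
    md_fit <- model$modalities[[md_new$label]]
    if (is.null(md_fit)) stop("unknown modality label: ", md_new$label)
    if (!identical(md_new$mask$marker_ids, md_fit$mask$marker_ids)) {
      stop("marker mismatch with the fitted model for modality '",
           md_new$label, "'")
    }
    md <- md_fit
    md$Y <- md_new$Y
    Cw <- .mask_weighted(md)
    S <- crossprod(Cw, md$mask$matrix)
    A_B <- A_B + md$scale^2 * crossprod(model$U, S %*% model$U)
    rhs <- rhs + md$scale * crossprod(model$U, crossprod(Cw, md$Y))
  }
  B_test <- .chol_solve((A_B + t(A_B)) / 2, rhs, "A_B")
  rownames(B_test) <- colnames(model$U)
  colnames(B_test) <- colnames(new_data[[1L]]$Y)
  B_test
}
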