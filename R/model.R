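# Probabilistic model: a shared non-negative pathway-to-latent weight
# matrix U (p x k) and per-sample loadings B (k x n) reconstruct each
# modality x as  Y_x ~ N(c_x * C_x U B, diag(sigma_x^2))  entrywise, where
# C_x is the binary pathway mask, sigma_x the per-marker noise standard
# deviations and c_x a modality scale factor. Entrywise Gaussian ARD
# priors with precisions Lambda (p x k) act on U and per-latent
# precisions delta on the rows of B.

#' Bundle one modality's observations with its mask and noise model
#'
#' @param Y Numeric matrix (markers x samples) or `NULL` for a fitted
#'   model stored without its training data. Row names, when present,
#'   must equal the mask's `marker_ids`.
#' @param mask A `pathway_mask` from [build_mask()].
#' @param sigma Positive per-marker noise standard deviations (default all
#'   ones, the fitting initialization).
#' @param scale Scalar modality factor multiplying the reconstruction;
#'   absorbs normalization inconsistencies between modalities.
#' @param label Short modality name, e.g. `"rna"` or `"prot"`.
#' @return An object of class `modality_data`.
#' @export
modality_data <- function(Y, mask, sigma = NULL, scale = 1, label = "modality") {
  stopifnot(inherits(mask, "pathway_mask"))
  m <- nrow(mask$matrix)
  if (!is.null(Y)) {
    stopifnot(is.matrix(Y), is.numeric(Y))
    if (nrow(Y) != m) stop("Y has ", nrow(Y), " rows but mask covers ", m, " markers")
    if (!is.null(rownames(Y)) && !identical(rownames(Y), mask$marker_ids)) {
      stop("Y row names do not match mask marker_ids (modality '", label, "')")
    }
    if (is.null(rownames(Y))) rownames(Y) <- mask$marker_ids
  }
  if (is.null(sigma)) sigma <- rep(1, m)
  stopifnot(is.numeric(sigma), length(sigma) == m)
  if (any(sigma <= 0) || anyNA(sigma)) stop("sigma must be strictly positive")
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale))
  structure(list(Y = Y, mask = mask, sigma = as.numeric(sigma),
                 scale = as.numeric(scale), label = as.character(label)),
            class = "modality_data")
}

#' @export
print.modality_data <- function(x, ...) {
  cat(sprintf("modality_data '%s': %d markers x %s samples, %d pathways, scale %.3g\n",
              x$label, nrow(x$mask$matrix),
              if (is.null(x$Y)) "?" else ncol(x$Y),
              ncol(x$mask$matrix), x$scale))
  invisible(x)
}

#' Construct a factor model state
#'
#' @param U Non-negative p x k pathway-to-latent weight matrix.
#' @param B k x n loading matrix (per-sample latent coordinates).
#' @param Lambda Positive p x k matrix of ARD prior precisions on U.
#' @param delta Positive length-k vector of prior precisions on the rows
#'   of B.
#' @param modalities A `modality_data` or list thereof; all must share the
#'   same pathway names and sample count.
#' @return An object of class `factor_model`.
#' @export
factor_model <- function(U, B, Lambda, delta, modalities) {
  if (inherits(modalities, "modality_data")) modalities <- list(modalities)
  stopifnot(length(modalities) >= 1L)
  lapply(modalities, function(md) stopifnot(inherits(md, "modality_data")))
  p <- nrow(U); k <- ncol(U); n <- ncol(B)
  stopifnot(is.matrix(U), is.matrix(B), nrow(B) == k,
            is.matrix(Lambda), nrow(Lambda) == p, ncol(Lambda) == k,
            length(delta) == k)
  if (any(U < 0)) stop("U must be non-negative")
  if (any(Lambda <= 0) || any(delta <= 0)) stop("Lambda and delta must be positive")
  pn <- modalities[[1L]]$mask$pathway_names
  for (md in modalities) {
    if (!identical(md$mask$pathway_names, pn)) {
      stop("all modalities must cover the same pathways in the same order")
    }
    if (ncol(md$mask$matrix) != p) stop("mask pathway count does not match U")
    if (!is.null(md$Y) && ncol(md$Y) != n) {
      stop("modality '", md$label, "' has ", ncol(md$Y),
           " samples but B has ", n)
    }
  }
  names(modalities) <- vapply(modalities, `[[`, character(1L), "label")
  structure(list(U = U, B = B, Lambda = Lambda, delta = as.numeric(delta),
                 modalities = modalities),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d pathways, %d latents, %d samples, %d modalit%s (%s)\n",
              nrow(x$U), ncol(x$U), ncol(x$B), length(x$modalities),
              if (length(x$modalities) == 1L) "y" else "ies",
              paste(names(x$modalities), collapse = ", ")))
  invisible(x)
}

# modality reconstruction c_x * C_x U B
.recon <- function(md, U, B) {
  md$scale * ((md$mask$matrix %*% U) %*% B)
}

# row-weighted mask Cw = diag(sigma^-2) C
.mask_weighted <- function(md) {
  md$mask$matrix * (1 / md$sigma^2)
}

#' Gaussian data log-likelihood of one modality
#'
#' Sum over all entries of `log N(Y[m, n]; scale * (C U B)[m, n],
#' sigma[m]^2)`, including normalization constants.
#'
#' @param modality A `modality_data` with observations.
#' @param U,B Parameter matrices.
#' @return Scalar log-likelihood.
#' @export
data_loglik <- function(modality, U, B) {
  stopifnot(inherits(modality, "modality_data"), !is.null(modality$Y))
  if (any(modality$sigma <= 0)) stop("sigma must be strictly positive")
  R <- modality$Y - .recon(modality, U, B)
  n <- ncol(modality$Y)
  w <- 1 / modality$sigma^2
  -0.5 * sum(w * rowSums(R^2)) - 0.5 * n * sum(log(2 * pi * modality$sigma^2))
}

#' Negative log joint density of parameters and observations
#'
#' The MAP objective: minus the sum of the per-modality data
#' log-likelihoods and of the Gaussian ARD log-priors on U and B (all
#' normalization constants included).
#'
#' @param model A [factor_model()].
#' @return Scalar objective value.
#' @export
neg_log_joint <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  ll <- sum(vapply(model$modalities, data_loglik, numeric(1L),
                   U = model$U, B = model$B))
  p <- nrow(model$U); k <- ncol(model$U); n <- ncol(model$B)
  lp_U <- 0.5 * sum(log(model$Lambda)) - 0.5 * p * k * log(2 * pi) -
    0.5 * sum(model$Lambda * model$U^2)
  lp_B <- 0.5 * n * sum(log(model$delta)) - 0.5 * k * n * log(2 * pi) -
    0.5 * sum(model$delta * rowSums(model$B^2))
  -(ll + lp_U + lp_B)
}

#' Analytic gradients of the MAP objective
#'
#' Returns the gradients of [neg_log_joint()] with respect to U and B,
#' summing the data terms over modalities:
#' `G_U = sum_x -c_x Cw_x' R_x B' + Lambda o U` and
#' `G_B = sum_x -c_x U' Cw_x' R_x + delta o B`, with residual
#' `R_x = Y_x - c_x C_x U B` and `Cw_x = diag(sigma_x^-2) C_x`.
#'
#' @param model A [factor_model()].
#' @return List with elements `G_U` (p x k) and `G_B` (k x n).
#' @export
model_gradients <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  U <- model$U; B <- model$B
  G_U <- model$Lambda * U
  G_B <- B * model$delta
  for (md in model$modalities) {
    R <- md$Y - .recon(md, U, B)
    CwR <- crossprod(.mask_weighted(md), R)            # p x n
    G_U <- G_U - md$scale * tcrossprod(CwR, B)         # p x k
    G_B <- G_B - md$scale * crossprod(U, CwR)          # k x n
  }
  list(G_U = G_U, G_B = G_B)
}

# per-session counter of Hessian evaluations, used to verify that the fit
# loop shares each Hessian between the Newton and hyperparameter updates
.hessian_counter <- new.env(parent = emptyenv())
.hessian_counter$U <- 0L
.hessian_counter$B <- 0L

#' Count or reset Hessian evaluations
#'
#' The evidence-based hyperparameter updates reuse the Hessian factors
#' already computed for the Newton steps; these helpers expose the
#' internal evaluation counter so that this sharing can be asserted.
#'
#' @return `hessian_eval_counts()` returns a named integer vector with
#'   components `U` and `B`.
#' @export
hessian_eval_counts <- function() {
  c(U = .hessian_counter$U, B = .hessian_counter$B)
}

#' @rdname hessian_eval_counts
#' @export
reset_hessian_eval_counts <- function() {
  .hessian_counter$U <- 0L
  .hessian_counter$B <- 0L
  invisible(NULL)
}

#' Hessian factors of the MAP objective
#'
#' Computes the (block-diagonal) Hessian of [neg_log_joint()]:
#' the k x k Kronecker factor `A_B = sum_x c_x^2 U' Cw_x' C_x U +
#' diag(delta)` of the B-Hessian `A_B (x) I_n`, and the pk x pk U-Hessian
#' `H_U = sum_x c_x^2 (B B') (x) (Cw_x' C_x) + diag(vec(Lambda))` under
#' the column-stacking vec convention `c(U)`. With `diagonal_U = TRUE`
#' only the diagonal of `H_U` is formed (vector of length pk), the cheap
#' approximation for large p*k.
#'
#' @param model A [factor_model()].
#' @param diagonal_U Logical; form only the diagonal of the U-Hessian.
#' @param components Which factors to compute (`"U"`, `"B"` or both).
#' @return Object of class `hessian_pair` with elements `H_U`, `A_B`
#'   (either may be `NULL` if not requested) and `diagonal_U`.
#' @export
model_hessians <- function(model, diagonal_U = FALSE,
                           components = c("U", "B")) {
  stopifnot(inherits(model, "factor_model"))
  components <- match.arg(components, several.ok = TRUE)
  U <- model$U; B <- model$B
  k <- ncol(U)
  H_U <- NULL; A_B <- NULL
  want_U <- "U" %in% components
  want_B <- "B" %in% components
  BBt <- if (want_U) tcrossprod(B) else NULL
  if (want_B) A_B <- diag(model$delta, k, k)
  if (want_U) {
    pk <- length(model$Lambda)
    H_U <- if (diagonal_U) as.numeric(model$Lambda) else
      diag(as.numeric(model$Lambda), pk, pk)
  }
  for (md in model$modalities) {
    Cw <- .mask_weighted(md)
    S <- crossprod(Cw, md$mask$matrix)                 # p x p, symmetric
    S <- (S + t(S)) / 2
    c2 <- md$scale^2
    if (want_B) A_B <- A_B + c2 * crossprod(U, S %*% U)
    if (want_U) {
      if (diagonal_U) {
        H_U <- H_U + c2 * as.numeric(outer(diag(S), diag(BBt)))
      } else {
        H_U <- H_U + c2 * kronecker(BBt, S)
      }
    }
  }
  if (want_B) {
    A_B <- (A_B + t(A_B)) / 2
    .hessian_counter$B <- .hessian_counter$B + 1L
  }
  if (want_U) .hessian_counter$U <- .hessian_counter$U + 1L
  structure(list(H_U = H_U, A_B = A_B, diagonal_U = diagonal_U,
                 cache = new.env(parent = emptyenv())),
            class = "hessian_pair")
}

# memoized Cholesky factor of a hessian_pair component, so the Newton
# step, the hyperparameter updates and the evidence share one
# factorization per iteration
.hp_chol <- function(hessians, comp) {
  cache <- hessians$cache
  key <- paste0("chol_", comp)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  R <- .chol_pd(hessians[[comp]], comp)
  if (!is.null(cache)) assign(key, R, envir = cache)
  R
}

# Cholesky-based linear solve: tolerates the severe ill-conditioning that
# arises when ARD precisions approach their clamping bound, while still
# erroring on genuinely non-positive-definite factors
.chol_solve <- function(M, b, what) {
  R <- .chol_pd(M, what)
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

# Cholesky with a clear error for non-positive-definite factors
.chol_pd <- function(M, what) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(out)) {
    stop("Hessian factor ", what, " is singular or not positive definite")
  }
  out
}

#' Laplace approximation to the log-evidence of the hyperparameters
#'
#' Approximates the marginal likelihood of the hyperparameters (noise,
#' ARD precisions, scales) at the MAP point: the log joint minus half the
#' log-determinants of the scaled Hessian blocks,
#' `log p(Y, U*, B*) - 1/2 log|H_U / 2pi| - 1/2 log|H_B / 2pi|`, using the
#' Kronecker identity `log|A_B (x) I_n| = n log|A_B|` for the B block.
#'
#' @param model A [factor_model()] at (or near) its MAP point.
#' @param hessians A `hessian_pair` from [model_hessians()] with both
#'   components.
#' @return Scalar approximate log-evidence.
#' @export
log_evidence <- function(model, hessians = model_hessians(model)) {
  stopifnot(inherits(model, "factor_model"), inherits(hessians, "hessian_pair"))
  p <- nrow(model$U); k <- ncol(model$U); n <- ncol(model$B)
  if (hessians$diagonal_U) {
    if (any(hessians$H_U <= 0)) {
      stop("Hessian factor H_U is not positive definite (model not at a proper MAP point)")
    }
    ld_U <- sum(log(hessians$H_U))
  } else {
    ld_U <- 2 * sum(log(diag(.hp_chol(hessians, "H_U"))))
  }
  ld_B <- n * 2 * sum(log(diag(.hp_chol(hessians, "A_B"))))
  log_joint <- -neg_log_joint(model)
  log_joint - 0.5 * (ld_U - p * k * log(2 * pi)) -
    0.5 * (ld_B - k * n * log(2 * pi))
}
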