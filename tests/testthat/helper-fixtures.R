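# Shared fixtures: random model instances built in code, plus scalar-loop
# oracles kept deliberately independent of the vectorized implementation.

make_modality <- function(m, p, k, n, label = "rna", scale = 1,
                          sigma = NULL, density = 0.3) {
  ids <- sprintf("%s_m%03d", label, seq_len(m))
  C <- matrix(rbinom(m * p, 1, density), m, p,
              dimnames = list(ids, sprintf("pw%02d", seq_len(p))))
  mask <- structure(list(matrix = C, marker_ids = ids,
                         pathway_names = colnames(C)),
                    class = "pathway_mask")
  Y <- matrix(rnorm(m * n), m, n,
              dimnames = list(ids, sprintf("s%02d", seq_len(n))))
  if (is.null(sigma)) sigma <- runif(m, 0.5, 2)
  modality_data(Y, mask, sigma = sigma, scale = scale, label = label)
}

# random model instance; bimodal adds a proteomics-like second view with a
# different scale factor
make_random_model <- function(seed, bimodal = FALSE, m = 25, m2 = 18,
                              p = 6, k = 3, n = 8, unit_noise = FALSE) {
  set.seed(seed)
  sig1 <- if (unit_noise) rep(1, m) else NULL
  mods <- list(rna = make_modality(m, p, k, n, "rna", scale = 0.8,
                                   sigma = sig1))
  if (bimodal) {
    sig2 <- if (unit_noise) rep(1, m2) else NULL
    mods$prot <- make_modality(m2, p, k, n, "prot", scale = 1.3,
                               sigma = sig2)
  }
  U <- matrix(abs(rnorm(p * k)), p, k)
  B <- matrix(rnorm(k * n), k, n)
  Lambda <- matrix(runif(p * k, 0.5, 2), p, k)
  delta <- runif(k, 0.5, 2)
  factor_model(U, B, Lambda, delta, mods)
}

# scalar-loop oracle for the per-modality Gaussian log-likelihood
loop_loglik <- function(md, U, B) {
  C <- md$mask$matrix
  total <- 0
  for (i in seq_len(nrow(md$Y))) {
    for (j in seq_len(ncol(md$Y))) {
      mu <- md$scale * sum(C[i, ] * (U %*% B[, j]))
      total <- total + dnorm(md$Y[i, j], mu, md$sigma[i], log = TRUE)
    }
  }
  total
}

# scalar-loop oracle for the full negative log joint
loop_neg_log_joint <- function(model) {
  ll <- sum(vapply(model$modalities, loop_loglik, numeric(1),
                   U = model$U, B = model$B))
  lp <- 0
  for (i in seq_len(nrow(model$U))) {
    for (j in seq_len(ncol(model$U))) {
      lp <- lp + dnorm(model$U[i, j], 0, 1 / sqrt(model$Lambda[i, j]), log = TRUE)
    }
  }
  for (i in seq_len(nrow(model$B))) {
    for (j in seq_len(ncol(model$B))) {
      lp <- lp + dnorm(model$B[i, j], 0, 1 / sqrt(model$delta[i]), log = TRUE)
    }
  }
  -(ll + lp)
}

# write a small GMT file from a named list of member vectors
write_gmt_lines <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  path
}

# downscaled benchmark configuration shared by the longer-running
# acceptance checks
small_bench_config <- function(n, seed) {
  sim_config(n = n, n_markers = 800, markers_per_pathway = 80, seed = seed)
}
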