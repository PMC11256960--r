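# Held-out evaluation protocol and downstream association statistics on
# pathway activities.

#' Held-out reconstruction log-likelihood per modality
#'
#' Evaluates, for each modality, the entrywise Gaussian log-density of the
#' held-out observations under the model's reconstruction
#' `scale * C U B_test` with the model's per-marker noise. Passing the
#' ground-truth model with noise-free observations gives the protocol's
#' upper-bound reference.
#'
#' @param model A [factor_model()] (fitted or ground truth).
#' @param test_data A `modality_data` or list of them holding the held-out
#'   observation columns.
#' @param B_test Loadings for the held-out samples, typically from
#'   [infer_loadings()].
#' @return Named numeric vector, one log-likelihood per modality.
#' @export
reconstruction_loglik <- function(model, test_data, B_test) {
  stopifnot(inherits(model, "factor_model"))
  if (inherits(test_data, "modality_data")) test_data <- list(test_data)
  if (ncol(B_test) != ncol(test_data[[1L]]$Y)) {
    stop("B_test has ", ncol(B_test), " columns but test data has ",
         ncol(test_data[[1L]]$Y), " samples")
  }
  out <- vapply(test_data, function(md_new) {
    md <- model$modalities[[md_new$label]]
    if (is.null(md)) stop("unknown modality label: ", md_new$label)
    md$Y <- md_new$Y
    data_loglik(md, model$U, B_test)
  }, numeric(1L))
  names(out) <- vapply(test_data, `[[`, character(1L), "label")
  out
}

#' Mean absolute error between fitted and true marker noises
#'
#' @param sigma_hat,sigma_true Positive numeric vectors of equal length.
#' @return Mean over markers of `|sigma_hat - sigma_true|`.
#' @export
noise_mae <- function(sigma_hat, sigma_true) {
  if (length(sigma_hat) != length(sigma_true)) {
    stop("sigma vectors differ in length (", length(sigma_hat), " vs ",
         length(sigma_true), ")")
  }
  mean(abs(sigma_hat - sigma_true))
}

#' Project loadings into pathway activities
#'
#' The interpretable per-sample representation: `P = U B`, the abundance
#' of each pathway in each sample.
#'
#' @param model A [factor_model()] or `pathfact_fit`.
#' @param B Loading matrix (defaults to the model's own loadings).
#' @return Object of class `pathway_activities`: list with `P` (p x n),
#'   `pathway_names` and `sample_ids`.
#' @export
pathway_activities <- function(model, B = NULL) {
  if (inherits(model, "pathfact_fit")) model <- model$model
  stopifnot(inherits(model, "factor_model"))
  if (is.null(B)) B <- model$B
  stopifnot(ncol(model$U) == nrow(B))
  P <- model$U %*% B
  structure(list(P = P,
                 pathway_names = rownames(model$U),
                 sample_ids = colnames(B)),
            class = "pathway_activities")
}

#' @export
print.pathway_activities <- function(x, ...) {
  cat(sprintf("pathway_activities: %d pathways x %d samples\n",
              nrow(x$P), ncol(x$P)))
  invisible(x)
}

#' Correlate pathway activities with a continuous covariate
#'
#' Pearson correlation of each pathway's activity across samples with a
#' continuous covariate (e.g. a tumor heterogeneity score), with the
#' two-sided p-value from the t-transform on n - 2 degrees of freedom.
#' Constant pathway rows get correlation 0, a missing p-value and a
#' `constant` flag.
#'
#' @param activities A [pathway_activities()] object.
#' @param covariate Numeric vector, one value per sample; must not be
#'   constant.
#' @param adjust `"none"` (default; raw p-values) or `"BH"` to add a
#'   Benjamini-Hochberg adjusted column.
#' @return Data frame with columns `pathway`, `correlation`, `p_value`,
#'   `constant` (and `p_adjusted` if requested), ordered by decreasing
#'   absolute correlation.
#' @export
associate_continuous <- function(activities, covariate,
                                 adjust = c("none", "BH")) {
  stopifnot(inherits(activities, "pathway_activities"))
  adjust <- match.arg(adjust)
  n <- ncol(activities$P)
  if (length(covariate) != n) stop("covariate length must equal sample count")
  if (n < 3L) stop("need at least 3 samples")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  res <- apply(activities$P, 1L, function(row) {
    if (stats::sd(row) == 0) return(c(0, NA_real_, 1))
    ct <- stats::cor.test(row, covariate, method = "pearson")
    c(unname(ct$estimate), ct$p.value, 0)
  })
  out <- data.frame(pathway = activities$pathway_names,
                    correlation = res[1L, ],
                    p_value = res[2L, ],
                    constant = res[3L, ] == 1,
                    row.names = NULL)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out[order(-abs(out$correlation)), , drop = FALSE]
}

#' Test pathway activities against a binary outcome label
#'
#' Welch two-sample t-test of each pathway's activity between the two
#' label groups (e.g. survival beyond a landmark time). The statistic's
#' sign is the group-with-label-1 mean minus the group-with-label-0 mean.
#'
#' @param activities A [pathway_activities()] object.
#' @param labels Binary vector (logical, 0/1, or two-level factor), one
#'   per sample; both groups need at least two members.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with columns `pathway`, `t_statistic`, `p_value`
#'   (and `p_adjusted` if requested), ordered by decreasing absolute
#'   statistic.
#' @export
associate_binary <- function(activities, labels, adjust = c("none", "BH")) {
  stopifnot(inherits(activities, "pathway_activities"))
  adjust <- match.arg(adjust)
  n <- ncol(activities$P)
  if (length(labels) != n) stop("labels length must equal sample count")
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels > 0)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop("each label group needs at least 2 members")
  }
  res <- apply(activities$P, 1L, function(row) {
    tt <- stats::t.test(row[labels == 1L], row[labels == 0L],
                        var.equal = FALSE)
    c(unname(tt$statistic), tt$p.value)
  })
  out <- data.frame(pathway = activities$pathway_names,
                    t_statistic = res[1L, ],
                    p_value = res[2L, ],
                    row.names = NULL)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out[order(-abs(out$t_statistic)), , drop = FALSE]
}

#' Write an association table to TSV
#'
#' @param table A data frame from [associate_continuous()] or
#'   [associate_binary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_association <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
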