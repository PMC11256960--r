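# Synthetic benchmark: ground-truth pathway structure mirroring a
# Hallmark-like collection (50 pathways grouped into 8 process
# categories), sample loadings from a Gaussian mixture of clusters, and
# heteroscedastic marker-level observation noise whose modality means and
# spreads follow the summary statistics observed on real tumor cohorts
# (mean noise 0.95 for RNA, 0.98 for proteomics, with a wider marker-level
# spread for RNA).

#' Configuration of the synthetic benchmark generator
#'
#' @param p Number of pathways (default 50).
#' @param k_true Number of ground-truth process categories / latent
#'   variables (default 8).
#' @param n Number of samples.
#' @param n_markers Size of the RNA marker universe (default 2000).
#' @param markers_per_pathway Markers drawn per pathway, overlaps across
#'   pathways allowed (default 200, approximating Hallmark set sizes).
#' @param prot_fraction Fraction of the RNA marker universe measured by
#'   the proteomics modality (default 0.25, approximating the ~4.6k
#'   proteins vs ~19.6k genes coverage ratio of matched assays).
#' @param n_clusters Number of sample clusters in the loading mixture
#'   (default 3).
#' @param within_cluster_sd Isotropic standard deviation of loadings
#'   around their cluster mean (default 1).
#' @param cluster_mean_sd Standard deviation of the cluster means
#'   (default 2, larger than `within_cluster_sd`).
#' @param noise_mean Named vector: mean marker noise per modality
#'   (defaults `rna = 0.95`, `prot = 0.98`).
#' @param noise_spread Named vector: marker-level standard deviation of
#'   the noise per modality (defaults `rna = 0.25`, `prot = 0.10`;
#'   proteomics narrower than RNA).
#' @param scales Named vector of true modality scale factors (default 1).
#' @param weighted_membership If `TRUE`, scale the binary ground-truth
#'   pathway-category memberships by positive log-normal draws for harder
#'   recovery tests.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(p = 50L, k_true = 8L, n = 100L, n_markers = 2000L,
                       markers_per_pathway = 200L, prot_fraction = 0.25,
                       n_clusters = 3L, within_cluster_sd = 1,
                       cluster_mean_sd = 2,
                       noise_mean = c(rna = 0.95, prot = 0.98),
                       noise_spread = c(rna = 0.25, prot = 0.10),
                       scales = c(rna = 1, prot = 1),
                       weighted_membership = FALSE, seed = 1L) {
  p <- as.integer(p); k_true <- as.integer(k_true); n <- as.integer(n)
  if (p < k_true) stop("need p >= k_true")
  if (n < 1L || k_true < 1L) stop("n and k_true must be positive")
  if (markers_per_pathway > n_markers) {
    stop("markers_per_pathway cannot exceed n_markers")
  }
  if (!(prot_fraction > 0 && prot_fraction <= 1)) {
    stop("prot_fraction must be in (0, 1]")
  }
  if (within_cluster_sd <= 0 || cluster_mean_sd < 0) {
    stop("cluster standard deviations must be positive (mean sd >= 0)")
  }
  if (any(noise_mean <= 0) || any(noise_spread < 0)) {
    stop("noise means must be positive and spreads >= 0")
  }
  structure(list(p = p, k_true = k_true, n = n,
                 n_markers = as.integer(n_markers),
                 markers_per_pathway = as.integer(markers_per_pathway),
                 prot_fraction = prot_fraction,
                 n_clusters = as.integer(n_clusters),
                 within_cluster_sd = within_cluster_sd,
                 cluster_mean_sd = cluster_mean_sd,
                 noise_mean = noise_mean, noise_spread = noise_spread,
                 scales = scales,
                 weighted_membership = isTRUE(weighted_membership),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# log-normal draws moment-matched to a given mean and standard deviation
.rlnorm_moment <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Draw the ground truth of the synthetic benchmark
#'
#' Generates: pathway-to-category assignments (round-robin over the
#' categories, then shuffled) defining the binary ground-truth weight
#' matrix `U_true`; RNA pathway membership by drawing
#' `markers_per_pathway` markers per pathway from the marker universe
#' (overlaps allowed); a proteomics mask obtained by restricting the RNA
#' mask to a global subsample of the marker universe (relabelled to
#' protein identifiers via a generated mapping table); clustered loadings
#' `B_true` from a Gaussian mixture; and per-marker noise standard
#' deviations from a log-normal law moment-matched to the configured
#' modality mean and spread.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_truth` with fields `U_true`,
#'   `B_true`, `cluster_labels` (0-based), `category_labels` (0-based),
#'   `sigma_true` (named list per modality), `masks` (named list of
#'   `pathway_mask`), `scales`, `mapping` (gene-to-protein table),
#'   `genesets` (the RNA [geneset_collection()]) and `config`.
#' @export
simulate_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$p; k <- config$k_true; n <- config$n

  category_labels <- sample(rep_len(seq_len(k) - 1L, p))
  U_true <- matrix(0, p, k,
                   dimnames = list(sprintf("pathway_%02d", seq_len(p)),
                                   sprintf("category_%d", seq_len(k) - 1L)))
  U_true[cbind(seq_len(p), category_labels + 1L)] <- 1
  if (config$weighted_membership) {
    U_true[U_true > 0] <- stats::rlnorm(p, 0, 0.25)
  }

  gene_ids <- sprintf("gene_%05d", seq_len(config$n_markers))
  sets <- lapply(seq_len(p), function(j) {
    list(name = rownames(U_true)[j], description = "synthetic",
         members = sample(gene_ids, config$markers_per_pathway))
  })
  genesets <- geneset_collection(sets)
  mask_rna <- build_mask(genesets, gene_ids)

  m_prot <- max(1L, round(config$prot_fraction * config$n_markers))
  sel <- sort(sample(config$n_markers, m_prot))
  prot_ids <- sprintf("prot_%05d", seq_len(m_prot))
  mapping <- data.frame(source = gene_ids[sel], target = prot_ids,
                        stringsAsFactors = FALSE)
  M_prot <- mask_rna$matrix[sel, , drop = FALSE]
  rownames(M_prot) <- prot_ids
  mask_prot <- structure(list(matrix = M_prot, marker_ids = prot_ids,
                              pathway_names = mask_rna$pathway_names),
                         class = "pathway_mask")

  cluster_labels <- sample(seq_len(config$n_clusters), n, replace = TRUE) - 1L
  centers <- matrix(stats::rnorm(k * config$n_clusters,
                                 sd = config$cluster_mean_sd),
                    k, config$n_clusters)
  B_true <- centers[, cluster_labels + 1L, drop = FALSE] +
    matrix(stats::rnorm(k * n, sd = config$within_cluster_sd), k, n)
  dimnames(B_true) <- list(colnames(U_true), sprintf("sample_%03d", seq_len(n)))

  sigma_true <- list(
    rna = .rlnorm_moment(config$n_markers, config$noise_mean[["rna"]],
                         config$noise_spread[["rna"]]),
    prot = .rlnorm_moment(m_prot, config$noise_mean[["prot"]],
                          config$noise_spread[["prot"]])
  )
  names(sigma_true$rna) <- gene_ids
  names(sigma_true$prot) <- prot_ids

  structure(list(U_true = U_true, B_true = B_true,
                 cluster_labels = cluster_labels,
                 category_labels = category_labels,
                 sigma_true = sigma_true,
                 masks = list(rna = mask_rna, prot = mask_prot),
                 scales = config$scales,
                 mapping = mapping, genesets = genesets, config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d pathways in %d categories, %d samples, ",
                     "%d RNA / %d protein markers\n"),
              nrow(x$U_true), ncol(x$U_true), ncol(x$B_true),
              length(x$sigma_true$rna), length(x$sigma_true$prot)))
  invisible(x)
}

#' Sample noisy observations from a synthetic ground truth
#'
#' Per modality, draws `Y = scale * C U_true B_true + E` with independent
#' heteroscedastic entries `E[m, n] ~ N(0, sigma_true[m]^2)`. The returned
#' `modality_data` objects have their `sigma` fields initialized to ones
#' (the fitting start), the truth staying available separately.
#'
#' @param truth A [simulate_truth()] result.
#' @param seed Seed for the observation noise (default derived from the
#'   truth's seed so that truth and data draws come from distinct
#'   streams).
#' @return Named list of `modality_data` (`rna`, `prot`).
#' @export
simulate_dataset <- function(truth, seed = truth$config$seed + 1000003L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  out <- lapply(names(truth$masks), function(lab) {
    mask <- truth$masks[[lab]]
    sig <- truth$sigma_true[[lab]]
    mu <- truth$scales[[lab]] * ((mask$matrix %*% truth$U_true) %*% truth$B_true)
    E <- matrix(stats::rnorm(length(mu), sd = sig), nrow(mu), ncol(mu))
    Y <- mu + E
    colnames(Y) <- colnames(truth$B_true)
    modality_data(Y, mask, label = lab)
  })
  names(out) <- names(truth$masks)
  out
}

#' Generate a complete synthetic benchmark instance
#'
#' Convenience wrapper drawing both the ground truth and one noisy
#' observation set from it.
#'
#' @param config A [sim_config()].
#' @return List with elements `data` (list of `modality_data`) and
#'   `truth` (the `synthetic_truth`).
#' @export
simulate_benchmark <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  list(data = simulate_dataset(truth), truth = truth)
}

#' Split modalities into train and test sample sets
#'
#' Splits every modality on the same sample columns, keeping masks,
#' noise and scales identical across the two parts.
#'
#' @param data List of `modality_data` sharing their sample columns.
#' @param train_idx Integer indices of the training samples.
#' @return List with elements `train` and `test`, each a list of
#'   `modality_data`.
#' @export
split_samples <- function(data, train_idx) {
  if (inherits(data, "modality_data")) data <- list(data)
  n <- ncol(data[[1L]]$Y)
  train_idx <- sort(unique(as.integer(train_idx)))
  stopifnot(all(train_idx >= 1L), all(train_idx <= n))
  test_idx <- setdiff(seq_len(n), train_idx)
  take <- function(md, idx) {
    md$Y <- md$Y[, idx, drop = FALSE]
    md
  }
  list(train = lapply(data, take, idx = train_idx),
       test = lapply(data, take, idx = test_idx))
}

#' Write a synthetic benchmark instance to disk
#'
#' Writes the observation matrices as TSV, the RNA gene sets as GMT, the
#' gene-to-protein mapping as a two-column TSV, and the ground truth
#' (weights, loadings, noise, labels) under a `truth/` subdirectory, so
#' the full pipeline can be exercised from files.
#'
#' @param bench A [simulate_benchmark()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(bench, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  truth <- bench$truth
  for (lab in names(bench$data)) {
    write_expression_matrix(bench$data[[lab]]$Y,
                            file.path(dir, paste0(lab, ".tsv")))
  }
  write_gmt(truth$genesets, file.path(dir, "genesets_rna.gmt"))
  utils::write.table(truth$mapping, file.path(dir, "mapping.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_expression_matrix(truth$U_true, file.path(dir, "truth", "U_true.tsv"))
  write_expression_matrix(truth$B_true, file.path(dir, "truth", "B_true.tsv"))
  for (lab in names(truth$sigma_true)) {
    utils::write.table(
      data.frame(marker = names(truth$sigma_true[[lab]]),
                 sigma = truth$sigma_true[[lab]]),
      file.path(dir, "truth", paste0("sigma_true_", lab, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(sample = colnames(truth$B_true), cluster = truth$cluster_labels),
    file.path(dir, "truth", "cluster_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(pathway = rownames(truth$U_true),
               category = truth$category_labels),
    file.path(dir, "truth", "category_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
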