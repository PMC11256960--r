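# Serialization of fitted models as a directory of plain-text TSV
# matrices plus a JSON run report, so fits can be archived, inspected and
# reused for held-out inference without binary files.

#' Write a fitted model to a directory of TSV files
#'
#' Writes `U.tsv` (pathways x latents), `B.tsv` (latents x samples),
#' `Lambda.tsv`, `delta.tsv`, `scales.tsv`, and per modality
#' `sigma_<label>.tsv` and `mask_<label>.tsv`, plus `report.json` with
#' the fitting traces and configuration echo.
#'
#' @param fit A `pathfact_fit` from [pathfact()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pathfact <- function(fit, dir) {
  stopifnot(inherits(fit, "pathfact_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- fit$model
  write_expression_matrix(model$U, file.path(dir, "U.tsv"))
  write_expression_matrix(model$B, file.path(dir, "B.tsv"))
  write_expression_matrix(model$Lambda, file.path(dir, "Lambda.tsv"))
  utils::write.table(data.frame(latent = colnames(model$U),
                                delta = model$delta),
                     file.path(dir, "delta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(modality = names(model$modalities),
               scale = vapply(model$modalities, `[[`, numeric(1L), "scale")),
    file.path(dir, "scales.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (md in model$modalities) {
    utils::write.table(data.frame(marker = md$mask$marker_ids,
                                  sigma = md$sigma),
                       file.path(dir, paste0("sigma_", md$label, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_expression_matrix(md$mask$matrix,
                            file.path(dir, paste0("mask_", md$label, ".tsv")))
  }
  jsonlite::write_json(fit$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a fitted model back from a directory
#'
#' Reconstructs the [factor_model()] (masks, noise, scales; observation
#' matrices are not stored) and the fit report written by
#' [write_pathfact()]. The result supports [infer_loadings()],
#' [pathway_activities()] and the association statistics.
#'
#' @param dir Directory written by [write_pathfact()].
#' @return A `pathfact_fit` whose modalities carry `Y = NULL`.
#' @export
read_pathfact <- function(dir) {
  U <- read_expression_matrix(file.path(dir, "U.tsv"))
  B <- read_expression_matrix(file.path(dir, "B.tsv"))
  Lambda <- read_expression_matrix(file.path(dir, "Lambda.tsv"))
  delta_df <- utils::read.delim(file.path(dir, "delta.tsv"))
  scales_df <- utils::read.delim(file.path(dir, "scales.tsv"))
  modalities <- lapply(seq_len(nrow(scales_df)), function(i) {
    lab <- scales_df$modality[i]
    M <- read_expression_matrix(file.path(dir, paste0("mask_", lab, ".tsv")))
    mask <- structure(list(matrix = M, marker_ids = rownames(M),
                           pathway_names = colnames(M)),
                      class = "pathway_mask")
    sig <- utils::read.delim(file.path(dir, paste0("sigma_", lab, ".tsv")))
    modality_data(NULL, mask, sigma = sig$sigma, scale = scales_df$scale[i],
                  label = lab)
  })
  report <- jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE)
  model <- factor_model(U, B, Lambda, delta_df$delta, modalities)
  structure(list(model = model, report = report), class = "pathfact_fit")
}
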