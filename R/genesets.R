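#' Construct a gene-set collection
#'
#' A gene-set collection is an ordered list of named marker sets (gene or
#' protein identifiers), the prior-knowledge input of the factor model.
#' Membership is binary and deduplicated; set names must be unique.
#'
#' @param sets A list whose elements are lists with fields `name`
#'   (string), `description` (string) and `members` (character vector).
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets = list()) {
  stopifnot(is.list(sets))
  sets <- lapply(sets, function(s) {
    stopifnot(is.character(s$name), length(s$name) == 1L, nzchar(s$name))
    members <- unique(as.character(s$members))
    members <- members[nzchar(members)]
    list(name = s$name,
         description = if (is.null(s$description)) "" else as.character(s$description)[1L],
         members = members)
  })
  nm <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1L])
  }
  structure(list(sets = sets), class = "geneset_collection")
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' @export
names.geneset_collection <- function(x) {
  vapply(x$sets, `[[`, character(1L), "name")
}

#' @export
print.geneset_collection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$members), integer(1L))
  cat("geneset_collection with", length(x), "sets",
      if (length(x) > 0L) sprintf("(median size %d)", as.integer(stats::median(sizes))) else "",
      "\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT dialect used for MSigDB downloads: one set
#' per line, first field the set name, second field an opaque description,
#' remaining fields the member identifiers. Duplicate members within a line
#' are collapsed; trailing empty fields are ignored.
#'
#' @param path Path to a GMT file.
#' @return A [geneset_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop(sprintf("malformed GMT line %d in '%s': fewer than 2 tab-separated fields",
                   i, path))
    }
    sets[[length(sets) + 1L]] <- list(
      name = fields[1L],
      description = fields[2L],
      members = if (length(fields) > 2L) fields[-(1:2)] else character(0L)
    )
  }
  geneset_collection(sets)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A [geneset_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column marker mapping table
#'
#' Headerless TSV with source identifiers in column 1 and target
#' identifiers in column 2 (e.g. gene to protein). One source may map to
#' several targets.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `source` and `target`.
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) stop("mapping table not found: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("source", "target"))
  if (ncol(df) != 2L) stop("mapping table must have exactly two columns")
  df
}

#' Translate gene sets across modalities via a mapping table
#'
#' Replaces each set's members by the union of all target identifiers
#' mapped from any member, e.g. translating gene-level pathways into the
#' protein markers measured by a proteomics assay. Members without a
#' mapping are dropped silently (counted in a warning); sets left empty are
#' retained so that pathway order stays aligned across modalities.
#'
#' @param collection A [geneset_collection()].
#' @param mapping A two-column data frame (source, target) as returned by
#'   [read_mapping_table()], or a two-column matrix.
#' @return A translated [geneset_collection()] with identical names/order.
#' @export
translate_sets <- function(collection, mapping) {
  stopifnot(inherits(collection, "geneset_collection"))
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  stopifnot(ncol(mapping) == 2L)
  map <- split(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
  n_dropped <- 0L
  n_members <- 0L
  sets <- lapply(collection$sets, function(s) {
    n_members <<- n_members + length(s$members)
    hit <- s$members %in% names(map)
    n_dropped <<- n_dropped + sum(!hit)
    s$members <- unique(unlist(map[s$members[hit]], use.names = FALSE))
    if (is.null(s$members)) s$members <- character(0L)
    s
  })
  out <- geneset_collection(sets)
  empty <- vapply(out$sets, function(s) length(s$members) == 0L, logical(1L))
  if (n_dropped > 0L || any(empty)) {
    warning(sprintf(
      "translate_sets: %d of %d members had no mapping; %d of %d sets empty after translation",
      n_dropped, n_members, sum(empty), length(out)))
  }
  out
}

#' Build a binary pathway membership mask
#'
#' Constructs the binary markers-by-pathways matrix C with C\[m, p\] = 1
#' iff marker m belongs to pathway p, aligned to a given marker universe.
#' Set members absent from `marker_ids` are ignored; markers in no set
#' yield all-zero rows (their signal is then fully noise-explained by the
#' model, which is well-defined for such rows).
#'
#' @param collection A [geneset_collection()].
#' @param marker_ids Character vector of unique marker identifiers giving
#'   the row order of the mask.
#' @return An object of class `pathway_mask`: a list with `matrix`
#'   (binary m x p matrix), `marker_ids` and `pathway_names`.
#' @export
build_mask <- function(collection, marker_ids) {
  stopifnot(inherits(collection, "geneset_collection"))
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker_ids: ", marker_ids[duplicated(marker_ids)][1L])
  }
  p <- length(collection)
  pnames <- names(collection)
  M <- matrix(0, nrow = length(marker_ids), ncol = p,
              dimnames = list(marker_ids, pnames))
  for (j in seq_len(p)) {
    M[marker_ids %in% collection$sets[[j]]$members, j] <- 1
  }
  if (p > 0L && any(colSums(M) == 0)) {
    warning("pathways with no covered markers (kept as zero columns): ",
            paste(pnames[colSums(M) == 0], collapse = ", "))
  }
  structure(list(matrix = M, marker_ids = marker_ids, pathway_names = pnames),
            class = "pathway_mask")
}

#' @export
print.pathway_mask <- function(x, ...) {
  cat(sprintf("pathway_mask: %d markers x %d pathways (%.1f%% coverage)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (length(x$matrix) > 0) 100 * mean(x$matrix) else 0))
  invisible(x)
}
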