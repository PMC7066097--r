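# Plain-text serialization: coordinate CSV, lead-field matrix with JSON
# sidecar, decomposition replay JSON, reconstruction CSV, case YAML.

#' Write sensor or source coordinates as CSV
#'
#' Columns: `id, x_mm, y_mm, z_mm[, kind]`.
#'
#' @param x a [SensorArray-class] or [SourceSpace-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCoordinatesCSV <- function(x, path) {
  pos <- coordinatesMm(x)
  df <- data.frame(id = seq_len(nrow(pos)), x_mm = pos[, 1L],
                   y_mm = pos[, 2L], z_mm = pos[, 3L])
  if (is(x, "SensorArray")) df$kind <- x@kind
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a coordinate CSV
#'
#' @param path CSV with columns `id, x_mm, y_mm, z_mm[, kind]`.
#' @return numeric n x 3 matrix of coordinates (mm), with a `kind`
#'   attribute when the column is present.
#' @export
readCoordinatesCSV <- function(path) {
  df <- read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("coordinate CSV must have columns x_mm, y_mm, z_mm",
         call. = FALSE)
  m <- as.matrix(df[, need])
  colnames(m) <- c("x", "y", "z")
  if ("kind" %in% names(df)) attr(m, "kind") <- df$kind[1L]
  m
}

#' Export a lead field as text matrix plus JSON sidecar
#'
#' The matrix is written whitespace-delimited (one sensor row per line,
#' full double precision); `<path>.json` records modality, units and the
#' 3K component layout.
#'
#' @param lead a [LeadField-class].
#' @param path matrix file; the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
writeLeadField <- function(lead, path) {
  stopifnot(is(lead, "LeadField"))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(format(lead@matrix, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(modality = lead@modality, units = lead@units,
         sensors = nrow(lead@matrix), positions = nSources(lead),
         layout = "component c of position j at column 3*(j-1)+c"),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Import a lead field written by [writeLeadField()]
#'
#' A user-supplied plain matrix is also accepted: without a sidecar the
#' modality must be given.
#'
#' @param path matrix file.
#' @param modality fallback modality when no sidecar exists.
#' @return a [LeadField-class].
#' @export
readLeadField <- function(path, modality = NULL) {
  M <- as.matrix(utils::read.table(path))
  dimnames(M) <- NULL
  sidecar <- paste0(path, ".json")
  units <- ""
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    modality <- meta$modality
    units <- meta$units
  } else if (is.null(modality)) {
    stop("no JSON sidecar found; supply 'modality'", call. = FALSE)
  }
  new("LeadField", matrix = M, modality = modality, units = units)
}

#' Export a decomposition for exact replay
#'
#' Stores seed, sparsity, level count and the per-level center indices
#' as JSON.
#'
#' @param dec a [MultiresDecomposition-class].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeDecompositionJSON <- function(dec, path) {
  stopifnot(is(dec, "MultiresDecomposition"))
  jsonlite::write_json(
    list(seed = dec@seed, sparsity = dec@sparsity,
         nLevels = length(dec@levels),
         centers = lapply(dec@levels, function(l) l@centers)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a decomposition from its JSON export
#'
#' @param path JSON file from [writeDecompositionJSON()].
#' @param space the [SourceSpace-class] the decomposition refers to.
#' @return a [MultiresDecomposition-class].
#' @export
readDecompositionJSON <- function(path, space) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  levels <- lapply(seq_len(meta$nLevels), function(l)
    .makeLevel(space@positions, as.integer(meta$centers[[l]]), l))
  new("MultiresDecomposition", levels = levels,
      sparsity = as.numeric(meta$sparsity),
      seed = as.numeric(meta$seed))
}

#' Export a reconstruction as per-position CSV
#'
#' Columns: position id, coordinates (mm), the three moment components
#' and the amplitude.
#'
#' @param x numeric length-3K estimate (or [RamusResult-class]).
#' @param space the [SourceSpace-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeReconstructionCSV <- function(x, space, path) {
  if (is(x, "RamusResult")) x <- currentEstimate(x)
  q <- matrix(x, nrow = 3L)
  pos <- coordinatesMm(space)
  df <- data.frame(id = seq_len(ncol(q)), x_mm = pos[, 1L],
                   y_mm = pos[, 2L], z_mm = pos[, 3L],
                   qx = q[1L, ], qy = q[2L, ], qz = q[3L, ],
                   amplitude = sourceAmplitudes(x))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a RAMUS result as text matrix plus JSON provenance sidecar
#'
#' Column 1 holds the final estimate, the remaining D columns the
#' per-decomposition normalized level means; `<path>.json` records the
#' configuration and seeds.
#'
#' @param result a [RamusResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRamusResult <- function(result, path) {
  stopifnot(is(result, "RamusResult"))
  M <- cbind(result@xFinal, result@perDecomposition)
  utils::write.table(format(M, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(result@provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a case configuration from YAML
#'
#' The file may carry any subset of the [caseConfig()] fields; `caseId`
#' is required and unspecified fields fall back to the case-table
#' defaults.
#'
#' @param path YAML file.
#' @return a [CaseConfig-class].
#' @export
readCaseConfigYAML <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$caseId))
    stop("config error: YAML case file lacks 'caseId'", call. = FALSE)
  args <- list(caseId = y$caseId)
  for (f in c("scaleFactor", "noisePct", "nRealizations", "nLevels",
              "nIter", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(caseConfig, args)
}

#' Write the shipped preset for a case id
#'
#' @param caseId case id `"A"`..`"I"`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
writeCaseConfigYAML <- function(caseId, path) {
  row <- .CASE_TABLE[.CASE_TABLE$caseId == toupper(caseId), ]
  if (nrow(row) != 1L)
    stop(sprintf("config error: unknown case id '%s'", caseId),
         call. = FALSE)
  yaml::write_yaml(c(as.list(row),
                     list(noisePct = 3, nRealizations = 50L,
                          nLevels = 3L, nIter = 10L)), path)
  invisible(path)
}
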