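#' Read an embedding table
#'
#' The embedding file dialect is tab-separated UTF-8 text with no header:
#' first column the item id, remaining columns the embedding vector, floats
#' written in full precision. Ragged rows, non-numeric cells and duplicate
#' ids are rejected with the offending row or id named.
#'
#' @param path path to a TSV embedding file
#' @return an [EmbeddingSet-class] with ids in file order
#' @seealso [writeEmbeddings()]
#' @export
readEmbeddings <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("embedding file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 bad, widths[1L], widths[bad]))
  }
  if (widths[1L] < 2L) stop("rows must carry an id and at least one value")
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate item id: '%s'", ids[anyDuplicated(ids)]))
  d <- widths[1L] - 1L
  vals <- matrix(NA_real_, length(parts), d)
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1L]))
    if (anyNA(v) || any(!is.finite(v)))
      stop(sprintf("non-numeric or non-finite cell in row %d", i))
    vals[i, ] <- v
  }
  EmbeddingSet(vals, ids = ids)
}

#' Write an embedding table
#'
#' Writes the TSV dialect read by [readEmbeddings()]; floats use 17
#' significant digits so a write/read round trip is exact.
#'
#' @param x an [EmbeddingSet-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeEmbeddings <- function(x, path) {
  stopifnot(is(x, "EmbeddingSet"))
  validObject(x)
  v <- embMatrix(x)
  num <- matrix(formatC(v, format = "g", digits = 17), nrow(v), ncol(v))
  rows <- paste(itemIds(x), apply(num, 1L, paste, collapse = "\t"),
                sep = "\t")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(rows, con)
  invisible(path)
}

#' Build a dataset manifest
#'
#' A manifest is a data.frame with one record per item: `id`, `uri` and an
#' optional ground-truth `label` used only for evaluation — the selection
#' pipeline itself never reads labels.
#'
#' @param x an [EmbeddingSet-class]
#' @param labels optional per-item class labels (character or factor)
#' @param uris optional per-item resource identifiers; defaults to
#'   `synthetic://<id>` for generated pools
#' @return a data.frame with columns `id`, `uri` and (if given) `label`
#' @export
generateManifest <- function(x, labels = NULL, uris = NULL) {
  stopifnot(is(x, "EmbeddingSet"))
  ids <- itemIds(x)
  if (is.null(uris)) uris <- paste0("synthetic://", ids)
  if (length(uris) != length(ids)) stop("uris length mismatch")
  m <- data.frame(id = ids, uri = as.character(uris),
                  stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != length(ids)) stop("labels length mismatch")
    m$label <- as.character(labels)
  }
  validateManifest(m)
  m
}

#' Validate a dataset manifest
#'
#' @param m a manifest data.frame
#' @return `m`, invisibly, or an error describing the violation
#' @export
validateManifest <- function(m) {
  if (!is.data.frame(m) || !all(c("id", "uri") %in% names(m)))
    stop("manifest must be a data.frame with columns id, uri")
  if (anyDuplicated(m$id))
    stop(sprintf("duplicate manifest id: '%s'", m$id[anyDuplicated(m$id)]))
  if ("label" %in% names(m) && anyNA(m$label))
    stop("labels must be present for all records or absent entirely")
  invisible(m)
}

#' Read / write a dataset manifest
#'
#' Manifests are CSV with header `id,uri,label`; the `label` column is
#' optional.
#'
#' @param path CSV path
#' @return for `readManifest`, the manifest data.frame; for
#'   `writeManifest`, `path` invisibly
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validateManifest(m)
  m
}

#' @rdname readManifest
#' @param m a manifest data.frame
#' @export
writeManifest <- function(m, path) {
  validateManifest(m)
  write.csv(m, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Define an embedding-extractor adapter
#'
#' The core pipeline consumes precomputed embeddings; actual feature
#' extraction (e.g. a DINOv2 backbone) is plugged in behind this contract.
#' An adapter maps a vector of item URIs to an [EmbeddingSet-class] whose
#' row order matches the input order and whose dimensionality is fixed
#' across calls. Metadata records what a downstream reader needs to
#' interpret the embeddings: token-pooling mode, input resolution and the
#' checkpoint identifier.
#'
#' @param name adapter name
#' @param embedFun function(uris, ids) -> [EmbeddingSet-class]
#' @param pooling token-pooling mode (default the global class-token
#'   representation)
#' @param resolution input resolution, pixels
#' @param checkpoint checkpoint identifier
#' @return an object of class `ExtractorAdapter`
#' @export
extractorAdapter <- function(name, embedFun, pooling = "class-token",
                             resolution = 256L, checkpoint = "unspecified") {
  stopifnot(is.character(name), is.function(embedFun))
  structure(list(name = name, embed = embedFun,
                 metadata = list(pooling = pooling,
                                 resolution = as.integer(resolution),
                                 checkpoint = checkpoint)),
            class = "ExtractorAdapter")
}

#' Run an extractor adapter and persist its output
#'
#' Writes the embedding TSV plus a JSON metadata sidecar
#' (`<path>.meta.json`) recording the adapter configuration.
#'
#' @param adapter an `ExtractorAdapter`
#' @param uris item URIs
#' @param ids item ids (defaults to the URIs)
#' @param path output embedding TSV path
#' @return the [EmbeddingSet-class] produced, invisibly
#' @export
runExtractor <- function(adapter, uris, ids = uris, path) {
  stopifnot(inherits(adapter, "ExtractorAdapter"))
  e <- adapter$embed(uris, ids)
  stopifnot(is(e, "EmbeddingSet"))
  if (!identical(itemIds(e), as.character(ids)))
    stop("adapter output row order must match input order")
  writeEmbeddings(e, path)
  jsonlite::write_json(c(list(name = adapter$name), adapter$metadata),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(e)
}
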