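#' Construct an EmbeddingSet
#'
#' @param values numeric matrix, items in rows, embedding dimensions in
#'   columns. All values must be finite.
#' @param ids character vector of unique item identifiers, one per row.
#'   Defaults to the rownames of `values`.
#' @return an [EmbeddingSet-class]
#' @examples
#' e <- EmbeddingSet(matrix(rnorm(12), 3, 4), ids = c("a", "b", "c"))
#' nItems(e); embDim(e)
#' @export
EmbeddingSet <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids))
    stop("item ids are required (pass `ids` or set rownames)")
  ids <- as.character(ids)
  if (length(ids) != nrow(values))
    stop("length of ids must equal the number of rows")
  rownames(values) <- ids
  new("EmbeddingSet", values = values)
}

#' @rdname coresel-accessors
#' @export
setMethod("itemIds", "EmbeddingSet", function(x) rownames(x@values))

#' @rdname coresel-accessors
#' @export
setMethod("nItems", "EmbeddingSet", function(x) nrow(x@values))

#' @rdname coresel-accessors
#' @export
setMethod("embDim", "EmbeddingSet", function(x) ncol(x@values))

#' @rdname coresel-accessors
#' @export
setMethod("embMatrix", "EmbeddingSet", function(x) x@values)

#' @export
setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet: %d items x %d dimensions\n",
              nItems(object), embDim(object)))
  n <- min(3L, nItems(object))
  cat("  ids:", paste(head(itemIds(object), n), collapse = ", "),
      if (nItems(object) > n) "..." else "", "\n")
})

#' Subset an EmbeddingSet by item
#'
#' @param x an [EmbeddingSet-class]
#' @param i item indices or ids
#' @param j,...,drop ignored (columns are never dropped)
#' @return an [EmbeddingSet-class] with the selected items
#' @export
setMethod("[", "EmbeddingSet", function(x, i, j, ..., drop = FALSE) {
  EmbeddingSet(x@values[i, , drop = FALSE])
})

#' L2-normalize embedding rows
#'
#' Rescales every embedding vector to unit Euclidean norm. Offered as a
#' preprocessing option; the clustering pipeline runs on raw embeddings by
#' default.
#'
#' @param x an [EmbeddingSet-class] with no all-zero row
#' @return an [EmbeddingSet-class] whose rows all have norm 1
#' @examples
#' e <- EmbeddingSet(matrix(c(3, 4), 1, 2), ids = "a")
#' embMatrix(l2Normalize(e))  # 0.6 0.8
#' @export
l2Normalize <- function(x) {
  stopifnot(is(x, "EmbeddingSet"))
  v <- embMatrix(x)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0))
    stop("cannot normalize all-zero rows: ",
         paste(itemIds(x)[nrm == 0], collapse = ", "))
  EmbeddingSet(v / nrm)
}
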