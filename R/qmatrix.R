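#' Construct and validate a Q-matrix
#'
#' The Q-matrix is the J x K binary incidence matrix linking items to the
#' cognitive attributes they measure: entry (j, k) is 1 when item j
#' requires attribute k. Validation enforces binary entries, at least one
#' attribute per item (an all-zero row makes the item uninformative about
#' every attribute), and unique labels.
#'
#' @param entries J x K matrix coercible to 0/1 integers.
#' @param item_labels,attribute_labels optional character labels;
#'   defaults `Item1..ItemJ` and `A1..AK`.
#' @return an object of class `qmatrix` (an integer matrix with dimnames).
#' @export
qmatrix <- function(entries, item_labels = NULL, attribute_labels = NULL) {
  entries <- as.matrix(entries)
  J <- nrow(entries); K <- ncol(entries)
  if (J < 1L || K < 1L) stop("Q-matrix must have at least one item and one attribute")
  if (is.null(item_labels)) item_labels <- rownames(entries)
  if (is.null(item_labels)) item_labels <- paste0("Item", seq_len(J))
  if (is.null(attribute_labels)) attribute_labels <- colnames(entries)
  if (is.null(attribute_labels)) attribute_labels <- paste0("A", seq_len(K))
  suppressWarnings(storage.mode(entries) <- "integer")
  bad <- which(is.na(entries) | (entries != 0L & entries != 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary Q-matrix entry at item %s, attribute %s",
                 item_labels[bad[1L, 1L]], attribute_labels[bad[1L, 2L]]))
  if (anyDuplicated(item_labels) || anyDuplicated(attribute_labels))
    stop("item and attribute labels must be unique")
  zero <- which(rowSums(entries) == 0L)
  if (length(zero) > 0L)
    stop("item(s) with no required attribute: ",
         paste(item_labels[zero], collapse = ", "))
  dimnames(entries) <- list(item_labels, attribute_labels)
  structure(entries, class = c("qmatrix", class(entries)))
}

#' Read a Q-matrix from a CSV file
#'
#' The file must have a header of attribute labels and one row per item.
#' An optional first column of item labels is detected automatically (a
#' non-binary first column is taken as labels); otherwise items are
#' labelled `Item1..ItemJ`. Row and column order are preserved.
#'
#' @param path path to a comma-delimited text file.
#' @return a validated [qmatrix].
#' @export
read_qmatrix <- function(path) {
  if (!file.exists(path)) stop("Q-matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (nrow(df) < 1L || ncol(df) < 1L) stop("empty Q-matrix file: ", path)
  first <- df[[1L]]
  # a leading label column is either non-numeric or explicitly named;
  # a numeric non-binary value elsewhere must surface as a parse error
  has_labels <- ncol(df) > 1L &&
    (any(grepl("[^0-9]", first)) ||
     tolower(colnames(df)[1L]) %in% c("item", "item no.", "item_no", "id", "label"))
  item_labels <- if (has_labels) first else NULL
  body <- if (has_labels) df[, -1L, drop = FALSE] else df
  K <- ncol(body); J <- nrow(body)
  ent <- matrix(NA_integer_, J, K)
  for (k in seq_len(K)) {
    v <- body[[k]]
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      j <- which(!ok)[1L]
      lab <- if (has_labels) item_labels[j] else paste0("Item", j)
      stop(sprintf("non-binary cell '%s' at item %s, attribute %s in %s",
                   v[j], lab, colnames(body)[k], path))
    }
    ent[, k] <- as.integer(v)
  }
  qmatrix(ent, item_labels = item_labels, attribute_labels = colnames(body))
}

#' Write a Q-matrix to CSV
#'
#' Inverse of [read_qmatrix()]: the written file round-trips bit-identically.
#'
#' @param q a [qmatrix].
#' @param path output path.
#' @export
write_qmatrix <- function(q, path) {
  df <- data.frame(Item = rownames(q), unclass(q), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Number of items measuring each attribute
#'
#' Column sums of the Q-matrix; attributes measured by few items are
#' poorly identified diagnostically.
#'
#' @param q a [qmatrix].
#' @return named integer vector of length K.
#' @export
attribute_item_counts <- function(q) {
  stopifnot(inherits(q, "qmatrix"))
  colSums(unclass(q))
}

#' Prune under-measured attributes from a Q-matrix
#'
#' Drops every attribute measured by fewer than `min_items` items — the
#' conventional minimum for reliable diagnostic identification is three
#' items per attribute — and re-validates the result. If pruning leaves
#' some item with no required attribute, that is an error naming the
#' item: silently cascading item removal would change J and desynchronize
#' any paired response file.
#'
#' @param q a [qmatrix].
#' @param min_items minimum number of items per retained attribute.
#' @return a list with `qmatrix` (the pruned matrix) and `removed`
#'   (character vector of dropped attribute labels, possibly empty).
#' @export
prune_attributes <- function(q, min_items = 3) {
  stopifnot(inherits(q, "qmatrix"), min_items >= 0)
  counts <- attribute_item_counts(q)
  drop <- which(counts < min_items)
  if (length(drop) == ncol(q)) stop("pruning would remove every attribute")
  if (length(drop) == 0L) return(list(qmatrix = q, removed = character(0)))
  kept <- unclass(q)[, -drop, drop = FALSE]
  zero <- which(rowSums(kept) == 0L)
  if (length(zero) > 0L)
    stop("pruning attributes ", paste(names(counts)[drop], collapse = ", "),
         " leaves item(s) with no attribute: ",
         paste(rownames(q)[zero], collapse = ", "))
  list(qmatrix = qmatrix(kept), removed = names(counts)[drop])
}

#' Read / write a binary response matrix
#'
#' A response matrix holds one row per examinee and one 0/1 column per
#' item. The CSV has a header of item labels and an optional first column
#' of examinee identifiers (auto-generated `E1..EN` when absent).
#' Missing responses are not supported.
#'
#' @param path CSV path.
#' @param n_items if given, the file's column count is checked against it.
#' @return an integer matrix with examinee ids as row names.
#' @export
read_responses <- function(path, n_items = NULL) {
  if (!file.exists(path)) stop("response file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  first <- df[[1L]]
  has_ids <- ncol(df) > 1L &&
    (any(grepl("[^0-9]", first)) ||
     tolower(colnames(df)[1L]) %in% c("id", "examinee", "student"))
  ids <- if (has_ids) first else paste0("E", seq_len(nrow(df)))
  body <- if (has_ids) df[, -1L, drop = FALSE] else df
  X <- as.matrix(body)
  if (!all(X %in% c("0", "1"))) {
    bad <- which(matrix(!(X %in% c("0", "1")), nrow(X)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary response at examinee %s, item %s in %s",
                 ids[bad[1L]], colnames(body)[bad[2L]], path))
  }
  storage.mode(X) <- "integer"
  if (!is.null(n_items) && ncol(X) != n_items)
    stop("response matrix has ", ncol(X), " items but the Q-matrix has ", n_items)
  rownames(X) <- ids
  X
}

#' @rdname read_responses
#' @param X integer 0/1 response matrix.
#' @export
write_responses <- function(X, path) {
  df <- data.frame(id = if (is.null(rownames(X))) paste0("E", seq_len(nrow(X)))
                        else rownames(X),
                   X, check.names = FALSE)
  colnames(df) <- c("id", if (is.null(colnames(X))) paste0("Item", seq_len(ncol(X)))
                          else colnames(X))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
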