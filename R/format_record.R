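#' Flat format-tagged metadata record
#'
#' A `format_record` is the common currency between the dialect adapters
#' and the transform engine: a format tag plus an ordered list of
#' (path, value) items as parsed from a native payload, with parse details
#' (source table, row index, unrecognized locations, spelling aliases) kept
#' in `dialect_meta`.
#'
#' @param format One of the four format labels.
#' @param items Data frame with character columns `path` and `value`
#'   (optionally `table` and `row` for the OMOP dialect).
#' @param dialect_meta List of parse details.
#' @return A `format_record`.
#' @export
format_record <- function(format, items = NULL, dialect_meta = list()) {
  fmt <- as_format_id(format)
  if (is.null(items) || nrow(items) == 0L) {
    items <- data.frame(path = character(0), value = character(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(items), all(c("path", "value") %in% names(items)))
  items$path <- as.character(items$path)
  items$value <- as.character(items$value)
  rownames(items) <- NULL
  structure(list(format = fmt, items = items, dialect_meta = dialect_meta),
            class = "format_record")
}

#' Number of metadata items in a format record
#' @param record A `format_record`.
#' @return Integer count.
#' @export
n_items <- function(record) {
  stopifnot(inherits(record, "format_record"))
  nrow(record$items)
}

# (path, value) pairs as a plain data.frame, dropping dialect bookkeeping;
# used by tests and the transform engine for item-equality checks.
item_pairs <- function(record) {
  record$items[, c("path", "value"), drop = FALSE]
}

# order-insensitive item equality: same multiset of (path, value) pairs
items_equal <- function(a, b) {
  pa <- item_pairs(a); pb <- item_pairs(b)
  if (nrow(pa) != nrow(pb)) return(FALSE)
  key <- function(d) sort(paste(d$path, d$value, sep = "\r"))
  identical(key(pa), key(pb))
}

#' @export
print.format_record <- function(x, ...) {
  cat("<format_record> ", x$format, ", ", nrow(x$items), " item(s)\n",
      sep = "")
  if (nrow(x$items)) {
    for (i in seq_len(nrow(x$items))) {
      cat("  ", format(x$items$path[i], width = 40), " ",
          x$items$value[i], "\n", sep = "")
    }
  }
  invisible(x)
}

# Which paths may legally repeat in each dialect: OMOP tables are row-sets,
# FHIR Meta.profile is an array, CDISC def:* attach as repeated elements.
# openEHR's flat path map cannot repeat a key.
path_repeatable <- function(format, path) {
  switch(as_format_id(format),
         OMOP = TRUE,
         OPENEHR = FALSE,
         FHIR = path == "Meta.profile",
         CDISC = startsWith(path, "def:"))
}
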