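#' Build the maximum-set convergence schema
#'
#' The convergence format is defined constructively as the union of every
#' semantic meaning in the crosswalk and the 19 essential items of the data
#' integration centre, deduplicated by meaning slug. Each schema item
#' records where it came from (`crosswalk`, `medic_essential` or `both`),
#' its priority level when it is an essential item, and its FAIR tags.
#'
#' @param registry A validated `crosswalk_registry`.
#' @return A data frame (class `convergence_schema`) with one row per
#'   convergence item and columns `meaning_id`, `origin`, `priority`,
#'   `fair_tags` and `value_kind`. Order is deterministic: crosswalk entries
#'   in registry order, then the essential-only items in priority-file
#'   order.
#' @export
#' @examples
#' schema <- build_schema(load_registry())
#' nrow(schema)
build_schema <- function(registry) {
  stopifnot(inherits(registry, "crosswalk_registry"))
  cw_ids <- names(registry$entries)
  pi <- registry$priority_items
  extra <- pi[!pi$meaning_id %in% cw_ids, , drop = FALSE]
  ids <- c(cw_ids, extra$meaning_id)
  origin <- ifelse(ids %in% cw_ids,
                   ifelse(ids %in% pi$meaning_id, "both", "crosswalk"),
                   "medic_essential")
  priority <- pi$priority[match(ids, pi$meaning_id)]
  fair <- pi$fair_tags[match(ids, pi$meaning_id)]
  fair[is.na(fair)] <- ""
  schema <- data.frame(
    meaning_id = ids,
    origin = origin,
    priority = priority,
    fair_tags = fair,
    value_kind = value_kind_of(ids),
    stringsAsFactors = FALSE
  )
  class(schema) <- c("convergence_schema", class(schema))
  schema
}

# Declared value-kind hints derived from the meaning labels; values are
# stored as text regardless (the four dialects disagree on lexical forms).
value_kind_of <- function(ids) {
  kind <- rep("text", length(ids))
  kind[grepl("datetime", ids)] <- "datetime"
  kind[grepl("(^|_)date$|_date_", ids)] <- "date"
  kind[grepl("(^|_)id$|_id_|identifier", ids)] <- "identifier"
  kind
}

#' Create an empty convergence record
#'
#' Every schema item is present as a slot with a null value and no source
#' paths; extension slots (unmapped source items retained during
#' transformation) start empty.
#'
#' @param schema A `convergence_schema` from [build_schema()].
#' @param provenance Free-text tag naming where the record's content came
#'   from (typically the source format).
#' @return A `convergence_record`.
#' @export
new_record <- function(schema, provenance = "") {
  if (!inherits(schema, "convergence_schema") || nrow(schema) == 0L) {
    stop("schema must be a non-empty convergence_schema", call. = FALSE)
  }
  slots <- lapply(seq_len(nrow(schema)), function(i) {
    list(value = NULL, source_paths = character(0), normalized = FALSE)
  })
  names(slots) <- schema$meaning_id
  structure(
    list(schema = schema, slots = slots, ext = list(),
         ambiguous = character(0), provenance = provenance),
    class = "convergence_record")
}

check_known_slot <- function(record, meaning_id) {
  if (!meaning_id %in% record$schema$meaning_id) {
    stop(structure(
      class = c("mcx_unknown_item", "error", "condition"),
      list(message = paste0("unknown convergence item: '", meaning_id,
                            "' is not in the schema"),
           call = NULL)))
  }
}

#' Read or write one convergence slot
#'
#' `conv_get()` returns the slot's value (a character vector for
#' list-valued slots, `NULL` when unfilled); `conv_set()` fills it.
#' Addressing a slug outside the schema raises a distinct
#' `mcx_unknown_item` condition.
#'
#' @param record A `convergence_record`.
#' @param meaning_id Schema slug.
#' @param value Character vector (or `NULL` to clear).
#' @param source_paths Format paths that produced the value (empty for
#'   user-authored values).
#' @param normalized Whether datetime normalization was applied on ingest.
#' @return `conv_get()`: the value; `conv_set()`: the modified record.
#' @export
conv_get <- function(record, meaning_id) {
  stopifnot(inherits(record, "convergence_record"))
  check_known_slot(record, meaning_id)
  record$slots[[meaning_id]]$value
}

#' @rdname conv_get
#' @export
conv_set <- function(record, meaning_id, value,
                     source_paths = character(0), normalized = FALSE) {
  stopifnot(inherits(record, "convergence_record"))
  check_known_slot(record, meaning_id)
  record$slots[[meaning_id]] <- list(
    value = if (is.null(value)) NULL else as.character(value),
    source_paths = as.character(source_paths),
    normalized = isTRUE(normalized))
  record
}

#' Fraction of convergence slots that carry a value
#'
#' Completeness of a record over its schema slots, optionally restricted to
#' one priority level of the essential items. Extension slots are not
#' counted: they describe source-format surplus, not schema coverage.
#'
#' @param record A `convergence_record`.
#' @param priority_level Optional priority filter (1, 2 or 3).
#' @return Fraction in `[0, 1]`; `NaN` (an undefined ratio, distinct from
#'   0) when the priority filter matches no slot.
#' @export
completeness <- function(record, priority_level = NULL) {
  stopifnot(inherits(record, "convergence_record"))
  ids <- record$schema$meaning_id
  if (!is.null(priority_level)) {
    stopifnot(priority_level %in% 1:3)
    ids <- ids[!is.na(record$schema$priority) &
                 record$schema$priority == priority_level]
  }
  if (length(ids) == 0L) return(NaN)
  filled <- vapply(ids, function(id) !is.null(record$slots[[id]]$value),
                   logical(1))
  mean(filled)
}

slot_to_list <- function(slot) {
  list(value = if (is.null(slot$value)) NULL else as.list(slot$value),
       source_paths = as.list(slot$source_paths),
       normalized = slot$normalized)
}

#' Serialize / deserialize a convergence record
#'
#' A record serializes to a single flat JSON document: one object whose
#' keys are the schema slugs (in schema order) followed by the extension
#' slots (sorted), each holding `{value, source_paths, normalized}`, plus
#' the reserved keys `_provenance` and `_ambiguous`. The key order is
#' stable, so `conv_to_json()` round-trips byte-identically through
#' `conv_from_json()`.
#'
#' @param record A `convergence_record`.
#' @param json JSON text produced by `conv_to_json()`.
#' @param schema The schema to rebind on read (defaults to the packaged
#'   registry's schema).
#' @return `conv_to_json()`: a JSON string; `conv_from_json()`: a
#'   `convergence_record`.
#' @export
conv_to_json <- function(record) {
  stopifnot(inherits(record, "convergence_record"))
  doc <- list(`_provenance` = record$provenance,
              `_ambiguous` = as.list(record$ambiguous))
  for (id in record$schema$meaning_id) {
    doc[[id]] <- slot_to_list(record$slots[[id]])
  }
  for (id in sort(names(record$ext))) {
    doc[[id]] <- slot_to_list(record$ext[[id]])
  }
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                pretty = TRUE))
}

#' @rdname conv_to_json
#' @export
conv_from_json <- function(json, schema = NULL) {
  if (is.null(schema)) schema <- build_schema(load_registry())
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rec <- new_record(schema, provenance = doc$`_provenance` %||% "")
  rec$ambiguous <- as.character(unlist(doc$`_ambiguous`, use.names = FALSE))
  for (id in setdiff(names(doc), c("_provenance", "_ambiguous"))) {
    slot <- list(
      value = if (is.null(doc[[id]]$value)) NULL
              else as.character(unlist(doc[[id]]$value)),
      source_paths = as.character(unlist(doc[[id]]$source_paths,
                                         use.names = FALSE)),
      normalized = isTRUE(doc[[id]]$normalized))
    if (startsWith(id, "ext:")) {
      rec$ext[[id]] <- slot
    } else {
      check_known_slot(rec, id)
      rec$slots[[id]] <- slot
    }
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.convergence_record <- function(x, ...) {
  filled <- sum(vapply(x$slots, function(s) !is.null(s$value), logical(1)))
  cat("<convergence_record>",
      if (nzchar(x$provenance)) paste0(" from ", x$provenance), "\n", sep = "")
  cat("  slots: ", filled, "/", length(x$slots), " filled; ",
      length(x$ext), " extension slot(s)\n", sep = "")
  for (id in x$schema$meaning_id) {
    v <- x$slots[[id]]$value
    if (!is.null(v)) {
      cat("  ", format(id, width = 24), " ",
          paste(v, collapse = " ; "), "\n", sep = "")
    }
  }
  invisible(x)
}
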