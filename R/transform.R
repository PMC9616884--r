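# Transform engine: format record -> convergence record -> any target
# format. The convergence record is the maximum set: every source item is
# either mapped through the crosswalk (possibly merged or split) or
# retained verbatim in a namespaced extension slot, so no information is
# lost; target emission always produces the complete registry structure for
# the target dialect, with unfed paths reported as NULL-filled.

# ---- merge/split codec -----------------------------------------------------
# Reversible qualifier syntax "key=value|key=value" with backslash escaping
# of the delimiter, "=" and the escape character itself. The syntax is an
# artifact convention; reversibility is the requirement.

merge_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("=", "\\=", x, fixed = TRUE)
  gsub("|", "\\|", x, fixed = TRUE)
}

merge_unescape <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "")[[1]]
    buf <- character(0); esc <- FALSE
    for (ch in chars) {
      if (esc) { buf <- c(buf, ch); esc <- FALSE }
      else if (ch == "\\") esc <- TRUE
      else buf <- c(buf, ch)
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

# split on a single-character separator, honouring backslash escapes
scan_split <- function(s, sep) {
  chars <- strsplit(s, "")[[1]]
  parts <- character(0); buf <- character(0); esc <- FALSE
  for (ch in chars) {
    if (esc) { buf <- c(buf, "\\", ch); esc <- FALSE }
    else if (ch == "\\") esc <- TRUE
    else if (ch == sep) { parts <- c(parts, paste(buf, collapse = "")); buf <- character(0) }
    else buf <- c(buf, ch)
  }
  if (esc) buf <- c(buf, "\\")
  c(parts, paste(buf, collapse = ""))
}

#' Define a reversible merge rule
#'
#' A merge rule joins several source paths into one convergence slot while
#' keeping the parts recoverable: each part is stored under a role
#' qualifier (`qualifier=value`, parts joined by `|`, with backslash
#' escaping), so splitting a joined value returns the original parts
#' exactly, including parts that contain the delimiter.
#'
#' @param meaning_id Convergence slot the rule feeds.
#' @param paths Ordered source paths (at least two).
#' @param qualifiers Role qualifier per path; defaults to the last
#'   colon-segment of each path.
#' @param delimiter Single-character join delimiter.
#' @return A `merge_rule`.
#' @export
merge_rule <- function(meaning_id, paths, qualifiers = NULL,
                       delimiter = "|") {
  stopifnot(length(paths) >= 2L, nchar(delimiter) == 1L)
  if (is.null(qualifiers)) {
    qualifiers <- vapply(strsplit(paths, ":", fixed = TRUE),
                         function(p) p[length(p)], "")
  }
  stopifnot(length(qualifiers) == length(paths),
            !anyDuplicated(qualifiers))
  structure(list(meaning_id = meaning_id, paths = paths,
                 qualifiers = qualifiers, delimiter = delimiter),
            class = "merge_rule")
}

# the packaged registry's only merge: openEHR original_author/publisher
rule_for_entry <- function(entry, format) {
  merge_rule(entry$meaning_id, entry$slots[[format]])
}

#' Join ordered parts under a merge rule, and split the inverse
#'
#' `merge_join()` encodes the parts (`NA` parts are omitted and come back
#' as `NA` from `merge_split()`); `merge_split()` recovers them. For any
#' parts, `merge_split(rule, merge_join(rule, parts))` is exact, delimiter
#' characters included.
#'
#' @param rule A [merge_rule()].
#' @param parts Character vector of parts, one per rule path (`NA`
#'   allowed).
#' @param value A joined value.
#' @return `merge_join()`: the joined string; `merge_split()`: character
#'   vector of parts aligned to `rule$paths`, `NA` where absent.
#' @export
merge_join <- function(rule, parts) {
  stopifnot(inherits(rule, "merge_rule"))
  if (length(parts) != length(rule$paths)) {
    stop("expected ", length(rule$paths), " part(s), got ", length(parts),
         call. = FALSE)
  }
  keep <- !is.na(parts)
  paste(paste0(merge_escape(rule$qualifiers[keep]), "=",
               merge_escape(parts[keep])),
        collapse = rule$delimiter)
}

#' @rdname merge_join
#' @export
merge_split <- function(rule, value) {
  stopifnot(inherits(rule, "merge_rule"), length(value) == 1L)
  out <- rep(NA_character_, length(rule$paths))
  names(out) <- rule$qualifiers
  if (!nzchar(value)) return(out)
  if (!is_merge_syntax(value)) {
    # foreign value (came from a format without the merge): first role
    out[1] <- value
    return(out)
  }
  for (piece in scan_split(value, rule$delimiter)) {
    kv <- scan_split(piece, "=")
    if (length(kv) != 2L) next
    q <- merge_unescape(kv[1])
    if (q %in% rule$qualifiers) out[q] <- merge_unescape(kv[2])
  }
  if (all(is.na(out))) out[1] <- value # no recognized qualifier: first role
  out
}

# joined-syntax sniff: at least one unescaped "="
is_merge_syntax <- function(value) {
  length(scan_split(value, "=")) >= 2L
}

# ---- loss report -----------------------------------------------------------

#' Loss report of a transformation leg
#'
#' Five lists partition all source items and all target-schema paths of a
#' transformation: `mapped` (one source path to one convergence slot),
#' `merged` (several source paths joined into one slot), `split` (one
#' source path feeding several slots), `source_unmapped_retained` (values
#' kept only convergence-side: unmapped source paths, or slots with no home
#' in the target format) and `target_null_filled` (target paths emitted
#' empty because no slot feeds them).
#'
#' @param mapped Data frame `(path, meaning_id)`.
#' @param merged List of `list(paths, meaning_id)`.
#' @param split List of `list(path, meaning_ids)`.
#' @param source_unmapped_retained Character vector.
#' @param target_null_filled Character vector.
#' @return A `loss_report`.
#' @export
loss_report <- function(mapped = NULL, merged = list(), split = list(),
                        source_unmapped_retained = character(0),
                        target_null_filled = character(0)) {
  if (is.null(mapped)) {
    mapped <- data.frame(path = character(0), meaning_id = character(0),
                         stringsAsFactors = FALSE)
  }
  structure(list(mapped = mapped, merged = merged, split = split,
                 source_unmapped_retained = source_unmapped_retained,
                 target_null_filled = target_null_filled),
            class = "loss_report")
}

#' Count of source items accounted for by a loss report
#'
#' Conservation check: for the ingest leg, `mapped` rows + paths inside
#' `merged` + `split` rows + retained paths must equal the number of source
#' items.
#'
#' @param report A `loss_report`.
#' @return Integer.
#' @export
accounted_items <- function(report) {
  stopifnot(inherits(report, "loss_report"))
  nrow(report$mapped) +
    sum(vapply(report$merged, function(m) length(m$paths), 0L)) +
    length(report$split) +
    length(report$source_unmapped_retained)
}

concat_loss_reports <- function(a, b) {
  loss_report(
    mapped = rbind(a$mapped, b$mapped),
    merged = c(a$merged, b$merged),
    split = c(a$split, b$split),
    source_unmapped_retained = c(a$source_unmapped_retained,
                                 b$source_unmapped_retained),
    target_null_filled = c(a$target_null_filled, b$target_null_filled))
}

#' Serialize a loss report to JSON
#'
#' Stable key order, suitable for CLI display and machine diffing.
#'
#' @param report A `loss_report`.
#' @return JSON string.
#' @export
loss_report_json <- function(report) {
  stopifnot(inherits(report, "loss_report"))
  doc <- list(
    mapped = lapply(seq_len(nrow(report$mapped)), function(i) {
      list(path = report$mapped$path[i],
           meaning_id = report$mapped$meaning_id[i])
    }),
    merged = lapply(report$merged, function(m) {
      list(paths = as.list(m$paths), meaning_id = m$meaning_id)
    }),
    split = lapply(report$split, function(s) {
      list(path = s$path, meaning_ids = as.list(s$meaning_ids))
    }),
    source_unmapped_retained = as.list(report$source_unmapped_retained),
    target_null_filled = as.list(report$target_null_filled))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE))
}

#' @export
print.loss_report <- function(x, ...) {
  cat("<loss_report>\n")
  cat("  mapped:            ", nrow(x$mapped), "\n", sep = "")
  cat("  merged:            ", length(x$merged), " rule application(s)\n",
      sep = "")
  cat("  split:             ", length(x$split), "\n", sep = "")
  cat("  retained (conv):   ", length(x$source_unmapped_retained), "\n",
      sep = "")
  cat("  target NULL-filled:", length(x$target_null_filled), "\n")
  invisible(x)
}

# ---- ISO 8601 guard --------------------------------------------------------
# FHIR Meta.lastUpdated and ODM AsOfDatetime guarantee ISO 8601 lexical
# forms; values on those paths are verified (never rewritten, so identity
# transformations stay byte-exact) and the flag records whether the
# guarantee held.

iso_guaranteed_paths <- c("Meta.lastUpdated", "ODM/AsOfDatetime")

is_iso8601 <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}(T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?([Zz]|[+-]\\d{2}:?\\d{2})?)?$",
        x)
}

# ---- ingest leg ------------------------------------------------------------

#' Map a format record into the convergence format
#'
#' Every source item ends up somewhere: merged through a merge rule, mapped
#' to its slot, fanned out to all meanings that share its path (the record
#' is then flagged ambiguous and the item reported as split), or retained
#' verbatim under a namespaced `ext:<format>:<path>` extension slot.
#' Convergence slots with no source contribution stay null. Unmapped input
#' is a reported outcome, never an error.
#'
#' @param record A `format_record`.
#' @param registry A validated `crosswalk_registry`.
#' @param schema Optional prebuilt schema (defaults to
#'   `build_schema(registry)`).
#' @return List with elements `record` (a `convergence_record`) and
#'   `report` (a `loss_report`).
#' @export
to_convergence <- function(record, registry, schema = NULL) {
  stopifnot(inherits(record, "format_record"),
            inherits(registry, "crosswalk_registry"))
  if (is.null(schema)) schema <- build_schema(registry)
  fmt <- record$format
  conv <- new_record(schema, provenance = fmt)
  items <- record$items
  consumed <- rep(FALSE, nrow(items))
  mapped <- list(); merged <- list(); split <- list()
  unmapped <- character(0)

  append_slot <- function(conv, id, value, path) {
    slot <- conv$slots[[id]]
    normalized <- slot$normalized ||
      (path %in% iso_guaranteed_paths && is_iso8601(value))
    conv$slots[[id]] <- list(value = c(slot$value, value),
                             source_paths = c(slot$source_paths, path),
                             normalized = normalized)
    conv
  }

  # merge rules first: the member paths are consumed as a group
  for (entry in registry$entries) {
    if (entry$cardinality[[fmt]] != "merge") next
    rule <- rule_for_entry(entry, fmt)
    idx <- which(!consumed & items$path %in% rule$paths)
    if (length(idx) == 0L) next
    parts <- rep(NA_character_, length(rule$paths))
    for (i in idx) {
      pos <- match(items$path[i], rule$paths)
      if (is.na(parts[pos])) parts[pos] <- items$value[i]
    }
    joined <- merge_join(rule, parts)
    conv <- conv_set(conv, entry$meaning_id, joined,
                     source_paths = items$path[idx])
    merged[[length(merged) + 1L]] <-
      list(paths = items$path[idx], meaning_id = entry$meaning_id)
    consumed[idx] <- TRUE
  }

  for (i in seq_len(nrow(items))) {
    if (consumed[i]) next
    path <- items$path[i]; value <- items$value[i]
    hits <- Filter(function(e) e$cardinality[[fmt]] != "merge",
                   lookup_by_format_path(registry, fmt, path))
    if (length(hits) == 0L) {
      id <- paste0("ext:", tolower(fmt), ":", path)
      slot <- conv$ext[[id]] %||%
        list(value = NULL, source_paths = character(0), normalized = FALSE)
      slot$value <- c(slot$value, value)
      slot$source_paths <- unique(c(slot$source_paths, path))
      conv$ext[[id]] <- slot
      unmapped <- c(unmapped, path)
      next
    }
    ids <- vapply(hits, `[[`, "", "meaning_id")
    for (id in ids) conv <- append_slot(conv, id, value, path)
    if (length(ids) == 1L) {
      mapped[[length(mapped) + 1L]] <-
        data.frame(path = path, meaning_id = ids, stringsAsFactors = FALSE)
    } else {
      split[[length(split) + 1L]] <- list(path = path, meaning_ids = ids)
      conv$ambiguous <- unique(c(conv$ambiguous, ids))
    }
  }

  report <- loss_report(
    mapped = if (length(mapped)) do.call(rbind, mapped) else NULL,
    merged = merged, split = split,
    source_unmapped_retained = unmapped)
  list(record = conv, report = report)
}

# ---- emission leg ----------------------------------------------------------

#' Emit a convergence record in a target format
#'
#' Every target path known to the registry is represented: populated when a
#' feeding slot is non-null, otherwise reported in `target_null_filled`
#' (serialization then omits it or leaves the cell empty, per dialect).
#' Slots with no home in the target -- including the extension slots and
#' the essential items the target cannot express -- are reported in
#' `source_unmapped_retained`: their values live on convergence-side only.
#' Identical values reaching one path from several meanings collapse to a
#' single item; differing values repeat where the dialect allows, otherwise
#' the first (registry order) wins.
#'
#' @param conv A `convergence_record`.
#' @param target Target format label.
#' @param registry A validated `crosswalk_registry`.
#' @return List with `record` (a `format_record`) and `report` (a
#'   `loss_report`). Never fails on missing source data: the target
#'   structure is always complete, NULL-filled.
#' @export
from_convergence <- function(conv, target, registry) {
  stopifnot(inherits(conv, "convergence_record"),
            inherits(registry, "crosswalk_registry"))
  fmt <- as_format_id(target)
  contributions <- list() # path -> list of list(values, meaning_id)
  order_seen <- character(0)
  retained <- character(0)
  mapped <- list(); merged <- list()

  contribute <- function(path, values, meaning_id) {
    if (!path %in% order_seen) order_seen <<- c(order_seen, path)
    contributions[[path]] <<- c(contributions[[path]],
                                list(list(values = values,
                                          meaning_id = meaning_id)))
  }

  for (entry in registry$entries) {
    id <- entry$meaning_id
    tpaths <- entry$slots[[fmt]]
    values <- conv$slots[[id]]$value
    if (length(tpaths) == 0L) {
      if (!is.null(values)) retained <- c(retained, id)
      next
    }
    if (is.null(values)) next
    if (entry$cardinality[[fmt]] == "merge") {
      rule <- rule_for_entry(entry, fmt)
      parts <- merge_split(rule, values[1])
      present <- which(!is.na(parts))
      for (k in present) contribute(tpaths[k], unname(parts[k]), id)
      if (length(present)) {
        merged[[length(merged) + 1L]] <-
          list(paths = tpaths[present], meaning_id = id)
      }
    } else {
      for (p in tpaths) contribute(p, values, id)
    }
  }

  # essential-only schema slots never have a format home
  essential_only <- setdiff(conv$schema$meaning_id, names(registry$entries))
  for (id in essential_only) {
    if (!is.null(conv$slots[[id]]$value)) retained <- c(retained, id)
  }
  retained <- c(retained, names(conv$ext))

  out_items <- list()
  merged_paths <- unique(unlist(lapply(merged, `[[`, "paths"),
                                use.names = FALSE))
  for (path in order_seen) {
    contribs <- contributions[[path]]
    vecs <- list(); srcs <- character(0)
    for (ct in contribs) {
      if (!any(vapply(vecs, identical, TRUE, y = ct$values))) {
        vecs[[length(vecs) + 1L]] <- ct$values
        srcs <- c(srcs, ct$meaning_id)
      }
    }
    values <- unlist(vecs, use.names = FALSE)
    if (!path_repeatable(fmt, path) && length(values) > 1L) {
      # non-repeatable path: first value (registry order) wins, the
      # conflicting meanings stay convergence-side
      retained <- c(retained, srcs[-1])
      values <- values[1]
      srcs <- srcs[1]
    }
    for (v in values) {
      out_items[[length(out_items) + 1L]] <-
        data.frame(path = path, value = v, stringsAsFactors = FALSE)
    }
    if (!path %in% merged_paths) {
      mapped[[length(mapped) + 1L]] <-
        data.frame(path = path, meaning_id = srcs[1],
                   stringsAsFactors = FALSE)
    }
  }

  null_filled <- setdiff(registry_paths(registry, fmt), order_seen)
  rec <- format_record(fmt, if (length(out_items)) do.call(rbind, out_items))
  report <- loss_report(
    mapped = if (length(mapped)) do.call(rbind, mapped) else NULL,
    merged = merged,
    source_unmapped_retained = unique(retained),
    target_null_filled = null_filled)
  list(record = rec, report = report)
}

#' Transform a native payload from one format to another
#'
#' Convenience composition: parse the source payload, map it into the
#' convergence format, emit the target format and serialize. The returned
#' loss report concatenates both legs.
#'
#' @param payload Source payload (in-memory object; see the adapter
#'   documentation for each dialect's shape).
#' @param source,target Format labels.
#' @param registry A validated `crosswalk_registry` (defaults to the
#'   packaged one).
#' @param lenient Retain unrecognized source locations (default) or drop
#'   them.
#' @return List with `payload` (target-native object), `record` (the
#'   intermediate `convergence_record`) and `report` (combined
#'   `loss_report`).
#' @export
#' @examples
#' reg <- load_registry()
#' omop <- list(cdm_source = data.frame(cdm_source_name = "UMG",
#'                                      cdm_source_abbreviation = "UMG"))
#' out <- transform_payload(omop, "omop", "openehr", reg)
#' out$payload
transform_payload <- function(payload, source, target, registry = NULL,
                              lenient = TRUE) {
  if (is.null(registry)) registry <- load_registry()
  src <- as_format_id(source); tgt <- as_format_id(target)
  rec <- parse_metadata(src, payload, lenient = lenient)
  leg1 <- to_convergence(rec, registry)
  leg2 <- from_convergence(leg1$record, tgt, registry)
  list(payload = serialize_metadata(tgt, leg2$record),
       record = leg1$record,
       report = concat_loss_reports(leg1$report, leg2$report))
}
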