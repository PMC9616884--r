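#' The four supported external metadata formats
#'
#' The crosswalk spans exactly four clinical data standards: the OMOP common
#' data model, openEHR, HL7 FHIR and CDISC ODM/Define-XML. The serialized
#' labels returned here are stable identifiers used throughout the package
#' (registry columns, CLI flags, loss reports).
#'
#' @return Character vector of the four format identifiers, in canonical
#'   order: `"OMOP"`, `"OPENEHR"`, `"FHIR"`, `"CDISC"`.
#' @export
#' @examples
#' mcx_formats()
mcx_formats <- function() {
  c("OMOP", "OPENEHR", "FHIR", "CDISC")
}

# Canonicalize a user-supplied format label ("omop", "openEHR", ...) to the
# registry identifier; errors listing the four valid labels.
as_format_id <- function(format) {
  if (length(format) != 1L || is.na(format) || !nzchar(format)) {
    stop("format must be a single non-empty string; one of: ",
         paste(mcx_formats(), collapse = ", "), call. = FALSE)
  }
  id <- toupper(gsub("[^A-Za-z]", "", format))
  if (!id %in% mcx_formats()) {
    stop("unknown format '", format, "'; must be one of: ",
         paste(mcx_formats(), collapse = ", "), call. = FALSE)
  }
  id
}

# Lookup aliases: printed-table typos and spelling variants accepted on
# lookup but never emitted. Names are the variant, values the canonical form.
mcx_slug_aliases <- c(
  lifecylce_state      = "lifecycle_state",
  consent_verifikation = "consent_verification"
)

mcx_path_aliases <- c(
  "resource_description:lifecylce_state" = "resource_description:lifecycle_state",
  "Meta.versionId"                       = "Meta.versionID"
)

# Normalize a priority-item label for matching: strip spaces, lowercase,
# map the Verifikation spelling. "SourceOriginal Contributor" and
# "DatalifecycleState" then match their canonical rows.
normalize_label <- function(x) {
  x <- tolower(gsub("[[:space:]]", "", x))
  gsub("verifikation", "verification", x, fixed = TRUE)
}

canonical_path <- function(path) {
  out <- unname(mcx_path_aliases[path])
  ifelse(is.na(out), path, out)
}

registry_file <- function(name, source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "registry", package = "metacrosswalk")
  }
  file.path(source, name)
}

read_registry_table <- function(path) {
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                      colClasses = "character", fill = TRUE,
                      blank.lines.skip = TRUE, strip.white = FALSE,
                      na.strings = NULL, fileEncoding = "UTF-8"),
    error = function(e) {
      stop("malformed registry file '", basename(path), "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (nrow(df) == 0L) {
    stop("registry file '", basename(path), "' contains no rows", call. = FALSE)
  }
  df
}

split_cell <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  trimws(strsplit(cell, "|", fixed = TRUE)[[1]])
}

#' Load the packaged metadata crosswalk and priority registries
#'
#' Reads the crosswalk table (one row per semantic meaning, with the item
#' path carried by each of the four formats), the essential-item priority
#' table (the 19 items a medical data integration centre requires, with
#' priority levels 1-3 and FAIR-principle tags) and the priority-to-path
#' matrix, and returns them as a validated registry object.
#'
#' The registry ships as three tab-delimited UTF-8 files under
#' `inst/extdata/registry/`; an alternative transcription can be supplied
#' via `source`. Loading fails, without returning a partial registry, when a
#' file is missing, empty or structurally malformed, or when a meaning
#' identifier is duplicated.
#'
#' @param source Optional directory containing `crosswalk.tsv`,
#'   `priorities.tsv` and `priority_matrix.tsv`. Defaults to the packaged
#'   registry.
#' @return A `crosswalk_registry` object with components `entries` (named
#'   list of crosswalk entries), `priority_items` (data frame of the 19
#'   essential items) and `priority_matrix` (named list mapping each item to
#'   its per-format paths).
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(reg$priority_items)
#' lookup_by_meaning(reg, "source_abbreviation")
load_registry <- function(source = NULL) {
  cw <- read_registry_table(registry_file("crosswalk.tsv", source))
  need <- c("meaning_id", "meaning_text", "omop", "openehr", "fhir", "cdisc")
  missing_cols <- setdiff(need, names(cw))
  if (length(missing_cols)) {
    stop("crosswalk.tsv is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"cardinality" %in% names(cw)) cw$cardinality <- ""
  dup <- cw$meaning_id[duplicated(cw$meaning_id)]
  if (length(dup)) {
    stop("duplicate meaning_id in crosswalk.tsv: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  entries <- vector("list", nrow(cw))
  names(entries) <- cw$meaning_id
  fmt_cols <- c(OMOP = "omop", OPENEHR = "openehr", FHIR = "fhir",
                CDISC = "cdisc")
  for (i in seq_len(nrow(cw))) {
    slots <- lapply(fmt_cols, function(col) split_cell(cw[[col]][i]))
    names(slots) <- names(fmt_cols)
    card <- c(OMOP = "one_to_one", OPENEHR = "one_to_one",
              FHIR = "one_to_one", CDISC = "one_to_one")
    spec <- split_cell(cw$cardinality[i])
    for (s in spec) {
      kv <- strsplit(s, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L) card[[as_format_id(kv[1])]] <- kv[2]
    }
    entries[[i]] <- structure(
      list(meaning_id = cw$meaning_id[i],
           meaning_text = cw$meaning_text[i],
           slots = slots,
           cardinality = card),
      class = "crosswalk_entry")
  }

  pr <- read_registry_table(registry_file("priorities.tsv", source))
  need_pr <- c("name", "priority", "description", "fair_tags",
               "metadata_class", "meaning_id")
  missing_pr <- setdiff(need_pr, names(pr))
  if (length(missing_pr)) {
    stop("priorities.tsv is missing column(s): ",
         paste(missing_pr, collapse = ", "), call. = FALSE)
  }
  priority_items <- data.frame(
    name = pr$name,
    priority = as.integer(pr$priority),
    description = pr$description,
    fair_tags = pr$fair_tags,
    metadata_class = pr$metadata_class,
    meaning_id = pr$meaning_id,
    mappable = pr$meaning_id %in% names(entries),
    stringsAsFactors = FALSE
  )

  pm <- read_registry_table(registry_file("priority_matrix.tsv", source))
  priority_matrix <- vector("list", nrow(pm))
  names(priority_matrix) <- pm$name
  for (i in seq_len(nrow(pm))) {
    slots <- lapply(fmt_cols, function(col) {
      if (col %in% names(pm)) canonical_path(split_cell(pm[[col]][i]))
      else character(0)
    })
    names(slots) <- names(fmt_cols)
    priority_matrix[[i]] <- slots
  }

  reg <- structure(
    list(entries = entries,
         priority_items = priority_items,
         priority_matrix = priority_matrix),
    class = "crosswalk_registry")

  rep_ok <- validate_registry(reg)
  if (nrow(rep_ok) > 0L) {
    stop("registry failed validation:\n  ",
         paste(rep_ok$message, collapse = "\n  "), call. = FALSE)
  }
  reg
}

#' Look up a crosswalk entry by its meaning identifier
#'
#' Absence is a value, not an error: an unknown slug returns `NULL`.
#' Spelling variants printed in the source tables (e.g. `lifecylce_state`)
#' are accepted as aliases of their corrected slugs.
#'
#' @param registry A `crosswalk_registry` from [load_registry()].
#' @param meaning_id Meaning slug, e.g. `"source_abbreviation"`.
#' @return The matching `crosswalk_entry`, or `NULL` when the slug is
#'   unknown.
#' @export
lookup_by_meaning <- function(registry, meaning_id) {
  stopifnot(inherits(registry, "crosswalk_registry"))
  id <- tolower(trimws(meaning_id))
  alias <- mcx_slug_aliases[id]
  if (!is.na(alias)) id <- unname(alias)
  # also accept the typo embedded inside a longer slug (data_lifecylce_state)
  id <- gsub("lifecylce", "lifecycle", id, fixed = TRUE)
  id <- gsub("verifikation", "verification", id, fixed = TRUE)
  registry$entries[[id]]
}

#' Find all crosswalk entries that carry a given format path
#'
#' One native path can serve several semantic meanings (Table-4 style reuse
#' of `metadata_concept_id` and `def:Origin`), so the result is a list.
#' Entries are returned in registry order.
#'
#' @inheritParams lookup_by_meaning
#' @param format One of the four format labels (case-insensitive).
#' @param path Item path in that format's dialect.
#' @return List of `crosswalk_entry` objects; empty list when no entry
#'   carries the path.
#' @export
lookup_by_format_path <- function(registry, format, path) {
  stopifnot(inherits(registry, "crosswalk_registry"))
  fmt <- as_format_id(format)
  p <- canonical_path(trimws(path))
  hits <- Filter(function(e) p %in% e$slots[[fmt]], registry$entries)
  unname(hits)
}

# All registry paths known for a format, in registry order, deduplicated.
registry_paths <- function(registry, format) {
  fmt <- as_format_id(format)
  unique(unlist(lapply(registry$entries, function(e) e$slots[[fmt]]),
                use.names = FALSE))
}

#' Validate a crosswalk registry against its structural invariants
#'
#' Checks every registry invariant and reports violations instead of
#' raising: each crosswalk entry has at least one non-empty format slot and
#' merge rules list at least two paths; meaning identifiers are unique; the
#' priority registry holds exactly 19 items with priorities in 1-3; every
#' priority-matrix path is resolvable as a slot of some crosswalk entry (or
#' the item is flagged standalone); and no (format, path, meaning) triple is
#' duplicated. The function is pure: it never modifies the registry and is
#' idempotent.
#'
#' @inheritParams lookup_by_meaning
#' @return A data frame with columns `where` and `message`, one row per
#'   violation; zero rows when the registry is valid (the packaged registry
#'   always validates clean).
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "crosswalk_registry"))
  viol <- list()
  add <- function(where, message) {
    viol[[length(viol) + 1L]] <<- data.frame(where = where, message = message,
                                             stringsAsFactors = FALSE)
  }

  ids <- vapply(registry$entries, `[[`, "", "meaning_id")
  if (anyDuplicated(ids)) {
    add("entries", paste0("duplicate meaning_id: ",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (e in registry$entries) {
    n_paths <- sum(lengths(e$slots))
    if (n_paths == 0L) {
      add(e$meaning_id, "crosswalk entry has all four format slots empty")
    }
    for (fmt in mcx_formats()) {
      paths <- e$slots[[fmt]]
      if (any(paths != trimws(paths))) {
        add(e$meaning_id, paste0(fmt, " path has leading/trailing whitespace"))
      }
      if (any(!nzchar(paths))) {
        add(e$meaning_id, paste0(fmt, " slot contains an empty path"))
      }
      if (e$cardinality[[fmt]] == "merge" && length(paths) < 2L) {
        add(e$meaning_id,
            paste0(fmt, " merge rule lists fewer than 2 paths"))
      }
    }
  }

  pi <- registry$priority_items
  if (nrow(pi) != 19L) {
    add("priority_items", paste0("expected 19 priority items, found ", nrow(pi)))
  }
  bad_pr <- !pi$priority %in% 1:3
  if (any(bad_pr)) {
    add("priority_items", paste0("priority outside {1,2,3} for: ",
                                 paste(pi$name[bad_pr], collapse = ", ")))
  }
  if (anyDuplicated(pi$name)) {
    add("priority_items", "duplicate priority item name")
  }

  # every priority-matrix path resolvable as a slot of some entry, unless the
  # item is standalone (meaning_id absent from the crosswalk => all cells empty)
  for (nm in names(registry$priority_matrix)) {
    slots <- registry$priority_matrix[[nm]]
    row <- pi[pi$name == nm, , drop = FALSE]
    standalone <- nrow(row) == 1L && !row$mappable
    for (fmt in mcx_formats()) {
      for (p in slots[[fmt]]) {
        if (standalone) {
          add(nm, "standalone priority item carries a matrix path")
        } else if (length(lookup_by_format_path(registry, fmt, p)) == 0L) {
          add(nm, paste0("matrix path not resolvable in crosswalk: ",
                         fmt, " ", p))
        }
      }
    }
  }

  # no duplicate (format, path, meaning_id) triples
  triples <- do.call(rbind, lapply(registry$entries, function(e) {
    do.call(rbind, lapply(mcx_formats(), function(fmt) {
      if (length(e$slots[[fmt]]) == 0L) return(NULL)
      data.frame(format = fmt, path = e$slots[[fmt]],
                 meaning_id = e$meaning_id, stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(triples) && anyDuplicated(triples)) {
    add("entries", "duplicate (format, path, meaning_id) triple")
  }

  if (length(viol) == 0L) {
    data.frame(where = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, viol)
  }
}

#' @export
print.crosswalk_entry <- function(x, ...) {
  cat("<crosswalk_entry> ", x$meaning_id, "\n", sep = "")
  cat("  meaning: ", x$meaning_text, "\n", sep = "")
  for (fmt in mcx_formats()) {
    paths <- x$slots[[fmt]]
    lbl <- if (length(paths)) paste(paths, collapse = " | ") else "-"
    card <- if (x$cardinality[[fmt]] != "one_to_one")
      paste0(" [", x$cardinality[[fmt]], "]") else ""
    cat(sprintf("  %-8s %s%s\n", fmt, lbl, card))
  }
  invisible(x)
}

#' @export
print.crosswalk_registry <- function(x, ...) {
  cat("<crosswalk_registry>\n")
  cat("  crosswalk entries: ", length(x$entries), "\n", sep = "")
  cat("  priority items:    ", nrow(x$priority_items),
      " (levels ", paste(sort(unique(x$priority_items$priority)),
                         collapse = "/"), ")\n", sep = "")
  cat("  formats:           ", paste(mcx_formats(), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# fair tags of one priority item as a character vector
fair_tags_of <- function(priority_items, name) {
  row <- priority_items[priority_items$name == name, , drop = FALSE]
  if (nrow(row) == 0L) return(character(0))
  tags <- row$fair_tags[1]
  if (!nzchar(tags)) return(character(0))
  trimws(strsplit(tags, ";", fixed = TRUE)[[1]])
}
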