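# openEHR adapter. The dialect's concrete syntax here is a flat JSON map of
# colon-delimited resource-description paths to scalar values; the standard
# itself does not prescribe a flat serialization, so the known-path list
# mirrors the resource_description / resource_description_item attributes
# named in the crosswalk.

openehr_known_paths <- c(
  "versionID", "name",
  "resource_description:parent_resource",
  "resource_description:original_author",
  "resource_description:original_publisher",
  "resource_description:lifecycle_state",
  "resource_description:copyright",
  "resource_description:references",
  "resource_description_item:language",
  "resource_description_item:use",
  "resource_description_item:purpose",
  "resource_description_item:original_resource")

parse_openehr <- function(payload, lenient = TRUE) {
  if (is.character(payload) && length(payload) == 1L) {
    payload <- jsonlite::fromJSON(payload, simplifyVector = FALSE)
  }
  if (!is.list(payload)) {
    stop("openEHR payload must be a flat path-to-value map (JSON object)",
         call. = FALSE)
  }
  if (length(payload) && is.null(names(payload))) {
    stop("openEHR payload map has unnamed elements", call. = FALSE)
  }
  items <- list(); unrecognized <- character(0); ignored <- character(0)
  aliased <- character(0)
  for (key in names(payload)) {
    v <- payload[[key]]
    if (is.null(v)) next
    if (length(v) != 1L || is.list(v)) {
      stop("openEHR path '", key, "' must carry a single scalar value",
           call. = FALSE)
    }
    path <- canonical_path(key)
    if (path != key) aliased <- c(aliased, key)
    if (!path %in% openehr_known_paths) {
      if (!lenient) { ignored <- c(ignored, path); next }
      unrecognized <- c(unrecognized, path)
    }
    items[[length(items) + 1L]] <-
      data.frame(path = path, value = as.character(v),
                 stringsAsFactors = FALSE)
  }
  format_record("OPENEHR", if (length(items)) do.call(rbind, items),
                dialect_meta = list(unrecognized = unique(unrecognized),
                                    ignored = unique(ignored),
                                    aliased = unique(aliased)))
}

serialize_openehr <- function(record) {
  items <- record$items
  if (anyDuplicated(items$path)) {
    stop("openEHR map cannot repeat path(s): ",
         paste(unique(items$path[duplicated(items$path)]), collapse = ", "),
         call. = FALSE)
  }
  out <- as.list(items$value)
  names(out) <- items$path
  out
}

read_openehr_payload <- function(path) {
  parse_json_file(path, "openEHR")
}

openehr_payload_text <- function(payload) {
  # stable, pretty JSON; keys in payload order
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                                null = "null"))
}

parse_json_file <- function(path, label) {
  if (!file.exists(path)) {
    stop(label, " payload file not found: ", path, call. = FALSE)
  }
  tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed ", label, " JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
}
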