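# FHIR adapter. The metadata subset sits in a single resource envelope
# (JSON): the Meta element (versionId, lastUpdated, profile) plus the
# dataset-level elements DataRequirement, RelatedArtifact, Contributor and
# UsageContext, all held as text. The crosswalk prints "Meta.versionID"
# while the FHIR standard spells the element "versionId": both are read,
# "versionId" is written, and the alias is noted in dialect_meta.

fhir_paths <- c("Meta.versionID", "Meta.lastUpdated", "Meta.profile",
                "DataRequirement", "DataRequirement.Profile",
                "DataRequirement.type", "RelatedArtifact", "Contributor",
                "UsageContext")

fhir_top_key <- c(DataRequirement = "dataRequirement",
                  RelatedArtifact = "relatedArtifact",
                  Contributor = "contributor",
                  UsageContext = "usageContext")

parse_fhir <- function(payload, lenient = TRUE) {
  if (is.character(payload) && length(payload) == 1L) {
    payload <- jsonlite::fromJSON(payload, simplifyVector = FALSE)
  }
  if (!is.list(payload)) {
    stop("FHIR payload must be a resource envelope (JSON object)",
         call. = FALSE)
  }
  items <- list(); unrecognized <- character(0); ignored <- character(0)
  meta <- list(versionId_alias = FALSE, data_requirement_text = FALSE)
  emit <- function(path, value) {
    items[[length(items) + 1L]] <<-
      data.frame(path = path, value = as.character(value),
                 stringsAsFactors = FALSE)
  }
  scalar <- function(v, where) {
    if (is.list(v) || length(v) != 1L) {
      stop("FHIR element '", where, "' must be a scalar", call. = FALSE)
    }
    as.character(v)
  }
  for (key in names(payload)) {
    v <- payload[[key]]
    if (is.null(v)) next
    if (key == "resourceType") {
      meta$resource_type <- scalar(v, key)
    } else if (key == "meta") {
      if (!is.list(v)) stop("FHIR meta must be an object", call. = FALSE)
      for (mk in names(v)) {
        mv <- v[[mk]]
        if (is.null(mv)) next
        if (mk %in% c("versionId", "versionID")) {
          if (mk == "versionID") meta$versionId_alias <- TRUE
          emit("Meta.versionID", scalar(mv, "meta.versionId"))
        } else if (mk == "lastUpdated") {
          emit("Meta.lastUpdated", scalar(mv, "meta.lastUpdated"))
        } else if (mk == "profile") {
          vals <- if (is.list(mv)) unlist(mv, use.names = FALSE) else mv
          for (p in vals) emit("Meta.profile", p)
        } else if (lenient) {
          unrecognized <- c(unrecognized, paste0("Meta.", mk))
          emit(paste0("Meta.", mk), scalar(mv, mk))
        } else {
          ignored <- c(ignored, paste0("Meta.", mk))
        }
      }
    } else if (key == "dataRequirement") {
      if (is.list(v)) {
        for (dk in names(v)) {
          dv <- v[[dk]]
          if (is.null(dv)) next
          if (dk == "text") {
            meta$data_requirement_text <- TRUE
            emit("DataRequirement", scalar(dv, "dataRequirement.text"))
          } else if (dk == "profile") {
            emit("DataRequirement.Profile", scalar(dv, dk))
          } else if (dk == "type") {
            emit("DataRequirement.type", scalar(dv, dk))
          } else if (lenient) {
            unrecognized <- c(unrecognized, paste0("DataRequirement.", dk))
            emit(paste0("DataRequirement.", dk), scalar(dv, dk))
          } else {
            ignored <- c(ignored, paste0("DataRequirement.", dk))
          }
        }
      } else {
        # bare element text: which child of DataRequirement carries the
        # creation date is unspecified, so the text is kept verbatim
        meta$data_requirement_text <- TRUE
        emit("DataRequirement", scalar(v, key))
      }
    } else if (key %in% fhir_top_key) {
      emit(names(fhir_top_key)[fhir_top_key == key], scalar(v, key))
    } else if (lenient) {
      unrecognized <- c(unrecognized, key)
      emit(key, scalar(v, key))
    } else {
      ignored <- c(ignored, key)
    }
  }
  meta$unrecognized <- unique(unrecognized)
  meta$ignored <- unique(ignored)
  format_record("FHIR", if (length(items)) do.call(rbind, items),
                dialect_meta = meta)
}

serialize_fhir <- function(record) {
  items <- record$items
  dup <- items$path[duplicated(items$path)]
  dup <- setdiff(unique(dup), "Meta.profile")
  if (length(dup)) {
    stop("FHIR element(s) cannot repeat: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- list(resourceType = record$dialect_meta$resource_type %||% "Basic")
  val1 <- function(path) {
    v <- items$value[items$path == path]
    if (length(v)) v[1] else NULL
  }
  meta <- list()
  if (!is.null(val1("Meta.versionID"))) meta$versionId <- val1("Meta.versionID")
  if (!is.null(val1("Meta.lastUpdated"))) meta$lastUpdated <- val1("Meta.lastUpdated")
  prof <- items$value[items$path == "Meta.profile"]
  if (length(prof)) meta$profile <- as.list(prof)
  if (length(meta)) out$meta <- meta

  dr <- list()
  if (!is.null(val1("DataRequirement"))) dr$text <- val1("DataRequirement")
  if (!is.null(val1("DataRequirement.Profile")))
    dr$profile <- val1("DataRequirement.Profile")
  if (!is.null(val1("DataRequirement.type")))
    dr$type <- val1("DataRequirement.type")
  if (length(dr)) {
    out$dataRequirement <-
      if (identical(names(dr), "text")) dr$text else dr
  }
  for (p in c("RelatedArtifact", "Contributor", "UsageContext")) {
    if (!is.null(val1(p))) out[[fhir_top_key[[p]]]] <- val1(p)
  }
  # unrecognized locations retained in lenient parses round-trip as-is
  known <- c(fhir_paths, "Meta.profile")
  extra <- items[!items$path %in% known, , drop = FALSE]
  for (i in seq_len(nrow(extra))) {
    p <- extra$path[i]
    if (startsWith(p, "Meta.")) {
      out$meta[[sub("^Meta\\.", "", p)]] <- extra$value[i]
    } else if (startsWith(p, "DataRequirement.")) {
      if (!is.list(out$dataRequirement)) {
        out$dataRequirement <- if (is.null(out$dataRequirement)) list()
                               else list(text = out$dataRequirement)
      }
      out$dataRequirement[[sub("^DataRequirement\\.", "", p)]] <- extra$value[i]
    } else {
      out[[p]] <- extra$value[i]
    }
  }
  out
}

read_fhir_payload <- function(path) {
  parse_json_file(path, "FHIR")
}

fhir_payload_text <- function(payload) {
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                                null = "null"))
}
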