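#' Parse the metadata subset of a native payload
#'
#' Dispatches to the dialect adapter for the given format and returns a
#' flat [format_record()]. Every recognized metadata location present in
#' the payload appears exactly once per occurrence, in payload document
#' order; unrecognized locations are retained with a flag in lenient mode
#' (the default) or dropped (and noted) in strict mode. Empty locations
#' never produce explicit-null items: nulls exist only convergence-side.
#'
#' Payload shapes per dialect:
#' \describe{
#'   \item{OMOP}{`list(metadata = <data frame>, cdm_source = <data frame>)`,
#'     either table optional; column names case-insensitive on read.}
#'   \item{OPENEHR}{flat named list (or JSON text) of colon-delimited paths
#'     to scalar values.}
#'   \item{FHIR}{resource envelope as a nested named list or JSON text.}
#'   \item{CDISC}{ODM XML as an `xml_document`, XML text or file path.}
#' }
#'
#' @param format Format label (case-insensitive).
#' @param payload Payload in the dialect's shape.
#' @param lenient Retain unrecognized locations (`TRUE`, default) or drop
#'   them.
#' @return A `format_record`.
#' @export
#' @examples
#' rec <- parse_metadata("omop",
#'   list(cdm_source = data.frame(cdm_source_name = "UMG")))
#' rec$items
parse_metadata <- function(format, payload, lenient = TRUE) {
  switch(as_format_id(format),
         OMOP = parse_omop(payload, lenient),
         OPENEHR = parse_openehr(payload, lenient),
         FHIR = parse_fhir(payload, lenient),
         CDISC = parse_cdisc(payload, lenient))
}

#' Serialize a format record back to its native payload
#'
#' Inverse of [parse_metadata()]: for any record, parsing the serialized
#' payload yields the record again item-for-item. Null-valued slots follow
#' each dialect's convention (OMOP: empty cell; openEHR/FHIR: key omitted;
#' CDISC: element/attribute omitted), so serialized payloads never carry
#' explicit nulls. An empty record serializes to the dialect's minimal
#' valid skeleton (OMOP tables with headers only; an ODM root with its
#' namespace).
#'
#' @param format Format label; must equal `record$format`.
#' @param record A `format_record`.
#' @return The native payload object (see [parse_metadata()] for shapes).
#' @export
serialize_metadata <- function(format, record) {
  fmt <- as_format_id(format)
  stopifnot(inherits(record, "format_record"))
  if (record$format != fmt) {
    stop("record is tagged ", record$format, ", cannot serialize as ", fmt,
         call. = FALSE)
  }
  switch(fmt,
         OMOP = serialize_omop(record),
         OPENEHR = serialize_openehr(record),
         FHIR = serialize_fhir(record),
         CDISC = serialize_cdisc(record))
}

#' Read / write a native payload from disk
#'
#' OMOP payloads live in a directory (`metadata.csv`, `cdm_source.csv`);
#' openEHR and FHIR payloads are single JSON files; CDISC payloads are
#' single ODM XML files. Writers are deterministic: the same payload
#' always produces the same bytes.
#'
#' @param format Format label.
#' @param path File (or, for OMOP, directory) path.
#' @param payload Native payload object.
#' @return `read_payload()`: the payload object; `write_payload()`: `path`,
#'   invisibly.
#' @export
read_payload <- function(format, path) {
  switch(as_format_id(format),
         OMOP = read_omop_payload(path),
         OPENEHR = read_openehr_payload(path),
         FHIR = read_fhir_payload(path),
         CDISC = read_cdisc_payload(path))
}

#' @rdname read_payload
#' @export
write_payload <- function(format, payload, path) {
  fmt <- as_format_id(format)
  if (fmt == "OMOP") return(write_omop_payload(payload, path))
  writeLines(payload_text(fmt, payload), path, useBytes = TRUE)
  invisible(path)
}

#' Canonical text rendering of a payload
#'
#' Used for deterministic on-disk output and byte-identity checks of the
#' fixture generator.
#'
#' @inheritParams read_payload
#' @param payload Native payload object.
#' @return Single string.
#' @export
payload_text <- function(format, payload) {
  switch(as_format_id(format),
         OMOP = omop_payload_text(payload),
         OPENEHR = openehr_payload_text(payload),
         FHIR = fhir_payload_text(payload),
         CDISC = cdisc_payload_text(payload))
}
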