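# CDISC adapter. One ODM v1.3-style XML document per payload: the root
# carries AsOfDatetime, Study/GlobalVariables/StudyDescription holds the
# study description, Study/MetaDataVersion carries the metadata version
# (OID) and its Name, and the def:-prefixed Define-XML items (Origin,
# AnnotatedCRF, LeafElement) attach as elements of one synthetic ItemDef
# container per record -- the crosswalk mixes ODM and Define-XML
# vocabularies without locating the def: items, and a single container
# keeps them addressable and repeatable. The Define-XML namespace is only
# declared when def: items are present.

odm_ns <- "http://www.cdisc.org/ns/odm/v1.3"
def_ns <- "http://www.cdisc.org/ns/def/v2.0"

cdisc_known_def <- c("def:Origin", "def:AnnotatedCRF", "def:LeafElement")

parse_cdisc <- function(payload, lenient = TRUE) {
  doc <- tryCatch({
    if (inherits(payload, "xml_document")) payload
    else xml2::read_xml(payload)
  }, error = function(e) {
    stop("CDISC payload is not well-formed XML: ", conditionMessage(e),
         call. = FALSE)
  })
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "ODM") {
    stop("CDISC payload root element must be ODM, found '",
         xml2::xml_name(root), "'", call. = FALSE)
  }
  items <- list(); unrecognized <- character(0); ignored <- character(0)
  emit <- function(path, value) {
    items[[length(items) + 1L]] <-
      data.frame(path = path, value = value, stringsAsFactors = FALSE)
    items <<- items
  }
  aod <- xml2::xml_attr(root, "AsOfDatetime")
  if (!is.na(aod)) emit("ODM/AsOfDatetime", aod)

  sd <- xml2::xml_find_first(
    root, "./*[local-name()='Study']/*[local-name()='GlobalVariables']/*[local-name()='StudyDescription']")
  if (!inherits(sd, "xml_missing")) emit("StudyDescription", xml2::xml_text(sd))

  mdv <- xml2::xml_find_first(
    root, "./*[local-name()='Study']/*[local-name()='MetaDataVersion']")
  if (!inherits(mdv, "xml_missing")) {
    oid <- xml2::xml_attr(mdv, "OID")
    if (!is.na(oid)) emit("ODM/Study/MetaDataVersion", oid)
    nm <- xml2::xml_attr(mdv, "Name")
    if (!is.na(nm)) emit("ODM/Study/MetaDataVersion/Name", nm)
    container <- xml2::xml_find_first(mdv, "./*[local-name()='ItemDef']")
    if (!inherits(container, "xml_missing")) {
      for (child in xml2::xml_children(container)) {
        path <- paste0("def:", xml2::xml_name(child))
        if (!path %in% cdisc_known_def) {
          if (!lenient) { ignored <- c(ignored, path); next }
          unrecognized <- c(unrecognized, path)
        }
        emit(path, xml2::xml_text(child))
      }
    }
  }
  format_record("CDISC", if (length(items)) do.call(rbind, items),
                dialect_meta = list(unrecognized = unique(unrecognized),
                                    ignored = unique(ignored)))
}

serialize_cdisc <- function(record) {
  items <- record$items
  singles <- c("ODM/AsOfDatetime", "StudyDescription",
               "ODM/Study/MetaDataVersion", "ODM/Study/MetaDataVersion/Name")
  dup <- intersect(unique(items$path[duplicated(items$path)]), singles)
  if (length(dup)) {
    stop("CDISC element(s) cannot repeat: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(items$path %in% singles | startsWith(items$path, "def:"))
  if (any(bad)) {
    stop("illegal CDISC path(s): ",
         paste(unique(items$path[bad]), collapse = ", "), call. = FALSE)
  }
  val1 <- function(path) {
    v <- items$value[items$path == path]
    if (length(v)) v[1] else NULL
  }
  def_items <- items[startsWith(items$path, "def:"), , drop = FALSE]

  attrs <- c(xmlns = odm_ns)
  if (nrow(def_items)) attrs <- c(attrs, "xmlns:def" = def_ns)
  if (!is.null(val1("ODM/AsOfDatetime"))) {
    attrs <- c(attrs, AsOfDatetime = val1("ODM/AsOfDatetime"))
  }
  attrs <- c(attrs, FileType = "Snapshot", FileOID = "metacrosswalk",
             ODMVersion = "1.3")
  root <- xml2::xml_new_root("ODM")
  for (a in names(attrs)) xml2::xml_set_attr(root, a, attrs[[a]])

  need_study <- !is.null(val1("StudyDescription")) ||
    !is.null(val1("ODM/Study/MetaDataVersion")) ||
    !is.null(val1("ODM/Study/MetaDataVersion/Name")) || nrow(def_items) > 0L
  if (need_study) {
    study <- xml2::xml_add_child(root, "Study", OID = "ST.1")
    if (!is.null(val1("StudyDescription"))) {
      gv <- xml2::xml_add_child(study, "GlobalVariables")
      xml2::xml_add_child(gv, "StudyDescription", val1("StudyDescription"))
    }
    need_mdv <- !is.null(val1("ODM/Study/MetaDataVersion")) ||
      !is.null(val1("ODM/Study/MetaDataVersion/Name")) || nrow(def_items) > 0L
    if (need_mdv) {
      mdv <- xml2::xml_add_child(study, "MetaDataVersion")
      if (!is.null(val1("ODM/Study/MetaDataVersion"))) {
        xml2::xml_set_attr(mdv, "OID", val1("ODM/Study/MetaDataVersion"))
      }
      if (!is.null(val1("ODM/Study/MetaDataVersion/Name"))) {
        xml2::xml_set_attr(mdv, "Name", val1("ODM/Study/MetaDataVersion/Name"))
      }
      if (nrow(def_items)) {
        container <- xml2::xml_add_child(mdv, "ItemDef", OID = "IT.META",
                                         Name = "metadata-container")
        for (i in seq_len(nrow(def_items))) {
          xml2::xml_add_child(container, def_items$path[i],
                              def_items$value[i])
        }
      }
    }
  }
  xml2::read_xml(as.character(root))
}

read_cdisc_payload <- function(path) {
  if (!file.exists(path)) {
    stop("CDISC payload file not found: ", path, call. = FALSE)
  }
  parse_cdisc_file_doc(path)
}

parse_cdisc_file_doc <- function(path) {
  tryCatch(xml2::read_xml(path), error = function(e) {
    stop("CDISC payload is not well-formed XML ('", path, "'): ",
         conditionMessage(e), call. = FALSE)
  })
}

cdisc_payload_text <- function(payload) {
  if (inherits(payload, "xml_document")) as.character(payload)
  else as.character(xml2::read_xml(payload))
}
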