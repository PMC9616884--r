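# OMOP CDM adapter: the metadata subset lives in two tables, METADATA and
# CDM_SOURCE, consumed and emitted as CSV (header mandatory) rather than a
# live database. Canonical column sets follow the CDM definition of the
# columns named in the crosswalk.

omop_metadata_cols <- c("metadata_concept_id", "metadata_type_concept_id",
                        "name", "value_as_string", "value_as_concept_id",
                        "metadata_date", "metadata_datetime")

omop_cdm_source_cols <- c("cdm_source_name", "cdm_source_abbreviation",
                          "cdm_holder", "source_description",
                          "source_description_reference")

empty_omop_table <- function(cols) {
  df <- as.data.frame(matrix(character(0), nrow = 0, ncol = length(cols)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

# one table -> items in payload document order (row-major, payload column
# order); column names matched case-insensitively, canonicalized on output
parse_omop_table <- function(df, table_name, canonical, lenient, state) {
  if (!is.data.frame(df)) {
    stop("OMOP ", table_name, " payload must be a data frame", call. = FALSE)
  }
  lc <- tolower(names(df))
  known <- canonical[match(lc, tolower(canonical))]
  if (all(is.na(known)) && ncol(df) > 0L) {
    stop("OMOP ", table_name, " table is missing every required column (",
         paste(canonical, collapse = ", "), ")", call. = FALSE)
  }
  for (r in seq_len(nrow(df))) {
    for (ci in seq_along(df)) {
      path <- known[ci]
      if (is.na(path)) {
        if (!lenient) {
          state$ignored <- c(state$ignored, names(df)[ci])
          next
        }
        path <- names(df)[ci]
        state$unrecognized <- c(state$unrecognized, path)
      }
      v <- df[[ci]][r]
      if (is.na(v) || !nzchar(as.character(v))) next # empty cell = NULL
      state$items[[length(state$items) + 1L]] <-
        data.frame(path = path, value = as.character(v),
                   table = table_name, row = r, stringsAsFactors = FALSE)
    }
  }
  state
}

parse_omop <- function(payload, lenient = TRUE) {
  if (!is.list(payload)) {
    stop("OMOP payload must be a list with elements 'metadata' and/or ",
         "'cdm_source'", call. = FALSE)
  }
  if (is.null(payload$metadata) && is.null(payload$cdm_source)) {
    stop("OMOP payload carries neither a metadata nor a cdm_source table",
         call. = FALSE)
  }
  state <- list(items = list(), unrecognized = character(0),
                ignored = character(0))
  if (!is.null(payload$metadata)) {
    state <- parse_omop_table(payload$metadata, "metadata",
                              omop_metadata_cols, lenient, state)
  }
  if (!is.null(payload$cdm_source)) {
    state <- parse_omop_table(payload$cdm_source, "cdm_source",
                              omop_cdm_source_cols, lenient, state)
  }
  items <- if (length(state$items)) do.call(rbind, state$items) else NULL
  format_record("OMOP", items,
                dialect_meta = list(unrecognized = unique(state$unrecognized),
                                    ignored = unique(state$ignored)))
}

serialize_omop <- function(record) {
  items <- record$items
  table_of <- function(path) {
    if (path %in% omop_metadata_cols) "metadata"
    else if (path %in% omop_cdm_source_cols) "cdm_source"
    else NA_character_
  }
  if (nrow(items)) {
    if (is.null(items$table)) items$table <- NA_character_
    guess <- vapply(items$path, table_of, "")
    items$table[is.na(items$table)] <- guess[is.na(items$table)]
    bad <- is.na(items$table)
    if (any(bad)) {
      stop("illegal OMOP path(s): ",
           paste(unique(items$path[bad]), collapse = ", "), call. = FALSE)
    }
  }
  build <- function(table_name, canonical) {
    sub <- items[nrow(items) > 0 & items$table == table_name, , drop = FALSE]
    extra <- setdiff(unique(sub$path), canonical)
    cols <- c(canonical, extra)
    if (nrow(sub) == 0L) return(empty_omop_table(canonical))
    # row placement: recorded row index when present, else occurrence order
    if (is.null(sub$row)) sub$row <- NA_integer_
    occ <- stats::ave(seq_len(nrow(sub)), sub$path, FUN = seq_along)
    sub$row[is.na(sub$row)] <- occ[is.na(sub$row)]
    n <- max(sub$row)
    df <- as.data.frame(matrix("", nrow = n, ncol = length(cols)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    for (i in seq_len(nrow(sub))) {
      df[sub$row[i], sub$path[i]] <- sub$value[i]
    }
    df
  }
  list(metadata = build("metadata", omop_metadata_cols),
       cdm_source = build("cdm_source", omop_cdm_source_cols))
}

read_omop_payload <- function(path) {
  if (!dir.exists(path)) {
    stop("OMOP payload path must be a directory holding metadata.csv ",
         "and/or cdm_source.csv: ", path, call. = FALSE)
  }
  read_one <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) return(NULL)
    utils::read.csv(fp, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8")
  }
  payload <- list(metadata = read_one("metadata.csv"),
                  cdm_source = read_one("cdm_source.csv"))
  if (is.null(payload$metadata) && is.null(payload$cdm_source)) {
    stop("no metadata.csv or cdm_source.csv found under ", path,
         call. = FALSE)
  }
  payload
}

write_omop_payload <- function(payload, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (is.null(payload$metadata)) payload$metadata <-
      empty_omop_table(omop_metadata_cols)
  if (is.null(payload$cdm_source)) payload$cdm_source <-
      empty_omop_table(omop_cdm_source_cols)
  utils::write.csv(payload$metadata, file.path(path, "metadata.csv"),
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  utils::write.csv(payload$cdm_source, file.path(path, "cdm_source.csv"),
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

omop_payload_text <- function(payload) {
  to_text <- function(df, cols) {
    if (is.null(df)) df <- empty_omop_table(cols)
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
    close(con)
    paste(out, collapse = "\n")
  }
  paste0("== metadata.csv ==\n",
         to_text(payload$metadata, omop_metadata_cols),
         "\n== cdm_source.csv ==\n",
         to_text(payload$cdm_source, omop_cdm_source_cols), "\n")
}
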