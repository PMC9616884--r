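test_that("recognized locations parse to one item per occurrence", {
  rec <- parse_metadata("omop", list(
    cdm_source = data.frame(cdm_source_name = "UMG Medical Center",
                            stringsAsFactors = FALSE)))
  expect_identical(rec$items$path, "cdm_source_name")
  expect_identical(rec$items$value, "UMG Medical Center")

  fhir <- parse_metadata("fhir", list(resourceType = "Basic",
                                      meta = list()))
  expect_identical(n_items(fhir), 0L)

  # datetime text is echoed unmodified
  odm <- paste0('<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" ',
                'AsOfDatetime="2022-10-28T00:00:00"/>')
  rec2 <- parse_metadata("cdisc", odm)
  expect_identical(rec2$items$path, "ODM/AsOfDatetime")
  expect_identical(rec2$items$value, "2022-10-28T00:00:00")
})

test_that("parse and serialize are inverse on generated fixtures", {
  profiles <- list(fixture_profile(1, fill_rate = 1, repeat_rate = 0),
                   fixture_profile(2, fill_rate = 0.5, repeat_rate = 0.5),
                   fixture_profile(3, fill_rate = 1, repeat_rate = 1,
                                   include_unmapped = TRUE))
  for (fmt in mcx_formats()) {
    for (pf in profiles) {
      payload <- generate_payload(fmt, pf, mcx_reg)
      rec <- parse_metadata(fmt, payload)
      rec2 <- parse_metadata(fmt, serialize_metadata(fmt, rec))
      expect_identical(rec2$items[c("path", "value")],
                       rec$items[c("path", "value")],
                       label = paste0(fmt, " seed ", pf$seed, " reparse"))
    }
  }
})

test_that("item order follows payload document order", {
  oe <- list("resource_description:copyright" = "CC-BY",
             "versionID" = "7",
             "resource_description:references" = "ref1")
  rec <- parse_metadata("openehr", oe)
  expect_identical(rec$items$path,
                   c("resource_description:copyright", "versionID",
                     "resource_description:references"))

  omop <- list(metadata = data.frame(
    metadata_date = c("2022-01-01", "2022-02-02"),
    metadata_concept_id = c("1", ""),
    stringsAsFactors = FALSE))
  rec2 <- parse_metadata("omop", omop)
  # row-major, payload column order; empty cells produce no item
  expect_identical(rec2$items$value, c("2022-01-01", "1", "2022-02-02"))
})

test_that("the OMOP reader accepts either table independently", {
  only_src <- parse_metadata("omop", list(
    cdm_source = data.frame(cdm_source_name = "A", cdm_holder = "B",
                            stringsAsFactors = FALSE)))
  expect_true(all(startsWith(only_src$items$path, "cdm_") |
                    only_src$items$path == "source_description"))

  expect_error(parse_metadata("omop", list()), "neither")
  expect_error(
    parse_metadata("omop", list(metadata = data.frame(bogus = "x"))),
    "missing every required column")
})

test_that("serializers refuse foreign records and illegal paths", {
  rec <- parse_metadata("openehr", list(versionID = "1"))
  expect_error(serialize_metadata("fhir", rec), "tagged OPENEHR")
  bad <- format_record("OMOP", data.frame(path = "not_a_column",
                                          value = "v",
                                          stringsAsFactors = FALSE))
  expect_error(serialize_metadata("omop", bad), "illegal OMOP path")
  dup <- format_record("OPENEHR",
                       data.frame(path = c("versionID", "versionID"),
                                  value = c("1", "2"),
                                  stringsAsFactors = FALSE))
  expect_error(serialize_metadata("openehr", dup), "repeat")
})

test_that("strict parsing drops unknown locations, lenient retains them", {
  oe <- list(versionID = "1", "resource_description:other_details" = "x")
  lenient <- parse_metadata("openehr", oe, lenient = TRUE)
  expect_identical(n_items(lenient), 2L)
  expect_identical(lenient$dialect_meta$unrecognized,
                   "resource_description:other_details")
  strict <- parse_metadata("openehr", oe, lenient = FALSE)
  expect_identical(n_items(strict), 1L)
  expect_identical(strict$dialect_meta$ignored,
                   "resource_description:other_details")
})

test_that("both FHIR versionId spellings read; the standard's is written", {
  a <- parse_metadata("fhir", list(meta = list(versionId = "5")))
  b <- parse_metadata("fhir", list(meta = list(versionID = "5")))
  expect_identical(a$items, b$items)
  expect_identical(a$items$path, "Meta.versionID")
  expect_true(b$dialect_meta$versionId_alias)
  out <- serialize_metadata("fhir", a)
  expect_identical(out$meta$versionId, "5")
  expect_null(out$meta$versionID)
})

test_that("malformed CDISC payloads fail with a located parse error", {
  expect_error(parse_metadata("cdisc", "<ODM><unclosed></ODM>"),
               "not well-formed")
  expect_error(parse_metadata("cdisc", "<NotODM/>"), "root element must be ODM")
})

test_that("empty records serialize to minimal parseable skeletons", {
  for (fmt in mcx_formats()) {
    skeleton <- serialize_metadata(fmt, format_record(fmt))
    rec <- parse_metadata(fmt, skeleton)
    expect_identical(n_items(rec), 0L, label = paste(fmt, "skeleton items"))
  }
  # OMOP skeleton still carries both headers
  sk <- serialize_metadata("OMOP", format_record("OMOP"))
  expect_identical(names(sk$metadata)[1], "metadata_concept_id")
  expect_identical(names(sk$cdm_source)[1], "cdm_source_name")
})

test_that("payloads survive a disk round-trip through read/write_payload", {
  tmp <- withr::local_tempdir()
  for (fmt in mcx_formats()) {
    payload <- generate_payload(fmt, fixture_profile(9, fill_rate = 0.8),
                                mcx_reg)
    path <- if (fmt == "OMOP") file.path(tmp, "omop")
            else file.path(tmp, paste0(tolower(fmt), ".pay"))
    write_payload(fmt, payload, path)
    back <- read_payload(fmt, path)
    expect_identical(parse_metadata(fmt, back)$items[c("path", "value")],
                     parse_metadata(fmt, payload)$items[c("path", "value")],
                     label = paste(fmt, "disk round-trip"))
  }
})
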