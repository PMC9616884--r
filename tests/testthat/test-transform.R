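test_that("ingest maps, merges and retains source items as specified", {
  omop <- parse_metadata("omop", list(
    cdm_source = data.frame(cdm_source_abbreviation = "UMG",
                            stringsAsFactors = FALSE)))
  res <- to_convergence(omop, mcx_reg, mcx_schema)
  expect_identical(conv_get(res$record, "source_abbreviation"), "UMG")
  expect_true("cdm_source_abbreviation" %in% res$report$mapped$path)

  oe <- parse_metadata("openehr", list(
    "resource_description:original_author" = "Smith",
    "resource_description:original_publisher" = "UMG Press"))
  res2 <- to_convergence(oe, mcx_reg, mcx_schema)
  joined <- conv_get(res2$record, "source_contributor")
  expect_identical(joined,
                   "original_author=Smith|original_publisher=UMG Press")
  expect_length(res2$report$merged, 1)
  expect_setequal(res2$report$merged[[1]]$paths,
                  c("resource_description:original_author",
                    "resource_description:original_publisher"))

  empty <- to_convergence(format_record("FHIR"), mcx_reg, mcx_schema)
  expect_identical(completeness(empty$record), 0)
  expect_identical(nrow(empty$report$mapped), 0L)
})

test_that("a reused source path feeds all its meanings and flags ambiguity", {
  rec <- parse_metadata("cdisc", paste0(
    '<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" ',
    'xmlns:def="http://www.cdisc.org/ns/def/v2.0">',
    '<Study OID="S"><MetaDataVersion><ItemDef OID="I" Name="n">',
    '<def:Origin>UMG</def:Origin>',
    '</ItemDef></MetaDataVersion></Study></ODM>'))
  res <- to_convergence(rec, mcx_reg, mcx_schema)
  expect_length(res$report$split, 1)
  fed <- res$report$split[[1]]$meaning_ids
  expect_true(all(c("source_name", "source_abbreviation",
                    "source_contributor") %in% fed))
  for (id in fed) expect_identical(conv_get(res$record, id), "UMG")
  expect_setequal(res$record$ambiguous, fed)
})

test_that("loss accounting conserves every source item", {
  for (fmt in mcx_formats()) {
    for (seed in fixture_seeds(12)) {
      pf <- fixture_profile(seed, fill_rate = (seed %% 4 + 1) / 4,
                            repeat_rate = 0.4,
                            include_unmapped = seed %% 2 == 0)
      rec <- parse_metadata(fmt, generate_payload(fmt, pf, mcx_reg))
      rep <- to_convergence(rec, mcx_reg, mcx_schema)$report
      expect_identical(accounted_items(rep), n_items(rec),
                       label = paste(fmt, "seed", seed, "conservation"))
    }
  }
})

test_that("unmapped source items are retained verbatim in extension slots", {
  oe <- parse_metadata("openehr",
                       list("resource_description:other_details" = "keep me"))
  res <- to_convergence(oe, mcx_reg, mcx_schema)
  expect_identical(res$report$source_unmapped_retained,
                   "resource_description:other_details")
  ext <- res$record$ext[["ext:openehr:resource_description:other_details"]]
  expect_identical(ext$value, "keep me")
  # and the extension survives document serialization
  back <- conv_from_json(conv_to_json(res$record), mcx_schema)
  expect_identical(
    back$ext[["ext:openehr:resource_description:other_details"]]$value,
    "keep me")
})

test_that("emission NULL-fills what the source cannot supply", {
  # an abbreviation has no home in openEHR: nothing emitted, value retained
  only_abbr <- make_conv("source_abbreviation", "UMG")
  res <- from_convergence(only_abbr, "OPENEHR", mcx_reg)
  expect_identical(n_items(res$record), 0L)
  expect_true("source_abbreviation" %in% res$report$source_unmapped_retained)

  # lifecycle state has no OMOP path
  lc <- make_conv("data_lifecycle_state", "creation")
  res2 <- from_convergence(lc, "OMOP", mcx_reg)
  expect_identical(n_items(res2$record), 0L)
  expect_true("data_lifecycle_state" %in%
                res2$report$source_unmapped_retained)

  # all-null record: complete target structure, every path NULL-filled
  res3 <- from_convergence(new_record(mcx_schema), "FHIR", mcx_reg)
  expect_identical(n_items(res3$record), 0L)
  expect_setequal(res3$report$target_null_filled,
                  c("Meta.versionID", "Meta.lastUpdated", "Meta.profile",
                    "DataRequirement", "DataRequirement.Profile",
                    "DataRequirement.type", "RelatedArtifact", "Contributor",
                    "UsageContext"))
})

test_that("emitted and NULL-filled paths exactly tile the target dialect", {
  for (fmt in mcx_formats()) {
    for (tgt in mcx_formats()) {
      pf <- fixture_profile(5, fill_rate = 0.6, repeat_rate = 0.3)
      rec <- parse_metadata(fmt, generate_payload(fmt, pf, mcx_reg))
      conv <- to_convergence(rec, mcx_reg, mcx_schema)$record
      res <- from_convergence(conv, tgt, mcx_reg)
      emitted <- unique(res$record$items$path)
      nulled <- res$report$target_null_filled
      all_paths <- unique(unlist(lapply(mcx_reg$entries,
                                        function(e) e$slots[[tgt]])))
      expect_length(intersect(emitted, nulled), 0)
      expect_setequal(c(emitted, nulled), all_paths)
    }
  }
})

test_that("identity transformation is lossless for registry-mapped items", {
  for (fmt in mcx_formats()) {
    for (seed in fixture_seeds(8)) {
      pf <- fixture_profile(seed, fill_rate = 0.8, repeat_rate = 0.4)
      payload <- generate_payload(fmt, pf, mcx_reg)
      out <- transform_payload(payload, fmt, fmt, mcx_reg)
      orig <- parse_metadata(fmt, payload)$items[c("path", "value")]
      got <- parse_metadata(fmt, out$payload)$items[c("path", "value")]
      key <- function(d) sort(paste(d$path, d$value, sep = "\r"))
      expect_identical(key(got), key(orig),
                       label = paste(fmt, "seed", seed, "identity items"))
    }
  }
})

test_that("mapped values relocate across formats with their meaning", {
  omop <- list(cdm_source = data.frame(cdm_source_name = "UMG Source",
                                       stringsAsFactors = FALSE))
  res <- transform_payload(omop, "omop", "openehr", mcx_reg)
  expect_identical(res$payload[["resource_description:parent_resource"]],
                   "UMG Source")

  # the openEHR contributor pair reconstructs from the OMOP holder column
  oe <- list("resource_description:original_author" = "Smith",
             "resource_description:original_publisher" = "UMG Press")
  via_omop <- transform_payload(oe, "openehr", "omop", mcx_reg)
  holder <- via_omop$payload$cdm_source$cdm_holder
  back <- transform_payload(via_omop$payload, "omop", "openehr", mcx_reg)
  expect_identical(back$payload[["resource_description:original_author"]],
                   "Smith")
  expect_identical(back$payload[["resource_description:original_publisher"]],
                   "UMG Press")
  expect_true(nzchar(holder))
})

test_that("two-leg round trips preserve items mapped in both directions", {
  # a path is round-trip-safe when it maps through exactly one meaning,
  # that meaning has exactly one target path, and the target path maps
  # back to that meaning alone (no fan-in/fan-out, no merges): reused
  # paths like def:Origin are ambiguous by design and may land elsewhere
  mapped_both <- function(path, s, t) {
    fwd <- lookup_by_format_path(mcx_reg, s, path)
    if (length(fwd) != 1L) return(FALSE)
    e <- fwd[[1]]
    if (e$cardinality[[s]] == "merge" || e$cardinality[[t]] == "merge") {
      return(FALSE)
    }
    tpaths <- e$slots[[t]]
    if (length(tpaths) != 1L) return(FALSE)
    back <- lookup_by_format_path(mcx_reg, t, tpaths)
    length(back) == 1L && identical(back[[1]]$meaning_id, e$meaning_id)
  }
  pairs <- expand.grid(s = mcx_formats(), t = mcx_formats(),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$s[i]; t <- pairs$t[i]
    for (seed in fixture_seeds(3)) {
      payload <- generate_payload(s, fixture_profile(seed, fill_rate = 0.7,
                                                     repeat_rate = 0),
                                  mcx_reg)
      there <- transform_payload(payload, s, t, mcx_reg)
      back <- transform_payload(there$payload, t, s, mcx_reg)
      orig <- parse_metadata(s, payload)$items
      final <- parse_metadata(s, back$payload)$items
      keep <- vapply(orig$path, mapped_both, TRUE, s = s, t = t)
      want <- paste(orig$path[keep], orig$value[keep], sep = "\r")
      have <- paste(final$path, final$value, sep = "\r")
      expect_true(all(want %in% have),
                  label = paste(s, "->", t, "->", s, "seed", seed,
                                "preserves two-way-mapped items"))
    }
  }
})

test_that("the merge codec is an exact inverse, including escapes", {
  rule <- merge_rule("source_contributor", c("p:author", "p:publisher"),
                     qualifiers = c("author", "publisher"))
  joined <- merge_join(rule, c("Smith", "UMG Press"))
  expect_identical(joined, "author=Smith|publisher=UMG Press")
  expect_identical(unname(merge_split(rule, joined)),
                   c("Smith", "UMG Press"))

  tricky <- merge_join(rule, c("a|b", "c"))
  expect_identical(unname(merge_split(rule, tricky)), c("a|b", "c"))

  set.seed(99)
  alphabet <- c(letters, "|", "=", "\\", " ", "0", ";")
  for (i in 1:60) {
    parts <- vapply(1:2, function(j) {
      paste(sample(alphabet, sample(0:12, 1), replace = TRUE),
            collapse = "")
    }, "")
    parts[parts == ""] <- "z" # empty and NA differ; keep parts non-empty
    if (i %% 5 == 0) parts[1] <- NA_character_
    got <- unname(merge_split(rule, merge_join(rule, parts)))
    expect_identical(got, parts, label = paste("fuzz case", i))
  }

  expect_error(merge_join(rule, "only-one"), "expected 2 part")
  # a foreign (unqualified) value lands on the first role
  expect_identical(unname(merge_split(rule, "plain text")),
                   c("plain text", NA))
})
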