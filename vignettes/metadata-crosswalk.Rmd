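---
title: "A registry-driven metadata crosswalk for OMOP, openEHR, FHIR and CDISC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A registry-driven metadata crosswalk for OMOP, openEHR, FHIR and CDISC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacrosswalk)
```

## The problem

A Medical Data Integration Center (MeDIC) joins clinical routine data and
research databases into one warehouse and must hand metadata back to
researchers in whichever standard they work in. The four standards in play
— the OMOP common data model, openEHR, HL7 FHIR and CDISC ODM/Define-XML —
grew for different purposes (database unification, EHR storage, exchange,
study documentation) and therefore carry dataset-level metadata in
mutually untranslatable places. No single one of them covers everything a
MeDIC needs, so any fixed target format loses information. This package
implements the alternative: a *crosswalk* of semantic meanings across the
four formats, a maximum-set *convergence format* defined as the union of
all crosswalk meanings with the MeDIC's essential items, fully accounted
transformations through that convergence format, and coverage/FAIR scoring
of the formats against the essential items.

## The registry

Three tab-delimited files under `inst/extdata/registry/` are the single
source of truth; they are transcriptions of published comparison tables,
kept as plain text so that every cell is diff-able and citable.

* `crosswalk.tsv` — 18 entries, one per semantic meaning, with the native
  path(s) of each format (empty cell = the format cannot express the
  meaning) and per-format cardinality rules. Multiple paths in one cell
  are `|`-separated. The only packaged merge rule is the openEHR
  contributor pair (`resource_description:original_author` +
  `resource_description:original_publisher`).
* `priorities.tsv` — the 19 essential items with priority level (1 = vital
  for operating the centre, 2 = data privacy and consent, 3 = additional
  context and language), description, FAIR tags and an
  intrinsic/provenance class. Seven of the 19 (the four consent items,
  reference metadata, source-system version, vesting period) have no
  native path in any format and are carried as standalone
  (`unmappable`) priority items rather than empty crosswalk rows — a
  crosswalk row with four empty slots would violate the registry's own
  invariants and add nothing.
* `priority_matrix.tsv` — the item-by-format path matrix from which the
  coverage matrix is computed.

Two transcription details are deliberate. First, the published tables
contain spelling variants (`lifecylce_state`, `ConsentVerifikation`,
spaced names such as `SourceOriginal Contributor`); the registry stores
corrected canonical forms and accepts the variants as lookup aliases, so
neither spelling is ever a silent miss. Second, the "name of the metadata
version" meaning is carried by a bare `name` column/path that exists in
both the OMOP `METADATA` table and the openEHR description; the entry
registers it in both slots rather than guessing a single owner.

The registry is validated on load (exactly 19 priority items, priorities
within 1–3, no empty entries, merge rules with at least two paths, every
matrix path resolvable, no duplicate format/path/meaning triples), and
`validate_registry()` re-runs the same checks as a pure report.

## The convergence format

`build_schema()` forms the union of crosswalk meanings and essential
items, deduplicated by slug: 18 + 19 with 12 shared gives 25 convergence
items. Values are stored as text with a declared value-kind hint (date,
datetime, identifier, text) because the four dialects disagree on lexical
forms; no eager coercion is done. For the two paths whose dialect
guarantees ISO 8601 (`Meta.lastUpdated`, `ODM/AsOfDatetime`) ingest
*verifies* the form and records the result in a `normalized` flag but
never rewrites the value — rewriting would break byte-exactness of
identity transformations for the sake of a cosmetic change.

A convergence record serializes to one flat JSON object (slug →
`{value, source_paths, normalized}`) in schema order with extension slots
sorted after; the key order is fixed, so serialization round-trips
byte-identically. Re-ingesting the same payload is idempotent: a slot's
(provenance, meaning, value) triple never duplicates.

## Transformation semantics

`to_convergence()` classifies every source item into exactly one of four
outcomes — merged (through a merge rule), mapped (unique meaning), split
(the path serves several meanings; all are fed and the record is flagged
ambiguous), or retained (no meaning: the value is kept verbatim under
`ext:<format>:<path>`). This exhaustiveness is the conservation invariant
the tests and the acceptance battery check on every fixture.

The reuse of native paths by several meanings is genuine in the source
material (`metadata_concept_id` serves both the metadata identifier and
version; `def:Origin` serves five meanings) and no disambiguation rule is
published, so the engine feeds *all* candidate meanings. On emission,
identical values converging on one target path collapse to a single item;
genuinely different values repeat where the dialect allows repetition
(OMOP rows, `Meta.profile`, `def:*` elements) and otherwise the first
contribution in registry order wins, with the losing meanings reported as
retained. This is the one place a round trip can relocate (never lose) a
value, and it only arises for the deliberately ambiguous paths.

`from_convergence()` NULL-fills: every registry path of the target is
either populated or listed in `target_null_filled`, and the serializers
realize NULL as the dialect's natural absence — an empty OMOP cell, an
omitted openEHR/FHIR key, an omitted CDISC element. Parsers consequently
never produce explicit-null items; nulls exist only convergence-side.
Convergence slots with no home in the target (the essential-only items,
extension slots, and meanings absent from the target format) are reported
in the retained list: the loss report has exactly five lists, and
"retained on the convergence side" is the same fate whether the value
arrived unmapped or cannot leave.

The merge codec encodes parts as `qualifier=value` pairs joined by `|`,
with backslash escaping of the delimiter, `=` and the escape character;
`NA` parts are omitted and recovered as `NA`. Reversibility is the
requirement, the syntax is a package convention. A value reaching a merge
slot from a format without the merge (e.g. OMOP's single `cdm_holder`
column) is not in qualifier syntax and is assigned to the first role on
emission.

## Dialect adapters

Each adapter covers exactly the metadata subset named in the crosswalk —
deliberately not full-standard validation. OMOP is consumed and emitted as
two CSV tables (`metadata.csv`, `cdm_source.csv`) with case-insensitive
headers on read and canonical headers on write. openEHR uses a flat JSON
path→value map (the source material gives paths, not a serialization).
FHIR uses one JSON resource envelope; the published `Meta.versionID`
spelling and the standard's `versionId` are both read, `versionId` is
written, and the alias is flagged. The element of `DataRequirement`
carrying the creation date is unspecified upstream, so the adapter keeps
the element's bare text verbatim and flags it. CDISC uses one ODM-style
XML document; the `def:`-prefixed Define-XML items attach as repeatable
elements of a single synthetic `ItemDef` container under
`MetaDataVersion`, since the source vocabulary mixes ODM and Define-XML
without locating them, and `StudyDescription` sits in its conventional
`GlobalVariables` position. The Define-XML namespace is declared only when
`def:` items are present.

All parsers run lenient by default (unknown locations retained and
flagged; strict mode drops and notes them), keep payload document order,
and satisfy parse∘serialize identity on items.

## Scoring and FAIR checking

The coverage matrix (19 × 4 logical) is a pure function of the registry.
The primary score is the per-priority-level count of covered items, which
is what "covers priority categories 1 and 2 as extensively as possible"
asks for; because no canonical weighting of the three levels is published,
the weighted sum is optional and clearly a package convention, defaulting
to 3/2/1. Weights never change the counts.

The FAIR checker reports exactly six verdicts for the metadata-facing
principles. F1, F3, I3 and R1.1 test concrete slots (`metadata_id`
non-blank; `affiliate_dataset_id`; `reference_metadata` or
`reference_data`; `usage_license_copyright`). F4 and A2 are
structural/organizational — a normalized convergence record is always
serializable to the indexable convergence document, and always exists
independently of data payloads — so they are reported as informational
passes with their reasons rather than silently omitted, keeping the
verdict count at six and the verdicts mutually independent.

## The fixture generator

`generate_payload()` produces small, dialect-valid payloads entirely from
a seed: a chosen fraction (`fill_rate`, default 0.75) of the format's
registry paths, readable values tagged with the seed, ISO 8601 forms on
date/datetime paths, optional repeats where the dialect allows them
(`repeat_rate`, default 0.25) and optionally one dialect-legal unknown
location to exercise extension-slot retention. The defaults emulate the
realistic middle ground of a partially documented source system: most but
not all metadata present, occasional repeated origins/profiles.

What the generator does *not* emulate bounds what green tests show about
real data: values are synthetic strings, not terminology-bound codes
(concept-id resolution is out of scope); FHIR payloads are single flat
envelopes, not bundles; CDISC payloads are metadata skeletons, not full
study definitions; and no malformed-but-plausible real-world payloads are
produced beyond the explicit error-case tests. The suites demonstrate
structural losslessness and accounting, not semantic correctness of
source values.

## Problem sizes and numerical choices

The test suite runs the property checks (conservation, round-trip,
NULL-fill tiling, identity losslessness) over seeded fixture batteries of
12 seeds per format, and the acceptance script over 100 seeds per format
with fill rates cycling through 0.25/0.5/0.75/1 and repeat rates
0/0.3/0.6; the merge codec is fuzzed over 200 random strings drawn from an
alphabet that includes the delimiter, the qualifier separator and the
escape character. These sizes were chosen to exercise every code path and
cardinality combination several times over while keeping the whole suite
in the tens of seconds. All randomness is seeded; the generator restores
the caller's RNG state.

Degenerate inputs are defined, not accidental: an empty payload parses to
a zero-item record and emits the dialect's minimal skeleton; an all-null
convergence record emits a complete, fully NULL-filled target; a
completeness query whose priority filter matches no slot returns `NaN`
(an undefined ratio, deliberately distinct from 0); absence in a meaning
lookup is `NULL`, not an error, while addressing an unknown convergence
slot raises a distinct condition class.

## Known limitations

* Only structural relocation of values: no vocabulary, unit or concept-id
  translation.
* The crosswalk ships the published excerpt plus the priority matrix; a
  fuller upstream crosswalk table can be dropped in via
  `load_registry(source = ...)` without code changes, and the registry row
  count is therefore not fixed.
* Ambiguous path reuse is resolved by fan-out and registry-order
  preference, which is deterministic but not semantically informed.
* Extension slots survive convergence-side only; they are not re-emitted
  into native payloads, including on identity transformations.
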