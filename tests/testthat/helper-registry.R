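# Shared fixtures: the packaged registry and schema, loaded once per run,
# plus independent oracle readers that go straight to the shipped TSV files
# (never through the registry loader) so that counting checks stay
# independent of the code paths they verify.

mcx_reg <- load_registry()
mcx_schema <- build_schema(mcx_reg)

registry_dir <- system.file("extdata", "registry", package = "metacrosswalk")

# raw table readers, independent of load_registry()
oracle_read <- function(file) {
  utils::read.delim(file.path(registry_dir, file), sep = "\t",
                    colClasses = "character", na.strings = NULL,
                    quote = "", fileEncoding = "UTF-8")
}

# hand-count oracle: priority partition straight from priorities.tsv
oracle_priority_counts <- function() {
  pr <- oracle_read("priorities.tsv")
  as.integer(table(factor(pr$priority, levels = c("1", "2", "3"))))
}

# hand-count oracle: per-format covered items straight from the matrix file
oracle_coverage_totals <- function() {
  pm <- oracle_read("priority_matrix.tsv")
  vapply(c("omop", "openehr", "fhir", "cdisc"), function(col) {
    if (!col %in% names(pm)) return(0L)
    sum(nzchar(trimws(pm[[col]])))
  }, integer(1))
}

# set-union oracle for the convergence schema size
oracle_schema_size <- function() {
  cw <- oracle_read("crosswalk.tsv")
  pr <- oracle_read("priorities.tsv")
  length(union(cw$meaning_id, pr$meaning_id))
}

# a convergence record with the given slots filled
make_conv <- function(filled = character(0), value = "x") {
  rec <- new_record(mcx_schema)
  for (id in filled) rec <- conv_set(rec, id, value)
  rec
}

# copy the packaged registry into a temp dir, optionally rewriting a file
local_registry_dir <- function(env = parent.frame()) {
  dir <- tempfile("registry")
  dir.create(dir)
  file.copy(list.files(registry_dir, full.names = TRUE), dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}

fixture_seeds <- function(n) seq_len(n) * 13L + 1L

fair_principles_vec <- c("F1", "F3", "F4", "A2", "I3", "R1.1")

# every native path a format contributes to the crosswalk
registry_paths_of <- function(fmt) {
  unique(unlist(lapply(mcx_reg$entries, function(e) e$slots[[fmt]]),
                use.names = FALSE))
}
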