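# Shared fixtures and independent oracles.

# the fixture knowledge base is immutable; build it once per test run
FIX <- fixture_kb()

# Independent parse of the verbatim gene-drug registry transcription
# (tests/testthat/table1.tsv): returns a data.frame of (gene, drug) pairs
# with lowercase drug names, qualifiers stripped but retained.
parse_registry_transcription <- function(path = test_path("table1.tsv")) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    drugs <- trimws(strsplit(raw$Drugs[i], ",", fixed = TRUE)[[1]])
    qual <- ifelse(grepl("\\(", drugs),
                   sub("^.*\\(([^)]*)\\).*$", "\\1", drugs), NA_character_)
    name <- tolower(trimws(sub("\\s*\\([^)]*\\)", "", drugs)))
    data.frame(gene = raw$Gene[i], drug = name, allele_qualifier = qual,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Independent phenoconversion truth table, coded directly from the four
# adjustment sentences: moderate inhibitor -> next lower activity phenotype;
# strong inhibitor -> poor metabolizer regardless of inferred phenotype;
# inducer -> next higher activity phenotype; no adjustment for poor
# metabolizers with inhibitors or ultrarapid (top-of-scale) metabolizers with
# inducers; inhibitor + inducer together -> no conversion; weak inhibitors
# and substrates alone never adjust. Returns the expected converted term
# (NA when no conversion applies).
oracle_phenoconvert <- function(scale, term_or_sentinel, weak, moderate,
                                strong, inducer) {
  if (term_or_sentinel %in% c("indeterminate", "unknown")) return(NA_character_)
  idx <- match(term_or_sentinel, scale)
  triggering_inhibitor <- moderate || strong
  if (triggering_inhibitor && inducer) return(NA_character_)
  if (strong) {
    if (idx == 1L) return(NA_character_)  # already poor
    return(scale[1])
  }
  if (moderate) {
    if (idx == 1L) return(NA_character_)
    return(scale[idx - 1L])
  }
  if (inducer) {
    if (idx == length(scale)) return(NA_character_)
    return(scale[idx + 1L])
  }
  NA_character_
}

# construct a synthetic interaction profile without consulting the catalog
make_profile <- function(gene, weak = character(0), moderate = character(0),
                         strong = character(0), inducers = character(0),
                         substrates = character(0)) {
  structure(list(gene = gene, substrates = substrates,
                 weak_inhibitors = weak, moderate_inhibitors = moderate,
                 strong_inhibitors = strong, inducers = inducers),
            class = "pgx_interaction_profile")
}

# write a patient document to a temp file and parse it back
patient_from_list <- function(doc) {
  path <- withr::local_tempfile(fileext = ".json", .local_envir = parent.frame())
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  parse_patient_input(path)
}

example_patient <- function() {
  patient_from_list(list(
    genotypes = list(
      list(gene = "CYP2D6", value = "*1/*2", note = "reported by external lab"),
      list(gene = "CYP2C19", value = "*1/*2"),
      list(gene = "CYP2C9", value = "*1/*3"),
      list(gene = "VKORC1", value = "-1639G>A A/G"),
      list(gene = "HLA-B", value = "*57:01 negative")
    ),
    current_medications = list("paroxetine", "rifampin"),
    considered_medications = list("codeine", "warfarin", "abacavir")
  ))
}

# a diplotype mapped in the fixture for every gene, for fully-genotyped runs
full_genotype_patient <- function() {
  patient_from_list(list(
    genotypes = list(
      list(gene = "CYP2B6", value = "*1/*6"),
      list(gene = "CYP2C19", value = "*1/*2"),
      list(gene = "CYP2C9", value = "*1/*3"),
      list(gene = "CYP2D6", value = "*1/*4"),
      list(gene = "CYP3A5", value = "*1/*3"),
      list(gene = "HLA-A", value = "*31:01 negative"),
      list(gene = "HLA-B", value = "*15:02 positive"),
      list(gene = "NUDT15", value = "*1/*3"),
      list(gene = "SLCO1B1", value = "*1/*5"),
      list(gene = "TPMT", value = "*1/*3A"),
      list(gene = "VKORC1", value = "A/G")
    ),
    current_medications = list(),
    considered_medications = list()
  ))
}
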