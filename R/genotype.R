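# Patient-input parsing and normalization: star-allele diplotypes, HLA
# presence calls, named-variant genotypes, and medication lists.

STAR_ALLELE_RE <- "^\\*([0-9]+)([A-Z]?)(?:x([0-9]+|N))?$"
HLA_ALLELE_RE <- "^\\*?([0-9]+:[0-9]+)$"

#' Normalize a raw genotype string into a canonical diplotype key
#'
#' Canonicalization depends on the gene's input mode:
#' \describe{
#'   \item{star_diplotype}{`"a/b"`; each allele must look like `*N`, with an
#'     optional single-letter subvariant (`*3A`) and optional copy-number
#'     suffix (`*1x2`, `*1xN`). Alleles are sorted numerically, then by
#'     subvariant letter, then by copy number, so lookup is insensitive to
#'     allele order: `"*2/*1"` and `"*1/*2"` both canonicalize to `"*1/*2"`.}
#'   \item{hla_presence}{`"<allele> positive|negative"`, e.g.
#'     `"*57:01 positive"`. Accepted status spellings: pos/positive/+/present
#'     and neg/negative/-/absent; the leading `*` on the allele is optional.}
#'   \item{variant_genotype}{A sorted base pair such as `"A/G"`; an optional
#'     leading variant label (e.g. `-1639G>A A/G`) is discarded.}
#' }
#'
#' @param gene_def Gene definition from [kb_gene()].
#' @param raw Raw genotype string as supplied by the user.
#' @return Canonical diplotype key (character scalar).
#' @export
#' @examples
#' kb <- fixture_kb()
#' normalize_diplotype(kb_gene(kb, "CYP2D6"), "*2/*1")      # "*1/*2"
#' normalize_diplotype(kb_gene(kb, "HLA-B"), "57:01 pos")   # "*57:01 positive"
normalize_diplotype <- function(gene_def, raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  raw <- trimws(raw)
  if (!nzchar(raw)) stop("empty genotype value", call. = FALSE)
  switch(gene_def$input_mode,
    star_diplotype = normalize_star_diplotype(raw),
    hla_presence = normalize_hla_call(raw),
    variant_genotype = normalize_variant_genotype(raw),
    stop(sprintf("unsupported input mode '%s'", gene_def$input_mode), call. = FALSE)
  )
}

normalize_star_diplotype <- function(raw) {
  parts <- trimws(strsplit(raw, "/", fixed = TRUE)[[1]])
  if (length(parts) != 2L) {
    stop(sprintf("expected two '/'-separated star alleles, got '%s'", raw), call. = FALSE)
  }
  m <- regmatches(parts, regexec(STAR_ALLELE_RE, parts))
  for (i in 1:2) {
    if (length(m[[i]]) == 0L) {
      stop(sprintf("malformed star allele token '%s'", parts[i]), call. = FALSE)
    }
  }
  num <- as.integer(vapply(m, `[`, character(1), 2L))
  suffix <- vapply(m, `[`, character(1), 3L)
  cn_raw <- vapply(m, `[`, character(1), 4L)
  # "xN" (unspecified copy count) sorts after any explicit count
  cn <- ifelse(cn_raw == "", 0L, ifelse(cn_raw == "N", .Machine$integer.max,
                                        suppressWarnings(as.integer(cn_raw))))
  ord <- order(num, suffix, cn)
  paste(parts[ord], collapse = "/")
}

normalize_hla_call <- function(raw) {
  tokens <- strsplit(trimws(raw), "\\s+")[[1]]
  if (length(tokens) != 2L) {
    stop(sprintf("expected '<allele> <status>' for an HLA presence call, got '%s'", raw),
         call. = FALSE)
  }
  m <- regmatches(tokens[1], regexec(HLA_ALLELE_RE, tokens[1]))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed HLA allele token '%s'", tokens[1]), call. = FALSE)
  }
  status <- switch(tolower(tokens[2]),
    "pos" = , "positive" = , "+" = , "present" = "positive",
    "neg" = , "negative" = , "-" = , "absent" = "negative",
    stop(sprintf("unrecognized HLA presence status '%s'", tokens[2]), call. = FALSE)
  )
  sprintf("*%s %s", m[2], status)
}

normalize_variant_genotype <- function(raw) {
  # accept an optional variant label before the genotype, e.g. "-1639G>A A/G"
  tokens <- strsplit(trimws(raw), "\\s+")[[1]]
  gt <- tokens[length(tokens)]
  m <- regmatches(gt, regexec("^([ACGT])/([ACGT])$", gt))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed variant genotype token '%s'", gt), call. = FALSE)
  }
  alleles <- sort(c(m[2], m[3]))
  paste(alleles, collapse = "/")
}

#' Normalize drug names against the knowledge base
#'
#' Case-insensitive, whitespace-trimmed matching against all drug names known
#' to the knowledge base (pair registry and interaction catalog) plus a
#' synonym table. Unrecognized drugs are retained and flagged, never silently
#' dropped: they surface in the report as unrecognized.
#'
#' @param kb A `pgx_kb`.
#' @param raw Character vector of drug names as supplied.
#' @return Data frame with columns `raw`, `canonical` and `recognized`.
#' @export
normalize_drug_name <- function(kb, raw) {
  stopifnot(is.character(raw))
  known <- unique(c(kb$pairs$drug, kb$interactions$drug))
  folded <- tolower(trimws(raw))
  synonyms <- drug_synonyms()
  canonical <- ifelse(folded %in% names(synonyms), unname(synonyms[folded]), folded)
  data.frame(raw = raw, canonical = canonical,
             recognized = canonical %in% known,
             stringsAsFactors = FALSE)
}

#' Parse a patient record from JSON or TSV
#'
#' Two documented input formats stand in for interactive entry:
#' \describe{
#'   \item{JSON}{An object with keys `genotypes` (array of `{gene, value,
#'     note}`), `current_medications`, `considered_medications` and optional
#'     `metadata`. The short aliases `current` and `considered` are accepted.}
#'   \item{TSV}{Three sections introduced by `[genotypes]`,
#'     `[current_medications]` and `[considered_medications]` lines. Genotype
#'     rows are `gene<TAB>value<TAB>note` (note optional); medication rows
#'     are one drug per line. Blank lines and `#` comments are ignored.}
#' }
#' Parsing never persists any input. Genotype and medication values are kept
#' as supplied; normalization happens downstream.
#'
#' @param path Path to the input document.
#' @param format `"json"`, `"tsv"`, or `"auto"` (default; sniffed from the
#'   file extension).
#' @return An object of class `pgx_patient` with fields `genotypes` (data
#'   frame: gene, raw_value, note), `current_medications`,
#'   `considered_medications` and `metadata`.
#' @export
parse_patient_input <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") parse_patient_json(path) else parse_patient_tsv(path)
}

new_patient <- function(genotypes, current, considered, metadata = list()) {
  if (nrow(genotypes) > 0L) {
    if (anyDuplicated(genotypes$gene)) {
      dup <- unique(genotypes$gene[duplicated(genotypes$gene)])
      stop(sprintf("duplicate genotype entry for gene %s", paste(dup, collapse = ", ")),
           call. = FALSE)
    }
    if (any(!nzchar(trimws(genotypes$raw_value)))) {
      stop("empty genotype value", call. = FALSE)
    }
  }
  structure(list(genotypes = genotypes,
                 current_medications = as.character(current),
                 considered_medications = as.character(considered),
                 metadata = metadata),
            class = "pgx_patient")
}

#' @export
print.pgx_patient <- function(x, ...) {
  cat(sprintf("<pgx_patient> %d genotype call(s), %d current, %d considered medication(s)\n",
              nrow(x$genotypes), length(x$current_medications),
              length(x$considered_medications)))
  invisible(x)
}

parse_patient_json <- function(path) {
  doc <- jsonlite::read_json(path)
  allowed <- c("genotypes", "current_medications", "considered_medications",
               "current", "considered", "metadata")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown top-level key(s) in patient document: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  entries <- doc$genotypes %||% list()
  genotypes <- data.frame(
    gene = vapply(entries, function(e) as.character(e$gene %||% NA_character_), character(1)),
    raw_value = vapply(entries, function(e) as.character(e$value %||% e$raw_value %||% NA_character_), character(1)),
    note = vapply(entries, function(e) as.character(e$note %||% NA_character_), character(1)),
    stringsAsFactors = FALSE
  )
  if (nrow(genotypes) > 0L && (anyNA(genotypes$gene) || anyNA(genotypes$raw_value))) {
    stop("each genotype entry needs 'gene' and 'value'", call. = FALSE)
  }
  current <- unlist(doc$current_medications %||% doc$current %||% list())
  considered <- unlist(doc$considered_medications %||% doc$considered %||% list())
  new_patient(genotypes, current %||% character(0), considered %||% character(0),
              metadata = lapply(doc$metadata %||% list(), as.character))
}

parse_patient_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  section <- NA_character_
  geno <- list()
  meds <- list(current_medications = character(0),
               considered_medications = character(0))
  metadata <- list()
  for (ln in lines) {
    header <- regmatches(ln, regexec("^\\[([a-z_]+)\\]\\s*$", trimws(ln)))[[1]]
    if (length(header) > 0L) {
      section <- header[2]
      if (!section %in% c("genotypes", "current_medications",
                          "considered_medications", "metadata")) {
        stop(sprintf("unknown section '[%s]' in patient document", section), call. = FALSE)
      }
      next
    }
    if (is.na(section)) {
      stop("patient TSV must start with a section header such as [genotypes]", call. = FALSE)
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (section == "genotypes") {
      if (length(fields) < 2L) {
        stop(sprintf("genotype row needs gene<TAB>value: '%s'", ln), call. = FALSE)
      }
      geno[[length(geno) + 1L]] <- data.frame(
        gene = trimws(fields[1]), raw_value = trimws(fields[2]),
        note = if (length(fields) >= 3L && nzchar(trimws(fields[3]))) trimws(fields[3]) else NA_character_,
        stringsAsFactors = FALSE)
    } else if (section == "metadata") {
      if (length(fields) >= 2L) metadata[[trimws(fields[1])]] <- trimws(fields[2])
    } else {
      meds[[section]] <- c(meds[[section]], trimws(fields[1]))
    }
  }
  genotypes <- if (length(geno) > 0L) do.call(rbind, geno) else
    data.frame(gene = character(0), raw_value = character(0), note = character(0),
               stringsAsFactors = FALSE)
  new_patient(genotypes, meds$current_medications, meds$considered_medications,
              metadata = metadata)
}

#' Serialize a patient record to JSON
#'
#' Inverse of [parse_patient_input()] for the JSON format; parse-serialize-
#' parse round trips preserve record equality.
#'
#' @param patient A `pgx_patient`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patient_json <- function(patient, path) {
  g <- patient$genotypes
  entries <- lapply(seq_len(nrow(g)), function(i) {
    e <- list(gene = g$gene[i], value = g$raw_value[i])
    if (!is.na(g$note[i])) e$note <- g$note[i]
    e
  })
  doc <- list(genotypes = entries,
              current_medications = as.list(patient$current_medications),
              considered_medications = as.list(patient$considered_medications))
  if (length(patient$metadata) > 0L) doc$metadata <- patient$metadata
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
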