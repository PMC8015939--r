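build_example_report <- function(patient = example_patient(),
                                 generated_on = "2026-02-01") {
  interp <- interpret_patient(FIX, patient)
  build_report(patient, FIX, interp, generated_on = generated_on)
}

test_that("report assembly is deterministic and carries header, notes and conversions", {
  model <- build_example_report()
  expect_identical(model$kb_version, FIX$version)
  expect_identical(model$kb_last_updated, FIX$last_updated)

  gr <- model$genetic_results
  expect_identical(gr$gene, sort(FIX$genes$symbol))
  d6 <- gr[gr$gene == "CYP2D6", ]
  expect_identical(d6$inferred_phenotype, "normal metabolizer")
  expect_identical(d6$converted_phenotype, "poor metabolizer")
  expect_identical(d6$conversion_basis, "strong_inhibitor")
  expect_identical(d6$triggering_drugs, "paroxetine")
  expect_identical(d6$note, "reported by external lab")
  # converted phenotype shown only when a conversion applied
  expect_true(all(nzchar(gr$converted_phenotype) ==
                  gr$conversion_basis %in% c("strong_inhibitor",
                                             "moderate_inhibitor", "inducer")))
  # weak inhibitors and substrates still listed for their genes
  cmt <- model$current_medication_table
  expect_identical(sort(cmt$gene),
                   sort(FIX$genes$symbol[FIX$genes$phenoconversion_eligible]))
  expect_identical(cmt$strong_inhibitors[cmt$gene == "CYP2D6"], "paroxetine")
  expect_identical(cmt$inducers[cmt$gene == "CYP2C19"], "rifampin")
  expect_true(nzchar(model$disclaimer))

  # byte-identical JSON from two assemblies of the same inputs
  model2 <- build_example_report()
  expect_identical(render_report(model, "json"), render_report(model2, "json"))
})

test_that("a patient with no genotypes yields all-unknown rows and none-strength resolutions", {
  p <- patient_from_list(list(genotypes = list()))
  model <- build_report(p, FIX, interpret_patient(FIX, p),
                        generated_on = "2026-02-01")
  expect_true(all(model$genetic_results$inferred_phenotype == "unknown"))
  expect_true(all(model$future_medications$strength == "none"))
  expect_identical(nrow(model$future_medications), 97L)
})

test_that("JSON rendering is schema-stable, round-trips, and covers the registry", {
  model <- build_example_report()
  txt <- render_report(model, "json")
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_identical(parsed$header$kb_last_updated, format(FIX$last_updated))
  expect_identical(parsed$header$generated_on, "2026-02-01")
  expect_length(parsed$future_medications, 97L)
  expect_length(parsed$genetic_results, 11L)
  # parse -> re-render is exact
  txt2 <- as.character(jsonlite::toJSON(parsed, auto_unbox = TRUE, pretty = 2,
                                        null = "null", na = "null"))
  expect_identical(txt2, txt)
  expect_error(render_report(model, "pdf"))
})

test_that("Markdown and HTML place the database-update date in the header and render all rows", {
  model <- build_example_report()
  md <- render_report(model, "markdown")
  header <- strsplit(md, "\n")[[1]][1:5]
  expect_match(paste(header, collapse = "\n"), format(FIX$last_updated), fixed = TRUE)
  # codeine row appears once in the considered table and once in the full list
  expect_identical(sum(grepl("^\\| CYP2D6 \\| codeine ", strsplit(md, "\n")[[1]])), 2L)
  # considered = codeine + abacavir + warfarin (two pairs) = 4 rows
  expect_length(grep("^\\|", strsplit(md, "\n")[[1]]),
                # genetic (11+2) + interactions (5+2) + considered (4+2) + future (97+2)
                11L + 2L + 5L + 2L + 4L + 2L + 97L + 2L)

  html <- render_report(model, "html")
  expect_match(html, sprintf("Database last updated: %s", format(FIX$last_updated)),
               fixed = TRUE)
  expect_identical(length(gregexpr("<tr>", html, fixed = TRUE)[[1]]),
                   (11L + 1L) + (5L + 1L) + (4L + 1L) + (97L + 1L))
})

test_that("unrecognized and unsupported drugs are surfaced, never dropped", {
  p <- patient_from_list(list(
    genotypes = list(list(gene = "CYP2D6", value = "*1/*2")),
    current_medications = list("paroxetine", "notadrug"),
    considered_medications = list("codeine", "alsonotadrug")))
  model <- build_report(p, FIX, interpret_patient(FIX, p),
                        generated_on = "2026-02-01")
  expect_identical(model$unrecognized_current, "notadrug")
  expect_identical(model$unsupported_considered, "alsonotadrug")
  expect_identical(unique(model$considered_medications$drug), "codeine")
  md <- render_report(model, "markdown")
  expect_match(md, "Unrecognized current medications: notadrug", fixed = TRUE)
  expect_match(md, "Unsupported considered medications: alsonotadrug", fixed = TRUE)
})

test_that("cli runs the documented subcommands with correct exit codes", {
  dir <- withr::local_tempdir()
  patient_path <- file.path(dir, "patient.json")
  write_patient_json(example_patient(), patient_path)
  out <- file.path(dir, "report.json")

  expect_identical(
    suppressMessages(cli_main(c("report", "--patient", patient_path,
                                "--kb", "fixture", "--format", "json",
                                "--out", out, "--date", "2026-02-01"))), 0L)
  expect_true(file.exists(out))
  parsed <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  expect_length(parsed$future_medications, 97L)

  # the CLI rendering equals the in-process rendering (golden stability)
  expect_identical(paste(readLines(out), collapse = "\n"),
                   render_report(build_example_report(), "json"))

  # kb stats prints the registry counts
  stats_out <- capture.output(
    status <- suppressMessages(cli_main(c("kb", "stats", "--kb", "fixture"))))
  expect_identical(status, 0L)
  expect_match(stats_out, "pairs=97 genes=11", all = FALSE)

  expect_identical(suppressMessages(cli_main(c("kb", "validate", "--kb", "fixture"))), 0L)

  fixdir <- file.path(dir, "kb-copy")
  expect_identical(
    suppressMessages(cli_main(c("kb", "init-fixture", "--out", fixdir))), 0L)
  expect_identical(kb_stats(load_kb(fixdir))$n_pairs, 97L)

  # usage errors exit 2
  expect_identical(suppressMessages(cli_main(c("report", "--out", out))), 2L)
  expect_identical(suppressMessages(cli_main(c("report", "--bogus"))), 2L)
  expect_identical(suppressMessages(cli_main(character(0))), 2L)
  expect_identical(suppressMessages(cli_main(c("kb", "frobnicate"))), 2L)
  # runtime failures exit 1
  expect_identical(
    suppressWarnings(suppressMessages(
      cli_main(c("report", "--patient", file.path(dir, "no.json"),
                 "--out", out)))), 1L)
})

test_that("cli filter flags restrict the future-medications table", {
  dir <- withr::local_tempdir()
  patient_path <- file.path(dir, "patient.json")
  write_patient_json(full_genotype_patient(), patient_path)
  out <- file.path(dir, "filtered.json")
  expect_identical(
    suppressMessages(cli_main(c("report", "--patient", patient_path,
                                "--out", out, "--date", "2026-02-01",
                                "--gene", "CYP2D6", "--class", "opioid",
                                "--actionable"))), 0L)
  parsed <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  drugs <- vapply(parsed$future_medications, function(r) r$drug, character(1))
  expect_setequal(drugs, c("codeine", "hydrocodone", "oxycodone", "tramadol"))
  expect_true(all(vapply(parsed$future_medications, function(r) r$actionable, logical(1))))
})

test_that("the tool writes nothing beyond the requested output file", {
  sandbox <- withr::local_tempdir()
  withr::local_dir(sandbox)
  write_patient_json(example_patient(), "patient.json")
  before <- list.files(sandbox, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  expect_identical(
    suppressMessages(cli_main(c("report", "--patient", "patient.json",
                                "--out", "report.md", "--format", "markdown",
                                "--date", "2026-02-01"))), 0L)
  after <- list.files(sandbox, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  expect_setequal(setdiff(after, before), "report.md")
})
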