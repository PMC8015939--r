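test_that("fixture knowledge base loads, self-validates and reports its statistics", {
  expect_s3_class(FIX, "pgx_kb")
  expect_identical(validate_kb(FIX), character(0))
  s <- kb_stats(FIX)
  expect_identical(s$n_pairs, 97L)
  expect_identical(s$n_genes, 11L)
  expect_identical(s$n_phenoconversion_genes, 5L)
  expect_true(nzchar(FIX$version))
  expect_s3_class(FIX$last_updated, "Date")
  # the eligible set is exactly the five supported CYP450 genes
  expect_setequal(FIX$genes$symbol[FIX$genes$phenoconversion_eligible],
                  c("CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A5"))
  # HLA presence genes have no activity scale
  expect_identical(FIX$genes$phenotype_scale[FIX$genes$input_mode == "hla_presence"],
                   c("", ""))
})

test_that("registry matches an independently parsed transcription of the supported pairs", {
  expected <- parse_registry_transcription()
  expect_identical(nrow(expected), 97L)
  got <- FIX$pairs
  key <- function(df) sort(paste(df$gene, df$drug, sep = "/"))
  expect_identical(key(got), key(expected))
  # per-gene drug counts, computed independently
  expect_identical(c(table(got$gene)), c(table(expected$gene)))
  # HLA allele qualifiers carried through
  eq <- expected[!is.na(expected$allele_qualifier), ]
  for (i in seq_len(nrow(eq))) {
    expect_identical(
      got$allele_qualifier[got$gene == eq$gene[i] & got$drug == eq$drug[i]],
      eq$allele_qualifier[i])
  }
  expect_identical(got$drug[got$gene == "CYP3A5"], "tacrolimus")
})

test_that("loading the shipped bundle reproduces the in-code fixture, and round trips", {
  shipped <- system.file("extdata", "kb", package = "pgxreport")
  kb <- load_kb(shipped)
  expect_identical(kb_stats(kb), kb_stats(FIX))
  expect_identical(kb$recommendations, FIX$recommendations)
  expect_identical(kb$diplotypes, FIX$diplotypes)
  expect_equal(kb$interactions, FIX$interactions)
  expect_identical(kb$last_updated, FIX$last_updated)
  # serialize -> load round trip
  dir <- withr::local_tempdir()
  write_kb(kb, dir)
  kb2 <- load_kb(dir)
  expect_identical(kb_stats(kb2), kb_stats(kb))
  expect_identical(kb2$genes, kb$genes)
  expect_identical(kb2$pairs, kb$pairs)
})

test_that("load_kb reports missing files and schema violations by name", {
  dir <- withr::local_tempdir()
  write_kb(FIX, dir)
  file.remove(file.path(dir, "interactions.tsv"))
  expect_error(load_kb(dir), "interactions file absent")
  expect_error(load_kb(file.path(dir, "nonexistent")), "does not exist")

  dir2 <- withr::local_tempdir()
  write_kb(FIX, dir2)
  file.remove(file.path(dir2, "manifest.json"))
  expect_error(load_kb(dir2), "manifest.json")

  # a recommendation for an unregistered pair must fail validation on load
  dir3 <- withr::local_tempdir()
  broken <- FIX
  broken$recommendations <- rbind(
    broken$recommendations,
    data.frame(drug = "warfarin", drug_class = "anticoagulant",
               genes = "CYP2D6", phenotype_key = "CYP2D6=poor metabolizer",
               text = "x", strength = "strong", source = "FDA",
               pathway_url = "", actionable = TRUE, placeholder = TRUE,
               stringsAsFactors = FALSE))
  write_kb(broken, dir3)
  expect_error(load_kb(dir3), "not in the gene-drug pair registry")
})

test_that("validate_kb returns named violations instead of raising", {
  kb <- FIX
  kb$interactions <- rbind(
    kb$interactions,
    data.frame(gene = "CYP2C19", drug = "rifampin2", role = "inducer",
               strength = "strong", evidence_auc_fold = NA_real_,
               evidence_clearance_pct = NA_real_, stringsAsFactors = FALSE))
  v <- validate_kb(kb)
  expect_length(v, 1L)
  expect_match(v, "inducers are not categorized by strength")

  kb2 <- FIX
  kb2$diplotypes <- rbind(
    kb2$diplotypes,
    data.frame(gene = "CYP2D6", diplotype = "*1/*3",
               phenotype = "rapid metabolizer", stringsAsFactors = FALSE))
  v2 <- validate_kb(kb2)
  expect_length(v2, 1L)
  expect_match(v2, "'rapid metabolizer' not valid")

  kb3 <- FIX
  kb3$diplotypes$diplotype[1] <- "*6/*1"   # non-canonical allele order
  expect_match(validate_kb(kb3), "not canonical", all = FALSE)
})

test_that("inhibitor strength classifier follows the AUC and clearance thresholds", {
  # AUC fold-increase: 1.25-2 weak, >2-5 moderate, >5 strong
  expect_identical(classify_inhibitor_strength(auc_fold = 1.25), "weak")
  expect_identical(classify_inhibitor_strength(auc_fold = 2.0), "weak")
  expect_identical(classify_inhibitor_strength(auc_fold = 2.01), "moderate")
  expect_identical(classify_inhibitor_strength(auc_fold = 5.0), "moderate")
  expect_identical(classify_inhibitor_strength(auc_fold = 5.01), "strong")
  expect_identical(classify_inhibitor_strength(auc_fold = 6.0), "strong")
  # clearance decrease: 20-49% weak, 50-80% moderate, >80% strong
  expect_identical(classify_inhibitor_strength(clearance_pct = 20), "weak")
  expect_identical(classify_inhibitor_strength(clearance_pct = 49.9), "weak")
  expect_identical(classify_inhibitor_strength(clearance_pct = 50), "moderate")
  expect_identical(classify_inhibitor_strength(clearance_pct = 80), "moderate")
  expect_identical(classify_inhibitor_strength(clearance_pct = 80.5), "strong")
  expect_identical(classify_inhibitor_strength(clearance_pct = 85), "strong")
  # both supplied: the stronger classification wins
  expect_identical(classify_inhibitor_strength(auc_fold = 1.5, clearance_pct = 85),
                   "strong")
  expect_identical(classify_inhibitor_strength(auc_fold = 3, clearance_pct = 25),
                   "moderate")
  # below the weak floor, or no evidence at all
  expect_error(classify_inhibitor_strength(auc_fold = 1.1), "below weak-inhibitor floor")
  expect_error(classify_inhibitor_strength(auc_fold = 1.0, clearance_pct = 10),
               "below weak-inhibitor floor")
  expect_error(classify_inhibitor_strength(), "at least one evidence value")
})

test_that("classifier is monotone non-decreasing in both evidence measures", {
  rank <- c(weak = 1L, moderate = 2L, strong = 3L)
  aucs <- c(1.25, 1.5, 2, 2.5, 3, 5, 5.5, 8, 20)
  expect_true(all(diff(rank[vapply(aucs, function(a)
    classify_inhibitor_strength(auc_fold = a), character(1))]) >= 0))
  clrs <- c(20, 30, 49, 50, 65, 80, 81, 90, 100)
  expect_true(all(diff(rank[vapply(clrs, function(c)
    classify_inhibitor_strength(clearance_pct = c), character(1))]) >= 0))
})

test_that("every fixture interaction with evidence stores the classifier's strength", {
  x <- FIX$interactions
  checked <- 0L
  for (i in seq_len(nrow(x))) {
    has_auc <- !is.na(x$evidence_auc_fold[i])
    has_clr <- !is.na(x$evidence_clearance_pct[i])
    if (!has_auc && !has_clr) next
    expect_identical(
      classify_inhibitor_strength(
        auc_fold = if (has_auc) x$evidence_auc_fold[i] else NULL,
        clearance_pct = if (has_clr) x$evidence_clearance_pct[i] else NULL),
      x$strength[i])
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
  # and the fixture must include paroxetine as a strong CYP2D6 inhibitor
  paroxetine <- x[x$gene == "CYP2D6" & x$drug == "paroxetine", ]
  expect_identical(paroxetine$role, "inhibitor")
  expect_identical(paroxetine$strength, "strong")
})

test_that("kb_stats of an empty knowledge base is all zeros", {
  empty <- new_kb("empty", "2026-01-01",
                  genes = FIX$genes[0, ], pairs = FIX$pairs[0, ],
                  diplotypes = FIX$diplotypes[0, ],
                  interactions = FIX$interactions[0, ],
                  recommendations = FIX$recommendations[0, ])
  expect_identical(kb_stats(empty),
                   list(n_genes = 0L, n_drugs = 0L, n_pairs = 0L,
                        n_phenoconversion_genes = 0L))
})
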