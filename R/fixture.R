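# Shipped fixture knowledge base: the full 97-pair gene-drug registry across
# 11 pharmacogenes, curated phenotype scales and diplotype maps, a
# Flockhart-style CYP interaction catalog, and placeholder-flagged
# recommendation records (one per registry pair per valid phenotype term).
# Recommendation texts are synthetic placeholders, not guideline prose.

fixture_registry <- function() {
  reg <- list(
    CYP2B6 = "efavirenz",
    CYP2C19 = c("amitriptyline", "citalopram", "clobazam", "clomipramine",
                "clopidogrel", "doxepin", "escitalopram", "esomeprazole",
                "imipramine", "lansoprazole", "omeprazole", "pantoprazole",
                "prasugrel", "sertraline", "ticagrelor", "trimipramine",
                "voriconazole"),
    CYP2C9 = c("aspirin", "celecoxib", "flurbiprofen", "ibuprofen",
               "lornoxicam", "meloxicam", "naproxen", "phenytoin",
               "piroxicam", "tenoxicam", "warfarin"),
    CYP2D6 = c("amiodarone", "amitriptyline", "amphetamine", "aripiprazole",
               "atenolol", "atomoxetine", "bisoprolol", "brexpiprazole",
               "cavedilol", "clomipramine", "clonidine", "clozapine",
               "codeine", "desipramine", "doxepin", "duloxetine",
               "eliglustat", "flecainide", "fluoxetine", "fluphenazine",
               "fluvoxamine", "haloperidol", "hydrocodone", "iloperidone",
               "imipramine", "methylphenidate", "metoprolol", "mirtazapine",
               "moclobemide", "nebivolol", "nortriptyline", "odansetron",
               "olanzapine", "oxycodone", "paroxetine", "perphenazine",
               "pimozide", "propafenone", "propranolol", "quetiapine",
               "risperidone", "tamoxifen", "tetrabenazine", "tramadol",
               "tropisetron", "trimipramine", "venlafaxine", "vortioxetine",
               "zuclopenthixol"),
    CYP3A5 = "tacrolimus",
    `HLA-A` = "carbamazepine",
    `HLA-B` = c("abacavir", "allopurinol", "carbamazepine", "oxcarbazepine",
                "phenytoin"),
    NUDT15 = c("azathioprine", "mercaptopurine", "thioguanine"),
    SLCO1B1 = c("atorvastatin", "fluvastatin", "rosuvastatin", "simvastatin"),
    TPMT = c("azathioprine", "mercaptopurine", "thioguanine"),
    VKORC1 = c("acenocoumarol", "warfarin")
  )
  qualifiers <- c(
    "HLA-A:carbamazepine" = "*31:01",
    "HLA-B:abacavir" = "*57:01",
    "HLA-B:allopurinol" = "*58:01",
    "HLA-B:carbamazepine" = "*15:02",
    "HLA-B:oxcarbazepine" = "*15:02",
    "HLA-B:phenytoin" = "*15:02"
  )
  pairs <- do.call(rbind, lapply(names(reg), function(g) {
    data.frame(gene = g, drug = reg[[g]], stringsAsFactors = FALSE)
  }))
  pairs$allele_qualifier <- unname(qualifiers[paste(pairs$gene, pairs$drug, sep = ":")])
  pairs
}

fixture_genes <- function() {
  mets <- function(...) join_multi(paste(c(...), "metabolizer"))
  data.frame(
    symbol = c("CYP2B6", "CYP2C19", "CYP2C9", "CYP2D6", "CYP3A5",
               "HLA-A", "HLA-B", "NUDT15", "SLCO1B1", "TPMT", "VKORC1"),
    input_mode = c(rep("star_diplotype", 5), "hla_presence", "hla_presence",
                   "star_diplotype", "star_diplotype", "star_diplotype",
                   "variant_genotype"),
    phenotype_scale = c(
      mets("poor", "intermediate", "normal", "rapid", "ultrarapid"),  # CYP2B6
      mets("poor", "intermediate", "normal", "rapid", "ultrarapid"),  # CYP2C19
      mets("poor", "intermediate", "normal"),                         # CYP2C9
      mets("poor", "intermediate", "normal", "ultrarapid"),           # CYP2D6
      mets("poor", "intermediate", "normal"),                         # CYP3A5
      "", "",                                                         # HLA-A/B
      "", "", "",                                                     # NUDT15/SLCO1B1/TPMT
      ""                                                              # VKORC1
    ),
    categorical_terms = c(
      "", "", "", "", "",
      "*31:01 positive|*31:01 negative",
      "*57:01 positive|*57:01 negative|*58:01 positive|*58:01 negative|*15:02 positive|*15:02 negative",
      mets("poor", "intermediate", "normal"),
      "poor function|decreased function|normal function",
      mets("poor", "intermediate", "normal"),
      "normal sensitivity|increased sensitivity|high sensitivity"
    ),
    phenoconversion_eligible = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

fixture_diplotypes <- function() {
  rows <- function(gene, ...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(gene = gene, diplotype = m[, 1], phenotype = m[, 2],
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    rows("CYP2B6",
         "*1/*1", "normal metabolizer",
         "*1/*6", "intermediate metabolizer",
         "*6/*6", "poor metabolizer",
         "*1/*4", "rapid metabolizer",
         "*4/*4", "ultrarapid metabolizer"),
    rows("CYP2C19",
         "*1/*1", "normal metabolizer",
         "*1/*2", "intermediate metabolizer",
         "*1/*3", "intermediate metabolizer",
         "*2/*2", "poor metabolizer",
         "*2/*3", "poor metabolizer",
         "*1/*17", "rapid metabolizer",
         "*17/*17", "ultrarapid metabolizer"),
    rows("CYP2C9",
         "*1/*1", "normal metabolizer",
         "*1/*2", "intermediate metabolizer",
         "*1/*3", "intermediate metabolizer",
         "*2/*2", "intermediate metabolizer",
         "*2/*3", "poor metabolizer",
         "*3/*3", "poor metabolizer"),
    rows("CYP2D6",
         "*1/*1", "normal metabolizer",
         "*1/*2", "normal metabolizer",
         "*2/*2", "normal metabolizer",
         "*1/*4", "intermediate metabolizer",
         "*1/*5", "intermediate metabolizer",
         "*4/*4", "poor metabolizer",
         "*3/*4", "poor metabolizer",
         "*4/*5", "poor metabolizer",
         "*1/*1x2", "ultrarapid metabolizer",
         "*2/*2x2", "ultrarapid metabolizer"),
    rows("CYP3A5",
         "*1/*1", "normal metabolizer",
         "*1/*3", "intermediate metabolizer",
         "*3/*3", "poor metabolizer"),
    rows("HLA-A",
         "*31:01 positive", "*31:01 positive",
         "*31:01 negative", "*31:01 negative"),
    rows("HLA-B",
         "*57:01 positive", "*57:01 positive",
         "*57:01 negative", "*57:01 negative",
         "*58:01 positive", "*58:01 positive",
         "*58:01 negative", "*58:01 negative",
         "*15:02 positive", "*15:02 positive",
         "*15:02 negative", "*15:02 negative"),
    rows("NUDT15",
         "*1/*1", "normal metabolizer",
         "*1/*3", "intermediate metabolizer",
         "*3/*3", "poor metabolizer"),
    rows("SLCO1B1",
         "*1/*1", "normal function",
         "*1/*5", "decreased function",
         "*1/*15", "decreased function",
         "*5/*5", "poor function",
         "*15/*15", "poor function"),
    rows("TPMT",
         "*1/*1", "normal metabolizer",
         "*1/*2", "intermediate metabolizer",
         "*1/*3A", "intermediate metabolizer",
         "*2/*3A", "poor metabolizer",
         "*3A/*3A", "poor metabolizer"),
    rows("VKORC1",
         "G/G", "normal sensitivity",
         "A/G", "increased sensitivity",
         "A/A", "high sensitivity")
  ))
}

fixture_interactions <- function() {
  row <- function(gene, drug, role, strength = "not_applicable",
                  auc = NA_real_, clr = NA_real_) {
    data.frame(gene = gene, drug = drug, role = role, strength = strength,
               evidence_auc_fold = auc, evidence_clearance_pct = clr,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # CYP2D6
    row("CYP2D6", "paroxetine", "inhibitor", "strong", auc = 6.9),
    row("CYP2D6", "fluoxetine", "inhibitor", "strong", auc = 6.0),
    row("CYP2D6", "quinidine", "inhibitor", "strong", clr = 88),
    row("CYP2D6", "duloxetine", "inhibitor", "moderate", auc = 2.6),
    row("CYP2D6", "cimetidine", "inhibitor", "weak", auc = 1.5),
    row("CYP2D6", "codeine", "substrate"),
    row("CYP2D6", "tramadol", "substrate"),
    row("CYP2D6", "metoprolol", "substrate"),
    row("CYP2D6", "atomoxetine", "substrate"),
    row("CYP2D6", "nortriptyline", "substrate"),
    row("CYP2D6", "risperidone", "substrate"),
    # CYP2C19
    row("CYP2C19", "fluvoxamine", "inhibitor", "strong", auc = 6.2),
    row("CYP2C19", "fluconazole", "inhibitor", "moderate", clr = 62),
    row("CYP2C19", "omeprazole", "inhibitor", "moderate", auc = 2.3),
    row("CYP2C19", "cimetidine", "inhibitor", "weak", auc = 1.4),
    row("CYP2C19", "rifampin", "inducer"),
    row("CYP2C19", "citalopram", "substrate"),
    row("CYP2C19", "omeprazole", "substrate"),
    row("CYP2C19", "clopidogrel", "substrate"),
    row("CYP2C19", "sertraline", "substrate"),
    row("CYP2C19", "voriconazole", "substrate"),
    # CYP2C9
    row("CYP2C9", "fluconazole", "inhibitor", "moderate", auc = 2.8),
    row("CYP2C9", "amiodarone", "inhibitor", "moderate", clr = 55),
    row("CYP2C9", "sulfamethoxazole", "inhibitor", "weak", auc = 1.6),
    row("CYP2C9", "rifampin", "inducer"),
    row("CYP2C9", "warfarin", "substrate"),
    row("CYP2C9", "phenytoin", "substrate"),
    row("CYP2C9", "celecoxib", "substrate"),
    row("CYP2C9", "ibuprofen", "substrate"),
    # CYP2B6
    row("CYP2B6", "ticlopidine", "inhibitor", "strong", auc = 5.1),
    row("CYP2B6", "voriconazole", "inhibitor", "moderate", clr = 60),
    row("CYP2B6", "clopidogrel", "inhibitor", "weak", auc = 1.8),
    row("CYP2B6", "rifampin", "inducer"),
    row("CYP2B6", "carbamazepine", "inducer"),
    row("CYP2B6", "efavirenz", "substrate"),
    # CYP3A5
    row("CYP3A5", "ketoconazole", "inhibitor", "strong", auc = 7.5),
    row("CYP3A5", "erythromycin", "inhibitor", "moderate", auc = 3.5),
    row("CYP3A5", "fluvoxamine", "inhibitor", "weak", auc = 1.6),
    row("CYP3A5", "rifampin", "inducer"),
    row("CYP3A5", "carbamazepine", "inducer"),
    row("CYP3A5", "phenytoin", "inducer"),
    row("CYP3A5", "tacrolimus", "substrate")
  ))
}

drug_class_table <- function() {
  cls <- list(
    TCA = c("amitriptyline", "clomipramine", "desipramine", "doxepin",
            "imipramine", "nortriptyline", "trimipramine"),
    SSRI = c("citalopram", "escitalopram", "fluoxetine", "fluvoxamine",
             "paroxetine", "sertraline"),
    SNRI = c("venlafaxine", "duloxetine"),
    `other antidepressant` = c("mirtazapine", "moclobemide", "vortioxetine"),
    antipsychotic = c("aripiprazole", "brexpiprazole", "clozapine",
                      "fluphenazine", "haloperidol", "iloperidone",
                      "olanzapine", "perphenazine", "pimozide", "quetiapine",
                      "risperidone", "zuclopenthixol"),
    opioid = c("codeine", "hydrocodone", "oxycodone", "tramadol"),
    `beta-blocker` = c("atenolol", "bisoprolol", "cavedilol", "metoprolol",
                       "nebivolol", "propranolol"),
    antiarrhythmic = c("amiodarone", "flecainide", "propafenone"),
    `ADHD agent` = c("amphetamine", "atomoxetine", "methylphenidate"),
    PPI = c("esomeprazole", "lansoprazole", "omeprazole", "pantoprazole"),
    antiplatelet = c("clopidogrel", "prasugrel", "ticagrelor"),
    NSAID = c("aspirin", "celecoxib", "flurbiprofen", "ibuprofen",
              "lornoxicam", "meloxicam", "naproxen", "piroxicam", "tenoxicam"),
    anticonvulsant = c("carbamazepine", "clobazam", "oxcarbazepine", "phenytoin"),
    anticoagulant = c("acenocoumarol", "warfarin"),
    statin = c("atorvastatin", "fluvastatin", "rosuvastatin", "simvastatin"),
    thiopurine = c("azathioprine", "mercaptopurine", "thioguanine"),
    antiretroviral = c("abacavir", "efavirenz"),
    antifungal = "voriconazole",
    immunosuppressant = "tacrolimus",
    antigout = "allopurinol",
    antiemetic = c("odansetron", "tropisetron")
  )
  out <- character(0)
  for (nm in names(cls)) out[cls[[nm]]] <- nm
  out
}

#' Drug-name synonym table
#'
#' Maps common alternative spellings onto the canonical registry spellings.
#'
#' @return Named character vector (lowercase synonym -> canonical name).
#' @keywords internal
drug_synonyms <- function() {
  c(ondansetron = "odansetron",
    carvedilol = "cavedilol",
    rifampicin = "rifampin",
    `acetylsalicylic acid` = "aspirin")
}

# Strength/actionability template applied to fixture placeholder records:
# phenotypes at the activity extremes (or risk-allele positive) get strong
# actionable placeholders, intermediate categories moderate actionable ones,
# and normal-activity categories a non-actionable "standard dosing" record.
fixture_rec_template <- function(term) {
  if (grepl("^(normal|\\*[0-9:]+ negative)", term) ||
      term %in% c("normal sensitivity", "normal function")) {
    list(strength = "none", actionable = FALSE,
         verb = "Standard dosing applies for")
  } else if (grepl("^(intermediate|decreased|increased|rapid)", term)) {
    list(strength = "moderate", actionable = TRUE,
         verb = "Consider dose adjustment of")
  } else {
    list(strength = "strong", actionable = TRUE,
         verb = "Avoid or adjust")
  }
}

fixture_recommendations <- function(genes, pairs) {
  classes <- drug_class_table()
  gene_source <- function(g) if (identical(g, "VKORC1")) "DPWG" else "CPIC"
  rec <- function(drug, rec_genes, terms, source, strength, actionable, verb,
                  pathway_url = "") {
    ctx <- paste(sprintf("%s %s", names(terms), unname(terms)), collapse = " and ")
    data.frame(
      drug = drug,
      drug_class = if (drug %in% names(classes)) classes[[drug]] else "other",
      genes = join_multi(rec_genes),
      phenotype_key = make_phenotype_key(terms),
      text = sprintf("%s %s (%s).", verb, drug, ctx),
      strength = strength, source = source, pathway_url = pathway_url,
      actionable = actionable, placeholder = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- list()
  # one single-gene record per registry pair per valid phenotype term;
  # for HLA pairs, only the Table-1 allele qualifier's terms apply
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]
    d <- pairs$drug[i]
    gi <- match(g, genes$symbol)
    terms <- c(split_multi(genes$phenotype_scale[gi]),
               split_multi(genes$categorical_terms[gi]))
    qual <- pairs$allele_qualifier[i]
    if (!is.na(qual) && nzchar(qual)) {
      terms <- terms[startsWith(terms, qual)]
    }
    for (term in terms) {
      tpl <- fixture_rec_template(term)
      out[[length(out) + 1L]] <- rec(d, g, stats::setNames(term, g),
                                     gene_source(g), tpl$strength,
                                     tpl$actionable, tpl$verb)
    }
  }
  # extra lower-preference sources for a few drugs, to exercise the hierarchy
  out[[length(out) + 1L]] <- rec("codeine", "CYP2D6",
    c(CYP2D6 = "poor metabolizer"), "DPWG", "strong", TRUE, "Avoid or adjust")
  out[[length(out) + 1L]] <- rec("codeine", "CYP2D6",
    c(CYP2D6 = "poor metabolizer"), "FDA", "strong", TRUE, "Avoid or adjust")
  out[[length(out) + 1L]] <- rec("codeine", "CYP2D6",
    c(CYP2D6 = "ultrarapid metabolizer"), "FDA", "strong", TRUE, "Avoid or adjust")
  out[[length(out) + 1L]] <- rec("clopidogrel", "CYP2C19",
    c(CYP2C19 = "intermediate metabolizer"), "FDA", "moderate", TRUE,
    "Consider dose adjustment of")
  out[[length(out) + 1L]] <- rec("clopidogrel", "CYP2C19",
    c(CYP2C19 = "poor metabolizer"), "DPWG", "strong", TRUE, "Avoid or adjust")
  # composite multi-gene records, preferred when both genes are callable
  composite <- function(drug, g1, terms1, g2, terms2) {
    for (t1 in terms1) for (t2 in terms2) {
      worst <- fixture_rec_template(t1)
      other <- fixture_rec_template(t2)
      if (match(other$strength, REC_STRENGTHS) < match(worst$strength, REC_STRENGTHS)) {
        worst <- other
      }
      out[[length(out) + 1L]] <<- rec(
        drug, c(g1, g2), stats::setNames(c(t1, t2), c(g1, g2)), "CPIC",
        worst$strength, worst$actionable, worst$verb)
    }
  }
  mets3 <- paste(c("poor", "intermediate", "normal"), "metabolizer")
  composite("warfarin", "CYP2C9", mets3, "VKORC1",
            c("normal sensitivity", "increased sensitivity", "high sensitivity"))
  composite("azathioprine", "NUDT15", mets3, "TPMT", mets3)
  composite("carbamazepine", "HLA-A", c("*31:01 positive", "*31:01 negative"),
            "HLA-B", c("*15:02 positive", "*15:02 negative"))
  res <- do.call(rbind, out)
  # a couple of stable pathway links, carried as opaque URLs
  res$pathway_url[res$drug == "codeine" & res$source == "CPIC"] <-
    "https://www.pharmgkb.org/pathway/PA146123006"
  res$pathway_url[res$drug == "warfarin" & grepl("\\|", res$genes)] <-
    "https://www.pharmgkb.org/pathway/PA451906"
  res
}

#' Built-in fixture knowledge base
#'
#' A complete, self-validating knowledge base covering all 97 supported
#' gene-drug pairs across the 11 supported pharmacogenes, including the HLA
#' risk-allele qualifiers (HLA-A *31:01 for carbamazepine; HLA-B *57:01
#' abacavir, *58:01 allopurinol, *15:02 carbamazepine / oxcarbazepine /
#' phenytoin), curated diplotype-to-phenotype maps, a CYP interaction catalog
#' (e.g. paroxetine as a strong CYP2D6 inhibitor) and at least one
#' recommendation record per registry pair. All recommendation texts are
#' synthetic placeholders flagged `placeholder = TRUE`; they are not
#' guideline prose.
#'
#' @return A validated `pgx_kb`.
#' @export
#' @examples
#' kb <- fixture_kb()
#' kb_stats(kb)$n_pairs   # 97
fixture_kb <- function() {
  genes <- fixture_genes()
  pairs <- fixture_registry()
  new_kb(
    version = "fixture-1.0",
    last_updated = "2026-01-15",
    genes = genes,
    pairs = pairs,
    diplotypes = fixture_diplotypes(),
    interactions = fixture_interactions(),
    recommendations = fixture_recommendations(genes, pairs)
  )
}
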