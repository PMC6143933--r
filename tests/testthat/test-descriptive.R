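test_that("frequency_table counts cases once per item with the stated order", {
  cohort <- mk_cohort(list(
    list(drugs = c("X", "X"), reactions = "R1"),     # duplicate mention collapses
    list(drugs = "X", reactions = "R1"),
    list(drugs = "Y", reactions = "R2")
  ))
  tab <- frequency_table(cohort, "drug")
  expect_equal(tab$item[1], "X")
  expect_equal(tab$count[1], 2)
  expect_equal(tab$pct[1], 66.67)

  # ties order alphabetically
  tied <- mk_cohort(c(
    lapply(1:4, function(i) list(drugs = c("ZETA", "ALPHA"), reactions = "R"))
  ))
  t2 <- frequency_table(tied, "drug")
  expect_equal(t2$item, c("ALPHA", "ZETA"))

  expect_error(frequency_table(cohort, "drug", top_n = 0))
  empty <- cohort; empty$cases$demo <- empty$cases$demo[0, ]; empty$n_cases <- 0L
  empty$cases$drugs <- empty$cases$drugs[0, ]
  expect_equal(nrow(frequency_table(empty, "drug")), 0)
})

test_that("an injected top drug at prevalence 0.2 ranks first with count in the binomial band", {
  cfg <- synthetic_config(
    n_cases = 500, seed = 123,
    drug_catalog = data.frame(
      name = c("TOPDRUG", "OTHER1", "OTHER2", "OTHER3"),
      prevalence = c(0.2, 0.05, 0.05, 0.05), stringsAsFactors = FALSE),
    signal_matrix = data.frame(drug = character(0), pt = character(0),
                               log_or = numeric(0)),
    duplicate_rate = 0
  )
  gen <- generate(cfg, tempfile())
  cases <- deduplicate(link_tables(read_quarter(gen$paths, cfg$quarter_label)))
  cohort <- filter_adolescent(cases, 0, 130)   # whole generated population
  tab <- frequency_table(cohort, "drug", top_n = 5)
  # background drugs absorb cases that drew no catalog drug; the claim
  # under test concerns the catalog drugs
  tab <- tab[!(tab$item %in% cfg$background_drugs), , drop = FALSE]
  expect_equal(tab$item[1], "TOPDRUG")
  # binomial band at p = 0.2, n = 500 as stated: [78, 122]
  expect_gte(tab$count[1], 78)
  expect_lte(tab$count[1], 122)
})

test_that("drug_drilldown uses the mention denominator", {
  # one case with two reactions: each 50.00
  c1 <- mk_cohort(list(list(drugs = "D", reactions = c("A", "B"))))
  dd <- drug_drilldown(c1, "D")
  expect_equal(dd$reactions$pct, c(50, 50))

  # 3 of 10 reaction mentions are gynaecomastia -> 30.00
  specs <- c(
    lapply(1:3, function(i) list(drugs = "D", reactions = "Gynaecomastia")),
    lapply(1:7, function(i) list(drugs = "D", reactions = paste0("R", i)))
  )
  dd2 <- drug_drilldown(mk_cohort(specs), "D")
  expect_equal(dd2$reactions$pct[dd2$reactions$item == "GYNAECOMASTIA"], 30)

  # absent drug -> empty tables
  dd3 <- drug_drilldown(c1, "NOSUCHDRUG")
  expect_equal(nrow(dd3$reactions), 0)
  expect_equal(dd3$n_cases, 0)
})

test_that("untruncated drill-down percentages sum to 100", {
  set.seed(7)
  specs <- lapply(1:60, function(i) {
    list(drugs = "D",
         reactions = sample(paste0("PT", 1:9), sample(1:3, 1)))
  })
  dd <- drug_drilldown(mk_cohort(specs), "D", top_n = 100)
  expect_lt(abs(sum(dd$reactions$pct) - 100), 0.05)
  expect_true(all(dd$reactions$pct <= 100))
})

test_that("reaction mixture ordering is recovered at 800 cases", {
  # mixture weights 0.21 / 0.11 / 0.07 over a flat tail: the empirical top-3
  # ordering matches the weights with overwhelming probability
  set.seed(2024)
  wts <- c(A1 = 0.21, A2 = 0.11, A3 = 0.07, B1 = 0.05, B2 = 0.05, B3 = 0.05)
  wts <- wts / sum(wts)
  specs <- lapply(1:800, function(i) {
    list(drugs = "RISPX", reactions = sample(names(wts), 1, prob = wts))
  })
  dd <- drug_drilldown(mk_cohort(specs), "RISPX", top_n = 3)
  expect_equal(dd$reactions$item, c("A1", "A2", "A3"))
})

test_that("rank_genes orders by score then symbol and handles short tables", {
  annot <- data.frame(
    drug = "RISPERIDONE",
    gene = c("DRD2", "PRL", "HTR2A"),
    score = c(25.88, 25.59, 21.38), stringsAsFactors = FALSE)
  expect_equal(rank_genes("risperidone", annot)$gene, c("DRD2", "PRL", "HTR2A"))

  annot2 <- data.frame(drug = "IBUPROFEN",
                       gene = c("PTGS2", "PTGS1", "ALB"),
                       score = c(32.79, 22.74, 16.90), stringsAsFactors = FALSE)
  expect_equal(rank_genes("IBUPROFEN", annot2, k = 1)$gene, "PTGS2")
  # k larger than the table: full sorted table
  expect_equal(nrow(rank_genes("IBUPROFEN", annot2, k = 50)), 3)
  # ties break by symbol
  tie <- data.frame(drug = "D", gene = c("ZZZ", "AAA"), score = c(5, 5),
                    stringsAsFactors = FALSE)
  expect_equal(rank_genes("D", tie)$gene, c("AAA", "ZZZ"))
  expect_equal(nrow(rank_genes("ABSENT", annot)), 0)
})

test_that("read_gene_annotations validates the TSV contract", {
  path <- file.path(system.file("extdata", package = "faersignal"),
                    "gene_annotations_synthetic.tsv")
  annot <- read_gene_annotations(path)
  expect_true(all(c("drug", "gene", "score") %in% names(annot)))
  expect_equal(rank_genes("RISPERIDONE", annot)$gene[1], "DRD2")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("drug\tgene\tscore", "D\tG\t5", "D\tG\t6"), bad)
  expect_error(read_gene_annotations(bad), "duplicate")
  bad2 <- tempfile(fileext = ".tsv")
  writeLines(c("drug\tgene\tscore", "D\tG\t-1"), bad2)
  expect_error(read_gene_annotations(bad2), "nonnegative")
})
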