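write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

test_that("multiple events on one (patient, gene) collapse to a complex record", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(patient = c("P1", "P1"), gene = c("TP53", "TP53"),
                       mut_class = c("missense", "nonsense")), f)
  m <- read_mutations(f)
  expect_equal(nrow(m), 1)
  expect_equal(m$mut_class, "complex")
  expect_true(is.na(m$position))

  ## a single event is passed through unchanged
  write_tsv(data.frame(patient = "P1", gene = "TP53",
                       mut_class = "nonsense"), f)
  expect_equal(read_mutations(f)$mut_class, "nonsense")

  ## 6 rows with 2 duplicated pairs -> 4 records
  write_tsv(data.frame(patient = c("P1", "P1", "P2", "P2", "P3", "P3"),
                       gene = c("A", "A", "B", "B", "C", "D"),
                       mut_class = "missense"), f)
  expect_equal(nrow(read_mutations(f)), 4)
})

test_that("collapsing is idempotent across a write/read round trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(patient = c("P1", "P1", "P2"),
                       gene = c("A", "A", "B"),
                       mut_class = c("missense", "splice_site", "nonsense")), f)
  m1 <- read_mutations(f)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(m1, f2)
  m2 <- read_mutations(f2)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
})

test_that("format errors name the problem", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(patient = "P1", gene = "A"), f)
  expect_error(read_mutations(f), "mut_class", class = "xshadow_format_error")
  write_tsv(data.frame(patient = character(0), gene = character(0),
                       mut_class = character(0)), f)
  expect_error(read_mutations(f), class = "xshadow_empty_error")
  write_tsv(data.frame(patient = "P1", gene = "A", mut_class = "weird"), f)
  expect_error(read_mutations(f), "weird", class = "xshadow_format_error")
})

test_that("MAF-lite dialect maps variant classifications to the vocabulary", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(Tumor_Sample_Barcode = c("P1", "P2", "P3"),
                       Hugo_Symbol = c("KRAS", "TP53", "PTEN"),
                       Variant_Classification = c("Missense_Mutation",
                                                  "Frame_Shift_Del", "Silent"),
                       Protein_position = c(12L, 100L, 5L)), f)
  m <- read_mutations(f, dialect = "maf_lite")
  expect_setequal(m$mut_class, c("missense", "frameshift_indel", "synonymous"))
  expect_equal(m$position[m$gene == "KRAS"], 12L)
})

test_that("copy-number calls are encoded as hdel/hlamp events", {
  calls <- matrix(c("hdel", "neutral", "neutral", "hlamp"), 2, 2,
                  dimnames = list(c("P1", "P2"), c("G1", "G2")))
  ev <- encode_cnv_events(calls)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$mut_class[ev$gene == "G1"], "hdel")
  expect_equal(ev$mut_class[ev$gene == "G2"], "hlamp")

  expect_equal(nrow(encode_cnv_events(matrix("neutral", 2, 2,
    dimnames = list(c("P1", "P2"), c("G1", "G2"))))), 0)

  set.seed(1)
  calls3 <- matrix("neutral", 3, 3,
                   dimnames = list(paste0("P", 1:3), paste0("G", 1:3)))
  calls3[cbind(c(1, 2, 3, 1), c(1, 2, 3, 3))] <- c("hdel", "hlamp", "hdel", "hlamp")
  expect_equal(nrow(encode_cnv_events(calls3)), 4)
  expect_error(encode_cnv_events(NULL), class = "xshadow_precondition_error")
})

test_that("cohort alignment intersects patients across inputs", {
  mut <- xshadow:::as_mutation_table(
    data.frame(patient = c("A", "B", "C"), gene = "G1", mut_class = "missense"))
  expr <- matrix(0, 3, 2, dimnames = list(c("B", "C", "D"), c("G1", "G2")))
  cn <- matrix(0, 2, 2, dimnames = list(c("B", "C"), c("G1", "G2")))
  al <- suppressMessages(align_cohort(mut, expr, cn))
  expect_setequal(al$patients, c("B", "C"))
  expect_setequal(rownames(al$expr), c("B", "C"))
  expect_setequal(al$mut$patient, c("B", "C"))

  ## identical patient sets pass through
  expr2 <- matrix(0, 3, 1, dimnames = list(c("A", "B", "C"), "G1"))
  al2 <- suppressMessages(align_cohort(mut, expr2))
  expect_equal(nrow(al2$mut), 3)

  expr3 <- matrix(0, 1, 1, dimnames = list("Z", "G1"))
  expect_error(suppressMessages(align_cohort(mut, expr3)),
               class = "xshadow_cohort_error")
})

test_that("influence-graph merging keeps the maximum weight per pair", {
  set.seed(5)
  genes <- paste0("g", 1:12)
  df <- data.frame(gene_a = sample(genes, 80, TRUE),
                   gene_b = sample(genes, 80, TRUE),
                   weight = runif(80))
  g <- read_influence_graph(df)
  ## brute force: per unordered pair, max weight among non-self edges
  df2 <- df[df$gene_a != df$gene_b, ]
  key <- paste(pmin(df2$gene_a, df2$gene_b), pmax(df2$gene_a, df2$gene_b))
  expected <- tapply(df2$weight, key, max)
  got <- setNames(g$weight, paste(g$gene_a, g$gene_b))
  expect_equal(sort(names(got)), sort(names(expected)))
  expect_equal(as.numeric(got[names(expected)]), as.numeric(expected))
  expect_true(all(g$gene_a != g$gene_b))
  expect_error(read_influence_graph(data.frame(gene_a = "a", gene_b = "b",
                                               weight = 1.2)),
               class = "xshadow_domain_error")
})

test_that("posterior tables round-trip through TSV to 1e-12", {
  sf <- small_sim_fit()
  dir <- withr::local_tempdir()
  write_posteriors(sf$fit, dir)
  back <- read_posteriors(dir)
  expect_equal(back$genes$p_d, sf$fit$genes$p_d, tolerance = 1e-12)
  expect_equal(back$mutations$p_f, sf$fit$mutations$p_f, tolerance = 1e-12)
  expect_equal(back$regulation$p_up, sf$fit$regulation$p_up, tolerance = 1e-12)
  expect_equal(nrow(back$genes), nrow(sf$fit$genes))
  expect_equal(nrow(back$mutations), nrow(sf$fit$mutations))
})

test_that("theta, EM trace and mixture serialisation round-trip", {
  sf <- small_sim_fit()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_theta(sf$fit$params, f1)
  back <- read_theta(f1)
  expect_equal(unclass(back), unclass(sf$fit$params), tolerance = 1e-12)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_em_trace(sf$fit$em, f2)
  tr <- utils::read.delim(f2)
  expect_equal(nrow(tr), length(sf$fit$em$loglik))
  expect_true(all(diff(tr$objective) >= -1e-8))

  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_tmixtures(sf$fit$mixtures, f3)
  mx <- utils::read.delim(f3)
  expect_equal(nrow(mx), 3 * length(sf$fit$mixtures))
  expect_equal(mx$loc[1:3], unname(sf$fit$mixtures[[1]]$loc))
})
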