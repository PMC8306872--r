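test_that("expression tables round-trip through the TSV dialect bit-identically", {
  set.seed(42)
  base <- matrix(runif(20, 0, 100), 5, 4)
  x <- make_flat_expression(base, k = 2)
  x$values <- x$values * exp(matrix(rnorm(length(x$values), 0, 0.3), nrow(x$values)))

  dir <- withr::local_tempdir()
  write_expression_table(x, dir)
  y <- read_expression_table(file.path(dir, "expression.tsv"),
                             file.path(dir, "metadata.tsv"))
  expect_identical(y$values, x$values)
  expect_identical(y$samples, x$samples)
})

test_that("reading rejects unknown samples, duplicate contigs and invalid FPKM", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tgenotype\ttreatment\treplicate",
               "s1\tL\tcontrol\t1", "s2\tL\tcadmium\t1",
               "s3\tH\tcontrol\t1", "s4\tH\tcadmium\t1"),
             file.path(dir, "meta.tsv"))

  writeLines(c("contig_id\ts1\ts2\ts3\tsX", "c1\t1\t2\t3\t4"),
             file.path(dir, "bad_sample.tsv"))
  expect_error(read_expression_table(file.path(dir, "bad_sample.tsv"),
                                     file.path(dir, "meta.tsv")), "sX")

  writeLines(c("contig_id\ts1\ts2\ts3\ts4", "c1\t1\t2\t3\t4", "c1\t5\t6\t7\t8"),
             file.path(dir, "dup.tsv"))
  expect_error(read_expression_table(file.path(dir, "dup.tsv"),
                                     file.path(dir, "meta.tsv")), "duplicate contig")

  writeLines(c("contig_id\ts1\ts2\ts3\ts4", "c1\t1\t-1.0\t3\t4"),
             file.path(dir, "neg.tsv"))
  err <- expect_error(read_expression_table(file.path(dir, "neg.tsv"),
                                            file.path(dir, "meta.tsv")))
  expect_match(conditionMessage(err), "c1")
  expect_match(conditionMessage(err), "s2")

  # header-only data section is a valid empty matrix
  writeLines("contig_id\ts1\ts2\ts3\ts4", file.path(dir, "empty.tsv"))
  empty <- read_expression_table(file.path(dir, "empty.tsv"),
                                 file.path(dir, "meta.tsv"))
  expect_equal(nrow(empty$values), 0)
  expect_equal(ncol(empty$values), 4)
})

test_that("the container enforces the design invariants", {
  m <- matrix(1, 1, 4, dimnames = list("c1", paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     genotype = c("L", "L", "H", "H"),
                     treatment = c("control", "cadmium", "control", "cadmium"),
                     replicate = 1L)
  expect_s3_class(expression_set(m, meta), "expression_set")

  meta_bad <- meta; meta_bad$genotype <- c("L", "L", "L", "L")
  expect_error(expression_set(m, meta_bad), "missing")
  meta_dup <- meta; meta_dup$sample_id <- c("s1", "s1", "s3", "s4")
  expect_error(expression_set(matrix(1, 1, 4, dimnames = list("c1", NULL)), meta_dup),
               "duplicate sample")
  expect_error(expression_set(m, transform(meta, genotype = c("X", "L", "H", "H"))),
               "genotype")
})

test_that("condition summaries give replicate means and n-1 standard deviations", {
  x <- make_expression(list(L.control = matrix(c(10, 20, 30), 1),
                            L.cadmium = matrix(27.4, 1, 1),
                            H.control = matrix(c(5, 5), 1),
                            H.cadmium = matrix(0, 1, 2)))
  s <- condition_summary(x)
  lc <- s[s$genotype == "L" & s$treatment == "control", ]
  expect_equal(lc$mean_fpkm, 20)
  expect_equal(lc$sd_fpkm, 10)  # hand value: sd(10,20,30) with n-1
  expect_equal(lc$n, 3)

  single <- s[s$genotype == "L" & s$treatment == "cadmium", ]
  expect_equal(single$mean_fpkm, 27.4)
  expect_equal(single$sd_fpkm, 0)

  zero <- s[s$genotype == "H" & s$treatment == "cadmium", ]
  expect_equal(zero$mean_fpkm, 0)

  # per-contig replicate counts add up to the number of samples
  expect_equal(sum(s$n), ncol(x$values))
})

test_that("condition summaries are invariant under replicate-column permutation", {
  set.seed(7)
  sim <- generate_dataset(generator_config(blocks = default_blocks(n_null = 30), seed = 3))
  x <- sim$expression
  perm <- sample(ncol(x$values))
  y <- expression_set(x$values[, perm, drop = FALSE], x$samples[perm, ])
  a <- condition_summary(x)
  b <- condition_summary(y)
  key <- function(d) d[order(d$contig_id, d$genotype, d$treatment),
                       c("contig_id", "genotype", "treatment", "mean_fpkm", "sd_fpkm", "n")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("annotation tables keep unannotated contigs out of the table, not dropped downstream", {
  dir <- withr::local_tempdir()
  writeLines(c("contig_id\tdescription\tagi_code\tterms",
               "c1\taquaporin pip1-2\tAT1G01620\ttransport;membrane",
               "c2\tno hits - unknown\t\t"),
             file.path(dir, "ann.tsv"))
  ann <- read_annotation_table(file.path(dir, "ann.tsv"))
  expect_equal(nrow(ann), 2)
  expect_true(is.na(ann$agi_code[2]))
  res <- over_representation(c("c1", "c3"), ann, c("c1", "c2", "c3", "c4"))
  expect_true(all(res$N == 4))  # c3/c4 unannotated but still in the universe
})
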