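test_that("omics matrices are read in either orientation with cleaning", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  ## genes-as-rows: 3 genes x 2 samples
  writeLines(c("gene\tS1\tS2", "g1\t1\t4", "g2\t2\t5", "g3\t3\t6"), tf)
  om <- read_omics_matrix(tf, "EXP", orientation = "genes-as-rows")
  expect_equal(dim(om$values), c(2L, 3L))
  expect_equal(rownames(om$values), c("S1", "S2"))
  expect_equal(colnames(om$values), c("G1", "G2", "G3"))  # upper-cased
  expect_equal(unname(om$values["S2", "G1"]), 4)

  ## duplicate gene columns collapse to their mean
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tG1\tG1\tG2", "S1\t1\t3\t7", "S2\t5\t5\t9"), tf2)
  om2 <- read_omics_matrix(tf2, "CNV")
  expect_equal(colnames(om2$values), c("G1", "G2"))
  expect_equal(unname(om2$values[, "G1"]), c(2, 5))

  ## a missing cell in a column of {1, 2, _, 2, 4} imputes the median 2
  ## (missingness is 20% in both its row and column: inside the keep bound)
  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste0("sample_id,G1,", paste0("X", 1:4, collapse = ",")),
               "S1,1,1,1,1,1", "S2,2,1,1,1,1", "S3,NA,1,1,1,1",
               "S4,2,1,1,1,1", "S5,4,1,1,1,1"), tf3)
  om3 <- read_omics_matrix(tf3, "MET")
  expect_equal(unname(om3$values["S3", "G1"]), 2)

  ## non-numeric body cell is a parse error naming the column
  tf4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tG1", "S1\toops"), tf4)
  expect_error(read_omics_matrix(tf4, "EXP"), "non-numeric.*G1")
})

test_that("omics write/read round trip is bit-exact", {
  set.seed(1)
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("S", 1:3), paste0("G", 1:4)))
  om <- omics_matrix(m, "EXP")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(om, tf)
  back <- read_omics_matrix(tf, "EXP")
  expect_identical(back$values, om$values)
})

test_that("GMT parsing respects order, de-duplication and exclusions", {
  tf <- withr::local_tempfile(fileext = ".gmt")
  n <- 186L
  lines <- sprintf("PW%03d\tdesc\t%s", seq_len(n),
                   vapply(seq_len(n), function(i)
                     paste(sprintf("g%d_%d", i, 1:4), collapse = "\t"),
                     character(1)))
  lines[5] <- "PW005\tdesc\tG1\tG1\tG2"       # duplicate gene within a set
  writeLines(lines, tf)
  excl <- sprintf("PW%03d", 1:40)
  pc <- read_gene_sets(tf, exclusions = excl)
  expect_s3_class(pc, "pathway_collection")
  expect_length(pc, 146L)                      # 186 - 40
  expect_equal(names(pc$pathways)[1], "PW041") # file order preserved
  pc_all <- read_gene_sets(tf)
  expect_length(pc_all, n)
  expect_equal(pc_all$pathways$PW005, c("G1", "G2"))  # first occurrence kept

  tf_bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("PW001\tdesc\tG1", "PW002\tonly-two-fields"), tf_bad)
  expect_error(read_gene_sets(tf_bad), "line 2")
})

test_that("survival labels form an exhaustive disjoint three-way partition", {
  clin <- clinical_table(c("a", "b", "c"), c(3.0, 1.5, 1.5), c(0L, 1L, 0L))
  lab <- assign_survival_labels(clin, threshold = 2)
  expect_equal(as.character(lab$class), c("LTS", "non-LTS", "excluded"))

  ## property over random cohorts: the three rules cover every case once
  set.seed(42)
  for (rep in 1:5) {
    t <- runif(100, 0, 5)
    e <- rbinom(100, 1, 0.6)
    cl <- assign_survival_labels(clinical_table(sprintf("s%d", 1:100), t, e))$class
    expect_false(anyNA(cl))
    expect_equal(as.character(cl),
                 ifelse(t > 2, "LTS", ifelse(e == 1, "non-LTS", "excluded")))
  }
  expect_warning(
    assign_survival_labels(clinical_table("x", 1, 0L), threshold = 2),
    "all samples excluded")
})

test_that("harmonize intersects samples and genes and is idempotent", {
  m1 <- matrix(1:12, 3, 4, dimnames = list(c("A", "B", "C"), paste0("G", 1:4)))
  m2 <- matrix(1:12, 3, 4, dimnames = list(c("B", "C", "D"), paste0("G", c(2:4, 9))))
  lab <- assign_survival_labels(
    clinical_table(c("A", "B", "C", "D"), c(3, 3, 3, 3), c(1L, 1L, 1L, 0L)))
  ds <- harmonize(list(omics_matrix(m1, "X"), omics_matrix(m2 * 1.0, "Y")), lab)
  expect_equal(ds$samples, c("B", "C"))
  expect_equal(ds$genes, c("G2", "G3", "G4"))
  expect_equal(rownames(ds$omics$X$values), rownames(ds$omics$Y$values))

  ds2 <- harmonize(ds$omics, lab)
  expect_identical(ds2$omics, ds$omics)        # idempotence

  m3 <- matrix(1.0, 1, 1, dimnames = list("Z", "G1"))
  expect_error(harmonize(list(omics_matrix(m1 * 1.0, "X"),
                              omics_matrix(m3, "W")), lab),
               "empty sample or gene intersection")
})

test_that("harmonized shapes match generator bookkeeping", {
  co <- generate_multiomics(synthetic_config(
    n_per_class = c("LTS" = 20L, "non-LTS" = 30L), n_excluded = 5L,
    n_pathways = 30L, genes_per_pathway = c(10L, 10L), planted = NULL,
    seed = 99))
  ds <- small_dataset(co)
  expect_equal(length(ds$samples), 50L)        # excluded samples dropped
  expect_equal(length(ds$genes), 300L)         # 30 pathways x 10 genes
  for (o in ds$omics) expect_equal(dim(o$values), c(50L, 300L))
})
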