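test_that("matrix_tsv reader echoes the file and enforces validity", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t0\t5", "g3\t10\t10"), tsv)
  m <- readExpressionTable(tsv)
  expect_identical(dimnames(m), list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_equal(unname(m), rbind(c(1, 2), c(0, 5), c(10, 10)))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "g1\t1", "g1\t2"), dup)
  expect_error(readExpressionTable(dup), "g1")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t-4"), neg)
  expect_error(readExpressionTable(neg), "g2.*s2")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3"), ragged)
  expect_error(readExpressionTable(ragged))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "g1\tNA"), bad)
  expect_error(readExpressionTable(bad), "missing")
})

test_that("per-sample two-column files reproduce the equivalent matrix_tsv", {
  m <- rand_abundance(10, 2, seed = 42)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTable(m, tsv)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste0("gene_id\t", colnames(m)[1]),
               paste(rownames(m), m[, 1], sep = "\t")), f1)
  writeLines(c(paste0("gene_id\t", colnames(m)[2]),
               paste(rownames(m), m[, 2], sep = "\t")), f2)
  expect_equal(readExpressionTable(c(f1, f2), "per_sample_two_column"),
               readExpressionTable(tsv, "matrix_tsv"))
})

test_that("gene-set readers parse both dialects and round-trip", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("P1\tdesc\tg1\tg2", gmt)
  gs <- readGeneSets(gmt, "gmt")
  expect_identical(geneSets(gs), list(P1 = c("g1", "g2")))

  two <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tP1", "g2\tP1", "g1\tP2"), two)
  gs2 <- readGeneSets(two, "two_column_tsv")
  expect_identical(geneSets(gs2), list(P1 = c("g1", "g2"), P2 = "g1"))

  dupgmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\td\tg1", "P1\td\tg2"), dupgmt)
  expect_error(readGeneSets(dupgmt), "duplicate pathway")

  emptygmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\td\tg1", "P2\td"), emptygmt)
  expect_warning(gs3 <- readGeneSets(emptygmt), "empty")
  expect_identical(names(gs3), "P1")

  # round trip of a random 5-pathway collection, both formats
  set.seed(9)
  sets <- lapply(1:5, function(i)
    sample(sprintf("g%02d", 1:40), sample(3:8, 1)))
  names(sets) <- sprintf("path%d", 1:5)
  coll <- GeneSetCollection(sets)
  for (fmt in c("gmt", "two_column_tsv")) {
    f <- withr::local_tempfile()
    writeGeneSets(coll, f, fmt)
    expect_identical(geneSets(readGeneSets(f, fmt)), geneSets(coll))
  }
})

test_that("sample design reader derives grid labels and rejects duplicates", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,concentration_index,time_index,replicate_index",
               "a,1,2,1", "b,3,4,2"), csv)
  d <- readSampleDesign(csv)
  expect_identical(d$label, c("ac1t2", "ac3t4"))
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,concentration_index,time_index,replicate_index",
               "a,1,1,1", "a,1,1,2"), dup)
  expect_error(readSampleDesign(dup), "duplicate")
})

test_that("gene filtering applies both policies, is idempotent, errors empty", {
  m <- rbind(g1 = c(1, 2), g2 = c(0, 5))
  colnames(m) <- c("s1", "s2")
  expect_message(f <- filterGenes(m, "all_positive"), "1 gene")
  expect_identical(rownames(f), "g1")

  pos <- rand_abundance(6, 3, seed = 2)
  expect_equal(suppressMessages(filterGenes(pos, "all_positive")), pos)

  # gene k positive in k/4 samples; keep those with >= half positive
  m4 <- rbind(g1 = c(1, 0, 0, 0), g2 = c(1, 1, 0, 0),
              g3 = c(1, 1, 1, 0), g4 = c(1, 1, 1, 1))
  colnames(m4) <- paste0("s", 1:4)
  kept <- suppressMessages(filterGenes(m4, "min_fraction_positive", 0.5))
  expect_identical(rownames(kept), c("g2", "g3", "g4"))

  for (seed in 1:3) {
    x <- rand_abundance(8, 4, seed)
    x[sample(length(x), 6)] <- 0
    once <- suppressMessages(filterGenes(x, "all_positive"))
    expect_identical(suppressMessages(filterGenes(once, "all_positive")),
                     once)
  }
  expect_error(suppressMessages(
    filterGenes(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
                "all_positive")), "no genes")
})

test_that("replicate collapse averages cells, reports dispersion, errors on
           empty cells", {
  # single replicate per cell: identity with zero dispersion
  v <- rand_abundance(5, 4, seed = 3)
  se1 <- grid_se(v, C = 2, Tn = 2, R = 1)
  col1 <- collapseReplicates(se1)
  expect_equal(unname(abundance(col1)), unname(v))
  expect_true(all(replicateDispersion(col1) == 0))
  expect_identical(colnames(col1), c("ac1t1", "ac1t2", "ac2t1", "ac2t2"))

  # arithmetic mean of (2, 4) is 3; geometric mean of (1, 100) is 10
  two <- matrix(c(2, 4), 1, 2, dimnames = list("g1", NULL))
  se2 <- grid_se(two, C = 1, Tn = 1, R = 2)
  expect_equal(unname(abundance(collapseReplicates(se2, "mean_linear"))),
               matrix(3))
  geo <- matrix(c(1, 100), 1, 2, dimnames = list("g1", NULL))
  se3 <- grid_se(geo, C = 1, Tn = 1, R = 2)
  colg <- collapseReplicates(se3, "mean_log", floor = 0)
  expect_equal(unname(abundance(colg)), matrix(10))
  expect_equal(unname(replicateDispersion(colg)),
               matrix(sd(log(c(1, 100)))))

  # mean_linear commutes with scalar scaling
  v2 <- rand_abundance(6, 8, seed = 4)
  se4 <- grid_se(v2, C = 2, Tn = 2, R = 2)
  se4x <- grid_se(v2 * 7, C = 2, Tn = 2, R = 2)
  expect_equal(abundance(collapseReplicates(se4x)),
               7 * abundance(collapseReplicates(se4)))

  # a grid cell with zero replicates is a hard error
  v3 <- rand_abundance(3, 2, seed = 5)
  colnames(v3) <- c("a", "b")
  gap <- SurprisalExperiment(v3, data.frame(
    sample_id = c("a", "b"), concentration_index = c(1L, 3L),
    time_index = 1L, replicate_index = 1L))
  expect_error(collapseReplicates(gap), "zero replicates")
})

test_that("experiment container rejects invalid designs and values", {
  v <- rand_abundance(3, 2, seed = 6)
  expect_error(SurprisalExperiment(v, data.frame(
    sample_id = "s01", concentration_index = 1L, time_index = 1L,
    replicate_index = 1L)), "design row")
  d <- data.frame(sample_id = colnames(v), concentration_index = 1L,
                  time_index = 1L, replicate_index = 1L)
  expect_error(SurprisalExperiment(v, d), "unique")
  v[1] <- -1
  d$replicate_index <- 1:2
  expect_error(SurprisalExperiment(v, d), "non-negative")
})
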