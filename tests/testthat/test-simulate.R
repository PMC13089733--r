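# Synthetic-data generators and their truth tables.

test_that("the annotation-mirroring spec reproduces the published geometry", {
  sim <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 1)
  mg <- sim$record
  expect_equal(genomeLength(mg), 15788L)
  s <- summarizeArchitecture(mg)
  expect_equal(s$n_spacers, 18L)
  expect_equal(s$n_overlaps, 7L)
  expect_equal(s$wraparound_unannotated, 151L)
  # planned gap vector recovered from coordinates
  gaps <- computeGaps(mg)
  expect_equal(gaps$gap, sim$truth$gap_plan)
  # planned gene order recovered
  expect_equal(orderTable(extractGeneOrder(mg)),
               sim$truth$gene_order, ignore_attr = TRUE)
})

test_that("generator output is byte-identical for a fixed seed", {
  a <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 77)
  b <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 77)
  expect_identical(a$record@sequence, b$record@sequence)
  expect_identical(a$truth, b$truth)
  c <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 78)
  expect_false(identical(a$record@sequence, c$record@sequence))
})

test_that("single-feature and inconsistent specs behave as specified", {
  spec <- genomeSpec(data.frame(name = "rrnX", kind = "rRNA", strand = "+"),
                     length_plan = 500L, gap_plan = integer(0),
                     wraparound = 0L)
  sim <- simulateMitogenome(spec, seed = 4)
  expect_equal(genomeLength(sim$record), 500L)
  expect_equal(nrow(computeGaps(sim$record)), 0L)
  # overlap larger than the upstream feature is a spec error
  expect_error(
    genomeSpec(data.frame(name = c("trnA", "trnB"), kind = "tRNA",
                          strand = "+"),
               length_plan = c(70L, 70L), gap_plan = -70L),
    "overlap exceeds")
})

test_that("per-feature base-count truth matches an independent tally", {
  sim <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 9)
  ft <- features(sim$record)
  for (i in c(1, 15, 37)) {  # a PCG, the minus-strand PCG, an rRNA
    s <- substr(sim$record@sequence, ft$start[i], ft$end[i])
    expect_equal(unname(sim$truth$base_counts[ft$name[i], ]),
                 unname(bruteBaseCounts(s)))
  }
})

test_that("empirical base frequencies converge to the composition weights", {
  w <- c(A = 0.5, C = 0.2, G = 0.2, T = 0.1)
  spec <- genomeSpec(data.frame(name = "rrnX", kind = "rRNA", strand = "+"),
                     length_plan = 100000L, gap_plan = integer(0),
                     wraparound = 0L, weights = w)
  sim <- simulateMitogenome(spec, seed = 15)
  counts <- bruteBaseCounts(sim$record@sequence)
  L <- sum(counts)
  for (b in names(w)) {
    se <- sqrt(w[b] * (1 - w[b]) / L)
    expect_lt(abs(counts[b] / L - w[b]), 3 * se)
  }
})

test_that("generator GenBank output round trips to the emitted record", {
  sim <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 6)
  gb <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(sim$record, gb)
  rt <- readGenBank(gb)
  expect_identical(rt@sequence, sim$record@sequence)
  cols <- c("name", "kind", "start", "end", "strand")
  expect_identical(features(rt)[cols], features(sim$record)[cols])
  expect_true(isCircular(rt))
})

test_that("haplotype truth has the published 16S structure at n = 30", {
  spec <- haplotypeSpec(30, 600, c(27, 1, 1, 1))  # 3 singleton mutations
  sim <- simulateHaplotypes(spec, seed = 5)
  expect_equal(sim$truth$H, 4L)
  expect_equal(sim$truth$S, 3L)
  expect_equal(sim$truth$k, 87 / 435)  # 27*3 ref pairs + 3 double pairs
  expect_equal(length(sim$alignment), 30L)
})

test_that("degenerate haplotype specs give exact closed forms", {
  one <- simulateHaplotypes(haplotypeSpec(5, 50, 5L), seed = 3)
  expect_equal(one$truth$H, 1L)
  expect_equal(one$truth$Hd, 0)
  expect_equal(one$truth$S, 0L)
  expect_equal(one$truth$k, 0)
  two <- simulateHaplotypes(haplotypeSpec(2, 100, c(1L, 1L)), seed = 3)
  expect_equal(two$truth$k, 1)
  expect_equal(two$truth$Pi, 0.01)
})

test_that("explicit mutation plans are honoured and validated", {
  plan <- list(data.frame(site = c(3L, 10L), base = c("T", "G")))
  # plan bases must differ from the reference; probe with a valid seed
  sim <- tryCatch(
    simulateHaplotypes(haplotypeSpec(4, 20, c(3L, 1L), mutations = plan),
                       seed = 2),
    error = function(e) e)
  if (inherits(sim, "error")) {
    expect_match(conditionMessage(sim), "replants")
  } else {
    m <- do.call(rbind, strsplit(as.character(sim$alignment), ""))
    expect_equal(unname(m[4, 3]), "T")
    expect_equal(unname(m[4, 10]), "G")
    expect_equal(sim$truth$S, 2L)
  }
  # out-of-range site is a spec error
  expect_error(haplotypeSpec(4, 20, c(3L, 1L),
                             mutations = list(data.frame(site = 25L,
                                                         base = "A"))),
               "site")
})

test_that("the two generators use independent random streams", {
  g1 <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 55)
  h <- simulateHaplotypes(haplotypeSpec(6, 40, c(5L, 1L)), seed = 55)
  g2 <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 55)
  expect_identical(g1$record@sequence, g2$record@sequence)
  # and neither disturbs the session RNG stream
  set.seed(123); expected <- runif(3)
  set.seed(123); invisible(runif(1))
  invisible(simulateHaplotypes(haplotypeSpec(6, 40, c(5L, 1L)), seed = 1))
  expect_identical(runif(2), expected[2:3])
})
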