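# Genetic codes, codon extraction, RSCU, amino-acid composition.

test_that("translation table 9 carries the documented substitutions", {
  code <- geneticCode(9)
  expect_equal(unname(code$codon_map[c("AGA", "AGG")]), c("S", "S"))
  expect_equal(unname(code$codon_map["AAA"]), "N")
  expect_equal(unname(code$codon_map["TGA"]), "W")
  expect_equal(unname(code$codon_map["ATA"]), "I")  # unlike tables 2/5
  expect_setequal(code$stop_codons, c("TAA", "TAG"))
  expect_equal(length(code$codon_map), 64L)
  expect_equal(length(code$sense_codons), 62L)
  # serine is 8-fold under table 9 (TCN + AGN), leucine 6-fold
  expect_equal(length(code$family$S), 8L)
  expect_equal(length(code$family$L), 6L)
  # standard code sanity: AGA is arginine, not a stop there
  expect_equal(unname(geneticCode(1)$codon_map["AGA"]), "R")
  expect_true("TGA" %in% geneticCode(1)$stop_codons)
  expect_error(geneticCode(3), "unsupported")
})

test_that("all supported code tables match the Biostrings reference", {
  for (id in c(1, 2, 5, 9)) {
    ref <- Biostrings::getGeneticCode(as.character(id))
    mine <- geneticCode(id)$codon_map
    expect_identical(as.character(mine[names(ref)]), as.character(ref),
                     label = paste("table", id))
  }
})

test_that("codon extraction splits, audits and flags as specified", {
  # planned 10-codon CDS written by hand
  cds <- paste0("ATG", "GCTGATCGTTTCCCAGGATCTACTGTT", "TAA")  # 33 bp
  pad <- strrep("A", 7)
  mg <- toyRecord(paste0(cds, pad),
                  data.frame(name = "cox1", start = 1L, end = 33L,
                             strand = "+"))
  ex <- extractCodons(mg, "cox1")
  expect_equal(length(ex$codons), 11L)
  expect_equal(ex$codons[1], "ATG")
  expect_equal(ex$codons[11], "TAA")
  expect_equal(ex$remainder, "")
  expect_true(ex$start_ok)
  expect_true(ex$stop_ok)
  # minus-strand extraction equals hand-built reverse complement
  mgrc <- toyRecord(paste0(pad, bsRevcomp(cds)),
                    data.frame(name = "cox1", start = 8L, end = 40L,
                               strand = "-"))
  exrc <- extractCodons(mgrc, "cox1")
  expect_identical(exrc$codons, ex$codons)
  # incomplete terminal stop: 688 bp gives 229 codons + "T"
  sim <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 2)
  e2 <- extractCodons(sim$record, c("cox2", "1933"))
  expect_equal(length(e2$codons), 229L)
  expect_equal(e2$remainder, "T")
  expect_true(e2$stop_ok)
  # internal stop warned with position
  bad <- paste0("ATG", "TAA", "GCT", "TAG")
  mgb <- toyRecord(bad, data.frame(name = "nad9", start = 1L, end = 12L,
                                   strand = "+"))
  expect_warning(exb <- extractCodons(mgb, "nad9"), "position.* 2")
  # too-short and non-PCG inputs rejected
  mgs <- toyRecord("ATGTA", data.frame(name = "nad9", start = 1L, end = 5L,
                                       strand = "+"))
  expect_error(extractCodons(mgs, "nad9"), "too short")
  mgt <- toyRecord(strrep("A", 70),
                   data.frame(name = "trnF", start = 1L, end = 70L,
                              strand = "+"))
  expect_error(extractCodons(mgt, "trnF"), "PCG")
})

test_that("generator codon and peptide truth is recovered exactly", {
  sim <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 13)
  code <- geneticCode(9)
  ft <- features(sim$record)
  pcgs <- ft[ft$kind == "PCG", ]
  for (i in seq_len(nrow(pcgs))) {
    nm <- pcgs$name[i]
    ex <- extractCodons(sim$record, pcgs[i, ], code)
    expect_identical(ex$codons, sim$truth$codons[[nm]], label = nm)
    expect_identical(ex$remainder, sim$truth$remainders[[nm]], label = nm)
    # independent translation oracle (Biostrings, table 9)
    body <- if (nzchar(ex$remainder)) ex$codons
      else ex$codons[-length(ex$codons)]
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(paste(body, collapse = "")),
      genetic.code = Biostrings::getGeneticCode("9"),
      no.init.codon = TRUE))
    expect_identical(pep, sim$truth$peptides[[nm]], label = nm)
  }
})

test_that("RSCU matches hand computations and conserves family sums", {
  code <- geneticCode(9)
  # 2-fold family with counts (3, 1)
  r <- rscu(c(TTT = 3, TTC = 1), code)
  expect_equal(unname(r[c("TTT", "TTC")]), c(1.5, 0.5))
  # uniform usage in a family gives all 1
  r2 <- rscu(setNames(rep(2L, 4), c("GTT", "GTC", "GTA", "GTG")), code)
  expect_equal(unname(r2[c("GTT", "GTC", "GTA", "GTG")]), rep(1, 4))
  # 4-fold boundary
  r3 <- rscu(c(CCT = 4), code)
  expect_equal(unname(r3[c("CCT", "CCC", "CCA", "CCG")]), c(4, 0, 0, 0))
  # unobserved families undefined, never zero
  expect_true(all(is.na(r3[code$family$W])))
  # family-sum conservation on random inputs
  set.seed(19)
  for (rep in 1:25) {
    counts <- setNames(rpois(62, lambda = runif(1, 0.5, 20)),
                       code$sense_codons)
    r <- rscu(counts, code)
    for (fam in code$family) {
      if (sum(counts[fam]) > 0)
        expect_equal(sum(r[fam]), length(fam))
      else
        expect_true(all(is.na(r[fam])))
    }
  }
})

test_that("amino-acid composition pools PCGs and sums to 100", {
  code <- geneticCode(9)
  expect_equal(unname(aminoAcidComposition(c(CTA = 5), code)["L"]), 100)
  sim <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 23)
  cu <- codonReport(sim$record, code)
  expect_equal(sum(cu@aa_pct), 100)
  # counts equal the generator truth (stops excluded)
  truth_counts <- table(unlist(lapply(names(sim$truth$codons), function(nm) {
    cd <- sim$truth$codons[[nm]]
    if (sim$truth$remainders[[nm]] == "") cd <- cd[-length(cd)]
    cd
  })))
  expect_equal(unname(cu@counts[names(truth_counts)]),
               unname(as.integer(truth_counts)))
  # total codons = sum floor(len/3) minus complete stops (brute re-count)
  ft <- features(sim$record)
  pcg <- ft[ft$kind == "PCG", ]
  lens <- featureLength(pcg$start, pcg$end, genomeLength(sim$record))
  expected_total <- sum(lens %/% 3L) - sum(lens %% 3L == 0L)
  expect_equal(sum(cu@counts), expected_total)
})

test_that("codonReport audits starts/stops and rejects PCG-free records", {
  sim <- simulateMitogenome(hatraLikeGenomeSpec(), seed = 29)
  cu <- codonReport(sim$record)
  expect_equal(nrow(cu@audit), 13L)
  expect_true(all(cu@audit$start_ok))
  expect_true(all(cu@audit$stop_ok))
  expect_true(all(cu@audit$n_internal_stops == 0L))
  expect_equal(sort(cu@audit$stop_observed[cu@audit$incomplete_stop]),
               c("T--", "T--"))  # cox2 and nad4
  mg <- toyRecord(strrep("A", 70),
                  data.frame(name = "trnF", start = 1L, end = 70L,
                             strand = "+"))
  expect_error(codonReport(mg), "no protein-coding")
})
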