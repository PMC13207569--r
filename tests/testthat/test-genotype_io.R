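write_lines <- function(lines, path) { writeLines(lines, path); path }

test_that("locus table reads in order and validates", {
  f <- write_lines(c("rsid\tchrom\tpos\teffect_allele\tother_allele",
                     "rs1\t1\t100\tA\tG",
                     "rs2\t2\t200\tC\tT",
                     "rs3\t3\t300\tG\tA"), tempfile(fileext = ".tsv"))
  tab <- read_locus_table(f)
  expect_s3_class(tab, "locus_table")
  expect_equal(tab$rsid, c("rs1", "rs2", "rs3"))
  expect_true(all(is.na(tab$beta)))

  bad <- write_lines(c("rsid\tchrom\tpos\teffect_allele\tother_allele",
                       "rs1\t1\t100\tA\tA"), tempfile(fileext = ".tsv"))
  expect_error(read_locus_table(bad), "effect_allele equals other_allele")

  dup <- write_lines(c("rsid\tchrom\tpos\teffect_allele\tother_allele",
                       "rs1\t1\t100\tA\tG", "rs1\t1\t101\tC\tT"),
                     tempfile(fileext = ".tsv"))
  expect_error(read_locus_table(dup), "duplicate rsid")

  pos <- write_lines(c("rsid\tchrom\tpos\teffect_allele\tother_allele",
                       "rs1\t1\tzero\tA\tG"), tempfile(fileext = ".tsv"))
  expect_error(read_locus_table(pos), "position")
})

test_that("shipped synthetic risk-score panel has 18 loci with betas", {
  f <- system.file("extdata", "prs_loci_synthetic.tsv", package = "locusdiff")
  tab <- read_locus_table(f)
  expect_equal(nrow(tab), 18L)
  expect_false(anyNA(tab$beta))
})

test_that("sample panel reading builds the two-level grouping", {
  f <- tempfile(fileext = ".tsv")
  write_lines(c("sample\tpop\tsuper_pop\tgender",
                "s1\tX1\tSUP\tmale", "s2\tX1\tSUP\tfemale",
                "s3\tX2\tSUP\t1", "s4\tX2\tSUP\t2"), f)
  pan <- read_panel(f)
  expect_equal(as.integer(table(pan$subpop)), c(2L, 2L))
  expect_equal(pan$sex, c("male", "female", "male", "female"))

  # full-size two-level panel: 26 subpopulations under 5 superpopulations
  big <- write_1kg_panel(tempfile(fileext = ".panel"))
  pan <- read_panel(big, allowed_superpops = c("AFR", "AMR", "EAS", "EUR", "SAS"))
  expect_equal(nrow(pan), 2504L)
  expect_equal(length(unique(pan$subpop)), 26L)
  expect_equal(sort(unique(pan$superpop)), c("AFR", "AMR", "EAS", "EUR", "SAS"))
  lay <- panel_1kg_layout()
  expect_equal(as.integer(table(pan$superpop)[c("AFR","AMR","EAS","EUR","SAS")]),
               as.integer(tapply(lay$size, lay$superpop, sum)[c("AFR","AMR","EAS","EUR","SAS")]))
})

test_that("panel validation rejects duplicates and ambiguous nesting", {
  f <- tempfile(fileext = ".tsv")
  write_lines(c("sample\tpop\tsuper_pop", "s1\tX1\tSUP", "s1\tX1\tSUP"), f)
  expect_error(read_panel(f), "twice")
  write_lines(c("sample\tpop\tsuper_pop",
                "s1\tX1\tSUPA", "s2\tX1\tSUPB"), f)
  expect_error(read_panel(f), "two superpopulations")
  write_lines(c("sample\tpop\tsuper_pop", "s1\tX1\tZZZ"), f)
  expect_error(read_panel(f, allowed_superpops = KG <- c("AFR")), "unknown")
})

make_vcf <- function(path, records, samples) {
  writeLines(c(
    "##fileformat=VCFv4.1",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

simple_panel <- function(samples) {
  pan <- data.frame(sample = samples, subpop = "X1", superpop = "SUP",
                    sex = NA_character_, stringsAsFactors = FALSE)
  class(pan) <- c("sample_panel", "data.frame")
  pan
}

test_that("dosage counts effect-allele copies in either orientation", {
  loci <- read_locus_table(write_lines(
    c("rsid\tchrom\tpos\teffect_allele\tother_allele",
      "rs1\t1\t100\tA\tG",   # effect == ALT
      "rs2\t1\t200\tC\tT"),  # effect == REF
    tempfile(fileext = ".tsv")))
  vcf <- make_vcf(tempfile(fileext = ".vcf"), c(
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1|1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1"),
    c("s1", "s2"))
  dm <- build_dosage_matrix(vcf, loci, simple_panel(c("s1", "s2")))
  expect_equal(unname(dm$dosage[, "rs1"]), c(1L, 2L))
  expect_equal(unname(dm$dosage[, "rs2"]), c(2L, 1L))
  expect_equal(nrow(dm$drops), 0L)
})

test_that("complete-case rule drops loci with any missing call, with reasons", {
  loci <- read_locus_table(write_lines(
    c("rsid\tchrom\tpos\teffect_allele\tother_allele",
      paste0("rs", 1:5, "\t1\t", 1:5 * 100, "\tA\tG", collapse = "\n")),
    tempfile(fileext = ".tsv")))
  recs <- c(
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t0/0",
    "1\t200\trs2\tG\tA\t.\tPASS\t.\tGT\t./.\t0/1",   # missing call
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/1",
    "1\t500\trs5\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/0")   # rs4 absent
  vcf <- make_vcf(tempfile(fileext = ".vcf"), recs, c("s1", "s2"))
  dm <- build_dosage_matrix(vcf, loci, simple_panel(c("s1", "s2")))
  expect_equal(colnames(dm$dosage), c("rs1", "rs3", "rs5"))
  expect_setequal(dm$drops$rsid, c("rs2", "rs4"))
  expect_equal(dm$drops$reason[dm$drops$rsid == "rs2"], "missing_genotype")
  expect_equal(dm$drops$reason[dm$drops$rsid == "rs4"], "absent_from_vcf")
})

test_that("non-flippable and multi-allelic records are dropped loudly", {
  loci <- read_locus_table(write_lines(
    c("rsid\tchrom\tpos\teffect_allele\tother_allele",
      "rs1\t1\t100\tA\tG", "rs2\t1\t200\tA\tG"),
    tempfile(fileext = ".tsv")))
  vcf <- make_vcf(tempfile(fileext = ".vcf"), c(
    "1\t100\trs1\tC\tT\t.\tPASS\t.\tGT\t0/0",       # alleles mismatch
    "1\t200\trs2\tG\tA,C\t.\tPASS\t.\tGT\t0/1"),    # multi-allelic
    "s1")
  expect_warning(dm <- build_dosage_matrix(vcf, loci, simple_panel("s1")),
                 "do not match")
  expect_equal(ncol(dm$dosage), 0L)
  expect_setequal(dm$drops$reason, c("allele_mismatch", "multiallelic"))
})

test_that("simulate -> write -> read round-trips dosages exactly", {
  ds <- simulate_dataset(sim_config(n_pops = 2, pop_sizes = 8, n_loci = 12,
                                    fst = 0.2, seed = 11))
  dir <- tempfile()
  paths <- write_fixture(ds, dir)
  loci <- read_locus_table(paths["loci"])
  pan <- read_panel(paths["panel"])
  dm <- build_dosage_matrix(paths[["vcf"]], loci, pan)
  expect_identical(dm$dosage, ds$dosage$dosage)
  expect_identical(pan$subpop, ds$panel$subpop)
})

test_that("consistent REF/ALT flips leave the dosage matrix unchanged", {
  ds <- simulate_dataset(sim_config(n_pops = 1, pop_sizes = 6, n_loci = 5,
                                    fst = 0, seed = 4))
  dir <- tempfile()
  paths <- write_fixture(ds, dir)
  # flip REF<->ALT and genotype codes in the VCF text
  lines <- readLines(paths[["vcf"]])
  body <- !startsWith(lines, "#")
  flip <- function(line) {
    f <- strsplit(line, "\t")[[1]]
    tmp <- f[4]; f[4] <- f[5]; f[5] <- tmp
    gt <- f[-(1:9)]
    gt <- chartr("01", "10", gt)
    paste(c(f[1:9], gt), collapse = "\t")
  }
  lines[body] <- vapply(lines[body], flip, character(1))
  flipped <- tempfile(fileext = ".vcf")
  writeLines(lines, flipped)
  loci <- read_locus_table(paths["loci"])
  pan <- read_panel(paths["panel"])
  dm1 <- build_dosage_matrix(paths[["vcf"]], loci, pan)
  dm2 <- build_dosage_matrix(flipped, loci, pan)
  expect_identical(dm1$dosage, dm2$dosage)
})
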