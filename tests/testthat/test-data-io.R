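test_that("drug table reader parses rows, multi-value cells and blanks", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("drug_id\tname\ttargets\tatc_codes",
                 "DB01269\tPanitumumab\tEGFR\tL01XC08",
                 "DB00002\tTwo\tEGFR;ERBB2\tL01XE03;N02BA01",
                 "DB00003\tThree\t\t"), tf)
    ds <- readDrugTable(tf)
    expect_s4_class(ds, "DrugSet")
    expect_equal(length(ds), 3L)
    expect_equal(as.character(targets(ds)[["DB01269"]]), "EGFR")
    expect_equal(as.character(atcCodes(ds)[["DB01269"]]), "L01XC08")
    expect_setequal(as.character(targets(ds)[["DB00002"]]),
                    c("EGFR", "ERBB2"))
    expect_length(atcCodes(ds)[["DB00003"]], 0L)
    expect_length(targets(ds)[["DB00003"]], 0L)
})

test_that("drug table reader rejects duplicates and drops bad ATC codes", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("drug_id\tname\ttargets\tatc_codes",
                 "DB1\tOne\tEGFR\tL01XC08",
                 "DB1\tOneAgain\tSRC\t"), tf)
    expect_error(readDrugTable(tf), "duplicate drug_id")

    writeLines(c("drug_id\tname\ttargets\tatc_codes",
                 "DB1\tOne\tEGFR\tL01XC08;BADCODE"), tf)
    expect_warning(ds <- readDrugTable(tf), "malformed ATC")
    expect_equal(as.character(atcCodes(ds)[["DB1"]]), "L01XC08")
})

test_that("drug table round-trips and is row-order independent", {
    ds <- tinyDrugs()
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeDrugTable(ds, tf)
    back <- readDrugTable(tf)
    expect_equal(drugIds(back), drugIds(ds))
    expect_equal(as.list(targets(back)), as.list(targets(ds)))
    expect_equal(as.list(atcCodes(back)), as.list(atcCodes(ds)))

    lines <- readLines(tf)
    writeLines(c(lines[1L], rev(lines[-1L])), tf)
    perm <- readDrugTable(tf)
    expect_equal(drugIds(perm), drugIds(back))
    expect_equal(as.list(targets(perm)), as.list(targets(back)))
})

test_that("GMT reader builds the union universe and validates lines", {
    tf <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("set1\tdesc\tA\tB", "set2\tdesc\tB\tC\tC"), tf)
    gsc <- readGmt(tf)
    expect_setequal(universe(gsc), c("A", "B", "C"))
    expect_equal(length(gsc), 2L)
    # duplicate gene within a line de-duplicated
    expect_equal(as.character(geneSets(gsc)[["set2"]]), c("B", "C"))

    writeLines(c("set1\tdesc\tA", "broken\tdesc"), tf)
    expect_error(readGmt(tf), "line 2")
    writeLines(character(0), tf)
    expect_error(readGmt(tf), "empty")
})

test_that("GMT round-trips and set order does not matter", {
    gsc <- GeneSetCollection(list(b = c("X", "Y"), a = c("Y", "Z")))
    tf <- withr::local_tempfile(fileext = ".gmt")
    writeGmt(gsc, tf)
    back <- readGmt(tf)
    expect_setequal(universe(back), universe(gsc))
    expect_equal(as.character(geneSets(back)[["a"]]), c("Y", "Z"))
    lines <- readLines(tf)
    writeLines(rev(lines), tf)
    expect_equal(as.list(geneSets(readGmt(tf))), as.list(geneSets(back)))
})

test_that("gene-effect reader keeps exact values and flags missing cells", {
    tf <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("cell_line,EGFR,SRC",
                 "ACH-1,-0.5,",
                 "ACH-2,0.25,-1.125"), tf)
    gem <- readGeneEffects(tf, lineage = c("ACH-1" = "LUNG",
                                           "ACH-2" = "LUNG"))
    m <- effectScores(gem)   # genes x cell lines
    expect_identical(m["EGFR", "ACH-1"], -0.5)
    expect_identical(m["SRC", "ACH-2"], -1.125)
    expect_true(is.na(m["SRC", "ACH-1"]))
    expect_equal(sum(is.na(m)), 1L)
})

test_that("gene-effect reader rejects bad columns and cells", {
    tf <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("cell_line,EGFR,EGFR", "ACH-1,0.1,0.2"), tf)
    expect_error(readGeneEffects(tf, lineage = c("ACH-1" = "LUNG")),
                 "repeated gene")
    writeLines(c("cell_line,EGFR", "ACH-1,abc"), tf)
    expect_error(readGeneEffects(tf, lineage = c("ACH-1" = "LUNG")),
                 "non-numeric.*EGFR")
})

test_that("gene-effect matrix round-trips bit-exactly with lineage", {
    set.seed(11)
    m <- matrix(rnorm(12), 3, 4,
                dimnames = list(paste0("CL", 1:3), paste0("G", 1:4)))
    m[2, 3] <- NA
    lin <- setNames(c("LUNG", "LUNG", "OTHER"), rownames(m))
    gem <- GeneEffectMatrix(m, lin)
    tf <- withr::local_tempfile(fileext = ".csv")
    lf <- withr::local_tempfile(fileext = ".tsv")
    writeGeneEffects(gem, tf, lf)
    back <- readGeneEffects(tf, lf)
    expect_identical(effectScores(back), effectScores(gem))
    expect_identical(lineage(back), lineage(gem))
})

test_that("seed lists resolve against the collection", {
    ds <- tinyDrugs()
    tf <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("DB01", "DB02", "DB99"), tf)
    expect_warning(ss <- readSeedList(tf, "LUNG", drugSet = ds),
                   "DB99")
    expect_setequal(drugIds(ss), c("DB01", "DB02"))
    writeLines("DB99", tf)
    expect_error(suppressWarnings(readSeedList(tf, "LUNG", drugSet = ds)),
                 "no seed drug")
})
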