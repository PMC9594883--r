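test_that("CSV reader parses records, labels and missing fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('title,abstract,label',
               '"A cluster trial","We randomized clinics",1',
               '"A drug trial","We randomized patients",0',
               '"A cohort study","",0'), path)
  cits <- read_citations_csv(path)
  expect_length(cits, 3)
  expect_equal(sapply(cits, `[[`, "label"), c(1L, 0L, 0L))
  expect_equal(cits[[3]]$abstract, "")          # empty cell, no error
  expect_equal(cits[[1]]$title, "A cluster trial")
})

test_that("CSV reader applies a declared label value map", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("title,abstract,label", "t1,a1,CRT", "t2,a2,nonCRT"), path)
  cits <- read_citations_csv(path, label_values = c(CRT = 1, nonCRT = 0))
  expect_equal(sapply(cits, `[[`, "label"), c(1L, 0L))
  # without the map the same file is a record-level error naming the ids
  expect_error(read_citations_csv(path), "unparseable label.*1")
})

test_that("CSV reader errors on a missing mandatory column and splits lists", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("title,keywords", "t1,a; b; c"), path)
  expect_error(read_citations_csv(path), "abstract")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Title,Abstract,MeSH", "t1,a1,Humans; Adult"), path2)
  cits <- read_citations_csv(path2)   # case-insensitive auto-detection
  expect_equal(cits[[1]]$subject_headings, c("Humans", "Adult"))
})

medline_fixture <- c(
  "PMID- 100",
  "TI  - A cluster randomized trial of",
  "      hand hygiene in schools",
  "AB  - We randomized 20 schools to an",
  "      intervention or control arm and",
  "      followed pupils for one year.",
  "MH  - Humans",
  "MH  - Schools",
  "OT  - cluster randomised",
  "",
  "PMID- 101",
  "TI  - An individually randomized drug trial",
  "AB  - Patients were randomized.",
  "MH  - Humans")

test_that("MEDLINE tagged reader joins continuations and keeps order", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(medline_fixture, path)
  cits <- read_medline_tagged(path)
  expect_length(cits, 2)
  expect_equal(cits[[1]]$record_id, "100")
  expect_equal(cits[[1]]$title,
               "A cluster randomized trial of hand hygiene in schools")
  expect_equal(cits[[1]]$abstract,
               paste("We randomized 20 schools to an intervention or",
                     "control arm and followed pupils for one year."))
  expect_equal(cits[[1]]$subject_headings, c("Humans", "Schools"))
  expect_equal(cits[[1]]$keywords, "cluster randomised")
  expect_equal(cits[[2]]$record_id, "101")
})

test_that("MEDLINE reader rejects files without field tags", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("this is just", "plain text"), path)
  expect_error(read_medline_tagged(path), "no recognizable")
})

test_that("RIS reader honours tag precedence and record delimiters", {
  path <- withr::local_tempfile(fileext = ".ris")
  writeLines(c("TY  - JOUR",
               "T1  - Secondary title",
               "TI  - Primary title",
               "AB  - An abstract",
               "KW  - cluster",
               "KW  - trial",
               "ER  - ",
               "TY  - JOUR",
               "T1  - Only T1 here",
               "N2  - N2 abstract",
               "ER  - "), path)
  cits <- read_ris(path)
  expect_length(cits, 2)
  expect_equal(cits[[1]]$title, "Primary title")     # TI wins over T1
  expect_equal(cits[[1]]$keywords, c("cluster", "trial"))
  expect_equal(cits[[2]]$title, "Only T1 here")
  expect_equal(cits[[2]]$abstract, "N2 abstract")
})

test_that("RIS reader handles empty files and missing terminators", {
  path <- withr::local_tempfile(fileext = ".ris")
  writeLines(character(), path)
  expect_length(read_ris(path), 0)
  writeLines(c("TY  - JOUR", "TI  - No end tag"), path)
  expect_error(read_ris(path), "no ER terminator")
})

test_that("results are written probability-sorted with deterministic ties", {
  res <- data.frame(record_id = c("a", "c", "b", "d"),
                    probability = c(0.2, 0.9, 0.5, 0.5),
                    predicted_label = c(0L, 1L, 1L, 1L),
                    cnn_wholeword = c(0.1, 0.9, 0.5, 0.5),
                    cnn_subword = c(0.2, 0.9, 0.5, 0.5),
                    svm = c(0.3, 0.9, 0.5, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, path)
  back <- read.csv(path)
  expect_equal(back$record_id, c("c", "b", "d", "a"))  # desc, tie by id
  # round trip preserves ids, probabilities (6 d.p.) and labels
  expect_equal(back$probability, c(0.9, 0.5, 0.5, 0.2), tolerance = 1e-9)
  expect_equal(back$predicted_label, c(1L, 1L, 1L, 0L))
})

test_that("an empty result set yields a header-only file", {
  res <- data.frame(record_id = character(), probability = numeric(),
                    predicted_label = integer())
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, path)
  expect_equal(nrow(read.csv(path)), 0)
  expect_match(readLines(path)[1], "record_id")
})
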