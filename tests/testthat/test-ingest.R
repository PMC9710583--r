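test_that("STITCH links are normalized, collapsed and malformed rows skipped", {
  # integer 0-1000 scores normalize by /1000
  f <- write_stitch_fixture(withr::local_tempfile(fileext = ".tsv"),
                            c("CIDm01\tP1\t400\t700",
                              "CIDm02\tP1\t700\t900",
                              "CIDm03\tP2\t150\t200"))
  net <- read_stitch_links(f)
  expect_setequal(net$edges$experimental, c(0.4, 0.7, 0.15))
  expect_setequal(net$edges$combined_score, c(0.7, 0.9, 0.2))

  # one malformed row among 10 -> 9 edges, 1 skip recorded
  rows <- sprintf("CIDm%02d\tP%d\t%d\t%d", 1:10, rep(1:2, 5),
                  seq(100, 1000, 100), seq(100, 1000, 100))
  rows[4] <- "CIDm04\tonly_two_fields"
  f2 <- write_stitch_fixture(withr::local_tempfile(fileext = ".tsv"), rows)
  expect_message(net2 <- read_stitch_links(f2), "skipped 1")
  expect_equal(nrow(net2$edges), 9)
  expect_equal(attr(net2, "ingest_log")$n_skipped, 1)

  # gzip transparency
  fgz <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(fgz, "wt")
  writeLines(c("chemical\tprotein\texperimental", "CIDm01\tP1\t500"), con)
  close(con)
  expect_equal(read_stitch_links(fgz)$edges$experimental, 0.5)

  # all rows malformed -> rejection
  f3 <- write_stitch_fixture(withr::local_tempfile(fileext = ".tsv"), "junk")
  expect_error(suppressMessages(read_stitch_links(f3)), "zero parsable rows")
})

test_that("identifier maps merge variants with max-collapse and drop unmapped", {
  f <- write_stitch_fixture(withr::local_tempfile(fileext = ".tsv"),
                            c("CIDs01\tP1\t300\t300",
                              "CIDm01\tP1\t800\t500",
                              "CIDx99\tP1\t900\t900"))
  m <- id_map(entries = c(CIDs01 = "CID1", CIDm01 = "CID1"),
              unmapped = "CIDx99")
  expect_message(net <- read_stitch_links(f, id_map = m), "dropped 1 unmapped")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$compound, "CID1")
  expect_equal(net$edges$experimental, 0.8)  # max over merged rows
  expect_error(id_map(entries = c(a = "b"), unmapped = "a"), "both")

  fm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "CIDs01\tCID1", "CIDx99\t"), fm)
  m2 <- read_id_map(fm)
  expect_equal(unname(m2$entries["CIDs01"]), "CID1")
  expect_equal(m2$unmapped, "CIDx99")
})

test_that("KGML reactions become enzyme-compound edges with C-number filtering", {
  entries <- list(
    list(id = "1", name = "ec:1.1.1.1", type = "enzyme", reaction = "rn:R00001"),
    list(id = "2", name = "cpd:C00022", type = "compound"),
    list(id = "3", name = "cpd:C00031", type = "compound"),
    list(id = "4", name = "gl:G00001", type = "compound"),   # glycan: dropped
    list(id = "5", name = "ec:2.2.2.2", type = "enzyme"))    # no reaction attr
  reactions <- list(
    list(id = "10", name = "rn:R00001", substrates = "2", products = c("3", "4")))
  f <- write_kgml_fixture(withr::local_tempfile(fileext = ".xml"),
                          entries, reactions)
  net <- read_kgml_network(f)
  # 1 enzyme x 2 C-number compounds (substrate + product); glycan excluded
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$compound, c("C00022", "C00031"))
  expect_equal(unique(net$edges$protein), "ec:1.1.1.1")
  expect_equal(unique(net$edges$kegg), 1)
})

test_that("KGML edges deduplicate across files and ignore file order", {
  e1 <- list(
    list(id = "1", name = "ec:1.1.1.1", type = "enzyme", reaction = "rn:R1"),
    list(id = "2", name = "cpd:C00001", type = "compound"),
    list(id = "3", name = "cpd:C00002", type = "compound"))
  r1 <- list(list(id = "9", name = "rn:R1", substrates = "2", products = "3"))
  e2 <- list(
    list(id = "1", name = "ec:1.1.1.1", type = "enzyme", reaction = "rn:R2"),
    list(id = "2", name = "cpd:C00001", type = "compound"),
    list(id = "4", name = "cpd:C00003", type = "compound"))
  r2 <- list(list(id = "8", name = "rn:R2", substrates = "2", products = "4"))
  fa <- write_kgml_fixture(withr::local_tempfile(fileext = ".xml"), e1, r1)
  fb <- write_kgml_fixture(withr::local_tempfile(fileext = ".xml"), e2, r2)
  ab <- read_kgml_network(c(fa, fb))
  ba <- read_kgml_network(c(fb, fa))
  # same enzyme-compound pair in two files counts once
  expect_equal(nrow(ab$edges), 3)
  expect_equal(ab$edges, ba$edges)

  # reaction without enzyme mapping is skipped and counted
  e3 <- list(list(id = "2", name = "cpd:C00001", type = "compound"),
             list(id = "3", name = "cpd:C00002", type = "compound"))
  f3 <- write_kgml_fixture(withr::local_tempfile(fileext = ".xml"), e3, r1)
  expect_error(read_kgml_network(f3), "no enzyme-compound edges")
  both <- read_kgml_network(c(fa, f3))
  expect_equal(attr(both, "ingest_log")$n_reactions_skipped, 1)

  # malformed XML is rejected by file name
  fbad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway><entry", fbad)
  expect_error(read_kgml_network(fbad), "cannot parse KGML")

  # three reactions sharing compounds: count equals manual enumeration
  e4 <- list(
    list(id = "1", name = "ec:1.1.1.1", type = "enzyme", reaction = "rn:Ra"),
    list(id = "2", name = "ec:2.2.2.2 ec:3.3.3.3", type = "enzyme",
         reaction = "rn:Rb rn:Rc"),
    list(id = "5", name = "cpd:C00010", type = "compound"),
    list(id = "6", name = "cpd:C00020", type = "compound"),
    list(id = "7", name = "cpd:C00030", type = "compound"))
  r4 <- list(
    list(id = "20", name = "rn:Ra", substrates = "5", products = "6"),
    list(id = "21", name = "rn:Rb", substrates = "6", products = "7"),
    list(id = "22", name = "rn:Rc", substrates = "5", products = "7"))
  f4 <- write_kgml_fixture(withr::local_tempfile(fileext = ".xml"), e4, r4)
  net4 <- read_kgml_network(f4)
  # manual: ec1x{C10,C20}; {ec2,ec3}x{C20,C30}; {ec2,ec3}x{C10,C30}
  want <- c("C00010 ec:1.1.1.1", "C00020 ec:1.1.1.1",
            "C00020 ec:2.2.2.2", "C00030 ec:2.2.2.2",
            "C00010 ec:2.2.2.2",
            "C00020 ec:3.3.3.3", "C00030 ec:3.3.3.3",
            "C00010 ec:3.3.3.3")
  expect_setequal(paste(net4$edges$compound, net4$edges$protein), want)
})

test_that("pair lists deduplicate and skip malformed rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\tprotein", "c1\tp1", "c1\tp2", "c1\tp1", "c2\tp1",
               "c3\t", "c4\tp4"), f)
  expect_message(pairs <- read_pair_list(f), "skipped 1")
  expect_equal(nrow(pairs), 4)

  fe <- withr::local_tempfile(fileext = ".tsv")
  writeLines("compound\tprotein", fe)
  expect_equal(nrow(read_pair_list(fe)), 0)

  # larger fixture: distinct-pair tally
  set.seed(8)
  cc <- sprintf("c%d", sample(12, 100, TRUE))
  pp <- sprintf("p%d", sample(12, 100, TRUE))
  fl <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\tprotein", paste(cc, pp, sep = "\t")), fl)
  expect_equal(nrow(read_pair_list(fl)),
               length(unique(paste(cc, pp))))
})

test_that("networks survive write/read round trips", {
  net <- random_net(8, 8, 0.4, seed = 21)
  net$edges$experimental <- round(runif(nrow(net$edges)), 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- read_network(f)
  ord <- function(e) e[order(e$compound, e$protein), ]
  expect_equal(ord(back$edges), ord(net$edges), ignore_attr = TRUE)
  expect_true(file.exists(paste0(f, ".json")))

  # the STITCH reader accepts the written dialect unchanged (scores <= 1)
  again <- read_stitch_links(f)
  expect_equal(ord(again$edges)$experimental, ord(net$edges)$experimental)
})
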