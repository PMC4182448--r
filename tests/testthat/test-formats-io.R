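test_that("BED lines map to records unchanged", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t110\tABF1\t0\t+",
               "chr2\t5\t25\tGAL4"), p)
  sites <- read_tfbs(p, "bed")
  expect_equal(sites$tf, c("ABF1", "GAL4"))
  expect_equal(sites$start, c(100L, 5L))
  expect_equal(sites$end, c(110L, 25L))
  expect_equal(sites$strand, c("+", "."))
})

test_that("GFF3 coordinates convert to 0-based half-open and match BED", {
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tscan\tTF_binding_site\t101\t110\t.\t+\t.\tID=x1;Name=ABF1"),
             g)
  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t110\tABF1\t0\t+", b)
  from_gff <- read_tfbs(g, "gff3")
  from_bed <- read_tfbs(b, "bed")
  expect_equal(from_gff[, c("tf", "chrom", "start", "end", "strand")],
               from_bed[, c("tf", "chrom", "start", "end", "strand")])
})

test_that("TSV dialect preserves row count and order", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf_label\tchrom\tstart\tend\tstrand",
               "A\tchr1\t10\t20\t+",
               "B\tchr1\t30\t40\t-",
               "A\tchr2\t5\t15\t."), p)
  sites <- read_tfbs(p, "tsv")
  expect_equal(nrow(sites), 3L)
  expect_equal(sites$tf, c("A", "B", "A"))
})

test_that("malformed input fails with file, line and field in the message", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t110\tA", "chr1\t200\t150\tB"), p)
  expect_error(read_tfbs(p, "bed"), "line 2.*end")

  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\ts\tsite\t10\t20\t.\t+\t.\tID=x", g)
  expect_error(read_tfbs(g, "gff3"), "line 1.*Name")

  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\tten\t20\tA", b)
  expect_error(read_tfbs(b, "bed"), "line 1.*start")
})

test_that("transaction serialization matches the documented line format", {
  db <- make_db(make_transaction(c(B = 0.5, A = 1.0), chrom = "chr1",
                                 span = c(100L, 400L)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_transactions(db, p)
  lines <- readLines(p)
  expect_match(lines[1], "^#")
  expect_equal(lines[2], "T1\tchr1:100-400\tA:1.0000;B:0.5000")

  empty <- make_db(list())
  write_transactions(empty, p)
  expect_equal(length(readLines(p)), 1L)   # header only
})

test_that("write/read round-trips random databases to 4 decimals", {
  for (seed in 1:8) {
    db <- random_db(seed, max_items = 8, max_n = 40)
    p <- withr::local_tempfile(fileext = ".tsv")
    write_transactions(db, p)
    back <- read_transactions(p)
    expect_equal(back$N, db$N)
    expect_equal(back$alphabet, db$alphabet)
    for (t in seq_len(db$N)) {
      a <- db$transactions[[t]]$items
      b <- back$transactions[[t]]$items
      expect_equal(names(b), names(a))
      expect_equal(unname(b), round(unname(a), 4), tolerance = 1e-12)
    }
  }
})

test_that("transaction files are validated on read", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# hdr", "T1\tchr1:0-10\tB:1.2000"), p)
  expect_error(read_transactions(p), "outside \\[0,1\\]")
  writeLines(c("# hdr", "T1\tchr1:0-10\tA:0.5000;A:0.6000"), p)
  expect_error(read_transactions(p), "duplicate TF")
})

test_that("result files carry the documented columns and BED scaling", {
  it <- data.frame(tf_list = "STE12,TEC1", size = 2L, support = 0.013,
                   stringsAsFactors = FALSE)
  it$items <- list(c("STE12", "TEC1"))
  it$p_value <- 2.5e-4
  it$postfit_support <- 0.012
  inst <- data.frame(chrom = "chr3", start = 100L, end = 180L,
                     tf_list = "STE12,TEC1", fit_degree = 0.6,
                     transaction_id = "T9", stringsAsFactors = FALSE)
  fi <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_results(it, inst, fi, fb)
  tab <- readLines(fi)
  expect_equal(tab[1], "id\ttf_list\tsize\tfuzzy_support\tp_value\tpostfit_support")
  expect_match(tab[2], "^1\tSTE12,TEC1\t2\t0\\.013000\t2\\.500e-04\t0\\.012000$")
  expect_equal(readLines(fb), "chr3\t100\t180\tSTE12,TEC1\t600\t.")

  write_results(it[0, ], inst[0, ], fi, fb)
  expect_equal(length(readLines(fi)), 1L)
  expect_equal(length(readLines(fb)), 0L)
})
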