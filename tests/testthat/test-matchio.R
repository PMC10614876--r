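# FASTA reading, hit-table parsing, and the TSV annotation format

test_that("read_fasta handles minimal, multiline, and header-token records", {
  fa <- write_tmp_fasta(c(">q1", "ACGT"))
  cat1 <- read_fasta(fa)
  expect_identical(names(cat1), "q1")
  expect_identical(as.character(cat1[["q1"]]), "ACGT")

  fa2 <- write_tmp_fasta(c(">a x", "AC", "GT", ">b", "NNN"))
  cat2 <- read_fasta(fa2)
  expect_identical(names(cat2), c("a", "b"))
  expect_identical(unname(Biostrings::width(cat2)), c(4L, 3L))
})

test_that("read_fasta maps residues outside {A,C,G,T,N} to N with a warning", {
  fa <- write_tmp_fasta(c(">a", "acgu"))
  expect_warning(cat1 <- read_fasta(fa), "replaced with N")
  expect_identical(as.character(cat1[["a"]]), "ACGN")
})

test_that("read_fasta rejects empty files and duplicate ids", {
  empty <- write_tmp_fasta(character(0))
  expect_error(read_fasta(empty), "no sequences")
  dup <- write_tmp_fasta(c(">a", "ACGT", ">a", "GGGG"))
  expect_error(read_fasta(dup), "a")
})

test_that("parse_nhmmer_tblout reads real nhmmer output and normalizes strands", {
  catalog <- c(fix_phage = 1200L)
  m <- parse_nhmmer_tblout(fixture_path("fix.tblout"), catalog)
  expect_identical(nrow(m), 2L)
  expect_identical(m$target_id, c("fix_genome", "fix_genome"))
  expect_identical(m$query_length, c(1200L, 1200L))
  plus <- m[m$strand == "+", ]
  minus <- m[m$strand == "-", ]
  # plus hit covers the forward planted copy
  expect_identical(c(plus$target_start, plus$target_end), c(3001L, 4200L))
  expect_identical(c(plus$query_start, plus$query_end), c(1L, 1200L))
  # minus hit (alifrom > ali-to in the file) is normalized start < end
  expect_identical(c(minus$target_start, minus$target_end), c(6201L, 7400L))
  expect_identical(c(minus$query_start, minus$query_end), c(1L, 1200L))
  expect_true(all(m$evalue == 0))
  expect_true(all(m$score > 1000))
})

test_that("parse_nhmmer_tblout handles comment-only input and malformed rows", {
  p <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c("# a comment", "#", "# another"), p)
  expect_identical(nrow(parse_nhmmer_tblout(p, c(q = 10L))), 0L)

  writeLines(c("# header", "g - q - 1 100"), p)
  expect_error(parse_nhmmer_tblout(p, c(q = 100L)), "line 2")

  row <- paste("g", "-", "q", "-", "1", "100", "1", "100", "1", "100",
               "5000", "+", "not_a_number", "10.0", "0.0", "-")
  writeLines(row, p)
  expect_error(parse_nhmmer_tblout(p, c(q = 100L)), "non-numeric")
})

test_that("parse_nhmmer_tblout requires query ids to be in the catalog", {
  expect_error(parse_nhmmer_tblout(fixture_path("fix.tblout"),
                                   c(other_phage = 1200L)),
               "fix_phage")
})

test_that("parse_blast_tab reads real blastn outfmt-6 output", {
  catalog <- c(fix_phage = 1200L)
  m <- parse_blast_tab(fixture_path("fix.blast6"), catalog)
  expect_identical(nrow(m), 2L)
  expect_identical(m$strand, c("+", "-"))
  expect_identical(m$target_start, c(3001L, 6201L))
  expect_identical(m$target_end, c(4200L, 7400L))
  expect_identical(m$query_start, c(1L, 1L))
  expect_identical(m$query_end, c(1200L, 1200L))
})

test_that("parse_blast_tab: empty file, strand inference, unknown query", {
  p <- withr::local_tempfile(fileext = ".tsv")
  file.create(p)
  expect_identical(nrow(parse_blast_tab(p, c(q = 10L))), 0L)

  writeLines(paste("q", "g", "95.0", "401", "5", "0", "1", "401",
                   "500", "100", "1e-50", "600", sep = "\t"), p)
  m <- parse_blast_tab(p, c(q = 4000L))
  expect_identical(m$strand, "-")
  expect_identical(m$target_start, 100L)
  expect_identical(m$target_end, 500L)

  writeLines(paste("mystery", "g", "95.0", "401", "5", "0", "1", "401",
                   "100", "500", "1e-50", "600", sep = "\t"), p)
  expect_error(parse_blast_tab(p, c(q = 4000L)), "mystery")
})

test_that("nhmmer and BLAST fixtures describing the same hits agree", {
  catalog <- c(fix_phage = 1200L)
  a <- parse_nhmmer_tblout(fixture_path("fix.tblout"), catalog)
  b <- parse_blast_tab(fixture_path("fix.blast6"), catalog)
  cols <- c("query_id", "query_length", "target_id", "query_start",
            "query_end", "target_start", "target_end", "strand")
  key <- function(m) do.call(paste, m[cols])
  expect_setequal(key(a), key(b))
})

test_that("parsed matches always satisfy the coordinate invariants", {
  catalog <- c(fix_phage = 1200L)
  for (m in list(parse_nhmmer_tblout(fixture_path("fix.tblout"), catalog),
                 parse_blast_tab(fixture_path("fix.blast6"), catalog))) {
    expect_true(all(m$target_start <= m$target_end))
    expect_true(all(m$query_start <= m$query_end))
    expect_true(all(m$query_end <= m$query_length))
  }
})

test_that("annotation TSV writes the documented columns and round-trips", {
  cfg <- pipeline_config()
  ann <- assign_integrations(joinable_pair(), cfg)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, p)
  header <- strsplit(readLines(p, n = 1L), "\t")[[1]]
  expect_identical(header,
                   c("phage_name", "evalue", "score", "query_start",
                     "query_end", "target_name", "target_start", "target_end",
                     "strand", "integration_id", "full_length"))
  body <- readLines(p)[-1]
  expect_length(body, 2L)
  expect_true(all(grepl("\t(True|False)$", body)))

  back <- read_annotation_tsv(p)
  expect_identical(length(unique(back$integration_id)), 1L)
  expect_identical(back$target_start, ann$target_start)
  expect_identical(back$target_end, ann$target_end)
  expect_identical(back$query_start, ann$query_start)
  expect_identical(back$full_length, ann$full_length)
})

test_that("empty annotation gives a header-only TSV that reads back empty", {
  cfg <- pipeline_config()
  ann <- assign_integrations(filter_matches(empty_annotation_input(), cfg), cfg)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, p)
  expect_length(readLines(p), 1L)
  expect_identical(nrow(read_annotation_tsv(p)), 0L)
})

test_that("TSV integration grouping is invariant to row order on disk", {
  cfg <- pipeline_config()
  three <- rbind(
    match_record("p", 12000, "g", 1, 3000, 100, 3100, score = 5),
    match_record("p", 12000, "g", 3050, 6000, 3500, 6450, score = 6),
    match_record("p", 12000, "g", 6050, 9000, 6800, 9750, score = 7)
  )
  ann <- assign_integrations(three, cfg)
  expect_identical(length(unique(ann$integration_id)), 1L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, p)
  lines <- readLines(p)
  shuffled <- c(lines[1], lines[c(4, 2, 3) ])
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(shuffled, p2)
  expect_identical(canonical_partition(read_annotation_tsv(p2),
                                       read_annotation_tsv(p2)$integration_id),
                   canonical_partition(ann, ann$integration_id))
})

test_that("read_annotation_tsv rejects unknown columns by name", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("phage_name", "evalue", "score", "query_start",
                       "query_end", "target_name", "target_start",
                       "target_end", "strand", "integration_id",
                       "full_length", "surprise"), collapse = "\t")), p)
  expect_error(read_annotation_tsv(p), "surprise")
})
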