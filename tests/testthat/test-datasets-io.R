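test_that("FASTA round-trips, including CRLF input", {
  recs <- c(one = random_dna(80, 1), two = random_dna(35, 2))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_identical(as.character(back), recs)

  # CRLF dialect
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(paste0(c(">crlf", "ACGTACGT"), "\r"), f2, sep = "\n")
  expect_identical(as.character(read_fasta(f2)), c(crlf = "ACGTACGT"))

  # many-record round trip
  lincae:::with_seed(3, many <- vapply(1:200, function(i) random_dna(60),
                                       character(1)))
  names(many) <- sprintf("r%03d", 1:200)
  f3 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(many, f3)
  expect_identical(as.character(read_fasta(f3)), many)

  expect_error(read_fasta(withr::local_tempfile(fileext = ".fa")), "not found")
})

test_that("BED parsing validates coordinates and preserves strand", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t12\t.\t0\t+", f)
  gr <- read_bed(f)
  expect_identical(GenomicRanges::start(gr), 11L)  # 0-based 10 -> 1-based 11
  expect_identical(GenomicRanges::end(gr), 12L)
  expect_identical(as.character(GenomicRanges::strand(gr)), "+")

  writeLines("chr1\t10\t10\tx\t0\t+", f)
  expect_error(read_bed(f), "start < end")

  # order-stable parse of a shuffled file
  lincae:::with_seed(5, {
    starts <- sample(1000, 20)
    lines <- sprintf("chr1\t%d\t%d", starts, starts + 2L)
  })
  writeLines(lines, f)
  expect_identical(GenomicRanges::start(read_bed(f)), starts + 1L)
})

test_that("window extraction centers the anchor by the coordinate law", {
  # source with known anchor at 1-based (100, 101)
  lincae:::with_seed(9, s <- random_dna(200))
  s <- paste0(substr(s, 1, 99), "AG", substr(s, 102, 200))
  genome <- Biostrings::DNAStringSet(c(src = s))
  sites <- GenomicRanges::GRanges("src", IRanges::IRanges(100, 101),
                                  strand = "+")
  w <- extract_windows(genome, sites, "donor", window_len = 15)
  # 0-based half-open [93, 108): anchor at window indices 6,7
  expect_identical(w$start, 94L)
  expect_identical(w$end, 108L)
  expect_identical(substr(w$sequence, 7, 8), "AG")
  expect_identical(w$sequence, substr(s, 94, 108))
  expect_identical(w$label, 1L)

  # acceptor default length 90, anchor at 0-based window indices 44,45
  w90 <- extract_windows(genome, sites, "acceptor")
  expect_identical(nchar(w90$sequence), 90L)
  expect_identical(substr(w90$sequence, 45, 46), "AG")

  # minus strand: window placed so the anchor's minus-strand read occupies
  # the central indices; window index 6 (0-based) maps to plus position 101,
  # so the plus-strand span is [93, 107], then reverse-complemented
  sites_m <- GenomicRanges::GRanges("src", IRanges::IRanges(100, 101),
                                    strand = "-")
  wm <- extract_windows(genome, sites_m, "donor", window_len = 15)
  plus_span <- substr(s, 93, 107)
  expect_identical(wm$sequence,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(plus_span))))
  expect_identical(wm$start, 93L)
  expect_identical(wm$end, 107L)

  # coordinate round-trip: window indices map back to the source anchor
  left <- 6L
  expect_identical(w$start + left, 100L)
})

test_that("edge sites are skipped with a logged count", {
  genome <- Biostrings::DNAStringSet(c(src = random_dna(30, 3)))
  sites <- GenomicRanges::GRanges("src", IRanges::IRanges(c(2, 15), c(3, 16)))
  expect_message(w <- extract_windows(genome, sites, "donor", 15), "skipped")
  expect_identical(nrow(w), 1L)
  expect_identical(attr(w, "skipped"), 1L)
})

test_that("negative construction respects policy, ratio and anchors", {
  pg <- tiny_planted(n_sites = 4, glen = 3000)
  neg_d <- make_negatives(pg$genome, pg$sites, "acceptor", 90,
                          policy = "decoy", ratio = 1, seed = 3)
  expect_identical(nrow(neg_d), 4L)
  expect_true(all(neg_d$label == 0L))
  expect_true(all(substr(neg_d$sequence, 45, 46) == "AG"))

  neg_r <- make_negatives(pg$genome, pg$sites, "acceptor", 90,
                          policy = "random", ratio = 2.5, seed = 3)
  expect_identical(nrow(neg_r), 10L)

  # no overlap with positive anchors (interval oracle)
  for (neg in list(neg_d, neg_r)) {
    anchors <- GenomicRanges::GRanges(neg$chrom,
      IRanges::IRanges(neg$start + 44L, neg$start + 45L))
    expect_identical(length(GenomicRanges::findOverlaps(anchors, pg$sites)), 0L)
  }

  # deterministic by seed
  again <- make_negatives(pg$genome, pg$sites, "acceptor", 90,
                          policy = "decoy", ratio = 1, seed = 3)
  expect_identical(neg_d, again)
  expect_error(make_negatives(pg$genome, pg$sites, "acceptor", 90,
                              ratio = 1e6, seed = 1), "insufficient")
})

test_that("train/validation split is stratified, disjoint, exhaustive", {
  ds <- generate_dataset(600, 400, motif_model("donor"), seed = 14)
  sp <- split_train_validation(ds, n_validation = 500, seed = 14)
  expect_identical(nrow(sp$validation), 500L)
  expect_identical(nrow(sp$train), 500L)
  expect_identical(sort(c(rownames(sp$train), rownames(sp$validation))),
                   sort(rownames(ds)))
  # stratification: validation positives within 1 of the proportional count
  expect_lte(abs(sum(sp$validation$label) - 300), 1)

  sp2 <- split_train_validation(ds, n_validation = 500, seed = 15)
  expect_false(identical(sp$validation$sequence, sp2$validation$sequence))
  expect_identical(nrow(sp2$validation), 500L)
  expect_error(split_train_validation(ds, n_validation = 1000), "smaller")
})

test_that("window sets round-trip through TSV", {
  ds <- generate_dataset(5, 5, motif_model("donor"), seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_windows_tsv(ds, f)
  back <- read_windows_tsv(f)
  rownames(ds) <- NULL
  expect_identical(as.data.frame(back), as.data.frame(ds))
})
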