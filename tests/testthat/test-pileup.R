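# 5'-end counting, MAPQ filtering, normalization, SAM interoperability.

test_that("5' ends follow the strand-specific coordinate convention", {
  g <- small_genome()
  reads <- make_reads(start = c(101, 101), end = c(230, 230),
                      strand = c("+", "-"), chrom = g$name)
  prof <- compute_five_prime_counts(reads, g)
  expect_equal(prof$watson[101], 1)
  expect_equal(prof$crick[230], 1)
  expect_equal(sum(prof$watson) + sum(prof$crick), 2)
  expect_equal(prof$library_size, 2L)

  empty <- compute_five_prime_counts(make_reads(integer(), integer(),
                                                character(), chrom = g$name), g)
  expect_equal(empty$library_size, 0L)
  expect_true(all(empty$watson == 0) && all(empty$crick == 0))

  bad <- make_reads(g$length - 10, g$length + 120, "+", chrom = g$name)
  expect_error(compute_five_prime_counts(bad, g), "read 1")
})

test_that("profiles equal an independent per-read tally", {
  g <- small_genome()
  r <- small_nicked_library()[seq_len(10000), ]
  prof <- compute_five_prime_counts(r, g)
  watson <- integer(g$length)
  crick <- integer(g$length)
  for (i in seq_len(nrow(r))) {     # brute-force oracle
    if (r$strand[i] == "+") {
      watson[r$start[i]] <- watson[r$start[i]] + 1L
    } else {
      crick[r$end[i]] <- crick[r$end[i]] + 1L
    }
  }
  expect_identical(prof$watson, watson)
  expect_identical(prof$crick, crick)
  expect_equal(prof$library_size, 10000L)
})

test_that("reversing strands and mirroring coordinates swaps the profile", {
  g <- small_genome()
  r <- small_nicked_library()[seq_len(20000), ]
  L <- g$length
  mirrored <- r
  mirrored$start <- L + 1L - r$end
  mirrored$end <- L + 1L - r$start
  mirrored$strand <- ifelse(r$strand == "+", "-", "+")
  p1 <- compute_five_prime_counts(r, g)
  p2 <- compute_five_prime_counts(mirrored, g)
  expect_identical(p2$crick, rev(p1$watson))
  expect_identical(p2$watson, rev(p1$crick))
})

test_that("MAPQ filtering removes multi-mappers and is idempotent", {
  reads <- make_reads(c(10, 20, 30), c(100, 110, 120), c("+", "-", "+"),
                      mapq = c(0L, 10L, 60L))
  f <- filter_unique_mappers(reads, 10)
  expect_equal(f$start, c(20, 30))                 # order preserved
  expect_identical(filter_unique_mappers(f, 10), f)
  expect_equal(nrow(filter_unique_mappers(reads[0, ], 10)), 0L)

  # simulated h90 library: duplicated cassettes get MAPQ 0, and after the
  # unique-mapper filter their interiors have no coverage at all
  g <- small_genome("h90_M")
  r <- fixture("lib_h90", simulate_library(g, sonication_params(20000, seed = 9)))
  cassette_runs <- g$ambiguous[g$ambiguous$end - g$ambiguous$start > 500, ]
  expect_equal(nrow(cassette_runs), 2L)            # mat1 and mat3 M cassettes
  kept <- filter_unique_mappers(r, 10)
  cov <- IRanges::coverage(IRanges::IRanges(kept$start, kept$end),
                           width = g$length)
  interior <- IRanges::IRanges(cassette_runs$start + 130L,
                               cassette_runs$end - 130L)
  expect_equal(max(max(cov[interior])), 0)
  # but unfiltered coverage there is dense
  cov_all <- IRanges::coverage(IRanges::IRanges(r$start, r$end),
                               width = g$length)
  expect_gt(min(min(cov_all[interior])), 0)
})

test_that("counts-per-million normalization scales and flags correctly", {
  prof <- five_prime_profile(c(0, 5, 0, 0), c(0, 0, 5, 0))
  prof$library_size <- 1e6
  norm <- normalize_profile(prof)
  expect_equal(norm$watson[2], 5.0)
  prof$library_size <- 2e6
  expect_equal(normalize_profile(prof)$watson[2], 2.5)
  expect_error(normalize_profile(norm), "already normalized")
  empty <- five_prime_profile(numeric(4), numeric(4))
  expect_error(normalize_profile(empty), "empty")
  # conservation: normalized mass totals 1e6 when every read is counted
  p <- small_nicked_profile()
  n <- normalize_profile(p)
  expect_equal(sum(n$watson) + sum(n$crick), 1e6)
})

test_that("profiles survive a SAM round trip", {
  g <- small_genome()
  r <- small_nicked_library()[seq_len(5000), ]
  sam <- tempfile(fileext = ".sam")
  write_sam(r, g, sam)
  r2 <- read_alignments(sam)
  expect_equal(nrow(r2), nrow(r))
  p1 <- compute_five_prime_counts(r, g)
  p2 <- compute_five_prime_counts(r2, g)
  expect_identical(p1$watson, p2$watson)
  expect_identical(p1$crick, p2$crick)
  # MAPQ survives too: filtering either table gives the same profile
  p3 <- compute_five_prime_counts(r2, g, min_mapq = 10)
  p4 <- compute_five_prime_counts(r, g, min_mapq = 10)
  expect_identical(p3$watson, p4$watson)
})

test_that("profile export writes bedGraph and TSV", {
  g <- small_genome()
  prof <- small_nicked_profile()
  prefix <- tempfile()
  files <- write_profile(prof, prefix)
  expect_true(all(file.exists(files)))
  tsv <- utils::read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tsv), g$length)
  expect_equal(tsv$watson, prof$watson)
  bg <- rtracklayer::import.bedGraph(paste0(prefix, ".watson.bedgraph"))
  expect_equal(sum(bg$score), sum(prof$watson))
})
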