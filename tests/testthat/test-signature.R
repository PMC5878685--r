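# Genome-wide screen and nick caller.

test_that("a single nick yields one strand-exclusive region containing it", {
  g <- small_genome()
  nick <- g$nick_sites$pos
  prof <- small_nicked_profile()
  models <- list(watson = fit_null(prof, "watson"),
                 crick = fit_null(prof, "crick"))
  sc <- genome_screen(prof, models$watson, models$crick)
  excl_w <- sc$watson$regions[sc$watson$regions$status == "strand_exclusive", ]
  expect_equal(nrow(excl_w), 1L)
  expect_true(excl_w$start <= nick && nick <= excl_w$end)
  expect_equal(excl_w$peak_pos, nick)
  # the weakened-zone enrichment on the Crick strand is not strand-exclusive
  expect_equal(sum(sc$crick$regions$status == "strand_exclusive"), 0L)
  expect_error(genome_screen(normalize_profile(prof), models$watson,
                             models$crick), "raw")
})

test_that("the caller recovers position and strand exactly across seeds", {
  g <- small_genome()
  nick <- g$nick_sites$pos
  for (seed in 1:5) {
    reads <- simulate_library(g, sonication_params(30000, seed = seed))
    prof <- compute_five_prime_counts(reads, g)
    calls <- call_nicks(prof)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$pos, nick)
    expect_equal(calls$nicked_strand, "+")
    expect_true(calls$asymmetric)
    # signature geometry: the opposite window faces the spike
    expect_true(calls$opp_window_start <= nick &&
                  nick <= calls$opp_window_start + calls$opp_window_size - 1)
    expect_gte(calls$opp_window_size, 2)
  }
})

test_that("M- and P-allele references yield calls 3 nt apart", {
  calls <- lapply(c("M_donorless", "P_donorless"), function(v) {
    g <- small_genome(v)
    reads <- simulate_library(g, sonication_params(30000, seed = 21))
    call_nicks(compute_five_prime_counts(reads, g))
  })
  expect_equal(nrow(calls[[1]]), 1L)
  expect_equal(nrow(calls[[2]]), 1L)
  expect_equal(abs(calls[[1]]$pos - calls[[2]]$pos), 3L)
})

test_that("nick-free libraries produce no calls and no exclusive regions", {
  g <- small_genome("nick_free")
  reads <- simulate_library(g, sonication_params(20000, imprint_fraction = 0,
                                                 seed = 17))
  prof <- compute_five_prime_counts(reads, g)
  calls <- call_nicks(prof)
  expect_equal(nrow(calls), 0L)
  screen <- attr(calls, "screen")
  expect_equal(sum(screen$watson$regions$status == "strand_exclusive"), 0L)
  expect_equal(sum(screen$crick$regions$status == "strand_exclusive"), 0L)
})

test_that("collapsed tandem repeats are enriched symmetrically, not called", {
  set.seed(31)
  seg <- random_dna(600)
  seq <- paste0(random_dna(5000), seg, random_dna(300), seg, random_dna(300),
                seg, random_dna(5000))
  g <- genome("tandem", seq,
              features = data.frame(label = c("dupA", "dupB", "dupC"),
                                    start = c(5001, 5901, 6801),
                                    end = c(5600, 6500, 7400)))
  expect_equal(nrow(g$repeats), 3L)
  reads <- simulate_library(g, sonication_params(30000, imprint_fraction = 0,
                                                 seed = 31))
  reads <- collapse_multimappers(reads, g)
  prof <- compute_five_prime_counts(reads, g)
  # null fitted on repeat-free background sequence: on a real-size genome a
  # collapsed repeat is a negligible fraction of the fit; on this toy genome
  # it would dominate the dispersion estimate
  models <- list(watson = fit_null(prof, "watson", c(1, 5000)),
                 crick = fit_null(prof, "crick", c(1, 5000)))
  sc <- genome_screen(prof, models$watson, models$crick)
  n_regions <- nrow(sc$watson$regions) + nrow(sc$crick$regions)
  expect_gt(n_regions, 0)                       # the artifact is detected...
  expect_equal(sum(sc$watson$regions$status == "strand_exclusive") +
                 sum(sc$crick$regions$status == "strand_exclusive"), 0L)
  expect_equal(nrow(call_nicks(prof, models)), 0L)  # ...but never called
})

test_that("an IP-style library around the nick gives the same call", {
  g <- small_genome()
  nick <- g$nick_sites$pos
  reads <- simulate_library(g, sonication_params(30000, seed = 42))
  whole <- call_nicks(compute_five_prime_counts(reads, g))
  ip_reads <- filter_reads_to_region(reads, nick - 300, nick + 300)
  expect_lt(nrow(ip_reads), nrow(reads) / 4)
  ip <- call_nicks(compute_five_prime_counts(ip_reads, g))
  expect_equal(nrow(ip), 1L)
  expect_equal(ip$pos, whole$pos)
  expect_equal(ip$nicked_strand, whole$nicked_strand)
})

test_that("nick calls export as TSV and BED", {
  g <- small_genome()
  calls <- call_nicks(small_nicked_profile())
  prefix <- tempfile()
  files <- write_nick_calls(calls, prefix)
  expect_true(all(file.exists(files)))
  bed <- rtracklayer::import.bed(paste0(prefix, ".calls.bed"))
  expect_equal(BiocGenerics::start(bed), calls$pos)
  expect_equal(as.character(BiocGenerics::strand(bed)), calls$nicked_strand)
})
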