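# Reference builder and sonication simulator.

test_that("mating-type references have the field's homology-box geometry", {
  g <- small_genome()
  feat_len <- function(g, label) {
    f <- g$features[g$features$label == label, ]
    f$end - f$start + 1L
  }
  expect_equal(feat_len(g, "mat1_H1"), 59L)
  expect_equal(feat_len(g, "mat1_H2"), 135L)
  expect_equal(nrow(g$nick_sites), 1L)
  expect_equal(g$nick_sites$strand, "+")
  # nick sits at the mat1-allele / H1 junction (first H1 base)
  expect_equal(g$nick_sites$pos,
               g$features$start[g$features$label == "mat1_H1"])

  h90 <- small_genome("h90_M")
  expect_equal(feat_len(h90, "mat2_H3"), 57L)
  for (box in c("H1", "H2")) {
    labels <- paste0("mat", 1:3, "_", box)
    seqs <- vapply(labels, function(l) {
      f <- h90$features[h90$features$label == l, ]
      substring(h90$sequence, f$start, f$end)
    }, character(1))
    expect_length(unique(seqs), 1L)  # verbatim copies per cassette
    expect_equal(Biostrings::countPattern(seqs[1],
                                          Biostrings::DNAString(h90$sequence)),
                 3L)
  }
  # duplicated sequence is annotated: both full M cassettes are ambiguous runs
  expect_true(nrow(h90$ambiguous) >= 2)
})

test_that("M and P variants place the nick exactly 3 nt apart", {
  for (pair in list(c("M_donorless", "P_donorless"), c("h90_M", "h90_P"))) {
    gm <- small_genome(pair[1])
    gp <- small_genome(pair[2])
    expect_equal(abs(gm$nick_sites$pos - gp$nick_sites$pos), 3L)
  }
  expect_equal(nrow(small_genome("nick_free")$nick_sites), 0L)
  expect_error(build_mat_region("no_such_variant"))
  expect_error(build_mat_region("M_donorless", flank_len = 10))
})

test_that("invalid genomes are rejected", {
  expect_error(genome("g", "ACGTACGT",
                      nick_sites = data.frame(pos = 100, strand = "+")),
               "outside")
  expect_error(genome("g", "ACGTACGT",
                      features = data.frame(label = "f", start = 5, end = 20)))
  expect_error(genome("g", "ACGTACGT",
                      nick_sites = data.frame(pos = 3, strand = "x")))
})

test_that("simulation is reproducible and seed-sensitive", {
  g <- small_genome()
  p <- sonication_params(2000, seed = 7)
  r1 <- simulate_library(g, p)
  r2 <- simulate_library(g, p)
  expect_identical(r1, r2)
  r3 <- simulate_library(g, sonication_params(2000, seed = 8))
  expect_false(identical(r1$start, r3$start))
})

test_that("every preserved break 5' end yields exactly one read", {
  r <- small_nicked_library()
  plus <- r$strand == "+"
  expect_equal(sum(plus), attr(r, "n_breaks_watson"))
  expect_equal(sum(!plus), attr(r, "n_breaks_crick"))
  # one read per distinct (molecule, 5' end): no duplicated break emits two
  expect_false(any(duplicated(r[plus, c("mol", "start")])))
  expect_false(any(duplicated(r[!plus, c("mol", "end")])))
  # a Watson 5' end exists at the nick for every imprinted molecule
  g <- small_genome()
  expect_gte(sum(r$start[plus] == g$nick_sites$pos), attr(r, "n_imprinted"))
  # reads respect read_length and genome bounds
  expect_true(all(r$end - r$start + 1L <= 130L))
  expect_true(all(r$start >= 1L & r$end <= g$length))
})

test_that("sonication fragment lengths match the configured mean", {
  # molecule-length genome (11.3 kb) so terminal fragments barely bias the mean
  g <- full_genome("nick_free")
  r <- simulate_library(g, sonication_params(5000, imprint_fraction = 0,
                                             mean_fragment_len = 300,
                                             seed = 3))
  # independent tally: reconstruct per-molecule fragments from Watson break
  # coordinates (read starts) plus the molecule boundaries
  starts <- r$start[r$strand == "+"]
  mols <- r$mol[r$strand == "+"]
  frag_lens <- unlist(lapply(split(starts, mols), function(b) {
    diff(c(1L, sort(b), g$length + 1L))
  }), use.names = FALSE)
  expect_lt(abs(mean(frag_lens) - 300) / 300, 0.05)
})

test_that("strand asymmetry arises only from nicks", {
  g <- small_genome("nick_free")
  r <- simulate_library(g, sonication_params(20000, imprint_fraction = 0,
                                             seed = 5))
  prof <- compute_five_prime_counts(r, g)
  # Watson and Crick per-position counts are statistically exchangeable
  tt <- t.test(prof$watson, prof$crick)
  expect_gt(tt$p.value, 0.01)
  # with a nick, the Watson count at the nick towers over the empirical null
  profn <- small_nicked_profile()
  nick <- small_genome()$nick_sites$pos
  null_counts <- profn$watson[-nick]
  expect_gt(profn$watson[nick], quantile(null_counts, 0.9999))
})

test_that("nicks outside the genome are rejected at simulation time", {
  g <- small_genome()
  g_bad <- g
  g_bad$nick_sites$pos <- g$length + 50L
  expect_error(simulate_library(g_bad, sonication_params(100, seed = 1)),
               "outside genome")
})
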