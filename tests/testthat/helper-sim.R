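# Shared, lazily-built simulation fixtures. Heavy objects are cached per
# test run so several test files can reuse the same library.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# small donor-less genome used by most unit tests (flank 1000, ~3.3 kb)
small_genome <- function(variant = "M_donorless") {
  fixture(paste0("g_", variant), build_mat_region(variant, flank_len = 1000))
}

# moderate nicked library on the small genome
small_nicked_library <- function() {
  fixture("lib_nicked_small",
          simulate_library(small_genome(), sonication_params(30000, seed = 42)))
}

small_nicked_profile <- function() {
  fixture("prof_nicked_small",
          compute_five_prime_counts(small_nicked_library(), small_genome()))
}

# full-scale genomes/profiles used by the acceptance tests (flank 5000)
full_genome <- function(variant) {
  fixture(paste0("gfull_", variant), build_mat_region(variant))
}

full_profile <- function(variant, n_molecules, seed, imprint_fraction = 0.3) {
  fixture(sprintf("proffull_%s_%d_%d_%g", variant, n_molecules, seed,
                  imprint_fraction), {
    g <- full_genome(variant)
    reads <- simulate_library(
      g, sonication_params(n_molecules, imprint_fraction = imprint_fraction,
                           seed = seed))
    compute_five_prime_counts(reads, g)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# manual read table builder
make_reads <- function(start, end, strand, mapq = 60L, chrom = "toy") {
  data.frame(chrom = rep_len(chrom, length(start)), start = as.integer(start),
             end = as.integer(end), strand = strand,
             mapq = rep_len(as.integer(mapq), length(start)))
}
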