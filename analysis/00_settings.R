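# Shared settings for the analysis scripts. Each numbered script is
# self-contained: it re-simulates its inputs deterministically from these
# seeds, so the scripts can be run independently and in any order.

library(nickscan)

SETTINGS <- list(
  flank_len = 5000L,        # toy reference flanks -> ~11.3-kb genome
  n_molecules = 1e5,        # template molecules per library
  imprint_fraction = 0.3,   # fraction of chromatids carrying the nick
  weakened_window = 20L,    # opposite-strand preferential breakage zone, nt
  seed_library = 11L,       # M-allele whole-extract library
  seed_p_library = 12L,     # P-allele library
  seed_control = 13L,       # nick-free (swi1-delta analog) library
  seed_wce = 14L            # whole-cell-extract library for tracks
)

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

m_library <- function(variant = "M_donorless", seed = SETTINGS$seed_library,
                      imprint_fraction = SETTINGS$imprint_fraction) {
  g <- build_mat_region(variant, flank_len = SETTINGS$flank_len)
  reads <- simulate_library(g, sonication_params(
    SETTINGS$n_molecules, imprint_fraction = imprint_fraction,
    weakened_window = SETTINGS$weakened_window, seed = seed))
  list(genome = g, reads = reads,
       profile = compute_five_prime_counts(reads, g))
}
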