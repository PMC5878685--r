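# Sonication / end-blunting library simulator.
#
# Molecules are full-length copies of the genome. Sonication breaks both
# strands together at random points (Poisson process, rate 1/mean_fragment_len
# per internucleotide bond). An imprinted molecule additionally carries a
# persistent single-strand break exactly at the nick, and its intact strand is
# mechanically weakened over a short window centred on the nick: with
# probability opposite_break_prob it breaks once, uniformly, inside that
# window. End blunting preserves the first nucleotide of every 5' end created
# by a break, and one read is emitted per preserved 5' end (truncated at the
# fragment end). Alignment coordinates are recorded directly; no aligner is
# run. Reads lying entirely inside sequence that occurs more than once in the
# genome get MAPQ 0, all others MAPQ 60.
#
# A break coordinate b (2..L) means both the cut between positions b-1 and b:
# it creates a Watson 5' end at b and a Crick 5' end at b-1. 5' ends at the
# molecule termini are not sequenced: template molecules stand in for long
# genomic DNA whose extraction ends are dispersed, and emitting them would
# place an artifactual spike at the ends of the toy genome.

#' Sonication simulation parameters
#'
#' @param n_molecules Number of template molecules (genome copies).
#' @param imprint_fraction Fraction of molecules carrying the persistent nick
#'   (0-1). Default 0.3.
#' @param mean_fragment_len Mean sonication fragment length, nt. Default 300
#'   (typical ChIP sonication target).
#' @param weakened_window Width, nt, of the opposite-strand preferential
#'   breakage zone centred on the nick. Default 20.
#' @param opposite_break_prob Probability that a nicked molecule's intact
#'   strand breaks inside the weakened window. Default 0.8.
#' @param read_length Read length, nt. Default 130.
#' @param seed RNG seed.
#' @return A list of class `"sonication_params"`.
#' @export
sonication_params <- function(n_molecules, imprint_fraction = 0.3,
                              mean_fragment_len = 300, weakened_window = 20L,
                              opposite_break_prob = 0.8, read_length = 130L,
                              seed = 1L) {
  if (imprint_fraction < 0 || imprint_fraction > 1) {
    stop("imprint_fraction must be in [0, 1]")
  }
  if (weakened_window < 1) stop("weakened_window must be >= 1")
  if (read_length < 20) stop("read_length must be >= 20")
  if (mean_fragment_len <= read_length) {
    stop("mean_fragment_len must exceed read_length")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 imprint_fraction = imprint_fraction,
                 mean_fragment_len = mean_fragment_len,
                 weakened_window = as.integer(weakened_window),
                 opposite_break_prob = opposite_break_prob,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sonication_params")
}

# Per-strand fragment bookkeeping: given molecule ids and break coordinates
# for one strand, return per-break neighbours within the molecule.
.strand_breaks <- function(mol, b, L) {
  o <- order(mol, b, method = "radix")
  mol <- mol[o]; b <- b[o]
  n <- length(b)
  if (n == 0) {
    return(list(mol = integer(), b = integer(),
                frag_end = integer(), frag_start = integer()))
  }
  keep <- c(TRUE, mol[-1] != mol[-n] | b[-1] != b[-n])
  mol <- mol[keep]; b <- b[keep]
  n <- length(b)
  same_next <- c(mol[-1] == mol[-n], FALSE)
  frag_end <- rep.int(L, n)               # end of fragment starting at b
  idx <- which(same_next)
  frag_end[idx] <- b[idx + 1L] - 1L
  same_prev <- c(FALSE, same_next[-n])
  frag_start <- rep.int(1L, n)            # start of fragment ending at b - 1
  idx <- which(same_prev)
  frag_start[idx] <- b[idx - 1L]
  list(mol = mol, b = b, frag_end = frag_end, frag_start = frag_start)
}

#' Simulate a sonicated, end-blunted, single-end sequencing library
#'
#' @param genome A [genome()] object (its `nick_sites` define the imprint).
#' @param params A [sonication_params()] object.
#' @return A `data.frame` of aligned reads with columns `chrom`, `start`,
#'   `end` (1-based, closed), `strand` (`"+"` Watson / `"-"` Crick), `mapq`
#'   and `mol` (template molecule id). Attributes `n_imprinted`,
#'   `n_breaks_watson`, `n_breaks_crick` record ground truth: the number of
#'   reads on each strand equals the number of preserved 5' ends, i.e. the
#'   number of distinct breaks on that strand.
#' @export
simulate_library <- function(genome, params) {
  stopifnot(inherits(genome, "genome"), inherits(params, "sonication_params"))
  L <- genome$length
  if (nrow(genome$nick_sites) > 0 &&
      (any(genome$nick_sites$pos < 1) || any(genome$nick_sites$pos > L))) {
    stop("nick position outside genome")
  }
  set.seed(params$seed)
  n <- params$n_molecules
  rl <- params$read_length
  ww <- params$weakened_window

  # common double-strand sonication breaks
  k <- stats::rpois(n, (L - 1) / params$mean_fragment_len)
  mol_c <- rep.int(seq_len(n), k)
  b_c <- sample.int(L - 1L, sum(k), replace = TRUE) + 1L

  # nick-specific single-strand breaks
  mol_w <- integer(); b_w <- integer()   # Watson-only breaks
  mol_k <- integer(); b_k <- integer()   # Crick-only breaks
  n_imprinted <- 0L
  if (nrow(genome$nick_sites) > 0 && params$imprint_fraction > 0) {
    imprinted <- which(stats::runif(n) < params$imprint_fraction)
    n_imprinted <- length(imprinted)
    for (i in seq_len(nrow(genome$nick_sites))) {
      pos <- genome$nick_sites$pos[i]
      nick_strand <- genome$nick_sites$strand[i]
      # break coordinate that creates a 5' end at `pos` on the nicked strand
      b_nick <- if (nick_strand == "+") pos else pos + 1L
      b_nick <- min(max(b_nick, 2L), L)
      opp <- imprinted[stats::runif(n_imprinted) < params$opposite_break_prob]
      b_opp <- pos - (ww %/% 2L) + sample.int(ww, length(opp), replace = TRUE) - 1L
      b_opp <- pmin(pmax(b_opp, 2L), L)
      if (nick_strand == "+") {
        mol_w <- c(mol_w, imprinted); b_w <- c(b_w, rep.int(b_nick, n_imprinted))
        mol_k <- c(mol_k, opp); b_k <- c(b_k, b_opp)
      } else {
        mol_k <- c(mol_k, imprinted); b_k <- c(b_k, rep.int(b_nick, n_imprinted))
        mol_w <- c(mol_w, opp); b_w <- c(b_w, b_opp)
      }
    }
  }

  watson <- .strand_breaks(c(mol_c, mol_w), c(b_c, b_w), L)
  crick <- .strand_breaks(c(mol_c, mol_k), c(b_c, b_k), L)

  # one read per preserved 5' end, truncated at the fragment end
  w_start <- watson$b
  w_end <- pmin(watson$b + rl - 1L, watson$frag_end)
  c_end <- crick$b - 1L
  c_start <- pmax(crick$b - rl, crick$frag_start)

  start <- c(w_start, c_start)
  end <- c(w_end, c_end)
  strand <- rep(c("+", "-"), c(length(w_start), length(c_start)))
  mol <- c(watson$mol, crick$mol)

  mapq <- rep.int(60L, length(start))
  if (nrow(genome$ambiguous) > 0) {
    amb_id <- integer(L)
    for (i in seq_len(nrow(genome$ambiguous))) {
      amb_id[genome$ambiguous$start[i]:genome$ambiguous$end[i]] <- i
    }
    inside <- amb_id[start] > 0L & amb_id[start] == amb_id[end]
    mapq[inside] <- 0L
  }

  reads <- data.frame(chrom = genome$name, start = start, end = end,
                      strand = strand, mapq = mapq, mol = mol)
  attr(reads, "n_imprinted") <- n_imprinted
  attr(reads, "n_breaks_watson") <- length(watson$b)
  attr(reads, "n_breaks_crick") <- length(crick$b)
  reads
}

#' Restrict reads to those whose 5' end falls inside a region
#'
#' Emulates an immunoprecipitated library concentrated around a binding
#' site: only reads whose biological 5' end lies inside `[start, end]` are
#' retained.
#'
#' @param reads Read table as returned by [simulate_library()].
#' @param start,end Region bounds (1-based, closed).
#' @return The filtered read table.
#' @export
filter_reads_to_region <- function(reads, start, end) {
  p5 <- ifelse(reads$strand == "+", reads$start, reads$end)
  reads[p5 >= start & p5 <= end, , drop = FALSE]
}

#' Collapse multi-mapping reads onto the primary repeat copy
#'
#' Emulates the reference-collapse artifact behind symmetric enriched
#' regions in real screens (repeats, mitochondrial-homology regions): reads
#' lying entirely inside a non-primary occurrence of a duplicated sequence
#' are relocated to the corresponding coordinates of the family's first
#' occurrence, inflating both strands there equally. Larger repeat families
#' take precedence where occurrences nest.
#'
#' @param reads Read table as returned by [simulate_library()].
#' @param genome The [genome()] the reads were simulated from.
#' @return The read table with relocated coordinates.
#' @export
collapse_multimappers <- function(reads, genome) {
  occ <- genome$repeats
  if (nrow(occ) == 0) return(reads)
  occ <- occ[order(occ$end - occ$start, decreasing = TRUE), , drop = FALSE]
  moved <- logical(nrow(reads))
  for (i in seq_len(nrow(occ))) {
    if (occ$start[i] == occ$primary_start[i]) next
    hit <- !moved & reads$start >= occ$start[i] & reads$end <= occ$end[i]
    shift <- occ$primary_start[i] - occ$start[i]
    reads$start[hit] <- reads$start[hit] + shift
    reads$end[hit] <- reads$end[hit] + shift
    moved <- moved | hit
  }
  reads
}

#' Write reads to a SAM file
#'
#' Coordinate-sorted single-end SAM with sequence taken from the genome
#' (reverse-complemented for Crick reads). Intended for modest library sizes
#' (fixtures, interoperability checks, track display).
#'
#' @param reads Read table as returned by [simulate_library()].
#' @param genome The [genome()] the reads are aligned to.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, genome, path) {
  o <- order(reads$start)
  reads <- reads[o, , drop = FALSE]
  seqs <- substring(genome$sequence, reads$start, reads$end)
  minus <- reads$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length),
    sprintf("read%d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
            seq_len(nrow(reads)), ifelse(minus, 16L, 0L), reads$chrom,
            reads$start, reads$mapq, reads$end - reads$start + 1L, seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Write reads to a FASTQ file
#'
#' Reads are written 5' to 3' (Crick reads reverse-complemented) with a
#' constant quality string.
#'
#' @inheritParams write_sam
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, genome, path) {
  seqs <- substring(genome$sequence, reads$start, reads$end)
  minus <- reads$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), con)
  invisible(path)
}
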