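# Strand-specific per-position 5'-end count ("5' count") profiles.
#
# A forward (Watson) read's biological 5' end is its leftmost aligned base;
# a reverse (Crick) read's 5' end is its rightmost aligned base. End blunting
# during library preparation conserves the first nucleotide of every
# sonicated fragment, so the per-position tallies of read 5' ends carry the
# fragmentation signal. Duplicate reads are deliberately retained: repeated
# identical 5' ends ARE the signal of a persistent nick, and deduplication
# would erase it. Statistics downstream use raw integer counts;
# counts-per-million normalization is for track export only.

#' Construct a 5'-count profile from count vectors
#'
#' Builds a `"five_prime_profile"` directly from per-position count
#' vectors, e.g. for synthetic calibration inputs;
#' [compute_five_prime_counts()] computes one from reads.
#'
#' @param watson,crick Equal-length non-negative count vectors.
#' @param chrom Chromosome name.
#' @return A `"five_prime_profile"` object.
#' @export
five_prime_profile <- function(watson, crick, chrom = "chr") {
  stopifnot(length(watson) == length(crick), all(watson >= 0), all(crick >= 0))
  structure(list(chrom = chrom, length = length(watson), watson = watson,
                 crick = crick, library_size = sum(watson) + sum(crick),
                 normalized = FALSE),
            class = "five_prime_profile")
}

#' Read aligned reads from a BAM or SAM file
#'
#' Thin wrapper over Rsamtools/GenomicAlignments producing the package's
#' plain read table. SAM input is converted to BAM in a temporary directory
#' first. The 5' count position of a read is its first/last aligned
#' reference base (soft clips ignored), which is what `start`/`end` of the
#' alignment provide.
#'
#' @param path Path to a BAM or SAM file.
#' @return Read `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `mapq`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, destination = sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = TRUE)
  }
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(what = "mapq"))
  data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
             start = BiocGenerics::start(ga),
             end = BiocGenerics::end(ga),
             strand = as.character(BiocGenerics::strand(ga)),
             mapq = S4Vectors::mcols(ga)$mapq)
}

#' Filter reads by mapping quality
#'
#' Removes multi-mapping reads, reproducing the `samtools view -q`
#' unique-mapper filter: only reads with `mapq >= min_mapq` are kept, order
#' preserved. Filtering is idempotent.
#'
#' @param reads Read table (`chrom`, `start`, `end`, `strand`, `mapq`).
#' @param min_mapq Minimum mapping quality kept (default 10).
#' @return The filtered read table.
#' @export
filter_unique_mappers <- function(reads, min_mapq = 10L) {
  reads[reads$mapq >= min_mapq, , drop = FALSE]
}

#' Compute a strand-specific 5'-end count profile
#'
#' Tallies, for every genomic position and each strand, the number of read
#' 5' ends mapped there: Watson (`+`) reads count at their leftmost aligned
#' coordinate, Crick (`-`) reads at their rightmost aligned coordinate.
#'
#' @param reads Read table (`chrom`, `start`, `end`, `strand`, `mapq`).
#' @param genome A [genome()] object the reads are aligned to (provides the
#'   chromosome name and length).
#' @param min_mapq Optional unique-mapper filter applied before counting
#'   (`NULL`, the default, counts all reads).
#' @return An object of class `"five_prime_profile"`: list with `chrom`,
#'   `length`, `watson` and `crick` (per-position count vectors),
#'   `library_size` (reads counted) and `normalized` (flag).
#' @examples
#' g <- build_mat_region("M_donorless", flank_len = 1000)
#' reads <- simulate_library(g, sonication_params(2000, seed = 7))
#' prof <- compute_five_prime_counts(reads, g)
#' prof$watson[g$nick_sites$pos]
#' @export
compute_five_prime_counts <- function(reads, genome, min_mapq = NULL) {
  if (!is.null(min_mapq)) reads <- filter_unique_mappers(reads, min_mapq)
  L <- genome$length
  bad <- which(reads$start < 1L | reads$end > L | reads$start > reads$end)
  if (length(bad) > 0) {
    stop(sprintf("read %d ([%d, %d] %s) falls outside genome '%s' (1..%d)",
                 bad[1], reads$start[bad[1]], reads$end[bad[1]],
                 reads$strand[bad[1]], genome$name, L))
  }
  plus <- reads$strand == "+"
  watson <- tabulate(reads$start[plus], nbins = L)
  crick <- tabulate(reads$end[!plus], nbins = L)
  structure(list(chrom = genome$name, length = L, watson = watson,
                 crick = crick, library_size = nrow(reads),
                 normalized = FALSE),
            class = "five_prime_profile")
}

#' @export
print.five_prime_profile <- function(x, ...) {
  cat(sprintf("<five_prime_profile> %s: %d bp, library size %d%s\n",
              x$chrom, x$length, x$library_size,
              if (x$normalized) " (counts per million)" else ""))
  invisible(x)
}

#' Normalize a 5'-count profile to counts per million
#'
#' Scales both strand vectors by `1e6 / library_size`. Normalized profiles
#' are for track export and display; the count null model requires raw
#' integer counts, so statistical functions refuse normalized input.
#'
#' @param profile A [compute_five_prime_counts()] profile.
#' @return The normalized profile (`normalized = TRUE`).
#' @export
normalize_profile <- function(profile) {
  if (profile$normalized) stop("profile is already normalized")
  if (profile$library_size == 0) stop("cannot normalize an empty library")
  s <- 1e6 / profile$library_size
  profile$watson <- profile$watson * s
  profile$crick <- profile$crick * s
  profile$normalized <- TRUE
  profile
}

#' Export a profile as per-strand bedGraph tracks and a TSV
#'
#' Writes `<prefix>.watson.bedgraph`, `<prefix>.crick.bedgraph` (nonzero
#' positions only) and `<prefix>.tsv` (`chrom`, `pos` 1-based, `watson`,
#' `crick`, all positions).
#'
#' @param profile A `five_prime_profile`.
#' @param prefix Output path prefix.
#' @return Invisibly, the character vector of files written.
#' @export
write_profile <- function(profile, prefix) {
  files <- character()
  for (s in c("watson", "crick")) {
    v <- profile[[s]]
    nz <- which(v != 0)
    gr <- GenomicRanges::GRanges(profile$chrom, IRanges::IRanges(nz, nz),
                                 score = v[nz])
    GenomeInfoDb::seqlengths(gr) <- profile$length
    f <- paste0(prefix, ".", s, ".bedgraph")
    rtracklayer::export.bedGraph(gr, f)
    files <- c(files, f)
  }
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(
    data.frame(chrom = profile$chrom, pos = seq_len(profile$length),
               watson = profile$watson, crick = profile$crick),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, tsv))
}
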