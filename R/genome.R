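# Toy mating-type reference genomes with ground-truth nick sites.
#
# The builders emulate the geometry of the fission-yeast mating-type region:
# cassettes share short homology boxes (H1 = 59 bp, H2 = 135 bp, H3 = 57 bp)
# that make the silent cassettes unalignable with unique mappers, and the
# persistent nick sits on the Watson strand at the junction between the mat1
# allele and the H1 box, three nucleotides apart between the M and P alleles.
# All coordinates are 1-based, closed intervals.

H1_LEN <- 59L
H2_LEN <- 135L
H3_LEN <- 57L
ALLELE_M_LEN <- 1104L
ALLELE_P_LEN <- 1101L
SPACER_LEN <- 2000L

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Construct a genome object
#'
#' Low-level constructor for the container used throughout the package.
#' Most users will call [build_mat_region()] instead.
#'
#' @param name Chromosome/contig name.
#' @param sequence Nucleotide sequence as a single character string.
#' @param features `data.frame` with columns `label`, `start`, `end`
#'   (1-based, closed). May be empty.
#' @param nick_sites `data.frame` with columns `pos`, `strand` giving
#'   ground-truth persistent nicks. `pos` is the coordinate of the 5' end
#'   created on the nicked strand; `strand` is `"+"` (Watson) or `"-"`
#'   (Crick). May be empty.
#' @return An object of class `"genome"`: a list with elements `name`,
#'   `sequence`, `length`, `features`, `nick_sites`, `repeats` (occurrence
#'   table of duplicated feature sequences) and `ambiguous` (merged runs of
#'   multi-mapping sequence).
#' @export
genome <- function(name, sequence,
                   features = data.frame(label = character(), start = integer(),
                                         end = integer()),
                   nick_sites = data.frame(pos = integer(), strand = character())) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  len <- nchar(sequence)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features) > 0) {
    if (any(features$start < 1L) || any(features$end > len) ||
        any(features$start > features$end)) {
      stop("feature intervals must satisfy 1 <= start <= end <= genome length")
    }
  }
  if (nrow(nick_sites) > 0) {
    nick_sites$pos <- as.integer(nick_sites$pos)
    if (any(nick_sites$pos < 1L) || any(nick_sites$pos > len)) {
      stop("nick position outside genome")
    }
    if (!all(nick_sites$strand %in% c("+", "-"))) {
      stop("nick strand must be '+' or '-'")
    }
  }
  g <- structure(
    list(name = name, sequence = sequence, length = len,
         features = features, nick_sites = nick_sites),
    class = "genome")
  rep <- find_repeats(g)
  g$repeats <- rep$occurrences
  g$ambiguous <- rep$ambiguous
  g
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d bp, %d features, %d nick site(s), %d repeat run(s)\n",
              x$name, x$length, nrow(x$features), nrow(x$nick_sites),
              nrow(x$ambiguous)))
  invisible(x)
}

#' Locate duplicated feature sequences in a genome
#'
#' Every distinct feature sequence that occurs more than once in the genome
#' (forward strand, exact match) defines a repeat family. Occurrences are
#' recorded individually (with the family's first occurrence as the primary
#' copy) and also merged into maximal runs of ambiguous sequence used for
#' rule-based MAPQ assignment: a read lying entirely inside one run cannot be
#' placed uniquely.
#'
#' @param g A [genome()] object (the `repeats`/`ambiguous` elements need not
#'   be present yet).
#' @return List with `occurrences` (`data.frame`: `family`, `start`, `end`,
#'   `primary_start`) and `ambiguous` (`data.frame`: `start`, `end`).
#' @export
find_repeats <- function(g) {
  occ <- data.frame(family = character(), start = integer(), end = integer(),
                    primary_start = integer())
  if (nrow(g$features) > 0) {
    subj <- Biostrings::DNAString(g$sequence)
    seqs <- substring(g$sequence, g$features$start, g$features$end)
    first <- !duplicated(seqs)
    for (i in which(first)) {
      m <- Biostrings::matchPattern(seqs[i], subj)
      if (length(m) > 1) {
        st <- BiocGenerics::start(m)
        occ <- rbind(occ, data.frame(
          family = g$features$label[i], start = as.integer(st),
          end = as.integer(BiocGenerics::end(m)),
          primary_start = as.integer(st[1])))
      }
    }
  }
  if (nrow(occ) > 0) {
    merged <- IRanges::reduce(IRanges::IRanges(occ$start, occ$end),
                              min.gapwidth = 1L)
    amb <- data.frame(start = BiocGenerics::start(merged),
                      end = BiocGenerics::end(merged))
  } else {
    amb <- data.frame(start = integer(), end = integer())
  }
  list(occurrences = occ, ambiguous = amb)
}

#' Build a toy mating-type region reference
#'
#' Assembles a synthetic reference emulating the fission-yeast mating-type
#' locus. All random components (flanks, spacers, homology boxes, allele
#' bodies) are drawn from a seeded RNG in a fixed order, so the same `seed`
#' yields byte-identical boxes and flanks across variants; in particular the
#' M and P variants differ only in the mat1 allele body, whose lengths differ
#' by exactly 3 nt, so the ground-truth nick (placed on the Watson strand at
#' the mat1-allele/H1 junction, i.e. the first base of H1) sits 3 nt apart
#' between M and P.
#'
#' Variants:
#' * `"M_donorless"`, `"P_donorless"`: mat1 only (donor cassettes deleted),
#'   no repeated sequence, one Watson nick.
#' * `"h90_M"`, `"h90_P"`: three cassettes (mat1, mat2-P, mat3-M) sharing
#'   verbatim H1/H2 boxes (H3 at mat2/mat3 only), creating multi-mapping
#'   ambiguity by construction; one Watson nick at mat1.
#' * `"nick_free"`: the M_donorless layout with no nick (negative control).
#'
#' @param variant One of `"M_donorless"`, `"P_donorless"`, `"h90_M"`,
#'   `"h90_P"`, `"nick_free"`.
#' @param flank_len Length of each random flank, nt (>= 1000).
#' @param seed RNG seed for sequence generation.
#' @return A [genome()] object.
#' @examples
#' g <- build_mat_region("M_donorless", flank_len = 1000)
#' subset(g$features, label == "mat1_H1")
#' @export
build_mat_region <- function(variant = c("M_donorless", "P_donorless", "h90_M",
                                         "h90_P", "nick_free"),
                             flank_len = 5000L, seed = 1L) {
  variant <- match.arg(variant)
  if (flank_len < 1000L) stop("flank_len must be >= 1000")
  flank_len <- as.integer(flank_len)
  set.seed(seed)
  # fixed draw order => identical shared components across variants
  flank_l <- random_dna(flank_len)
  h1 <- random_dna(H1_LEN)
  h2 <- random_dna(H2_LEN)
  h3 <- random_dna(H3_LEN)
  allele_m <- random_dna(ALLELE_M_LEN)
  allele_p <- random_dna(ALLELE_P_LEN)
  spacer1 <- random_dna(SPACER_LEN)
  spacer2 <- random_dna(SPACER_LEN)
  flank_r <- random_dna(flank_len)

  mat1_allele <- switch(variant,
    M_donorless = allele_m, h90_M = allele_m, nick_free = allele_m,
    P_donorless = allele_p, h90_P = allele_p)

  parts <- list()
  feats <- list()
  pos <- 0L
  add <- function(seqstr, label = NULL) {
    parts[[length(parts) + 1L]] <<- seqstr
    w <- nchar(seqstr)
    if (!is.null(label)) {
      feats[[length(feats) + 1L]] <<- data.frame(
        label = label, start = pos + 1L, end = pos + w)
    }
    pos <<- pos + w
    invisible(NULL)
  }
  cassette <- function(prefix, allele, with_h3) {
    cas_start <- pos + 1L
    if (with_h3) add(h3, paste0(prefix, "_H3"))
    add(h2, paste0(prefix, "_H2"))
    add(allele, paste0(prefix, "_allele"))
    add(h1, paste0(prefix, "_H1"))
    feats[[length(feats) + 1L]] <<- data.frame(
      label = prefix, start = cas_start, end = pos)
    invisible(NULL)
  }

  add(flank_l)
  cassette("mat1", mat1_allele, with_h3 = FALSE)
  if (variant %in% c("h90_M", "h90_P")) {
    add(spacer1)
    cassette("mat2", allele_p, with_h3 = TRUE)
    add(spacer2)
    cassette("mat3", allele_m, with_h3 = TRUE)
  }
  add(flank_r)

  features <- do.call(rbind, feats)
  h1_start <- features$start[features$label == "mat1_H1"]
  nick_sites <- if (variant == "nick_free") {
    data.frame(pos = integer(), strand = character())
  } else {
    data.frame(pos = h1_start, strand = "+")
  }
  genome(name = paste0("toy_", variant), sequence = paste(parts, collapse = ""),
         features = features, nick_sites = nick_sites)
}

#' Write a genome to FASTA and BED
#'
#' Writes `<prefix>.fa` (sequence), `<prefix>.features.bed` (annotated
#' features) and, when nick sites exist, `<prefix>.nicks.bed`
#' (ground-truth nick sites, strand-aware).
#'
#' @param g A [genome()] object.
#' @param prefix Output path prefix.
#' @return Invisibly, the character vector of files written.
#' @export
write_genome <- function(g, prefix) {
  fa <- paste0(prefix, ".fa")
  seq <- Biostrings::DNAStringSet(g$sequence)
  names(seq) <- g$name
  Biostrings::writeXStringSet(seq, fa)
  files <- fa
  if (nrow(g$features) > 0) {
    gr <- GenomicRanges::GRanges(g$name,
                                 IRanges::IRanges(g$features$start, g$features$end),
                                 name = g$features$label)
    bed <- paste0(prefix, ".features.bed")
    rtracklayer::export.bed(gr, bed)
    files <- c(files, bed)
  }
  if (nrow(g$nick_sites) > 0) {
    gr <- GenomicRanges::GRanges(g$name,
                                 IRanges::IRanges(g$nick_sites$pos, g$nick_sites$pos),
                                 strand = g$nick_sites$strand,
                                 name = "nick")
    bed <- paste0(prefix, ".nicks.bed")
    rtracklayer::export.bed(gr, bed)
    files <- c(files, bed)
  }
  invisible(files)
}
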