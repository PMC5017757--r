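#' Container for a single-species synthetic genome
#'
#' Holds one or more contigs, each tagged with the species it belongs to.
#' Species tags drive the construction of hybrid references and the
#' truth-species labels of simulated reads.
#'
#' @param sequences Named character vector of contig sequences over A/C/G/T.
#' @param species Character vector (`"human"` or `"mouse"`), one per contig,
#'   or a single value recycled to all contigs.
#' @return An object of class `species_genome` with elements `name`,
#'   `species` and `sequence`.
#' @export
species_genome <- function(sequences, species) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("contigs must have unique non-empty names")
  if (any(nchar(sequences) == 0L)) stop("contig sequences must be non-empty")
  if (any(grepl("[^ACGT]", sequences)))
    stop("contig sequences must contain only A, C, G, T")
  species <- rep_len(match.arg(species, c("human", "mouse"), several.ok = TRUE),
                     length(sequences))
  structure(
    list(name = nm, species = unname(species), sequence = unname(sequences)),
    class = "species_genome"
  )
}

#' @export
print.species_genome <- function(x, ...) {
  cat(sprintf("species_genome: %d contig(s), %s bp total\n",
              length(x$name), format(sum(nchar(x$sequence)), big.mark = ",")))
  for (i in seq_along(x$name))
    cat(sprintf("  %s [%s] %d bp\n", x$name[i], x$species[i],
                nchar(x$sequence[i])))
  invisible(x)
}

#' Configuration for a synthetic human/mouse genome pair
#'
#' Describes a pair of homologous single-contig genomes: the human sequence is
#' drawn at random and acts as the ancestor; the mouse homolog is derived from
#' it by i.i.d. substitutions at rate `divergence` outside ssPAL loci. Inside
#' each locus the flanking primer sites are kept identical between the species
#' and a single internal indel shifts the mouse amplicon to its configured
#' length, so orthologous amplicons differ in length exactly as the real loci
#' do.
#'
#' @param length Genome length in bases.
#' @param divergence Per-base substitution rate in `[0, 1)` between the
#'   species outside ssPAL loci. Human/mouse genome-wide divergence is on the
#'   order of 10% in alignable regions, which is the default.
#' @param loci List of locus placements, each a list with elements `locus`
#'   (an [sspal_locus()]) and `offset` (0-based start of the human amplicon).
#' @param seed Integer seed; required, all randomness is local to the call.
#' @return An object of class `genome_pair_config`.
#' @export
genome_pair_config <- function(length, divergence = 0.10, loci = list(), seed) {
  length <- as.integer(length)
  stopifnot(length > 0L, is.numeric(divergence))
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  if (missing(seed)) stop("seed is required")
  if (base::length(loci) > 0L) {
    off <- vapply(loci, function(p) as.integer(p$offset), integer(1))
    len <- vapply(loci, function(p) p$locus$human_len, integer(1))
    if (any(off < 0L) || any(off + len > length))
      stop("every locus must lie fully inside [0, length)")
    o <- order(off)
    off <- off[o]; len <- len[o]
    if (base::length(off) > 1L && any(off[-1] < (off + len)[-base::length(off)]))
      stop("loci must not overlap")
    loci <- loci[o]
  }
  structure(list(length = length, divergence = divergence, loci = loci,
                 seed = as.integer(seed)),
            class = "genome_pair_config")
}

# Mouse version of one human amplicon: primer sites untouched, one internal
# indel shifting the length from human_len to mouse_len.
.mouse_amplicon <- function(amp_bases, locus) {
  pf <- if (!is.null(locus$forward_primer)) nchar(locus$forward_primer) else 20L
  pr <- if (!is.null(locus$reverse_primer)) nchar(locus$reverse_primer) else 20L
  delta <- locus$mouse_len - locus$human_len
  interior <- amp_bases[(pf + 1L):(length(amp_bases) - pr)]
  if (length(interior) <= abs(delta) + 2L)
    stop("amplicon interior too short to carry the configured indel")
  mid <- length(interior) %/% 2L
  interior <-
    if (delta > 0L) {
      append(interior, sample(DNA_BASES, delta, replace = TRUE), after = mid)
    } else {
      interior[-((mid + 1L):(mid - delta))]
    }
  c(amp_bases[seq_len(pf)], interior,
    amp_bases[(length(amp_bases) - pr + 1L):length(amp_bases)])
}

.substitute_bases <- function(bases, rate) {
  if (rate == 0 || length(bases) == 0L) return(bases)
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    cur <- match(bases[hit], DNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    bases[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  bases
}

#' Generate a homologous human/mouse genome pair
#'
#' Draws a random human contig, then derives its mouse homolog: i.i.d.
#' substitutions at the configured divergence outside ssPAL loci, and inside
#' each locus an unchanged pair of primer sites around a single internal indel
#' that sets the mouse amplicon length. If a locus carries primer sequences
#' they are stamped at the amplicon ends of the human contig (forward primer
#' at the start, reverse complement of the reverse primer at the end) so both
#' amplicons are amplifiable by the same primer pair.
#'
#' @param config A [genome_pair_config()].
#' @param contig_prefix Base name for the contigs (suffixed `_human` /
#'   `_mouse`).
#' @return A list with elements `human` and `mouse` (each a
#'   [species_genome()]) and `loci`, a data frame mapping each locus to its
#'   amplicon interval (0-based start, exclusive end) on both contigs.
#' @export
#' @examples
#' cfg <- genome_pair_config(5000, divergence = 0.1,
#'                           loci = list(list(locus = sspal_pair43(), offset = 1000)),
#'                           seed = 7)
#' pair <- make_genome_pair(cfg)
#' pair$loci
make_genome_pair <- function(config, contig_prefix = "syn1") {
  stopifnot(inherits(config, "genome_pair_config"))
  with_seed(config$seed, {
    human <- sample(DNA_BASES, config$length, replace = TRUE)
    # stamp primer sequences at amplicon ends where known
    for (p in config$loci) {
      loc <- p$locus
      if (is.null(loc$forward_primer) || is.null(loc$reverse_primer)) next
      fwd <- strsplit(loc$forward_primer, "")[[1]]
      rev <- strsplit(revcomp(loc$reverse_primer), "")[[1]]
      human[p$offset + seq_along(fwd)] <- fwd
      human[p$offset + loc$human_len - length(rev) + seq_along(rev)] <- rev
    }
    mouse <- character(0)
    loci_map <- list()
    prev <- 0L
    for (p in config$loci) {
      loc <- p$locus
      off <- as.integer(p$offset)
      if (off > prev) {
        mouse <- c(mouse,
                   .substitute_bases(human[(prev + 1L):off], config$divergence))
      }
      amp <- human[(off + 1L):(off + loc$human_len)]
      m_amp <- .mouse_amplicon(amp, loc)
      loci_map[[length(loci_map) + 1L]] <- data.frame(
        pair_id = loc$pair_id,
        human_start = off, human_end = off + loc$human_len,
        mouse_start = length(mouse), mouse_end = length(mouse) + length(m_amp),
        stringsAsFactors = FALSE
      )
      mouse <- c(mouse, m_amp)
      prev <- off + loc$human_len
    }
    if (prev < config$length) {
      mouse <- c(mouse, .substitute_bases(human[(prev + 1L):config$length],
                                          config$divergence))
    }
    list(
      human = species_genome(
        setNames(paste(human, collapse = ""), paste0(contig_prefix, "_human")),
        "human"),
      mouse = species_genome(
        setNames(paste(mouse, collapse = ""), paste0(contig_prefix, "_mouse")),
        "mouse"),
      loci = if (length(loci_map)) do.call(rbind, loci_map) else
        data.frame(pair_id = character(0), human_start = integer(0),
                   human_end = integer(0), mouse_start = integer(0),
                   mouse_end = integer(0))
    )
  })
}

#' Read and write species-tagged genomes as FASTA
#'
#' The species of each contig is encoded as a `|human` / `|mouse` suffix on
#' the FASTA header, so a concatenated hybrid reference file remains
#' self-describing.
#'
#' @param genome A [species_genome()].
#' @param path File path.
#' @return `read_genome_fasta()` returns a [species_genome()];
#'   `write_genome_fasta()` returns `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "species_genome"))
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- paste0(genome$name, "|", genome$species)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- strsplit(names(x), "|", fixed = TRUE)
  if (any(lengths(hdr) != 2L))
    stop("FASTA headers must be of the form 'name|human' or 'name|mouse'")
  species_genome(
    setNames(as.character(x), vapply(hdr, `[`, "", 1L)),
    vapply(hdr, `[`, "", 2L)
  )
}

# concatenate two species_genomes (used to build hybrid references)
.bind_genomes <- function(a, b) {
  species_genome(
    setNames(c(a$sequence, b$sequence), c(a$name, b$name)),
    c(a$species, b$species)
  )
}
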