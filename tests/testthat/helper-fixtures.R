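# Shared fixture builders; everything is generated in code at test time.

# Pileup object from explicit per-position counts.
make_pileup <- function(contig, pos, A = 0L, C = 0L, G = 0L, T = 0L) {
  d <- data.frame(pos = as.integer(pos), A = A, C = C, G = G, T = T)
  d$depth <- d$A + d$C + d$G + d$T
  attr(d, "contig") <- contig
  class(d) <- c("pileup", "data.frame")
  d
}

# Single-contig human genome from a literal sequence.
manual_genome <- function(seq, name = "chrT_human", species = "human") {
  species_genome(setNames(seq, name), species)
}

# A small diverged human/mouse pair reused across alignment tests.
small_pair <- function(length = 20000, divergence = 0.10, seed = 7,
                       loci = list()) {
  make_genome_pair(genome_pair_config(length, divergence, loci, seed = seed))
}

# Reads that tile a contig end to end, one read per read_len window.
tiling_reads <- function(genome, read_len) {
  L <- nchar(genome$sequence[1])
  starts <- seq(0L, L - read_len, by = read_len)
  read_set(sprintf("t%04d", seq_along(starts)),
           substring(genome$sequence[1], starts + 1L, starts + read_len),
           genome$species[1], genome$name[1], starts, "+")
}
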