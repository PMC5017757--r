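#' Draw a somatic mutation truth set
#'
#' Samples `n` distinct positions uniformly over the human contigs of a
#' genome, assigns each an alternate allele drawn uniformly from the three
#' non-reference bases, and attaches a variant allele frequency (VAF) by
#' cycling through `vafs` in order — `n` divisible by `length(vafs)` gives an
#' exactly balanced design across VAF levels.
#'
#' @param genome A [species_genome()] with at least one human contig.
#' @param n Number of mutations; must not exceed the number of eligible
#'   (human) positions.
#' @param vafs Variant allele frequencies in `(0, 1]`, cycled over the
#'   sampled positions.
#' @param seed Integer seed.
#' @return A data frame of class `mutation_set` with columns `contig`,
#'   `pos` (0-based), `ref`, `alt`, `vaf`, sorted by contig and position.
#' @export
spike_mutation_set <- function(genome, n, vafs = c(0.05, 0.1, 0.2, 0.5), seed) {
  stopifnot(inherits(genome, "species_genome"))
  n <- as.integer(n)
  if (missing(seed)) stop("seed is required")
  if (any(vafs <= 0 | vafs > 1)) stop("VAFs must lie in (0, 1]")
  hu <- which(genome$species == "human")
  if (!length(hu)) stop("genome has no human contigs to mutate")
  lens <- nchar(genome$sequence[hu])
  total <- sum(lens)
  if (n > total) stop("n exceeds the number of eligible positions")
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vaf = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    class(empty) <- c("mutation_set", "data.frame")
    return(empty)
  }
  with_seed(seed, {
    g <- sort(sample.int(total, n)) - 1L
    ci <- findInterval(g, cumsum(c(0, lens)), rightmost.closed = FALSE)
    pos <- g - c(0L, cumsum(lens))[ci]
    contig <- genome$name[hu][ci]
    ref <- substring(genome$sequence[hu][ci], pos + 1L, pos + 1L)
    shift <- sample.int(3L, n, replace = TRUE)
    alt <- DNA_BASES[((match(ref, DNA_BASES) - 1L + shift) %% 4L) + 1L]
    out <- data.frame(contig = contig, pos = as.integer(pos), ref = ref,
                      alt = alt, vaf = vafs[((seq_len(n) - 1L) %% length(vafs)) + 1L],
                      stringsAsFactors = FALSE)
    out <- out[order(out$contig, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("mutation_set", "data.frame")
    out
  })
}

#' Read and write mutation truth sets as minimal VCF
#'
#' Truth sets and somatic calls travel as minimal VCF v4.2: CHROM, 1-based
#' POS, ID ".", REF, ALT, QUAL ".", FILTER "PASS", and an INFO field carrying
#' `VAF=` (truth sets) or `DP=;AD=;P=` (calls).
#'
#' @param muts A `mutation_set` data frame.
#' @param path File path.
#' @return `read_mutations_vcf()` returns a `mutation_set` data frame.
#' @export
write_mutations_vcf <- function(muts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Spiked variant allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(muts))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF=%g",
                       muts$contig, muts$pos + 1L, muts$ref, muts$alt,
                       muts$vaf), con)
  invisible(path)
}

#' @rdname write_mutations_vcf
#' @export
read_mutations_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0), vaf = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    vaf <- suppressWarnings(as.numeric(sub("^.*VAF=([0-9.eE+-]+).*$", "\\1",
                                           f[, 8])))
    out <- data.frame(contig = f[, 1], pos = as.integer(f[, 2]) - 1L,
                      ref = f[, 4], alt = f[, 5], vaf = vaf,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("mutation_set", "data.frame")
  out
}
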