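#' Virtual sample container
#'
#' Bundles a read set with the provenance of its construction. Three labels
#' are used: `virtual_normal` (unmutated reads), `virtual_tumor` (reads with
#' spiked somatic mutations) and `virtual_xenograft` (tumor reads partially
#' replaced by mouse reads at contamination level lambda).
#'
#' @param label One of `"virtual_normal"`, `"virtual_tumor"`,
#'   `"virtual_xenograft"`.
#' @param reads A [read_set()].
#' @param provenance Named list (depths, lambda, mutation-set id, seeds...).
#'   A `virtual_xenograft` must record `lambda`.
#' @return An object of class `virtual_sample`.
#' @export
virtual_sample <- function(label, reads, provenance = list()) {
  label <- match.arg(label,
                     c("virtual_normal", "virtual_tumor", "virtual_xenograft"))
  stopifnot(inherits(reads, "read_set"), is.list(provenance))
  if (label == "virtual_xenograft" && is.null(provenance$lambda))
    stop("a virtual_xenograft must record its contamination level lambda")
  structure(list(label = label, reads = reads, provenance = provenance),
            class = "virtual_sample")
}

#' @export
print.virtual_sample <- function(x, ...) {
  cat(sprintf("%s: %d reads", x$label, nrow(x$reads)))
  if (!is.null(x$provenance$lambda))
    cat(sprintf(", lambda = %g", x$provenance$lambda))
  cat("\n")
  invisible(x)
}

#' Downsample a read set to a target depth
#'
#' Each read is independently retained with probability
#' `target_depth / current_depth`.
#'
#' @param reads A [read_set()].
#' @param current_depth,target_depth Fold-coverages; `target_depth` must not
#'   exceed `current_depth`.
#' @param seed Integer seed.
#' @return The downsampled [read_set()].
#' @export
downsample_reads <- function(reads, current_depth, target_depth, seed) {
  stopifnot(inherits(reads, "read_set"), current_depth > 0, target_depth >= 0)
  if (target_depth > current_depth)
    stop("target_depth must not exceed current_depth")
  if (missing(seed)) stop("seed is required")
  p <- target_depth / current_depth
  with_seed(seed, {
    keep <- runif(nrow(reads)) < p
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Spike somatic mutations into reads
#'
#' For each mutation, every read whose truth interval covers the mutated
#' position has that base switched to the alternate allele independently with
#' probability `vaf` (minus-strand reads receive the complement at the
#' mirrored read position). All other bases are untouched, so the expected
#' alternate-allele fraction in a downstream pileup equals the spiked VAF.
#'
#' @param reads A [read_set()] with truth placements on the mutated genome.
#' @param mutations A [spike_mutation_set()] data frame.
#' @param seed Integer seed.
#' @return The mutated [read_set()].
#' @export
spike_reads <- function(reads, mutations, seed) {
  stopifnot(inherits(reads, "read_set"), inherits(mutations, "mutation_set"))
  if (missing(seed)) stop("seed is required")
  if (!nrow(reads) || !nrow(mutations)) return(reads)
  read_len <- nchar(reads$sequence[1])
  seqs <- reads$sequence
  with_seed(seed, {
    for (mi in seq_len(nrow(mutations))) {
      m <- mutations[mi, ]
      if (!any(reads$truth_contig == m$contig)) {
        warning(sprintf("mutation at %s:%d skipped: contig absent from reads",
                        m$contig, m$pos + 1L))
        next
      }
      cover <- which(reads$truth_contig == m$contig &
                       reads$truth_pos <= m$pos &
                       m$pos < reads$truth_pos + read_len)
      if (!length(cover)) next
      flip <- cover[runif(length(cover)) < m$vaf]
      for (i in flip) {
        off <- m$pos - reads$truth_pos[i]  # 0-based offset on the genome
        if (reads$truth_strand[i] == "+") {
          substring(seqs[i], off + 1L, off + 1L) <- m$alt
        } else {
          j <- read_len - off
          substring(seqs[i], j, j) <- complement_base(m$alt)
        }
      }
    }
    out <- reads
    out$sequence <- seqs
    out
  })
}

#' Contaminate a tumor read set with mouse reads
#'
#' Each human tumor read is independently replaced, with probability `lam`,
#' by a mouse read drawn without replacement from the supplied pool. The
#' total read count is preserved exactly, so increasing contamination
#' manifests downstream as loss of human depth of coverage — mouse reads are
#' subsequently discarded by hybrid-reference alignment.
#'
#' @param tumor_reads A [read_set()] (the virtual tumor).
#' @param mouse_reads A [read_set()] pool of mouse reads; must be large
#'   enough to supply the replacements.
#' @param lam Contamination level lambda in `[0, 1]`.
#' @param seed Integer seed.
#' @param provenance Extra provenance entries to record.
#' @return A [virtual_sample()] labelled `virtual_xenograft`.
#' @export
contaminate <- function(tumor_reads, mouse_reads, lam, seed,
                        provenance = list()) {
  stopifnot(inherits(tumor_reads, "read_set"), inherits(mouse_reads, "read_set"))
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1)
    stop("lam must be a single value in [0, 1]")
  if (missing(seed)) stop("seed is required")
  n <- nrow(tumor_reads)
  with_seed(seed, {
    replace_mask <- runif(n) < lam
    m <- sum(replace_mask)
    if (m > nrow(mouse_reads))
      stop(sprintf("mouse read pool exhausted: need %d reads, have %d",
                   m, nrow(mouse_reads)))
    out <- tumor_reads
    if (m > 0) {
      take <- sample.int(nrow(mouse_reads), m)
      out[replace_mask, ] <- mouse_reads[take, ]
    }
    rownames(out) <- NULL
    class(out) <- c("read_set", "data.frame")
    virtual_sample("virtual_xenograft", out,
                   c(list(lambda = lam, seed = as.integer(seed),
                          n_replaced = m), provenance))
  })
}
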