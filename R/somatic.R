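#' Pile up aligned reads into per-base base counts
#'
#' Counts A/C/G/T occurrences at every reference position covered by the
#' supplied alignments (minus-strand reads are reverse-complemented into
#' reference orientation first). Positions with zero depth are omitted.
#'
#' @param alignments An `alignment_set`, typically the unique human records
#'   from [exclude_mouse()].
#' @param reads The [read_set()] the alignments were computed from; every
#'   aligned `read_id` must be present.
#' @param ref The [build_reference()] object.
#' @param contig Contig to pile up.
#' @return A data frame of class `pileup` with columns `pos` (0-based),
#'   `A`, `C`, `G`, `T`, `depth`, and attribute `contig`.
#' @export
pileup_reads <- function(alignments, reads, ref, contig) {
  stopifnot(inherits(alignments, "alignment_set"), inherits(reads, "read_set"),
            inherits(ref, "hybrid_reference"))
  ci <- match(contig, ref$genome$name)
  if (is.na(ci)) stop(sprintf("unknown contig '%s'", contig))
  a <- alignments[!is.na(alignments$contig) & alignments$contig == contig, ]
  ix <- match(a$read_id, reads$id)
  if (anyNA(ix)) stop("alignment read_id(s) missing from the read set")
  seqs <- reads$sequence[ix]
  neg <- a$strand == "-"
  if (any(neg)) seqs[neg] <- .revcomp_batch(seqs[neg])
  L <- nchar(ref$genome$sequence[ci])
  counts <- cpp_pileup(L, as.integer(a$pos), seqs)
  depth <- colSums(counts)
  covered <- which(depth > 0L)
  out <- data.frame(pos = covered - 1L,
                    A = counts[1, covered], C = counts[2, covered],
                    G = counts[3, covered], T = counts[4, covered],
                    depth = depth[covered])
  attr(out, "contig") <- contig
  class(out) <- c("pileup", "data.frame")
  out
}

#' Call somatic variants from tumor and matched normal pileups
#'
#' A transparent binomial tumor-versus-normal caller. At each tumor site the
#' alternate allele is the most frequent non-reference base; the site is
#' called iff (i) tumor depth >= `min_tumor_depth`, (ii) alternate count >=
#' `min_alt`, (iii) the binomial upper tail `P(X >= alt_count | depth,
#' error_rate / 3)` is below `alpha` (the per-specific-allele error rate is a
#' third of the per-base rate), and (iv) the matched normal carries an
#' alternate fraction of at most `normal_max_alt_frac` at the site (germline
#' and shared-artifact exclusion; a site absent from the normal pileup counts
#' as alternate-free).
#'
#' @param tumor,normal [pileup_reads()] data frames on the same contig of the
#'   same reference.
#' @param ref The [build_reference()] object (source of reference bases).
#' @param params Caller parameters: `min_tumor_depth` (10), `min_alt` (3),
#'   `error_rate` (0.01, must be in (0,1)), `alpha` (1e-3),
#'   `normal_max_alt_frac` (0.03).
#' @return A data frame of class `variant_calls` with columns `contig`,
#'   `pos` (0-based), `ref`, `alt`, `depth`, `alt_count`, `p_value`.
#' @export
call_somatic <- function(tumor, normal, ref,
                         params = list()) {
  stopifnot(inherits(tumor, "pileup"), inherits(normal, "pileup"),
            inherits(ref, "hybrid_reference"))
  contig <- attr(tumor, "contig")
  if (!identical(contig, attr(normal, "contig")))
    stop("tumor and normal pileups must be on the same contig")
  p <- modifyList(list(min_tumor_depth = 10L, min_alt = 3L, error_rate = 0.01,
                       alpha = 1e-3, normal_max_alt_frac = 0.03), params)
  if (p$error_rate <= 0 || p$error_rate >= 1)
    stop("error_rate must lie strictly inside (0, 1)")
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("variant_calls", "data.frame")
  if (!nrow(tumor)) return(empty)
  ci <- match(contig, ref$genome$name)
  refbase <- substring(ref$genome$sequence[ci], tumor$pos + 1L, tumor$pos + 1L)
  ref_idx <- match(refbase, DNA_BASES)
  m <- as.matrix(tumor[, DNA_BASES])
  m[cbind(seq_len(nrow(m)), ref_idx)] <- -1L
  alt_idx <- max.col(m, ties.method = "first")
  alt_count <- m[cbind(seq_len(nrow(m)), alt_idx)]
  p_value <- pbinom(alt_count - 1L, tumor$depth, p$error_rate / 3,
                    lower.tail = FALSE)
  ni <- match(tumor$pos, normal$pos)
  n_alt <- ifelse(is.na(ni), 0L,
                  as.matrix(normal[, DNA_BASES])[cbind(ni, alt_idx)])
  n_depth <- ifelse(is.na(ni), 0L, normal$depth[ni])
  n_frac <- ifelse(n_depth > 0, n_alt / n_depth, 0)
  called <- tumor$depth >= p$min_tumor_depth & alt_count >= p$min_alt &
    p_value < p$alpha & n_frac <= p$normal_max_alt_frac
  out <- data.frame(contig = rep(contig, sum(called)), pos = tumor$pos[called],
                    ref = refbase[called], alt = DNA_BASES[alt_idx[called]],
                    depth = tumor$depth[called],
                    alt_count = as.integer(alt_count[called]),
                    p_value = p_value[called], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Write somatic calls as minimal VCF
#'
#' @param calls A [call_somatic()] result.
#' @param path File path.
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Tumor depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Tumor alternate count\">",
    "##INFO=<ID=P,Number=1,Type=Float,Description=\"Binomial tail probability\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d;P=%g",
                       calls$contig, calls$pos + 1L, calls$ref, calls$alt,
                       calls$depth, calls$alt_count, calls$p_value), con)
  invisible(path)
}

.bin_label <- function(breaks) {
  sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1])
}

.metrics <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) { if (fn == 0) 1 else 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Score somatic calls against a known truth set
#'
#' A call is a true positive when its (contig, position, alternate allele)
#' triple matches a truth entry, otherwise a false positive; truth entries
#' never called are false negatives. True positives and false negatives are
#' binned by the truth VAF, false positives by their observed alternate
#' fraction. Metrics follow the 0/0 conventions: precision is 1 when nothing
#' was called and nothing was missed (0 when calls exist but none are true),
#' recall is 1 on an empty truth set, and F1 is 0 when both are 0.
#'
#' @param calls A [call_somatic()] result.
#' @param truth A [spike_mutation_set()] truth set.
#' @param vaf_bins Increasing break points partitioning `(0, 1]` into
#'   half-open bins `(b[i], b[i+1]]`; default `c(0, 0.1, 0.2, 0.33, 1)`.
#' @param lam Optional contamination level annotated on every row.
#' @return A data frame of class `eval_points`: one row per VAF bin plus an
#'   `overall` row, with columns `lam`, `vaf_bin`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_calls <- function(calls, truth, vaf_bins = c(0, 0.1, 0.2, 0.33, 1),
                           lam = NA_real_) {
  stopifnot(is.data.frame(calls), is.data.frame(truth))
  if (length(vaf_bins) < 2 || any(diff(vaf_bins) <= 0) ||
      vaf_bins[1] != 0 || vaf_bins[length(vaf_bins)] != 1)
    stop("vaf_bins must be increasing breaks from 0 to 1 (non-overlapping bins)")
  key <- function(d) paste(d$contig, d$pos, d$alt, sep = ":")
  call_key <- key(calls)
  truth_key <- key(truth)
  is_tp <- call_key %in% truth_key
  truth_called <- truth_key %in% call_key
  labels <- .bin_label(vaf_bins)
  bin_of <- function(v) labels[findInterval(v, vaf_bins, left.open = TRUE,
                                            rightmost.closed = TRUE)]
  tp_bin <- bin_of(truth$vaf[match(call_key[is_tp], truth_key)])
  fn_bin <- bin_of(truth$vaf[!truth_called])
  fp_bin <- bin_of(pmin(1, calls$alt_count[!is_tp] / calls$depth[!is_tp]))
  rows <- lapply(labels, function(b) {
    tp <- sum(tp_bin == b); fp <- sum(fp_bin == b); fn <- sum(fn_bin == b)
    mt <- .metrics(tp, fp, fn)
    data.frame(lam = lam, vaf_bin = b, tp = tp, fp = fp, fn = fn,
               precision = mt[["precision"]], recall = mt[["recall"]],
               f1 = mt[["f1"]], stringsAsFactors = FALSE)
  })
  tp <- sum(is_tp); fp <- sum(!is_tp); fn <- sum(!truth_called)
  mt <- .metrics(tp, fp, fn)
  rows[[length(rows) + 1L]] <-
    data.frame(lam = lam, vaf_bin = "overall", tp = tp, fp = fp, fn = fn,
               precision = mt[["precision"]], recall = mt[["recall"]],
               f1 = mt[["f1"]], stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("eval_points", "data.frame")
  out
}

#' Sweep mouse-read contamination levels through the virtual-PDX pipeline
#'
#' End-to-end benchmark of the effect of mouse stromal admixture on somatic
#' mutation calling. One synthetic human/mouse genome pair is drawn; a
#' virtual normal (30x) and an independently simulated virtual tumor (60x,
#' with spiked mutations at known VAFs) are built; for each contamination
#' level lambda, tumor reads are randomly replaced by mouse reads, the
#' xenograft is aligned to the concatenated hybrid reference, mouse-assigned
#' and ambiguous reads are dropped, and mutations are called against the
#' matched virtual normal and scored against the truth set per VAF bin.
#'
#' Per-lambda child seeds are derived from the master seed with
#' [derive_seed()], so any single lambda can be re-run in isolation.
#'
#' @param lambdas Contamination levels in `[0, 1]` (non-empty).
#' @param seed Master seed.
#' @param genome_length Human contig length in bases.
#' @param divergence Human/mouse per-base divergence.
#' @param n_mutations Number of spiked somatic mutations.
#' @param vafs Spiked VAF levels (cycled over mutations).
#' @param normal_depth,tumor_depth Mean fold-coverage of the virtual normal
#'   and tumor.
#' @param read_len Read length in bases.
#' @param error_rate Per-base sequencing error rate of the simulated reads.
#' @param k Aligner seed k-mer length.
#' @param caller_params Parameter overrides for [call_somatic()].
#' @param vaf_bins Breaks for [evaluate_calls()].
#' @return An object of class `contamination_sweep`: list with `eval` (tidy
#'   per-(lambda, bin) metric table), `coverage` (per-lambda mean DoC and
#'   `frac_ge` summaries on the human contig), `truth`, and the generation
#'   parameters.
#' @export
contamination_sweep <- function(lambdas, seed,
                                genome_length = 60000L, divergence = 0.10,
                                n_mutations = 40L,
                                vafs = c(0.05, 0.1, 0.2, 0.5),
                                normal_depth = 30, tumor_depth = 60,
                                read_len = 100L, error_rate = 0.001,
                                k = 15L, caller_params = list(),
                                vaf_bins = c(0, 0.1, 0.2, 0.33, 1)) {
  if (!length(lambdas)) stop("lambdas must be non-empty")
  if (any(lambdas < 0 | lambdas > 1)) stop("every lambda must lie in [0, 1]")
  if (missing(seed)) stop("seed is required")
  pair <- make_genome_pair(genome_pair_config(genome_length, divergence,
                                              seed = derive_seed(seed, 1L)))
  human <- pair$human; mouse <- pair$mouse
  hcontig <- human$name[1]
  ref <- build_reference(human, mouse, k = k)
  truth <- spike_mutation_set(human, n_mutations, vafs,
                              seed = derive_seed(seed, 2L))
  normal_reads <- simulate_reads(human, normal_depth, read_len, error_rate,
                                 seed = derive_seed(seed, 3L))
  tumor_reads <- simulate_reads(human, tumor_depth, read_len, error_rate,
                                seed = derive_seed(seed, 4L))
  tumor_reads <- spike_reads(tumor_reads, truth, seed = derive_seed(seed, 5L))
  mouse_pool <- simulate_reads(mouse, 1.2 * tumor_depth, read_len, error_rate,
                               seed = derive_seed(seed, 6L))
  normal_aln <- exclude_mouse(align_reads(normal_reads, ref), ref)
  normal_pile <- pileup_reads(normal_aln, normal_reads, ref, hcontig)
  evals <- list(); covs <- list()
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    vx <- contaminate(tumor_reads, mouse_pool, lam,
                      seed = derive_seed(seed, 100L + li))
    aln <- exclude_mouse(align_reads(vx$reads, ref), ref)
    cov <- coverage(aln, ref, hcontig, read_len)
    pile <- pileup_reads(aln, vx$reads, ref, hcontig)
    calls <- call_somatic(pile, normal_pile, ref, caller_params)
    evals[[li]] <- evaluate_calls(calls, truth, vaf_bins, lam = lam)
    covs[[li]] <- data.frame(lam = lam, mean_doc = cov$mean_doc,
                             frac_ge15 = cov$frac_ge[["15"]])
  }
  structure(list(eval = do.call(rbind, evals),
                 coverage = do.call(rbind, covs),
                 truth = truth,
                 params = list(lambdas = lambdas, seed = seed,
                               genome_length = genome_length,
                               divergence = divergence,
                               n_mutations = n_mutations, vafs = vafs,
                               normal_depth = normal_depth,
                               tumor_depth = tumor_depth,
                               read_len = read_len, error_rate = error_rate,
                               k = k)),
            class = "contamination_sweep")
}

#' @export
print.contamination_sweep <- function(x, ...) {
  cat(sprintf("contamination_sweep: %d lambda level(s), %d mutations\n",
              length(x$params$lambdas), nrow(x$truth)))
  ov <- x$eval[x$eval$vaf_bin == "overall", ]
  print.data.frame(ov[, c("lam", "tp", "fp", "fn", "precision", "recall", "f1")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot F1 against contamination level per VAF bin
#'
#' @param x A [contamination_sweep()] result.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.contamination_sweep <- function(x, ...) {
  e <- x$eval[x$eval$vaf_bin != "overall", ]
  bins <- unique(e$vaf_bin)
  lams <- sort(unique(e$lam))
  m <- sapply(bins, function(b) e$f1[e$vaf_bin == b][order(e$lam[e$vaf_bin == b])])
  graphics::matplot(lams, m, type = "b", pch = 19, lty = 1,
                    xlab = expression(lambda ~ "(mouse contamination)"),
                    ylab = "F1", ylim = c(0, 1), ...)
  graphics::legend("bottomleft", legend = paste("VAF", bins), col = seq_along(bins),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}

#' Write an evaluation table as tidy TSV
#'
#' @param evals An `eval_points` data frame (or the `eval` element of a
#'   sweep).
#' @param path File path.
#' @export
write_eval_tsv <- function(evals, path) {
  write.table(evals, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
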