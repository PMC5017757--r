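#' Build an indexed (hybrid) alignment reference
#'
#' Concatenates the contigs of one or two species into a single reference and
#' builds a full k-mer index over it: every forward-strand k-mer position of
#' every contig is recorded, and reads are queried in both orientations at
#' alignment time. Aligning xenograft-derived reads against such a hybrid
#' human/mouse reference lets each read go to its best-matching species, which
#' is the basis for excluding mouse reads before mutation calling.
#'
#' @param human A [species_genome()] (any species mix is accepted; named for
#'   the common case).
#' @param mouse Optional second [species_genome()]; `NULL` builds a
#'   single-species reference.
#' @param k Seed k-mer length, in `[11, 31]`.
#' @return An object of class `hybrid_reference` holding the combined genome,
#'   `k`, and the compiled k-mer index.
#' @export
build_reference <- function(human, mouse = NULL, k = 15L) {
  stopifnot(inherits(human, "species_genome"))
  genome <- if (is.null(mouse)) human else .bind_genomes(human, mouse)
  k <- as.integer(k)
  ptr <- cpp_build_index(genome$sequence, k)
  structure(list(genome = genome, k = k, ptr = ptr),
            class = "hybrid_reference")
}

#' @export
print.hybrid_reference <- function(x, ...) {
  np <- cpp_index_positions(x$ptr)
  cat(sprintf("hybrid_reference: k = %d, %d contig(s)\n", x$k,
              length(x$genome$name)))
  for (i in seq_along(x$genome$name))
    cat(sprintf("  %s [%s] %d bp, %d indexed k-mer positions\n",
                x$genome$name[i], x$genome$species[i],
                nchar(x$genome$sequence[i]), np[i]))
  invisible(x)
}

#' Number of indexed k-mer positions per contig
#'
#' For a contig of length `L` this is `L - k + 1` (forward-strand positions).
#'
#' @param ref A [build_reference()] object.
#' @return Named integer vector.
#' @export
ref_index_positions <- function(ref) {
  stopifnot(inherits(ref, "hybrid_reference"))
  setNames(cpp_index_positions(ref$ptr), ref$genome$name)
}

#' Align reads to a reference by seed and extend
#'
#' Candidate placements come from exact k-mer seed matches at three fixed
#' read offsets (start, middle, end) in both orientations; each candidate is
#' scored by ungapped full-length comparison (score = matches - mismatches).
#' A read is `unique` when exactly one placement attains the best score,
#' `ambiguous` when several tie (typically reads from regions still identical
#' between the species), and `unmapped` when no candidate is found or the
#' best placement exceeds `max_mismatch` mismatches.
#'
#' @param reads A [read_set()].
#' @param ref A [build_reference()] object.
#' @param max_mismatch Maximum mismatches for a placement to count as mapped;
#'   default 10% of the read length.
#' @return A data frame of class `alignment_set` with columns `read_id`,
#'   `contig`, `pos` (0-based), `strand`, `score`, `n_best`, `status`.
#' @export
align_reads <- function(reads, ref, max_mismatch = NULL) {
  stopifnot(inherits(reads, "read_set"), inherits(ref, "hybrid_reference"))
  if (!nrow(reads)) {
    out <- data.frame(read_id = character(0), contig = character(0),
                      pos = integer(0), strand = character(0),
                      score = integer(0), n_best = integer(0),
                      status = character(0), stringsAsFactors = FALSE)
    class(out) <- c("alignment_set", "data.frame")
    return(out)
  }
  read_len <- nchar(reads$sequence[1])
  if (read_len < ref$k) stop("read length must be >= the index k")
  if (is.null(max_mismatch)) max_mismatch <- floor(0.1 * read_len)
  r <- cpp_align_reads(ref$ptr, reads$sequence, as.integer(max_mismatch))
  out <- data.frame(
    read_id = reads$id,
    contig = ifelse(is.na(r$contig_idx), NA_character_,
                    ref$genome$name[r$contig_idx]),
    pos = r$pos,
    strand = ifelse(is.na(r$strand), NA_character_,
                    c("+", "-")[r$strand + 1L]),
    score = r$score,
    n_best = r$n_best,
    status = c("unique", "ambiguous", "unmapped")[r$status + 1L],
    stringsAsFactors = FALSE
  )
  attr(out, "read_len") <- read_len
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Drop mouse-assigned and ambiguous alignments
#'
#' Records placed on mouse contigs are removed, as are ambiguous
#' (multi-mapping) records — a read tying between species carries no reliable
#' species assignment — and unmapped records. What remains is the unique
#' human-contig alignment set used for coverage and mutation calling.
#'
#' @param alignments An [align_reads()] result against a hybrid reference.
#' @param ref The [build_reference()] object the alignments were made
#'   against.
#' @return The filtered `alignment_set`.
#' @export
exclude_mouse <- function(alignments, ref) {
  stopifnot(inherits(alignments, "alignment_set"),
            inherits(ref, "hybrid_reference"))
  sp <- setNames(ref$genome$species, ref$genome$name)
  keep <- alignments$status == "unique" &
    !is.na(alignments$contig) & sp[alignments$contig] == "human"
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "read_len") <- attr(alignments, "read_len")
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Per-base depth of coverage on one contig
#'
#' @param alignments An `alignment_set` (typically unique human records from
#'   [exclude_mouse()]).
#' @param ref The reference the alignments were made against.
#' @param contig Contig name; must exist in the reference.
#' @param read_len Read length; defaults to the length recorded on the
#'   alignment set.
#' @param thresholds Depth thresholds at which to report the fraction of
#'   bases covered at least that deeply; always includes 15.
#' @return An object of class `coverage_profile`: list with `contig`,
#'   `depth` (integer per-base array), `mean_doc` and `frac_ge` (named
#'   fractions).
#' @export
coverage <- function(alignments, ref, contig, read_len = NULL,
                     thresholds = c(1, 15, 30)) {
  stopifnot(inherits(alignments, "alignment_set"),
            inherits(ref, "hybrid_reference"))
  ci <- match(contig, ref$genome$name)
  if (is.na(ci)) stop(sprintf("unknown contig '%s'", contig))
  if (is.null(read_len)) read_len <- attr(alignments, "read_len")
  if (is.null(read_len)) stop("read_len is required")
  L <- nchar(ref$genome$sequence[ci])
  a <- alignments[!is.na(alignments$contig) & alignments$contig == contig, ]
  starts <- a$pos + 1L                       # 1-based
  ends <- pmin(a$pos + read_len, L) + 1L     # exclusive, clipped at L + 1
  delta <- tabulate(starts, nbins = L)
  ends_in <- ends[ends <= L]
  delta <- delta - tabulate(ends_in, nbins = L)
  depth <- cumsum(delta)
  thresholds <- sort(unique(c(thresholds, 15)))
  frac_ge <- vapply(thresholds, function(t) mean(depth >= t), numeric(1))
  structure(list(contig = contig, depth = as.integer(depth),
                 mean_doc = sum(as.numeric(depth)) / L,
                 frac_ge = setNames(frac_ge, thresholds)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile [%s]: mean DoC %.2f\n", x$contig, x$mean_doc))
  for (t in names(x$frac_ge))
    cat(sprintf("  fraction of bases at depth >= %s: %.4f\n", t,
                x$frac_ge[[t]]))
  invisible(x)
}

#' Write alignments and coverage to disk
#'
#' Alignments go to a minimal TSV (`read_id`, `contig`, `pos1based`,
#' `strand`, `score`, `n_best`, `status`); coverage to a two-column TSV
#' (`pos`, `depth`, 1-based) plus a JSON summary of `mean_doc` and `frac_ge`.
#'
#' @param alignments An `alignment_set`.
#' @param profile A [coverage()] profile.
#' @param path,tsv_path,json_path Output paths.
#' @return The written path(s), invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  d <- data.frame(read_id = alignments$read_id, contig = alignments$contig,
                  pos1based = alignments$pos + 1L, strand = alignments$strand,
                  score = alignments$score, n_best = alignments$n_best,
                  status = alignments$status)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
write_coverage <- function(profile, tsv_path, json_path = NULL) {
  stopifnot(inherits(profile, "coverage_profile"))
  write.table(data.frame(pos = seq_along(profile$depth), depth = profile$depth),
              tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to write the coverage JSON summary")
    jsonlite::write_json(list(contig = profile$contig,
                              mean_doc = profile$mean_doc,
                              frac_ge = as.list(profile$frac_ge)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}
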