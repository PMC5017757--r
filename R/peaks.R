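#' Detect peaks in a fragment-analysis trace
#'
#' Subtracts the median intensity as baseline, then reports local maxima
#' above a height threshold relative to the global maximum. Peak boundaries
#' are the flanking minima of the (lightly smoothed) trace, capped at
#' centroid +/- 3 bp, and each peak's area is the trapezoid integral of the
#' baseline-subtracted trace between its boundaries.
#'
#' Maxima are located on a 5-point moving average of the trace so that grid
#' jitter in a noisy trace does not split one peak into several; heights and
#' areas are measured on the unsmoothed baseline-subtracted trace.
#'
#' @param trace An [electropherogram()].
#' @param min_rel_height Minimum peak height as a fraction of the global
#'   (baseline-subtracted) maximum. The default 0.005 keeps a 1% minor
#'   component visible at the default noise level while rejecting baseline
#'   ripple.
#' @return A data frame of peaks with columns `centroid`, `height`, `area`,
#'   `left`, `right`, `species` (all `"unassigned"`), sorted by centroid.
#'   Zero rows when the trace is flat.
#' @export
detect_peaks <- function(trace, min_rel_height = 0.005) {
  stopifnot(inherits(trace, "electropherogram"))
  empty <- data.frame(centroid = numeric(0), height = numeric(0),
                      area = numeric(0), left = numeric(0), right = numeric(0),
                      species = character(0), stringsAsFactors = FALSE)
  y <- trace$intensity - median(trace$intensity)
  if (max(y) <= 0) return(empty)
  n <- length(y)
  ys <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  th <- min_rel_height * max(ys)
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] &
                ys[2:(n - 1)] >= ys[3:n], FALSE) & ys >= th
  idx <- which(is_max)
  if (!length(idx)) return(empty)
  # merge maxima closer than 0.5 bp, keeping the taller
  step <- median(diff(trace$size))
  keep <- logical(length(idx))
  i <- 1L
  while (i <= length(idx)) {
    j <- i
    while (j < length(idx) &&
           (trace$size[idx[j + 1L]] - trace$size[idx[j]]) < 0.5) j <- j + 1L
    grp <- idx[i:j]
    keep[i - 1L + which.max(ys[grp])] <- TRUE
    i <- j + 1L
  }
  idx <- idx[keep]
  cap <- max(1L, round(3 / step))
  peaks <- lapply(idx, function(p) {
    l <- p
    while (l > 1L && ys[l - 1L] <= ys[l] && (p - l) < cap) l <- l - 1L
    r <- p
    while (r < n && ys[r + 1L] <= ys[r] && (r - p) < cap) r <- r + 1L
    area <- pracma::trapz(trace$size[l:r], pmax(y[l:r], 0))
    data.frame(centroid = trace$size[p], height = y[p], area = area,
               left = trace$size[l], right = trace$size[r],
               species = "unassigned", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, peaks)
  out <- out[out$area > 0, , drop = FALSE]
  out[order(out$centroid), , drop = FALSE]
}

#' Assign detected peaks to species by amplicon size
#'
#' A peak is labelled mouse or human when its centroid lies within `tol` bp
#' of that species' amplicon length for the locus; at most one peak per
#' species is labelled (largest area wins). All other peaks are left
#' `"unassigned"`.
#'
#' @param peaks Peak data frame from [detect_peaks()].
#' @param locus An [sspal_locus()].
#' @param tol Assignment tolerance in bp; must be positive and smaller than
#'   half the inter-species amplicon length gap, otherwise assignments would
#'   be ambiguous.
#' @return The peak data frame with the `species` column filled in.
#' @export
assign_species <- function(peaks, locus, tol = 1.5) {
  stopifnot(inherits(locus, "sspal_locus"), is.data.frame(peaks))
  gap <- abs(locus$human_len - locus$mouse_len)
  if (tol <= 0 || tol >= gap / 2)
    stop(sprintf("tol must lie in (0, %.2f) for this locus", gap / 2))
  if (!nrow(peaks)) return(peaks)
  peaks$species <- "unassigned"
  for (sp in c("mouse", "human")) {
    target <- if (sp == "mouse") locus$mouse_len else locus$human_len
    cand <- which(abs(peaks$centroid - target) <= tol)
    if (length(cand)) peaks$species[cand[which.max(peaks$area[cand])]] <- sp
  }
  peaks
}

#' Estimate the mouse DNA fraction from species-assigned peak areas
#'
#' The fraction of mouse template in the PCR is estimated as the mouse peak
#' area over the total assigned peak area, `A_mouse / (A_mouse + A_human)`;
#' peak areas are proportional to the species template amounts. A missing
#' species peak contributes zero area; if neither species peak is present the
#' reaction is reported as failed.
#'
#' @param peaks Species-assigned peak data frame from [assign_species()].
#' @param pair_id Primer pair identifier recorded on the result.
#' @return Named numeric vector `c(mouse = ..., human = ...)` summing to 1.
#' @export
estimate_fraction <- function(peaks, pair_id = "pair") {
  stopifnot(is.data.frame(peaks))
  a_mouse <- sum(peaks$area[peaks$species == "mouse"])
  a_human <- sum(peaks$area[peaks$species == "human"])
  if (a_mouse + a_human <= 0)
    stop(sprintf("no amplification for %s: neither species peak present",
                 pair_id))
  f <- a_mouse / (a_mouse + a_human)
  c(mouse = f, human = 1 - f)
}

#' Quantify one trace end to end
#'
#' Convenience chain: [detect_peaks()], [assign_species()],
#' [estimate_fraction()].
#'
#' @inheritParams detect_peaks
#' @inheritParams assign_species
#' @return Named numeric vector `c(mouse = ..., human = ...)`, with the
#'   species-assigned peak table attached as attribute `"peaks"`.
#' @export
quant_trace <- function(trace, locus, min_rel_height = 0.005, tol = 1.5) {
  pk <- assign_species(detect_peaks(trace, min_rel_height), locus, tol)
  est <- estimate_fraction(pk, locus$pair_id)
  attr(est, "peaks") <- pk
  est
}

#' Read and write pre-called peak tables
#'
#' Peak-caller exports are a four-column TSV: `pair_id`, `size_bp`, `height`,
#' `area`. Peaks read from such a table carry no boundary information and are
#' unassigned until [assign_species()] is run.
#'
#' @param peaks Peak data frame (as from [detect_peaks()]).
#' @param pair_id Pair identifier written alongside each row.
#' @param path File path.
#' @return `read_peak_table()` returns a named list of peak data frames, one
#'   per `pair_id` present in the file.
#' @export
write_peak_table <- function(peaks, pair_id, path) {
  write.table(data.frame(pair_id = pair_id, size_bp = peaks$centroid,
                         height = peaks$height, area = peaks$area),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  d <- read.delim(path, header = TRUE)
  need <- c("pair_id", "size_bp", "height", "area")
  if (!all(need %in% names(d)))
    stop("peak table must have columns pair_id, size_bp, height, area")
  lapply(split(d, d$pair_id), function(g) {
    data.frame(centroid = g$size_bp, height = g$height, area = g$area,
               left = NA_real_, right = NA_real_, species = "unassigned",
               stringsAsFactors = FALSE)
  })
}
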