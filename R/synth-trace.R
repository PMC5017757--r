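#' Trace noise model for synthetic electropherograms
#'
#' Parameters of the synthetic capillary-electrophoresis trace generator.
#' Peaks are Gaussian in fragment size; additive intensity noise is i.i.d.
#' Gaussian scaled to the major peak height and the trace is truncated at
#' zero (fluorescence cannot be negative).
#'
#' Defaults (peak sigma 0.4 bp, noise 0.2% of the major peak height, zero
#' baseline) describe a clean modern fragment-analysis run: peaks a few grid
#' points wide, baseline ripple well below a 1% minor component.
#'
#' @param peak_sigma Gaussian peak width (standard deviation) in bp.
#' @param noise_sd Additive noise standard deviation, as a fraction of the
#'   largest peak height.
#' @param baseline Constant baseline intensity.
#' @param seed Integer seed; must be set (here or by the caller supplying
#'   replicate-level seeds) before a trace with `noise_sd > 0` is synthesized.
#' @return An object of class `trace_noise_model`.
#' @export
trace_noise_model <- function(peak_sigma = 0.4, noise_sd = 0.002,
                              baseline = 0, seed = NULL) {
  stopifnot(peak_sigma > 0, noise_sd >= 0, baseline >= 0)
  structure(list(peak_sigma = peak_sigma, noise_sd = noise_sd,
                 baseline = baseline,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "trace_noise_model")
}

#' Construct an electropherogram from size/intensity points
#'
#' @param pair_id ssPAL primer pair the trace belongs to.
#' @param size Fragment sizes in bp, strictly increasing.
#' @param intensity Non-negative fluorescence intensities, same length.
#' @return An object of class `electropherogram`.
#' @export
electropherogram <- function(pair_id, size, intensity) {
  stopifnot(length(size) == length(intensity), length(size) > 0)
  if (any(diff(size) <= 0)) stop("sizes must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(pair_id = pair_id, size = as.numeric(size),
                 intensity = as.numeric(intensity)),
            class = "electropherogram")
}

#' @export
print.electropherogram <- function(x, ...) {
  cat(sprintf("electropherogram [%s]: %d points, %.1f-%.1f bp, max intensity %.3g\n",
              x$pair_id, length(x$size), min(x$size), max(x$size),
              max(x$intensity)))
  invisible(x)
}

#' Synthesize a two-species electropherogram
#'
#' Emulates the fragment-analysis trace of one ssPAL PCR: a Gaussian peak at
#' the mouse amplicon size whose area is proportional to the mouse template
#' fraction, a Gaussian at the human amplicon size with area proportional to
#' the human fraction, a constant baseline, and additive Gaussian intensity
#' noise truncated at zero. The trace is sampled on a 0.1 bp grid spanning
#' both amplicon sizes with a 15 bp margin.
#'
#' @param locus An [sspal_locus()].
#' @param mouse_fraction Mouse template fraction in `[0, 1]`.
#' @param noise A [trace_noise_model()].
#' @param total_area Total peak area (arbitrary intensity·bp units) shared by
#'   the two peaks in proportion to the template fractions.
#' @return An [electropherogram()].
#' @export
#' @examples
#' tr <- synth_electropherogram(sspal_pair43(), 0.5, trace_noise_model(noise_sd = 0))
#' plot(tr$size, tr$intensity, type = "l", xlab = "size (bp)", ylab = "RFU")
synth_electropherogram <- function(locus, mouse_fraction,
                                   noise = trace_noise_model(),
                                   total_area = 1000) {
  stopifnot(inherits(locus, "sspal_locus"), inherits(noise, "trace_noise_model"))
  if (!is.numeric(mouse_fraction) || length(mouse_fraction) != 1L ||
      mouse_fraction < 0 || mouse_fraction > 1)
    stop("mouse_fraction must be a single value in [0, 1]")
  lo <- min(locus$human_len, locus$mouse_len) - 15
  hi <- max(locus$human_len, locus$mouse_len) + 15
  grid <- seq(lo, hi, by = 0.1)
  s <- noise$peak_sigma
  gauss <- function(mu, area) area * stats::dnorm(grid, mean = mu, sd = s)
  signal <- noise$baseline +
    gauss(locus$mouse_len, total_area * mouse_fraction) +
    gauss(locus$human_len, total_area * (1 - mouse_fraction))
  if (noise$noise_sd > 0) {
    if (is.null(noise$seed))
      stop("the trace_noise_model needs a seed when noise_sd > 0")
    major <- total_area * max(mouse_fraction, 1 - mouse_fraction) /
      (s * sqrt(2 * pi))
    eps <- with_seed(noise$seed,
                     rnorm(length(grid), 0, noise$noise_sd * major))
    signal <- signal + eps
  }
  electropherogram(locus$pair_id, grid, pmax(signal, 0))
}

#' Read and write raw traces as two-column TSV
#'
#' The on-disk form is the two-column export of a fragment-analysis run:
#' `size_bp` and `intensity`, tab-separated, with a header line.
#'
#' @param trace An [electropherogram()].
#' @param path File path.
#' @param pair_id Pair identifier to attach on read.
#' @return `read_trace_tsv()` returns an [electropherogram()].
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "electropherogram"))
  write.table(data.frame(size_bp = trace$size, intensity = trace$intensity),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path, pair_id) {
  d <- read.delim(path, header = TRUE)
  if (!all(c("size_bp", "intensity") %in% names(d)))
    stop("trace TSV must have columns 'size_bp' and 'intensity'")
  electropherogram(pair_id, d$size_bp, d$intensity)
}
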