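#' Combine per-pair mouse fractions into one estimate
#'
#' The two ssPAL primer pairs yield highly similar fractions on the same
#' sample; the combined estimate is their arithmetic mean. Sensitivity of the
#' assay is lost outside the 1%-99% mixture range, so combined estimates
#' below 1% or above 99% carry a censoring flag.
#'
#' @param per_pair Either a named numeric vector of per-pair mouse fractions
#'   (names are pair ids) or a named list of `c(mouse = ..., human = ...)`
#'   vectors as returned by [estimate_fraction()].
#' @param expected_pairs Optional character vector of pair ids that should be
#'   present; a warning is raised for each missing one and the combined value
#'   falls back to the mean of the available pairs.
#' @return An object of class `fraction_estimate`: list with `per_pair`
#'   (named mouse fractions), `combined` (mean mouse fraction) and
#'   `censor_flag` (`"none"`, `"below_1pct"` or `"above_99pct"`).
#' @export
#' @examples
#' combine_pairs(c(pair5 = 0.994, pair43 = 0.984))
combine_pairs <- function(per_pair, expected_pairs = NULL) {
  if (is.list(per_pair))
    per_pair <- vapply(per_pair, function(x) unname(x[["mouse"]]), numeric(1))
  if (!length(per_pair)) stop("at least one primer pair is required")
  if (is.null(names(per_pair)) || any(!nzchar(names(per_pair))))
    stop("per-pair fractions must be named by pair id")
  if (any(per_pair < 0 | per_pair > 1))
    stop("mouse fractions must lie in [0, 1]")
  if (!is.null(expected_pairs)) {
    miss <- setdiff(expected_pairs, names(per_pair))
    if (length(miss))
      warning(sprintf(
        "pair(s) %s missing; combined estimate uses the available pair(s) only",
        paste(miss, collapse = ", ")))
  }
  combined <- mean(per_pair)
  flag <- if (combined < 0.01) "below_1pct"
          else if (combined > 0.99) "above_99pct"
          else "none"
  structure(list(per_pair = per_pair, combined = combined, censor_flag = flag),
            class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat("ssPAL fraction estimate\n")
  for (p in names(x$per_pair))
    cat(sprintf("  %-8s mouse %.1f%% / human %.1f%%\n", p,
                100 * x$per_pair[[p]], 100 * (1 - x$per_pair[[p]])))
  cat(sprintf("  combined mouse fraction: %.1f%%", 100 * x$combined))
  if (x$censor_flag != "none")
    cat(sprintf("  [censored: %s — outside the assay's 1-99%% sensitivity range]",
                x$censor_flag))
  cat("\n")
  invisible(x)
}

#' Classify the species of origin of a tumor sample
#'
#' A combined murine fraction strictly above the threshold (default 95%)
#' flags the sample as likely mouse in origin — typically a spontaneous
#' murine malignancy (e.g. lymphoma) that has overgrown the engrafted human
#' tumor — and warrants confirmatory STR analysis. The threshold comparison
#' is strict: exactly 95% is still called a human tumor.
#'
#' @param est A [combine_pairs()] estimate, or a bare combined mouse
#'   fraction.
#' @param threshold Decision threshold in `(0, 1)`.
#' @return An object of class `origin_call` with elements
#'   `combined_mouse_fraction`, `threshold` and `verdict` (`"human_tumor"`
#'   or `"suspect_mouse"`).
#' @export
#' @examples
#' classify_origin(combine_pairs(c(pair5 = 0.994, pair43 = 0.984)))
classify_origin <- function(est, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  f <- if (inherits(est, "fraction_estimate")) est$combined else as.numeric(est)
  stopifnot(length(f) == 1L, f >= 0, f <= 1)
  structure(list(combined_mouse_fraction = f, threshold = threshold,
                 verdict = if (f > threshold) "suspect_mouse" else "human_tumor"),
            class = "origin_call")
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("origin call: %s (combined mouse fraction %.1f%%, threshold >%.0f%%)\n",
              x$verdict, 100 * x$combined_mouse_fraction, 100 * x$threshold))
  invisible(x)
}

#' Run a synthetic dilution series through the quantitation chain
#'
#' For each true mouse fraction, `replicates` synthetic traces are generated
#' and pushed through peak detection, species assignment and fraction
#' estimation. The detection limit of the assay is the smallest tested
#' fraction at which the mouse peak is detected in at least 95% of
#' replicates.
#'
#' @param locus An [sspal_locus()].
#' @param fractions True mouse fractions to test, each in `[0, 1]`.
#' @param replicates Traces per fraction (>= 1).
#' @param noise A [trace_noise_model()]; its seed field is ignored, each
#'   replicate gets a child seed derived from `seed`.
#' @param seed Master seed.
#' @param min_rel_height,tol Passed to [detect_peaks()] / [assign_species()].
#' @return A data frame of class `dilution_series` with columns
#'   `true_fraction`, `mean_estimate`, `sd`, `detected_rate`, and attribute
#'   `detection_limit` (NA when no tested fraction reaches 95% detection).
#' @export
dilution_series <- function(locus, fractions, replicates = 100,
                            noise = trace_noise_model(), seed,
                            min_rel_height = 0.005, tol = 1.5) {
  stopifnot(inherits(locus, "sspal_locus"), all(fractions >= 0 & fractions <= 1))
  if (replicates < 1) stop("replicates must be >= 1")
  if (missing(seed)) stop("seed is required")
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    est <- numeric(replicates)
    det <- logical(replicates)
    for (j in seq_len(replicates)) {
      nm <- trace_noise_model(noise$peak_sigma, noise$noise_sd, noise$baseline,
                              seed = derive_seed(seed, (i - 1L) * replicates + j))
      tr <- synth_electropherogram(locus, f, nm)
      pk <- assign_species(detect_peaks(tr, min_rel_height), locus, tol)
      det[j] <- any(pk$species == "mouse")
      est[j] <- tryCatch(estimate_fraction(pk, locus$pair_id)[["mouse"]],
                         error = function(e) NA_real_)
    }
    data.frame(true_fraction = f, mean_estimate = mean(est, na.rm = TRUE),
               sd = if (replicates > 1) sd(est, na.rm = TRUE) else 0,
               detected_rate = mean(det))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$true_fraction), , drop = FALSE]
  hit <- out$true_fraction[out$detected_rate >= 0.95]
  attr(out, "detection_limit") <- if (length(hit)) min(hit) else NA_real_
  class(out) <- c("dilution_series", "data.frame")
  out
}

#' @export
print.dilution_series <- function(x, ...) {
  cat("ssPAL dilution series\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  dl <- attr(x, "detection_limit")
  cat(if (is.na(dl)) "detection limit: not reached on the tested grid\n"
      else sprintf("detection limit: %.3g%% mouse DNA\n", 100 * dl))
  invisible(x)
}

#' Build a passage series of fraction estimates
#'
#' @param line_id PDX line identifier.
#' @param passage Integer passage numbers (>= 0), strictly increasing.
#' @param estimates Combined mouse fractions (numeric) or a list of
#'   [combine_pairs()] objects, one per passage.
#' @return An object of class `passage_series`.
#' @export
passage_series <- function(line_id, passage, estimates) {
  passage <- as.integer(passage)
  if (any(passage < 0L)) stop("passages must be >= 0")
  if (any(diff(passage) <= 0L)) stop("passages must be strictly increasing")
  f <- if (is.list(estimates))
    vapply(estimates, function(e) e$combined, numeric(1)) else
      as.numeric(estimates)
  stopifnot(length(f) == length(passage), all(f >= 0 & f <= 1))
  structure(list(line_id = line_id, passage = passage, mouse_fraction = f),
            class = "passage_series")
}

#' Summarize the stability of mouse stromal content across passages
#'
#' The stroma-to-cancer-cell ratio of a PDX line is a characteristic of the
#' model: after engraftment it remains within a narrow range over successive
#' passages. This summarizes that range.
#'
#' @param series A [passage_series()] with at least two passages.
#' @return List with `mean`, `sd`, `range` (max minus min of the combined
#'   mouse fraction) and `per_passage` (data frame for plotting).
#' @export
passage_stability <- function(series) {
  stopifnot(inherits(series, "passage_series"))
  f <- series$mouse_fraction
  if (length(f) < 2L) stop("at least two passages are required")
  list(mean = mean(f), sd = sd(f), range = max(f) - min(f),
       per_passage = data.frame(passage = series$passage, mouse_fraction = f))
}

#' Summarize combined mouse fractions across a PDX cohort
#'
#' Tabulates the combined mouse fraction per line and group means per
#' histology; when exactly two histology groups each have at least two lines,
#' the routine two-sample comparison (Welch two-tailed t-test) is run via
#' [stats::t.test()].
#'
#' @param lines Data frame with columns `line_id`, `mouse_fraction` and
#'   `histology` (one row per line); `mouse_fraction` may also be a list
#'   column of [combine_pairs()] objects.
#' @return List with `lines` (per-line table), `groups` (per-histology n,
#'   mean, sd) and `test` (an `htest` or NULL).
#' @export
cohort_summary <- function(lines) {
  stopifnot(is.data.frame(lines), nrow(lines) >= 1L,
            all(c("line_id", "mouse_fraction", "histology") %in% names(lines)))
  if (is.list(lines$mouse_fraction))
    lines$mouse_fraction <- vapply(lines$mouse_fraction,
                                   function(e) e$combined, numeric(1))
  groups <- do.call(rbind, lapply(split(lines, lines$histology), function(g) {
    data.frame(histology = g$histology[1], n = nrow(g),
               mean_fraction = mean(g$mouse_fraction),
               sd = if (nrow(g) > 1) sd(g$mouse_fraction) else NA_real_)
  }))
  rownames(groups) <- NULL
  test <- NULL
  if (nrow(groups) == 2L && all(groups$n >= 2L)) {
    sp <- split(lines$mouse_fraction, lines$histology)
    test <- t.test(sp[[1]], sp[[2]])
  }
  list(lines = lines[, c("line_id", "mouse_fraction", "histology")],
       groups = groups, test = test)
}

#' Write fraction estimates and origin calls as TSV
#'
#' One row per sample: per-pair mouse fractions, the combined fraction, the
#' censoring flag, and the origin verdict at the given threshold.
#'
#' @param estimates Named list of [combine_pairs()] objects (names are sample
#'   or line ids).
#' @param path File path.
#' @param threshold Classification threshold passed to [classify_origin()].
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(estimates, path, threshold = 0.95) {
  stopifnot(length(estimates) >= 1L, !is.null(names(estimates)))
  pairs <- sort(unique(unlist(lapply(estimates, function(e) names(e$per_pair)))))
  rows <- lapply(names(estimates), function(id) {
    e <- estimates[[id]]
    per <- setNames(rep(NA_real_, length(pairs)), pairs)
    per[names(e$per_pair)] <- e$per_pair
    cbind(data.frame(sample_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(per)),
          data.frame(combined = e$combined, censor_flag = e$censor_flag,
                     verdict = classify_origin(e, threshold)$verdict,
                     stringsAsFactors = FALSE))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' ssPAL measurements of four suspect PDX lines
#'
#' Published ssPAL percentages (per primer pair, murine and human) for four
#' PDX lines whose murine content proved so high that STR follow-up showed
#' they were not human tumors. Rows whose two percentages do not sum to
#' exactly 100 (rounding in the source table) are renormalized by their sum
#' when converted to fractions.
#'
#' @param path Optional path to a TSV with columns `line_id`, `pair_id`,
#'   `murine_pct`, `human_pct`; defaults to the panel shipped with the
#'   package.
#' @return Data frame with those four columns plus `mouse_fraction`, the
#'   renormalized per-pair murine fraction.
#' @export
#' @examples
#' panel <- pdx_origin_panel()
#' ests <- lapply(split(panel, panel$line_id), function(g)
#'   combine_pairs(setNames(g$mouse_fraction, g$pair_id)))
#' vapply(ests, function(e) classify_origin(e)$verdict, "")
pdx_origin_panel <- function(path = system.file("extdata",
                                                "sspal_origin_panel.tsv",
                                                package = "pdxpurity")) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("line_id", "pair_id", "murine_pct", "human_pct") %in% names(d)))
  d$mouse_fraction <- d$murine_pct / (d$murine_pct + d$human_pct)
  d
}
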