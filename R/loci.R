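#' Define an ssPAL locus
#'
#' An ssPAL (species-specific PCR amplicon length) locus is a primer pair
#' amplifying a region conserved between human and mouse whose PCR products
#' differ slightly in length between the two species. The product length
#' difference, resolved by capillary electrophoresis, is what makes the locus
#' informative about the species composition of a DNA mixture.
#'
#' Two loci are built in: primer pair 5 (Ribonuclease P/MRP 38 kDa subunit
#' region on human 10p13; 272 bp human product, 278 bp mouse product) and
#' primer pair 43 (RC3H2 region on human 9q34; 211 bp human product, 206 bp
#' mouse product). Use [sspal_pair5()] / [sspal_pair43()] for these.
#'
#' @param pair_id Identifier, e.g. `"pair5"`.
#' @param human_len,mouse_len Amplicon lengths in bp (primer to primer,
#'   inclusive). Must differ.
#' @param forward_primer,reverse_primer Primer sequences (DNA strings); the
#'   reverse primer is given 5'->3' on the opposite strand, as ordered.
#' @return An object of class `sspal_locus`.
#' @export
#' @examples
#' sspal_pair43()
sspal_locus <- function(pair_id, human_len, mouse_len,
                        forward_primer = NULL, reverse_primer = NULL) {
  stopifnot(is.character(pair_id), length(pair_id) == 1L, nzchar(pair_id))
  human_len <- as.integer(human_len)
  mouse_len <- as.integer(mouse_len)
  if (human_len <= 0L || mouse_len <= 0L)
    stop("amplicon lengths must be positive")
  if (human_len == mouse_len)
    stop("human and mouse amplicon lengths must differ for an ssPAL locus")
  structure(
    list(pair_id = pair_id, human_len = human_len, mouse_len = mouse_len,
         forward_primer = forward_primer, reverse_primer = reverse_primer),
    class = "sspal_locus"
  )
}

#' @rdname sspal_locus
#' @export
sspal_pair5 <- function() {
  sspal_locus("pair5", human_len = 272L, mouse_len = 278L,
              forward_primer = "TCATTGGCTTAAAATGTGT",
              reverse_primer = "TTTATTTTAAGGGGTTGTAATG")
}

#' @rdname sspal_locus
#' @export
sspal_pair43 <- function() {
  sspal_locus("pair43", human_len = 211L, mouse_len = 206L,
              forward_primer = "CTATTCCTATAGCACAAAGG",
              reverse_primer = "GATGGTGTACACCCATCATG")
}

#' @export
print.sspal_locus <- function(x, ...) {
  cat(sprintf("ssPAL locus '%s': human %d bp / mouse %d bp amplicon\n",
              x$pair_id, x$human_len, x$mouse_len))
  invisible(x)
}
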