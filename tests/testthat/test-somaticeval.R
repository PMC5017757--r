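pair <- small_pair(length = 10000, divergence = 0.10, seed = 7)
ref <- build_reference(pair$human, pair$mouse, k = 15)
hname <- pair$human$name

test_that("pileups count bases read by read", {
  rd <- read_set("r1", substring(pair$human$sequence, 101, 200), "human",
                 hname, 100L, "+")
  a <- align_reads(rd, ref)
  p <- pileup_reads(a, rd, ref, hname)
  expect_equal(nrow(p), 100L)
  expect_true(all(p$depth == 1L))
  refbases <- substring(pair$human$sequence, p$pos + 1, p$pos + 1)
  expect_true(all(as.matrix(p[, c("A", "C", "G", "T")])[
    cbind(seq_len(100), match(refbases, c("A", "C", "G", "T")))] == 1L))
  # two overlapping reads disagreeing at one site
  s2 <- substring(pair$human$sequence, 151, 250)
  refb <- substring(s2, 1, 1)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  substring(s2, 1, 1) <- altb
  rd2 <- read_set(c("r1", "r2"),
                  c(substring(pair$human$sequence, 101, 200), s2),
                  "human", hname, c(100L, 150L), "+")
  p2 <- pileup_reads(align_reads(rd2, ref), rd2, ref, hname)
  site <- p2[p2$pos == 150L, ]
  expect_equal(site$depth, 2L)
  expect_equal(site[[refb]], 1L)
  expect_equal(site[[altb]], 1L)
  # alignments whose reads are missing are rejected
  a_bad <- a; a_bad$read_id <- "missing"
  expect_error(pileup_reads(a_bad, rd, ref, hname), "missing")
})

test_that("the binomial caller applies depth, count, tail and germline rules", {
  site <- 500L
  refb <- substring(pair$human$sequence, site + 1, site + 1)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  counts <- function(n_ref, n_alt) {
    out <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
    out[refb] <- n_ref; out[altb] <- n_alt
    out
  }
  tum <- do.call(make_pileup, c(list(hname, site), as.list(counts(30L, 30L))))
  nrm0 <- do.call(make_pileup, c(list(hname, site), as.list(counts(30L, 0L))))
  calls <- call_somatic(tum, nrm0, ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$alt, altb)
  expect_equal(calls$ref, refb)
  expect_lt(calls$p_value, 1e-30)
  # no alternate reads: not called
  tum0 <- do.call(make_pileup, c(list(hname, site), as.list(counts(60L, 0L))))
  expect_equal(nrow(call_somatic(tum0, nrm0, ref)), 0L)
  # germline exclusion: half-alt normal
  nrm_het <- do.call(make_pileup, c(list(hname, site), as.list(counts(15L, 15L))))
  expect_equal(nrow(call_somatic(tum, nrm_het, ref)), 0L)
  expect_error(call_somatic(tum, nrm0, ref, list(error_rate = 0)), "error_rate")
})

test_that("the caller matches a brute-force enumeration oracle at depth <= 12", {
  # oracle: same gates, binomial tail summed term by term over alt counts
  oracle_called <- function(depth, alt_count, n_alt_frac,
                            e = 0.01, alpha = 1e-3, min_depth = 10,
                            min_alt = 3, max_naf = 0.03) {
    tail <- sum(vapply(alt_count:depth, function(k)
      choose(depth, k) * (e / 3)^k * (1 - e / 3)^(depth - k), numeric(1)))
    depth >= min_depth && alt_count >= min_alt && tail < alpha &&
      n_alt_frac <= max_naf
  }
  site <- 777L
  refb <- substring(pair$human$sequence, site + 1, site + 1)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  for (depth in 1:12) {
    for (alt in 0:depth) {
      counts <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
      counts[refb] <- depth - alt; counts[altb] <- alt
      tum <- do.call(make_pileup, c(list(hname, site), as.list(counts)))
      nrm <- make_pileup(hname, site, A = 10L)
      nrm[[refb]] <- 10L
      if (refb != "A") nrm$A <- 0L
      nrm$depth <- 10L
      got <- nrow(call_somatic(tum, nrm, ref)) == 1L
      expect_identical(got, oracle_called(depth, alt, 0),
                       label = sprintf("depth %d alt %d", depth, alt))
    }
  }
})

test_that("evaluation applies exact matching and the 0/0 conventions", {
  truth <- data.frame(contig = "c", pos = c(10L, 20L, 30L),
                      ref = "A", alt = "T", vaf = c(0.05, 0.2, 0.5))
  mkcalls <- function(pos, alt, depth = 60L, alt_count = 30L) {
    data.frame(contig = rep("c", length(pos)), pos = pos,
               ref = rep("A", length(pos)), alt = rep(alt, length.out = length(pos)),
               depth = rep(depth, length.out = length(pos)),
               alt_count = rep(alt_count, length.out = length(pos)),
               p_value = rep(0, length(pos)), stringsAsFactors = FALSE)
  }
  # calls exactly equal to truth
  ev <- evaluate_calls(mkcalls(c(10L, 20L, 30L), "T"), truth)
  ov <- ev[ev$vaf_bin == "overall", ]
  expect_equal(c(ov$precision, ov$recall, ov$f1), c(1, 1, 1))
  # no calls, non-empty truth
  ev0 <- evaluate_calls(mkcalls(integer(0), character(0)), truth)
  ov0 <- ev0[ev0$vaf_bin == "overall", ]
  expect_equal(ov0$recall, 0)
  expect_equal(ov0$f1, 0)
  # matching needs the alternate allele, not just the position
  ev_alt <- evaluate_calls(mkcalls(10L, "G"), truth)
  ov_alt <- ev_alt[ev_alt$vaf_bin == "overall", ]
  expect_equal(ov_alt$tp, 0L)
  expect_equal(ov_alt$fp, 1L)
  # printed-count arithmetic: 9 TP among 196 calls
  big_truth <- data.frame(contig = "c", pos = 1:9, ref = "A", alt = "T",
                          vaf = 0.5)
  big_calls <- mkcalls(1:196, "T")
  evb <- evaluate_calls(big_calls, big_truth)
  ovb <- evb[evb$vaf_bin == "overall", ]
  expect_equal(ovb$tp, 9L)
  expect_equal(ovb$fp, 187L)
  expect_equal(ovb$precision, 9 / 196)
  expect_error(evaluate_calls(mkcalls(10L, "T"), truth,
                              vaf_bins = c(0, 0.5, 0.3, 1)), "vaf_bins")
})

test_that("the contamination sweep preserves truth accounting and direction", {
  sw <- contamination_sweep(c(0, 0.5, 0.9), seed = 3, genome_length = 20000,
                            n_mutations = 40)
  ov <- sw$eval[sw$eval$vaf_bin == "overall", ]
  expect_true(all(ov$tp + ov$fn == 40L))
  expect_true(all(sw$eval$tp >= 0 & sw$eval$fp >= 0 & sw$eval$fn >= 0))
  # lambda = 0, high-VAF calling is essentially perfect
  top <- sw$eval[sw$eval$lam == 0 & sw$eval$vaf_bin %in% c("(0.2,0.33]", "(0.33,1]"), ]
  expect_true(all(top$f1 >= 0.95))
  # heavy contamination degrades the lowest VAF bin
  low <- sw$eval[sw$eval$vaf_bin == "(0,0.1]", ]
  expect_lt(low$f1[low$lam == 0.9], low$f1[low$lam == 0])
  # depth loss: mean DoC tracks (1 - lambda) * 60
  expect_true(all(abs(sw$coverage$mean_doc - (1 - sw$coverage$lam) * 60) < 3))
  expect_error(contamination_sweep(numeric(0), seed = 1), "non-empty")
})

test_that("with no mouse reads, human-only and hybrid references call alike", {
  p <- small_pair(length = 15000, divergence = 0.10, seed = 19)
  truth <- spike_mutation_set(p$human, 20, seed = 20)
  normal <- simulate_reads(p$human, 30, 100, 0.001, seed = 21)
  tum <- spike_reads(simulate_reads(p$human, 60, 100, 0.001, seed = 22),
                     truth, seed = 23)
  calls_for <- function(r) {
    na <- exclude_mouse(align_reads(normal, r), r)
    ta <- exclude_mouse(align_reads(tum, r), r)
    call_somatic(pileup_reads(ta, tum, r, p$human$name),
                 pileup_reads(na, normal, r, p$human$name), r)
  }
  hybrid <- build_reference(p$human, p$mouse, k = 15)
  human_only <- build_reference(p$human, k = 15)
  expect_equal(calls_for(hybrid), calls_for(human_only))
})

test_that("sweeps are bit-reproducible under a fixed master seed", {
  a <- contamination_sweep(c(0, 0.6), seed = 5, genome_length = 8000,
                           n_mutations = 12)
  b <- contamination_sweep(c(0, 0.6), seed = 5, genome_length = 8000,
                           n_mutations = 12)
  expect_identical(a$eval, b$eval)
  expect_identical(a$coverage, b$coverage)
})
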