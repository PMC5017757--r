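test_that("zero divergence with no loci yields identical genomes", {
  pair <- make_genome_pair(genome_pair_config(2000, 0, seed = 1))
  expect_identical(pair$human$sequence, pair$mouse$sequence)
  expect_equal(pair$human$species, "human")
  expect_equal(pair$mouse$species, "mouse")
})

test_that("observed mismatch fraction matches the binomial model", {
  L <- 10000
  pair <- make_genome_pair(genome_pair_config(L, 0.10, seed = 7))
  h <- strsplit(pair$human$sequence, "")[[1]]
  m <- strsplit(pair$mouse$sequence, "")[[1]]
  mism <- sum(h != m)
  # 99% binomial interval for Binomial(L, 0.1)
  expect_gte(mism, qbinom(0.005, L, 0.10))
  expect_lte(mism, qbinom(0.995, L, 0.10))
})

test_that("embedded ssPAL loci have the configured amplicon lengths", {
  loci <- list(list(locus = sspal_pair5(), offset = 500),
               list(locus = sspal_pair43(), offset = 2000))
  pair <- make_genome_pair(genome_pair_config(5000, 0.10, loci, seed = 3))
  lm <- pair$loci
  expect_equal(lm$human_end - lm$human_start, c(272L, 211L))
  expect_equal(lm$mouse_end - lm$mouse_start, c(278L, 206L))
  # primer sites identical between species at both amplicon ends
  for (i in seq_len(nrow(lm))) {
    loc <- loci[[i]]$locus
    pf <- nchar(loc$forward_primer); pr <- nchar(loc$reverse_primer)
    h_start <- substring(pair$human$sequence, lm$human_start[i] + 1,
                         lm$human_start[i] + pf)
    m_start <- substring(pair$mouse$sequence, lm$mouse_start[i] + 1,
                         lm$mouse_start[i] + pf)
    expect_identical(h_start, m_start)
    expect_identical(h_start, loc$forward_primer)
    h_end <- substring(pair$human$sequence, lm$human_end[i] - pr + 1,
                       lm$human_end[i])
    m_end <- substring(pair$mouse$sequence, lm$mouse_end[i] - pr + 1,
                       lm$mouse_end[i])
    expect_identical(h_end, m_end)
  }
})

test_that("invalid genome-pair configurations are rejected", {
  expect_error(genome_pair_config(1000, 1.0, seed = 1), "divergence")
  expect_error(genome_pair_config(100, 0.1,
                                  list(list(locus = sspal_pair5(), offset = 0)),
                                  seed = 1), "inside")
  expect_error(genome_pair_config(1000, 0.1,
                                  list(list(locus = sspal_pair43(), offset = 10),
                                       list(locus = sspal_pair43(), offset = 100)),
                                  seed = 1), "overlap")
})

test_that("noise-free traces have the expected peak structure", {
  quiet <- trace_noise_model(noise_sd = 0)
  # degenerate mixture: single human peak
  tr0 <- synth_electropherogram(sspal_pair43(), 0, quiet)
  pk0 <- detect_peaks(tr0)
  expect_equal(nrow(pk0), 1L)
  expect_lt(abs(pk0$centroid - 211), 0.1)
  # symmetric mixture: equal areas
  tr5 <- synth_electropherogram(sspal_pair43(), 0.5, quiet)
  pk5 <- detect_peaks(tr5)
  expect_equal(nrow(pk5), 2L)
  expect_lt(abs(pk5$area[1] / pk5$area[2] - 1), 1e-6)
  expect_error(synth_electropherogram(sspal_pair43(), 1.5, quiet), "mouse_fraction")
})

test_that("noisy trace round-trips through the quantitation chain", {
  tr <- synth_electropherogram(sspal_pair43(), 0.25, trace_noise_model(seed = 3))
  est <- quant_trace(tr, sspal_pair43())
  expect_lt(abs(est[["mouse"]] - 0.25), 0.02)
})

test_that("mutation sets respect n, uniqueness, ref bases, and VAF cycling", {
  pair <- small_pair(length = 5000, seed = 2)
  expect_equal(nrow(spike_mutation_set(pair$human, 0, seed = 1)), 0L)
  muts <- spike_mutation_set(pair$human, 50, seed = 1)
  expect_equal(nrow(muts), 50L)
  expect_false(any(duplicated(paste(muts$contig, muts$pos))))
  expect_identical(muts$ref,
                   substring(pair$human$sequence, muts$pos + 1, muts$pos + 1))
  expect_true(all(muts$ref != muts$alt))
  m4 <- spike_mutation_set(pair$human, 40, vafs = c(0.05, 0.1, 0.2, 0.5),
                           seed = 9)
  expect_equal(unname(table(m4$vaf)), rep(10L, 4), ignore_attr = TRUE)
  expect_error(spike_mutation_set(pair$mouse, 10, seed = 1), "human")
})

test_that("simulated read counts, content and depth behave as specified", {
  g <- small_pair(length = 10000, divergence = 0, seed = 31)$human  # 10 kb
  reads <- simulate_reads(g, 30, 100, 0, seed = 5)
  expect_equal(nrow(reads), 3000L)  # round(30 * 10000 / 100)
  # error-free reads equal a genome substring (rc on the minus strand)
  idx <- seq(1, nrow(reads), by = 37)
  for (i in idx) {
    sub <- substring(g$sequence, reads$truth_pos[i] + 1, reads$truth_pos[i] + 100)
    expected <- if (reads$truth_strand[i] == "+") sub else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    expect_identical(reads$sequence[i], expected)
  }
  # Poisson-like depth away from contig edges
  ref <- build_reference(g, k = 15)
  aln <- align_reads(reads, ref)
  cov <- coverage(aln[aln$status == "unique", ], ref, g$name[1], 100)
  interior <- cov$depth[101:(length(cov$depth) - 100)]
  expect_lt(abs(mean(interior) - 30), 4 * sqrt(30 / length(interior)) + 0.5)
  expect_gt(var(interior) / mean(interior), 0.7)
  expect_lt(var(interior) / mean(interior), 1.3)
  expect_error(simulate_reads(g, 30, 20000, 0, seed = 1), "read_len")
})

test_that("every generator is bit-reproducible under a fixed seed", {
  cfg <- genome_pair_config(3000, 0.1,
                            list(list(locus = sspal_pair43(), offset = 700)),
                            seed = 11)
  expect_identical(make_genome_pair(cfg), make_genome_pair(cfg))
  nm <- trace_noise_model(seed = 4)
  expect_identical(synth_electropherogram(sspal_pair43(), 0.3, nm),
                   synth_electropherogram(sspal_pair43(), 0.3, nm))
  g <- small_pair(length = 4000, seed = 2)$human
  expect_identical(simulate_reads(g, 10, 100, 0.01, seed = 6),
                   simulate_reads(g, 10, 100, 0.01, seed = 6))
  expect_identical(spike_mutation_set(g, 20, seed = 8),
                   spike_mutation_set(g, 20, seed = 8))
})
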