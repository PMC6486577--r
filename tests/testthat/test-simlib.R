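spec_left <- library_spec(loxP, "left")

test_that("library sampling matches the 79/21 randomization design", {
  # degenerate: canonical_fraction 1 gives an all-canonical library
  pure <- sample_library(library_spec(loxP, "left", canonical_fraction = 1),
                         50, seed = 1)
  expect_true(all(pure$variant == loxP$left_half))
  expect_true(all(nchar(pure$umi) == 10L))

  n <- 1e5
  lib <- sample_library(spec_left, n, seed = 42)
  mism <- hamming_distance(lib$variant, loxP$left_half)
  # binomial mean 13 x 0.21 = 2.73 mutations per half-site
  expect_equal(mean(mism), 2.73, tolerance = 0.02 / 2.73)

  # per-position base frequencies 0.79 / 0.07 x 3 within 3 binomial SEs
  se79 <- sqrt(0.79 * 0.21 / n)
  se07 <- sqrt(0.07 * 0.93 / n)
  for (k in c(1L, 7L, 13L)) {
    b <- substr(lib$variant, k, k)
    canon <- substr(loxP$left_half, k, k)
    expect_lt(abs(mean(b == canon) - 0.79), 3 * se79)
    for (o in setdiff(c("A", "C", "G", "T"), canon))
      expect_lt(abs(mean(b == o) - 0.07), 3 * se07)
  }
})

test_that("selection acceptance follows p_max * prod(w)^gamma", {
  w <- uniform_weights(loxP, "left", 0.5)
  n <- 2e4

  # gamma = 0: every molecule accepted at p_max regardless of sequence
  m0 <- selection_model(w, loxP, "left", gamma = 0, p_max = 0.4)
  lib <- sample_library(spec_left, n, seed = 5)
  sel <- select_recombinants(lib, m0, seed = 6)
  expect_equal(mean(sel$recombined), 0.4, tolerance = 3 * sqrt(0.4 * 0.6 / n) / 0.4)
  mut <- hamming_distance(lib$variant, loxP$left_half) >= 2
  expect_equal(mean(sel$recombined[mut]), mean(sel$recombined[!mut]),
               tolerance = 0.05)

  # canonical half-site: acceptance exactly p_max; one w=0.5 mutation: p_max/2
  canon_lib <- data.frame(variant = rep(loxP$left_half, n),
                          umi = rep("ACGTACGTAC", n))
  single <- sub("^A", "C", loxP$left_half)  # one mutation (string pos 1)
  mut_lib <- data.frame(variant = rep(single, n), umi = rep("ACGTACGTAC", n))
  m1 <- selection_model(w, loxP, "left", gamma = 1, p_max = 0.8)
  p_can <- mean(select_recombinants(canon_lib, m1, seed = 7)$recombined)
  p_mut <- mean(select_recombinants(mut_lib, m1, seed = 8)$recombined)
  expect_equal(p_can, 0.8, tolerance = 3 * sqrt(0.8 * 0.2 / n) / 0.8)
  expect_equal(p_mut, 0.4, tolerance = 3 * sqrt(0.4 * 0.6 / n) / 0.4)
})

test_that("expected_enrichment closed form is exact and matches a Monte-Carlo oracle", {
  w <- uniform_weights(loxP, "left", 0.5)
  neutral <- selection_model(uniform_weights(loxP, "left", 1), loxP, "left")
  expect_equal(unname(expected_enrichment(neutral, spec_left)), rep(1, 13))

  m1 <- selection_model(w, loxP, "left", gamma = 1)
  m2 <- selection_model(w, loxP, "left", gamma = 2)
  # 0.21 / (3 * 0.07 * 0.5) = 2;  0.21 / (3 * 0.07 * 0.25) = 4
  expect_equal(unname(expected_enrichment(m1, spec_left)), rep(2, 13))
  expect_equal(unname(expected_enrichment(m2, spec_left)), rep(4, 13))

  # independent generative-process oracle, per-position weights
  w_var <- uniform_weights(loxP, "left",
                           w_by_position = seq(0.3, 0.9, length.out = 13))
  mv <- selection_model(w_var, loxP, "left", gamma = 1)
  r_mc <- oracle_expected_r(loxP, "left", w_var, gamma = 1, f = 0.79,
                            n = 5e5, seed = 99)
  expect_equal(unname(expected_enrichment(mv, spec_left)), r_mc,
               tolerance = 0.06)
})

test_that("read emission hits the target depth and round-trips losslessly", {
  cfg <- sim_config(3e4, 1e5, mean_reads_per_molecule = 4,
                    seq_error_rate = 0, seed = 21)
  m <- selection_model(uniform_weights(loxP, "left", 0.5), loxP, "left")
  out <- simulate_recseq(spec_left, m, cfg, withr::local_tempdir())
  # zero-truncated Poisson thinned toward n_reads: within 5% at 1e5
  expect_lt(abs(out$n_pre_reads - 1e5) / 1e5, 0.05)

  # error-free reads recover each molecule's UMI and variant exactly.
  # The only exception the extractor permits: a read whose random
  # UMI/junction happens to spell out a second core upstream of the true
  # one is sliced at the leftmost occurrence (and counted in multi_core).
  lay <- read_layout(loxP, "left")
  seqs <- read_fastq(out$pre_fastq)
  ext <- extract_reads(seqs, lay)
  expect_true(all(ext$status == "pass"))
  single_core <- lengths(gregexpr(loxP$core, seqs, fixed = TRUE)) == 1L
  pairs <- paste(ext$umi, ext$variant)
  manifest_pairs <- paste(out$manifest_df$umi, out$manifest_df$variant)
  expect_true(all(pairs[single_core] %in% manifest_pairs))
  expect_lte(sum(!pairs %in% manifest_pairs), attr(ext, "multi_core"))
})

test_that("identical seeds give byte-identical outputs", {
  cfg <- sim_config(2000, 5000, seed = 77)
  m <- selection_model(uniform_weights(loxP, "left", 0.5), loxP, "left")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  o1 <- simulate_recseq(spec_left, m, cfg, d1)
  o2 <- simulate_recseq(spec_left, m, cfg, d2)
  for (f in c("pre.fastq", "post.fastq", "manifest.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("stringency erosion: enrichment collapses to 1 as gamma -> 0", {
  w <- uniform_weights(loxP, "left", 0.5)
  gammas <- c(0, 0.5, 1, 2)
  r_by_gamma <- sapply(gammas, function(g) {
    m <- selection_model(w, loxP, "left", gamma = g)
    mean(expected_enrichment(m, spec_left))
  })
  expect_true(all(diff(r_by_gamma) > 0))
  expect_equal(r_by_gamma[1], 1)

  # measured: a gamma = 0 run is flat, a gamma = 1 run is enriched
  lay <- read_layout(loxP, "left")
  measure <- function(g, seed) {
    m <- selection_model(w, loxP, "left", gamma = g, p_max = 0.5)
    out <- simulate_recseq(spec_left, m,
                           sim_config(4e4, 3e4, seed = seed),
                           withr::local_tempdir())
    pre <- filter_reads(extract_reads(out$pre_fastq, lay))$kept
    post <- filter_reads(extract_reads(out$post_fastq, lay))$kept
    profile_r(enrichment_profile(tally_counts(pre, loxP, "left"),
                                 tally_counts(post, loxP, "left")))
  }
  r0 <- measure(0, 31); r1 <- measure(1, 32)
  expect_equal(unname(r0), rep(1, 13), tolerance = 0.1)
  expect_true(all(r1 > r0 + 0.3))
})

test_that("background survival dilutes enrichment toward 1", {
  w <- uniform_weights(loxP, "left", 0.5)
  lay <- read_layout(loxP, "left")
  run_eps <- function(eps, seed) {
    m <- selection_model(w, loxP, "left", gamma = 1, p_max = 0.05,
                         background_survival = eps)
    out <- simulate_recseq(spec_left, m, sim_config(4e4, 3e4, seed = seed),
                           withr::local_tempdir())
    pre <- filter_reads(extract_reads(out$pre_fastq, lay))$kept
    post <- filter_reads(extract_reads(out$post_fastq, lay))$kept
    profile_r(enrichment_profile(tally_counts(pre, loxP, "left"),
                                 tally_counts(post, loxP, "left")))
  }
  dev <- vapply(lapply(c(0, 0.01, 0.1), run_eps, seed = 55),
                function(r) mean(abs(log2(r))), numeric(1))
  expect_true(dev[3] < dev[2] && dev[2] < dev[1])
})

test_that("kappa falls with recombination activity at fixed background", {
  # kappa counts captured unique molecules, so it tracks how far the
  # recombined pool rises above the (fixed) surviving background
  w <- uniform_weights(loxP, "left", 0.5)
  lay <- read_layout(loxP, "left")
  kap <- vapply(c(1, 0.1, 0.01), function(pm) {
    m <- selection_model(w, loxP, "left", gamma = 1, p_max = pm,
                         background_survival = 0.02)
    out <- simulate_recseq(spec_left, m, sim_config(4e4, 3e4, seed = 56),
                           withr::local_tempdir())
    post <- filter_reads(extract_reads(out$post_fastq, lay))$kept
    kappa_score(umi_stats(post))$kappa
  }, numeric(1))
  expect_true(kap[3] < kap[2] && kap[2] < kap[1])
})
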