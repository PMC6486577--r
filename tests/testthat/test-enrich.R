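toy <- target_site("toy", "ACG", "TTAA", "CGT")  # positions 3,4,5

test_that("tally maps string columns onto center-out positions", {
  # 10 identical canonical variants
  ct <- tally_counts(rep("ACG", 10), toy, "left")
  expect_identical(rownames(ct), c("3", "4", "5"))
  for (p in rownames(ct)) {
    expect_identical(unname(ct[p, position_base(toy, "left", as.integer(p))]),
                     10L)
    expect_identical(sum(ct[p, ]), 10L)
  }

  # left side: string column 1 is the OUTERMOST position (5)
  ct2 <- tally_counts(c("ACG", "TCG"), toy, "left")
  expect_identical(unname(ct2["5", "A"]), 1L)
  expect_identical(unname(ct2["5", "T"]), 1L)
  expect_identical(unname(ct2["3", "G"]), 2L)

  # right side: string column 1 is the INNERMOST position (3)
  ct3 <- tally_counts(c("CGT", "GGT"), toy, "right")
  expect_identical(unname(ct3["3", "C"]), 1L)
  expect_identical(unname(ct3["3", "G"]), 1L)

  expect_error(tally_counts(character(0), toy, "left"), "zero reads")
  expect_error(tally_counts("ACGT", toy, "left"), "length")
})

test_that("tally is order-free", {
  withr::with_seed(2, {
    v <- sample(c("ACG", "TCG", "AAG", "ACC"), 100, TRUE)
    expect_identical(unclass(tally_counts(v, toy, "left")),
                     unclass(tally_counts(rev(v), toy, "left")))
  })
})

test_that("enrichment implements r = (A/B)/(alpha/beta)", {
  # identical pre and post tables: r = 1 exactly (pseudocounts cancel)
  ct <- tally_counts(c(rep("ACG", 8), "TCG", "ACC"), toy, "left")
  p0 <- enrichment_profile(ct, ct)
  expect_equal(p0$table$r, rep(1, 3))
  expect_equal(p0$table$log2_r, rep(0, 3))
  expect_true(all(abs(p0$per_base - 1) < 1e-12))

  # direct substitution: post A = 90k, B = 10k; pre alpha = .75
  mk <- function(canon_n, other_n) {
    m <- matrix(as.integer(other_n / 3), 3, 4,
                dimnames = list(c("3", "4", "5"), c("A", "C", "G", "T")))
    canon <- canonical_bases <- c("G", "C", "A")  # toy left innermost first
    for (i in 1:3) m[i, canon[i]] <- as.integer(canon_n)
    structure(m, class = c("count_table", "matrix"), site = toy,
              side = "left", n_reads = as.integer(canon_n + other_n))
  }
  pre <- mk(75000, 25000)
  post <- mk(90000, 10000)
  p <- enrichment_profile(pre, post)
  expect_equal(p$table$r, rep(3, 3), tolerance = 1e-3)
  expect_equal(p$table$alpha + p$table$beta, rep(1, 3))

  # mismatched sides refuse to pair
  expect_error(enrichment_profile(tally_counts("ACG", toy, "left"),
                                  tally_counts("CGT", toy, "right")),
               "pairing error")
})

test_that("per-base matrix is canonical-normalized", {
  # canonical cell is exactly 1 (log2 = 0) whatever the counts
  withr::with_seed(9, {
    v1 <- replicate(200, paste(sample(c("A", "C", "G", "T"), 3, TRUE),
                               collapse = ""))
    v2 <- replicate(300, paste(sample(c("A", "C", "G", "T"), 3, TRUE),
                               collapse = ""))
  })
  p <- enrichment_profile(tally_counts(v1, toy, "left"),
                          tally_counts(v2, toy, "left"))
  canon <- c(`3` = "G", `4` = "C", `5` = "A")
  for (pos in names(canon))
    expect_identical(unname(p$per_base[pos, canon[[pos]]]), 1)

  # a base depleted 4-fold relative to canonical: e = 0.25, log2 = -2
  pre <- matrix(c(400L, 400L, 100L, 100L), 1, 4,
                dimnames = list("1", c("A", "C", "G", "T")))
  post <- matrix(c(400L, 100L, 100L, 100L), 1, 4,
                 dimnames = list("1", c("A", "C", "G", "T")))
  one <- target_site("one", "A", "CC", "T", numbering_start = 1)
  wrap <- function(m, n) structure(m, class = c("count_table", "matrix"),
                                   site = one, side = "left", n_reads = n)
  pb <- enrichment_profile(wrap(pre, 1000L), wrap(post, 700L),
                           pseudocount = 0)$per_base
  expect_equal(unname(pb["1", "C"]), 0.25)
  expect_equal(unname(log2(pb["1", "C"])), -2)
})

test_that("r is invariant to post-count rescaling at depth", {
  # every base must be well represented for the pseudocount to vanish
  withr::with_seed(26, {
    v_pre <- do.call(paste0, lapply(1:3, function(i)
      sample(c("A", "C", "G", "T"), 40000, TRUE, c(.6, .15, .15, .1))))
    v_post <- do.call(paste0, lapply(1:3, function(i)
      sample(c("A", "C", "G", "T"), 40000, TRUE, c(.75, .1, .1, .05))))
  })
  pre <- tally_counts(v_pre, toy, "left")
  post <- tally_counts(v_post, toy, "left")
  r1 <- enrichment_profile(pre, post)$table$r
  post10 <- structure(unclass(post) * 10L, class = c("count_table", "matrix"),
                      site = toy, side = "left",
                      n_reads = attr(post, "n_reads") * 10L)
  r10 <- enrichment_profile(pre, post10)$table$r
  expect_equal(r10, r1, tolerance = 1e-3)
})

test_that("replicate aggregation is the positionwise geometric mean", {
  p2 <- profile_with_r(loxP, "left", 2)
  p8 <- profile_with_r(loxP, "left", 8)
  agg <- aggregate_profiles(list(a = p2, b = p8))
  expect_equal(unname(profile_r(agg)), rep(4, 13), tolerance = 1e-3)
  expect_identical(agg$n_replicates, 2L)

  # idempotence
  one <- aggregate_profiles(list(p2))
  expect_equal(profile_r(one), profile_r(p2))

  # log-domain oracle on random replicate values
  withr::with_seed(4, {
    ps <- lapply(1:5, function(i) profile_with_r(loxP, "left",
                                                 stats::runif(1, 0.5, 6)))
  })
  agg5 <- aggregate_profiles(ps)
  rmat <- do.call(rbind, lapply(ps, profile_r))
  expect_equal(unname(profile_r(agg5)), unname(exp(colMeans(log(rmat)))))

  expect_error(aggregate_profiles(list()), "empty")
  expect_error(aggregate_profiles(list(p2, profile_with_r(loxP, "right", 2))),
               "mix")
})

test_that("full-site assembly concatenates with primed labels", {
  left <- profile_with_r(loxP, "left", 2)
  right <- profile_with_r(loxP, "right", 3)
  fs <- assemble_full_site(left, right)
  expect_identical(nrow(fs$table), 26L)
  expect_identical(fs$table$position,
                   c(as.character(17:5), paste0(5:17, "'")))
  # no recomputation: values carried over
  expect_equal(fs$table$r, c(rep(2, 13), rep(3, 13)), tolerance = 1e-3)
  expect_error(assemble_full_site(right, left), "assembly error")

  # assembling a profile with itself (relabelled) gives a mirror-symmetric
  # full profile
  sym <- assemble_full_site(left, profile_with_r(loxP, "right", 2))
  l <- sym$table$r[sym$table$side == "left"]
  r <- sym$table$r[sym$table$side == "right"]
  expect_equal(rev(l), r, tolerance = 2e-3)
})

test_that("profiles serialize as TSV", {
  d <- withr::local_tempdir()
  p <- profile_with_r(loxP, "left", 2)
  path <- write_profile(p, file.path(d, "p.tsv"))
  tab <- utils::read.delim(path)
  expect_identical(nrow(tab), 13L)
  expect_true(all(c("position", "r", "log2_r", "log2_e_A") %in% names(tab)))
})
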