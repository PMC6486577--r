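## shared small fixtures; simulations are generated in code at test time

loxP <- builtin_site("loxP")

## brute-force positionwise mismatch count, independent of the package path
oracle_hamming <- function(a, b) {
  mapply(function(x, y) sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]]),
         a, b, USE.NAMES = FALSE)
}

## Monte-Carlo oracle for the expected enrichment ratio: simulates the
## generative selection process directly (no reads, no pipeline) and
## forms (A/B)/(alpha/beta) per position from molecule counts.
oracle_expected_r <- function(site, side, w_matrix, gamma, f, n, seed) {
  hs <- if (side == "left") site$left_half else site$right_half
  L <- nchar(hs)
  canon_k <- strsplit(hs, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    mat <- matrix("", n, L)
    for (k in seq_len(L)) {
      others <- setdiff(bases, canon_k[k])
      mat[, k] <- sample(c(canon_k[k], others), n, TRUE,
                         c(f, rep((1 - f) / 3, 3)))
    }
    p <- rep(1, n)
    for (k in seq_len(L)) {
      row <- if (side == "left") L - k + 1L else k
      p <- p * (w_matrix[row, ][match(mat[, k], bases)])^gamma
    }
    acc <- runif(n) < p
  })
  r <- numeric(L)
  for (k in seq_len(L)) {
    canonical <- mat[, k] == canon_k[k]
    A <- sum(canonical & acc); B <- sum(!canonical & acc)
    a <- sum(canonical); b <- sum(!canonical)
    row <- if (side == "left") L - k + 1L else k
    r[row] <- (A / B) / (a / b)
  }
  r
}

## random target site with given segment lengths
random_site <- function(name, l = 5L, c = 4L, r = 5L) {
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  target_site(name, rnd(l), rnd(c), rnd(r))
}

## directly construct a full-site profile with prescribed r values
## (left_r/right_r ordered innermost position first)
make_full_profile <- function(site, left_r, right_r) {
  Ll <- nchar(site$left_half); Lr <- nchar(site$right_half)
  stopifnot(length(left_r) == Ll, length(right_r) == Lr)
  li <- rev(seq_len(Ll))
  tab <- data.frame(
    position = c(position_labels(site, "left")[li],
                 position_labels(site, "right", "primed")),
    side = c(rep("left", Ll), rep("right", Lr)),
    r = c(left_r[li], right_r),
    stringsAsFactors = FALSE)
  tab$log2_r <- log2(tab$r)
  per_base <- matrix(1, nrow(tab), 4,
                     dimnames = list(tab$position, c("A", "C", "G", "T")))
  structure(list(table = tab, per_base = per_base, site = site),
            class = "full_site_profile")
}

## count-table pair engineered to give (approximately) a target r at
## every position, with counts large enough that the pseudocount is
## negligible
profile_with_r <- function(site, side, r, depth = 20000L) {
  hs <- if (side == "left") site$left_half else site$right_half
  L <- nchar(hs)
  canon <- position_base(site, side, site_positions(site, side))
  mk <- function(frac_canon) {
    m <- matrix(0L, L, 4, dimnames = list(
      as.character(site_positions(site, side)), c("A", "C", "G", "T")))
    for (i in seq_len(L)) {
      m[i, ] <- round(depth * (1 - frac_canon) / 3)
      m[i, canon[i]] <- round(depth * frac_canon)
    }
    structure(m, class = c("count_table", "matrix"), site = site,
              side = side, n_reads = depth)
  }
  pre <- mk(0.5)                      # alpha/beta = 1
  post <- mk(r / (r + 1))             # A/B = r
  enrichment_profile(pre, post)
}

## independent window-by-window scanning oracle (one strand)
oracle_scan <- function(seq_string, pattern) {
  chars <- strsplit(seq_string, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  m <- length(pat)
  starts <- integer(0)
  for (s in seq_len(length(chars) - m + 1L)) {
    win <- chars[s:(s + m - 1L)]
    ok <- all(win %in% c("A", "C", "G", "T")) &&
      all(pat == "N" | pat == win)
    if (ok) starts <- c(starts, s)
  }
  starts
}

tre_profile <- function() {
  ltr <- builtin_site("loxLTR")
  left_r <- rep(1, 13); right_r <- rep(1, 13)
  names(left_r) <- names(right_r) <- as.character(5:17)
  left_r[as.character(c(14, 13, 11, 8, 7, 6, 5))] <- 3
  right_r[as.character(c(5, 6, 7, 10, 11, 12))] <- 3
  make_full_profile(ltr, left_r, right_r)
}

brec1_profile <- function() {
  btr <- builtin_site("loxBTR")
  left_r <- rep(1, 13); right_r <- rep(1, 13)
  names(left_r) <- names(right_r) <- as.character(5:17)
  left_r[as.character(c(11, 9, 7, 6, 5))] <- 2.5
  right_r[as.character(c(5, 6, 7, 10, 12, 13))] <- 2.5
  make_full_profile(btr, left_r, right_r)
}

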