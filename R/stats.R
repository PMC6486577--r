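#' Per-position two-sample t-tests between enzyme variants
#'
#' Pooled-variance (equal-variance) two-sample Student's t-test at each
#' full-site position, comparing log2 enrichment of a variant enzyme's
#' replicates against a reference enzyme's replicates, with Bonferroni
#' correction over the family of positions.
#'
#' @param variant,reference numeric matrices, replicates x positions, of
#'   log2 enrichment values; identical column labels.
#' @param alpha significance level applied to the adjusted p-values.
#' @param family Bonferroni family size; defaults to the number of
#'   positions.
#' @return data.frame with columns `position`, `mean_variant`,
#'   `mean_reference`, `t`, `p`, `p_adj`, `significant`.
#' @export
per_position_test <- function(variant, reference, alpha = 0.05,
                              family = NULL) {
  variant <- as.matrix(variant); reference <- as.matrix(reference)
  if (nrow(variant) < 2L || nrow(reference) < 2L)
    stop("insufficient-replicates error: need >= 2 replicates per group",
         call. = FALSE)
  if (ncol(variant) != ncol(reference))
    stop("position sets differ between groups", call. = FALSE)
  if (is.null(family)) family <- ncol(variant)
  n1 <- nrow(variant); n2 <- nrow(reference)
  m1 <- colMeans(variant); m2 <- colMeans(reference)
  v1 <- apply(variant, 2L, stats::var)
  v2 <- apply(reference, 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m1 - m2) / se, ifelse(m1 == m2, 0, Inf))
  p <- ifelse(is.finite(tstat),
              2 * stats::pt(-abs(tstat), df = n1 + n2 - 2), 0)
  p[tstat == 0] <- 1
  p_adj <- pmin(1, p * family)
  data.frame(
    position = colnames(variant) %||% as.character(seq_along(m1)),
    mean_variant = m1, mean_reference = m2, t = tstat, p = p,
    p_adj = p_adj, significant = p_adj <= alpha,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from ranks with average-tie handling.  For pooled sample
#' sizes up to `exact_max` the two-sided p-value is exact, obtained by
#' full enumeration of all assignments of the pooled values to the two
#' groups (correct under ties); beyond that a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest pooled size for exact enumeration.
#' @return list with `U` (statistic of `x`), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  if (N <= exact_max) {
    idx <- utils::combn(N, n1)
    Us <- apply(idx, 2L, function(i) sum(rk[i]) - n1 * (n1 + 1) / 2)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tie_term))
    if (sigma == 0) return(list(U = U, p = 1, method = "degenerate"))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p = p, method = method)
}

#' Whole-profile difference test between enzyme variants
#'
#' Tests whether a variant enzyme's full-site log-enrichment profile
#' differs from a reference enzyme's by comparing the absolute residuals.
#' The residual of a replicate at a position is its log2 enrichment minus
#' the reference group's mean log2 enrichment at that position; the pooled
#' absolute residuals of the two groups are compared with a two-sided
#' Mann-Whitney U test, Bonferroni-corrected over the number of variants
#' in the comparison batch.
#'
#' @param variant,reference numeric matrices, replicates x positions, of
#'   log2 enrichment values.
#' @param n_comparisons Bonferroni family size (number of enzyme variants
#'   compared in the analysis run).
#' @return list with `U`, `p`, `p_adj`, `method`, group sizes.
#' @export
profile_test <- function(variant, reference, n_comparisons = 1L) {
  variant <- as.matrix(variant); reference <- as.matrix(reference)
  if (nrow(variant) == 0L || nrow(reference) == 0L)
    stop("profile_test: empty group", call. = FALSE)
  if (ncol(variant) != ncol(reference))
    stop("position sets differ between groups", call. = FALSE)
  ref_mean <- colMeans(reference)
  res_var <- abs(sweep(variant, 2L, ref_mean))
  res_ref <- abs(sweep(reference, 2L, ref_mean))
  mw <- mann_whitney_u(as.numeric(res_var), as.numeric(res_ref))
  list(U = mw$U, p = mw$p, p_adj = min(1, mw$p * n_comparisons),
       method = mw$method,
       n_variant = length(res_var), n_reference = length(res_ref))
}

#' Left/right half-site asymmetry test
#'
#' Pairs each left half-site position with its mirrored right half-site
#' position (same center-out number) and applies a paired two-sided
#' t-test to the log2 enrichment differences.  A perfectly palindromic
#' preference gives t = 0, p = 1.
#'
#' @param left,right numeric vectors of log2 enrichment values at
#'   mirrored positions (innermost first), or a `full_site_profile` as
#'   the single first argument.
#' @return list with `t`, `df`, `p`, `mean_difference`, and `degenerate`
#'   (TRUE when all differences are equal and non-zero, reported as
#'   p -> 0 with a warning).
#' @export
asymmetry_test <- function(left, right = NULL) {
  if (inherits(left, "full_site_profile")) {
    tab <- left$table
    l <- tab$log2_r[tab$side == "left"]
    r <- tab$log2_r[tab$side == "right"]
    ## left half printed outermost-first; mirror pairing wants matching
    ## center-out numbers
    left <- rev(l); right <- r
  }
  if (length(left) != length(right))
    stop("pairing error: half-sites have unequal position counts",
         call. = FALSE)
  if (length(left) < 2L)
    stop("pairing error: need >= 2 paired observations", call. = FALSE)
  d <- left - right
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_difference = 0,
                  degenerate = FALSE))
    warning("degenerate variance: all paired differences identical and ",
            "non-zero; p reported as 0")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  list(t = tstat, df = n - 1,
       p = 2 * stats::pt(-abs(tstat), df = n - 1),
       mean_difference = mean(d), degenerate = FALSE)
}

#' Feature matrix of replicate profiles
#'
#' One row per experiment replicate, columns the log2 enrichment values
#' over all full-site positions — the exact input used for
#' similarity-embedding visualisations of replicate profiles.
#'
#' @param profiles named list of `full_site_profile`s (or
#'   `enrichment_profile`s sharing site/side).
#' @return numeric matrix with replicate row names and position column
#'   names; no missing cells.
#' @export
feature_matrix <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  rows <- lapply(profiles, function(p) {
    tab <- p$table
    v <- tab$log2_r
    names(v) <- tab$position
    v
  })
  cols <- names(rows[[1L]])
  for (v in rows)
    if (!identical(names(v), cols))
      stop("inconsistent position sets across profiles", call. = FALSE)
  m <- do.call(rbind, rows)
  if (is.null(rownames(m)) || any(!nzchar(rownames(m))))
    rownames(m) <- paste0("replicate", seq_len(nrow(m)))
  if (anyNA(m)) stop("feature matrix contains missing cells", call. = FALSE)
  m
}

#' 2-D embedding of a feature matrix
#'
#' Delegated, deterministic embedding for visualisation only (classical
#' multidimensional scaling on Euclidean row distances); the feature
#' matrix itself is the exact, exported artefact.
#'
#' @param fm matrix from [feature_matrix()].
#' @return matrix n x 2 of coordinates.
#' @export
embed_profiles <- function(fm) {
  stopifnot(is.matrix(fm))
  k <- min(2L, nrow(fm) - 1L)
  coords <- stats::cmdscale(stats::dist(fm), k = k)
  if (ncol(coords) < 2L)
    coords <- cbind(coords, 0)
  colnames(coords) <- c("dim1", "dim2")
  coords
}
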