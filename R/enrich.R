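#' Per-position base counts of a sample
#'
#' Tabulates, for every center-out half-site position, how many kept reads
#' carry each base.  Row order is innermost position first (e.g. 5..17 for
#' a Cre-family site); rows sum to the read count at every position.
#'
#' @param variants character vector of half-site variant strings (genome
#'   orientation), or the `kept` data.frame from [filter_reads()].
#' @param site a `target_site`.
#' @param side which half-site the variants came from.
#' @return an object of class `count_table`: integer matrix positions x
#'   A/C/G/T with attributes `site`, `side`, `n_reads`.
#' @export
tally_counts <- function(variants, site, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(site, "target_site"))
  if (is.data.frame(variants)) variants <- variants$variant
  if (length(variants) == 0L)
    stop("tally error: zero reads (experiment unusable)", call. = FALSE)
  hs <- half_site(site, side)
  L <- nchar(hs)
  if (any(nchar(variants) != L))
    stop("variant length does not match the half-site", call. = FALSE)
  positions <- site_positions(site, side)
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(as.character(positions), DNA_BASES))
  for (k in seq_len(L)) {
    row <- if (side == "left") L - k + 1L else k
    tab <- table(factor(substr(variants, k, k), levels = DNA_BASES))
    counts[row, ] <- as.integer(tab)
  }
  structure(counts, class = c("count_table", "matrix"),
            site = site, side = side, n_reads = length(variants))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %s %s half-site, %d reads\n",
              attr(x, "site")$name, attr(x, "side"), attr(x, "n_reads")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

canonical_bases <- function(site, side) {
  position_base(site, side, site_positions(site, side))
}

#' Per-position enrichment profile
#'
#' For each half-site position i the post-selection counts of the
#' canonical base (A_i) and of the non-canonical bases summed (B_i) are
#' compared with the pre-selection (input library) fractions alpha_i and
#' beta_i via the enrichment score
#' \deqn{r_i = (A_i/B_i) / (\alpha_i/\beta_i).}
#' Values above 1 indicate preference for the canonical base.  A
#' pseudocount is added to all four aggregates before forming ratios so
#' zero counts cannot produce divisions by zero; at typical read depths
#' (1e5-1e6) its effect is negligible.
#'
#' Also computes the per-base matrix used for heat maps:
#' `e[i, b] = (F_post(i,b)/F_pre(i,b)) / (F_post(i,c)/F_pre(i,c))` with
#' pseudocounted frequencies F and canonical base c, so `e[i, c] = 1`
#' (log2 = 0) exactly.
#'
#' @param pre,post `count_table`s of the input library and the
#'   post-selection sample for the same site/side.
#' @param pseudocount added to count aggregates (default 0.5).
#' @param replicate_id optional label.
#' @return an object of class `enrichment_profile`: list with `table`
#'   (data.frame position/A/B/alpha/beta/r/log2_r), `per_base` (matrix of
#'   e values), `site`, `side`, `replicate_id`.
#' @export
enrichment_profile <- function(pre, post, pseudocount = 0.5,
                               replicate_id = NA_character_) {
  stopifnot(inherits(pre, "count_table"), inherits(post, "count_table"))
  same <- identical(attr(pre, "site")$name, attr(post, "site")$name) &&
    identical(attr(pre, "side"), attr(post, "side"))
  if (!same)
    stop("pairing error: pre and post count tables refer to different ",
         "sites or sides", call. = FALSE)
  site <- attr(pre, "site"); side <- attr(pre, "side")
  canon <- canonical_bases(site, side)
  L <- nrow(pre)
  pc <- pseudocount

  A <- B <- a_pre <- b_pre <- numeric(L)
  for (i in seq_len(L)) {
    c_i <- canon[i]
    nc <- setdiff(DNA_BASES, c_i)
    A[i] <- post[i, c_i] + pc
    B[i] <- sum(post[i, nc]) + pc
    a_pre[i] <- pre[i, c_i] + pc
    b_pre[i] <- sum(pre[i, nc]) + pc
  }
  alpha <- a_pre / (a_pre + b_pre)
  beta <- b_pre / (a_pre + b_pre)
  r <- (A / B) / (alpha / beta)

  ## per-base heat-map matrix, canonical-normalized frequency ratio
  Fpost <- (unclass(post) + pc) / rowSums(unclass(post) + pc)
  Fpre <- (unclass(pre) + pc) / rowSums(unclass(pre) + pc)
  ratio <- Fpost / Fpre
  canon_ratio <- ratio[cbind(seq_len(L), match(canon, DNA_BASES))]
  e <- ratio / canon_ratio

  tab <- data.frame(position = rownames(pre), A = A, B = B,
                    alpha = alpha, beta = beta, r = r, log2_r = log2(r),
                    stringsAsFactors = FALSE)
  structure(
    list(table = tab, per_base = e, site = site, side = side,
         replicate_id = replicate_id, pseudocount = pc),
    class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf("enrichment_profile: %s %s half-site%s\n", x$site$name,
              x$side,
              if (!is.na(x$replicate_id)) paste0(" [", x$replicate_id, "]")
              else ""))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Enrichment ratios of a profile
#'
#' @param profile an `enrichment_profile` or `full_site_profile`.
#' @return named numeric vector of r values (names = position labels).
#' @export
profile_r <- function(profile) {
  if (inherits(profile, "full_site_profile")) {
    r <- profile$table$r
    names(r) <- profile$table$position
    return(r)
  }
  stopifnot(inherits(profile, "enrichment_profile"))
  r <- profile$table$r
  names(r) <- profile$table$position
  r
}

#' Geometric-mean aggregation of replicate profiles
#'
#' Positionwise geometric mean of r_i (and of the per-base matrices)
#' across independent replicates of the same site/side, the convention
#' used for all reported profiles.  Per-replicate values are retained for
#' plotting.
#'
#' @param replicates list of `enrichment_profile`s with identical
#'   site/side.
#' @return an `enrichment_profile` with `replicate_id = "aggregate"`,
#'   extra fields `n_replicates` and `replicate_r` (matrix replicate x
#'   position).
#' @export
aggregate_profiles <- function(replicates) {
  if (inherits(replicates, "enrichment_profile")) replicates <- list(replicates)
  if (length(replicates) == 0L)
    stop("aggregation error: empty replicate set", call. = FALSE)
  ref <- replicates[[1L]]
  for (p in replicates) {
    stopifnot(inherits(p, "enrichment_profile"))
    if (!identical(p$site$name, ref$site$name) ||
        !identical(p$side, ref$side))
      stop("aggregation error: replicates mix sites or sides", call. = FALSE)
  }
  rmat <- do.call(rbind, lapply(replicates, function(p) p$table$r))
  colnames(rmat) <- ref$table$position
  r <- exp(colMeans(log(rmat)))
  e <- exp(Reduce(`+`, lapply(replicates, function(p) log(p$per_base))) /
             length(replicates))
  tab <- ref$table
  tab$A <- tab$B <- tab$alpha <- tab$beta <- NULL
  tab$r <- unname(r)
  tab$log2_r <- log2(tab$r)
  out <- ref
  out$table <- tab
  out$per_base <- e
  out$replicate_id <- "aggregate"
  out$n_replicates <- length(replicates)
  out$replicate_r <- rmat
  out
}

#' Position labels for one half-site
#'
#' @param site a `target_site`.
#' @param side `"left"` or `"right"`.
#' @param style `"plain"` (bare numbers) or `"primed"` (right-half
#'   positions suffixed with a prime, the printed convention).
#' @return character vector of labels, innermost position first.
#' @export
position_labels <- function(site, side = c("left", "right"),
                            style = c("primed", "plain")) {
  side <- match.arg(side)
  style <- match.arg(style)
  pos <- site_positions(site, side)
  if (side == "right" && style == "primed") paste0(pos, "'")
  else as.character(pos)
}

#' Assemble a full-site profile from the two half-site experiments
#'
#' Specificity over a full target is read out from two experiments — one
#' with the left half-site randomized, one with the right — and assembled
#' by concatenating their enrichment values (no recomputation).  Position
#' order follows the printed site left to right: outermost left position
#' first, then inward, then the right half outward with primed labels.
#'
#' @param left profile from the left-randomized experiment.
#' @param right profile from the right-randomized experiment.
#' @return an object of class `full_site_profile`: list with `table`
#'   (position label, side, r, log2_r), `per_base`, `site`.
#' @export
assemble_full_site <- function(left, right) {
  stopifnot(inherits(left, "enrichment_profile"),
            inherits(right, "enrichment_profile"))
  if (left$side != "left" || right$side != "right")
    stop("assembly error: need one left-randomized and one ",
         "right-randomized profile", call. = FALSE)
  if (!identical(left$site$name, right$site$name))
    stop("assembly error: profiles come from different sites", call. = FALSE)
  site <- left$site
  ## left half printed outermost-first; profiles store innermost-first
  li <- rev(seq_len(nrow(left$per_base)))
  ri <- seq_len(nrow(right$per_base))
  tab <- data.frame(
    position = c(position_labels(site, "left")[li],
                 position_labels(site, "right", "primed")[ri]),
    side = c(rep("left", length(li)), rep("right", length(ri))),
    r = c(left$table$r[li], right$table$r[ri]),
    log2_r = c(left$table$log2_r[li], right$table$log2_r[ri]),
    stringsAsFactors = FALSE)
  per_base <- rbind(left$per_base[li, , drop = FALSE],
                    right$per_base[ri, , drop = FALSE])
  rownames(per_base) <- tab$position
  structure(list(table = tab, per_base = per_base, site = site),
            class = "full_site_profile")
}

#' @export
print.full_site_profile <- function(x, ...) {
  cat(sprintf("full_site_profile: %s (%d positions)\n", x$site$name,
              nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a profile as TSV
#'
#' @param profile an `enrichment_profile` or `full_site_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  tab <- profile$table
  lg <- log2(profile$per_base)
  colnames(lg) <- paste0("log2_e_", colnames(lg))
  utils::write.table(cbind(tab, as.data.frame(lg)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
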