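#' Per-variant read and UMI statistics
#'
#' One record per distinct half-site variant in the post-selection sample:
#' its read count, percent abundance (100 x reads/total) and the number of
#' distinct UMIs observed for it.  UMIs are deduplicated by exact string
#' match (no error-tolerant clustering).
#'
#' @param kept data.frame with columns `variant` and `umi` (e.g. the
#'   `kept` component of [filter_reads()]).
#' @return data.frame with columns `variant`, `reads`, `percent`, `umis`,
#'   sorted by decreasing read count.
#' @export
umi_stats <- function(kept) {
  stopifnot(is.data.frame(kept), all(c("variant", "umi") %in% names(kept)))
  if (nrow(kept) == 0L)
    stop("quality error: zero reads", call. = FALSE)
  reads <- table(kept$variant)
  key <- !duplicated(paste0(kept$variant, "\r", kept$umi))
  umis <- table(kept$variant[key])
  variants <- names(reads)
  out <- data.frame(
    variant = variants,
    reads = as.integer(reads),
    percent = 100 * as.integer(reads) / nrow(kept),
    umis = as.integer(umis[variants]),
    stringsAsFactors = FALSE)
  out[order(-out$reads), , drop = FALSE]
}

#' Experiment quality score kappa
#'
#' kappa is derived from the relationship between how abundant each
#' sequence variant is in the post-selection library and how many distinct
#' UMIs (independent molecules) support it: the slope of the best-fit
#' (ordinary least squares) line, divided by 1e4.  A large kappa means the
#' enrichment signal is backed by many independent recombination events;
#' with homogeneous read sampling, kappa * 1e6 approximates the number of
#' distinct post-selection molecules.
#'
#' The default regresses UMI count on percent abundance, which makes kappa
#' track captured recombination events; `orientation =
#' "abundance_on_umi"` gives the transposed (literal plotting-order) fit.
#'
#' @param stats data.frame from [umi_stats()].
#' @param orientation which variable is the regression response.
#' @return an object of class `kappa_result`: list with `slope`,
#'   `intercept`, `r_squared`, `kappa`, `n_variants`.
#' @export
kappa_score <- function(stats,
                        orientation = c("umi_on_abundance",
                                        "abundance_on_umi")) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(stats), all(c("percent", "umis") %in% names(stats)))
  if (nrow(stats) < 2L)
    stop("degenerate-fit error: need >= 2 distinct variants", call. = FALSE)
  x <- if (orientation == "umi_on_abundance") stats$percent else stats$umis
  y <- if (orientation == "umi_on_abundance") stats$umis else stats$percent
  x <- as.numeric(x); y <- as.numeric(y)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    stop("degenerate-fit error: zero variance in the regressor", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         kappa = slope / 1e4, n_variants = nrow(stats),
         orientation = orientation),
    class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa = %.3f (slope %.1f, r^2 %.3f, %d variants)\n",
              x$kappa, x$slope, x$r_squared, x$n_variants))
  invisible(x)
}

#' Classify experiment power from replicate kappa values
#'
#' kappa_avg is the arithmetic mean over replicates; experiments are
#' well-powered when kappa_avg exceeds 1.5, modestly influenced by
#' background between 0.5 and 1.5, and heavily influenced by background
#' below 0.5.
#'
#' @param kappas numeric vector of per-replicate kappa values (or a list
#'   of `kappa_result`s).
#' @return list with `kappa_avg` and `label` (one of `well_powered`,
#'   `modest_background`, `heavy_background`).
#' @export
classify_power <- function(kappas) {
  if (is.list(kappas))
    kappas <- vapply(kappas, function(k) k$kappa, numeric(1))
  stopifnot(is.numeric(kappas), length(kappas) >= 1L)
  kavg <- mean(kappas)
  label <- if (kavg > 1.5) "well_powered"
           else if (kavg >= 0.5) "modest_background"
           else "heavy_background"
  list(kappa_avg = kavg, label = label)
}
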