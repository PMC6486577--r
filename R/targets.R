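#' Recombinase target sites
#'
#' A target site is the recognition sequence of a site-specific recombinase
#' (SSR): a left half-site and a right half-site flanking a central core
#' (spacer) where strand exchange occurs.  For the Cre family the site is
#' 34 bp: two 13-bp inverted-repeat half-sites around an asymmetric 8-bp
#' core.  Half-site positions are numbered center-out: the innermost base
#' (adjacent to the core) gets `numbering_start`, increasing outward.  For
#' an 8-bp core the default start is 8/2 + 1 = 5, so Cre-family half-site
#' positions run 5..17.  Right-half positions are conventionally rendered
#' with a prime (e.g. 10').
#'
#' @param name short identifier, e.g. `"loxP"`.
#' @param left_half,core,right_half DNA strings (A/C/G/T; case-folded).
#' @param numbering_start integer position assigned to the innermost
#'   half-site base.  Default `nchar(core)/2 + 1`.
#' @return an object of class `target_site`.
#' @examples
#' lox <- builtin_site("loxP")
#' position_base(lox, "left", 5)
#' @export
target_site <- function(name, left_half, core, right_half,
                        numbering_start = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  left_half <- clean_dna(left_half, "left_half")
  core <- clean_dna(core, "core")
  right_half <- clean_dna(right_half, "right_half")
  if (is.null(numbering_start)) numbering_start <- nchar(core) %/% 2 + 1L
  numbering_start <- as.integer(numbering_start)
  stopifnot(numbering_start >= 1L)
  structure(
    list(name = name, left_half = left_half, core = core,
         right_half = right_half, numbering_start = numbering_start),
    class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("target_site '%s' (%d bp)\n", x$name, nchar(site_sequence(x))))
  cat(sprintf("  left  %s  [positions %d..%d]\n", x$left_half,
              x$numbering_start, x$numbering_start + nchar(x$left_half) - 1L))
  cat(sprintf("  core  %s\n", x$core))
  cat(sprintf("  right %s  [positions %d'..%d']\n", x$right_half,
              x$numbering_start, x$numbering_start + nchar(x$right_half) - 1L))
  invisible(x)
}

#' Full site sequence
#'
#' @param site a `target_site`.
#' @return the concatenated left half + core + right half string.
#' @export
site_sequence <- function(site) {
  stopifnot(inherits(site, "target_site"))
  paste0(site$left_half, site$core, site$right_half)
}

half_site <- function(site, side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") site$left_half else site$right_half
}

#' Center-out half-site position numbers
#'
#' @param site a `target_site`.
#' @param side `"left"` or `"right"`.
#' @return integer vector of position numbers, innermost first.
#' @export
site_positions <- function(site, side = c("left", "right")) {
  side <- match.arg(side)
  hs <- half_site(site, side)
  seq.int(site$numbering_start, length.out = nchar(hs))
}

#' Canonical base at a center-out half-site position
#'
#' The left half-site is read outward toward the 5' end (right-to-left in
#' the printed sequence); the right half-site outward toward the 3' end.
#'
#' @param site a `target_site`.
#' @param side `"left"` or `"right"`.
#' @param index center-out position number
#'   (`numbering_start .. numbering_start + half length - 1`).
#' @return single base.
#' @export
position_base <- function(site, side = c("left", "right"), index) {
  side <- match.arg(side)
  stopifnot(inherits(site, "target_site"))
  hs <- half_site(site, side)
  L <- nchar(hs)
  ns <- site$numbering_start
  index <- as.integer(index)
  if (any(index < ns | index >= ns + L))
    stop(sprintf("position %s out of range %d..%d for %s half-site of '%s'",
                 paste(index[index < ns | index >= ns + L], collapse = ","),
                 ns, ns + L - 1L, side, site$name), call. = FALSE)
  k <- if (side == "left") L - (index - ns) else index - ns + 1L
  substring(hs, k, k)
}

#' Fraction of diverged positions between two sites
#'
#' Positionwise (Hamming) mismatch fraction between two sites of identical
#' segment lengths, e.g. loxP vs the evolved targets loxLTR (50%) and
#' loxBTR (68%).
#'
#' @param a,b `target_site` objects with identical segment lengths.
#' @param include_core compare the core as well as the half-sites.
#' @return fraction in `[0, 1]`.
#' @export
percent_divergence <- function(a, b, include_core = TRUE) {
  stopifnot(inherits(a, "target_site"), inherits(b, "target_site"))
  same <- nchar(a$left_half) == nchar(b$left_half) &&
    nchar(a$core) == nchar(b$core) &&
    nchar(a$right_half) == nchar(b$right_half)
  if (!same)
    stop(sprintf("sites '%s' and '%s' have incompatible segment lengths",
                 a$name, b$name), call. = FALSE)
  sa <- if (include_core) site_sequence(a) else paste0(a$left_half, a$right_half)
  sb <- if (include_core) site_sequence(b) else paste0(b$left_half, b$right_half)
  hamming_distance(sa, sb) / nchar(sa)
}

#' Replace the core with its reverse complement
#'
#' Models the "inverted core" control library: half-sites unchanged, the
#' (generally non-palindromic) core reverse-complemented.
#'
#' @param site a `target_site`.
#' @return a new `target_site`.
#' @export
invert_core <- function(site) {
  stopifnot(inherits(site, "target_site"))
  target_site(paste0(site$name, "-invcore"), site$left_half,
              revcomp(site$core), site$right_half, site$numbering_start)
}

#' Bundled target-site definitions
#'
#' `loxP` is the 34-bp Cre target; `loxLTR` and `loxBTR` are the targets of
#' the evolved variants Tre and Brec1 (50% and 68% diverged from loxP).
#' Definitions for further sites (rox, loxV, attP, attB) are left to the
#' user via [read_sites()] since their half-site/core partitions and
#' numbering conventions vary.
#'
#' @param name one of `"loxP"`, `"loxLTR"`, `"loxBTR"`.
#' @return a `target_site`.
#' @export
builtin_site <- function(name = c("loxP", "loxLTR", "loxBTR")) {
  name <- match.arg(name)
  switch(name,
    loxP   = target_site("loxP",   "ATAACTTCGTATA", "ATGTATGC", "TATACGAAGTTAT"),
    loxLTR = target_site("loxLTR", "ACAACATCCTATT", "ACACCCTA", "TATGCCAACATGG"),
    loxBTR = target_site("loxBTR", "AACCCACTGCTTA", "AGCCTCAA", "TAAAGCTTGCCTT"))
}

#' Read target-site definitions from a plain-text config
#'
#' Blocks of `key = value` lines separated by blank lines; keys `name`,
#' `left_half`, `core`, `right_half` and optional `numbering_start`.
#' Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return named list of `target_site` objects.
#' @export
read_sites <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  sites <- list()
  for (blk in blocks) {
    blk <- trimws(blk[nzchar(trimws(blk))])
    if (!length(blk)) next
    kv <- strsplit(blk, "\\s*=\\s*")
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, `[`, character(1), 2L)
    names(vals) <- keys
    need <- c("name", "left_half", "core", "right_half")
    if (!all(need %in% keys))
      stop("site block missing keys: ",
           paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
    ns <- if ("numbering_start" %in% keys)
      as.integer(vals[["numbering_start"]]) else NULL
    s <- target_site(vals[["name"]], vals[["left_half"]], vals[["core"]],
                     vals[["right_half"]], ns)
    sites[[s$name]] <- s
  }
  sites
}
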