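#' Read layout of a selection-library amplicon
#'
#' Describes how a sequencing read is assembled: 5' flank, UMI, full target
#' site (left half + core + right half), 3' flank.  One half-site per
#' experiment is randomized; the core is constant and serves as the exact
#' alignment anchor.
#'
#' @param site a `target_site`.
#' @param randomized_side `"left"` or `"right"`.
#' @param umi_length UMI barcode length (nt).
#' @param flank_5p,flank_3p constant sequences flanking the UMI + substrate
#'   (stand-ins for the hairpin/priming regions; may be empty strings).
#' @param search_both_strands also try the reverse complement of a read
#'   when the core is not found on the forward strand.
#' @return an object of class `read_layout`.
#' @export
read_layout <- function(site, randomized_side = c("left", "right"),
                        umi_length = 10L,
                        flank_5p = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
                        flank_3p = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                        search_both_strands = TRUE) {
  stopifnot(inherits(site, "target_site"))
  randomized_side <- match.arg(randomized_side)
  umi_length <- as.integer(umi_length)
  stopifnot(umi_length >= 1L)
  flank_5p <- clean_dna(flank_5p, "flank_5p", allow_empty = TRUE)
  flank_3p <- clean_dna(flank_3p, "flank_3p", allow_empty = TRUE)
  structure(
    list(site = site, randomized_side = randomized_side,
         umi_length = umi_length, flank_5p = flank_5p, flank_3p = flank_3p,
         search_both_strands = isTRUE(search_both_strands)),
    class = "read_layout")
}

## expected read for a given half-site variant (error-free)
assemble_read <- function(layout, variant) {
  s <- layout$site
  left <- if (layout$randomized_side == "left") variant
          else rep(s$left_half, length(variant))
  right <- if (layout$randomized_side == "right") variant
           else rep(s$right_half, length(variant))
  list(left = left, right = right)
}

#' Hamming distance between equal-length strings
#'
#' Gap-free positionwise mismatch count; vectorised over pairs.
#'
#' @param a,b character vectors of equal-length strings (recycled).
#' @return integer vector of mismatch counts.
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b)))
    stop("hamming_distance requires equal-length strings (gap-free comparison)",
         call. = FALSE)
  w <- nchar(a[1L])
  if (length(unique(nchar(a))) > 1L) {
    return(mapply(function(x, y) {
      sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
    }, a, b, USE.NAMES = FALSE))
  }
  d <- integer(n)
  for (j in seq_len(w)) d <- d + (substr(a, j, j) != substr(b, j, j))
  d
}

#' Extract half-site variants and UMIs from reads
#'
#' Locates the exact target core in each read (forward strand first, then
#' the reverse complement when enabled), then slices the randomized
#' half-site and the UMI at fixed offsets relative to the core.  No gaps
#' are permitted anywhere; the core must match exactly.  Mismatches are
#' counted over the randomized half-site against the canonical half-site.
#'
#' @param seqs character vector of read sequences, or a file path to a
#'   FASTQ file (plain or gzip).
#' @param layout a `read_layout`.
#' @return data.frame with columns `variant`, `umi`, `mismatches`,
#'   `status` (one of `pass`, `fail_no_core`, `fail_malformed`) and
#'   `strand`; attribute `multi_core` counts reads whose matched strand
#'   contains the core more than once (leftmost occurrence used).
#' @export
extract_reads <- function(seqs, layout) {
  stopifnot(inherits(layout, "read_layout"))
  if (length(seqs) == 1L && file.exists(seqs)) seqs <- read_fastq(seqs)
  seqs <- toupper(seqs)
  s <- layout$site
  core <- s$core
  Ll <- nchar(s$left_half); Lr <- nchar(s$right_half)
  um <- layout$umi_length

  pos <- as.integer(regexpr(core, seqs, fixed = TRUE))
  strand <- rep("+", length(seqs))
  if (layout$search_both_strands && any(pos < 0L)) {
    miss <- which(pos < 0L)
    rc <- revcomp(seqs[miss])
    p2 <- as.integer(regexpr(core, rc, fixed = TRUE))
    hit2 <- p2 > 0L
    seqs[miss[hit2]] <- rc[hit2]
    pos[miss[hit2]] <- p2[hit2]
    strand[miss[hit2]] <- "-"
  }

  n <- length(seqs)
  variant <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  status <- rep("fail_no_core", n)

  found <- pos > 0L
  ## count second core occurrences on the matched strand (report only)
  multi <- 0L
  if (any(found)) {
    after <- substr(seqs[found], pos[found] + 1L, nchar(seqs[found]))
    multi <- sum(grepl(core, after, fixed = TRUE))
  }

  if (any(found)) {
    i <- which(found)
    cs <- pos[i]
    left_start <- cs - Ll
    umi_start <- left_start - um
    right_end <- cs + nchar(core) + Lr - 1L
    ok <- umi_start >= 1L & right_end <= nchar(seqs[i])
    status[i[!ok]] <- "fail_malformed"
    j <- i[ok]
    if (length(j)) {
      cj <- pos[j]
      if (layout$randomized_side == "left") {
        variant[j] <- substr(seqs[j], cj - Ll, cj - 1L)
        ref <- s$left_half
      } else {
        variant[j] <- substr(seqs[j], cj + nchar(core),
                             cj + nchar(core) + Lr - 1L)
        ref <- s$right_half
      }
      umi[j] <- substr(seqs[j], cj - Ll - um, cj - Ll - 1L)
      mism[j] <- hamming_distance(variant[j], ref)
      status[j] <- "pass"
    }
  }

  out <- data.frame(variant = variant, umi = umi, mismatches = mism,
                    status = status, strand = strand,
                    stringsAsFactors = FALSE)
  attr(out, "multi_core") <- multi
  out
}

#' Apply the mismatch filter
#'
#' Keeps successfully extracted reads with at most `max_mismatches`
#' half-site mismatches relative to the canonical sequence.  Reads with
#' more mismatches are treated as sequencing artefacts (e.g. indels, which
#' inflate the gap-free mismatch count) and discarded.
#'
#' @param extracted data.frame from [extract_reads()].
#' @param max_mismatches mismatch ceiling (default 6: reads with more than
#'   six mismatches are removed).
#' @return list with `kept` (data.frame of passing reads) and `report`
#'   (named counts per outcome class; sums to the input count).
#' @export
filter_reads <- function(extracted, max_mismatches = 6L) {
  stopifnot(is.data.frame(extracted))
  if (nrow(extracted) == 0L) {
    warning("no reads to filter")
    report <- c(total = 0L, kept = 0L, fail_no_core = 0L,
                fail_malformed = 0L, fail_too_many_mismatches = 0L)
    return(list(kept = extracted, report = report))
  }
  status <- extracted$status
  too_many <- status == "pass" & extracted$mismatches > max_mismatches
  status[too_many] <- "fail_too_many_mismatches"
  kept <- extracted[status == "pass", , drop = FALSE]
  report <- c(total = nrow(extracted),
              kept = sum(status == "pass"),
              fail_no_core = sum(status == "fail_no_core"),
              fail_malformed = sum(status == "fail_malformed"),
              fail_too_many_mismatches = sum(too_many),
              multi_core = attr(extracted, "multi_core") %||% 0L)
  list(kept = kept, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read sequences from a FASTQ file
#'
#' @param path FASTQ file, plain or gzip.  Quality scores are discarded
#'   (no quality filtering is applied anywhere in the pipeline).
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x, use.names = FALSE)
}

#' Write reads to a FASTQ file
#'
#' Constant quality scores ('I' = Q40); read ids are `prefix`-1..n.
#'
#' @param seqs character vector of read sequences.
#' @param path output path (`.gz` suffix gzips).
#' @param prefix read-id prefix.
#' @export
write_fastq <- function(seqs, path, prefix = "read") {
  n <- length(seqs)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  rec <- paste0("@", prefix, "-", seq_len(n), "\n", seqs, "\n+\n",
                strrep("I", nchar(seqs)))
  writeLines(rec, con)
  invisible(path)
}
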