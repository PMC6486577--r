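#' Build a degenerate search motif from a full-site profile
#'
#' Positions whose aggregate enrichment exceeds `threshold` (strictly)
#' are fixed at the target site's canonical base; all other half-site
#' positions and the whole core become wildcards (N).  Leading and
#' trailing all-N positions are trimmed from the flattened search string
#' (the trim offsets are retained so hits can be mapped back to the full
#' site frame).  This reproduces the minimal-substrate-motif construction
#' used for genomic pseudosite prediction.
#'
#' @param profile an aggregate `full_site_profile`.
#' @param threshold enrichment cutoff (default 2; strictly greater-than).
#' @return an object of class `specificity_motif`: list with `pattern`
#'   (trimmed A/C/G/T/N string), `labelled` (e.g. `"A14C13NT11..."`),
#'   `full_pattern`, `trim_left`, `trim_right`, `threshold`, `site`.
#' @export
build_motif <- function(profile, threshold = 2.0) {
  stopifnot(inherits(profile, "full_site_profile"))
  site <- profile$site
  tab <- profile$table
  Ll <- nchar(site$left_half); C <- nchar(site$core)
  Lr <- nchar(site$right_half)
  stopifnot(nrow(tab) == Ll + Lr)
  specified <- tab$r > threshold
  if (!any(specified))
    stop("empty-motif error: no position exceeds the enrichment threshold; ",
         "a scan would be unconstrained", call. = FALSE)
  full_seq <- site_sequence(site)
  half_chars <- c(strsplit(site$left_half, "")[[1L]],
                  strsplit(site$right_half, "")[[1L]])
  pattern <- rep("N", Ll + C + Lr)
  lab <- character(Ll + C + Lr)
  lab[(Ll + 1):(Ll + C)] <- "N"
  for (k in seq_len(Ll + Lr)) {
    gpos <- if (k <= Ll) k else k + C  # genome index of this profile row
    if (specified[k]) {
      pattern[gpos] <- half_chars[k]
      lab[gpos] <- paste0(half_chars[k], tab$position[k])
    } else lab[gpos] <- "N"
  }
  spec_idx <- which(pattern != "N")
  trim_left <- min(spec_idx) - 1L
  trim_right <- length(pattern) - max(spec_idx)
  keep <- seq.int(min(spec_idx), max(spec_idx))
  structure(
    list(pattern = paste(pattern[keep], collapse = ""),
         labelled = paste(lab[keep], collapse = ""),
         full_pattern = paste(pattern, collapse = ""),
         trim_left = trim_left, trim_right = trim_right,
         threshold = threshold, site = site,
         n_specified = length(spec_idx)),
    class = "specificity_motif")
}

#' @export
print.specificity_motif <- function(x, ...) {
  cat(sprintf("specificity_motif for %s (r > %g, %d specified positions)\n",
              x$site$name, x$threshold, x$n_specified))
  cat("  pattern  ", x$pattern, "\n", sep = "")
  cat("  labelled ", x$labelled, "\n", sep = "")
  invisible(x)
}

## all windows of `seq_string` matching the pattern characters at the
## specified indices; windows containing non-ACGT characters never match
match_windows <- function(seq_string, pattern) {
  m <- nchar(pattern)
  L <- nchar(seq_string)
  if (L < m) return(integer(0))
  sr <- charToRaw(seq_string)
  pr <- charToRaw(pattern)
  nwin <- L - m + 1L
  ok <- rep(TRUE, nwin)
  for (j in seq_len(m)) {
    if (pr[j] == charToRaw("N")) next
    ok <- ok & (sr[j:(j + nwin - 1L)] == pr[j])
  }
  valid <- as.integer(sr) %in%
    as.integer(charToRaw(paste(DNA_BASES, collapse = "")))
  bad <- cumsum(!valid)
  ok <- ok & (bad[m:L] - c(0L, bad)[seq_len(nwin)]) == 0L
  which(ok)
}

#' Scan genome sequences for pseudosite motif matches
#'
#' Tests every window of motif length on both strands; N in the motif
#' matches any of A/C/G/T, while ambiguity codes in the genome match
#' nothing.  Overlapping hits are all reported.  Coordinates are 0-based
#' half-open on the forward strand.  For each hit the oriented full-site
#' frame (the trimmed flanks restored from the genome) is used to count
#' mismatches against the cognate site outside the core; hits too close
#' to a sequence edge to restore the frame get `NA` there.
#'
#' @param motif a `specificity_motif`.
#' @param genome named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path (plain or gzip).
#' @return data.frame with columns `seqname`, `start`, `end`, `strand`,
#'   `match` (motif-oriented matched sequence) and `noncore_mismatches`.
#' @export
scan_pseudosites <- function(motif, genome) {
  stopifnot(inherits(motif, "specificity_motif"))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- sub("\\s.*$", "", nm)
  }
  if (!is.character(genome) || length(genome) == 0L)
    stop("I/O error: unreadable or empty genome input", call. = FALSE)
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  genome <- toupper(genome)
  m <- nchar(motif$pattern)
  pat_fwd <- motif$pattern
  pat_rev <- revcomp(motif$pattern)  # N complements to N
  site <- motif$site
  hits <- list()
  for (sn in names(genome)) {
    s <- genome[[sn]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_fwd else pat_rev
      starts <- match_windows(s, pat)
      if (!length(starts)) next
      win <- substring(s, starts, starts + m - 1L)
      matched <- if (strand == "+") win else revcomp(win)
      ## restore the untrimmed site frame on the motif's own orientation
      tl <- if (strand == "+") motif$trim_left else motif$trim_right
      tr <- if (strand == "+") motif$trim_right else motif$trim_left
      fs <- starts - tl
      fe <- starts + m - 1L + tr
      in_bounds <- fs >= 1L & fe <= nchar(s)
      frame <- rep(NA_character_, length(starts))
      frame[in_bounds] <- substring(s, fs[in_bounds], fe[in_bounds])
      if (strand == "-") frame[in_bounds] <- revcomp(frame[in_bounds])
      nm_mm <- rep(NA_integer_, length(starts))
      nm_mm[in_bounds] <- noncore_mismatches(frame[in_bounds], site)
      hits[[length(hits) + 1L]] <- data.frame(
        seqname = sn, start = starts - 1L, end = starts - 1L + m,
        strand = strand, match = matched, noncore_mismatches = nm_mm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      match = character(0),
                      noncore_mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$seqname, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Non-core mismatch count against the cognate site
#'
#' Hamming distance between an oriented full-site-frame sequence and the
#' cognate target, excluding the core positions (where strand exchange
#' occurs and complementarity, not identity, is required).
#'
#' @param seqs character vector of sequences of full-site length, in the
#'   site's orientation.
#' @param site the cognate `target_site`.
#' @return integer vector of mismatch counts.
#' @export
noncore_mismatches <- function(seqs, site) {
  stopifnot(inherits(site, "target_site"))
  full <- site_sequence(site)
  if (any(nchar(seqs) != nchar(full)))
    stop("frame misalignment: sequence length differs from the full site",
         call. = FALSE)
  Ll <- nchar(site$left_half); C <- nchar(site$core)
  ref_noncore <- paste0(site$left_half, site$right_half)
  q_noncore <- paste0(substr(seqs, 1L, Ll),
                      substr(seqs, Ll + C + 1L, nchar(full)))
  hamming_distance(q_noncore, ref_noncore)
}

#' Write pseudosite hits as 6-column BED
#'
#' Coordinates stay 0-based half-open; `name` is the motif's target-site
#' name, `score` the non-core mismatch count.
#'
#' @param hits data.frame from [scan_pseudosites()].
#' @param motif the `specificity_motif` used for the scan.
#' @param path output path.
#' @export
write_hits_bed <- function(hits, motif, path) {
  bed <- data.frame(hits$seqname, hits$start, hits$end,
                    paste0(motif$site$name, "-pseudosite"),
                    ifelse(is.na(hits$noncore_mismatches), 0L,
                           hits$noncore_mismatches),
                    hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
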