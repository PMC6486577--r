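#' Randomized substrate library specification
#'
#' Emulates the library design of the selection experiment: one half-site
#' of the target is partially randomized during synthesis — each position
#' carries the wild-type base with probability `canonical_fraction`
#' (default 0.79) and each of the three other bases with probability
#' `(1 - canonical_fraction)/3` (default 0.07) — while the core and the
#' other half-site stay fixed.  Each molecule carries a random UMI.
#'
#' @param site a `target_site`.
#' @param randomized_side `"left"` or `"right"` (only one half-site is
#'   randomized per experiment).
#' @param canonical_fraction per-position wild-type base probability.
#' @param umi_length UMI length in nt.
#' @param flank_5p,flank_3p constant flanks used when reads are emitted.
#' @return an object of class `library_spec`.
#' @export
library_spec <- function(site, randomized_side = c("left", "right"),
                         canonical_fraction = 0.79, umi_length = 10L,
                         flank_5p = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
                         flank_3p = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC") {
  stopifnot(inherits(site, "target_site"),
            canonical_fraction > 0, canonical_fraction <= 1)
  randomized_side <- match.arg(randomized_side)
  structure(
    list(site = site, randomized_side = randomized_side,
         canonical_fraction = canonical_fraction,
         umi_length = as.integer(umi_length),
         flank_5p = clean_dna(flank_5p, "flank_5p", allow_empty = TRUE),
         flank_3p = clean_dna(flank_3p, "flank_3p", allow_empty = TRUE)),
    class = "library_spec")
}

#' Multiplicative independent-position selection model
#'
#' A molecule whose randomized half-site is `s` recombines with probability
#' `p_max * prod_i w[i, s_i]^gamma`.  Per-position weights `w` lie in
#' (0, 1] with the canonical base fixed at 1; the stringency exponent
#' `gamma` is a protein:DNA-ratio analogue (`gamma = 0` reproduces the
#' specificity erosion seen with excess enzyme — every substrate is
#' accepted at the same rate).  Non-recombined molecules survive
#' exonuclease digestion as background with probability
#' `background_survival`.
#'
#' @param weights numeric matrix, rows = half-site positions (innermost
#'   first, i.e. ordered by center-out position number), columns A/C/G/T.
#'   Canonical entries must equal 1.
#' @param site,side used to locate canonical bases for validation.
#' @param gamma stringency exponent (>= 0).
#' @param p_max maximal acceptance probability in (0, 1].
#' @param background_survival background survival fraction in [0, 1).
#' @return an object of class `selection_model`.
#' @seealso [uniform_weights()] for a convenient weight matrix.
#' @export
selection_model <- function(weights, site, side = c("left", "right"),
                            gamma = 1, p_max = 1, background_survival = 0) {
  side <- match.arg(side)
  stopifnot(inherits(site, "target_site"),
            is.matrix(weights), ncol(weights) == 4L,
            gamma >= 0, p_max > 0, p_max <= 1,
            background_survival >= 0, background_survival < 1)
  colnames(weights) <- DNA_BASES
  hs <- half_site(site, side)
  L <- nchar(hs)
  stopifnot(nrow(weights) == L)
  if (any(weights <= 0) || any(weights > 1))
    stop("selection weights must lie in (0, 1]", call. = FALSE)
  canon <- position_base(site, side, site_positions(site, side))
  for (i in seq_len(L))
    if (weights[i, canon[i]] != 1)
      stop("canonical-base weight must be 1 at every position", call. = FALSE)
  rownames(weights) <- as.character(site_positions(site, side))
  structure(
    list(weights = weights, site = site, side = side, gamma = gamma,
         p_max = p_max, background_survival = background_survival),
    class = "selection_model")
}

#' Uniform non-canonical weight matrix
#'
#' All non-canonical bases get weight `w` at every position (canonical
#' bases 1).  `w_by_position` overrides `w` per position.
#'
#' @param site,side define the canonical half-site.
#' @param w scalar weight for non-canonical bases.
#' @param w_by_position optional numeric vector (length = half-site
#'   length, innermost position first).
#' @return numeric matrix suitable for [selection_model()].
#' @export
uniform_weights <- function(site, side = c("left", "right"), w = 0.5,
                            w_by_position = NULL) {
  side <- match.arg(side)
  hs <- half_site(site, side)
  L <- nchar(hs)
  wv <- if (is.null(w_by_position)) rep(w, L) else w_by_position
  stopifnot(length(wv) == L, all(wv > 0), all(wv <= 1))
  canon <- position_base(site, side, site_positions(site, side))
  m <- matrix(rep(wv, 4L), nrow = L, ncol = 4L,
              dimnames = list(as.character(site_positions(site, side)),
                              DNA_BASES))
  for (i in seq_len(L)) m[i, canon[i]] <- 1
  m
}

#' Simulation run configuration
#'
#' @param n_molecules number of library molecules.
#' @param n_reads target number of emitted reads per FASTQ file.
#' @param mean_reads_per_molecule Poisson mean of per-molecule read counts
#'   (PCR/loading proxy); molecules drawing zero reads silently drop.
#' @param seq_error_rate per-base substitution error probability.
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_molecules, n_reads,
                       mean_reads_per_molecule = 2,
                       seq_error_rate = 0, seed = 1L) {
  stopifnot(n_molecules >= 1, n_reads >= 1, mean_reads_per_molecule > 0,
            seq_error_rate >= 0, seq_error_rate < 1)
  structure(
    list(n_molecules = as.integer(n_molecules),
         n_reads = as.integer(n_reads),
         mean_reads_per_molecule = mean_reads_per_molecule,
         seq_error_rate = seq_error_rate, seed = as.integer(seed)),
    class = "sim_config")
}

#' Draw a randomized substrate library
#'
#' Each molecule's randomized half-site is drawn position-independently
#' (canonical base with probability `canonical_fraction`, each other base
#' with `(1 - canonical_fraction)/3`); UMIs are uniform over
#' `4^umi_length`.
#'
#' @param spec a `library_spec`.
#' @param n number of molecules.
#' @param seed integer seed.
#' @return data.frame with columns `variant` (half-site string) and `umi`.
#' @export
sample_library <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "library_spec"), n >= 1)
  site <- spec$site
  side <- spec$randomized_side
  hs <- half_site(site, side)
  L <- nchar(hs)
  f <- spec$canonical_fraction
  canon <- position_base(site, side, site_positions(site, side))
  ## genome-orientation character matrix of the half-site
  with_seed(seed, {
    cols <- vector("list", L)
    for (k in seq_len(L)) {
      b <- substr(hs, k, k)  # canonical base at string index k
      others <- setdiff(DNA_BASES, b)
      cols[[k]] <- sample(c(b, others), n, replace = TRUE,
                          prob = c(f, rep((1 - f) / 3, 3)))
    }
    variant <- do.call(paste0, cols)
    umi_cols <- replicate(spec$umi_length,
                          sample(DNA_BASES, n, replace = TRUE),
                          simplify = FALSE)
    umi <- do.call(paste0, umi_cols)
  })
  data.frame(variant = variant, umi = umi, stringsAsFactors = FALSE)
}

## log selection weight of each molecule under a model; variants are in
## genome orientation, weight rows in center-out order
molecule_log_weight <- function(variants, model) {
  site <- model$site
  side <- model$side
  hs <- half_site(site, side)
  L <- nchar(hs)
  lw <- numeric(length(variants))
  logW <- log(model$weights)
  for (k in seq_len(L)) {
    ## string index k -> center-out row: left half counts outward
    ## right-to-left, right half left-to-right
    row <- if (side == "left") L - k + 1L else k
    base <- substr(variants, k, k)
    lw <- lw + logW[row, ][match(base, DNA_BASES)]
  }
  lw
}

#' Apply the selection model to a library
#'
#' Each molecule independently recombines with probability
#' `p_max * prod_i w^gamma`; non-recombined molecules independently
#' survive digestion as background with probability `background_survival`.
#'
#' @param molecules data.frame from [sample_library()].
#' @param model a `selection_model`.
#' @param seed integer seed.
#' @return `molecules` with added logical columns `recombined` and
#'   `background` (mutually exclusive).
#' @export
select_recombinants <- function(molecules, model, seed = 1L) {
  stopifnot(inherits(model, "selection_model"), is.data.frame(molecules))
  p <- model$p_max * exp(model$gamma * molecule_log_weight(molecules$variant,
                                                           model))
  with_seed(seed, {
    rec <- stats::runif(nrow(molecules)) < p
    bg <- !rec & stats::runif(nrow(molecules)) < model$background_survival
  })
  molecules$recombined <- rec
  molecules$background <- bg
  molecules
}

## per-molecule read counts: zero-truncated Poisson(mu), thinned to about
## n_reads total when oversampled
read_counts <- function(n_mol, mu, n_reads) {
  u <- stats::runif(n_mol, stats::dpois(0, mu), 1)
  cnt <- stats::qpois(u, mu)
  tot <- sum(cnt)
  if (tot > n_reads) cnt <- stats::rbinom(n_mol, cnt, n_reads / tot)
  cnt
}

## build full read strings for molecules, with substitution errors
molecules_to_reads <- function(molecules, counts, spec) {
  keep <- counts > 0L
  idx <- rep(which(keep), counts[keep])
  site <- spec$site
  halves <- assemble_read(
    structure(list(site = site, randomized_side = spec$randomized_side),
              class = "read_layout"),
    molecules$variant[idx])
  paste0(spec$flank_5p, molecules$umi[idx], halves$left, site$core,
         halves$right, spec$flank_3p)
}

apply_seq_errors <- function(reads, rate) {
  if (rate == 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads[1L])
  stopifnot(all(nchar(reads) == L))
  n_err <- stats::rbinom(1L, length(reads) * L, rate)
  if (n_err == 0L) return(reads)
  pos <- sample.int(length(reads) * L, n_err)
  ri <- (pos - 1L) %/% L + 1L
  ci <- (pos - 1L) %% L + 1L
  for (k in seq_len(n_err)) {
    old <- substr(reads[ri[k]], ci[k], ci[k])
    new <- sample(setdiff(DNA_BASES, old), 1L)
    substr(reads[ri[k]], ci[k], ci[k]) <- new
  }
  reads
}

#' Emit pre- and post-selection FASTQ files plus a ground-truth manifest
#'
#' Pre-selection reads are sampled from the whole library; post-selection
#' reads from the recombined + background pool.  Each read is
#' `flank_5p + UMI + left half + core + right half + flank_3p` with
#' per-base substitution errors at `seq_error_rate`.  Deterministic for a
#' fixed config.
#'
#' @param molecules selected library (from [select_recombinants()]).
#' @param spec a `library_spec`.
#' @param config a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return list with paths `pre_fastq`, `post_fastq`, `manifest`,
#'   `truth`, and the manifest data.frame.
#' @export
emit_fastq <- function(molecules, spec, config, out_dir) {
  stopifnot(inherits(spec, "library_spec"), inherits(config, "sim_config"),
            is.data.frame(molecules),
            all(c("recombined", "background") %in% names(molecules)))
  post_pool <- molecules[molecules$recombined | molecules$background, ,
                         drop = FALSE]
  if (nrow(molecules) == 0L || nrow(post_pool) == 0L)
    stop("simulation error: empty read pool (no molecules survived selection)",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mu <- config$mean_reads_per_molecule
  with_seed(child_seed(config$seed, 3L), {
    pre_counts <- read_counts(nrow(molecules), mu, config$n_reads)
    pre_reads <- apply_seq_errors(
      molecules_to_reads(molecules, pre_counts, spec), config$seq_error_rate)
    post_counts <- read_counts(nrow(post_pool), mu, config$n_reads)
    post_reads <- apply_seq_errors(
      molecules_to_reads(post_pool, post_counts, spec), config$seq_error_rate)
  })
  pre_path <- file.path(out_dir, "pre.fastq")
  post_path <- file.path(out_dir, "post.fastq")
  write_fastq(pre_reads, pre_path, "pre")
  write_fastq(post_reads, post_path, "post")
  manifest <- data.frame(umi = molecules$umi, variant = molecules$variant,
                         recombined = molecules$recombined,
                         background = molecules$background,
                         stringsAsFactors = FALSE)
  man_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.json")
  truth <- list(
    site = spec$site[c("name", "left_half", "core", "right_half",
                       "numbering_start")],
    randomized_side = spec$randomized_side,
    canonical_fraction = spec$canonical_fraction,
    umi_length = spec$umi_length,
    config = unclass(config))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE)
  list(pre_fastq = pre_path, post_fastq = post_path, manifest = man_path,
       truth = truth_path, manifest_df = manifest,
       n_pre_reads = length(pre_reads), n_post_reads = length(post_reads))
}

#' Full simulation convenience wrapper
#'
#' [sample_library()] + [select_recombinants()] + [emit_fastq()] under a
#' single seed.
#'
#' @inheritParams emit_fastq
#' @param model a `selection_model`.
#' @return as [emit_fastq()], plus the selected `molecules`.
#' @export
simulate_recseq <- function(spec, model, config, out_dir) {
  mol <- sample_library(spec, config$n_molecules,
                        seed = child_seed(config$seed, 1L))
  mol <- select_recombinants(mol, model, seed = child_seed(config$seed, 2L))
  out <- emit_fastq(mol, spec, config, out_dir)
  out$molecules <- mol
  out
}

#' Closed-form expected enrichment under the simulator
#'
#' Under independent-position multiplicative selection with no background
#' (`background_survival = 0`), the per-position enrichment ratio
#' `r_i = (A_i/B_i)/(alpha_i/beta_i)` converges to
#' `r*_i = beta / sum_{b != canonical} alpha_b * w[i,b]^gamma`
#' with `alpha_b = (1 - canonical_fraction)/3` and
#' `beta = 1 - canonical_fraction`; it is independent of `p_max` and of
#' the other positions.
#'
#' @param model a `selection_model`.
#' @param spec a `library_spec` (for `canonical_fraction`).
#' @return named numeric vector of expected ratios, one per center-out
#'   position.
#' @export
expected_enrichment <- function(model, spec) {
  stopifnot(inherits(model, "selection_model"), inherits(spec, "library_spec"))
  f <- spec$canonical_fraction
  alpha_b <- (1 - f) / 3
  beta <- 1 - f
  site <- model$site
  canon <- position_base(site, model$side, site_positions(site, model$side))
  W <- model$weights^model$gamma
  denom <- vapply(seq_len(nrow(W)), function(i) {
    sum(alpha_b * W[i, setdiff(DNA_BASES, canon[i])])
  }, numeric(1))
  r <- beta / denom
  names(r) <- rownames(model$weights)
  r
}
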