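#' Analysis run configuration
#'
#' Declarative description of one selection experiment: the target site,
#' the read layout, a sample table with exactly one pre-selection (input
#' library) sample and one or more post-selection replicates, and the
#' analysis parameters.
#'
#' @param site a `target_site`.
#' @param randomized_side which half-site was randomized.
#' @param samples data.frame with columns `role` (`"pre"`/`"post"`),
#'   `replicate` (label) and `fastq` (file path).
#' @param umi_length,flank_5p,flank_3p read-layout parameters (see
#'   [read_layout()]).
#' @param max_mismatches mismatch-filter ceiling (default 6).
#' @param pseudocount enrichment pseudocount (default 0.5).
#' @param motif_threshold enrichment cutoff for motif building (default 2).
#' @param kappa_orientation regression orientation for [kappa_score()].
#' @param out_dir output directory for reports (NULL = no files written).
#' @param seed integer seed recorded in the report.
#' @return an object of class `run_config`.
#' @export
run_config <- function(site, randomized_side, samples,
                       umi_length = 10L,
                       flank_5p = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
                       flank_3p = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                       max_mismatches = 6L, pseudocount = 0.5,
                       motif_threshold = 2.0,
                       kappa_orientation = "umi_on_abundance",
                       out_dir = NULL, seed = 1L) {
  stopifnot(inherits(site, "target_site"), is.data.frame(samples),
            all(c("role", "replicate", "fastq") %in% names(samples)))
  if (sum(samples$role == "pre") != 1L)
    stop("validation error: exactly one pre-library sample required",
         call. = FALSE)
  if (!any(samples$role == "post"))
    stop("validation error: at least one post-selection sample required",
         call. = FALSE)
  missing <- samples$fastq[!file.exists(samples$fastq)]
  if (length(missing))
    stop("validation error: missing FASTQ file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(
    list(site = site, randomized_side = randomized_side, samples = samples,
         umi_length = as.integer(umi_length), flank_5p = flank_5p,
         flank_3p = flank_3p, max_mismatches = as.integer(max_mismatches),
         pseudocount = pseudocount, motif_threshold = motif_threshold,
         kappa_orientation = kappa_orientation, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' The JSON mirrors [run_config()] arguments; the site is given inline
#' (`name`, `left_half`, `core`, `right_half`, optional
#' `numbering_start`) or by builtin name (`site: "loxP"`).  Relative
#' FASTQ paths are resolved against the config file's directory.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  site <- if (is.character(cfg$site)) builtin_site(cfg$site)
    else target_site(cfg$site$name, cfg$site$left_half, cfg$site$core,
                     cfg$site$right_half, cfg$site$numbering_start)
  samples <- as.data.frame(cfg$samples, stringsAsFactors = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", samples$fastq)
  samples$fastq[rel] <- file.path(dirname(path), samples$fastq[rel])
  args <- cfg[setdiff(names(cfg), c("site", "samples"))]
  do.call(run_config, c(list(site = site, samples = samples), args))
}

process_sample <- function(fastq, layout, max_mismatches) {
  seqs <- read_fastq(fastq)
  extracted <- extract_reads(seqs, layout)
  filter_reads(extracted, max_mismatches)
}

#' Run the analysis pipeline on one experiment
#'
#' Executes extract -> filter -> tally -> enrichment -> kappa ->
#' aggregate for every post-selection replicate against the single
#' pre-selection sample.  Deterministic for fixed inputs.  When
#' `config$out_dir` is set, profiles, kappa values, filter reports and a
#' JSON run report are written there.
#'
#' @param config a `run_config`.
#' @return an object of class `run_report`: list with `filter_reports`,
#'   `pre_counts`, `profiles` (per replicate), `aggregate`, `kappas`,
#'   `power`, `config`.
#' @export
run_recseq <- function(config) {
  stopifnot(inherits(config, "run_config"))
  layout <- read_layout(config$site, config$randomized_side,
                        config$umi_length, config$flank_5p, config$flank_3p)
  samples <- config$samples
  pre_row <- which(samples$role == "pre")
  post_rows <- which(samples$role == "post")

  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for sample '%s': %s",
                   what, id, conditionMessage(e)), call. = FALSE))
  }

  filter_reports <- list()
  pre_id <- samples$replicate[pre_row]
  pre <- stage("extract/filter", pre_id,
               process_sample(samples$fastq[pre_row], layout,
                              config$max_mismatches))
  filter_reports[[pre_id]] <- pre$report
  pre_counts <- stage("tally", pre_id,
                      tally_counts(pre$kept, config$site,
                                   config$randomized_side))

  profiles <- list()
  kappas <- numeric(0)
  for (i in post_rows) {
    id <- samples$replicate[i]
    post <- stage("extract/filter", id,
                  process_sample(samples$fastq[i], layout,
                                 config$max_mismatches))
    filter_reports[[id]] <- post$report
    counts <- stage("tally", id,
                    tally_counts(post$kept, config$site,
                                 config$randomized_side))
    profiles[[id]] <- stage("enrichment", id,
                            enrichment_profile(pre_counts, counts,
                                               config$pseudocount,
                                               replicate_id = id))
    kap <- stage("kappa", id,
                 kappa_score(umi_stats(post$kept),
                             config$kappa_orientation))
    kappas[id] <- kap$kappa
  }
  aggregate <- aggregate_profiles(profiles)
  power <- classify_power(kappas)
  if (power$label != "well_powered")
    warning(sprintf("kappa_avg = %.2f: experiment %s", power$kappa_avg,
                    sub("_", " ", power$label)), call. = FALSE)

  report <- structure(
    list(filter_reports = filter_reports, pre_counts = pre_counts,
         profiles = profiles, aggregate = aggregate, kappas = kappas,
         power = power, config = config,
         version = as.character(utils::packageVersion("recseq"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %s, %s half-site randomized, %d replicate(s)\n",
              x$config$site$name, x$config$randomized_side,
              length(x$profiles)))
  cat(sprintf("  kappa_avg %.3f (%s)\n", x$power$kappa_avg, x$power$label))
  cat("  aggregate r by position:\n")
  print(round(profile_r(x$aggregate), 3))
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `profile_<replicate>.tsv` and `profile_aggregate.tsv`,
#' `kappa.tsv`, `filter_report.json` and `report.json` under `dir`.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(report$profiles))
    write_profile(report$profiles[[id]],
                  file.path(dir, paste0("profile_", id, ".tsv")))
  write_profile(report$aggregate, file.path(dir, "profile_aggregate.tsv"))
  utils::write.table(
    data.frame(replicate = names(report$kappas), kappa = report$kappas),
    file.path(dir, "kappa.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(lapply(report$filter_reports, as.list),
                       file.path(dir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg <- report$config
  jsonlite::write_json(
    list(schema = "recseq-report/1",
         version = report$version,
         site = cfg$site[c("name", "left_half", "core", "right_half",
                           "numbering_start")],
         randomized_side = cfg$randomized_side,
         parameters = cfg[c("umi_length", "max_mismatches", "pseudocount",
                            "motif_threshold", "kappa_orientation", "seed")],
         kappa = as.list(report$kappas),
         kappa_avg = report$power$kappa_avg,
         power = report$power$label,
         aggregate_r = as.list(profile_r(report$aggregate)),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}

#' Bundled miniature simulated datasets
#'
#' Writes a small seeded simulation (about 1e4 reads) plus an
#' expected-output snapshot, for tests and documentation:
#' \describe{
#'   \item{cre-neutral}{stringency 0 — every r_i is 1 in expectation.}
#'   \item{cre-selective}{uniform non-canonical weight 0.5 — closed-form
#'     expected r_i = 2 at every position.}
#'   \item{background-heavy}{weak selection swamped by surviving
#'     background — classified `heavy_background`.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory.
#' @param seed integer seed.
#' @return list with the simulation output paths and `expected` (the
#'   closed-form expected enrichment, where defined).
#' @export
recseq_fixture <- function(name = c("cre-neutral", "cre-selective",
                                    "background-heavy"),
                           dir, seed = 20190426) {
  name <- match.arg(name)
  site <- builtin_site("loxP")
  spec <- library_spec(site, "left")
  w <- uniform_weights(site, "left", 0.5)
  model <- switch(name,
    "cre-neutral" = selection_model(w, site, "left", gamma = 0, p_max = 0.25),
    "cre-selective" = selection_model(w, site, "left", gamma = 1),
    "background-heavy" = selection_model(w, site, "left", gamma = 1,
                                         p_max = 0.002,
                                         background_survival = 0.05))
  config <- sim_config(n_molecules = 20000L, n_reads = 10000L,
                       mean_reads_per_molecule = 2, seq_error_rate = 0,
                       seed = seed)
  out <- simulate_recseq(spec, model, config, dir)
  expected <- if (model$background_survival == 0)
    expected_enrichment(model, spec) else NULL
  jsonlite::write_json(list(fixture = name, expected_r = expected),
                       file.path(dir, "expected.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out$expected <- expected
  out$name <- name
  out
}
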