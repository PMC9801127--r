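## Pipeline configuration and subcommand runner: thin orchestration over
## the module functions, writing TSV/FASTA/FASTQ artifacts plus a
## machine-readable run log so any run can be replayed exactly.

PIPELINE_DEFAULTS <- list(
  references = "", annotations = "", treated_fastq = "",
  untreated_fastq = "", kinetics_tsv = "", output_dir = ".",
  target_label = "22", mutable_labels = "",
  min_depth = 1000, site_threshold = 0.01, loss_threshold = 0.05,
  min_total = 100, min_score_fraction = 0.6,
  match = 1, mismatch = -1, gap = -2,
  n_reads = 10000, error_rate = 0.001, signature_rate = 0.79,
  stop_rate = 0, adapter = DEFAULT_ADAPTER, seed = 1,
  try_reverse_complement = FALSE, count_mode = "substring")

#' Build a validated pipeline configuration
#'
#' Flat key-value settings with defaults; precedence is
#' \code{overrides > file > defaults}.  Numeric thresholds are validated
#' (\code{site_threshold} and \code{loss_threshold} in \code{[0,1]},
#' \code{min_depth >= 1}).
#'
#' @param path optional config file: one \code{key = value} per line,
#'   \code{#} comments allowed.
#' @param ... or \code{overrides}, named overrides.
#' @param overrides named list merged over the file values.
#' @return named list of settings.
#' @export
pipelineConfig <- function(path = NULL, ..., overrides = list()) {
  cfg <- PIPELINE_DEFAULTS
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) < 2L)
        stop("malformed config line: '", ln, "'", call. = FALSE)
      key <- trimws(kv[1L])
      if (!key %in% names(PIPELINE_DEFAULTS))
        stop("unknown config key: '", key, "'", call. = FALSE)
      val <- trimws(paste(kv[-1L], collapse = "="))
      cfg[[key]] <- val
    }
  }
  overrides <- c(list(...), overrides)
  for (key in names(overrides)) {
    if (!key %in% names(PIPELINE_DEFAULTS))
      stop("unknown config key: '", key, "'", call. = FALSE)
    cfg[[key]] <- overrides[[key]]
  }
  for (key in names(cfg)) {
    proto <- PIPELINE_DEFAULTS[[key]]
    if (is.numeric(proto)) cfg[[key]] <- as.numeric(cfg[[key]])
    if (is.logical(proto)) cfg[[key]] <- as.logical(cfg[[key]])
  }
  if (cfg$site_threshold < 0 || cfg$site_threshold > 1 ||
      cfg$loss_threshold < 0 || cfg$loss_threshold > 1)
    stop("rate thresholds must lie in [0, 1]", call. = FALSE)
  if (cfg$min_depth < 1) stop("min_depth must be >= 1", call. = FALSE)
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop("error_rate must lie in [0, 1]", call. = FALSE)
  cfg
}

writeRunLog <- function(cfg, name, dir) {
  log <- c(sprintf("subcommand = %s", name),
           sprintf("package_version = %s",
                   as.character(packageVersion("trnamap"))),
           sprintf("r_version = %s", R.version.string),
           vapply(names(cfg), function(k)
             sprintf("%s = %s", k, paste(cfg[[k]], collapse = ",")),
             character(1L)))
  writeLines(log, file.path(dir, paste0("run-", name, ".log")))
}

requireInput <- function(path, what) {
  if (!nzchar(path) || !file.exists(path))
    stop("missing input: ", what, " ('", path, "')", call. = FALSE)
  path
}

loadConfigReferences <- function(cfg) {
  loadReferences(requireInput(cfg$references, "reference FASTA"),
                 requireInput(cfg$annotations, "annotation TSV"))
}

#' Run one pipeline subcommand
#'
#' Subcommands: \code{design} (variant library FASTA + TSV),
#' \code{cassette} (T7 template FASTA + TSV), \code{simulate} (paired
#' treated/untreated FASTQ + truth TSV), \code{profile} (per-reference
#' mutation-profile TSVs, subtracted profile, called sites, summary),
#' \code{count} (per-variant M_rate TSV), \code{analyze} (activity
#' classification + element summary from a count table), and
#' \code{fit-kinetics} (Michaelis-Menten fit of a \code{S, v} TSV).
#' Every run writes a \code{run-<subcommand>.log} echoing the full
#' configuration for exact replay, and every table has a header row.
#'
#' @param name subcommand name.
#' @param config a [pipelineConfig()].
#' @return invisibly, the output directory.
#' @export
runSubcommand <- function(name, config) {
  name <- match.arg(name, c("design", "cassette", "simulate", "profile",
                            "count", "analyze", "fit-kinetics"))
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- NULL
  lib <- function() {
    refs <- loadConfigReferences(config)
    trna <- refs[[1L]]
    mut <- if (nzchar(config$mutable_labels))
      strsplit(config$mutable_labels, ",", fixed = TRUE)[[1L]] else NULL
    designPointVariantLibrary(trna, targetLabel = config$target_label,
                              mutableLabels = mut)
  }
  switch(name,
    design = {
      l <- lib()
      writeVariantFasta(l, file.path(dir, "variants.fasta"))
      writeTsv(as.data.frame(variants(l))[,
               c("name", "positionLabel", "wtBase", "newBase", "sequence")],
               file.path(dir, "variants.tsv"))
    },
    cassette = {
      refs <- loadConfigReferences(config)
      cs <- lapply(refs, buildT7Cassette)
      writeCassetteFasta(cs, file.path(dir, "cassettes.fasta"))
      writeTsv(data.frame(
        id = vapply(cs, function(c) c@id, character(1L)),
        template = vapply(cs, dnaTemplate, character(1L)),
        extra_g_added = vapply(cs, function(c) c@extraGAdded, logical(1L)),
        cca_added = vapply(cs, function(c) c@ccaAdded, logical(1L)),
        transcript = vapply(cs, predictedTranscript, character(1L))),
        file.path(dir, "cassettes.tsv"))
    },
    simulate = {
      refs <- loadConfigReferences(config)
      ids <- names(refs)
      sigs <- lapply(ids, function(i)
        modificationSignature(i, config$target_label,
                              config$signature_rate,
                              stopRate = config$stop_rate))
      ps <- poolSpec(setNames(rep(1, length(ids)), ids))
      for (role in c("treated", "untreated")) {
        sim <- simulateSample(
          ps, refs, sigs,
          simConfig(config$n_reads, errorRate = config$error_rate,
                    adapter = config$adapter,
                    seed = deriveSeed(config$seed,
                                      if (role == "treated") 1L else 2L)),
          treated = role == "treated")
        writeFastq(sim, file.path(dir, paste0(role, ".fastq")))
        if (role == "treated")
          writeTsv(sim$truth, file.path(dir, "truth.tsv"))
      }
    },
    profile = {
      refs <- loadConfigReferences(config)
      scoring <- list(match = as.integer(config$match),
                      mismatch = as.integer(config$mismatch),
                      gap = as.integer(config$gap))
      prof <- function(path, role) {
        reads <- readFastq(requireInput(path, paste0(role, " FASTQ")))
        tr <- trimAdapter(reads, config$adapter)
        asg <- assignReads(setNames(tr$sequence, rownames(tr)), refs,
                           scoring = scoring,
                           minScoreFraction = config$min_score_fraction,
                           tryReverseComplement =
                             isTRUE(config$try_reverse_complement))
        buildProfile(asg, refs, minDepth = config$min_depth,
                     sampleRole = role)
      }
      pt <- prof(config$treated_fastq, "treated")
      pu <- prof(config$untreated_fastq, "untreated")
      sub <- subtractBackground(pt, pu)
      for (i in names(sub))
        writeTsv(as.data.frame(profileData(sub[[i]])),
                 file.path(dir, paste0("profile-", i, ".tsv")))
      writeTsv(as.data.frame(callModifiedPositions(
        sub, threshold = config$site_threshold)),
        file.path(dir, "modified-positions.tsv"))
      writeTsv(data.frame(
        reference = names(sub),
        analyzable = !(names(sub) %in% metadata(sub)$notAnalyzable)),
        file.path(dir, "summary.tsv"))
    },
    count = {
      l <- lib()
      tr <- readFastq(requireInput(config$treated_fastq, "treated FASTQ"))
      un <- readFastq(requireInput(config$untreated_fastq,
                                   "untreated FASTQ"))
      mr <- countVariantLibrary(tr, un, l, mode = config$count_mode,
                                minTotal = config$min_total)
      writeTsv(as.data.frame(mr), file.path(dir, "mrate.tsv"))
    },
    analyze = {
      l <- lib()
      mrPath <- file.path(dir, "mrate.tsv")
      mr <- read.delim(requireInput(mrPath, "mrate.tsv (run 'count' first)"))
      act <- classifyVariants(mr, l, lossThreshold = config$loss_threshold)
      writeTsv(as.data.frame(act), file.path(dir, "activity.tsv"))
      writeTsv(as.data.frame(summarizeElements(act, parentTRNA(l))),
               file.path(dir, "elements.tsv"))
    },
    `fit-kinetics` = {
      d <- read.delim(requireInput(config$kinetics_tsv, "kinetics TSV"))
      fit <- fitMichaelisMenten(d)
      writeTsv(data.frame(Km = km(fit), Vmax = vmax(fit), rss = fit@rss,
                          converged = converged(fit),
                          message = fit@message),
               file.path(dir, "kinetic-fit.tsv"))
    })
  writeRunLog(config, name, dir)
  invisible(dir)
}
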