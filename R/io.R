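#' Write and read an epoch container
#'
#' Epochs are stored as a directory holding `epochs.rds` (the numeric array
#' plus axes: `data` trials x channels x samples, `times`, `sfreq`,
#' `channels`) and `events.tsv` (one row of trial metadata per epoch).  The
#' round trip is lossless.  `read_epochs()` validates the layout and stops
#' with a schema error naming the offending field on any mismatch; when a
#' neighborhood graph is supplied, channels missing from it are reported
#' with a warning.
#'
#' @param epochs An `"epoch_set"`.
#' @param path Directory to create/use.
#' @param neighbors Optional adjacency list to cross-check channel labels.
#' @return `read_epochs()` returns the `"epoch_set"`; `write_epochs()` the
#'   path, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(data = epochs$data, times = epochs$times, sfreq = epochs$sfreq,
               channels = epochs$channels), file.path(path, "epochs.rds"))
  utils::write.table(epochs$events, file.path(path, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path, neighbors = NULL) {
  f <- file.path(path, "epochs.rds")
  if (!file.exists(f)) stop("schema error: missing dataset 'epochs.rds' in ", path)
  raw <- readRDS(f)
  for (field in c("data", "times", "sfreq", "channels"))
    if (is.null(raw[[field]])) stop("schema error: missing field '", field, "'")
  ev_file <- file.path(path, "events.tsv")
  if (!file.exists(ev_file)) stop("schema error: missing events table 'events.tsv'")
  events <- utils::read.delim(ev_file, stringsAsFactors = FALSE)
  d <- dim(raw$data)
  if (length(d) != 3) stop("schema error: field 'data' must be a 3-d array")
  if (length(raw$times) != d[3])
    stop("schema error: field 'times' length does not match the sample dimension")
  if (length(raw$channels) != d[2])
    stop("schema error: field 'channels' length does not match the channel dimension")
  if (nrow(events) != d[1])
    stop("schema error: events table has ", nrow(events),
         " rows but 'data' has ", d[1], " trials")
  if (!is.null(neighbors)) {
    orphan <- setdiff(raw$channels, names(neighbors))
    if (length(orphan))
      warning("channels absent from the neighborhood graph: ",
              paste(orphan, collapse = ", "))
  }
  structure(list(data = raw$data, times = raw$times, sfreq = raw$sfreq,
                 channels = raw$channels, events = events),
            class = "epoch_set")
}

#' Pipeline configuration
#'
#' Bundles every stage's settings.  Unknown keys are rejected so that typos
#' in configuration files fail before any stage runs.
#'
#' @param sim Named list of [sim_params()] overrides.
#' @param tfr Named list of [tfr_config()] arguments.
#' @param cluster Named list of [cluster_config()] arguments (the pipeline
#'   default scales the permutation count to 500).
#' @param nAGQ Quadrature nodes for the mixed models.
#' @param min_trials Minimum trials per memory condition for a subject to
#'   enter the EEG analyses.
#' @param theta_band Frequency restriction applied to the positive-cluster
#'   FROI (default 2-4 Hz); `NULL` for none.
#' @param seed Global integer seed; per-stage child seeds are derived from
#'   it deterministically.
#' @param out_dir Output directory for pipeline artifacts.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = list(), tfr = list(),
                            cluster = list(n_perm = 500L), nAGQ = 10L,
                            min_trials = 10L, theta_band = c(2, 4),
                            seed = 1L, out_dir = tempfile("oscsme_")) {
  cfg <- list(sim = sim, tfr = tfr, cluster = cluster, nAGQ = nAGQ,
              min_trials = min_trials, theta_band = theta_band,
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

# deterministic child seed for stage k of global seed (kept below 2^31)
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483587)
}

#' Run the full subsequent-memory analysis pipeline
#'
#' Executes simulate -> behavior -> tfr -> baseline -> cluster -> froi ->
#' glmm on synthetic data and writes every stage's artifacts (events and
#' rate tables as TSV, cluster and model results as JSON, intermediate
#' arrays as RDS) plus a manifest with MD5 hashes into `cfg$out_dir`.
#' Per-subject single-trial arrays are spooled to disk so memory stays flat
#' in the number of subjects.  With `resume = TRUE`, stages whose output
#' files already exist are loaded instead of recomputed.
#'
#' @param cfg A [pipeline_config()].
#' @param resume Reuse existing stage outputs in `cfg$out_dir`?
#' @param verbose Print stage progress?
#' @return List of class `"pipeline_result"` with `events`, `rates`,
#'   `anova`, `clusters`, `trial_table`, `models`, `excluded`, `out_dir`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(sim_params, cfg$sim)
  tcfg <- do.call(tfr_config, cfg$tfr)
  graph <- channel_neighbors(params$montage)
  manifest <- list(seed = cfg$seed, stages = list())
  say <- function(...) if (verbose) message(...)
  stamp <- function(stage, files, t0) {
    manifest$stages[[stage]] <<- list(
      files = as.list(tools::md5sum(files[file.exists(files)])),
      seconds = round(as.numeric(Sys.time()) - t0, 2))
  }

  subjects <- data.frame(
    subject = c(sprintf("y_%02d", seq_len(params$n_subjects[["younger"]])),
                sprintf("o_%02d", seq_len(params$n_subjects[["older"]]))),
    age_group = rep(c("younger", "older"), params$n_subjects[c("younger", "older")]),
    stringsAsFactors = FALSE
  )

  # ---- behavior: designs, outcomes, responses, exclusions -----------------
  t0 <- as.numeric(Sys.time())
  beh_file <- file.path(cfg$out_dir, "behavior.rds")
  if (resume && file.exists(beh_file)) {
    say("behavior: reusing ", beh_file)
    beh <- readRDS(beh_file)
  } else {
    say("behavior: simulating ", nrow(subjects), " subjects")
    beh <- list(designs = list(), meta = list(), keep = character(0))
    for (i in seq_len(nrow(subjects))) {
      id <- subjects$subject[i]
      sseed <- child_seed(cfg$seed, i)
      design <- generate_design(params$n_scenes, seed = sseed)
      meta <- simulate_behavior(design, params, subject = id,
                                age_group = subjects$age_group[i],
                                seed = sseed + 1L)
      resp <- simulate_responses(design, meta, params, seed = sseed + 2L)
      chance <- item_chance_check(resp)
      counts <- table(factor(categorize(resp),
                             levels = c("miss", "item_only", "pair")))
      ok <- chance$keep && min_trial_filter(counts, cfg$min_trials)
      beh$designs[[id]] <- design
      beh$meta[[id]] <- meta
      if (ok) beh$keep <- c(beh$keep, id)
    }
    saveRDS(beh, beh_file)
  }
  events <- do.call(rbind, beh$meta)
  rownames(events) <- NULL
  ev_file <- file.path(cfg$out_dir, "events.tsv")
  utils::write.table(events, ev_file, sep = "\t", row.names = FALSE, quote = FALSE)
  excluded <- setdiff(names(beh$meta), beh$keep)
  mm <- events[events$condition %in% c("match", "mismatch") &
                 events$subject %in% beh$keep, ]
  rates <- response_rates(mm)
  anova_tab <- rate_anova(rates)
  rates_file <- file.path(cfg$out_dir, "rates.tsv")
  utils::write.table(rates, rates_file, sep = "\t", row.names = FALSE, quote = FALSE)
  anova_file <- file.path(cfg$out_dir, "anova.json")
  jsonlite::write_json(anova_tab, anova_file, dataframe = "rows", digits = NA)
  stamp("behavior", c(ev_file, rates_file, anova_file), t0)

  # ---- EEG per subject: epochs -> tfr -> baseline -> tmaps + single-trial --
  t0 <- as.numeric(Sys.time())
  tmap_file <- file.path(cfg$out_dir, "tmaps.rds")
  st_dir <- file.path(cfg$out_dir, "singletrial")
  dir.create(st_dir, showWarnings = FALSE)
  if (resume && file.exists(tmap_file)) {
    say("eeg: reusing ", tmap_file)
    tmaps <- readRDS(tmap_file)
  } else {
    tmaps <- list()
    for (id in beh$keep) {
      say("eeg: subject ", id)
      i <- match(id, names(beh$meta))
      meta <- beh$meta[[id]]
      epochs <- simulate_epochs(meta, params, seed = child_seed(cfg$seed, 1000L + i))
      tfr <- morlet_power(epochs, tcfg)
      mm_idx <- which(meta$condition %in% c("match", "mismatch"))
      tfr_mm <- tfr
      tfr_mm$power <- tfr$power[mm_idx, , , , drop = FALSE]
      tfr_mm$events <- meta[mm_idx, ]
      base <- fit_baseline(tfr_mm)
      tmaps[[id]] <- lapply(
        stats::setNames(nm = c("miss", "item_only", "pair")),
        function(cond) condition_tmap(tfr_mm, base, cond))
      st <- single_trial_t(tfr_mm, base)
      saveRDS(st, file.path(st_dir, paste0(id, ".rds")))
    }
    saveRDS(tmaps, tmap_file)
  }
  stamp("eeg", tmap_file, t0)

  # ---- group-level cluster statistics -------------------------------------
  t0 <- as.numeric(Sys.time())
  cl_file <- file.path(cfg$out_dir, "clusters.json")
  cl_rds <- file.path(cfg$out_dir, "clusters.rds")
  if (resume && file.exists(cl_rds)) {
    say("cluster: reusing ", cl_rds)
    clusters <- readRDS(cl_rds)
  } else {
    say("cluster: permutation test over ", length(tmaps), " subjects")
    ccfg_args <- cfg$cluster
    ccfg_args$seed <- child_seed(cfg$seed, 2000L)
    ccfg <- do.call(cluster_config, ccfg_args)
    clusters <- permutation_test(tmaps, graph, ccfg)
    saveRDS(clusters, cl_rds)
  }
  jsonlite::write_json(
    lapply(clusters$clusters, function(cl) {
      list(sign = cl$sign, mass = cl$mass, p = cl$p,
           significant = isTRUE(cl$significant),
           n_points = nrow(cl$members), channels = cl$channels,
           freq_range = cl$freq_range, time_range = cl$time_range,
           members = cl$members)
    }),
    cl_file, auto_unbox = TRUE, digits = NA)
  stamp("cluster", c(cl_file, cl_rds), t0)

  # ---- FROI extraction and trial table ------------------------------------
  t0 <- as.numeric(Sys.time())
  tab_file <- file.path(cfg$out_dir, "trial_table.tsv")
  if (resume && file.exists(tab_file)) {
    say("froi: reusing ", tab_file)
    trial_table <- utils::read.delim(tab_file, stringsAsFactors = FALSE)
  } else {
    froi_theta <- build_froi(clusters, +1, restriction = cfg$theta_band)
    froi_alpha <- build_froi(clusters, -1)
    rows <- list()
    for (id in names(tmaps)) {
      st <- readRDS(file.path(st_dir, paste0(id, ".rds")))
      th <- froi_extract(st, froi_theta)
      al <- froi_extract(st, froi_alpha)
      rows[[id]] <- make_trial_table(st$events, th, al)
    }
    trial_table <- do.call(rbind, rows)
    rownames(trial_table) <- NULL
    utils::write.table(trial_table, tab_file, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  stamp("froi", tab_file, t0)

  # ---- single-trial mixed models ------------------------------------------
  t0 <- as.numeric(Sys.time())
  glmm_file <- file.path(cfg$out_dir, "glmm.json")
  say("glmm: fitting item-only and pair models")
  models <- fit_outcome_models(trial_table, nAGQ = cfg$nAGQ)
  glmm_json <- lapply(models, function(m) {
    s <- summary(m$fit)
    list(coefficients = as.data.frame(s$coefficients),
         sigma = m$fit$sigma, logLik = m$fit$logLik,
         AIC = m$fit$AIC, BIC = m$fit$BIC, conditional_r2 = m$r2,
         lrt_eeg = m$lrt_eeg, lrt_null = m$lrt_null)
  })
  jsonlite::write_json(glmm_json, glmm_file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  stamp("glmm", glmm_file, t0)

  manifest_file <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, digits = NA)
  structure(
    list(events = events, rates = rates, anova = anova_tab,
         clusters = clusters, trial_table = trial_table, models = models,
         excluded = excluded, out_dir = cfg$out_dir, manifest = manifest),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("oscsme pipeline run:", length(unique(x$events$subject)), "subjects (",
      length(x$excluded), "excluded )\n")
  print(x$anova)
  print(x$clusters)
  for (nm in names(x$models))
    cat(sprintf("%s model: conditional R2 = %.3f, EEG LRT p = %.3g\n",
                nm, x$models[[nm]]$r2, x$models[[nm]]$lrt_eeg$p))
  cat("artifacts in", x$out_dir, "\n")
  invisible(x)
}
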