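#' Experiment configuration
#'
#' Describes a full simulate-and-compare study: which connectome, which
#' models at which coupling presets, how many runs per condition, and which
#' analysis metrics to compute. The study-scale defaults (30 default-coupling
#' runs, 20 at low/high, 15 minutes at dt = 0.1 ms) match the full design;
#' `preset = "desk"` switches to a desk-scale configuration (dt = 1 ms,
#' 180 s, 3 runs) for quick checks.
#'
#' @param connectome_seed seed for [generate_synthetic_connectome()], or
#'   `connectome_paths = list(weights=, lengths=)` to load TSVs
#' @param connectome_paths optional TSV paths overriding the synthetic source
#' @param n_rois connectome size when synthetic
#' @param models character vector among `"firing_rate"`, `"kuramoto"`
#' @param couplings coupling presets among `"low"`, `"default"`, `"high"`
#' @param n_runs named runs-per-condition, e.g. `c(default = 30, low = 20,
#'   high = 20)`
#' @param duration,dt,tr simulation length (s), Euler step (s), scanner TR (s)
#' @param metrics metric toggles among `"fc"`, `"coactivation"`, `"qpp"`,
#'   `"states"`, `"rqa"`
#' @param include_surrogate logical; add a surrogate resting-state dataset as
#'   the empirical stand-in
#' @param seed master seed; every run seed is derived from it
#' @param preset `"study"` or `"desk"`
#' @return an `experiment_config` list
#' @export
experiment_config <- function(connectome_seed = 1L, connectome_paths = NULL,
                              n_rois = 66L,
                              models = c("firing_rate", "kuramoto"),
                              couplings = "default",
                              n_runs = c(default = 30L, low = 20L, high = 20L),
                              duration = 900, dt = 1e-4, tr = 0.72,
                              metrics = c("fc", "coactivation", "qpp",
                                          "states", "rqa"),
                              include_surrogate = FALSE, seed = 1L,
                              preset = c("study", "desk")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    duration <- 180 # leaves ~190 TRs after the neural and hemodynamic discards
    dt <- 1e-3
    n_runs <- c(default = 3L, low = 3L, high = 3L)
  }
  models <- match.arg(models, c("firing_rate", "kuramoto"), several.ok = TRUE)
  couplings <- match.arg(couplings, c("low", "default", "high"),
                         several.ok = TRUE)
  metrics <- match.arg(metrics, c("fc", "coactivation", "qpp", "states",
                                  "rqa"), several.ok = TRUE)
  if (any(n_runs[couplings] < 1L))
    stop_invalid("invalid argument: n_runs must be >= 1 for every coupling level")
  structure(list(connectome_seed = as.integer(connectome_seed),
                 connectome_paths = connectome_paths, n_rois = as.integer(n_rois),
                 models = models, couplings = couplings, n_runs = n_runs,
                 duration = duration, dt = dt, tr = tr, metrics = metrics,
                 include_surrogate = include_surrogate,
                 seed = as.integer(seed), preset = preset),
            class = "experiment_config")
}

load_or_generate_connectome <- function(cfg) {
  if (!is.null(cfg$connectome_paths)) {
    W <- unname(read_matrix(cfg$connectome_paths$weights))
    L <- unname(read_matrix(cfg$connectome_paths$lengths))
    connectome(W, lengths = L, normalize = TRUE)
  } else {
    generate_synthetic_connectome(cfg$n_rois, seed = cfg$connectome_seed)
  }
}

#' Run a full simulate-and-compare experiment
#'
#' Executes connectome generation, per-condition simulation ensembles
#' (model x coupling x run), Balloon-Windkessel conversion, TR downsampling,
#' preprocessing, the enabled analysis metrics, and assembles a comparison
#' report. Every random draw derives from the master seed. Per-run failures
#' are recorded (with the error message) without aborting the ensemble.
#'
#' @param cfg an [experiment_config()]
#' @return a `comparison_report`: per-dataset metric summaries, pairwise
#'   similarity tables, a qualitative ranking table, and provenance
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  conn <- load_or_generate_connectome(cfg)
  conditions <- expand.grid(model = cfg$models, coupling = cfg$couplings,
                            stringsAsFactors = FALSE)
  n_total <- sum(cfg$n_runs[conditions$coupling])
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L,
                                          n_total + cfg$n_runs["default"]))
  si <- 0L
  datasets <- list()
  for (ci in seq_len(nrow(conditions))) {
    model <- conditions$model[ci]
    coupling <- conditions$coupling[ci]
    nr <- cfg$n_runs[[coupling]]
    key <- paste(model, coupling, sep = ".")
    runs <- vector("list", nr)
    for (r in seq_len(nr)) {
      si <- si + 1L
      run_seed <- seeds[si]
      runs[[r]] <- tryCatch({
        sim_cfg <- simulation_config(model = model,
                                     k = coupling_presets(model, coupling),
                                     dt = cfg$dt, duration = cfg$duration,
                                     seed = run_seed)
        raw <- simulate_bold(conn, sim_cfg, tr = cfg$tr)
        list(raw = raw, pre = preprocess_pipeline(raw), seed = run_seed,
             ok = TRUE)
      }, error = function(e) list(ok = FALSE, seed = run_seed,
                                  error = conditionMessage(e)))
    }
    datasets[[key]] <- list(model = model, coupling = coupling, runs = runs)
  }
  if (isTRUE(cfg$include_surrogate)) {
    nr <- cfg$n_runs[["default"]]
    n_trs <- max(200L, floor(cfg$duration / cfg$tr))
    runs <- lapply(seq_len(nr), function(r) {
      scfg <- surrogate_rest_config(n_rois = conn$n_rois, n_trs = n_trs,
                                    tr = cfg$tr, seed = seeds[n_total + r])
      raw <- generate_surrogate_rest(scfg)
      list(raw = raw, pre = preprocess_pipeline(raw),
           seed = seeds[n_total + r], ok = TRUE)
    })
    datasets[["surrogate.default"]] <- list(model = "surrogate",
                                            coupling = "default", runs = runs)
  }
  report <- analyze_datasets(datasets, conn, cfg)
  report$provenance <- list(seed = cfg$seed, seeds = seeds[seq_len(si)],
                            preset = cfg$preset, dt = cfg$dt,
                            duration = cfg$duration, tr = cfg$tr,
                            n_rois = conn$n_rois,
                            failures = sum(vapply(datasets, function(d)
                              sum(!vapply(d$runs, `[[`, logical(1), "ok")),
                              numeric(1))))
  class(report) <- "comparison_report"
  report
}

# metric computations shared by run_experiment; operates on the nested
# datasets list and returns the report skeleton
analyze_datasets <- function(datasets, conn, cfg) {
  met <- cfg$metrics
  summaries <- list()
  qpps <- list()
  stacks <- list()
  for (key in names(datasets)) {
    ds <- datasets[[key]]
    ok_runs <- Filter(function(r) isTRUE(r$ok), ds$runs)
    s <- list(model = ds$model, coupling = ds$coupling,
              n_runs = length(ok_runs))
    if (!length(ok_runs)) { summaries[[key]] <- s; next }
    if ("fc" %in% met) {
      fcs <- lapply(ok_runs, function(r) average_fc(r$pre))
      s$mean_fc <- Reduce(`+`, fcs) / length(fcs)
      s$fc_sc_similarity <- fc_similarity(s$mean_fc, conn$weights)
      s$spectral_slope <- mean(vapply(ok_runs, function(r)
        spectral_slope(r$raw), numeric(1)))
    }
    if ("coactivation" %in% met) {
      co_fc <- vapply(ok_runs, function(r) {
        co <- coactivation_matrix(r$pre, threshold = 1)
        fc <- average_fc(r$pre)
        sym <- co$sym
        sym[!is.finite(sym)] <- 0
        fc_similarity(sym, fc)
      }, numeric(1))
      s$coactivation_fc_corr <- mean(co_fc)
      co <- coactivation_matrix(ok_runs[[1L]]$pre, threshold = 1)
      co0 <- coactivation_matrix(ok_runs[[1L]]$pre, threshold = 0)
      s$coactivation <- co$sym
      s$coactivation_thresh0 <- co0$sym
    }
    if ("qpp" %in% met) {
      qpp_runs <- lapply(seq_along(ok_runs), function(i)
        find_qpp(ok_runs[[i]]$pre, seed = ok_runs[[i]]$seed))
      qpps[[key]] <- qpp_runs
      s$qpp_template <- qpp_runs[[1L]]$template
      s$qpp_peak_rate_per_min <- mean(vapply(qpp_runs, function(q)
        length(q$peaks) / (length(q$corr_vector) * cfg$tr / 60), numeric(1)))
    }
    if ("states" %in% met) {
      stacks[[key]] <- pool_fc_stacks(lapply(seq_along(ok_runs), function(i)
        sliding_window_fc(ok_runs[[i]]$pre,
                          run_id = paste(key, i, sep = "_"))))
    }
    if ("rqa" %in% met) {
      rq <- lapply(ok_runs, function(r) rqa_metrics(recurrence_plot(r$pre)))
      s$rqa <- data.frame(rr = vapply(rq, `[[`, numeric(1), "rr"),
                          avg_diag_len = vapply(rq, `[[`, numeric(1),
                                                "avg_diag_len"),
                          entropy = vapply(rq, `[[`, numeric(1), "entropy"))
    }
    summaries[[key]] <- s
  }
  report <- list(datasets = summaries)
  if ("qpp" %in% met && length(qpps) >= 2L) {
    keys <- names(qpps)
    pairs <- utils::combn(keys, 2L)
    qs <- data.frame(a = pairs[1L, ], b = pairs[2L, ], corr = NA_real_)
    for (i in seq_len(ncol(pairs))) {
      al <- align_templates(qpps[[pairs[1L, i]]][[1L]],
                            qpps[[pairs[2L, i]]][[1L]])
      qs$corr[i] <- al$corr
    }
    report$qpp_cross_similarity <- qs
    report$qpp_occurrence <- template_occurrence_stats(
      lapply(qpps, function(q) unlist(lapply(q, `[[`, "corr_vector"))))
  }
  if ("states" %in% met && length(stacks)) {
    pooled <- pool_fc_stacks(stacks)
    model <- cluster_states(pooled, seed = cfg$seed)
    stats <- per_run_state_stats(model, tr = cfg$tr)
    stats$dataset <- sub("_[0-9]+$", "", stats$run_id)
    report$states <- list(model = model, per_run = stats)
    report$states$per_dataset <- lapply(split(stats, stats$dataset),
      function(df) list(mean_n_states = mean(df$n_states),
                        mean_dwell_s = mean(df$mean_dwell_s),
                        mean_centroid_dist = mean(df$mean_centroid_dist,
                                                  na.rm = TRUE)))
    report$states$transitions <- lapply(names(stacks), function(key) {
      sel <- grepl(paste0("^", key, "_"), model$run_id)
      sub <- model
      sub$labels <- model$labels[sel]
      sub$run_id <- model$run_id[sel]
      transition_analysis(sub)
    })
    names(report$states$transitions) <- names(stacks)
  }
  report$ranking <- rank_models(report)
  report
}

# qualitative model ranking across the five analysis techniques; when a
# surrogate dataset is present each model is ranked by closeness to it,
# otherwise the table records the per-model values side by side
rank_models <- function(report) {
  rows <- c("static_fc", "point_process", "qpp", "kmeans", "rqa")
  ds <- report$datasets
  keys <- names(ds)
  fr <- grep("^firing_rate\\.default", keys, value = TRUE)
  km <- grep("^kuramoto\\.default", keys, value = TRUE)
  out <- data.frame(technique = rows, firing_rate = NA_real_,
                    kuramoto = NA_real_)
  get <- function(key, field) {
    v <- if (length(key)) ds[[key]][[field]] else NULL
    if (is.null(v)) NA_real_ else v
  }
  out$firing_rate[1] <- get(fr, "fc_sc_similarity")
  out$kuramoto[1] <- get(km, "fc_sc_similarity")
  out$firing_rate[2] <- get(fr, "coactivation_fc_corr")
  out$kuramoto[2] <- get(km, "coactivation_fc_corr")
  out$firing_rate[3] <- get(fr, "qpp_peak_rate_per_min")
  out$kuramoto[3] <- get(km, "qpp_peak_rate_per_min")
  if (!is.null(report$states)) {
    pd <- report$states$per_dataset
    out$firing_rate[4] <- if (length(fr) && !is.null(pd[[fr]]))
      pd[[fr]]$mean_n_states else NA_real_
    out$kuramoto[4] <- if (length(km) && !is.null(pd[[km]]))
      pd[[km]]$mean_n_states else NA_real_
  }
  out$firing_rate[5] <- if (length(fr) && !is.null(ds[[fr]]$rqa))
    mean(ds[[fr]]$rqa$entropy) else NA_real_
  out$kuramoto[5] <- if (length(km) && !is.null(ds[[km]]$rqa))
    mean(ds[[km]]$rqa$entropy) else NA_real_
  out
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (machine-readable), `report.md` (human-readable table
#' of the five analysis techniques) and figure-ready TSV matrices per metric
#' under `dir`.
#'
#' @param report a [run_experiment()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  if (is.null(report$datasets) || !length(report$datasets))
    stop_invalid("validation error: report is missing section 'datasets'")
  if (is.null(report$ranking))
    stop_invalid("validation error: report is missing section 'ranking'")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  scalar_fields <- c("model", "coupling", "n_runs", "fc_sc_similarity",
                     "spectral_slope", "coactivation_fc_corr",
                     "qpp_peak_rate_per_min")
  js <- list(datasets = lapply(report$datasets, function(s)
               s[intersect(scalar_fields, names(s))]),
             ranking = report$ranking,
             qpp_cross_similarity = report$qpp_cross_similarity,
             provenance = report$provenance[c("seed", "preset", "dt",
                                              "duration", "tr", "n_rois",
                                              "failures")])
  if (!is.null(report$states))
    js$states <- list(per_run = report$states$per_run,
                      per_dataset = report$states$per_dataset,
                      sparsity = lapply(report$states$transitions,
                                        `[[`, "sparsity_fraction"))
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  paths <- c(paths, jp)
  for (key in names(report$datasets)) {
    s <- report$datasets[[key]]
    if (!is.null(s$mean_fc)) {
      p <- file.path(dir, paste0("fc_", key, ".tsv"))
      write_matrix(s$mean_fc, p)
      paths <- c(paths, p)
    }
    if (!is.null(s$qpp_template)) {
      p <- file.path(dir, paste0("qpp_template_", key, ".tsv"))
      write_matrix(s$qpp_template, p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(report$states)) {
    p <- file.path(dir, "state_centroids.tsv")
    write_matrix(report$states$model$centroids, p)
    paths <- c(paths, p)
    for (key in names(report$states$transitions)) {
      p <- file.path(dir, paste0("transitions_", key, ".tsv"))
      write_matrix(report$states$transitions[[key]]$transition_matrix, p)
      paths <- c(paths, p)
    }
  }
  md <- c("# Model comparison report", "",
          sprintf("Master seed: %s; preset: %s; %g s at dt %g s; TR %g s.",
                  report$provenance$seed, report$provenance$preset,
                  report$provenance$duration, report$provenance$dt,
                  report$provenance$tr), "",
          "| Analysis technique | Firing rate | Kuramoto |",
          "|---|---|---|",
          vapply(seq_len(nrow(report$ranking)), function(i)
            sprintf("| %s | %.3f | %.3f |", report$ranking$technique[i],
                    report$ranking$firing_rate[i],
                    report$ranking$kuramoto[i]), character(1)))
  mp <- file.path(dir, "report.md")
  writeLines(md, mp)
  paths <- c(paths, mp)
  invisible(paths)
}
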