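#' Pipeline configuration
#'
#' Bundles the sub-configurations of a full simulated study run. All
#' randomness flows from the single \code{seed}: each stage receives
#' the derived seed \code{seed + k * 10007 (mod 2^31 - 1)} with a fixed
#' per-stage offset k, so runs are reproducible end to end from one
#' integer.
#'
#' @param seed global integer seed.
#' @param n_participants cohort size.
#' @param cohort,friction,trials,perception,bootstrap optional
#'   pre-built sub-configs; defaults are derived from \code{seed}.
#' @param n_trace_participants how many participants additionally get
#'   per-trial force-trace simulation + extraction (0 disables the
#'   stage; it is a closure check, the analysis uses the true
#'   coefficients).
#' @param output_dir optional directory for the report CSVs.
#' @param benchmark_table optional path to a deposited participant
#'   table; when set, generation is skipped and the analysis runs on
#'   the file contents.
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1L, n_participants = 60,
                            cohort = NULL, friction = NULL, trials = NULL,
                            perception = NULL, bootstrap = NULL,
                            n_trace_participants = 0,
                            output_dir = NULL, benchmark_table = NULL) {
  sub_seed <- function(k) as.integer((seed + k * 10007) %% (2^31 - 1))
  structure(list(
    seed = as.integer(seed),
    cohort = if (is.null(cohort))
      cohort_config(n_participants = n_participants, seed = sub_seed(1))
      else cohort,
    friction = if (is.null(friction))
      friction_model_config(seed = sub_seed(2)) else friction,
    trials = if (is.null(trials)) trial_config() else trials,
    perception = if (is.null(perception))
      perception_model_config(seed = sub_seed(3)) else perception,
    bootstrap = if (is.null(bootstrap))
      bootstrap_config(seed = sub_seed(4)) else bootstrap,
    n_trace_participants = n_trace_participants,
    trace_seed = sub_seed(5),
    output_dir = output_dir,
    benchmark_table = benchmark_table
  ), class = "pipeline_config")
}

physiology_predictors <- function(tab, with_mc = TRUE) {
  cols <- c("sc_hydration", "ue", "r2", "sc_thickness")
  if (with_mc) cols <- c(cols, "mc_density")
  tab[, cols, drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Sequences the study's analysis: cohort generation (or benchmark
#' table import), friction-coefficient generation, optional force-trace
#' simulation and extraction closure, descriptive statistics,
#' correlation matrices, the two principal component analyses (friction
#' and perception outcomes; physiology and age), composite outcomes,
#' Table-3-style multiple regressions with Johnson relative weights,
#' the MC-by-hydration interaction model, the Weibull psychometric fit
#' with JND, and the MC-density age-decay fit with bootstrap CI. Writes
#' every table as CSV (with a seed/config-hash header line) when
#' \code{output_dir} is set.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Object of class \code{"report_bundle"}: a list of stage
#'   results and tables (see names), plus a \code{log} data frame of
#'   stage row counts and timings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, n, t0)
    log[[length(log) + 1]] <<- data.frame(stage = name, n = n,
                                          seconds = round(tic() - t0, 3))

  run_stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    res
  }

  benchmark <- !is.null(config$benchmark_table)
  if (benchmark) {
    t0 <- tic()
    imported <- run_stage("import", read_participant_table(config$benchmark_table))
    cohort <- imported$cohort
    mu <- imported$mu
    perception <- imported$perception
    stage("import", nrow(cohort), t0)
  } else {
    t0 <- tic()
    cohort <- run_stage("cohort", generate_cohort(config$cohort))
    stage("cohort", nrow(cohort), t0)
    t0 <- tic()
    mu <- run_stage("friction", generate_friction_coefficients(
      cohort, config$friction))
    stage("friction", nrow(mu), t0)
    t0 <- tic()
    perception <- run_stage("perception", generate_perception_data(
      cohort, config$perception))
    stage("perception", nrow(perception$two_point), t0)
  }

  extraction <- NULL
  if (!benchmark && config$n_trace_participants > 0) {
    t0 <- tic()
    extraction <- run_stage("extraction", {
      idx <- seq_len(min(config$n_trace_participants, nrow(cohort)))
      mu_cols <- grep("^mu_", names(mu), value = TRUE)
      rows <- list()
      for (i in idx) for (s in mu_cols) {
        tr <- generate_force_trace(mu[[s]][i], config$trials,
                                   seed = config$trace_seed + 131 * i +
                                     match(s, mu_cols))
        fs <- friction_coefficient(tr)
        rows[[length(rows) + 1]] <- data.frame(
          id = mu$id[i], sample = sub("^mu_", "", s),
          mu_true = mu[[s]][i], mu_extracted = fs$mu_median,
          cycle_rate = fs$cycle_rate)
      }
      do.call(rbind, rows)
    })
    stage("extraction", nrow(extraction), t0)
  }

  # descriptives + correlation matrices
  t0 <- tic()
  descriptives <- cohort_descriptives(cohort)
  phys_cols <- c("age", "sc_hydration", "sc_thickness", "sg_density",
                 "ridge_distance", "mc_density", "r0", "ue", "r2")
  phys_cols <- intersect(phys_cols, names(cohort))
  cor_physiology <- correlation_matrix_table(cohort[, phys_cols])
  mu_cols <- grep("^mu_", names(mu), value = TRUE)
  cor_friction <- correlation_matrix_table(mu[, mu_cols])
  stage("descriptives", nrow(descriptives), t0)

  # perception summaries
  t0 <- tic()
  if (!is.null(perception$pillar_detections)) {
    det <- detection_probability(perception$pillar_detections)
    pillar_rate <- det$per_participant
    detection_table <- det$per_sample
  } else if (!is.null(perception$pillar_rate)) {
    pillar_rate <- perception$pillar_rate
    detection_table <- NULL
  } else stop("pipeline stage 'perception_summary' failed: no pillar data")
  two_point <- perception$two_point$threshold_mm
  stage("perception_summary", length(two_point), t0)

  # PCA on friction + perception outcomes, and on physiology + age
  t0 <- tic()
  pca_outcome_tab <- cbind(mu[, mu_cols],
                           two_point = two_point,
                           pillar_rate = pillar_rate)
  pca_outcomes <- pca_varimax(pca_outcome_tab)
  pca_physiology <- pca_varimax(
    cohort[, intersect(c("mc_density", "age", "r2", "sc_thickness",
                         "ridge_distance", "sc_hydration", "sg_density",
                         "r0"), names(cohort))])
  stage("pca", pca_outcomes$n, t0)

  # composites and regressions
  t0 <- tic()
  composites <- build_composites(mu, pillar_rate, two_point)
  X5 <- physiology_predictors(cohort)
  regressions <- list(
    mu_rough = ols_fit(X5, composites$mu_rough),
    mu_fibril = ols_fit(X5, composites$mu_fibril),
    s_perc = ols_fit(X5, composites$s_perc))
  regression_table <- do.call(rbind, lapply(names(regressions), function(o) {
    f <- regressions[[o]]
    row <- data.frame(outcome = o, r_squared = f$r_squared,
                      df_resid = f$df_resid)
    for (v in names(f$t_values)) {
      row[[paste0("t_", v)]] <- f$t_values[[v]]
      row[[paste0("p_", v)]] <- f$p_values[[v]]
    }
    row
  }))
  X4 <- physiology_predictors(cohort, with_mc = FALSE)
  weights_rough <- johnson_relative_weights(X4, composites$mu_rough)
  per_sample_weights <- sample_regressions(mu[, mu_cols], X4)
  interaction <- interaction_model(cohort$mc_density,
                                   cohort$sc_hydration,
                                   composites$s_perc)
  stage("regression", nrow(regression_table), t0)

  # psychometric fit (needs raw pairwise outcomes; absent in benchmark tables)
  psychometric <- NULL
  if (!is.null(perception$roughness)) {
    t0 <- tic()
    rough_agg <- stats::aggregate(success ~ rel_diff,
                                  data = perception$roughness,
                                  FUN = function(s) c(sum(s), length(s)))
    psychometric <- fit_weibull(rough_agg$rel_diff,
                                rough_agg$success[, 1],
                                rough_agg$success[, 2])
    stage("psychometric", psychometric$n_obs, t0)
  }

  # MC density age decay
  t0 <- tic()
  keep <- is.finite(cohort$age) & is.finite(cohort$mc_density)
  decay <- fit_age_decay(cohort$age[keep], cohort$mc_density[keep],
                         bootstrap = config$bootstrap)
  stage("decay", sum(keep), t0)

  out <- list(cohort = cohort, mu = mu, perception = perception,
              extraction = extraction,
              descriptives = descriptives,
              cor_physiology = cor_physiology,
              cor_friction = cor_friction,
              detection = detection_table,
              pca_outcomes = pca_outcomes,
              pca_physiology = pca_physiology,
              composites = composites,
              regressions = regressions,
              regression_table = regression_table,
              weights_rough = weights_rough,
              per_sample_weights = per_sample_weights,
              interaction = interaction,
              psychometric = psychometric,
              decay = decay,
              seed = config$seed,
              config_hash = config_hash(config),
              log = do.call(rbind, log))
  class(out) <- "report_bundle"
  if (!is.null(config$output_dir)) write_report_bundle(out, config$output_dir)
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Report bundle (seed %d, config %s)\n", x$seed, x$config_hash))
  cat(sprintf("  %d participants; %d outcome PCA components (%.1f%% cum.)\n",
              nrow(x$cohort), x$pca_outcomes$n_components,
              x$pca_outcomes$cumulative_pct[x$pca_outcomes$n_components]))
  cat(sprintf("  mu_rough mean %.2f; regression R^2: %s\n",
              mean(x$composites$mu_rough),
              paste(sprintf("%s %.2f", x$regression_table$outcome,
                            x$regression_table$r_squared), collapse = ", ")))
  cat(sprintf("  JND %.3f; MC half-life %.1f y [%.1f, %.1f]\n",
              x$psychometric$jnd, x$decay$half_life,
              x$decay$ci_low, x$decay$ci_high))
  cat("\nStage log:\n"); print(x$log)
  invisible(x)
}

# order-independent short hash of the deparsed config (djb2)
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "output_dir")]),
             collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^28
  sprintf("%07x", h)
}

#' Write the report bundle as CSV files
#'
#' Each table is written with a leading comment line
#' \code{# seed=<seed> config=<hash>} followed by a normal header row.
#'
#' @param bundle a \code{"report_bundle"}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("# seed=%d config=%s", bundle$seed, bundle$config_hash)
  wr <- function(obj, name, rownames = FALSE) {
    path <- file.path(dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(obj, con, sep = ",", row.names = rownames,
                       col.names = TRUE, qmethod = "double")
    close(con)
  }
  wr(bundle$cohort, "cohort")
  wr(bundle$mu, "friction_coefficients")
  wr(bundle$descriptives, "descriptives")
  wr(as.data.frame(bundle$cor_physiology), "correlations_physiology",
     rownames = TRUE)
  wr(as.data.frame(bundle$cor_friction), "correlations_friction",
     rownames = TRUE)
  wr(as.data.frame(round(bundle$pca_outcomes$loadings, 3)),
     "pca_outcomes_loadings", rownames = TRUE)
  wr(as.data.frame(round(bundle$pca_physiology$loadings, 3)),
     "pca_physiology_loadings", rownames = TRUE)
  wr(bundle$composites, "composites")
  wr(bundle$regression_table, "regressions")
  wr(bundle$per_sample_weights, "relative_weights_per_sample")
  wr(data.frame(k = bundle$psychometric$k, d = bundle$psychometric$d,
                jnd = bundle$psychometric$jnd,
                log_likelihood = bundle$psychometric$log_likelihood),
     "psychometric_fit")
  wr(data.frame(slope = bundle$decay$slope,
                half_life = bundle$decay$half_life,
                R_log = bundle$decay$R,
                ci_low = bundle$decay$ci_low,
                ci_high = bundle$decay$ci_high), "decay_fit")
  if (!is.null(bundle$extraction)) wr(bundle$extraction, "extraction")
  invisible(dir)
}

# alias map for deposited/benchmark tables; keys are lower-cased,
# punctuation-stripped column names
column_aliases <- function() {
  list(
    id = c("id", "participant", "subject"),
    age = "age",
    sex = c("sex", "gender"),
    sc_hydration = c("sc_hydration", "schydration", "hydration"),
    sc_thickness = c("sc_thickness", "scthickness", "thickness"),
    sg_density = c("sg_density", "sgdensity", "sg_per_mm2", "sgpermm2"),
    ridge_distance = c("ridge_distance", "ridgedistance", "ridge"),
    mc_density = c("mc_density", "mcdensity", "mcs_per_mm2", "mcspermm2",
                   "mc_per_mm2"),
    r0 = "r0", ue = "ue", r2 = "r2",
    two_point = c("two_point", "twopoint", "two_points", "twopoints",
                  "two_point_mm", "threshold_mm"),
    pillar_rate = c("pillar_rate", "av_percep_pillar", "avperceppillar",
                    "pillar_perception", "perception_pillar")
  )
}

#' Read a participant table (benchmark mode)
#'
#' Imports a deposited-style CSV of per-participant results, mapping
#' recognized column-name variants onto the package vocabulary
#' (\code{age, sex, sc_hydration, sc_thickness, sg_density,
#' ridge_distance, mc_density, r0, ue, r2}, friction columns
#' \code{mu_<sample>}, perception columns \code{two_point} and
#' \code{pillar_rate}). Unknown columns are preserved and flagged in
#' the attribute \code{"unknown_columns"}; a non-numeric cell in a
#' numeric column is reported with its row and column.
#'
#' @param path CSV file path (header row; \code{#} lines are skipped).
#' @param required canonical names that must be present.
#' @return List with \code{cohort} (physiology data frame), \code{mu}
#'   (id + friction columns), \code{perception} (list in the shape
#'   produced by \code{\link{generate_perception_data}}, as far as the
#'   table allows) and \code{unknown_columns}.
#' @export
read_participant_table <- function(path,
                                   required = c("age", "sc_hydration",
                                                "sc_thickness",
                                                "mc_density", "ue", "r2")) {
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  norm <- function(x) gsub("[^a-z0-9_]", "", gsub("[ ./-]", "_",
                                                  tolower(trimws(x))))
  nm <- norm(names(raw))
  aliases <- column_aliases()
  canonical <- rep(NA_character_, length(nm))
  for (canon in names(aliases))
    canonical[nm %in% norm(aliases[[canon]])] <- canon
  mu_idx <- grepl("^mu_?", nm) | grepl("^mus", nm)
  canonical[mu_idx] <- paste0("mu_", sub("^mu_?s?", "S",
                                         sub("^mus", "S", nm[mu_idx])))
  # pillar labels like mu40_120 -> mu_40_120
  bad_s <- grepl("^mu_S[0-9]+_[0-9]+$", canonical) & !is.na(canonical)
  canonical[bad_s] <- sub("^mu_S", "mu_", canonical[bad_s])
  unknown <- names(raw)[is.na(canonical)]
  canonical[is.na(canonical)] <- nm[is.na(canonical)]
  names(raw) <- canonical

  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  numeric_cols <- setdiff(names(raw), c("id", "sex"))
  for (v in numeric_cols) {
    if (is.character(raw[[v]])) {
      conv <- suppressWarnings(as.numeric(raw[[v]]))
      bad <- which(!is.na(raw[[v]]) & raw[[v]] != "" & is.na(conv))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                     v, bad[1], raw[[v]][bad[1]]))
      raw[[v]] <- conv
    }
  }
  if (!"id" %in% names(raw)) raw$id <- sprintf("P%03d", seq_len(nrow(raw)))

  phys <- intersect(c("id", "age", "sex", "sc_hydration", "sc_thickness",
                      "sg_density", "ridge_distance", "mc_density", "r0",
                      "ue", "r2"), names(raw))
  mu_cols <- grep("^mu_", names(raw), value = TRUE)
  perception <- list(
    two_point = if ("two_point" %in% names(raw))
      data.frame(id = raw$id, threshold_mm = raw$two_point) else NULL,
    pillar_detections = NULL,
    pillar_rate = if ("pillar_rate" %in% names(raw))
      stats::setNames(raw$pillar_rate, raw$id) else NULL,
    roughness = NULL)
  list(cohort = raw[, phys, drop = FALSE],
       mu = raw[, c("id", mu_cols), drop = FALSE],
       perception = perception,
       unknown_columns = unknown)
}

#' Read a pipeline configuration from a YAML file
#'
#' Structured-text configuration: top-level \code{seed} is mandatory;
#' optional keys \code{n_participants}, \code{n_trace_participants},
#' \code{output_dir}, \code{benchmark_table} and sub-maps
#' \code{cohort}, \code{friction}, \code{perception}, \code{bootstrap}
#' whose entries are passed to the respective config constructors.
#'
#' @param path YAML file.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config file must set a seed")
  args <- list(seed = as.integer(y$seed))
  for (k in c("n_participants", "n_trace_participants", "output_dir",
              "benchmark_table"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  sub_seed <- function(k) as.integer((args$seed + k * 10007) %% (2^31 - 1))
  if (!is.null(y$cohort)) {
    defaults <- list(seed = sub_seed(1))
    if (!is.null(y$n_participants))
      defaults$n_participants <- y$n_participants
    args$cohort <- do.call(cohort_config,
                           utils::modifyList(defaults, y$cohort))
  }
  if (!is.null(y$friction))
    args$friction <- do.call(friction_model_config,
                             utils::modifyList(list(seed = sub_seed(2)),
                                               y$friction))
  if (!is.null(y$perception))
    args$perception <- do.call(perception_model_config,
                               utils::modifyList(list(seed = sub_seed(3)),
                                                 y$perception))
  if (!is.null(y$bootstrap))
    args$bootstrap <- do.call(bootstrap_config,
                              utils::modifyList(list(seed = sub_seed(4)),
                                                y$bootstrap))
  do.call(pipeline_config, args)
}
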