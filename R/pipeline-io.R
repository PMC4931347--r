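#' Table schemas used by the pipeline
#'
#' Named list of column-name/column-type schemas for the delimited
#' (TSV) files the pipeline reads and writes. Types are `"integer"`,
#' `"numeric"` or `"character"`; `chosen_loc` and `correct_loc` accept
#' NA (unanswered / no correct target).
#'
#' @return Named list of schemas.
#' @export
table_schemas <- function() {
  list(
    trials = c(trial_id = "integer", condition = "character",
               eccentricity_deg = "numeric", s1 = "numeric",
               s2 = "numeric", s3 = "numeric", s4 = "numeric",
               correct_loc = "integer", chosen_loc = "integer"),
    vertices = c(vertex_id = "integer", region = "character",
                 quadrant = "character", ecc_deg = "numeric",
                 polar_deg = "numeric", sigma_deg = "numeric",
                 area_mm2 = "numeric"),
    maps_fits = c(observer = "integer", condition = "character",
                  eccentricity_deg = "numeric", location = "integer",
                  mu = "numeric", sigma = "numeric",
                  fit_error = "numeric", n_trials = "integer"),
    prf_fits = c(unit = "integer", x = "numeric", y = "numeric",
                 spread = "numeric", amplitude = "numeric",
                 r = "numeric")
  )
}

#' Write a pipeline table as tab-separated text
#'
#' @param df Data frame matching one of the [table_schemas()].
#' @param path Output file.
#' @param schema Schema name (validated before writing) or NULL to
#'   skip validation.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, schema = NULL) {
  if (!is.null(schema)) df <- validate_table(df, schema)
  # print doubles with 17 significant digits so values round-trip exactly
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and validate a pipeline table
#'
#' @param path TSV file with a header row.
#' @param schema Schema name from [table_schemas()].
#' @return Validated data frame with typed columns.
#' @export
read_table_tsv <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", na.strings = "NA",
                          stringsAsFactors = FALSE)
  validate_table(df, schema)
}

validate_table <- function(df, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) stop("unknown schema: ", schema)
  sc <- schemas[[schema]]
  missing <- setdiff(names(sc), names(df))
  if (length(missing) > 0L) {
    stop("table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in names(sc)) {
    v <- df[[col]]
    df[[col]] <- switch(sc[[col]],
      integer = {
        iv <- suppressWarnings(as.integer(v))
        bad <- which(!is.na(v) & is.na(iv))
        if (length(bad) > 0L) {
          stop("column '", col, "': non-integer value at line ",
               bad[1L] + 1L)
        }
        iv
      },
      numeric = {
        nv <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(v) & is.na(nv))
        if (length(bad) > 0L) {
          stop("column '", col, "': non-numeric value at line ",
               bad[1L] + 1L)
        }
        nv
      },
      character = as.character(v)
    )
  }
  df
}

#' Default run configuration
#'
#' All seeds and tunable parameters of a full pipeline run, suitable
#' for YAML round-tripping with [write_run_config()] /
#' [read_run_config()].
#'
#' @param seed Master seed (mandatory for reproducibility).
#' @param n_observers,n_trials,coupling Synthetic-world parameters.
#' @param eccentricities Stimulus eccentricities (degrees).
#' @param fit_restarts Restarts of the MAPS fitter.
#' @param fit_prfs Whether to simulate BOLD and fit pRFs (slow) or use
#'   the vertex table's spreads directly.
#' @param prf_subsample When fitting pRFs, vertices per quadrant to
#'   fit.
#' @param grid_n Aperture grid resolution (pixels per side).
#' @param bold_noise_sd BOLD noise SD.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_observers = 10L, n_trials = 200L,
                       coupling = 0.5,
                       eccentricities = c(1.96, 3.92, 7.84),
                       fit_restarts = 20L, fit_prfs = FALSE,
                       prf_subsample = 25L, grid_n = 61L,
                       bold_noise_sd = 0.5) {
  structure(
    list(seed = as.integer(seed), n_observers = as.integer(n_observers),
         n_trials = as.integer(n_trials), coupling = coupling,
         eccentricities = eccentricities,
         fit_restarts = as.integer(fit_restarts),
         fit_prfs = isTRUE(fit_prfs),
         prf_subsample = as.integer(prf_subsample),
         grid_n = as.integer(grid_n), bold_noise_sd = bold_noise_sd),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Fit the MAPS model for every run in a synthetic world
#'
#' @param world A `synthetic_world` from [make_world()].
#' @param restarts Restarts per fit.
#' @return `maps_fits` data frame (see [table_schemas()]).
#' @export
fit_world_maps <- function(world, restarts = 20L) {
  rows <- list()
  for (o in seq_len(world$n_observers)) {
    for (cond in c("isolated", "delboeuf")) {
      for (e in world$eccentricities) {
        tr <- world$trials[[o]][[cond]][[as.character(e)]]
        fit <- fit_maps_model(tr, restarts = restarts)
        rows[[length(rows) + 1L]] <- data.frame(
          observer = o, condition = cond, eccentricity_deg = e,
          location = 1:4, mu = fit$mu, sigma = fit$sigma,
          fit_error = fit$fit_error, n_trials = fit$n_trials
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Assemble the per-location analysis dataset
#'
#' Joins the behavioural fits with the cortical predictors into the
#' full design (observers x eccentricities x quadrants), the input to
#' the statistical battery.
#'
#' @param maps_fits Fit table from [fit_world_maps()].
#' @param cortex_summaries List (per observer) of [summarize_cortex()]
#'   outputs.
#' @return Data frame with one row per observer/eccentricity/quadrant:
#'   biases and dispersions per condition plus `spread_hat`,
#'   `local_area`, `quadrant_area_pct`.
#' @export
build_location_dataset <- function(maps_fits, cortex_summaries) {
  iso <- maps_fits[maps_fits$condition == "isolated", ]
  del <- maps_fits[maps_fits$condition == "delboeuf", ]
  key <- function(d) paste(d$observer, d$eccentricity_deg, d$location)
  del <- del[match(key(iso), key(del)), ]
  cort <- do.call(rbind, lapply(seq_along(cortex_summaries), function(o) {
    cbind(observer = o, cortex_summaries[[o]])
  }))
  ck <- paste(cort$observer, cort$ecc, cort$location)
  m <- match(key(iso), ck)
  data.frame(
    observer = iso$observer, eccentricity = iso$eccentricity_deg,
    quadrant = quadrant_labels()[iso$location],
    location = iso$location,
    bias_isolated = iso$mu, bias_delboeuf = del$mu,
    dispersion_isolated = iso$sigma, dispersion_delboeuf = del$sigma,
    spread_hat = cort$spread_hat[m], local_area = cort$local_area[m],
    quadrant_area_pct = cort$quadrant_area_pct[m]
  )
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a coupled world, fits the MAPS detector model to every
#' run, (optionally) simulates BOLD series and fits pRFs per vertex,
#' summarises the cortical architecture, joins everything into the
#' location dataset, and runs the statistical battery.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_report`: `config`, `dataset`,
#'   `maps_fits`, `stats` (pooled / demeaned / regression /
#'   second-level results for pRF spread vs isolated-circle bias),
#'   `pca`, and `condition_matrix`.
#' @export
run_full_pipeline <- function(config = run_config()) {
  set.seed(config$seed)
  world <- make_world(config$n_observers, config$n_trials,
                      config$coupling, config$eccentricities)
  maps_fits <- fit_world_maps(world, restarts = config$fit_restarts)

  cortices <- world$cortices
  if (config$fit_prfs) {
    ap <- build_apertures(aperture_config(grid_n = config$grid_n))
    gp <- prf_grid_predictions(ap)
    cortices <- lapply(cortices, function(vt) {
      idx <- unlist(lapply(split(seq_len(nrow(vt)), vt$quadrant),
                           utils::head, config$prf_subsample))
      sub <- vt[sort(idx), , drop = FALSE]
      bold <- make_bold(sub, ap, noise_sd = config$bold_noise_sd)
      fits <- fit_prf(bold$series, ap, grid_pred = gp)
      sub$sigma_deg <- fits$spread
      sub$ecc_deg <- sqrt(fits$x^2 + fits$y^2)
      sub$polar_deg <- (atan2(fits$y, fits$x) * 180 / pi) %% 360
      sub
    })
  }
  summaries <- lapply(cortices, summarize_cortex,
                      ecc = config$eccentricities)
  dataset <- build_location_dataset(maps_fits, summaries)

  stats <- list(
    pooled = pooled_pearson(dataset$spread_hat, dataset$bias_isolated),
    demeaned = demeaned_correlation(dataset$spread_hat,
                                    dataset$bias_isolated,
                                    dataset$observer,
                                    dataset$eccentricity),
    regression = variance_partition_regression(
      dataset$spread_hat, dataset$bias_isolated, dataset$observer,
      dataset$eccentricity, dataset$quadrant),
    second_level = second_level_location_correlation(
      dataset$spread_hat, dataset$bias_isolated, dataset$observer,
      dataset$eccentricity)
  )
  pca <- pca_six_variable(dataset[, c("bias_isolated", "bias_delboeuf",
                                      "dispersion_isolated",
                                      "dispersion_delboeuf",
                                      "spread_hat", "local_area")])
  wide <- stats::reshape(
    dataset[, c("observer", "location", "eccentricity", "bias_isolated",
                "bias_delboeuf")],
    direction = "wide", idvar = c("observer", "location"),
    timevar = "eccentricity")
  cond_mat <- condition_correlation_matrix(wide[, -(1:2)])

  structure(
    list(config = config, dataset = dataset, maps_fits = maps_fits,
         stats = stats, pca = pca, condition_matrix = cond_mat),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Synthetic pipeline report\n")
  cat("  observers:", x$config$n_observers,
      " trials/run:", x$config$n_trials,
      " coupling:", x$config$coupling, "\n")
  cat("  pooled spread-bias correlation: ")
  print(x$stats$pooled)
  cat("  demeaned correlation: ")
  print(x$stats$demeaned)
  cat("  PCA percent variance:",
      paste(round(x$pca$percent_variance, 1), collapse = ", "), "\n")
  invisible(x)
}
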