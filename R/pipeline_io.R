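#' Readers for the study CSV schemas
#'
#' Strict, validated CSV input. Each reader requires its schema columns
#' (header mandatory, UTF-8), preserves unknown extra columns with a
#' warning, and enforces the unit policy: user-facing temperatures are
#' always deg C - a `temp_c` column whose values look like kelvin
#' (>= 200) is rejected with a message.
#'
#' Schemas:
#' * `od_masses.csv`: treatment, time_min, m0_g, m_wet_g, m_dry_g, dw_wb
#' * `storage_tvc.csv`: treatment, temp_c, time_d, log_cfu_g
#' * `storage_sensory.csv`: treatment, temp_c, time_d, attribute, score
#' * `color.csv`: treatment, temp_c, time_d, replicate, L, a, b
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @name study-readers
NULL

read_schema <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("%s: unknown column(s) preserved: %s", basename(path),
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  if ("temp_c" %in% names(df) && any(df$temp_c >= 200)) {
    stop(sprintf(
      "%s: temp_c values >= 200 look like kelvin; temperatures must be deg C",
      basename(path)), call. = FALSE)
  }
  df
}

#' @rdname study-readers
#' @export
read_od_masses <- function(path) {
  read_schema(path, c("treatment", "time_min", "m0_g", "m_wet_g", "m_dry_g",
                      "dw_wb"))
}

#' @rdname study-readers
#' @export
read_storage_tvc <- function(path) {
  read_schema(path, c("treatment", "temp_c", "time_d", "log_cfu_g"))
}

#' @rdname study-readers
#' @export
read_storage_sensory <- function(path) {
  read_schema(path, c("treatment", "temp_c", "time_d", "attribute", "score"))
}

#' @rdname study-readers
#' @export
read_color <- function(path) {
  read_schema(path, c("treatment", "temp_c", "time_d", "replicate",
                      "L", "a", "b"))
}

#' Pipeline run configuration
#'
#' @param od_masses,storage_tvc,storage_sensory Paths to the input CSVs
#'   (any may be `NULL` to skip that stage).
#' @param color Optional path to replicate color readings.
#' @param T_ref_celsius Arrhenius reference temperature, deg C.
#' @param limits A [shelf_life_limits()].
#' @param r2_min Primary-fit acceptance threshold on r2.
#' @param predict_temps_c Temperatures for the shelf-life table; default:
#'   the storage temperatures present in the data.
#' @param outdir Output directory for reports (`NULL`: nothing written).
#' @return A `run_config` list.
#' @export
run_config <- function(od_masses = NULL, storage_tvc = NULL,
                       storage_sensory = NULL, color = NULL,
                       T_ref_celsius = 4, limits = shelf_life_limits(),
                       r2_min = 0.7, predict_temps_c = NULL,
                       outdir = NULL) {
  stopifnot(inherits(limits, "shelf_life_limits"))
  structure(list(od_masses = od_masses, storage_tvc = storage_tvc,
                 storage_sensory = storage_sensory, color = color,
                 T_ref_celsius = T_ref_celsius, limits = limits,
                 r2_min = r2_min, predict_temps_c = predict_temps_c,
                 outdir = outdir),
            class = "run_config")
}

#' Run the full shelf-life modelling pipeline
#'
#' Per treatment: penetration fits of water loss and solid gain; per
#' storage temperature, Gompertz fits of total viable counts (with fit
#' quality) and zero-order sensory fits; Arrhenius secondary fits of the
#' accepted rates; and a shelf-life table across the requested
#' temperatures with the limiting spoilage mode. A treatment whose growth
#' series are all classified `no_growth_trend` gets a microbially *stable*
#' endpoint and its shelf life is sensory-limited.
#'
#' Individual series whose fits fail are reported in `$fit_errors` without
#' aborting the remaining series. If `outdir` is set, a machine-readable
#' `report.json`, a human-readable `report.txt`, and `od_fits.csv` /
#' `shelf_life.csv` tables are written.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list with components `od_fits`,
#'   `growth_fits`, `sensory_fits`, `secondary`, `shelf_life`,
#'   `fit_errors`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  errors <- list()
  note_error <- function(stage, id, e) {
    errors[[length(errors) + 1L]] <<- list(stage = stage, series = id,
                                           message = conditionMessage(e))
  }

  ## ---- osmotic-dehydration stage ----
  od_fits <- NULL
  if (!is.null(config$od_masses)) {
    od <- read_od_masses(config$od_masses)
    od_fits <- do.call(rbind, lapply(split(od, od$treatment), function(d) {
      d <- d[order(d$time_min), ]
      ser <- withCallingHandlers(
        build_od_series(d, dw_wb = d$dw_wb[1]),
        warning = function(w) invokeRestart("muffleWarning"))
      do.call(rbind, lapply(c("wl", "sg"), function(resp) {
        f <- fit_penetration(ser, resp)
        data.frame(treatment = d$treatment[1], response = resp,
                   k = f$k, se_k = f$se_k, r2 = f$r2)
      }))
    }))
    rownames(od_fits) <- NULL
  }

  ## ---- primary growth fits ----
  growth_fits <- list()
  if (!is.null(config$storage_tvc)) {
    tvc <- read_storage_tvc(config$storage_tvc)
    for (tr in unique(tvc$treatment)) {
      dtr <- tvc[tvc$treatment == tr, ]
      growth_fits[[tr]] <- list()
      for (Tc in sort(unique(dtr$temp_c))) {
        d <- dtr[dtr$temp_c == Tc, ]
        d <- d[order(d$time_d), ]
        key <- sprintf("%s@%g", tr, Tc)
        fit <- tryCatch(
          fit_gompertz(growth_series(d$time_d, d$log_cfu_g, Tc),
                       r2_min = config$r2_min),
          error = function(e) { note_error("gompertz", key, e); NULL })
        if (!is.null(fit)) growth_fits[[tr]][[as.character(Tc)]] <- fit
      }
    }
  }

  ## ---- primary sensory fits ----
  sensory_fits <- list()
  if (!is.null(config$storage_sensory)) {
    sens <- read_storage_sensory(config$storage_sensory)
    for (tr in unique(sens$treatment)) {
      dtr <- sens[sens$treatment == tr, ]
      sensory_fits[[tr]] <- list()
      for (Tc in sort(unique(dtr$temp_c))) {
        d <- dtr[dtr$temp_c == Tc, ]
        d <- d[order(d$time_d), ]
        key <- sprintf("%s@%g", tr, Tc)
        fit <- tryCatch(
          fit_zero_order(sensory_series(d$time_d, d$score, Tc,
                                        attribute = d$attribute[1])),
          error = function(e) { note_error("zero_order", key, e); NULL })
        if (!is.null(fit)) sensory_fits[[tr]][[as.character(Tc)]] <- fit
      }
    }
  }

  ## ---- secondary models + shelf life, per treatment ----
  secondary <- list()
  sl_rows <- list()
  treatments <- union(names(growth_fits), names(sensory_fits))
  for (tr in treatments) {
    gf <- growth_fits[[tr]]
    sf <- sensory_fits[[tr]]

    accepted <- Filter(function(f) f$quality$accepted, gf)
    mu_model <- NULL
    lag_model <- NULL
    microbially_stable <- length(gf) > 0 && length(accepted) == 0
    if (length(accepted) >= 2) {
      temps <- vapply(accepted, `[[`, 0, "temperature")
      mu_model <- tryCatch(
        fit_arrhenius(temps, vapply(accepted, `[[`, 0, "mu_m"),
                      config$T_ref_celsius),
        error = function(e) { note_error("arrhenius_mu", tr, e); NULL })
      lag_model <- fit_lag_model(
        temps, vapply(accepted, `[[`, 0, "lambda"),
        reliable = vapply(accepted, `[[`, TRUE, "lambda_reliable"),
        T_ref_celsius = config$T_ref_celsius)
    } else if (length(accepted) == 1) {
      # single usable temperature: temperature-independent fallback rate
      mu_model <- accepted[[1]]$mu_m
      lag_model <- accepted[[1]]$lambda
    }
    logN0 <- if (length(gf)) mean(vapply(gf, `[[`, 0, "logN0")) else NA_real_

    ks_model <- NULL
    if (length(sf) >= 2) {
      ks_model <- tryCatch(
        fit_arrhenius(vapply(sf, `[[`, 0, "temperature"),
                      vapply(sf, `[[`, 0, "k_s"), config$T_ref_celsius),
        error = function(e) { note_error("arrhenius_ks", tr, e); NULL })
    } else if (length(sf) == 1) {
      ks_model <- sf[[1]]$k_s
    }
    S0 <- if (length(sf)) mean(vapply(sf, `[[`, 0, "S0")) else NA_real_

    secondary[[tr]] <- list(mu = mu_model, lag = lag_model, ks = ks_model,
                            logN0 = logN0, S0 = S0,
                            microbially_stable = microbially_stable)

    temps_pred <- config$predict_temps_c
    if (is.null(temps_pred)) {
      temps_pred <- sort(unique(c(
        if (length(gf)) vapply(gf, `[[`, 0, "temperature"),
        if (length(sf)) vapply(sf, `[[`, 0, "temperature"))))
    }
    for (Tc in temps_pred) {
      sl_s <- if (!is.null(ks_model) && !is.na(S0)) {
        as.numeric(shelf_life_sensory(S0, ks_model, Tc, config$limits))
      } else NA_real_
      sl_m <- if (microbially_stable || is.null(mu_model)) {
        Inf
      } else {
        as.numeric(shelf_life_microbial(logN0, mu_model, lag_model, Tc,
                                        config$limits))
      }
      res <- combined_shelf_life(if (is.na(sl_s)) Inf else sl_s, sl_m, Tc)
      sl_rows[[length(sl_rows) + 1L]] <- data.frame(
        treatment = tr, temp_c = Tc,
        sl_sensory_d = sl_s, sl_microbial_d = sl_m,
        sl_combined_d = res$sl_combined, limiting_mode = res$limiting_mode)
    }
  }
  shelf_life <- if (length(sl_rows)) do.call(rbind, sl_rows) else NULL

  report <- structure(
    list(od_fits = od_fits, growth_fits = growth_fits,
         sensory_fits = sensory_fits, secondary = secondary,
         shelf_life = shelf_life, fit_errors = errors,
         config = config),
    class = "pipeline_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$od_fits)) {
    utils::write.csv(report$od_fits, file.path(outdir, "od_fits.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$shelf_life)) {
    utils::write.csv(report$shelf_life,
                     file.path(outdir, "shelf_life.csv"), row.names = FALSE)
  }
  json <- list(
    od_fits = report$od_fits,
    growth_fits = lapply(report$growth_fits, function(l) {
      lapply(l, function(f) {
        list(temperature = f$temperature, logN0 = f$logN0, logNm = f$logNm,
             mu_m = f$mu_m, lambda = f$lambda,
             se = as.list(f$se), r2 = f$r2,
             quality = f$quality$reason,
             lambda_reliable = f$lambda_reliable)
      })
    }),
    sensory_fits = lapply(report$sensory_fits, function(l) {
      lapply(l, function(f) {
        list(temperature = f$temperature, S0 = f$S0, k_s = f$k_s,
             direction = f$direction, se_S0 = f$se_S0, se_ks = f$se_ks,
             r2 = f$r2)
      })
    }),
    secondary = lapply(report$secondary, function(s) {
      arr <- function(m) {
        if (inherits(m, "arrhenius_fit")) {
          list(k_ref = m$k_ref, T_ref_c = m$T_ref_celsius,
               Ea_J_mol = m$Ea, se_Ea = m$se_Ea, r2 = m$r2, n_temps = m$n)
        } else if (is.numeric(m)) list(constant = m) else NULL
      }
      list(mu = arr(s$mu),
           lag = if (inherits(s$lag, "lag_model")) {
             if (s$lag$degenerate) list(degenerate = TRUE)
             else c(list(degenerate = FALSE), arr(s$lag$fit))
           } else arr(s$lag),
           ks = arr(s$ks), logN0 = s$logN0, S0 = s$S0,
           microbially_stable = s$microbially_stable)
    }),
    shelf_life = report$shelf_life,
    fit_errors = report$fit_errors)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null", force = TRUE)

  txt <- file.path(outdir, "report.txt")
  con <- file(txt, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  invisible(txt)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Shelf-life modelling report ==\n\n")
  if (!is.null(x$od_fits)) {
    cat("Penetration fits (k in g/(g DW s^0.5)):\n")
    print(x$od_fits, row.names = FALSE)
    cat("\n")
  }
  for (tr in names(x$growth_fits)) {
    cat("Growth fits -", tr, "\n")
    for (f in x$growth_fits[[tr]]) { cat("  "); print(f) }
  }
  for (tr in names(x$sensory_fits)) {
    cat("Sensory fits -", tr, "\n")
    for (f in x$sensory_fits[[tr]]) { cat("  "); print(f) }
  }
  for (tr in names(x$secondary)) {
    s <- x$secondary[[tr]]
    cat("Secondary models -", tr,
        if (s$microbially_stable) "(microbially stable)" else "", "\n")
    if (inherits(s$mu, "arrhenius_fit")) { cat("  mu_m: "); print(s$mu) }
    if (inherits(s$ks, "arrhenius_fit")) { cat("  k_s:  "); print(s$ks) }
  }
  if (!is.null(x$shelf_life)) {
    cat("\nShelf-life table (days):\n")
    print(x$shelf_life, row.names = FALSE, digits = 4)
  }
  if (length(x$fit_errors)) {
    cat("\nFit failures:\n")
    for (e in x$fit_errors) {
      cat(sprintf("  [%s] %s: %s\n", e$stage, e$series, e$message))
    }
  }
  invisible(x)
}
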