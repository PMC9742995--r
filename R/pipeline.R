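## File I/O, configuration and the end-to-end experiment runner: for each
## dataset, fit both Monod kinetics and the allocation model, then export
## fit tables, model curves and allocation sweeps as plain CSV.

.dataset_columns <- c("species", "irradiance_umol_m2_s", "no3_uM",
                      "growth_per_day")

#' Read a growth dataset from CSV
#'
#' Expected dialect: UTF-8, comma-separated, "." decimal, header columns
#' \code{species}, \code{irradiance_umol_m2_s}, \code{no3_uM},
#' \code{growth_per_day}.  Rows are kept in file order; malformed cells
#' are reported with their row index and column name.
#'
#' @param path path to the CSV file.
#' @return a [GrowthDataset-class] with provenance \code{"file"}.
#' @export
readDatasetCsv <- function(path) {
  if (!file.exists(path))
    stop("dataset file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(.dataset_columns, names(df))
  if (length(missing))
    stop("dataset ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(df))
    stop("dataset ", path, " has no data rows", call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("dataset ", path, ": non-numeric value in column '", col,
           "', row ", bad[1L], call. = FALSE)
    v
  }
  no3 <- num("no3_uM")
  if (any(no3 < 0))
    stop("dataset ", path, ": negative no3_uM in row ",
         which(no3 < 0)[1L], call. = FALSE)
  growthDataset(no3, num("growth_per_day"),
                species = df$species[1L],
                irradiance = num("irradiance_umol_m2_s")[1L],
                provenance = "file")
}

#' Write a growth dataset to CSV
#'
#' Inverse of [readDatasetCsv()]; numeric values are written as full-
#' precision decimal text so a write-then-read round trip is exact.
#'
#' @param dataset a [GrowthDataset-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDatasetCsv <- function(dataset, path) {
  stopifnot(is(dataset, "GrowthDataset"))
  df <- data.frame(species = dataset@species,
                   irradiance_umol_m2_s = .num_chr(dataset@irradiance),
                   no3_uM = .num_chr(dataset@no3),
                   growth_per_day = .num_chr(dataset@mu_obs),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision, locale-independent decimal text
.num_chr <- function(x) formatC(x, digits = 17, format = "g")

#' Write a table of fit results
#'
#' One row per dataset and model with the point estimates, central 95
#' percent intervals, residual sum of squares and chain acceptance rate;
#' columns are in a fixed order so identical fits reproduce the file
#' byte-identically.
#'
#' @param results list of [FitResult-class] objects.
#' @param labels character vector of dataset labels, same length.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFitTable <- function(results, labels, path) {
  if (length(results) != length(labels))
    stop("results and labels must have equal length", call. = FALSE)
  cols <- c("dataset", "model",
            "param_1", "estimate_1", "lo95_1", "hi95_1",
            "param_2", "estimate_2", "lo95_2", "hi95_2",
            "rss", "acceptance_rate")
  rows <- lapply(seq_along(results), function(i) {
    fr <- results[[i]]
    stopifnot(is(fr, "FitResult"))
    pn <- names(fr@estimate)
    data.frame(dataset = labels[[i]], model = fr@model,
               param_1 = pn[1L], estimate_1 = fr@estimate[[1L]],
               lo95_1 = fr@ci[1L, 1L], hi95_1 = fr@ci[1L, 2L],
               param_2 = pn[2L], estimate_2 = fr@estimate[[2L]],
               lo95_2 = fr@ci[2L, 1L], hi95_2 = fr@ci[2L, 2L],
               rss = fr@rss, acceptance_rate = fr@chain@acceptanceRate,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                    cols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experiment configuration file
#'
#' Flat \code{key = value} text with one \code{[dataset <name>]} section
#' per dataset.  Global keys: \code{output_dir}, \code{iterations},
#' \code{seed}, \code{sigma}, \code{curve_points}.  Dataset keys: either
#' \code{file} (a CSV path) or \code{generate} (\code{monod} or
#' \code{cfm}) with the generator's parameters (\code{mu_max}, \code{Ks}
#' or \code{A_pho}, \code{A_N}; plus \code{noise_sd}, \code{n_points},
#' \code{seed}), and \code{irradiance}.
#'
#' @param path path to the configuration file.
#' @return a config list consumable by [runExperiment()].
#' @export
readExperimentConfig <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list(datasets = list())
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[dataset\\s+.+\\]$", ln)) {
      section <- sub("^\\[dataset\\s+(.+)\\]$", "\\1", ln)
      cfg$datasets[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      val <- trimws(paste(kv[-1L], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      if (is.finite(num) && key != "file" && key != "generate") val <- num
      if (is.null(section)) cfg[[key]] <- val
      else cfg$datasets[[section]][[key]] <- val
    } else {
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    }
  }
  cfg
}

.cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

# Materialize one dataset block (file or generator) into a GrowthDataset.
.load_config_dataset <- function(name, ds, global_seed) {
  irr <- .cfg_get(ds, "irradiance", 200)
  if (!is.null(ds$file)) {
    d <- readDatasetCsv(ds$file)
    return(d)
  }
  if (is.null(ds$generate))
    stop("dataset '", name, "': needs either 'file' or 'generate'",
         call. = FALSE)
  seed <- as.integer(.cfg_get(ds, "seed", global_seed))
  noise <- .cfg_get(ds, "noise_sd", 0.05)
  n <- as.integer(.cfg_get(ds, "n_points", 10))
  if (identical(ds$generate, "monod")) {
    tp <- monodParams(.cfg_get(ds, "mu_max", 1.0), .cfg_get(ds, "Ks", 2.0))
    generateMonodDataset(tp, seq(0, 4 * tp@Ks, length.out = n),
                         noise_sd = noise, seed = seed, species = name,
                         irradiance = irr)
  } else if (identical(ds$generate, "cfm")) {
    tp <- cfmParams(I = irr,
                    A_pho = .cfg_get(ds, "A_pho", 3.0),
                    A_N = .cfg_get(ds, "A_N", 0.1))
    generateCfmDataset(tp, seq(0, 4 * crossoverNo3(tp), length.out = n),
                       noise_sd = noise, seed = seed, species = name)
  } else {
    stop("dataset '", name, "': unknown generator '", ds$generate, "'",
         call. = FALSE)
  }
}

#' Run a full experiment
#'
#' For every dataset in the configuration: load (or generate) the data,
#' fit Monod kinetics and the allocation model by Metropolis-Hastings,
#' and write the output bundle to \code{output_dir}:
#' \code{monod_fits.csv} and \code{cfm_fits.csv} (one row per dataset),
#' per-dataset \code{<name>_curves.csv} (nitrate grid with both fitted
#' model curves and the limitation label) and
#' \code{<name>_allocation.csv} (allocation sweep at the fitted
#' parameters), plus \code{run.log} recording seeds, iteration counts and
#' acceptance rates.  All datasets are loaded and validated before any
#' output is written, so a broken dataset reference fails cleanly.
#'
#' @param config a config list from [readExperimentConfig()] or built
#'   directly: global keys \code{output_dir}, \code{iterations},
#'   \code{seed}, \code{sigma}, \code{curve_points} and a named
#'   \code{datasets} list (see [readExperimentConfig()]).
#' @return invisibly, a list with the per-dataset fit results and the
#'   paths written.
#' @export
runExperiment <- function(config) {
  out_dir <- .cfg_get(config, "output_dir", "phytoalloc_out")
  iterations <- as.integer(.cfg_get(config, "iterations", 20000))
  seed <- as.integer(.cfg_get(config, "seed", 1))
  sigma <- .cfg_get(config, "sigma", 0.05)
  curve_points <- as.integer(.cfg_get(config, "curve_points", 50))
  if (!length(config$datasets))
    stop("config contains no datasets", call. = FALSE)
  names_ds <- names(config$datasets)

  # validate everything before writing anything
  datasets <- lapply(names_ds, function(nm) {
    tryCatch(.load_config_dataset(nm, config$datasets[[nm]], seed),
             error = function(e)
               stop("dataset '", nm, "': ", conditionMessage(e),
                    call. = FALSE))
  })
  names(datasets) <- names_ds

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logline <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  logline("experiment start: ", length(datasets), " dataset(s), seed ",
          seed, ", ", iterations, " iterations, sigma ", sigma)

  results <- list()
  for (i in seq_along(datasets)) {
    nm <- names_ds[[i]]
    d <- datasets[[i]]
    ds_seed <- seed + i
    prog <- function(it, lp, acc)
      logline(nm, ": iteration ", it, ", log-posterior ",
              signif(lp, 6), ", acceptance ", signif(acc, 3))
    fm <- fitMonod(d, iterations = iterations, seed = ds_seed,
                   sigma = sigma, progress = prog)
    logline(nm, ": monod fit done, acceptance ",
            signif(fm@chain@acceptanceRate, 3))
    base <- cfmParams(I = d@irradiance)
    fc <- fitCfm(d, base, iterations = iterations, seed = ds_seed + 1000L,
                 sigma = sigma, progress = prog)
    logline(nm, ": cfm fit done, acceptance ",
            signif(fc@chain@acceptanceRate, 3))

    fitted <- setFittedParams(base, A_pho = fc@estimate[["A_pho"]],
                              A_N = fc@estimate[["A_N"]])
    cross <- crossoverNo3(fitted)
    grid <- seq(0, max(max(d@no3), 2 * cross),
                length.out = curve_points)
    mp <- monodParams(fm@estimate[["mu_max"]], fm@estimate[["Ks"]])
    sweep <- allocationSweep(fitted, grid)
    curves <- data.frame(no3_uM = grid,
                         mu_monod = monodGrowth(grid, mp),
                         mu_cfm = sweep$mu,
                         limitation = sweep$limitation,
                         stringsAsFactors = FALSE)
    curve_path <- file.path(out_dir, paste0(nm, "_curves.csv"))
    utils::write.csv(curves, curve_path, row.names = FALSE, quote = FALSE)
    alloc_path <- file.path(out_dir, paste0(nm, "_allocation.csv"))
    utils::write.csv(sweep, alloc_path, row.names = FALSE, quote = FALSE)
    logline(nm, ": crossover ", signif(cross, 6), " uM; curves and ",
            "allocation sweep written")
    results[[nm]] <- list(data = d, monod = fm, cfm = fc,
                          crossover = cross,
                          curves = curve_path, allocation = alloc_path)
  }
  monod_path <- file.path(out_dir, "monod_fits.csv")
  cfm_path <- file.path(out_dir, "cfm_fits.csv")
  writeFitTable(lapply(results, `[[`, "monod"), names_ds, monod_path)
  writeFitTable(lapply(results, `[[`, "cfm"), names_ds, cfm_path)
  logline("experiment done: fit tables written")
  invisible(list(results = results,
                 paths = c(monod_fits = monod_path, cfm_fits = cfm_path,
                           log = log_path)))
}
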