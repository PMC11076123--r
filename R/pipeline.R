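#' Run the full bottleneck-transmission analysis pipeline
#'
#' Orchestrates the whole analysis: obtain per-individual counts (from the
#' synthetic generator or from a file), derive worker- and nymph-source
#' community compositions by [average_composition()], fit Monte-Carlo and
#' analytic [transmission_model()] curves for both sources, locate the
#' minimum propagule sizes, tabulate how many dispersing alates exceed
#' them, and write all results plus a reproducibility manifest. All
#' randomness flows from the single master seed recorded in the manifest;
#' identical configuration and seed give byte-identical outputs.
#'
#' Files written to \code{output_dir}: \code{curves.tsv} (scenario, mode,
#' n_cells, efficiency), \code{min_cells.json} (Monte-Carlo minimum at
#' efficiency 1.0 and the seed-free analytic minimum at threshold
#' \code{1 - 1/(2 * iterations)}, per scenario), \code{exceedance.tsv}
#' (alates above each minimum) and \code{manifest.json}. An optional
#' efficiency plot is written when \code{plot = TRUE}; plotting failures
#' never fail the pipeline.
#'
#' @param output_dir directory for outputs; created if needed.
#' @param input \code{"synthetic"} (default) or \code{"files"}.
#' @param samples_file path to a CSV/TSV count table ([read_samples()]),
#'   required for \code{input = "files"}.
#' @param config [synthetic_config()] used in synthetic mode.
#' @param n_grid,iterations simulation grid and iteration count, as in
#'   [transmission_model()].
#' @param seed master seed (integer).
#' @param alate_caste caste whose totals are compared with the minima.
#' @param plot also write \code{curves.png}.
#' @param verbose log stage progress to stderr.
#' @return Invisibly, a list with the fitted models, minima, exceedance
#'   table and output file paths.
#' @export
run_pipeline <- function(output_dir,
                         input = c("synthetic", "files"),
                         samples_file = NULL,
                         config = synthetic_config(),
                         n_grid = seq(500L, 10000L, by = 500L),
                         iterations = 5000,
                         seed = 1,
                         alate_caste = "A7",
                         plot = FALSE,
                         verbose = TRUE) {
  input <- match.arg(input)
  say <- function(...) if (verbose) message("[protrans] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  samples <- stage(if (input == "synthetic") "generate_dataset" else "read_samples", {
    if (input == "synthetic") {
      say("generating synthetic dataset (seed %d)", seed)
      generate_dataset(config, seed = seed)$samples
    } else {
      if (is.null(samples_file)) stop("'samples_file' is required")
      say("reading samples from %s", samples_file)
      read_samples(samples_file)
    }
  })

  comps <- stage("average_composition", {
    say("averaging worker and nymph compositions")
    list(worker = average_composition(samples, "worker"),
         nymph = average_composition(samples, "nymph"))
  })

  scen_seeds <- derive_seeds(seed + 7919, length(comps))
  models <- stage("transmission_model", {
    say("fitting Monte-Carlo curves (%d iterations, %d grid points)",
        iterations, length(n_grid))
    mc <- lapply(seq_along(comps), function(i) {
      transmission_model(comps[[i]], n_grid = n_grid,
                         iterations = iterations, seed = scen_seeds[i],
                         mode = "monte_carlo")
    })
    names(mc) <- names(comps)
    an <- lapply(comps, transmission_model, n_grid = n_grid,
                 mode = "analytic")
    list(monte_carlo = mc, analytic = an)
  })

  ref_threshold <- 1 - 1 / (2 * iterations)
  minima <- stage("min_cells", {
    lapply(names(comps), function(sc) {
      list(scenario = sc,
           monte_carlo = min_cells(models$monte_carlo[[sc]], 1.0)$min_cells,
           analytic = min_cells(models$analytic[[sc]], ref_threshold)$min_cells,
           analytic_threshold = ref_threshold)
    })
  })
  names(minima) <- names(comps)

  exceedance <- stage("fraction_above_threshold", {
    do.call(rbind, lapply(names(comps), function(sc) {
      thr <- minima[[sc]]$monte_carlo
      if (is.na(thr)) thr <- minima[[sc]]$analytic
      fr <- fraction_above_threshold(samples, alate_caste, thr)
      data.frame(scenario = sc, alate_caste = alate_caste,
                 threshold_cells = thr, k_above = fr$k, n = fr$n,
                 fraction = fr$fraction)
    }))
  })

  paths <- stage("write_outputs", {
    say("writing outputs to %s", output_dir)
    curves <- do.call(rbind, lapply(c("monte_carlo", "analytic"), function(md) {
      do.call(rbind, lapply(names(comps), function(sc) {
        m <- models[[md]][[sc]]
        data.frame(scenario = sc, mode = md, n_cells = m$n_grid,
                   efficiency = m$efficiency)
      }))
    }))
    curves_path <- file.path(output_dir, "curves.tsv")
    utils::write.table(curves, curves_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    min_path <- file.path(output_dir, "min_cells.json")
    jsonlite::write_json(minima, min_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    exc_path <- file.path(output_dir, "exceedance.tsv")
    utils::write.table(exceedance, exc_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    manifest <- list(
      package = "protrans",
      version = as.character(utils::packageVersion("protrans")),
      input = input,
      samples_file = if (is.null(samples_file)) NA else samples_file,
      n_individuals = nrow(samples),
      seed = seed,
      iterations = iterations,
      n_grid = range(n_grid),
      grid_points = length(n_grid),
      analytic_threshold = ref_threshold,
      scenario_seeds = stats::setNames(as.list(scen_seeds), names(comps)),
      compositions = lapply(comps, function(cc) {
        stats::setNames(as.list(cc$proportions), cc$species_groups)
      })
    )
    man_path <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    list(curves = curves_path, min_cells = min_path, exceedance = exc_path,
         manifest = man_path)
  })

  if (plot) {
    tryCatch({
      png_path <- file.path(output_dir, "curves.png")
      grDevices::png(png_path, width = 800, height = 500)
      on.exit(grDevices::dev.off(), add = TRUE)
      m <- models$monte_carlo
      graphics::plot(m$nymph$n_grid, m$nymph$efficiency, type = "b", pch = 16,
                     col = "firebrick", ylim = c(0, 1),
                     xlab = "cells transmitted (N)",
                     ylab = "transmission efficiency",
                     main = "Worker- vs nymph-source transmission")
      graphics::lines(m$worker$n_grid, m$worker$efficiency, type = "b",
                      pch = 16, col = "steelblue")
      graphics::legend("bottomright", legend = c("nymph source", "worker source"),
                       col = c("firebrick", "steelblue"), pch = 16, bty = "n")
      paths$plot <- png_path
    }, error = function(e) {
      warning("plotting failed (pipeline unaffected): ", conditionMessage(e))
    })
  }

  say("done")
  invisible(list(samples = samples, compositions = comps, models = models,
                 minima = minima, exceedance = exceedance, paths = paths))
}
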