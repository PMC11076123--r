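#' Exact probability that a transmitted sample contains every species group
#'
#' Probability that \code{n} cells drawn i.i.d. (with replacement) from a
#' source community with proportions p contain at least one cell of every
#' species group, computed by inclusion-exclusion over subsets of groups:
#' \deqn{P(n) = \sum_{S} (-1)^{|S|} (1 - \sum_{i \in S} p_i)^n.}
#' This is the exact counterpart of the Monte-Carlo transmission efficiency
#' and is used as its seed-free reference.
#'
#' With \code{require_all = TRUE} (default) groups with p_i = 0 are counted
#' in the "every group" criterion, so any zero proportion forces P = 0;
#' this surfaces data problems rather than silently dropping groups. Set
#' \code{require_all = FALSE} to restrict the criterion to groups with
#' positive proportion.
#'
#' @param composition a [community_composition()] or bare proportion vector.
#' @param n vector of non-negative integer cell numbers.
#' @param require_all whether zero-proportion groups count towards "all
#'   groups present".
#' @return Numeric vector of probabilities in [0, 1], one per \code{n}.
#'   Exactly 0 whenever \code{n} is below the number of required groups.
#' @export
#' @examples
#' prob_full_transmission(c(0.5, 0.5), 2)    # 0.5
#' prob_full_transmission(c(0.9, 0.1), 3)    # 0.270
prob_full_transmission <- function(composition, n, require_all = TRUE) {
  comp <- as_composition(composition)
  p <- comp$proportions
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n))) {
    stop("'n' must be non-negative integers")
  }
  if (require_all && any(p == 0)) {
    return(rep(0, length(n)))
  }
  q <- p[p > 0]
  k <- length(q)
  if (k > 25) {
    stop("more than 25 positive-proportion groups: subset enumeration is ",
         "infeasible, use the Monte-Carlo mode")
  }
  # subset sums and parities by iterative doubling over groups
  sums <- 0
  parity <- 0L
  for (qi in q) {
    sums <- c(sums, sums + qi)
    parity <- c(parity, parity + 1L)
  }
  base <- pmax(1 - sums, 0)
  sign <- ifelse(parity %% 2L == 0L, 1, -1)
  out <- vapply(n, function(nn) sum(sign * base^nn), numeric(1))
  out[n < k] <- 0 # exact: n draws cannot cover more than n groups
  pmin(pmax(out, 0), 1)
}

#' Draw one hypothetical alate community and report species presence
#'
#' Samples \code{n_cells} cells with replacement from the source community
#' (one multinomial draw, distributionally identical to n i.i.d.
#' categorical draws) and reports, per species group, whether at least one
#' cell was transmitted.
#'
#' @inheritParams prob_full_transmission
#' @param n_cells non-negative integer, number of cells transmitted.
#' @param seed optional integer seed for reproducibility; when \code{NULL}
#'   the current RNG stream is used.
#' @return Named logical vector, \code{TRUE} where the group is present.
#'   Groups with p_i = 0 are never present.
#' @export
sample_transmission <- function(composition, n_cells, seed = NULL) {
  comp <- as_composition(composition)
  if (length(n_cells) != 1 || !is.finite(n_cells) || n_cells < 0 ||
      n_cells != floor(n_cells)) {
    stop("'n_cells' must be a single non-negative integer")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rmultinom(1, size = n_cells, prob = comp$proportions)[, 1]
  stats::setNames(counts > 0, comp$species_groups)
}

#' Monte-Carlo transmission efficiency at one propagule size
#'
#' Fraction of simulated alates (iterations) that receive at least one cell
#' of every species group when \code{n_cells} cells are sampled with
#' replacement from the source community.
#'
#' @inheritParams sample_transmission
#' @param iterations positive integer number of simulated alates.
#' @return A single number in [0, 1].
#' @export
transmission_efficiency <- function(composition, n_cells, iterations = 5000,
                                    seed = NULL, require_all = TRUE) {
  comp <- as_composition(composition)
  if (length(iterations) != 1 || !is.finite(iterations) || iterations < 1 ||
      iterations != floor(iterations)) {
    stop("'iterations' must be a positive integer")
  }
  if (length(n_cells) != 1 || !is.finite(n_cells) || n_cells < 0 ||
      n_cells != floor(n_cells)) {
    stop("'n_cells' must be a single non-negative integer")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- comp$proportions
  need <- if (require_all) seq_along(p) else which(p > 0)
  if (length(need) == 0) stop("composition has no required groups")
  counts <- stats::rmultinom(iterations, size = n_cells, prob = p)
  mean(colSums(counts[need, , drop = FALSE] > 0) == length(need))
}

# deterministic per-grid-point substreams from one master seed, so results
# do not depend on internal batching; kept below 2^31
derive_seeds <- function(seed, k) {
  as.integer((as.numeric(seed) + 48271 * seq_len(k)) %% 2147483629 + 1)
}

#' Fit a transmission-efficiency curve for a source community
#'
#' The central model object: transmission efficiency E(N) — the proportion
#' of hypothetical alates that receive every protist species group — as a
#' function of the number N of cells transmitted from a source community
#' (worker-gut or nymph-gut composition). \code{mode = "monte_carlo"}
#' resamples \code{iterations} alates per grid point by multinomial
#' sampling with replacement; \code{mode = "analytic"} evaluates the exact
#' inclusion-exclusion probability of [prob_full_transmission()].
#'
#' @inheritParams prob_full_transmission
#' @param n_grid strictly increasing vector of positive integers, the
#'   propagule sizes N at which the curve is evaluated. Default 500 to
#'   10000 cells in steps of 500.
#' @param iterations simulated alates per grid point (Monte-Carlo mode).
#' @param seed master seed; per-grid-point substreams are derived from it
#'   deterministically. When \code{NULL} a seed is drawn and recorded.
#' @param mode \code{"monte_carlo"} (default) or \code{"analytic"}.
#' @return An object of class \code{"transmission_model"} with components
#'   \code{composition}, \code{n_grid}, \code{efficiency}, \code{iterations}
#'   (\code{NA} in analytic mode), \code{seed}, \code{mode},
#'   \code{require_all} and \code{call}. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{simulate},
#'   \code{residuals}, \code{plot}, plus [min_cells()].
#' @seealso [min_cells()], [average_composition()], [default_compositions()]
#' @export
#' @examples
#' comp <- default_compositions()$nymph
#' fit <- transmission_model(comp, mode = "analytic")
#' min_cells(fit, threshold = 1 - 1e-4)
transmission_model <- function(composition,
                               n_grid = seq(500L, 10000L, by = 500L),
                               iterations = 5000, seed = NULL,
                               mode = c("monte_carlo", "analytic"),
                               require_all = TRUE) {
  mode <- match.arg(mode)
  comp <- as_composition(composition)
  if (length(n_grid) == 0 || any(!is.finite(n_grid)) || any(n_grid <= 0) ||
      any(n_grid != floor(n_grid)) || is.unsorted(n_grid, strictly = TRUE)) {
    stop("'n_grid' must be strictly increasing positive integers")
  }
  if (mode == "analytic") {
    eff <- prob_full_transmission(comp, n_grid, require_all = require_all)
    iterations <- NA_integer_
    seed <- NA_integer_
  } else {
    if (length(iterations) != 1 || !is.finite(iterations) || iterations < 1 ||
        iterations != floor(iterations)) {
      stop("'iterations' must be a positive integer")
    }
    if (is.null(seed)) seed <- sample.int(2147483600L, 1)
    sub <- derive_seeds(seed, length(n_grid))
    eff <- vapply(seq_along(n_grid), function(i) {
      transmission_efficiency(comp, n_grid[i], iterations = iterations,
                              seed = sub[i], require_all = require_all)
    }, numeric(1))
  }
  structure(
    list(composition = comp, n_grid = as.integer(n_grid), efficiency = eff,
         iterations = as.integer(iterations), seed = as.integer(seed),
         mode = mode, require_all = require_all, call = match.call()),
    class = "transmission_model"
  )
}

#' Minimum number of transmitted cells for full community transmission
#'
#' Smallest grid propagule size N whose efficiency reaches the threshold.
#' With the default threshold 1.0 in Monte-Carlo mode this is the smallest
#' N at which every simulated alate received all species groups — a
#' statistic that depends on the grid resolution, the iteration count and
#' the seed. The analytic curve at threshold \code{1 - 1/(2 * iterations)}
#' is the seed-free reference reported alongside by
#' \code{summary.transmission_model}.
#'
#' @param model a [transmission_model()] fit.
#' @param threshold efficiency threshold in (0, 1], default 1.0.
#' @param refine analytic mode only: if \code{TRUE}, bisect between grid
#'   points to the exact smallest integer N reaching the threshold.
#' @return A list of class \code{"min_cells"} with \code{min_cells}
#'   (integer, or \code{NA} if no grid point qualifies), \code{threshold},
#'   \code{mode} and \code{refined}.
#' @export
min_cells <- function(model, threshold = 1.0, refine = FALSE) {
  stopifnot(inherits(model, "transmission_model"))
  if (length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop("'threshold' must be in (0, 1]")
  }
  ok <- model$efficiency >= threshold - 1e-12
  idx <- which(ok)[1]
  n_star <- if (is.na(idx)) NA_integer_ else model$n_grid[idx]
  refined <- FALSE
  if (refine && !is.na(n_star)) {
    if (model$mode != "analytic") {
      stop("'refine = TRUE' requires an analytic-mode model")
    }
    lo <- if (idx == 1) 1L else model$n_grid[idx - 1] + 1L
    hi <- n_star
    while (lo < hi) {
      mid <- (lo + hi) %/% 2
      if (prob_full_transmission(model$composition, mid,
                                 require_all = model$require_all) >=
          threshold - 1e-12) {
        hi <- mid
      } else {
        lo <- mid + 1L
      }
    }
    n_star <- as.integer(lo)
    refined <- TRUE
  }
  structure(list(min_cells = n_star, threshold = threshold,
                 mode = model$mode, refined = refined),
            class = "min_cells")
}

#' @export
print.min_cells <- function(x, ...) {
  cat(sprintf("Minimum cells for efficiency >= %g (%s%s): %s\n",
              x$threshold, x$mode, if (x$refined) ", refined" else "",
              if (is.na(x$min_cells)) "not reached on grid" else x$min_cells))
  invisible(x)
}

#' @export
print.transmission_model <- function(x, ...) {
  cat("Transmission-efficiency model (", x$mode, " mode)\n", sep = "")
  if (nzchar(x$composition$source)) cat("Source community:", x$composition$source, "\n")
  cat(sprintf("Grid: %d propagule sizes, %d..%d cells\n",
              length(x$n_grid), min(x$n_grid), max(x$n_grid)))
  if (x$mode == "monte_carlo") {
    cat(sprintf("Iterations per grid point: %d (seed %d)\n",
                x$iterations, x$seed))
  }
  mc <- min_cells(x, 1.0)
  cat(sprintf("Minimum cells at efficiency 1.0: %s\n",
              if (is.na(mc$min_cells)) "not reached on grid" else mc$min_cells))
  invisible(x)
}

#' @export
coef.transmission_model <- function(object, ...) {
  stats::setNames(object$composition$proportions,
                  object$composition$species_groups)
}

#' @describeIn transmission_model analytic retention probability at new
#'   propagule sizes \code{n} (defaults to the fitted grid).
#' @param object,x a fitted \code{transmission_model}.
#' @param ... unused.
#' @export
predict.transmission_model <- function(object, n = object$n_grid, ...) {
  prob_full_transmission(object$composition, n,
                         require_all = object$require_all)
}

#' @describeIn transmission_model Monte-Carlo presence draws: an
#'   \code{nsim} x groups logical matrix of simulated alate communities at
#'   propagule size \code{n_cells} (default: largest grid value).
#' @param nsim number of simulated alates.
#' @param n_cells propagule size for \code{simulate}.
#' @export
simulate.transmission_model <- function(object, nsim = 1, seed = NULL,
                                        n_cells = max(object$n_grid), ...) {
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rmultinom(nsim, size = n_cells,
                             prob = object$composition$proportions)
  out <- t(counts > 0)
  colnames(out) <- object$composition$species_groups
  out
}

#' @describeIn transmission_model Monte-Carlo efficiency minus the analytic
#'   probability at each grid point (all zeros for an analytic fit).
#' @export
residuals.transmission_model <- function(object, ...) {
  object$efficiency - predict(object)
}

#' @export
summary.transmission_model <- function(object, ...) {
  iters <- if (is.na(object$iterations)) 5000L else object$iterations
  ref_threshold <- 1 - 1 / (2 * iters)
  analytic_eff <- predict(object)
  analytic_model <- object
  analytic_model$efficiency <- analytic_eff
  analytic_model$mode <- "analytic"
  structure(
    list(model = object,
         table = data.frame(n_cells = object$n_grid,
                            efficiency = object$efficiency,
                            analytic = analytic_eff),
         min_cells = min_cells(object, 1.0),
         analytic_reference = min_cells(analytic_model, ref_threshold),
         reference_threshold = ref_threshold),
    class = "summary.transmission_model"
  )
}

#' @export
print.summary.transmission_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("Analytic reference minimum (threshold %.6f): %s\n",
              x$reference_threshold,
              if (is.na(x$analytic_reference$min_cells))
                "not reached on grid" else x$analytic_reference$min_cells))
  cat("\nEfficiency curve:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn transmission_model efficiency against propagule size, with
#'   the analytic curve overlaid for Monte-Carlo fits.
#' @export
plot.transmission_model <- function(x, ...) {
  args <- list(...)
  defaults <- list(x = x$n_grid, y = x$efficiency, type = "b", pch = 16,
                   xlab = "cells transmitted (N)",
                   ylab = "transmission efficiency E(N)", ylim = c(0, 1),
                   main = sprintf("Transmission efficiency (%s)", x$mode))
  do.call(graphics::plot, utils::modifyList(defaults, args))
  if (x$mode == "monte_carlo") {
    graphics::lines(x$n_grid, predict(x), lty = 2, col = "grey40")
    graphics::legend("bottomright", legend = c("Monte-Carlo", "analytic"),
                     lty = c(1, 2), pch = c(16, NA), bty = "n")
  }
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
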