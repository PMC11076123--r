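# fixed split of the eight non-focal groups; scaled per caste to whatever
# proportion mass the two calibrated large parabasalids leave over
.background_weights <- c(
  Pyrsonympha_spp = 0.25, Dinenympha_exilis = 0.20,
  Dinenympha_porteri_III = 0.08, Dinenympha_porteri_IV = 0.06,
  Dinenympha_spp1 = 0.22, Dinenympha_spp2 = 0.12,
  Holomastigotes_sp = 0.02, small_protists = 0.05
)

.make_caste_composition <- function(tr_agilis, te_mirabilis, label) {
  rest <- .background_weights * (1 - tr_agilis - te_mirabilis)
  p <- c(rest[c("Pyrsonympha_spp", "Dinenympha_exilis",
                "Dinenympha_porteri_III", "Dinenympha_porteri_IV",
                "Dinenympha_spp1", "Dinenympha_spp2")],
         Trichonympha_agilis = unname(tr_agilis),
         Teranympha_mirabilis = unname(te_mirabilis),
         rest[c("Holomastigotes_sp", "small_protists")])
  p <- p[default_species_groups()$name]
  community_composition(p, names(p), source = label)
}

# published caste calibration: mean/s.e. totals and percentage proportions
# of the two rare large parabasalids; A0 counts are not published and
# borrow the nymph values
.caste_calibration <- function() {
  data.frame(
    caste_group = c("worker", "moulted_worker", "nymph", "A0", "A2", "A7", "A7w"),
    mean_total = c(79248.6, 0, 8992.1, 8992.1, 8457.0, 5193.5, 6770.2),
    se_total = c(4432.9, 0, 933.2, 933.2, 503.8, 370.1, 428.5),
    tr_agilis = c(0.0048, 0.0048, 0.0293, 0.0293, 0.0330, 0.0293, 0.0398),
    te_mirabilis = c(0.0014, 0.0014, 0.0027, 0.0027, 0.0029, 0.0024, 0.0031),
    stringsAsFactors = FALSE
  )
}

#' Default worker and nymph source communities
#'
#' Ten-group community compositions calibrated to the published caste-level
#' percentage proportions of the two rarest groups: \emph{Trichonympha
#' agilis} at 0.48\% of the worker community vs 2.93\% in nymphs, and
#' \emph{Teranympha mirabilis} (the rarest group in both) at 0.14\% vs
#' 0.27\%. The remaining eight groups share the leftover mass according to
#' a fixed documented split of common oxymonads and minor groups; these
#' eight proportions are a stated modelling default, not measured values.
#'
#' @return Named list with elements \code{worker} and \code{nymph}, each a
#'   [community_composition()].
#' @export
#' @examples
#' sapply(default_compositions(), function(cc) min(cc$proportions))
default_compositions <- function() {
  cal <- .caste_calibration()
  mk <- function(cg) {
    row <- cal[cal$caste_group == cg, ]
    .make_caste_composition(row$tr_agilis, row$te_mirabilis,
                            sprintf("calibrated default, caste=%s", cg))
  }
  list(worker = mk("worker"), nymph = mk("nymph"))
}

#' Configuration of the synthetic count-data generator
#'
#' All parameters of [generate_dataset()]. Defaults reproduce the study
#' design: two colonies; caste mean total abundances of ~79,000 cells in
#' workers falling to ~5,000-9,000 in nymphs and alates, with freshly
#' moulted workers protist-free; the two rare large parabasalids enriched
#' 2-6-fold in nymphs/alates relative to workers; individual-level
#' compositional overdispersion (Dirichlet-multinomial); a small
#' multiplicative colony effect on composition; and sexes assigned at an
#' even ratio with no effect on composition.
#'
#' @param n_colonies number of colonies.
#' @param n_per_caste named integer vector, individuals per caste per
#'   colony.
#' @param kappa Dirichlet concentration of individual compositions around
#'   the caste/colony expectation; larger = less overdispersion;
#'   \code{Inf} removes it entirely.
#' @param colony_effect_sd sd of the log-normal multiplicative colony
#'   perturbation of base proportions (renormalised); 0 disables it.
#' @param sex_ratio probability an individual of a sexed caste (nymphs and
#'   alates) is male; workers are recorded as sex \code{"unknown"}.
#' @param n_reference assumed empirical group size used to convert the
#'   published standard errors of caste totals to standard deviations
#'   (sd = s.e. * sqrt(n_reference)).
#' @param caste_calibration data frame overriding the built-in per-caste
#'   calibration (columns \code{caste_group}, \code{mean_total},
#'   \code{se_total}, \code{tr_agilis}, \code{te_mirabilis}).
#' @return A list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_colonies = 2,
                             n_per_caste = c(worker = 20, moulted_worker = 5,
                                             nymph = 20, A0 = 0, A2 = 20,
                                             A7 = 20, A7w = 20),
                             kappa = 200,
                             colony_effect_sd = 0.1,
                             sex_ratio = 0.5,
                             n_reference = 20,
                             caste_calibration = .caste_calibration()) {
  if (n_colonies < 1 || n_colonies != floor(n_colonies)) {
    stop("'n_colonies' must be a positive integer")
  }
  if (is.null(names(n_per_caste)) ||
      !all(names(n_per_caste) %in% caste_groups())) {
    stop("'n_per_caste' must be named with recognised caste groups")
  }
  if (any(n_per_caste < 0) || any(n_per_caste != floor(n_per_caste))) {
    stop("'n_per_caste' must be non-negative integers")
  }
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0) {
    stop("'kappa' must be positive (possibly Inf)")
  }
  if (colony_effect_sd < 0) stop("'colony_effect_sd' must be non-negative")
  if (sex_ratio < 0 || sex_ratio > 1) stop("'sex_ratio' must be in [0, 1]")
  needed <- c("caste_group", "mean_total", "se_total", "tr_agilis",
              "te_mirabilis")
  if (!all(needed %in% names(caste_calibration))) {
    stop("'caste_calibration' must have columns ",
         paste(needed, collapse = ", "))
  }
  if (any(caste_calibration$mean_total < 0) ||
      any(caste_calibration$se_total < 0)) {
    stop("calibrated totals must be non-negative")
  }
  structure(
    list(n_colonies = as.integer(n_colonies),
         n_per_caste = n_per_caste,
         kappa = kappa,
         colony_effect_sd = colony_effect_sd,
         sex_ratio = sex_ratio,
         n_reference = n_reference,
         caste_calibration = caste_calibration),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic protist count-data configuration\n")
  cat(sprintf("Colonies: %d; kappa = %g; colony effect sd = %g; sex ratio = %g\n",
              x$n_colonies, x$kappa, x$colony_effect_sd, x$sex_ratio))
  cat("Individuals per caste per colony:\n")
  print(x$n_per_caste)
  invisible(x)
}

# lognormal parameters matched to a target mean and sd
.lnorm_params <- function(mean, sd) {
  sdlog <- sqrt(log1p((sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic per-individual protist count dataset
#'
#' Hierarchical generative model standing in for the empirical count data:
#' per-individual total abundance is log-normal, moment-matched to the
#' published caste mean and s.e.-derived sd, rounded to an integer
#' (moulted workers are fixed at exactly 0); the individual's composition
#' is a Dirichlet draw with concentration \code{kappa} around the caste
#' base composition perturbed multiplicatively per colony; counts are one
#' multinomial draw of the total over that composition. Deterministic
#' given \code{seed}.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @return List with \code{samples} (wide per-individual table as from
#'   [read_samples()]) and \code{truth} (a list recording the seed, the
#'   configuration, the per-colony composition perturbation factors and
#'   the realised per-colony x caste expected proportions and configured
#'   mean totals).
#' @export
#' @examples
#' sim <- generate_dataset(synthetic_config(), seed = 1)
#' head(sim$samples[, 1:6])
generate_dataset <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  panel <- default_species_groups()
  k <- nrow(panel)
  cal <- config$caste_calibration
  colonies <- as.character(utils::as.roman(seq_len(config$n_colonies)))

  colony_factors <- matrix(
    exp(stats::rnorm(config$n_colonies * k, 0, config$colony_effect_sd)),
    nrow = config$n_colonies, dimnames = list(colonies, panel$name)
  )

  rows <- list()
  expected <- list()
  for (col_i in seq_along(colonies)) {
    colony <- colonies[col_i]
    for (cg in names(config$n_per_caste)) {
      n_ind <- config$n_per_caste[[cg]]
      if (n_ind == 0) next
      row <- cal[cal$caste_group == cg, ]
      if (nrow(row) == 0) stop("caste ", sQuote(cg), " missing from calibration")
      base <- .make_caste_composition(row$tr_agilis, row$te_mirabilis,
                                      cg)$proportions
      p_colony <- base * colony_factors[colony, ]
      p_colony <- p_colony / sum(p_colony)
      expected[[paste(colony, cg, sep = ".")]] <-
        list(colony_id = colony, caste_group = cg,
             expected_proportions = stats::setNames(p_colony, panel$name),
             mean_total = row$mean_total)
      sexed <- !cg %in% c("worker", "moulted_worker")
      for (i in seq_len(n_ind)) {
        if (row$mean_total == 0) {
          total <- 0L
        } else {
          lp <- .lnorm_params(row$mean_total,
                              row$se_total * sqrt(config$n_reference))
          total <- as.integer(round(stats::rlnorm(1, lp$meanlog, lp$sdlog)))
        }
        if (is.infinite(config$kappa)) {
          comp <- p_colony
        } else {
          g <- stats::rgamma(k, shape = config$kappa * p_colony)
          comp <- if (sum(g) > 0) g / sum(g) else p_colony
        }
        counts <- stats::rmultinom(1, size = total, prob = comp)[, 1]
        names(counts) <- panel$name
        sex <- if (sexed) {
          sample(c("male", "female"), 1,
                 prob = c(config$sex_ratio, 1 - config$sex_ratio))
        } else "unknown"
        rows[[length(rows) + 1]] <- data.frame(
          individual_id = sprintf("%s_%s_%02d", colony, cg, i),
          colony_id = colony, caste_group = cg, sex = sex,
          t(counts), total = as.integer(sum(counts)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  list(samples = samples,
       truth = list(seed = seed, config = config,
                    colony_factors = colony_factors, expected = expected))
}
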