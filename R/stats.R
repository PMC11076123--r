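#' Caste-wise abundance and composition summaries
#'
#' Mean and standard error (sd / sqrt(n)) of per-individual total protist
#' counts and of per-individual percentage proportions, for each caste
#' present in the sample table. The standard error of a single individual
#' is defined as 0, with a warning. Proportions are computed only from
#' individuals with a positive total (freshly moulted workers carry no
#' protists, so their composition is undefined and reported as \code{NA}).
#'
#' @param samples wide per-individual sample table.
#' @param castes castes to summarise; defaults to every recognised caste
#'   present in the data. A requested caste with no individuals is skipped
#'   with a warning.
#' @return An object of class \code{"caste_summary"}: a list with
#'   \code{totals} (data frame: caste_group, n, mean_total, se_total) and
#'   \code{proportions} (data frame: caste_group, species_group,
#'   mean_percent, se_percent).
#' @export
summarize_castes <- function(samples,
                             castes = intersect(caste_groups(),
                                                unique(samples$caste_group))) {
  groups <- species_columns(samples)
  empty <- castes[!castes %in% samples$caste_group]
  if (length(empty)) {
    warning("no individuals for caste(s): ", paste(empty, collapse = ", "),
            "; skipped")
    castes <- setdiff(castes, empty)
  }
  if (length(castes) == 0) stop("no castes to summarise")

  warned_single <- FALSE
  se_of <- function(x) {
    if (length(x) == 1) {
      if (!warned_single) {
        warning("standard error of a single individual set to 0")
        warned_single <<- TRUE
      }
      return(0)
    }
    stats::sd(x) / sqrt(length(x))
  }

  totals <- do.call(rbind, lapply(castes, function(cg) {
    tot <- samples$total[samples$caste_group == cg]
    data.frame(caste_group = cg, n = length(tot),
               mean_total = mean(tot), se_total = se_of(tot))
  }))

  proportions <- do.call(rbind, lapply(castes, function(cg) {
    sub <- samples[samples$caste_group == cg, , drop = FALSE]
    counts <- as.matrix(sub[, groups, drop = FALSE])
    tot <- rowSums(counts)
    pos <- tot > 0
    if (!any(pos)) {
      return(data.frame(caste_group = cg, species_group = groups,
                        mean_percent = NA_real_, se_percent = NA_real_))
    }
    pct <- 100 * counts[pos, , drop = FALSE] / tot[pos]
    data.frame(caste_group = cg, species_group = groups,
               mean_percent = colMeans(pct),
               se_percent = apply(pct, 2, se_of))
  }))
  rownames(proportions) <- NULL

  structure(list(totals = totals, proportions = proportions),
            class = "caste_summary")
}

#' @export
print.caste_summary <- function(x, digits = 4, ...) {
  cat("Caste-wise total protist counts (mean +/- s.e.):\n")
  print(x$totals, row.names = FALSE, digits = digits)
  cat("\nMean percentage proportions per species group:\n")
  wide <- stats::reshape(
    x$proportions[, c("caste_group", "species_group", "mean_percent")],
    idvar = "species_group", timevar = "caste_group", direction = "wide"
  )
  names(wide) <- sub("^mean_percent\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Fold enrichment of a species group between castes
#'
#' Ratio of a mean proportion in a target caste to the same group's mean
#' proportion in a reference caste, with the nearest-integer fold. The
#' rare large parabasalids are enriched severalfold in nymphs relative to
#' workers: 2.93 / 0.48 gives a sixfold enrichment for \emph{Trichonympha
#' agilis}, 0.27 / 0.14 a twofold one for \emph{Teranympha mirabilis}.
#'
#' @param target mean proportion (or percentage) in the target caste.
#' @param reference mean proportion in the reference caste, on the same
#'   scale; must be positive.
#' @return List with \code{ratio} (target / reference) and \code{fold}
#'   (integer, \code{round(ratio)}).
#' @export
#' @examples
#' fold_change(2.93, 0.48) # ratio 6.10, fold 6
fold_change <- function(target, reference) {
  if (length(target) != 1 || length(reference) != 1 ||
      !is.finite(target) || !is.finite(reference)) {
    stop("'target' and 'reference' must be single finite numbers")
  }
  if (reference <= 0) stop("'reference' must be positive")
  ratio <- target / reference
  list(ratio = ratio, fold = as.integer(round(ratio)))
}

#' Fraction of individuals above an abundance threshold
#'
#' How many individuals of a caste harbour strictly more than
#' \code{threshold_cells} protists — e.g. how many dispersing alates carry
#' more cells than the simulated minimum required for full community
#' transmission.
#'
#' @param samples wide per-individual sample table.
#' @param caste_group caste to assess.
#' @param threshold_cells abundance threshold; comparison is strict
#'   (\code{total > threshold_cells}).
#' @return List with \code{k} (individuals above), \code{n} (individuals in
#'   the caste) and \code{fraction} (k / n).
#' @export
fraction_above_threshold <- function(samples, caste_group, threshold_cells) {
  tot <- samples$total[samples$caste_group == caste_group]
  if (length(tot) == 0) stop("no individuals in caste ", sQuote(caste_group))
  k <- sum(tot > threshold_cells)
  list(k = k, n = length(tot), fraction = k / length(tot))
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' \deqn{BC(x, y) = 1 - 2 \sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)}
#' Symmetric, 0 for identical counts, 1 for disjoint supports.
#'
#' @param x,y non-negative count vectors over the same species panel (if
#'   both are named, names must match); not both all-zero.
#' @return Dissimilarity in [0, 1].
#' @export
#' @examples
#' bray_curtis(c(2, 1), c(1, 3)) # 3/7
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y))) {
    stop("'x' and 'y' are over different species panels")
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0)) {
    stop("counts must be finite and non-negative")
  }
  s <- sum(x) + sum(y)
  if (s == 0) stop("both vectors are all-zero; dissimilarity undefined")
  1 - 2 * sum(pmin(x, y)) / s
}

#' Pairwise Bray-Curtis dissimilarity matrix for a sample table
#'
#' @param samples wide per-individual sample table; individuals with zero
#'   total are dropped with a warning (their dissimilarity is undefined).
#' @return Square symmetric matrix with individual ids as dimnames.
#' @export
bray_curtis_matrix <- function(samples) {
  groups <- species_columns(samples)
  keep <- samples$total > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " individual(s) with zero total count")
    samples <- samples[keep, , drop = FALSE]
  }
  counts <- as.matrix(samples[, groups, drop = FALSE])
  n <- nrow(counts)
  out <- matrix(0, n, n,
                dimnames = list(samples$individual_id, samples$individual_id))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      out[i, j] <- out[j, i] <- bray_curtis(counts[i, ], counts[j, ])
    }
  }
  out
}

#' Detection ratio of a species group within a caste
#'
#' Fraction of individuals of a caste in which the group was detected
#' (count > 0).
#'
#' @param samples wide per-individual sample table.
#' @param caste_group caste to assess.
#' @param species_group species-group column name.
#' @return Fraction in [0, 1].
#' @export
detection_ratio <- function(samples, caste_group, species_group) {
  sub <- samples[samples$caste_group == caste_group, , drop = FALSE]
  if (nrow(sub) == 0) stop("no individuals in caste ", sQuote(caste_group))
  if (!species_group %in% species_columns(samples)) {
    stop("unknown species group ", sQuote(species_group))
  }
  mean(sub[[species_group]] > 0)
}

#' Cell-shape circularity
#'
#' \code{4 * pi * area / perimeter^2}; 1.0 for a perfect circle, smaller
#' for elongated or folded cells. By the isoperimetric inequality the value
#' cannot exceed 1 for a true planar shape; values slightly above 1 from
#' measurement noise are clipped to 1, with a warning when the excess is
#' larger than 1e-6.
#'
#' @param area cell area, um^2; positive.
#' @param perimeter cell perimeter, um; positive.
#' @return Circularity in (0, 1].
#' @export
#' @examples
#' circularity(pi, 2 * pi) # unit circle: 1
#' circularity(1, 4)       # unit square: pi/4
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    stop("'area' and 'perimeter' must be positive")
  }
  circ <- 4 * pi * area / perimeter^2
  if (any(circ > 1 + 1e-6)) {
    warning("circularity above 1 by more than 1e-6; clipped ",
            "(inconsistent area/perimeter measurements?)")
  }
  pmin(circ, 1)
}
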