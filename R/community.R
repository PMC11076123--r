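#' Scale a haemocytometer count up to a whole-gut population estimate
#'
#' Cells counted in a small aliquot of the gut suspension are scaled to the
#' full suspension volume: \code{floor(raw_count * suspension_volume /
#' counted_volume)}. Estimates are rounded down to the nearest integer. A
#' small tolerance (1e-9) absorbs floating-point representation error of
#' decimal volumes before the floor, so that e.g. 10 cells in 0.8 ul of a
#' 150 ul suspension give exactly 1875.
#'
#' @param raw_count non-negative integer vector, cells counted.
#' @param counted_volume positive numeric vector, counted aliquot in ul.
#' @param suspension_volume positive numeric vector, total suspension in ul;
#'   must be at least \code{counted_volume}.
#' @return Integer vector of estimated population sizes.
#' @export
#' @examples
#' estimate_population(10, 0.8, 150) # 1875
#' estimate_population(7, 3.2, 30)   # floor(65.625) = 65
estimate_population <- function(raw_count, counted_volume, suspension_volume) {
  if (any(!is.finite(raw_count)) || any(raw_count < 0) ||
      any(raw_count != floor(raw_count))) {
    stop("'raw_count' must be non-negative integers")
  }
  if (any(!is.finite(counted_volume)) || any(counted_volume <= 0) ||
      any(!is.finite(suspension_volume)) || any(suspension_volume <= 0)) {
    stop("volumes must be positive")
  }
  if (any(counted_volume > suspension_volume)) {
    stop("'counted_volume' must not exceed 'suspension_volume'")
  }
  as.integer(floor(raw_count * suspension_volume / counted_volume + 1e-9))
}

#' Community composition of the protist species groups
#'
#' A named, ordered proportion vector over a species-group panel, the
#' p_i fed to the transmission model. Proportions are renormalised to sum
#' exactly to 1 at construction.
#'
#' @param proportions non-negative numeric vector with positive sum.
#' @param species_groups character vector of unique group names, same
#'   length; defaults to \code{names(proportions)}.
#' @param source free-text provenance (caste, colonies, averaging rule).
#' @return An object of class \code{"community_composition"}: a list with
#'   elements \code{species_groups}, \code{proportions} and \code{source}.
#' @export
#' @examples
#' community_composition(c(a = 3, b = 1))
community_composition <- function(proportions,
                                  species_groups = names(proportions),
                                  source = "") {
  if (!is.numeric(proportions) || length(proportions) == 0) {
    stop("'proportions' must be a non-empty numeric vector")
  }
  if (any(!is.finite(proportions)) || any(proportions < 0)) {
    stop("'proportions' must be finite and non-negative")
  }
  if (sum(proportions) <= 0) stop("'proportions' must have a positive sum")
  if (is.null(species_groups)) {
    species_groups <- paste0("group_", seq_along(proportions))
  }
  if (length(species_groups) != length(proportions)) {
    stop("'species_groups' must name every proportion")
  }
  if (anyDuplicated(species_groups)) stop("species group names must be unique")
  structure(
    list(
      species_groups = as.character(species_groups),
      proportions = unname(proportions / sum(proportions)),
      source = as.character(source)
    ),
    class = "community_composition"
  )
}

#' @export
print.community_composition <- function(x, digits = 4, ...) {
  cat("Community composition (", length(x$species_groups), " species groups)\n",
      sep = "")
  if (nzchar(x$source)) cat("Source:", x$source, "\n")
  print(stats::setNames(round(x$proportions, digits), x$species_groups))
  invisible(x)
}

as_composition <- function(x) {
  if (inherits(x, "community_composition")) return(x)
  if (is.numeric(x)) return(community_composition(x))
  stop("expected a 'community_composition' or a numeric proportion vector")
}

#' Read per-individual protist count tables
#'
#' Reads a long-format count table (one row per individual x species group)
#' or a wide table previously written by [write_samples()] and returns the
#' wide per-individual sample table used throughout the package. Field
#' separator is auto-detected from the extension (\code{.tsv}/\code{.txt}/
#' \code{.tab} are tab-separated, everything else comma-separated).
#'
#' Long files must carry columns \code{individual_id}, \code{colony_id},
#' \code{caste_group}, \code{sex}, \code{species_group} and either a
#' pre-estimated \code{count} column or a raw \code{raw_count} column. In
#' the raw dialect the haemocytometer scale-up of [estimate_population()] is
#' applied row-wise; \code{counted_volume} and \code{suspension_volume}
#' columns override the panel/caste defaults of [default_counted_volume()]
#' and [default_suspension_volume()]. Species groups absent for an
#' individual are filled with zero counts. Unknown caste or species labels,
#' duplicated (individual, species) rows, negative or non-integer counts all
#' raise errors naming the offending rows.
#'
#' @param path path to a UTF-8 CSV/TSV file with header.
#' @param panel species-group panel data frame, see
#'   [default_species_groups()].
#' @return A data frame with one row per individual: \code{individual_id},
#'   \code{colony_id}, \code{caste_group}, \code{sex}, one integer column
#'   per panel group, and \code{total}.
#' @export
read_samples <- function(path, panel = default_species_groups()) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt", "tab")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "",
                          fileEncoding = "UTF-8")
  if ("species_group" %in% names(df)) {
    return(.samples_from_long(df, panel))
  }
  if (all(panel$name %in% names(df))) {
    return(.samples_from_wide(df, panel))
  }
  stop("unrecognised file layout: need a 'species_group' column (long format) ",
       "or one column per panel species group (wide format)")
}

.check_integer_counts <- function(x, what) {
  bad <- !is.finite(x) | x < 0 | x != floor(x)
  if (any(bad)) {
    stop(sprintf("column '%s' must contain non-negative integers; offending rows: %s",
                 what, paste(which(bad), collapse = ", ")))
  }
  as.integer(x)
}

.check_levels <- function(x, allowed, what) {
  bad <- !(x %in% allowed)
  if (any(bad)) {
    stop(sprintf("unknown %s value(s) %s in row(s) %s",
                 what,
                 paste(sQuote(unique(x[bad])), collapse = ", "),
                 paste(which(bad), collapse = ", ")))
  }
  x
}

.samples_from_long <- function(df, panel) {
  required <- c("individual_id", "colony_id", "caste_group", "sex", "species_group")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  .check_levels(df$caste_group, caste_groups(), "caste_group")
  .check_levels(df$species_group, panel$name, "species_group")
  .check_levels(df$sex, c("male", "female", "unknown"), "sex")
  dup <- duplicated(df[, c("individual_id", "species_group")])
  if (any(dup)) {
    stop("duplicate (individual_id, species_group) row(s): ",
         paste(which(dup), collapse = ", "))
  }

  if ("count" %in% names(df)) {
    counts <- .check_integer_counts(df$count, "count")
  } else if ("raw_count" %in% names(df)) {
    raw <- .check_integer_counts(df$raw_count, "raw_count")
    size <- panel$size_class[match(df$species_group, panel$name)]
    cv <- if ("counted_volume" %in% names(df)) df$counted_volume else
      default_counted_volume(size)
    sv <- if ("suspension_volume" %in% names(df)) df$suspension_volume else
      default_suspension_volume(df$caste_group)
    counts <- estimate_population(raw, cv, sv)
  } else {
    stop("need a 'count' or 'raw_count' column")
  }

  ids <- unique(df$individual_id)
  meta <- df[!duplicated(df$individual_id),
             c("individual_id", "colony_id", "caste_group", "sex")]
  # each individual must have consistent metadata across its rows
  key <- paste(df$colony_id, df$caste_group, df$sex)
  if (any(tapply(key, df$individual_id, function(k) length(unique(k))) > 1)) {
    stop("inconsistent colony/caste/sex metadata within an individual")
  }
  mat <- matrix(0L, nrow = length(ids), ncol = nrow(panel),
                dimnames = list(NULL, panel$name))
  mat[cbind(match(df$individual_id, ids),
            match(df$species_group, panel$name))] <- counts
  out <- cbind(meta[match(ids, meta$individual_id), , drop = FALSE],
               as.data.frame(mat))
  rownames(out) <- NULL
  out$total <- as.integer(rowSums(mat))
  out
}

.samples_from_wide <- function(df, panel) {
  required <- c("individual_id", "colony_id", "caste_group", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  .check_levels(df$caste_group, caste_groups(), "caste_group")
  .check_levels(df$sex, c("male", "female", "unknown"), "sex")
  if (anyDuplicated(df$individual_id)) stop("duplicate individual_id rows")
  for (g in panel$name) df[[g]] <- .check_integer_counts(df[[g]], g)
  out <- df[, c(required, panel$name)]
  out$total <- as.integer(rowSums(out[, panel$name, drop = FALSE]))
  if ("total" %in% names(df) &&
      !all(df$total == out$total)) {
    stop("stored 'total' column disagrees with the sum of group counts")
  }
  out
}

#' Write a wide per-individual sample table
#'
#' @param samples wide sample table as returned by [read_samples()] or
#'   [generate_dataset()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a community composition
#'
#' The composition is written as a two-column TSV (\code{species_group},
#' \code{proportion}); provenance goes to a JSON sidecar at
#' \code{<path>.json}. [read_composition()] restores both.
#'
#' @param composition a [community_composition()] object.
#' @param path TSV path.
#' @param sidecar write the JSON provenance sidecar (default \code{TRUE}).
#' @return \code{path}, invisibly (for the writer); the composition for the
#'   reader.
#' @export
write_composition <- function(composition, path, sidecar = TRUE) {
  composition <- as_composition(composition)
  utils::write.table(
    data.frame(species_group = composition$species_groups,
               proportion = composition$proportions),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  if (sidecar) {
    jsonlite::write_json(
      list(source = composition$source,
           species_groups = composition$species_groups,
           proportions = composition$proportions),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_composition
#' @export
read_composition <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  source <- ""
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    source <- jsonlite::read_json(sidecar)$source
  }
  community_composition(df$proportion, df$species_group, source = source)
}

#' Average per-individual compositions into a source community
#'
#' Builds the hypothetical source community for the transmission model by
#' averaging empirical individuals of one caste across colonies. The default
#' (\code{method = "individual"}) converts each matched individual to a
#' proportion vector (counts / total) and averages those arithmetically, so
#' every individual carries equal weight regardless of its gut population
#' size; \code{method = "pooled"} instead sums counts over individuals and
#' normalises the pooled vector, weighting individuals by abundance. The
#' result is renormalised to sum to 1.
#'
#' @param samples wide per-individual sample table.
#' @param caste_group caste to average over (see [caste_groups()]).
#' @param colonies optional character vector restricting to these colony
#'   ids; default uses all colonies present.
#' @param method \code{"individual"} (default) or \code{"pooled"}.
#' @return A [community_composition()] whose \code{source} records the
#'   filter and averaging rule.
#' @export
average_composition <- function(samples, caste_group, colonies = NULL,
                                method = c("individual", "pooled")) {
  method <- match.arg(method)
  sel <- samples$caste_group == caste_group
  if (!is.null(colonies)) sel <- sel & samples$colony_id %in% colonies
  matched <- samples[sel, , drop = FALSE]
  if (nrow(matched) == 0) {
    stop(sprintf("no samples match caste_group '%s'%s", caste_group,
                 if (is.null(colonies)) "" else
                   paste0(" in colonies ", paste(colonies, collapse = ", "))))
  }
  groups <- species_columns(matched)
  counts <- as.matrix(matched[, groups, drop = FALSE])
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("individual(s) with zero total count: ",
         paste(matched$individual_id[totals == 0], collapse = ", "))
  }
  p <- switch(method,
    individual = colMeans(counts / totals),
    pooled = colSums(counts) / sum(counts)
  )
  community_composition(
    p, groups,
    source = sprintf("caste=%s; colonies=%s; rule=%s mean of %d individuals",
                     caste_group,
                     paste(sort(unique(matched$colony_id)), collapse = "+"),
                     method, nrow(matched))
  )
}
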