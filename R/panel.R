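#' Default protist species-group panel
#'
#' The ten microscopy-distinguishable count categories used to enumerate the
#' hindgut protist community of \emph{Reticulitermes speratus}. Sixteen
#' morphological species are pooled into ten groups because several
#' \emph{Dinenympha} species cannot be told apart in live preparations. The
#' two large parabasalids (\emph{Trichonympha agilis} and \emph{Teranympha
#' mirabilis}) are counted over a larger haemocytometer area than the other
#' groups, which the \code{size_class} column records.
#'
#' @return A data frame with one row per species group and columns
#'   \code{name} (unique short label), \code{size_class} (\code{"large"} or
#'   \code{"other"}, which determines the default counted volume) and
#'   \code{member_species} (list column of the morphological species pooled
#'   into the group).
#' @seealso [default_counted_volume()], [read_samples()]
#' @export
#' @examples
#' default_species_groups()
default_species_groups <- function() {
  data.frame(
    name = c(
      "Pyrsonympha_spp", "Dinenympha_exilis", "Dinenympha_porteri_III",
      "Dinenympha_porteri_IV", "Dinenympha_spp1", "Dinenympha_spp2",
      "Trichonympha_agilis", "Teranympha_mirabilis", "Holomastigotes_sp",
      "small_protists"
    ),
    size_class = c(
      "other", "other", "other", "other", "other", "other",
      "large", "large", "other", "other"
    ),
    member_species = I(list(
      c("Pyrsonympha grandis", "Pyrsonympha modesta"),
      "Dinenympha exilis",
      "Dinenympha porteri type III",
      "Dinenympha porteri type IV",
      c("Dinenympha rugosa", "Dinenympha porteri type I",
        "Dinenympha porteri type II"),
      c("Dinenympha leidyi", "Dinenympha parva"),
      "Trichonympha agilis",
      "Teranympha mirabilis",
      "Holomastigotes sp.",
      c("Trichomonoides sp.", "Hexamastix sp.", "Microjoenia sp.")
    )),
    stringsAsFactors = FALSE
  )
}

#' Recognised caste/group labels
#'
#' Caste and treatment groups for which per-individual counts are modelled:
#' workers, freshly moulted workers (protist-free), last-instar nymphs, and
#' alates on the day of eclosion (A0), two days after (A2), seven days after
#' in isolation (A7) and seven days after while kept with workers (A7w).
#'
#' @return Character vector of valid \code{caste_group} values.
#' @export
caste_groups <- function() {
  c("worker", "moulted_worker", "nymph", "A0", "A2", "A7", "A7w")
}

#' Default haemocytometer volumes
#'
#' Large protists are counted over 16 haemocytometer squares (3.2 ul), all
#' other groups over the 4 corner squares (0.8 ul). Gut contents of workers
#' are suspended in 150 ul; nymphs and alates, with far fewer cells, in
#' 30 ul.
#'
#' @param size_class character vector of \code{"large"} / \code{"other"}.
#' @param caste_group character vector of caste labels (see [caste_groups()]).
#' @return Numeric vector of volumes in microlitres.
#' @export
default_counted_volume <- function(size_class) {
  stopifnot(all(size_class %in% c("large", "other")))
  ifelse(size_class == "large", 3.2, 0.8)
}

#' @rdname default_counted_volume
#' @export
default_suspension_volume <- function(caste_group) {
  stopifnot(all(caste_group %in% caste_groups()))
  ifelse(caste_group == "worker", 150, 30)
}

# metadata columns of a wide sample table; everything else is a species group
.meta_cols <- c("individual_id", "colony_id", "caste_group", "sex", "total")

# species-group columns of a wide sample table, in table order
species_columns <- function(samples) {
  setdiff(names(samples), .meta_cols)
}
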