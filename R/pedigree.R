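#' Build a pedigree of candidate-allele carriers
#'
#' A pedigree is a tibble of family members with affected status and carrier
#' genotypes for up to two candidate alleles (allele A, by convention the
#' paternal mutation for autosomal recessive families or the single X-linked
#' mutation; allele B the maternal mutation). Carrier states are
#' `"yes"`/`"no"`/`"unknown"`. Founders have no parents; every non-founder
#' must have both parents present in the pedigree.
#'
#' @param members A data frame with columns `family_id`, `member_id`,
#'   `father_id`, `mother_id` (`NA` for founders), `sex`
#'   (`"male"`/`"female"`), `affected` (logical), `carries_allele_a`,
#'   `carries_allele_b`, and optionally `proband` (logical, marks the index
#'   patient; default `FALSE`).
#' @return A tibble of class `rd_pedigree`.
#' @export
pedigree <- function(members) {
  m <- tibble::as_tibble(members)
  if (!"proband" %in% names(m)) m$proband <- FALSE
  needed <- c("family_id", "member_id", "father_id", "mother_id", "sex",
              "affected", "carries_allele_a", "carries_allele_b", "proband")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols)) {
    stop("pedigree is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- m[, needed]
  m$member_id <- as.character(m$member_id)
  m$father_id <- as.character(m$father_id)
  m$mother_id <- as.character(m$mother_id)
  validate_pedigree(structure(m, class = c("rd_pedigree", class(tibble::tibble()))))
}

#' @noRd
validate_pedigree <- function(m) {
  if (anyDuplicated(m$member_id)) {
    stop("duplicate member id: ", m$member_id[duplicated(m$member_id)][1L],
         call. = FALSE)
  }
  for (col in c("father_id", "mother_id")) {
    unknown <- setdiff(stats::na.omit(m[[col]]), m$member_id)
    if (length(unknown)) {
      stop("unknown parent id in pedigree: ", unknown[1L], call. = FALSE)
    }
  }
  half <- xor(is.na(m$father_id), is.na(m$mother_id))
  if (any(half)) {
    stop("member ", m$member_id[half][1L],
         " has exactly one parent; non-founders need both", call. = FALSE)
  }
  if (!all(m$sex %in% c("male", "female"))) {
    stop("pedigree sex must be \"male\" or \"female\"", call. = FALSE)
  }
  gt_levels <- c("yes", "no", "unknown")
  if (!all(m$carries_allele_a %in% gt_levels) ||
      !all(m$carries_allele_b %in% gt_levels)) {
    stop("carrier states must be yes/no/unknown", call. = FALSE)
  }
  # acyclicity: repeatedly peel members whose parents are already peeled
  peeled <- is.na(m$father_id)
  repeat {
    newly <- !peeled & m$father_id %in% m$member_id[peeled] &
      m$mother_id %in% m$member_id[peeled]
    if (!any(newly)) break
    peeled <- peeled | newly
  }
  if (!all(peeled)) {
    stop("pedigree relations are cyclic around member ",
         m$member_id[!peeled][1L], call. = FALSE)
  }
  m
}

#' Pedigree founders and children
#' @noRd
ped_children <- function(ped) ped[!is.na(ped$father_id), ]

#' @export
print.rd_pedigree <- function(x, ...) {
  cat(sprintf("# rd_pedigree: family %s, %d members (%d affected)\n",
              x$family_id[1L], nrow(x), sum(x$affected)))
  NextMethod()
}
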