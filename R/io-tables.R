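#' Read a disease-gene panel
#'
#' The panel is a TSV with columns `gene`, `chrom` (one gene per line); the
#' bundled default emulates a 160-gene retinal dystrophy panel. Duplicate
#' gene symbols are an error.
#'
#' @param path Path to the panel TSV.
#' @return A tibble with columns `gene`, `chrom`.
#' @export
read_panel <- function(path) {
  p <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), chrom = readr::col_character()
  ))
  validate_panel(tibble::as_tibble(p[, c("gene", "chrom")]))
}

#' @noRd
validate_panel <- function(p) {
  dup <- p$gene[duplicated(p$gene)]
  if (length(dup)) {
    stop("duplicate gene(s) in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- !p$chrom %in% chrom_labels()
  if (any(bad)) {
    stop("invalid panel chromosome label(s): ",
         paste(unique(p$chrom[bad]), collapse = ", "), call. = FALSE)
  }
  p
}

#' @rdname read_panel
#' @param panel A panel tibble.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel[, c("gene", "chrom")], path)
  invisible(path)
}

#' Read a site-frequency catalog
#'
#' A dbSNP-style catalog: TSV with columns `chrom`, `pos`, `ref`, `alt`,
#' `af`. `af` may be empty, representing a known site with no recorded
#' frequency (such sites are retained by the frequency filter, which removes
#' only sites whose recorded frequency exceeds the threshold).
#'
#' @param path Path to the catalog TSV.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `af`.
#' @export
read_frequency_catalog <- function(path) {
  cat <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    af = readr::col_double()
  ))
  validate_frequency_catalog(tibble::as_tibble(cat))
}

#' @noRd
validate_frequency_catalog <- function(cat) {
  if (any(!is.na(cat$af) & (cat$af < 0 | cat$af > 1))) {
    stop("catalog frequencies must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(cat$chrom, cat$pos, cat$ref, cat$alt, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate site(s) in frequency catalog: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  cat
}

#' @rdname read_frequency_catalog
#' @param catalog A frequency-catalog tibble.
#' @export
write_frequency_catalog <- function(catalog, path) {
  readr::write_tsv(catalog[, c("chrom", "pos", "ref", "alt", "af")], path)
  invisible(path)
}

#' Read a known-mutation catalog
#'
#' TSV with columns `gene`, `hgvs_c`, `protein`, `status`
#' (`known`/`novel`), `reference`. `(gene, hgvs_c)` pairs must be unique.
#' Records with status `known` represent mutations already described in the
#' literature at the time of the study; `novel` records are the study's own
#' discoveries and do not count as previously known when annotating
#' candidates.
#'
#' @param path Path to the catalog TSV.
#' @return A tibble with the five columns above.
#' @export
read_mutation_catalog <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), hgvs_c = readr::col_character(),
    protein = readr::col_character(), status = readr::col_character(),
    reference = readr::col_character()
  ))
  validate_mutation_catalog(tibble::as_tibble(m))
}

#' @noRd
validate_mutation_catalog <- function(m) {
  key <- paste(m$gene, m$hgvs_c)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, hgvs_c) in mutation catalog: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  if (!all(m$status %in% c("known", "novel"))) {
    stop("mutation catalog status must be \"known\" or \"novel\"", call. = FALSE)
  }
  m
}

#' @rdname read_mutation_catalog
#' @param catalog A mutation-catalog tibble.
#' @export
write_mutation_catalog <- function(catalog, path) {
  readr::write_tsv(
    catalog[, c("gene", "hgvs_c", "protein", "status", "reference")], path,
    na = ""
  )
  invisible(path)
}

#' Read a pedigree with candidate-allele carrier genotypes
#'
#' Combines a standard 6-column PED file (`family`, `id`, `father`, `mother`,
#' `sex` 1=male/2=female, `phenotype` 1=unaffected/2=affected) with a
#' genotype TSV (`id`, `carries_allele_a`, `carries_allele_b`, each
#' `yes`/`no`/`unknown`, and an optional logical `proband` column marking
#' the index patient). Founders have no parents; a parent id that is not a
#' member is an error.
#'
#' @param ped_path Path to the PED file (whitespace-separated, no header).
#' @param genotype_path Path to the genotype TSV.
#' @return A tibble of class `rd_pedigree`; see [pedigree()].
#' @export
read_pedigree <- function(ped_path, genotype_path) {
  ped <- utils::read.table(
    ped_path, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("family_id", "member_id", "father_id", "mother_id",
                  "sex", "phenotype")
  )
  ped$member_id <- as.character(ped$member_id)
  ped$father_id <- as.character(ped$father_id)
  ped$mother_id <- as.character(ped$mother_id)
  geno <- readr::read_tsv(genotype_path, col_types = readr::cols(
    id = readr::col_character(),
    carries_allele_a = readr::col_character(),
    carries_allele_b = readr::col_character(),
    .default = readr::col_guess()
  ))
  members <- tibble::tibble(
    family_id = as.character(ped$family_id),
    member_id = ped$member_id,
    father_id = dplyr::na_if(ped$father_id, "0"),
    mother_id = dplyr::na_if(ped$mother_id, "0"),
    sex = dplyr::case_match(as.character(ped$sex),
                            "1" ~ "male", "2" ~ "female",
                            .default = NA_character_),
    affected = as.character(ped$phenotype) == "2"
  )
  members <- dplyr::left_join(members, geno, by = c(member_id = "id"))
  members$carries_allele_a[is.na(members$carries_allele_a)] <- "unknown"
  members$carries_allele_b[is.na(members$carries_allele_b)] <- "unknown"
  if (!"proband" %in% names(members)) members$proband <- FALSE
  members$proband[is.na(members$proband)] <- FALSE
  pedigree(members)
}

#' @rdname read_pedigree
#' @param ped A pedigree tibble.
#' @param path,genotype_path Output paths for the PED and genotype TSV.
#' @export
write_pedigree <- function(ped, path, genotype_path) {
  utils::write.table(
    data.frame(
      family = ped$family_id, id = ped$member_id,
      father = ifelse(is.na(ped$father_id), "0", ped$father_id),
      mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
      sex = ifelse(ped$sex == "male", 1L, 2L),
      phenotype = ifelse(ped$affected, 2L, 1L)
    ),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  readr::write_tsv(
    tibble::tibble(
      id = ped$member_id,
      carries_allele_a = ped$carries_allele_a,
      carries_allele_b = ped$carries_allele_b,
      proband = ped$proband
    ),
    genotype_path
  )
  invisible(path)
}
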