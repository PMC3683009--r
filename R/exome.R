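#' Consequence classes
#'
#' The seven mutually exclusive functional classes a variant annotation may
#' carry. The first five ("non-silent" classes) can alter a coding transcript
#' and are the classes the cascade keeps by default; `synonymous` and
#' `noncoding` changes are dropped at step 1.
#'
#' @return A character vector of class labels.
#' @export
#' @examples
#' consequence_classes()
#' nonsilent_classes()
consequence_classes <- function() {
  c("missense", "nonsense", "frameshift_indel", "inframe_indel",
    "splice_site", "synonymous", "noncoding")
}

#' @rdname consequence_classes
#' @export
nonsilent_classes <- function() {
  c("missense", "nonsense", "frameshift_indel", "inframe_indel", "splice_site")
}

#' Chromosome labels accepted by the package
#' @noRd
chrom_labels <- function() c(as.character(1:22), "X", "Y")

#' Build a patient exome
#'
#' An exome is a tibble of called, annotated variants for one index patient,
#' with the patient's identifier and sex attached as attributes. One row is
#' one called ALT allele. Hemizygous male chrX calls are encoded as
#' `homozygous_alt` (the usual caller behaviour) and re-interpreted as
#' hemizygous downstream from sex plus chromosome.
#'
#' @param variants A data frame with columns `chrom` (1-22, X, Y), `pos`
#'   (1-based), `ref`, `alt`, `gene` (symbol, or `""` for noncoding
#'   variants), `consequence` (one of [consequence_classes()]), `zygosity`
#'   (`"heterozygous"` or `"homozygous_alt"`), and optionally `rs_id`
#'   (catalog identifier or `NA`), `cat_af` (catalog allele frequency or
#'   `NA`) and `hgvs_c` (coding-change string or `NA`).
#' @param patient_id Non-empty patient identifier.
#' @param sex `"male"`, `"female"`, or `NA` (unknown; required before the
#'   recessive-model step whenever chrX variants are present).
#'
#' @return A tibble of class `rd_exome` with attributes `patient_id` and
#'   `sex`.
#' @export
#' @examples
#' exome(
#'   data.frame(
#'     chrom = "1", pos = 100L, ref = "A", alt = "T",
#'     gene = "ABCA4", consequence = "missense", zygosity = "heterozygous"
#'   ),
#'   patient_id = "pt1", sex = "female"
#' )
exome <- function(variants, patient_id, sex = NA_character_) {
  if (!is.character(patient_id) || length(patient_id) != 1L ||
      is.na(patient_id) || !nzchar(patient_id)) {
    stop("`patient_id` must be a single non-empty string", call. = FALSE)
  }
  sex <- as.character(sex)
  if (length(sex) != 1L || (!is.na(sex) && !sex %in% c("male", "female"))) {
    stop("`sex` must be \"male\", \"female\" or NA", call. = FALSE)
  }
  v <- tibble::as_tibble(variants)
  if (nrow(v) == 0L) v <- empty_variant_tbl()
  optional <- c(rs_id = NA_character_, cat_af = NA_real_, hgvs_c = NA_character_)
  for (col in names(optional)) {
    if (!col %in% names(v)) v[[col]] <- optional[[col]]
  }
  v <- dplyr::mutate(
    v,
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    ref = as.character(.data$ref),
    alt = as.character(.data$alt),
    gene = as.character(.data$gene),
    consequence = as.character(.data$consequence),
    zygosity = as.character(.data$zygosity),
    rs_id = as.character(.data$rs_id),
    cat_af = as.double(.data$cat_af),
    hgvs_c = as.character(.data$hgvs_c)
  )
  v <- v[, c("chrom", "pos", "ref", "alt", "gene", "consequence", "zygosity",
             "rs_id", "cat_af", "hgvs_c")]
  out <- new_rd_exome(v, patient_id = patient_id, sex = sex)
  validate_exome(out)
}

#' Low-level constructor (no validation)
#' @noRd
new_rd_exome <- function(variants, patient_id, sex) {
  structure(
    variants,
    patient_id = patient_id,
    sex = sex,
    class = c("rd_exome", class(tibble::tibble()))
  )
}

#' Validate an exome's invariants
#'
#' Checks column types, chromosome labels, positive positions, `ref != alt`,
#' legal consequence and zygosity labels, and that every variant with a
#' coding consequence carries a gene symbol.
#'
#' @param x An `rd_exome`.
#' @return `x`, invisibly-validated (returned unchanged).
#' @export
validate_exome <- function(x) {
  stopifnot(inherits(x, "rd_exome"))
  if (nrow(x) == 0L) return(x)
  bad_chrom <- !x$chrom %in% chrom_labels()
  if (any(bad_chrom)) {
    stop("invalid chromosome label(s): ",
         paste(unique(x$chrom[bad_chrom]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(x$pos) | x$pos < 1L)) {
    stop("`pos` must be a positive 1-based coordinate", call. = FALSE)
  }
  if (any(x$ref == x$alt)) stop("`ref` must differ from `alt`", call. = FALSE)
  bad_csq <- !x$consequence %in% consequence_classes()
  if (any(bad_csq)) {
    stop("unknown consequence class(es): ",
         paste(unique(x$consequence[bad_csq]), collapse = ", "), call. = FALSE)
  }
  if (!all(x$zygosity %in% c("heterozygous", "homozygous_alt"))) {
    stop("`zygosity` must be \"heterozygous\" or \"homozygous_alt\"",
         call. = FALSE)
  }
  missing_gene <- x$consequence != "noncoding" & !nzchar(x$gene)
  if (any(missing_gene)) {
    stop("coding variants must carry a gene symbol (",
         sum(missing_gene), " without one)", call. = FALSE)
  }
  if (any(!is.na(x$cat_af) & (x$cat_af < 0 | x$cat_af > 1))) {
    stop("`cat_af` must lie in [0, 1]", call. = FALSE)
  }
  x
}

#' Patient metadata accessors
#'
#' @param x An `rd_exome`.
#' @return `patient_id()` the patient identifier; `patient_sex()` `"male"`,
#'   `"female"` or `NA`.
#' @export
patient_id <- function(x) attr(x, "patient_id", exact = TRUE)

#' @rdname patient_id
#' @export
patient_sex <- function(x) attr(x, "sex", exact = TRUE)

#' Rebuild an exome around a filtered variant table, keeping metadata
#' @noRd
restore_exome <- function(variants, template) {
  new_rd_exome(tibble::as_tibble(variants),
               patient_id = patient_id(template),
               sex = patient_sex(template))
}

#' @export
print.rd_exome <- function(x, ...) {
  cat(sprintf("# rd_exome: patient %s (%s), %d variant%s\n",
              patient_id(x),
              ifelse(is.na(patient_sex(x)), "sex unknown", patient_sex(x)),
              nrow(x), if (nrow(x) == 1L) "" else "s"))
  NextMethod()
}

#' Variant site key used for catalog matching
#' @noRd
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}
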