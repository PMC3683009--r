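#' Read a single-patient annotated VCF
#'
#' Reads a VCF v4.x file in the package's annotation dialect: a single sample
#' column with `GT`, and per-record INFO keys `GENE` (gene symbol),
#' `CSQ_CLASS` (one of [consequence_classes()]), plus optional `RS` (catalog
#' identifier), `CAT_AF` (catalog allele frequency) and `HGVSC` (coding-change
#' string). Multi-allelic records are split into one variant per ALT allele.
#' Reference calls (`0/0`) and no-calls (`./.`) are excluded. The patient
#' identifier is taken from the sample column name; the patient's sex from a
#' `##patient_sex=` header line when present.
#'
#' `GENE` is required for every record whose `CSQ_CLASS` is not `noncoding`;
#' `CSQ_CLASS` is always required. A record missing a required key is a parse
#' error naming the key and the offending line.
#'
#' @param path Path to a VCF file.
#' @return An [exome()] (`rd_exome` tibble).
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- character()
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  n_body <- 0L
  sample_line <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (startsWith(line, "##")) header <- c(header, line)
    else if (startsWith(line, "#CHROM")) sample_line <- line
    else n_body <- n_body + 1L
  }
  if (is.null(sample_line)) stop("not a VCF: no #CHROM header line", call. = FALSE)
  cols <- strsplit(sample_line, "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stop("VCF has no sample column", call. = FALSE)
  if (length(cols) > 10L) {
    stop("multi-sample VCF not supported (found ",
         length(cols) - 9L, " samples)", call. = FALSE)
  }
  pid <- cols[10L]
  sex_line <- grep("^##patient_sex=", header, value = TRUE)
  sex <- if (length(sex_line)) sub("^##patient_sex=", "", sex_line[1L]) else NA_character_

  if (n_body == 0L) {
    return(exome(empty_variant_tbl(), patient_id = pid, sex = sex))
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt[, 2L]
  info_get <- function(key) vcfR::extract.info(v, element = key)

  gene <- info_get("GENE")
  csq <- info_get("CSQ_CLASS")
  rs <- info_get("RS")
  af <- info_get("CAT_AF")
  hgvs <- info_get("HGVSC")

  miss_csq <- which(is.na(csq))
  if (length(miss_csq)) {
    stop("missing required INFO key CSQ_CLASS at VCF record ", miss_csq[1L],
         " (", fix$CHROM[miss_csq[1L]], ":", fix$POS[miss_csq[1L]], ")",
         call. = FALSE)
  }
  miss_gene <- which(is.na(gene) & csq != "noncoding")
  if (length(miss_gene)) {
    stop("missing required INFO key GENE at VCF record ", miss_gene[1L],
         " (", fix$CHROM[miss_gene[1L]], ":", fix$POS[miss_gene[1L]], ")",
         call. = FALSE)
  }
  gene[is.na(gene)] <- ""

  gt <- sub(":.*", "", gt_raw)
  base <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, gene = gene, consequence = csq, zygosity = NA_character_,
    rs_id = rs, cat_af = suppressWarnings(as.double(af)), hgvs_c = hgvs
  )
  # vectorized path for biallelic records; loop only over multi-allelics
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  simple <- base[!multi, ]
  gt_s <- gsub("|", "/", gt[!multi], fixed = TRUE)
  n1 <- (substr(gt_s, 1L, 1L) == "1") + (substr(gt_s, 3L, 3L) == "1")
  n1[is.na(n1)] <- 0L # no-calls (./.) are excluded
  simple$zygosity <- ifelse(n1 >= 2L, "homozygous_alt", "heterozygous")
  simple <- simple[n1 > 0L, ]

  rows <- list(simple)
  for (i in which(multi)) {
    if (is.na(gt[i])) next
    alleles <- strsplit(gsub("|", "/", gt[i], fixed = TRUE), "/", fixed = TRUE)[[1]]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- if (is.na(af[i])) rep(NA_real_, length(alts))
           else suppressWarnings(as.double(strsplit(af[i], ",", fixed = TRUE)[[1]]))
    hgvss <- if (is.na(hgvs[i])) rep(NA_character_, length(alts))
             else strsplit(hgvs[i], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      n_alt <- sum(alleles == as.character(a))
      if (n_alt == 0L) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
        alt = alts[a], gene = gene[i], consequence = csq[i],
        zygosity = if (n_alt >= 2L) "homozygous_alt" else "heterozygous",
        rs_id = rs[i], cat_af = afs[min(a, length(afs))],
        hgvs_c = hgvss[min(a, length(hgvss))]
      )
    }
  }
  variants <- dplyr::bind_rows(rows)
  if (nrow(variants) == 0L) variants <- empty_variant_tbl()
  exome(variants, patient_id = pid, sex = sex)
}

#' Write a patient exome as an annotated VCF
#'
#' Emits VCF v4.2 in the dialect consumed by [read_vcf()]: one record per
#' variant row, a single sample column named after the patient, genotype
#' `0/1` for heterozygous and `1/1` for homozygous-alt rows, and INFO keys
#' `GENE`, `CSQ_CLASS` and (when present) `RS`, `CAT_AF`, `HGVSC`. An empty
#' exome yields a header-only file. `read_vcf(write_vcf(x))` reproduces every
#' typed field.
#'
#' @param x An [exome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "rd_exome"))
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.na(patient_sex(x))) paste0("##patient_sex=", patient_sex(x)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    paste0("##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class: ",
           paste(consequence_classes(), collapse = "|"), "\">"),
    "##INFO=<ID=RS,Number=1,Type=String,Description=\"Frequency-catalog identifier\">",
    "##INFO=<ID=CAT_AF,Number=A,Type=Float,Description=\"Catalog allele frequency\">",
    "##INFO=<ID=HGVSC,Number=A,Type=String,Description=\"Coding change (HGVS c.)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", patient_id(x)), collapse = "\t")
  )
  body <- character(0)
  if (nrow(x) > 0L) {
    ord <- order(match(x$chrom, chrom_labels()), x$pos, x$ref, x$alt)
    v <- x[ord, ]
    info <- paste0(
      ifelse(nzchar(v$gene), paste0("GENE=", v$gene, ";"), ""),
      "CSQ_CLASS=", v$consequence,
      ifelse(!is.na(v$rs_id), paste0(";RS=", v$rs_id), ""),
      ifelse(!is.na(v$cat_af), paste0(";CAT_AF=", format(v$cat_af, scientific = FALSE, trim = TRUE,
                                digits = 15)), ""),
      ifelse(!is.na(v$hgvs_c), paste0(";HGVSC=", v$hgvs_c), "")
    )
    body <- paste(
      v$chrom, v$pos,
      ifelse(is.na(v$rs_id), ".", v$rs_id),
      v$ref, v$alt, ".", ".", info, "GT",
      ifelse(v$zygosity == "homozygous_alt", "1/1", "0/1"),
      sep = "\t"
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @noRd
empty_variant_tbl <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gene = character(), consequence = character(), zygosity = character(),
    rs_id = character(), cat_af = double(), hgvs_c = character()
  )
}
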