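#' Configure the five-step filtering cascade
#'
#' Bundles the reference data and thresholds the cascade needs: the set of
#' consequence classes retained at step 1, the disease-gene panel used at
#' step 2, the site-frequency catalog and allele-frequency threshold used at
#' step 3, and the known-mutation catalog used at step 5.
#'
#' The frequency filter removes a variant only when the catalog records a
#' frequency for its exact site and alleles and that frequency is *strictly*
#' greater than `af_threshold`: catalogued sites with no recorded frequency,
#' and sites at exactly the threshold, are retained.
#'
#' @param panel Gene-panel tibble (`gene`, `chrom`); see [read_panel()].
#' @param frequency_catalog Site-frequency tibble; see
#'   [read_frequency_catalog()]. May be empty.
#' @param mutation_catalog Known-mutation tibble; see
#'   [read_mutation_catalog()]. May be empty.
#' @param af_threshold Allele-frequency cut-off in `[0, 1]`; default 0.02
#'   (variants commoner than 2% in the catalog are removed).
#' @param kept_classes Consequence classes retained at step 1; defaults to
#'   the five non-silent classes, [nonsilent_classes()].
#' @return A list of class `rd_cascade_config`.
#' @export
#' @examples
#' cfg <- cascade_config(panel = default_panel())
#' cfg$af_threshold
cascade_config <- function(panel,
                           frequency_catalog = NULL,
                           mutation_catalog = NULL,
                           af_threshold = 0.02,
                           kept_classes = nonsilent_classes()) {
  if (!is.numeric(af_threshold) || length(af_threshold) != 1L ||
      is.na(af_threshold) || af_threshold < 0 || af_threshold > 1) {
    stop("`af_threshold` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!all(kept_classes %in% consequence_classes())) {
    stop("`kept_classes` contains unknown consequence classes", call. = FALSE)
  }
  if (is.null(frequency_catalog)) {
    frequency_catalog <- tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), af = double()
    )
  }
  if (is.null(mutation_catalog)) {
    mutation_catalog <- tibble::tibble(
      gene = character(), hgvs_c = character(), protein = character(),
      status = character(), reference = character()
    )
  }
  structure(
    list(
      af_threshold = af_threshold,
      kept_classes = kept_classes,
      panel = validate_panel(tibble::as_tibble(panel)),
      frequency_catalog = validate_frequency_catalog(tibble::as_tibble(frequency_catalog)),
      mutation_catalog = validate_mutation_catalog(tibble::as_tibble(mutation_catalog))
    ),
    class = "rd_cascade_config"
  )
}

#' Step 1: eliminate noncoding and silent variants
#'
#' Keeps exactly the variants whose consequence class is in
#' `config$kept_classes` (by default: missense, nonsense, frameshift and
#' in-frame indels, and splice-site substitutions); synonymous and noncoding
#' changes are eliminated.
#'
#' @param exome An [exome()].
#' @param config An [cascade_config()].
#' @return A filtered `rd_exome` (input unmodified).
#' @export
step1_coding_nonsilent <- function(exome, config) {
  stopifnot(inherits(exome, "rd_exome"))
  restore_exome(exome[exome$consequence %in% config$kept_classes, ], exome)
}

#' Step 2: restrict to the disease-gene panel
#'
#' Keeps exactly the variants whose gene symbol appears in `config$panel`.
#'
#' @inheritParams step1_coding_nonsilent
#' @return A filtered `rd_exome`.
#' @export
step2_panel <- function(exome, config) {
  stopifnot(inherits(exome, "rd_exome"))
  restore_exome(exome[exome$gene %in% config$panel$gene, ], exome)
}

#' Step 3: remove common catalogued variants
#'
#' Removes a variant if and only if the frequency catalog contains its exact
#' `(chrom, pos, ref, alt)` site, the catalog records a frequency there, and
#' that frequency is strictly greater than `config$af_threshold`. Rare
#' catalogued variants, catalogued sites without a recorded frequency, and
#' uncatalogued variants are all retained.
#'
#' @inheritParams step1_coding_nonsilent
#' @return A filtered `rd_exome`.
#' @export
step3_frequency <- function(exome, config) {
  stopifnot(inherits(exome, "rd_exome"))
  cat <- config$frequency_catalog
  common <- cat[!is.na(cat$af) & cat$af > config$af_threshold, ]
  common_key <- paste(common$chrom, common$pos, common$ref, common$alt, sep = ":")
  restore_exome(exome[!variant_key(exome) %in% common_key, ], exome)
}

#' Step 4: recessive / X-linked candidate-gene model
#'
#' Groups the surviving variants by gene and keeps the genes whose variant
#' load can explain recessive disease in the index patient:
#'
#' * `AR_homozygous` — at least one homozygous variant;
#' * `AR_compound_het` — at least two distinct heterozygous variants
#'   (assumed in trans; an index-only analysis cannot phase);
#' * `XL_hemizygous` — the patient is male, the gene lies on chrX, and at
#'   least one variant of any reported zygosity is present (male chrX calls
#'   are hemizygous regardless of the VCF genotype encoding).
#'
#' Several genes may qualify in one patient; all are returned, sorted by
#' gene symbol. A patient of unknown sex with chrX variants is an error,
#' since hemizygosity cannot be resolved.
#'
#' @inheritParams step1_coding_nonsilent
#' @param sex Patient sex; defaults to the exome's `sex` attribute.
#' @return A tibble of class `rd_candidates`: one row per supporting
#'   variant, with columns `gene`, `model`, `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`, `hgvs_c`.
#' @export
step4_recessive <- function(exome, config, sex = patient_sex(exome)) {
  stopifnot(inherits(exome, "rd_exome"))
  if (any(exome$chrom == "X") && (is.na(sex) || !sex %in% c("male", "female"))) {
    stop("patient sex is required to interpret chrX variants ",
         "(hemizygosity in males); set `sex`", call. = FALSE)
  }
  empty <- tibble::tibble(
    gene = character(), model = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    zygosity = character(), hgvs_c = character()
  )
  if (nrow(exome) == 0L) return(new_candidates(empty))

  per_gene <- exome |>
    tibble::as_tibble() |>
    dplyr::filter(nzchar(.data$gene)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_hom = sum(.data$zygosity == "homozygous_alt"),
      n_het_distinct = dplyr::n_distinct(
        paste(.data$chrom, .data$pos, .data$ref, .data$alt)[
          .data$zygosity == "heterozygous"]),
      on_x = any(.data$chrom == "X"),
      n_any = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(model = dplyr::case_when(
      .data$on_x & identical(sex, "male") & .data$n_any >= 1L ~ "XL_hemizygous",
      .data$n_hom >= 1L ~ "AR_homozygous",
      .data$n_het_distinct >= 2L ~ "AR_compound_het",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$model))

  out <- exome |>
    tibble::as_tibble() |>
    dplyr::inner_join(per_gene[, c("gene", "model")], by = "gene") |>
    dplyr::select("gene", "model", "chrom", "pos", "ref", "alt",
                  "zygosity", "hgvs_c") |>
    dplyr::arrange(.data$gene, .data$pos, .data$ref, .data$alt)
  new_candidates(out)
}

#' Step 5: annotate candidates as known or novel
#'
#' Flags each supporting variant as previously known if and only if its
#' `(gene, hgvs_c)` pair matches a mutation-catalog record with status
#' `"known"`; everything else — including variants lacking an HGVS coding
#' change, which are flagged with a warning — is novel. Candidates are
#' otherwise unchanged.
#'
#' @param candidates An `rd_candidates` tibble from [step4_recessive()].
#' @inheritParams step1_coding_nonsilent
#' @return The candidates tibble with an added logical `known` column.
#' @export
step5_annotate_known <- function(candidates, config) {
  stopifnot(inherits(candidates, "rd_candidates"))
  known_set <- config$mutation_catalog
  known_set <- known_set[known_set$status == "known", c("gene", "hgvs_c")]
  out <- tibble::as_tibble(candidates)
  if (nrow(out) == 0L) {
    out$known <- logical()
    return(new_candidates(out))
  }
  n_missing <- sum(is.na(out$hgvs_c))
  if (n_missing > 0L) {
    warning(n_missing, " candidate variant(s) lack an HGVS coding change; ",
            "flagged novel", call. = FALSE)
  }
  out$known <- !is.na(out$hgvs_c) &
    paste(out$gene, out$hgvs_c) %in% paste(known_set$gene, known_set$hgvs_c)
  new_candidates(out)
}

#' @noRd
new_candidates <- function(tbl) {
  structure(tbl, class = c("rd_candidates", class(tibble::tibble())))
}

#' Run the full five-step cascade on one index patient
#'
#' Applies, in order: the coding/non-silent consequence filter, the
#' disease-gene panel restriction, the allele-frequency filter, the
#' recessive/X-linked candidate-gene model, and known/novel annotation.
#' Returns both the per-step surviving-variant trace (the study's per-step
#' count table) and the annotated candidate genes.
#'
#' @inheritParams step4_recessive
#' @return A list of class `rd_cascade` with elements `patient_id`, `sex`,
#'   `trace` (tibble `step`, `count`, with steps `total`,
#'   `coding_nonsilent`, `in_panel`, `rare`, `candidate_variants`) and
#'   `candidates` (annotated `rd_candidates`). The trace counts are monotone
#'   non-increasing.
#' @export
#' @examples
#' cfg <- cascade_config(panel = default_panel())
#' ex <- exome(
#'   data.frame(
#'     chrom = "1", pos = c(100L, 200L), ref = "A", alt = "T", gene = "ABCA4",
#'     consequence = "missense", zygosity = "heterozygous"
#'   ),
#'   patient_id = "pt1", sex = "female"
#' )
#' res <- run_cascade(ex, cfg)
#' glance(res)
run_cascade <- function(exome, config, sex = patient_sex(exome)) {
  s1 <- step1_coding_nonsilent(exome, config)
  s2 <- step2_panel(s1, config)
  s3 <- step3_frequency(s2, config)
  s4 <- step4_recessive(s3, config, sex = sex)
  s5 <- step5_annotate_known(s4, config)
  trace <- tibble::tibble(
    step = c("total", "coding_nonsilent", "in_panel", "rare",
             "candidate_variants"),
    count = c(nrow(exome), nrow(s1), nrow(s2), nrow(s3), nrow(s5))
  )
  structure(
    list(patient_id = patient_id(exome), sex = sex, trace = trace,
         candidates = s5),
    class = "rd_cascade"
  )
}

#' @export
print.rd_cascade <- function(x, ...) {
  genes <- unique(x$candidates$gene)
  cat(sprintf("# rd_cascade: patient %s\n", x$patient_id))
  cat(paste0("  ", format(x$trace$step, width = 20), x$trace$count,
             collapse = "\n"), "\n")
  cat("  candidate genes: ",
      if (length(genes)) paste(genes, collapse = ", ") else "(none)", "\n",
      sep = "")
  invisible(x)
}

#' Tidy the candidates of a cascade result
#'
#' @param x An `rd_cascade` from [run_cascade()].
#' @param ... Unused.
#' @return A tibble of annotated supporting variants with a leading
#'   `patient_id` column (one row per supporting variant).
#' @method tidy rd_cascade
#' @export
tidy.rd_cascade <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(patient_id = rep(x$patient_id, nrow(x$candidates))),
    tibble::as_tibble(x$candidates)
  )
}

#' One-row summary of a cascade result
#'
#' @param x An `rd_cascade` from [run_cascade()].
#' @param ... Unused.
#' @return A one-row tibble: `patient_id`, the five per-step surviving
#'   counts, `n_candidate_genes`, and `solved` (at least one candidate
#'   gene).
#' @method glance rd_cascade
#' @export
glance.rd_cascade <- function(x, ...) {
  counts <- stats::setNames(as.list(x$trace$count), paste0("n_", x$trace$step))
  dplyr::bind_cols(
    tibble::tibble(patient_id = x$patient_id),
    tibble::as_tibble(counts),
    tibble::tibble(
      n_candidate_genes = dplyr::n_distinct(x$candidates$gene),
      solved = dplyr::n_distinct(x$candidates$gene) > 0L
    )
  )
}
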