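#' Parameters of the synthetic exome generator
#'
#' The defaults encode the count structure the cascade expects of a real
#' whole-exome experiment in this study design: about 67,000 called variants
#' per exome, of which about 12,000 are coding and non-silent, 108--143 fall
#' in the 160-gene disease panel, and 18--34 of those are rare (catalog
#' frequency at most `af_threshold`, or not catalogued at all).
#'
#' @param seed Master seed; per-patient substreams are derived from it and
#'   the patient identifier, so cohort composition is order-independent.
#' @param mean_total_variants Poisson mean of the total variant count
#'   (default 67000).
#' @param mean_coding_nonsilent Poisson mean of the coding non-silent
#'   subset (default 12000).
#' @param panel_count_range Integer range (inclusive) for the uniform draw
#'   of coding non-silent panel-gene variants (default `c(108, 143)`).
#' @param rare_count_range Integer range for the uniform draw of rare
#'   panel variants (default `c(18, 34)`).
#' @param af_threshold Allele-frequency threshold separating rare from
#'   common (default 0.02).
#' @param n_spurious_panel_variants Extra spurious heterozygous panel-gene
#'   variants planted per patient on top of the scenario's own variants
#'   (default 0; the compound-heterozygote false-call scenario uses 2 via
#'   its scenario specification instead).
#' @return A list of class `rd_generator_params`.
#' @export
generator_params <- function(seed = 1L,
                             mean_total_variants = 67000,
                             mean_coding_nonsilent = 12000,
                             panel_count_range = c(108L, 143L),
                             rare_count_range = c(18L, 34L),
                             af_threshold = 0.02,
                             n_spurious_panel_variants = 0L) {
  if (mean_coding_nonsilent > mean_total_variants) {
    stop("mean_coding_nonsilent must not exceed mean_total_variants",
         call. = FALSE)
  }
  ok_range <- function(r) length(r) == 2L && !any(is.na(r)) &&
    r[1] >= 0 && r[1] <= r[2]
  if (!ok_range(panel_count_range) || !ok_range(rare_count_range)) {
    stop("count ranges must be non-empty with non-negative bounds",
         call. = FALSE)
  }
  if (rare_count_range[2] > panel_count_range[1]) {
    stop("rare_count_range upper bound must not exceed panel_count_range ",
         "lower bound", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed),
         mean_total_variants = mean_total_variants,
         mean_coding_nonsilent = mean_coding_nonsilent,
         panel_count_range = as.integer(panel_count_range),
         rare_count_range = as.integer(rare_count_range),
         af_threshold = af_threshold,
         n_spurious_panel_variants = as.integer(n_spurious_panel_variants)),
    class = "rd_generator_params"
  )
}

#' The default 160-gene retinal dystrophy panel
#'
#' Six real RD genes (ABCA4, USH2A and NMNAT1 on chr1, RP1 and CNGB3 on
#' chr8, CHM on chrX) plus 154 synthetic placeholder genes spread over the
#' autosomes and chrX, standing in for the remainder of a curated RD panel
#' whose full membership is not public. Placeholder symbols are prefixed
#' `RDGP`.
#'
#' @return A 160-row tibble with columns `gene`, `chrom`.
#' @export
default_panel <- function() {
  real <- tibble::tibble(
    gene = c("ABCA4", "USH2A", "NMNAT1", "RP1", "CNGB3", "CHM"),
    chrom = c("1", "1", "1", "8", "8", "X")
  )
  n <- 154L
  chroms <- c(rep(as.character(1:22), length.out = n - 4L), rep("X", 4L))
  placeholders <- tibble::tibble(
    gene = sprintf("RDGP%03d", seq_len(n)),
    chrom = chroms
  )
  dplyr::bind_rows(real, placeholders)
}

#' @noRd
background_gene_pool <- function(n = 800L) {
  tibble::tibble(
    gene = sprintf("BGRD%04d", seq_len(n)),
    chrom = rep(chrom_labels()[1:23], length.out = n)
  )
}

#' Synthetic locus starts: genes are laid out along each chromosome in
#' panel order; planted variants sit within the first 20 kb of a locus and
#' background variants in [start + 20kb, start + 220kb], so background draws
#' can never collide with a planted site.
#' @noRd
gene_loci <- function(gene_map, base = 1e6) {
  gene_map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(start = as.integer(base + (dplyr::row_number() - 1L) * 5e5)) |>
    dplyr::ungroup()
}

#' The catalogued mutations of the emulated study
#'
#' A transcription of the study's mutation table: 15 distinct mutations in
#' six RD genes, 8 of them novel at publication (the duplicated CNGB3
#' frameshift, observed in two families, appears once). Used both as the
#' step-5 annotation catalog and to define the planted causal variants.
#'
#' @return A 15-row mutation-catalog tibble (`gene`, `hgvs_c`, `protein`,
#'   `status`, `reference`).
#' @export
default_mutation_catalog <- function() {
  tibble::tribble(
    ~gene, ~hgvs_c, ~protein, ~status, ~reference,
    "ABCA4", "c.287delA", "p.N96Tfs*19", "novel", NA,
    "ABCA4", "c.6148G>C", "p.V2050L", "known", "Allikmets et al.",
    "ABCA4", "c.4720G>T", "p.E1574*", "known", "Maia-Lopes et al.",
    "ABCA4", "c.950delG", "p.G317Afs*57", "novel", NA,
    "ABCA4", "c.2285C>A", "p.A762E", "known", "Aguirre-Lamban et al.",
    "CHM", "c.863dupA", "p.M289Y*18", "novel", NA,
    "USH2A", "c.920_923dupGCCA", "p.H308Qfs*16", "known", "Weston et al.",
    "USH2A", "c.12574C>T", "p.R4192C", "novel", NA,
    "CNGB3", "c.1148delC", "p.T383Ifs*13", "known", "Sundin et al.",
    "CNGB3", "c.1666G>T", "p.E556*", "novel", NA,
    "RP1", "c.1625C>G", "p.S542*", "novel", NA,
    "RP1", "c.4804C>T", "p.Q1602*", "novel", NA,
    "RP1", "c.5173C>T", "p.Q1725*", "novel", NA,
    "NMNAT1", "c.507G>A", "p.W169*", "known", "Chiang et al.",
    "NMNAT1", "c.769G>A", "p.E257K", "known", "Chiang et al."
  )
}

#' Write the bundled mutation-table fixture
#'
#' Emits [default_mutation_catalog()] as a mutation-catalog TSV readable by
#' [read_mutation_catalog()].
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_table1 <- function(path) {
  write_mutation_catalog(default_mutation_catalog(), path)
}

#' The default 12-family study scenarios
#'
#' One row per family: identifier, index patient, index sex, causal gene
#' and genotype configuration, and the list of variants planted in the
#' index exome. Ten families carry causal genotypes (three ABCA4, two RP1,
#' two CNGB3, one X-linked CHM, one USH2A, one NMNAT1); two carry none and
#' remain molecularly unsolved. The CNGB3-homozygous family additionally
#' carries two spurious heterozygous USH2A calls, emulating a false-positive
#' compound heterozygote that sequencing validation would later reject.
#'
#' @return A 12-row tibble with a `variants` list-column.
#' @export
family_scenarios <- function() {
  cat <- default_mutation_catalog()
  pick <- function(gene, hgvs, zygosity) {
    rec <- cat[cat$gene == gene & cat$hgvs_c == hgvs, ]
    stopifnot(nrow(rec) == 1L)
    tibble::tibble(
      gene = rec$gene, hgvs_c = rec$hgvs_c, protein = rec$protein,
      consequence = classify_hgvs(rec$hgvs_c, rec$protein),
      zygosity = zygosity, status = rec$status, spurious = FALSE
    )
  }
  spurious <- function(gene, hgvs, protein) {
    tibble::tibble(
      gene = gene, hgvs_c = hgvs, protein = protein,
      consequence = "missense", zygosity = "heterozygous",
      status = "novel", spurious = TRUE
    )
  }
  het <- "heterozygous"; hom <- "homozygous_alt"
  tibble::tibble(
    family_id = c("RP-0674", "RP-0298", "RP-1102", "RP-1164", "RP-1263",
                  "RP-1659", "RP-1174", "RP-0137", "RP-0235", "RP-1116",
                  "RP-0886", "RP-0461"),
    patient_id = c("01-0570", "95-0103", "07-0366", "07-0360", "08-0177",
                   "10-1367", "04-0834", "1601", "2343", "06-1075",
                   "09-0001", "09-0002"),
    sex = c("female", "female", "male", "male", "female", "female",
            "female", "male", "female", "female", "female", "female"),
    causal_gene = c("ABCA4", "ABCA4", "ABCA4", "CHM", "USH2A", "CNGB3",
                    "CNGB3", "RP1", "RP1", "NMNAT1", NA, NA),
    config = c("AR_compound_het", "AR_compound_het", "AR_homozygous",
               "XL_hemizygous", "AR_compound_het", "AR_compound_het",
               "AR_homozygous", "AR_compound_het", "AR_homozygous",
               "AR_compound_het", "none", "none"),
    variants = list(
      dplyr::bind_rows(pick("ABCA4", "c.287delA", het),
                       pick("ABCA4", "c.6148G>C", het)),
      dplyr::bind_rows(pick("ABCA4", "c.4720G>T", het),
                       pick("ABCA4", "c.950delG", het)),
      pick("ABCA4", "c.2285C>A", hom),
      pick("CHM", "c.863dupA", hom), # male chrX: called hom, hemizygous
      dplyr::bind_rows(pick("USH2A", "c.920_923dupGCCA", het),
                       pick("USH2A", "c.12574C>T", het)),
      dplyr::bind_rows(pick("CNGB3", "c.1148delC", het),
                       pick("CNGB3", "c.1666G>T", het)),
      dplyr::bind_rows(pick("CNGB3", "c.1148delC", hom),
                       spurious("USH2A", "c.1003C>G", "p.P335A"),
                       spurious("USH2A", "c.9106A>G", "p.T3036A")),
      dplyr::bind_rows(pick("RP1", "c.1625C>G", het),
                       pick("RP1", "c.4804C>T", het)),
      pick("RP1", "c.5173C>T", hom),
      dplyr::bind_rows(pick("NMNAT1", "c.507G>A", het),
                       pick("NMNAT1", "c.769G>A", het)),
      empty_plant_tbl(),
      empty_plant_tbl()
    )
  )
}

#' @noRd
empty_plant_tbl <- function() {
  tibble::tibble(
    gene = character(), hgvs_c = character(), protein = character(),
    consequence = character(), zygosity = character(), status = character(),
    spurious = logical()
  )
}

#' Infer a consequence class from HGVS coding/protein notation
#' @noRd
classify_hgvs <- function(hgvs_c, protein) {
  if (grepl("del|dup", hgvs_c)) return("frameshift_indel")
  if (grepl("\\*$", protein) && !grepl("fs", protein)) return("nonsense")
  "missense"
}

#' Turn an HGVS c. description into synthetic VCF-style alleles
#'
#' Supports simple substitutions (`c.123A>G`), deletions (`c.123delA`) and
#' duplications (`c.123dupA`, `c.120_123dupGCCA`). Indels are left-anchored
#' on a synthetic `A` reference base, as in VCF. The genomic position is the
#' gene's synthetic locus start plus the coding offset; coordinates are
#' synthetic throughout.
#' @noRd
hgvs_to_alleles <- function(hgvs_c) {
  if (grepl("^c\\.\\d+[ACGT]>[ACGT]$", hgvs_c)) {
    m <- regmatches(hgvs_c, regexec("^c\\.(\\d+)([ACGT])>([ACGT])$", hgvs_c))[[1]]
    return(list(offset = as.integer(m[2]), ref = m[3], alt = m[4]))
  }
  if (grepl("^c\\.\\d+del[ACGT]+$", hgvs_c)) {
    m <- regmatches(hgvs_c, regexec("^c\\.(\\d+)del([ACGT]+)$", hgvs_c))[[1]]
    return(list(offset = as.integer(m[2]) - 1L, ref = paste0("A", m[3]),
                alt = "A"))
  }
  if (grepl("^c\\.\\d+(_\\d+)?dup[ACGT]+$", hgvs_c)) {
    m <- regmatches(hgvs_c,
                    regexec("^c\\.(\\d+)(_\\d+)?dup([ACGT]+)$", hgvs_c))[[1]]
    return(list(offset = as.integer(m[2]), ref = "A", alt = paste0("A", m[4])))
  }
  stop("unsupported HGVS description: ", hgvs_c, call. = FALSE)
}

#' Deterministic per-patient substream seed
#' @noRd
patient_seed <- function(master_seed, patient_id) {
  h <- 0
  for (k in utf8ToInt(patient_id)) h <- (h * 31 + k) %% 2147483647
  as.integer((h + (as.double(master_seed) %% 2147483647) * 7919) %% 2147483647)
}

#' Generate one synthetic index-patient exome
#'
#' Draws the four count strata (total ~ Poisson, coding non-silent ~
#' Poisson, panel count and rare count ~ uniform integer on their ranges),
#' fills them with background variants over a synthetic gene map, and
#' plants the scenario's causal (and spurious) variants with rare,
#' non-silent, panel-consistent attributes and the configured zygosity.
#' Background rare panel variants are heterozygous, at most one per gene,
#' never in the scenario's own genes, and never on chrX for a male index,
#' so the recessive-model step recovers exactly the planted configuration.
#' Every planted variant is asserted at generation time to survive the
#' class, panel and frequency filters. Fully reproducible from
#' `params$seed` and the patient identifier.
#'
#' @param params A [generator_params()].
#' @param scenario One row of [family_scenarios()] (or `NULL` for a pure
#'   background exome).
#' @param patient_id Patient identifier; defaults to the scenario's.
#' @param sex Patient sex; defaults to the scenario's, else `"female"`.
#' @return An [exome()]. Rows with a non-`NA` `rs_id` are the variants
#'   catalogued in the cohort frequency catalog (their `cat_af` is the
#'   catalogued frequency, `NA` for known-site-no-frequency entries).
#' @export
generate_exome <- function(params, scenario = NULL, patient_id = NULL,
                           sex = NULL) {
  stopifnot(inherits(params, "rd_generator_params"))
  if (!is.null(scenario)) {
    scenario <- tibble::as_tibble(scenario)
    stopifnot(nrow(scenario) == 1L)
    patient_id <- patient_id %||% scenario$patient_id
    sex <- sex %||% scenario$sex
    plants_spec <- scenario$variants[[1L]]
  } else {
    plants_spec <- empty_plant_tbl()
  }
  patient_id <- patient_id %||% "synthetic"
  sex <- sex %||% "female"

  panel <- default_panel()
  loci <- gene_loci(panel)
  bg_loci <- gene_loci(background_gene_pool(), base = 1.3e8)

  if (nrow(plants_spec) > 0L && !all(plants_spec$gene %in% panel$gene)) {
    stop("scenario gene(s) absent from the panel: ",
         paste(setdiff(plants_spec$gene, panel$gene), collapse = ", "),
         call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(patient_seed(params$seed, patient_id))

  # planted variants -------------------------------------------------------
  plants <- purrr::pmap(plants_spec, function(gene, hgvs_c, protein,
                                              consequence, zygosity, status,
                                              spurious) {
    al <- hgvs_to_alleles(hgvs_c)
    locus <- loci[loci$gene == gene, ]
    tibble::tibble(
      chrom = locus$chrom, pos = locus$start + al$offset,
      ref = al$ref, alt = al$alt, gene = gene, consequence = consequence,
      zygosity = zygosity, rs_id = NA_character_, cat_af = NA_real_,
      hgvs_c = hgvs_c
    )
  }) |> dplyr::bind_rows()
  if (nrow(plants) == 0L) plants <- empty_variant_tbl()

  n_extra_spurious <- params$n_spurious_panel_variants
  if (n_extra_spurious > 0L) {
    host <- setdiff(panel$gene, c(plants_spec$gene,
                                  if (identical(sex, "male"))
                                    panel$gene[panel$chrom == "X"]))[1L]
    locus <- loci[loci$gene == host, ]
    plants <- dplyr::bind_rows(plants, tibble::tibble(
      chrom = locus$chrom,
      pos = locus$start + 100L * seq_len(n_extra_spurious),
      ref = "C", alt = "T", gene = host, consequence = "missense",
      zygosity = "heterozygous", rs_id = NA_character_, cat_af = NA_real_,
      hgvs_c = sprintf("c.%dC>T", 100L * seq_len(n_extra_spurious))
    ))
  }

  # stratum sizes -----------------------------------------------------------
  n_total <- stats::rpois(1L, params$mean_total_variants)
  n_cns <- min(stats::rpois(1L, params$mean_coding_nonsilent), n_total)
  n_panel <- min(sample_range(params$panel_count_range), n_cns)
  n_rare <- min(sample_range(params$rare_count_range), n_panel)
  k <- nrow(plants)
  if (k > n_rare && n_rare > 0L) {
    stop("scenario plants more variants than the rare stratum holds",
         call. = FALSE)
  }
  n_rare_bg <- max(n_rare - k, 0L)
  n_common <- n_panel - n_rare
  n_cns_nonpanel <- n_cns - n_panel
  n_noncns <- n_total - n_cns

  # background rare panel variants: het, one per gene, panel genes only,
  # excluding the scenario's genes and (for males) chrX genes
  eligible <- loci[!loci$gene %in% plants$gene, ]
  if (identical(sex, "male")) eligible <- eligible[eligible$chrom != "X", ]
  if (n_rare_bg > nrow(eligible)) {
    stop("rare stratum larger than the eligible panel", call. = FALSE)
  }
  rare_loci <- eligible[sample.int(nrow(eligible), n_rare_bg), ]
  rare_bg <- draw_background(rare_loci$gene, rare_loci$chrom, rare_loci$start,
                             classes = c("missense", "nonsense",
                                         "frameshift_indel", "inframe_indel",
                                         "splice_site"),
                             class_w = c(.70, .08, .08, .06, .08),
                             zygosity = "heterozygous", parity = 1L)
  if (n_rare_bg > 0L) {
    in_cat <- stats::runif(n_rare_bg)
    rare_bg$rs_id <- ifelse(in_cat < 0.5, sprintf("rs9%07d", sample.int(9e6, n_rare_bg)),
                            NA_character_)
    rare_bg$cat_af <- ifelse(in_cat < 0.35,
                             stats::runif(n_rare_bg, 1e-4, params$af_threshold),
                             NA_real_)
    rare_bg$cat_af[is.na(rare_bg$rs_id)] <- NA_real_
  }

  # common catalogued panel variants (removed by the frequency filter)
  common_idx <- sample.int(nrow(loci), n_common, replace = TRUE)
  common <- draw_background(loci$gene[common_idx], loci$chrom[common_idx],
                            loci$start[common_idx],
                            classes = nonsilent_classes(),
                            class_w = c(.78, .04, .04, .06, .08),
                            zygosity = NULL, parity = 0L)
  if (n_common > 0L) {
    common$rs_id <- sprintf("rs1%07d", sample.int(9e6, n_common))
    common$cat_af <- stats::runif(n_common, params$af_threshold + 1e-4, 0.5)
  }

  # coding non-silent variants outside the panel
  bg_idx <- sample.int(nrow(bg_loci), n_cns_nonpanel, replace = TRUE)
  cns_bg <- draw_background(bg_loci$gene[bg_idx], bg_loci$chrom[bg_idx],
                            bg_loci$start[bg_idx],
                            classes = nonsilent_classes(),
                            class_w = c(.72, .06, .07, .06, .09),
                            zygosity = NULL, parity = 0L)
  if (n_cns_nonpanel > 0L) {
    has_rs <- stats::runif(n_cns_nonpanel) < 0.6
    cns_bg$rs_id[has_rs] <- sprintf("rs2%07d", sample.int(9e6, sum(has_rs)))
    cns_bg$cat_af[has_rs] <- stats::runif(sum(has_rs), 1e-4, 0.5)
  }

  # noncoding and synonymous remainder
  n_syn <- round(0.15 * n_noncns)
  syn_idx <- sample.int(nrow(bg_loci), n_syn, replace = TRUE)
  syn <- draw_background(bg_loci$gene[syn_idx], bg_loci$chrom[syn_idx],
                         bg_loci$start[syn_idx],
                         classes = "synonymous", class_w = 1,
                         zygosity = NULL, parity = 0L)
  n_nc <- n_noncns - n_syn
  nc <- tibble::tibble(
    chrom = sample(chrom_labels()[1:23], n_nc, replace = TRUE,
                   prob = c(rep(1, 22), 0.5)),
    pos = sample.int(2.4e8, n_nc, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n_nc, replace = TRUE),
    alt = NA_character_, gene = "", consequence = "noncoding",
    zygosity = sample(c("heterozygous", "homozygous_alt"), n_nc,
                      replace = TRUE, prob = c(.8, .2)),
    rs_id = NA_character_, cat_af = NA_real_, hgvs_c = NA_character_
  )
  nc$alt <- flip_base(nc$ref)

  variants <- dplyr::bind_rows(plants, rare_bg, common, cns_bg, syn, nc)

  # enforce unique sites (background only; plants are unique by design)
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    variants$pos[dup] <- variants$pos[dup] + 2L * sample.int(50L, sum(dup), replace = TRUE)
    key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  }

  out <- exome(dplyr::arrange(variants, match(.data$chrom, chrom_labels()),
                              .data$pos),
               patient_id = patient_id, sex = sex)
  assert_plants_survive(out, plants, params)
  out
}

#' @noRd
sample_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq.int(r[1], r[2]), 1L)
}

#' @noRd
draw_background <- function(gene, chrom, start, classes, class_w,
                            zygosity = NULL, parity = 0L) {
  n <- length(gene)
  if (n == 0L) {
    return(empty_variant_tbl())
  }
  # positions within [start+20kb, start+220kb]; parity separates rare (odd)
  # from common (even) sites so independent draws can never share a site
  pos <- start + 20000L + 2L * sample.int(100000L, n, replace = TRUE) + parity
  csq <- sample(classes, n, replace = TRUE, prob = class_w)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- flip_base(ref)
  is_indel <- csq %in% c("frameshift_indel", "inframe_indel")
  ref[is_indel] <- paste0(ref[is_indel], "CT")
  alt[is_indel] <- substr(ref[is_indel], 1L, 1L)
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    consequence = csq,
    zygosity = zygosity %||% sample(c("heterozygous", "homozygous_alt"), n,
                                    replace = TRUE, prob = c(.8, .2)),
    rs_id = NA_character_, cat_af = NA_real_, hgvs_c = NA_character_
  )
}

#' @noRd
flip_base <- function(ref) {
  c(A = "G", C = "T", G = "A", T = "C")[ref]
}

#' Planted variants must survive the class, panel and frequency filters
#' @noRd
assert_plants_survive <- function(ex, plants, params) {
  if (nrow(plants) == 0L) return(invisible(TRUE))
  panel <- default_panel()
  stopifnot(
    all(plants$consequence %in% nonsilent_classes()),
    all(plants$gene %in% panel$gene),
    all(is.na(plants$cat_af) | plants$cat_af <= params$af_threshold),
    all(paste(plants$chrom, plants$pos, plants$ref, plants$alt) %in%
          paste(ex$chrom, ex$pos, ex$ref, ex$alt))
  )
  invisible(TRUE)
}

#' Generate the full synthetic cohort
#'
#' Generates one index exome per family scenario, the shared panel, the
#' cohort frequency catalog (assembled from the catalogued background
#' variants of all exomes), the known-mutation catalog, and one pedigree per
#' family.
#'
#' @param params A [generator_params()].
#' @param scenarios A scenario tibble; defaults to the 12 families of
#'   [family_scenarios()].
#' @return A list of class `rd_cohort`: `exomes` (named list of
#'   [exome()]s), `panel`, `frequency_catalog`, `mutation_catalog`,
#'   `pedigrees` (named list of [pedigree()]s), `manifest` (one row per
#'   family).
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(generator_params(seed = 1))
#' coh$manifest
#' }
generate_cohort <- function(params = generator_params(),
                            scenarios = family_scenarios()) {
  stopifnot(inherits(params, "rd_generator_params"))
  if (anyDuplicated(scenarios$family_id)) {
    stop("duplicated family id: ",
         scenarios$family_id[duplicated(scenarios$family_id)][1L],
         call. = FALSE)
  }
  exomes <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    generate_exome(params, scenarios[i, ])
  })
  names(exomes) <- scenarios$patient_id
  catalog <- catalog_from_exomes(exomes)
  structure(
    list(
      exomes = exomes,
      panel = default_panel(),
      frequency_catalog = catalog,
      mutation_catalog = default_mutation_catalog(),
      pedigrees = default_pedigrees(scenarios),
      manifest = scenarios[, c("family_id", "patient_id", "sex",
                               "causal_gene", "config")]
    ),
    class = "rd_cohort"
  )
}

#' Assemble a frequency catalog from generated exomes
#'
#' Collects every catalogued variant (non-`NA` `rs_id`) across the given
#' exomes into a site-frequency catalog, one entry per distinct site.
#'
#' @param exomes A list of [exome()]s (or a single exome).
#' @return A frequency-catalog tibble.
#' @export
catalog_from_exomes <- function(exomes) {
  if (inherits(exomes, "rd_exome")) exomes <- list(exomes)
  purrr::map(exomes, function(ex) {
    tibble::as_tibble(ex)[!is.na(ex$rs_id),
                          c("chrom", "pos", "ref", "alt", "cat_af")]
  }) |>
    dplyr::bind_rows() |>
    dplyr::rename(af = "cat_af") |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .keep_all = TRUE)
}

#' Cascade configuration matching a generated cohort
#'
#' @param cohort An `rd_cohort` from [generate_cohort()].
#' @param af_threshold Allele-frequency threshold (default 0.02).
#' @return An [cascade_config()] using the cohort's panel and catalogs.
#' @export
cohort_config <- function(cohort, af_threshold = 0.02) {
  cascade_config(
    panel = cohort$panel,
    frequency_catalog = cohort$frequency_catalog,
    mutation_catalog = cohort$mutation_catalog,
    af_threshold = af_threshold
  )
}

#' Default pedigree templates per scenario
#'
#' The USH2A-family analog gets the study's informative sibship (parents
#' plus six siblings: three affected compound heterozygotes including the
#' index, three unaffected of unknown genotype); the X-linked family gets a
#' carrier mother and two affected sons; every other family gets a parents +
#' index + unaffected-sibling quartet.
#'
#' @param scenarios A scenario tibble; defaults to [family_scenarios()].
#' @return A named list of [pedigree()]s.
#' @export
default_pedigrees <- function(scenarios = family_scenarios()) {
  make_member <- function(family_id, member_id, father_id, mother_id, sex,
                          affected, a, b, proband = FALSE) {
    tibble::tibble(family_id = family_id, member_id = member_id,
                   father_id = father_id, mother_id = mother_id, sex = sex,
                   affected = affected, carries_allele_a = a,
                   carries_allele_b = b, proband = proband)
  }
  peds <- purrr::pmap(
    scenarios[, c("family_id", "patient_id", "sex", "config")],
    function(family_id, patient_id, sex, config) {
      fa <- make_member(family_id, "father", NA, NA, "male", FALSE, "yes", "no")
      mo <- make_member(family_id, "mother", NA, NA, "female", FALSE, "no", "yes")
      if (family_id == "RP-1263") {
        sibs <- dplyr::bind_rows(
          make_member(family_id, patient_id, "father", "mother", sex, TRUE,
                      "yes", "yes", proband = TRUE),
          make_member(family_id, "sib-a1", "father", "mother", "male", TRUE,
                      "yes", "yes"),
          make_member(family_id, "sib-a2", "father", "mother", "female", TRUE,
                      "yes", "yes"),
          make_member(family_id, "sib-u1", "father", "mother", "male", FALSE,
                      "unknown", "unknown"),
          make_member(family_id, "sib-u2", "father", "mother", "female", FALSE,
                      "unknown", "unknown"),
          make_member(family_id, "sib-u3", "father", "mother", "female", FALSE,
                      "unknown", "unknown")
        )
        return(pedigree(dplyr::bind_rows(fa, mo, sibs)))
      }
      if (config == "XL_hemizygous") {
        fa <- make_member(family_id, "father", NA, NA, "male", FALSE, "no", "no")
        mo <- make_member(family_id, "mother", NA, NA, "female", FALSE, "yes", "no")
        kids <- dplyr::bind_rows(
          make_member(family_id, patient_id, "father", "mother", "male", TRUE,
                      "yes", "no", proband = TRUE),
          make_member(family_id, "brother", "father", "mother", "male", TRUE,
                      "yes", "no")
        )
        return(pedigree(dplyr::bind_rows(fa, mo, kids)))
      }
      geno <- if (config == "none") "unknown" else "yes"
      kids <- dplyr::bind_rows(
        make_member(family_id, patient_id, "father", "mother", sex, TRUE,
                    geno, geno, proband = TRUE),
        make_member(family_id, "sib-u1", "father", "mother",
                    if (sex == "male") "female" else "male", FALSE,
                    "unknown", "unknown")
      )
      pedigree(dplyr::bind_rows(fa, mo, kids))
    }
  )
  stats::setNames(peds, scenarios$family_id)
}

#' Write a generated cohort to disk
#'
#' Emits, under `dir`: one annotated VCF per index patient
#' (`<patient>.vcf`), `panel.tsv`, `frequency_catalog.tsv`,
#' `mutation_catalog.tsv`, one `<family>.ped` plus
#' `<family>_genotypes.tsv` per family, and `manifest.tsv`.
#'
#' @param cohort An `rd_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ex in cohort$exomes) {
    write_vcf(ex, file.path(dir, paste0(patient_id(ex), ".vcf")))
  }
  write_panel(cohort$panel, file.path(dir, "panel.tsv"))
  write_frequency_catalog(cohort$frequency_catalog,
                          file.path(dir, "frequency_catalog.tsv"))
  write_mutation_catalog(cohort$mutation_catalog,
                         file.path(dir, "mutation_catalog.tsv"))
  for (fam in names(cohort$pedigrees)) {
    write_pedigree(cohort$pedigrees[[fam]],
                   file.path(dir, paste0(fam, ".ped")),
                   file.path(dir, paste0(fam, "_genotypes.tsv")))
  }
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"), na = "")
  invisible(dir)
}

#' Gene-dropping simulation through a pedigree
#'
#' Simulates Mendelian transmission of the two candidate alleles from the
#' founders down the pedigree: each child independently receives each
#' parental mutant allele with probability 1/2. Founders keep their observed
#' carrier states, which must not be `"unknown"`. Used as a Monte-Carlo
#' cross-check of the exact enumeration in [segregation_probability()].
#'
#' @param ped An [pedigree()].
#' @param n_replicates Number of independent transmission replicates.
#' @param seed RNG seed.
#' @return A tibble with columns `replicate`, `member_id`,
#'   `carries_allele_a`, `carries_allele_b` (`"yes"`/`"no"`).
#' @export
drop_alleles <- function(ped, n_replicates, seed = 1L) {
  stopifnot(inherits(ped, "rd_pedigree"))
  founders <- ped[is.na(ped$father_id), ]
  if (any(founders$carries_allele_a == "unknown" |
          founders$carries_allele_b == "unknown")) {
    bad <- founders$member_id[founders$carries_allele_a == "unknown" |
                                founders$carries_allele_b == "unknown"][1L]
    stop("founder ", bad, " has an unknown carrier genotype", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  # per member x replicate carrier matrices, resolved in generation order
  has_a <- has_b <- matrix(NA, nrow = nrow(ped), ncol = n_replicates,
                           dimnames = list(ped$member_id, NULL))
  is_founder <- is.na(ped$father_id)
  has_a[is_founder, ] <- ped$carries_allele_a[is_founder] == "yes"
  has_b[is_founder, ] <- ped$carries_allele_b[is_founder] == "yes"
  unresolved <- !is_founder
  while (any(unresolved)) {
    idx <- which(unresolved)
    ready <- idx[!is.na(has_a[ped$father_id[idx], 1L]) &
                   !is.na(has_a[ped$mother_id[idx], 1L])]
    if (!length(ready)) stop("unresolvable pedigree order", call. = FALSE)
    for (i in ready) {
      fa <- ped$father_id[i]; mo <- ped$mother_id[i]
      coin_fa <- stats::runif(n_replicates) < 0.5
      coin_mo <- stats::runif(n_replicates) < 0.5
      # a carrier parent transmits its single mutant allele with prob 1/2
      has_a[i, ] <- (has_a[fa, ] & coin_fa) | (has_a[mo, ] & coin_mo)
      coin_fa2 <- stats::runif(n_replicates) < 0.5
      coin_mo2 <- stats::runif(n_replicates) < 0.5
      has_b[i, ] <- (has_b[fa, ] & coin_fa2) | (has_b[mo, ] & coin_mo2)
      unresolved[i] <- FALSE
    }
  }
  tibble::tibble(
    replicate = rep(seq_len(n_replicates), each = nrow(ped)),
    member_id = rep(ped$member_id, times = n_replicates),
    carries_allele_a = ifelse(as.vector(has_a), "yes", "no"),
    carries_allele_b = ifelse(as.vector(has_b), "yes", "no")
  )
}

#' Monte-Carlo cosegregation probability by gene dropping
#'
#' Estimates the probability computed exactly by
#' [segregation_probability()] as the fraction of [drop_alleles()]
#' replicates in which every pedigree member's simulated carrier state is
#' compatible with the observed genotypes and every member's affected
#' status matches the model.
#'
#' @inheritParams segregation_probability
#' @param n_replicates Number of gene-dropping replicates.
#' @param seed RNG seed.
#' @return The estimated probability (a single number).
#' @export
cosegregation_mc <- function(ped, model = c("AR", "XL"), n_replicates = 10000L,
                             seed = 1L, include_index = TRUE) {
  model <- match.arg(model)
  sim_ped <- ped
  if (!include_index) sim_ped <- pedigree(ped[!ped$proband, ])
  drops <- drop_alleles(sim_ped, n_replicates, seed = seed)
  kids <- ped_children(sim_ped)
  if (nrow(kids) == 0L) return(1)
  drops <- drops[drops$member_id %in% kids$member_id, ]
  obs <- kids[match(drops$member_id, kids$member_id), ]
  got_a <- drops$carries_allele_a == "yes"
  got_b <- drops$carries_allele_b == "yes"
  ok <- (obs$carries_allele_a == "unknown" |
           (obs$carries_allele_a == "yes") == got_a) &
    (obs$carries_allele_b == "unknown" |
       (obs$carries_allele_b == "yes") == got_b)
  if (model == "AR") {
    ok <- ok & ((got_a & got_b) == obs$affected)
  } else {
    ok <- ok & ifelse(obs$sex == "male", got_a == obs$affected, !obs$affected)
  }
  consistent <- tapply(ok, drops$replicate, all)
  mean(consistent)
}
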