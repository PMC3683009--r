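# Shared fixture builders. Everything is generated in code; the full-scale
# default cohort is built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

default_cohort_cached <- function(seed = 42L) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_cache[[key]])) {
    coh <- generate_cohort(generator_params(seed = seed))
    .fixture_cache[[key]] <- coh
    .fixture_cache[[paste0("results_", seed)]] <- run_cohort(coh)
  }
  .fixture_cache[[key]]
}

default_results_cached <- function(seed = 42L) {
  default_cohort_cached(seed)
  .fixture_cache[[paste0("results_", seed)]]
}

# reduced-scale generator parameters for fast property tests
small_params <- function(seed = 1L) {
  generator_params(
    seed = seed,
    mean_total_variants = 2000,
    mean_coding_nonsilent = 400,
    panel_count_range = c(30L, 40L),
    rare_count_range = c(8L, 15L)
  )
}

# a hand-sized exome with one variant per consequence class
seven_class_exome <- function() {
  exome(
    tibble::tibble(
      chrom = c("1", "1", "1", "8", "8", "1", "2"),
      pos = 101:107,
      ref = "A", alt = "T",
      gene = c("ABCA4", "ABCA4", "USH2A", "RP1", "CNGB3", "NMNAT1", ""),
      consequence = c("missense", "nonsense", "frameshift_indel",
                      "inframe_indel", "splice_site", "synonymous",
                      "noncoding"),
      zygosity = "heterozygous"
    ),
    patient_id = "seven", sex = "female"
  )
}

# minimal config: default panel, tiny catalogs
tiny_config <- function(...) {
  cascade_config(panel = default_panel(), ...)
}

# sibship pedigree: n_aff affected compound-het children (first one the
# proband), n_unaff unaffected children of unknown genotype
ar_sibship <- function(n_aff, n_unaff, family_id = "FAM") {
  n <- n_aff + n_unaff
  kid_ids <- if (n > 0L) paste0("c", seq_len(n)) else character()
  pedigree(tibble::tibble(
    family_id = family_id,
    member_id = c("fa", "mo", kid_ids),
    father_id = c(NA, NA, rep("fa", n)),
    mother_id = c(NA, NA, rep("mo", n)),
    sex = c("male", "female", rep(c("male", "female"), length.out = n)),
    affected = c(FALSE, FALSE, rep(c(TRUE, FALSE), c(n_aff, n_unaff))),
    carries_allele_a = c("yes", "no", rep(c("yes", "unknown"), c(n_aff, n_unaff))),
    carries_allele_b = c("no", "yes", rep(c("yes", "unknown"), c(n_aff, n_unaff))),
    proband = c(FALSE, FALSE, n_aff > 0 & seq_len(n) == 1L)
  ))
}

# brute-force oracle for the recessive-model step: per gene, loop over all
# variants and test the three qualifying rules naively
step4_oracle <- function(ex, sex) {
  genes <- unique(ex$gene[nzchar(ex$gene)])
  out <- list()
  for (g in sort(genes)) {
    rows <- ex[ex$gene == g & nzchar(ex$gene), ]
    n_hom <- 0L
    het_sites <- character()
    on_x <- FALSE
    for (i in seq_len(nrow(rows))) {
      if (rows$zygosity[i] == "homozygous_alt") n_hom <- n_hom + 1L
      if (rows$zygosity[i] == "heterozygous") {
        het_sites <- union(het_sites, paste(rows$chrom[i], rows$pos[i],
                                            rows$ref[i], rows$alt[i]))
      }
      if (rows$chrom[i] == "X") on_x <- TRUE
    }
    model <- NULL
    if (on_x && identical(sex, "male") && nrow(rows) >= 1L) {
      model <- "XL_hemizygous"
    } else if (n_hom >= 1L) {
      model <- "AR_homozygous"
    } else if (length(het_sites) >= 2L) {
      model <- "AR_compound_het"
    }
    if (!is.null(model)) out[[g]] <- model
  }
  out
}

# order-independent comparison of two variant tables on the typed fields
expect_same_variants <- function(a, b, tol = 1e-9) {
  cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "zygosity",
            "rs_id", "hgvs_c")
  sort_key <- function(x) order(x$chrom, x$pos, x$ref, x$alt)
  a2 <- tibble::as_tibble(a)[sort_key(a), ]
  b2 <- tibble::as_tibble(b)[sort_key(b), ]
  expect_equal(as.data.frame(a2[, cols]), as.data.frame(b2[, cols]),
               ignore_attr = TRUE)
  expect_equal(a2$cat_af, b2$cat_af, tolerance = tol)
}
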