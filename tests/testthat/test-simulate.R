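test_that("generation is deterministic in the seed and varies across seeds", {
  a1 <- generate_exome(small_params(5L), patient_id = "det")
  a2 <- generate_exome(small_params(5L), patient_id = "det")
  b <- generate_exome(small_params(6L), patient_id = "det")
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  expect_false(identical(as.data.frame(a1), as.data.frame(b)))

  # per-patient substreams: another patient's exome does not disturb this one
  c1 <- generate_exome(small_params(5L), patient_id = "other")
  expect_false(identical(as.data.frame(a1), as.data.frame(c1)))
  a3 <- generate_exome(small_params(5L), patient_id = "det")
  expect_identical(as.data.frame(a1), as.data.frame(a3))
})

test_that("zeroed parameters with no scenario give an empty exome", {
  p <- generator_params(seed = 1L, mean_total_variants = 0,
                        mean_coding_nonsilent = 0,
                        panel_count_range = c(0L, 0L),
                        rare_count_range = c(0L, 0L))
  expect_equal(nrow(generate_exome(p, patient_id = "zero")), 0L)
})

test_that("the strata are nested and sized as configured", {
  params <- small_params(3L)
  scen <- family_scenarios()[5, ] # USH2A compound het
  ex <- generate_exome(params, scen)
  cfg <- tiny_config(frequency_catalog = catalog_from_exomes(ex))
  s1 <- step1_coding_nonsilent(ex, cfg)
  s2 <- step2_panel(s1, cfg)
  s3 <- step3_frequency(s2, cfg)
  key <- function(e) paste(e$chrom, e$pos, e$ref, e$alt)
  expect_true(all(key(s1) %in% key(ex)))
  expect_true(all(key(s2) %in% key(s1)))
  expect_true(all(key(s3) %in% key(s2)))
  expect_gte(nrow(s2), params$panel_count_range[1])
  expect_lte(nrow(s2), params$panel_count_range[2])
  expect_gte(nrow(s3), params$rare_count_range[1])
  expect_lte(nrow(s3), params$rare_count_range[2])
  # planted causal variants survive all three filters
  expect_true(all(scen$variants[[1]]$hgvs_c %in% s3$hgvs_c))
})

test_that("strata means calibrate to the generator targets over repeated cohorts", {
  n_cohorts <- 20L
  stats <- purrr::map(seq_len(n_cohorts), function(s) {
    coh <- generate_cohort(small_params(100L + s))
    cfg <- cohort_config(coh)
    purrr::map(coh$exomes, function(ex) {
      s1 <- step1_coding_nonsilent(ex, cfg)
      s2 <- step2_panel(s1, cfg)
      s3 <- step3_frequency(s2, cfg)
      tibble::tibble(total = nrow(ex), cns = nrow(s1), panel = nrow(s2),
                     rare = nrow(s3))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  p <- small_params(1L)
  expect_lt(abs(mean(stats$total) / p$mean_total_variants - 1), 0.05)
  expect_lt(abs(mean(stats$cns) / p$mean_coding_nonsilent - 1), 0.05)
  expect_lt(abs(mean(stats$panel) / mean(p$panel_count_range) - 1), 0.05)
  expect_lt(abs(mean(stats$rare) / mean(p$rare_count_range) - 1), 0.05)
  expect_true(all(stats$panel >= p$panel_count_range[1] &
                    stats$panel <= p$panel_count_range[2]))
  expect_true(all(stats$rare >= p$rare_count_range[1] &
                    stats$rare <= p$rare_count_range[2]))
})

test_that("the default scenarios encode the 12-family study design", {
  scen <- family_scenarios()
  expect_equal(nrow(scen), 12L)
  expect_equal(sum(is.na(scen$causal_gene)), 2L)
  tally <- table(scen$causal_gene)
  expect_equal(tally[["ABCA4"]], 3L)
  expect_equal(tally[["RP1"]], 2L)
  expect_equal(tally[["CNGB3"]], 2L)
  expect_equal(tally[["CHM"]], 1L)
  expect_equal(tally[["USH2A"]], 1L)
  expect_equal(tally[["NMNAT1"]], 1L)
  # X-linked scenario: male index, chrX gene
  xl <- scen[scen$config == "XL_hemizygous", ]
  expect_equal(xl$sex, "male")
  expect_equal(default_panel()$chrom[default_panel()$gene == xl$causal_gene],
               "X")
  # the dual-candidate scenario carries two spurious USH2A calls
  rp1174 <- scen[scen$family_id == "RP-1174", ]$variants[[1]]
  expect_equal(sum(rp1174$spurious), 2L)
  expect_equal(unique(rp1174$gene[rp1174$spurious]), "USH2A")

  expect_error(
    generate_cohort(small_params(1L),
                    scenarios = dplyr::bind_rows(scen, scen[1, ])),
    "duplicated family id")
  expect_equal(length(generate_cohort(small_params(1L),
                                      scenarios = scen[1, ])$exomes), 1L)
})

test_that("the bundled mutation table has 15 distinct records, 8 novel", {
  cat <- default_mutation_catalog()
  expect_equal(nrow(dplyr::distinct(cat, gene, hgvs_c)), 15L)
  expect_equal(sum(cat$status == "novel"), 8L)
  # the recurrent CNGB3 frameshift appears exactly once
  expect_equal(sum(cat$hgvs_c == "c.1148delC"), 1L)
})

test_that("a scenario gene missing from the panel is rejected", {
  scen <- family_scenarios()[1, ]
  scen$variants[[1]]$gene <- "NOTAPANELGENE"
  expect_error(generate_exome(small_params(1L), scen), "absent from the panel")
})

test_that("gene-dropping through a three-generation pedigree resolves all members", {
  ped2 <- pedigree(tibble::tibble(
    family_id = "F",
    member_id = c("gf", "gm", "mo", "fa", "kid"),
    father_id = c(NA, NA, NA, "gf", "fa"),
    mother_id = c(NA, NA, NA, "gm", "mo"),
    sex = c("male", "female", "female", "male", "male"),
    affected = FALSE,
    carries_allele_a = c("yes", "no", "no", "unknown", "unknown"),
    carries_allele_b = "no",
    proband = FALSE
  ))
  d <- drop_alleles(ped2, n_replicates = 2000L, seed = 11L)
  kid <- d[d$member_id == "kid", ]
  # kid inherits the grandfather's allele through fa with prob 1/4
  expect_lt(abs(mean(kid$carries_allele_a == "yes") - 0.25), 0.03)
})
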