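test_that("step 1 keeps exactly the non-silent consequence classes", {
  cfg <- tiny_config()
  ex <- seven_class_exome()
  out <- step1_coding_nonsilent(ex, cfg)
  expect_setequal(out$consequence, nonsilent_classes())
  expect_equal(nrow(out), 5L)
  expect_equal(nrow(ex), 7L) # input unmodified

  empty <- exome(data.frame(), "e")
  expect_equal(nrow(step1_coding_nonsilent(empty, cfg)), 0L)
})

test_that("step 2 keeps exactly the panel genes", {
  ex <- exome(
    tibble::tibble(
      chrom = "1", pos = 1:3, ref = "A", alt = "T",
      gene = c("ABCA4", "FAKEGENE", "USH2A"),
      consequence = "missense", zygosity = "heterozygous"
    ), "p")
  cfg2 <- cascade_config(panel = tibble::tibble(gene = c("ABCA4", "USH2A"),
                                                chrom = c("1", "1")))
  expect_setequal(step2_panel(ex, cfg2)$gene, c("ABCA4", "USH2A"))

  cfg_empty <- cascade_config(panel = tibble::tibble(gene = character(),
                                                     chrom = character()))
  expect_equal(nrow(step2_panel(ex, cfg_empty)), 0L)
})

test_that("step 3 removes only catalogued variants strictly above the threshold", {
  ex <- exome(
    tibble::tibble(
      chrom = "1", pos = 1:4, ref = "A", alt = "T", gene = "ABCA4",
      consequence = "missense", zygosity = "heterozygous"
    ), "p")
  catalog <- tibble::tibble(
    chrom = "1", pos = 1:4, ref = "A", alt = "T",
    af = c(0.5, 0.02, 0.01, NA)
  )
  cfg <- tiny_config(frequency_catalog = catalog)
  out <- step3_frequency(ex, cfg)
  # 0.5 removed; 0.02 kept (strict inequality); 0.01 and the
  # known-site-without-frequency entry kept
  expect_setequal(out$pos, 2:4)

  cfg1 <- tiny_config(frequency_catalog = catalog, af_threshold = 1)
  expect_equal(nrow(step3_frequency(ex, cfg1)), 4L)
})

test_that("step 4 calls homozygous, compound-het and hemizygous configurations", {
  cfg <- tiny_config()
  mk <- function(rows, sex = "female") {
    exome(tibble::as_tibble(rows), patient_id = "p", sex = sex)
  }
  hom <- mk(tibble::tibble(chrom = "1", pos = 10L, ref = "A", alt = "T",
                           gene = "ABCA4", consequence = "missense",
                           zygosity = "homozygous_alt"))
  out <- step4_recessive(hom, cfg)
  expect_equal(unique(out$gene), "ABCA4")
  expect_equal(unique(out$model), "AR_homozygous")

  chm <- mk(tibble::tibble(chrom = "X", pos = 20L, ref = "A", alt = "AT",
                           gene = "CHM", consequence = "frameshift_indel",
                           zygosity = "homozygous_alt"), sex = "male")
  out <- step4_recessive(chm, cfg)
  expect_equal(unique(out$model), "XL_hemizygous")
  expect_error(step4_recessive(chm, cfg, sex = NA_character_), "sex")

  single_het <- mk(tibble::tibble(chrom = "1", pos = 30L, ref = "A", alt = "T",
                                  gene = "ABCA4", consequence = "missense",
                                  zygosity = "heterozygous"))
  expect_equal(nrow(step4_recessive(single_het, cfg)), 0L)

  dual <- mk(tibble::tibble(
    chrom = c("8", "1", "1"), pos = c(40L, 50L, 60L), ref = "A", alt = "T",
    gene = c("CNGB3", "USH2A", "USH2A"),
    consequence = "missense",
    zygosity = c("homozygous_alt", "heterozygous", "heterozygous")
  ))
  out <- step4_recessive(dual, cfg)
  expect_setequal(unique(out$gene), c("CNGB3", "USH2A"))
  expect_equal(out$gene, sort(out$gene)) # report order: by gene symbol
})

test_that("step 5 flags known mutations from the catalog and warns on missing HGVS", {
  cfg <- tiny_config(mutation_catalog = default_mutation_catalog())
  cand <- structure(
    tibble::tibble(
      gene = c("CNGB3", "CHM", "RP1"), model = "AR_homozygous",
      chrom = c("8", "X", "8"), pos = 1:3, ref = "A", alt = "T",
      zygosity = "homozygous_alt",
      hgvs_c = c("c.1148delC", "c.863dupA", NA)
    ),
    class = c("rd_candidates", class(tibble::tibble()))
  )
  expect_warning(out <- step5_annotate_known(cand, cfg), "HGVS")
  expect_identical(out$known, c(TRUE, FALSE, FALSE))

  empty <- step4_recessive(exome(data.frame(), "p"), cfg)
  expect_equal(nrow(step5_annotate_known(empty, cfg)), 0L)
})

test_that("run_cascade composes the five steps and traces hand-computable counts", {
  # 8 variants: 2 noncoding/silent, 2 off-panel, 1 common catalogued,
  # 3 rare panel variants of which two make one compound het gene
  ex <- exome(tibble::tibble(
    chrom = c("2", "3", "4", "4", "1", "1", "1", "1"),
    pos = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
    ref = "A", alt = "T",
    gene = c("", "OFF1", "OFF2", "OFF2", "ABCA4", "ABCA4", "ABCA4", "NMNAT1"),
    consequence = c("noncoding", "synonymous", "missense", "missense",
                    "missense", "nonsense", "missense", "missense"),
    zygosity = "heterozygous",
    hgvs_c = c(NA, NA, NA, NA, "c.10A>T", "c.20A>T", "c.30A>T", "c.40A>T")
  ), patient_id = "hand", sex = "female")
  catalog <- tibble::tibble(chrom = "1", pos = 7L, ref = "A", alt = "T",
                            af = 0.3)
  cfg <- tiny_config(frequency_catalog = catalog)
  res <- run_cascade(ex, cfg)
  expect_equal(res$trace$count, c(8L, 6L, 4L, 3L, 2L))
  expect_true(all(diff(res$trace$count) <= 0))
  expect_equal(unique(res$candidates$gene), "ABCA4")
  expect_equal(unique(res$candidates$model), "AR_compound_het")

  g <- glance(res)
  expect_identical(g$n_candidate_genes, 1L)
  expect_true(g$solved)
  td <- tidy(res)
  expect_equal(td$patient_id, rep("hand", 2))

  empty_res <- run_cascade(exome(data.frame(), "e"), cfg)
  expect_equal(empty_res$trace$count, rep(0L, 5))
  expect_equal(nrow(empty_res$candidates), 0L)
})

test_that("filter steps are monotone, idempotent, and steps 1-3 commute pairwise", {
  for (seed in c(11L, 12L, 13L)) {
    ex <- generate_exome(small_params(seed), patient_id = paste0("prop", seed))
    cfg <- tiny_config(frequency_catalog = catalog_from_exomes(ex))
    steps <- list(step1_coding_nonsilent, step2_panel, step3_frequency)
    key <- function(e) paste(e$chrom, e$pos, e$ref, e$alt)
    cur <- ex
    for (s in steps) {
      nxt <- s(cur, cfg)
      expect_true(all(key(nxt) %in% key(cur)))      # subset
      expect_equal(key(s(nxt, cfg)), key(nxt))      # idempotent
      cur <- nxt
    }
    for (i in 1:3) for (j in 1:3) {
      if (i >= j) next
      ab <- steps[[j]](steps[[i]](ex, cfg), cfg)
      ba <- steps[[i]](steps[[j]](ex, cfg), cfg)
      expect_setequal(key(ab), key(ba))
    }
  }
})

test_that("step 4 agrees with a brute-force oracle on small random exomes", {
  cfg <- tiny_config()
  panel <- default_panel()
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(0:30, 1)
    sex <- sample(c("male", "female"), 1)
    genes <- sample(panel$gene[panel$chrom != "X" | sex == "male"], 6)
    chroms <- panel$chrom[match(genes, panel$gene)]
    pick <- sample(6, n, replace = TRUE)
    ex <- exome(tibble::tibble(
      chrom = chroms[pick], pos = sample.int(1e6, n), ref = "A", alt = "T",
      gene = genes[pick], consequence = "missense",
      zygosity = sample(c("heterozygous", "homozygous_alt"), n,
                        replace = TRUE, prob = c(.7, .3))
    ), patient_id = "oracle", sex = sex)
    got <- step4_recessive(ex, cfg)
    want <- step4_oracle(ex, sex)
    got_models <- unique(tibble::as_tibble(got)[, c("gene", "model")])
    expect_equal(nrow(got_models), length(want))
    if (length(want) > 0L) {
      expect_identical(
        stats::setNames(got_models$model, got_models$gene),
        unlist(want)[got_models$gene]
      )
    }
  }
})
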