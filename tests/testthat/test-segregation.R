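test_that("enumeration reproduces hand-derived sibship probabilities", {
  # 3 affected compound-het (index included) + 3 unaffected: 27/4096
  res <- segregation_probability(ar_sibship(3, 3), model = "AR")
  expect_identical(res$n_vectors, 4096L)
  expect_identical(res$n_consistent, 27L)
  expect_equal(res$probability, 27 / 4096)

  # 1 affected + 2 unaffected: 9/64 over the 4^3 = 64 vectors
  res <- segregation_probability(ar_sibship(1, 2), model = "AR")
  expect_identical(res$n_vectors, 64L)
  expect_equal(res$probability, 9 / 64)

  # pedigree with no non-founders: empty product
  founders_only <- pedigree(tibble::tibble(
    family_id = "F", member_id = c("fa", "mo"), father_id = NA_character_,
    mother_id = NA_character_, sex = c("male", "female"), affected = FALSE,
    carries_allele_a = c("yes", "no"), carries_allele_b = c("no", "yes"),
    proband = FALSE
  ))
  expect_equal(segregation_probability(founders_only, "AR")$probability, 1)
})

test_that("X-linked enumeration handles hemizygous sons", {
  # 2 affected hemizygous sons + 1 unaffected non-carrier son: 1/8
  ped <- pedigree(tibble::tibble(
    family_id = "F", member_id = c("fa", "mo", "s1", "s2", "s3"),
    father_id = c(NA, NA, "fa", "fa", "fa"),
    mother_id = c(NA, NA, "mo", "mo", "mo"),
    sex = c("male", "female", "male", "male", "male"),
    affected = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    carries_allele_a = c("no", "yes", "yes", "yes", "no"),
    carries_allele_b = "no",
    proband = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  ))
  res <- segregation_probability(ped, model = "XL")
  expect_identical(res$n_vectors, 8L)
  expect_equal(res$probability, 1 / 8)
})

test_that("excluding the index drops it from the enumeration", {
  ped <- ar_sibship(3, 3)
  incl <- segregation_probability(ped, "AR", include_index = TRUE)
  excl <- segregation_probability(ped, "AR", include_index = FALSE)
  expect_equal(incl$probability, closed_form_ar(3, 3))
  expect_equal(excl$probability, closed_form_ar(2, 3))
  expect_identical(excl$n_vectors, 1024L)
})

test_that("enumeration equals the closed form over a grid of sibships", {
  for (a in 0:3) for (u in 0:3) {
    res <- segregation_probability(ar_sibship(a, u), "AR")
    expect_equal(res$probability, closed_form_ar(a, u),
                 info = sprintf("a=%d u=%d", a, u))
  }
  expect_error(closed_form_ar(-1, 0), "non-negative")
})

test_that("probabilities over all child genotype configurations sum to one", {
  for (n in 1:4) {
    combos <- expand.grid(rep(list(1:4), n)) # both / A only / B only / neither
    total <- 0
    for (r in seq_len(nrow(combos))) {
      states <- unlist(combos[r, ])
      a <- c("yes", "yes", "no", "no")[states]
      b <- c("yes", "no", "yes", "no")[states]
      ped <- pedigree(tibble::tibble(
        family_id = "F",
        member_id = c("fa", "mo", paste0("c", seq_len(n))),
        father_id = c(NA, NA, rep("fa", n)),
        mother_id = c(NA, NA, rep("mo", n)),
        sex = c("male", "female", rep("female", n)),
        affected = c(FALSE, FALSE, states == 1L),
        carries_allele_a = c("yes", "no", a),
        carries_allele_b = c("no", "yes", b),
        proband = FALSE
      ))
      total <- total + segregation_probability(ped, "AR")$probability
    }
    expect_equal(total, 1, info = paste("n =", n))
  }
})

test_that("each added consistent member scales the probability by its Mendelian ratio", {
  for (a in 0:2) for (u in 0:2) {
    p0 <- segregation_probability(ar_sibship(a, u), "AR")$probability
    p_aff <- segregation_probability(ar_sibship(a + 1, u), "AR")$probability
    p_unaff <- segregation_probability(ar_sibship(a, u + 1), "AR")$probability
    expect_equal(p_aff, p0 / 4)
    expect_equal(p_unaff, p0 * 3 / 4)
  }
})

test_that("truncation (not rounding) gives the three-decimal quoted value", {
  expect_equal(truncate_probability(27 / 4096), 0.006)
  expect_equal(truncate_probability(0.0069), 0.006)
  expect_equal(round(27 / 4096, 3), 0.007) # rounding would not match
})

test_that("gene-dropping Monte Carlo agrees with the exact enumeration", {
  ped <- ar_sibship(3, 3)
  p_exact <- segregation_probability(ped, "AR")$probability
  n <- 10000L
  p_mc <- cosegregation_mc(ped, "AR", n_replicates = n, seed = 99L)
  half_width <- stats::qnorm(0.995) * sqrt(p_exact * (1 - p_exact) / n)
  expect_lt(abs(p_mc - p_exact), half_width + 1e-12)
})

test_that("drop_alleles transmits parental alleles at Mendelian rates", {
  ped <- ar_sibship(1, 0)
  expect_error(
    drop_alleles(pedigree(dplyr::mutate(
      ped, carries_allele_a = dplyr::if_else(member_id == "fa",
                                             "unknown", carries_allele_a))),
      10L),
    "founder fa"
  )
  n <- 10000L
  drops <- drop_alleles(ped, n_replicates = n, seed = 7L)
  kid <- drops[drops$member_id == "c1", ]
  frac_ch <- mean(kid$carries_allele_a == "yes" & kid$carries_allele_b == "yes")
  half_width <- stats::qnorm(0.995) * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(frac_ch - 0.25), half_width)

  # no children: founder states replicated unchanged
  founders_only <- pedigree(ped[is.na(ped$father_id), ])
  d0 <- drop_alleles(founders_only, n_replicates = 3L, seed = 1L)
  expect_true(all(d0$carries_allele_a[d0$member_id == "fa"] == "yes"))
  expect_true(all(d0$carries_allele_b[d0$member_id == "mo"] == "yes"))
})
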