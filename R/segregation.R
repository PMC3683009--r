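#' Exact Mendelian cosegregation probability
#'
#' Computes, by exhaustive enumeration of transmission vectors, the
#' probability that Mendelian transmission of the candidate alleles through
#' the pedigree produces a genotype/phenotype configuration at least as
#' constrained as the observed one. This is the probability that the
#' observed perfect cosegregation arose by chance if the alleles were
#' transmitted independently of disease — small values support causality.
#'
#' Under the autosomal recessive (`"AR"`) model the parents are obligate
#' carriers in trans: the father carries allele A, the mother allele B, and
#' each child independently receives or misses each parental mutant allele,
#' giving 4 equiprobable transmissions per child. Under the X-linked
#' (`"XL"`) model the mother is an obligate carrier and each child receives
#' or misses the maternal mutant X (2 transmissions per child); affected
#' status requires the mutant X in males, and females are modelled as never
#' affected. A transmission vector is consistent when every genotyped
#' member's observed carrier state matches and every member's affected
#' status matches the model (affected iff compound heterozygous for AR;
#' affected iff a mutant-X male for XL). The returned probability is the
#' consistent fraction.
#'
#' @param ped An [pedigree()]. Every non-founder must have both parents in
#'   the pedigree; the enumeration runs over the non-founder children.
#' @param model `"AR"` or `"XL"`.
#' @param include_index Include the index patient (rows with
#'   `proband = TRUE`) in the enumeration? Defaults to `TRUE`; with `FALSE`
#'   the proband is dropped entirely, as when asking whether the *rest* of
#'   the family cosegregates.
#' @return A list of class `rd_segregation`: `probability`,
#'   `n_consistent`, `n_vectors` (`probability = n_consistent/n_vectors`),
#'   `model`, `n_children`, `include_index`.
#' @seealso [closed_form_ar()] for the analytic special case.
#' @export
#' @examples
#' # 3 affected compound-het children, 3 unaffected: (1/4)^3 (3/4)^3
#' ped <- pedigree(tibble::tibble(
#'   family_id = "F", member_id = c("fa", "mo", paste0("c", 1:6)),
#'   father_id = c(NA, NA, rep("fa", 6)), mother_id = c(NA, NA, rep("mo", 6)),
#'   sex = c("male", "female", rep(c("male", "female"), 3)),
#'   affected = c(FALSE, FALSE, rep(c(TRUE, FALSE), each = 3)),
#'   carries_allele_a = c("yes", "no", rep("yes", 3), rep("unknown", 3)),
#'   carries_allele_b = c("no", "yes", rep("yes", 3), rep("unknown", 3))
#' ))
#' segregation_probability(ped, model = "AR")$probability * 4096
segregation_probability <- function(ped, model = c("AR", "XL"),
                                    include_index = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(ped, "rd_pedigree"))
  kids <- ped_children(ped)
  if (!include_index) kids <- kids[!kids$proband, ]
  n <- nrow(kids)
  states_per_child <- if (model == "AR") 4L else 2L
  if (n > 12L) {
    stop("enumeration over ", states_per_child, "^", n,
         " transmission vectors is too large; at most 12 children",
         call. = FALSE)
  }
  n_vectors <- states_per_child^n
  if (n == 0L) {
    return(new_segregation(1, 1L, 1L, model, 0L, include_index))
  }

  # state s in 0..3 encodes (got paternal A, got maternal B) for AR;
  # s in 0..1 encodes (got maternal mutant X) for XL.
  grid <- as.matrix(expand.grid(rep(list(seq_len(states_per_child) - 1L), n)))
  consistent <- rep(TRUE, nrow(grid))
  for (j in seq_len(n)) {
    s <- grid[, j]
    if (model == "AR") {
      has_a <- s %% 2L == 1L
      has_b <- s %/% 2L == 1L
    } else {
      has_a <- s == 1L
      has_b <- rep(FALSE, length(s))
    }
    ok <- matches_carrier(has_a, kids$carries_allele_a[j]) &
      matches_carrier(has_b, kids$carries_allele_b[j])
    if (model == "AR") {
      ok <- ok & ((has_a & has_b) == kids$affected[j])
    } else {
      if (kids$carries_allele_b[j] == "yes") {
        stop("XL model uses carries_allele_a for the X allele; member ",
             kids$member_id[j], " has carries_allele_b = yes", call. = FALSE)
      }
      if (kids$sex[j] == "male") {
        ok <- ok & (has_a == kids$affected[j])
      } else {
        # carrier females are unaffected; an affected female never fits
        ok <- ok & !kids$affected[j]
      }
    }
    consistent <- consistent & ok
  }
  n_consistent <- sum(consistent)
  new_segregation(n_consistent / n_vectors, n_consistent, n_vectors,
                  model, n, include_index)
}

#' @noRd
matches_carrier <- function(has, observed) {
  switch(observed,
         yes = has,
         no = !has,
         unknown = rep(TRUE, length(has)))
}

#' @noRd
new_segregation <- function(p, n_consistent, n_vectors, model, n_children,
                            include_index) {
  structure(
    list(probability = p, n_consistent = as.integer(n_consistent),
         n_vectors = as.integer(n_vectors), model = model,
         n_children = n_children, include_index = include_index),
    class = "rd_segregation"
  )
}

#' Closed-form autosomal recessive cosegregation probability
#'
#' Analytic special case of [segregation_probability()]: when every
#' affected sibling must be compound heterozygous and every unaffected
#' sibling must not be, the chance of a consistent transmission is 1/4 per
#' affected and 3/4 per unaffected sibling, giving
#' `(1/4)^n_affected * (3/4)^n_unaffected`.
#'
#' @param n_affected,n_unaffected Non-negative sibling counts.
#' @return The probability.
#' @export
#' @examples
#' closed_form_ar(3, 3) # 27/4096
closed_form_ar <- function(n_affected, n_unaffected) {
  if (n_affected < 0 || n_unaffected < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  0.25^n_affected * 0.75^n_unaffected
}

#' Truncate a probability to a fixed number of decimal places
#'
#' Truncation (not rounding) towards zero, the convention used when quoting
#' cosegregation probabilities to a fixed precision: 27/4096 = 0.00659...
#' prints as 0.006 at three decimals.
#'
#' @param p Probability (or any non-negative number).
#' @param digits Decimal places to keep (default 3).
#' @return The truncated value.
#' @export
truncate_probability <- function(p, digits = 3L) {
  floor(p * 10^digits) / 10^digits
}

#' @export
print.rd_segregation <- function(x, ...) {
  cat(sprintf(
    "# rd_segregation (%s model): p = %.6g (%d of %d transmission vectors, %d children%s)\n",
    x$model, x$probability, x$n_consistent, x$n_vectors, x$n_children,
    if (x$include_index) ", index included" else ", index excluded"))
  invisible(x)
}

#' Tidy a cosegregation result
#'
#' @param x An `rd_segregation`.
#' @param ... Unused.
#' @return A one-row tibble with `probability`, `n_consistent`,
#'   `n_vectors`, `model`, `n_children`, `include_index`.
#' @method tidy rd_segregation
#' @export
tidy.rd_segregation <- function(x, ...) {
  tibble::tibble(
    probability = x$probability, n_consistent = x$n_consistent,
    n_vectors = x$n_vectors, model = x$model, n_children = x$n_children,
    include_index = x$include_index
  )
}

#' @rdname tidy.rd_segregation
#' @method glance rd_segregation
#' @export
glance.rd_segregation <- function(x, ...) tidy.rd_segregation(x, ...)
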