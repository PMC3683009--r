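#' Summarise cascade results across a cohort
#'
#' Computes the cohort-level diagnostic yield: how many index patients the
#' cascade solved (at least one candidate gene after annotation), the
#' solved fraction, the per-gene tally of candidate genes, and the number of
#' distinct and novel candidate mutations. Distinct mutations are
#' deduplicated on `(gene, hgvs_c)`; a mutation is novel when it does not
#' match the known set of the mutation catalog. Note that unvalidated
#' spurious calls, when present, count here — validation is outside the
#' cascade.
#'
#' @param results A list of `rd_cascade` objects (one per index patient),
#'   as returned by [run_cascade()].
#' @param mutation_catalog A mutation-catalog tibble.
#' @return A list of class `rd_cohort_summary` with elements `n_families`,
#'   `n_solved`, `solved_fraction`, `percent_solved` (nearest integer),
#'   `gene_tally` (tibble `gene`, `n_families`), `n_distinct_mutations`,
#'   `n_novel_mutations`, and `per_patient` (bound [glance.rd_cascade()]
#'   rows).
#' @export
summarize_cohort <- function(results, mutation_catalog = NULL) {
  if (length(results) == 0L) {
    stop("cannot summarise an empty cohort", call. = FALSE)
  }
  stopifnot(all(purrr::map_lgl(results, inherits, "rd_cascade")))
  ids <- purrr::map_chr(results, "patient_id")
  if (anyDuplicated(ids)) {
    stop("duplicate patient id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  per_patient <- purrr::map(results, glance) |> dplyr::bind_rows()
  cand <- purrr::map(results, tidy) |> dplyr::bind_rows()
  n_fam <- length(results)
  n_solved <- sum(per_patient$solved)

  gene_tally <- cand |>
    dplyr::distinct(.data$patient_id, .data$gene) |>
    dplyr::count(.data$gene, name = "n_families") |>
    dplyr::arrange(dplyr::desc(.data$n_families), .data$gene)

  muts <- dplyr::distinct(cand, .data$gene, .data$hgvs_c, .keep_all = TRUE)
  known_set <- character()
  if (!is.null(mutation_catalog)) {
    mc <- mutation_catalog[mutation_catalog$status == "known", ]
    known_set <- paste(mc$gene, mc$hgvs_c)
  }
  n_novel <- sum(!paste(muts$gene, muts$hgvs_c) %in% known_set)

  structure(
    list(
      n_families = n_fam,
      n_solved = n_solved,
      solved_fraction = n_solved / n_fam,
      percent_solved = as.integer(round(100 * n_solved / n_fam)),
      gene_tally = gene_tally,
      n_distinct_mutations = nrow(muts),
      n_novel_mutations = n_novel,
      per_patient = per_patient
    ),
    class = "rd_cohort_summary"
  )
}

#' @export
print.rd_cohort_summary <- function(x, ...) {
  cat(sprintf("# rd_cohort_summary: %d of %d families solved (%d%%)\n",
              x$n_solved, x$n_families, x$percent_solved))
  cat(sprintf("  %d distinct candidate mutations, %d novel\n",
              x$n_distinct_mutations, x$n_novel_mutations))
  print(x$gene_tally)
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x An `rd_cohort_summary`.
#' @param ... Unused.
#' @method glance rd_cohort_summary
#' @export
glance.rd_cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_families = x$n_families, n_solved = x$n_solved,
    solved_fraction = x$solved_fraction, percent_solved = x$percent_solved,
    n_distinct_mutations = x$n_distinct_mutations,
    n_novel_mutations = x$n_novel_mutations
  )
}

#' Run the cascade over every exome of a cohort
#'
#' @param cohort An `rd_cohort` from [generate_cohort()].
#' @param config A [cascade_config()]; defaults to [cohort_config()].
#' @return A named list of `rd_cascade` results, one per index patient.
#' @export
run_cohort <- function(cohort, config = cohort_config(cohort)) {
  purrr::map(cohort$exomes, run_cascade, config = config)
}

#' Write cascade reports as TSV files
#'
#' Writes the per-step surviving-count trace and the annotated candidate
#' table (one row per supporting variant) with a deterministic column
#' order.
#'
#' @param result An `rd_cascade` from [run_cascade()].
#' @param trace_path,candidates_path Output paths (either may be `NULL` to
#'   skip).
#' @return `result`, invisibly.
#' @export
report_cascade <- function(result, trace_path = NULL, candidates_path = NULL) {
  stopifnot(inherits(result, "rd_cascade"))
  if (!is.null(trace_path)) readr::write_tsv(result$trace, trace_path)
  if (!is.null(candidates_path)) {
    cand <- tidy(result)
    cand <- cand[, c("patient_id", "gene", "model", "hgvs_c", "zygosity",
                     "known", "chrom", "pos", "ref", "alt")]
    readr::write_tsv(cand, candidates_path, na = "")
  }
  invisible(result)
}

#' Rebuild cascade results from report files
#'
#' Reads the `<patient>_trace.tsv` / `<patient>_candidates.tsv` pairs
#' written by [report_cascade()] back into `rd_cascade` objects, so that a
#' directory of per-patient reports can be summarised with
#' [summarize_cohort()].
#'
#' @param dir Directory containing the report TSV pairs.
#' @return A named list of `rd_cascade` objects.
#' @export
read_cascade_results <- function(dir) {
  trace_files <- sort(list.files(dir, pattern = "_trace\\.tsv$",
                                 full.names = TRUE))
  if (!length(trace_files)) stop("no *_trace.tsv files in ", dir, call. = FALSE)
  res <- purrr::map(trace_files, function(tf) {
    pid_file <- sub("_trace\\.tsv$", "", basename(tf))
    cf <- file.path(dir, paste0(pid_file, "_candidates.tsv"))
    cand <- readr::read_tsv(cf, col_types = readr::cols(
      patient_id = readr::col_character(), gene = readr::col_character(),
      model = readr::col_character(), hgvs_c = readr::col_character(),
      zygosity = readr::col_character(), known = readr::col_logical(),
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character()
    ))
    pid <- if (nrow(cand)) cand$patient_id[1L] else pid_file
    cand <- cand[, c("gene", "model", "chrom", "pos", "ref", "alt",
                     "zygosity", "hgvs_c", "known")]
    structure(
      list(patient_id = pid, sex = NA_character_, trace = read_trace(tf),
           candidates = structure(cand, class = c("rd_candidates",
                                                  class(tibble::tibble())))),
      class = "rd_cascade"
    )
  })
  stats::setNames(res, purrr::map_chr(res, "patient_id"))
}

#' @rdname report_cascade
#' @param path Path to a trace TSV written by `report_cascade()`.
#' @export
read_trace <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    step = readr::col_character(), count = readr::col_integer()
  ))
}
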