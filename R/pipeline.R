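# Per-genome annotation workflow and the truth-evaluation harness.

#' Annotate prophage integrations in one or more genomes
#'
#' For each genome FASTA: obtain homology matches (from the built-in
#' detector or a precomputed nhmmer/BLAST table), filter them, chain
#' fragments into integrations, and write a per-genome annotation TSV and
#' BED file. A dataset-wide JSON summary with per-query occurrence
#' profiles and a run manifest are written once. Genomes are processed
#' independently, so results do not depend on input order.
#'
#' @param genome_fastas Character vector of genome FASTA paths.
#' @param phage_fasta Query-phage FASTA path.
#' @param out_dir Output directory (created if needed).
#' @param hits Optional precomputed hit table path(s): one per genome or a
#'   single table covering all genomes. Required unless
#'   `hits_format = "builtin"`.
#' @param hits_format `"builtin"` (run [naive_detect()]), `"nhmmer"`, or
#'   `"blast"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the pooled annotation table, the
#'   integration summary, the profiles, and the output paths.
#' @export
annotate_run <- function(genome_fastas, phage_fasta, out_dir,
                         hits = NULL,
                         hits_format = c("builtin", "nhmmer", "blast"),
                         config = pipeline_config()) {
  hits_format <- match.arg(hits_format)
  if (length(genome_fastas) < 1L) stop("need at least one genome FASTA", call. = FALSE)
  if (hits_format != "builtin") {
    if (is.null(hits)) {
      stop(sprintf("hits_format '%s' requires precomputed hit table(s)",
                   hits_format), call. = FALSE)
    }
    if (!length(hits) %in% c(1L, length(genome_fastas))) {
      stop("'hits' must be a single table or one per genome", call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  queries <- read_fasta(phage_fasta)
  ann_all <- list()
  paths <- list()
  for (i in seq_along(genome_fastas)) {
    gpath <- genome_fastas[i]
    gcat <- read_fasta(gpath)
    matches <- switch(
      hits_format,
      builtin = naive_detect(gcat, queries),
      nhmmer = parse_nhmmer_tblout(if (length(hits) == 1L) hits else hits[i],
                                   queries),
      blast = parse_blast_tab(if (length(hits) == 1L) hits else hits[i],
                              queries)
    )
    if (hits_format != "builtin" && nrow(matches) > 0L) {
      unknown_t <- setdiff(unique(matches$target_id), names(gcat))
      matches <- matches[matches$target_id %in% names(gcat), , drop = FALSE]
      if (length(hits) != 1L && length(unknown_t) > 0L) {
        stop(sprintf("hit table references unknown target id(s): %s",
                     paste(unknown_t, collapse = ", ")), call. = FALSE)
      }
    }
    ann <- assign_integrations(filter_matches(matches, config), config)
    base <- sub("\\.(fa|fasta|fna)$", "", basename(gpath), ignore.case = TRUE)
    tsv <- file.path(out_dir, paste0(base, ".tsv"))
    bed <- file.path(out_dir, paste0(base, ".bed"))
    write_annotation_tsv(ann, tsv)
    export_bed(ann, bed)
    pf_log("INFO", "annotate",
           sprintf("%s: %d match(es) -> %d integration(s)", base, nrow(ann),
                   length(unique(ann$integration_id))))
    ann_all[[i]] <- ann
    paths[[base]] <- list(tsv = tsv, bed = bed)
  }
  annotation <- do.call(rbind, ann_all)
  profiles <- build_profiles(annotation, queries)
  summary_path <- file.path(out_dir, "summary.json")
  export_summary_json(annotation, profiles, summary_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    tool = "prophagr", version = as.character(packageVersion("prophagr")),
    command = "annotate",
    inputs = list(genomes = genome_fastas, phages = phage_fasta,
                  hits = hits, hits_format = hits_format),
    config = unclass(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = c(lapply(paths, unlist), list(summary = summary_path))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(annotation = annotation,
                 integrations = integration_summary(annotation),
                 profiles = profiles,
                 paths = c(paths, list(summary = summary_path,
                                       manifest = manifest_path))))
}

#' Compare an annotation against simulator ground truth
#'
#' For every planted integration, reports whether it was recovered as a
#' single integration (exactly one reported integration of the same query
#' overlapping its genome span, with both boundaries within
#' `boundary_tol`), the boundary errors in nucleotides, and whether the
#' full-length flag agrees with the expectation.
#'
#' @param annotation Annotated match table, or path to an annotation TSV.
#' @param truth Truth table from [plant_integrations()], or path to a
#'   truth TSV.
#' @param boundary_tol Tolerated boundary error in nucleotides. Seed-based
#'   detection cannot anchor closer than one seed length to a copy
#'   boundary, hence the default 14 (= 15-mer seed - 1).
#' @return An object of class `pf_check`: a list with `report` (one row
#'   per planting) and `summary` (recovery and full-length agreement
#'   rates).
#' @export
check_run <- function(annotation, truth, boundary_tol = 14L) {
  if (is.character(annotation)) annotation <- read_annotation_tsv(annotation)
  if (is.character(truth)) truth <- read_truth_tsv(truth)
  summ <- integration_summary(annotation)
  tids <- unique(truth$truth_id)
  rows <- lapply(tids, function(id) {
    tp <- truth[truth$truth_id == id, , drop = FALSE]
    span_start <- min(tp$genome_start)
    span_end <- max(tp$genome_end)
    obs <- summ[summ$target_id == tp$target_id[1L] &
                  summ$query_id == tp$query_id[1L] &
                  summ$genome_end >= span_start &
                  summ$genome_start <= span_end, , drop = FALSE]
    n_obs <- nrow(obs)
    if (n_obs == 1L) {
      err_start <- obs$genome_start - span_start
      err_end <- obs$genome_end - span_end
      recovered <- abs(err_start) <= boundary_tol && abs(err_end) <= boundary_tol
      fl_obs <- obs$full_length
      fl_agree <- identical(fl_obs, tp$expected_full_length[1L])
    } else {
      err_start <- NA_integer_
      err_end <- NA_integer_
      recovered <- FALSE
      fl_obs <- NA
      fl_agree <- NA
    }
    data.frame(
      truth_id = id, query_id = tp$query_id[1L], target_id = tp$target_id[1L],
      n_observed = n_obs,
      observed_ids = paste(obs$integration_id, collapse = ","),
      recovered_single = recovered,
      boundary_error_start = err_start, boundary_error_end = err_end,
      expected_full_length = tp$expected_full_length[1L],
      observed_full_length = fl_obs, full_length_agree = fl_agree,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  if (is.null(report)) report <- data.frame()
  n <- nrow(report)
  res <- list(
    report = report,
    summary = list(
      n_truth = n,
      recovery_rate = if (n > 0L) mean(report$recovered_single) else NA_real_,
      full_length_agreement =
        if (n > 0L) mean(report$full_length_agree, na.rm = TRUE) else NA_real_
    )
  )
  class(res) <- "pf_check"
  res
}

#' @export
print.pf_check <- function(x, ...) {
  s <- x$summary
  cat(sprintf("planted integrations: %d\n", s$n_truth))
  cat(sprintf("recovered as single integrations: %.3f\n", s$recovery_rate))
  cat(sprintf("full-length flag agreement: %.3f\n", s$full_length_agreement))
  if (nrow(x$report) > 0L) {
    bad <- x$report[!x$report$recovered_single, , drop = FALSE]
    if (nrow(bad) > 0L) {
      cat("not recovered as single integrations:\n")
      for (i in seq_len(nrow(bad))) {
        cat(sprintf("  %s (%s on %s): %d observed id(s) [%s]\n",
                    bad$truth_id[i], bad$query_id[i], bad$target_id[i],
                    bad$n_observed[i], bad$observed_ids[i]))
      }
    }
  }
  invisible(x)
}
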