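# Position-occurrence profiles along query phages, plus JSON/BED export.

#' Per-position occurrence profiles along each query phage
#'
#' For every query phage with at least one integration, counts, at each
#' query position, how many integrations in the dataset cover that
#' position. Each integration contributes +1 to every position in the
#' union of its fragments' query intervals, so positions covered by two
#' overlapping fragments of the same integration count once.
#'
#' @param annotation Output of [assign_integrations()] (possibly pooled
#'   over many target genomes).
#' @param catalog Query catalog giving query lengths (a `DNAStringSet`
#'   from [read_fasta()] or a named integer vector).
#' @return A named list, one element per query id, each a list with
#'   `query_id`, `length`, and the integer `counts` vector of that length.
#'   Conservation holds by construction and is asserted on every build:
#'   `sum(counts)` equals the summed query coverage of the contributing
#'   integrations.
#' @examples
#' ann <- assign_integrations(
#'   match_record("p", 200, "g", 1, 100, 1, 100), pipeline_config())
#' build_profiles(ann, c(p = 200))$p$counts[c(1, 100, 101)]
#' @export
build_profiles <- function(annotation, catalog) {
  lens <- .cat_lengths(catalog)
  if (nrow(annotation) == 0L) return(stats::setNames(list(), character(0)))
  unknown <- setdiff(unique(annotation$query_id), names(lens))
  if (length(unknown) > 0L) {
    stop(sprintf("integration(s) reference query id(s) absent from catalog: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  profiles <- list()
  for (qid in sort(unique(annotation$query_id))) {
    qa <- annotation[annotation$query_id == qid, , drop = FALSE]
    n <- lens[[qid]]
    # one reduced range set per integration, then stacked coverage
    per_int <- lapply(split(seq_len(nrow(qa)), qa$integration_id), function(idx) {
      IRanges::reduce(IRanges::IRanges(start = qa$query_start[idx],
                                       end = qa$query_end[idx]))
    })
    all_ranges <- do.call(c, unname(per_int))
    counts <- as.integer(IRanges::coverage(all_ranges, width = n))
    total_cov <- sum(vapply(per_int, function(r) sum(IRanges::width(r)),
                            numeric(1)))
    stopifnot(sum(counts) == total_cov,
              max(counts) <= length(per_int))
    profiles[[qid]] <- list(query_id = qid, length = as.integer(n),
                            counts = counts)
  }
  profiles
}

#' Export the dataset-wide JSON summary
#'
#' Serializes, per target genome, every integration (span, strand,
#' full-length flag, fragments) and, per query phage, the occurrence
#' counts array plus the query-side extent of every integration matching
#' that query. The document carries a `schema_version` field and is
#' validated against the schema shipped in
#' `system.file("schema", "summary-schema.json", package = "prophagr")`
#' before writing.
#'
#' @param annotation Output of [assign_integrations()].
#' @param profiles Output of [build_profiles()] for the same run.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_summary_json <- function(annotation, profiles, path) {
  summ <- integration_summary(annotation)
  genomes <- lapply(sort(unique(summ$target_id)), function(tid) {
    gs <- summ[summ$target_id == tid, , drop = FALSE]
    list(
      target_id = tid,
      integrations = lapply(seq_len(nrow(gs)), function(i) {
        id <- gs$integration_id[i]
        f <- annotation[annotation$integration_id == id, , drop = FALSE]
        list(
          id = id,
          phage = gs$query_id[i],
          start = gs$genome_start[i],
          end = gs$genome_end[i],
          strand = gs$strand[i],
          full_length = gs$full_length[i],
          query_coverage_nt = gs$query_coverage_nt[i],
          fragments = lapply(seq_len(nrow(f)), function(j) {
            list(query_start = f$query_start[j], query_end = f$query_end[j],
                 target_start = f$target_start[j], target_end = f$target_end[j],
                 evalue = f$evalue[j], score = f$score[j])
          })
        )
      })
    )
  })
  queries <- lapply(unname(profiles), function(p) {
    qs <- summ[summ$query_id == p$query_id, , drop = FALSE]
    qext <- lapply(seq_len(nrow(qs)), function(i) {
      id <- qs$integration_id[i]
      f <- annotation[annotation$integration_id == id, , drop = FALSE]
      list(id = id, target = qs$target_id[i],
           query_start = min(f$query_start), query_end = max(f$query_end),
           full_length = qs$full_length[i])
    })
    list(query_id = p$query_id, length = p$length, counts = p$counts,
         integrations = qext)
  })
  doc <- list(schema_version = "1.0", genomes = genomes, queries = queries)
  .validate_summary(doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# minimal structural validation against the shipped schema: presence and
# type of every required property, recursively over the arrays
#' @keywords internal
.validate_summary <- function(doc) {
  stopifnot(is.character(doc$schema_version), is.list(doc$genomes),
            is.list(doc$queries))
  for (g in doc$genomes) {
    stopifnot(is.character(g$target_id), is.list(g$integrations))
    for (it in g$integrations) {
      need <- c("id", "phage", "start", "end", "strand", "full_length",
                "fragments")
      miss <- setdiff(need, names(it))
      if (length(miss) > 0L) {
        stop(sprintf("summary integration record lacks field(s): %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
      }
      stopifnot(it$start <= it$end, it$strand %in% c("+", "-"),
                is.logical(it$full_length), length(it$fragments) >= 1L)
    }
  }
  for (q in doc$queries) {
    stopifnot(is.character(q$query_id), length(q$counts) == q$length,
              all(q$counts >= 0L))
  }
  invisible(TRUE)
}

#' Export integrations as BED6
#'
#' One row per integration: `chrom` = target id, 0-based half-open
#' `start`/`end` converted from the internal 1-based inclusive span, name
#' = integration id, score = `min(1000, round(best fragment score))`,
#' strand. Rows sorted by `(chrom, start)`.
#'
#' @param annotation Output of [assign_integrations()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(annotation, path) {
  summ <- integration_summary(annotation)
  bed <- data.frame(
    chrom = summ$target_id,
    start = summ$genome_start - 1L,
    end = summ$genome_end,
    name = summ$integration_id,
    score = pmin(1000, round(pmax(summ$best_score, 0))),
    strand = summ$strand,
    stringsAsFactors = FALSE
  )
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  write.table(bed, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
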