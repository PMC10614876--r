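#' Pipeline configuration: all thresholds of the annotation workflow
#'
#' Bundles the tunable thresholds used by [filter_matches()],
#' [joinable()], [assign_integrations()] and [call_full_length()].
#'
#' @param evalue_max Maximum E-value retained by match filtering
#'   (inclusive). Default `1e-5`.
#' @param gap_fraction_k Maximum gap between consecutive fragments on the
#'   bacterial genome, expressed as a fraction of the query phage length
#'   (the fragment gap threshold `k`). Default `0.25`.
#' @param max_query_overlap_theta Maximum overlap, in nucleotides, that
#'   two consecutive fragments may share on the query phage (`theta`).
#'   Gaps on the query are never penalized. Default `50`.
#' @param full_length_fraction Minimum fraction of the query phage that an
#'   integration must cover to be called full length (inclusive).
#'   Default `0.70`.
#' @param min_match_length Minimum match length on the target genome, in
#'   nucleotides; shorter matches are discarded by [filter_matches()].
#'   Default `0` (no length filtering); a stringent survey of short
#'   filamentous phages might set `1000`.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$gap_fraction_k
#' @export
pipeline_config <- function(evalue_max = 1e-5,
                            gap_fraction_k = 0.25,
                            max_query_overlap_theta = 50L,
                            full_length_fraction = 0.70,
                            min_match_length = 0L) {
  .assert_scalar_number(evalue_max, "evalue_max")
  .assert_scalar_number(gap_fraction_k, "gap_fraction_k")
  .assert_scalar_number(max_query_overlap_theta, "max_query_overlap_theta")
  .assert_scalar_number(full_length_fraction, "full_length_fraction")
  .assert_scalar_number(min_match_length, "min_match_length")
  if (evalue_max <= 0) stop("evalue_max must be > 0", call. = FALSE)
  if (gap_fraction_k <= 0) stop("gap_fraction_k must be > 0", call. = FALSE)
  if (max_query_overlap_theta < 0) {
    stop("max_query_overlap_theta must be >= 0", call. = FALSE)
  }
  if (full_length_fraction <= 0 || full_length_fraction > 1) {
    stop("full_length_fraction must be in (0, 1]", call. = FALSE)
  }
  if (min_match_length < 0) stop("min_match_length must be >= 0", call. = FALSE)
  structure(
    list(
      evalue_max = as.numeric(evalue_max),
      gap_fraction_k = as.numeric(gap_fraction_k),
      max_query_overlap_theta = as.integer(max_query_overlap_theta),
      full_length_fraction = as.numeric(full_length_fraction),
      min_match_length = as.integer(min_match_length)
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  cat(sprintf("  evalue_max:              %g\n", x$evalue_max))
  cat(sprintf("  gap_fraction_k:          %g\n", x$gap_fraction_k))
  cat(sprintf("  max_query_overlap_theta: %d nt\n", x$max_query_overlap_theta))
  cat(sprintf("  full_length_fraction:    %g\n", x$full_length_fraction))
  cat(sprintf("  min_match_length:        %d nt\n", x$min_match_length))
  invisible(x)
}
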