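# Defragmentation: filter homology matches, chain colinear fragments into
# integrations, and call full-length status from query coverage.

#' Filter matches by E-value and match length
#'
#' Retains exactly the matches with `evalue <= evalue_max` and a target
#' match length (`target_end - target_start + 1`) of at least
#' `min_match_length`. Input order is preserved and the input is not
#' modified; the operation is idempotent.
#'
#' @param matches A match table.
#' @param config A [pipeline_config()].
#' @return The retained rows of `matches`.
#' @examples
#' m <- rbind(
#'   match_record("p", 1000, "g", 1, 500, 1, 500, evalue = 1e-3),
#'   match_record("p", 1000, "g", 1, 500, 1000, 1499, evalue = 1e-6)
#' )
#' filter_matches(m, pipeline_config())
#' @export
filter_matches <- function(matches, config = pipeline_config()) {
  matches <- validate_matches(matches)
  if (nrow(matches) == 0L) return(matches)
  len <- matches$target_end - matches$target_start + 1L
  keep <- matches$evalue <= config$evalue_max & len >= config$min_match_length
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Can two consecutive matches be joined into one integration?
#'
#' Evaluates the four joining criteria for a pair of matches with `prev`
#' preceding `next_` on the target genome:
#'
#' * **A** — both matches name the same query phage, the same target
#'   genome, and the same strand;
#' * **B** — the matches occur in the same order on the query as on the
#'   genome (colinearity; mirrored on the minus strand);
#' * **Ca** — the gap on the genome is bounded: `|i - j| <= n * k`, where
#'   `i` is `prev`'s target end, `j` is `next_`'s target start, `n` the
#'   query length, and `k` the gap fraction;
#' * **Cb** — overlap on the query is bounded by `theta` nucleotides.
#'   Gaps on the query are never penalized (they may reflect large
#'   deletions in the integrated copy), so only genuine overlap counts.
#'
#' @param prev,next_ One-row match tables with
#'   `prev$target_start <= next_$target_start` (an error otherwise).
#' @param config A [pipeline_config()].
#' @return `TRUE` iff all four criteria hold.
#' @examples
#' a <- match_record("p", 12000, "g", 1, 4900, 100, 5000)
#' b <- match_record("p", 12000, "g", 4950, 6950, 7000, 9000)
#' joinable(a, b, pipeline_config())  # genome gap 2000 <= 0.25 * 12000
#' @export
joinable <- function(prev, next_, config = pipeline_config()) {
  if (prev$target_start > next_$target_start) {
    stop("joinable: 'prev' must not start after 'next_' on the target genome",
         call. = FALSE)
  }
  # A: same query, target, strand
  if (prev$query_id != next_$query_id ||
      prev$target_id != next_$target_id ||
      prev$strand != next_$strand) {
    return(FALSE)
  }
  # B: colinear order on query and genome
  if (prev$strand == "+") {
    colinear <- next_$query_start >= prev$query_start &&
      next_$query_end >= prev$query_end
  } else {
    colinear <- next_$query_end <= prev$query_end &&
      next_$query_start <= prev$query_start
  }
  if (!colinear) return(FALSE)
  # Ca: genome gap bounded by k * n
  n <- prev$query_length
  if (abs(prev$target_end - next_$target_start) > config$gap_fraction_k * n) {
    return(FALSE)
  }
  # Cb: query overlap (only) bounded by theta
  if (prev$strand == "+") {
    overlap <- prev$query_end - next_$query_start + 1L
  } else {
    overlap <- next_$query_end - prev$query_start + 1L
  }
  if (overlap > 0L && overlap > config$max_query_overlap_theta) return(FALSE)
  TRUE
}

#' Total query coverage of a set of fragments
#'
#' Length of the union of the fragments' `[query_start, query_end]`
#' intervals; positions covered by overlapping fragments count once.
#'
#' @param fragments A match table of fragments of one integration (all
#'   sharing `query_id`).
#' @return Covered query length in nucleotides.
#' @examples
#' f <- rbind(match_record("p", 1000, "g", 1, 100, 1, 100),
#'            match_record("p", 1000, "g", 51, 150, 201, 300))
#' query_coverage(f)  # 150
#' @export
query_coverage <- function(fragments) {
  if (nrow(fragments) == 0L) stop("no fragments", call. = FALSE)
  if (length(unique(fragments$query_id)) != 1L) {
    stop("fragments must share one query_id", call. = FALSE)
  }
  r <- IRanges::reduce(IRanges::IRanges(start = fragments$query_start,
                                        end = fragments$query_end))
  sum(IRanges::width(r))
}

#' Full-length call for one integration
#'
#' An integration is full length when its query coverage reaches at least
#' `full_length_fraction` of the query phage length (inclusive boundary:
#' coverage of exactly the threshold counts).
#'
#' @param fragments The integration's fragments (a match table sharing one
#'   `query_id` and `query_length`).
#' @param config A [pipeline_config()].
#' @return Logical.
#' @examples
#' f <- match_record("p", 1000, "g", 1, 700, 1, 700)
#' call_full_length(f, pipeline_config())  # 700/1000 >= 0.70
#' @export
call_full_length <- function(fragments, config = pipeline_config()) {
  n <- fragments$query_length[1L]
  query_coverage(fragments) >= config$full_length_fraction * n
}

#' Chain filtered matches into integrations
#'
#' Groups matches by `(target_id, query_id, strand)`, sorts each group by
#' `(target_start, target_end, query_start)`, and performs a greedy
#' left-to-right scan: each match is linked to the immediately preceding
#' group member iff [joinable()] holds, otherwise it starts a new chain.
#' Each chain becomes one integration; every input match lands in exactly
#' one. Integration ids are deterministic, `"<target_id>_<ordinal>"`
#' numbered along the genome.
#'
#' @param matches A filtered match table (see [filter_matches()]).
#' @param config A [pipeline_config()].
#' @return The match table with two added columns: `integration_id` and
#'   logical `full_length`, rows sorted by genome position. Use
#'   [integration_summary()] for one row per integration.
#' @export
assign_integrations <- function(matches, config = pipeline_config()) {
  matches <- validate_matches(matches)
  if (nrow(matches) == 0L) {
    out <- matches
    out$integration_id <- character(0)
    out$full_length <- logical(0)
    return(out)
  }
  ord <- order(matches$target_id, matches$query_id, matches$strand,
               matches$target_start, matches$target_end, matches$query_start)
  m <- matches[ord, , drop = FALSE]
  rownames(m) <- NULL
  grp <- paste(m$target_id, m$query_id, m$strand, sep = "\r")
  chain <- integer(nrow(m))
  chain[1L] <- 1L
  nchain <- 1L
  if (nrow(m) > 1L) {
    for (i in 2L:nrow(m)) {
      if (grp[i] == grp[i - 1L] &&
          joinable(m[i - 1L, ], m[i, ], config)) {
        chain[i] <- chain[i - 1L]
      } else {
        nchain <- nchain + 1L
        chain[i] <- nchain
      }
    }
  }
  # number chains along each target genome for stable, readable ids
  starts <- tapply(m$target_start, chain, min)
  ends <- tapply(m$target_end, chain, max)
  qid <- tapply(m$query_id, chain, `[`, 1L)
  std <- tapply(m$strand, chain, `[`, 1L)
  tid <- tapply(m$target_id, chain, `[`, 1L)
  chains <- data.frame(
    chain = as.integer(names(starts)),
    target_id = as.character(tid), start = as.integer(starts),
    end = as.integer(ends), query_id = as.character(qid),
    strand = as.character(std), stringsAsFactors = FALSE
  )
  chains <- chains[order(chains$target_id, chains$start, chains$end,
                         chains$query_id, chains$strand), , drop = FALSE]
  ordinal <- stats::ave(seq_len(nrow(chains)), chains$target_id,
                        FUN = seq_along)
  ids <- stats::setNames(paste0(chains$target_id, "_", ordinal), chains$chain)
  m$integration_id <- unname(ids[as.character(chain)])
  # full-length from the union of each chain's query intervals
  fl <- vapply(split(seq_len(nrow(m)), m$integration_id), function(idx) {
    call_full_length(m[idx, , drop = FALSE], config)
  }, logical(1))
  m$full_length <- unname(fl[m$integration_id])
  m <- m[order(m$target_id, m$target_start, m$target_end, m$query_start), ,
         drop = FALSE]
  rownames(m) <- NULL
  m
}

#' One-row-per-integration summary of an annotated match table
#'
#' @param annotation Output of [assign_integrations()] (or
#'   [read_annotation_tsv()]).
#' @return A `data.frame` with one row per integration: id, query, target,
#'   strand, genome span, fragment count, query coverage, best fragment
#'   score, and the full-length flag; sorted by genome position.
#' @export
integration_summary <- function(annotation) {
  if (nrow(annotation) == 0L) {
    return(data.frame(
      integration_id = character(0), query_id = character(0),
      target_id = character(0), strand = character(0),
      genome_start = integer(0), genome_end = integer(0),
      n_fragments = integer(0), query_coverage_nt = integer(0),
      best_score = numeric(0), full_length = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  parts <- split(seq_len(nrow(annotation)), annotation$integration_id)
  rows <- lapply(parts, function(idx) {
    f <- annotation[idx, , drop = FALSE]
    data.frame(
      integration_id = f$integration_id[1L],
      query_id = f$query_id[1L],
      target_id = f$target_id[1L],
      strand = f$strand[1L],
      genome_start = min(f$target_start),
      genome_end = max(f$target_end),
      n_fragments = nrow(f),
      query_coverage_nt = query_coverage(f),
      best_score = max(f$score),
      full_length = f$full_length[1L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$target_id, out$genome_start, out$genome_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
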