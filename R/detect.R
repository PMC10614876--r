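# Built-in naive homology detector: exact k-mer seeding on both strands,
# ungapped x-drop extension along the diagonal, and merging of
# overlapping same-diagonal hits. Deterministic; no statistical
# calibration (E-value is reported as 0 so downstream E-value filtering
# passes naive hits through).

# positions (1-based) of all k-mers of `seq` that contain no N, together
# with the k-mer strings
#' @keywords internal
.kmer_index <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(list(pos = integer(0), kmer = character(0)))
  pos <- seq_len(L - k + 1L)
  km <- substring(seq, pos, pos + k - 1L)
  ok <- !grepl("N", km, fixed = TRUE)
  list(pos = pos[ok], kmer = km[ok])
}

# x-drop extension over a +1/-1 score vector `s` (in extension order,
# starting adjacent to the seed): returns how many positions to keep
#' @keywords internal
.xdrop_extent <- function(s, xdrop) {
  if (length(s) == 0L) return(0L)
  cs <- cumsum(s)
  peak <- cummax(cs)
  stopidx <- which(peak - cs > xdrop)
  lim <- if (length(stopidx) == 0L) length(cs) else stopidx[1L]
  best <- which.max(cs[seq_len(lim)])
  if (cs[best] <= 0L) 0L else best
}

#' Naive k-mer seed-and-extend homology detection
#'
#' Finds all exact `seed_kmer`-mers shared between each query (both
#' strands) and each target contig via a k-mer index, extends each seed
#' ungapped in both directions (score +1 per match, -3 per mismatch, the
#' usual nucleotide seed-extension weights) until the running score drops
#' `xdrop` below its maximum, trims each extension to its
#' maximum-scoring extent, and merges hits that lie on the same
#' (query, genome) diagonal with overlapping extents. `N` never matches.
#' Reported scores are match-minus-mismatch counts over the final
#' extent; E-values are reported as 0.
#'
#' This detector has no sensitivity to diverged sequence beyond what
#' exact seeds provide; it exists so the full annotation pipeline runs
#' offline, not as a replacement for a profile-HMM search.
#'
#' @param genome Target catalog (a `DNAStringSet` or named character
#'   vector; one entry per contig).
#' @param queries Query catalog with residues.
#' @param seed_kmer Seed length in nucleotides (>= 4). Default 15.
#' @param xdrop Extension termination threshold in score units. Default 20.
#' @param min_score Minimum score of a reported hit. Because naive hits
#'   carry no E-value, this reporting floor plays the role a significance
#'   threshold plays for a calibrated search tool: it suppresses the
#'   short chance hits that a lone shared k-mer produces. Default
#'   `2 * seed_kmer`.
#' @return A match table, coordinates normalized as in the rest of the
#'   package (`target_start <= target_end`; minus-strand hits carry
#'   `strand = "-"` with query coordinates on the query forward strand),
#'   `source = "naive"`.
#' @export
naive_detect <- function(genome, queries, seed_kmer = 15L, xdrop = 20L,
                         min_score = 2L * seed_kmer) {
  if (seed_kmer < 4L) stop("seed_kmer must be >= 4", call. = FALSE)
  gseqs <- .cat_seqs(genome)
  qseqs <- .cat_seqs(queries)
  k <- as.integer(seed_kmer)
  out <- list()
  for (tid in names(gseqs)) {
    g <- gseqs[[tid]]
    gidx <- .kmer_index(g, k)
    if (length(gidx$pos) == 0L) next
    graw <- charToRaw(g)
    gN <- graw == charToRaw("N")
    for (qid in names(qseqs)) {
      qfwd <- qseqs[[qid]]
      nq <- nchar(qfwd)
      for (strand in c("+", "-")) {
        qs <- if (strand == "+") qfwd else revcomp(qfwd)
        hits <- .scan_one(g, graw, gN, gidx, qs, k, xdrop)
        if (is.null(hits) || nrow(hits) == 0L) next
        hits <- hits[hits$score >= min_score, , drop = FALSE]
        if (nrow(hits) == 0L) next
        if (strand == "+") {
          q1 <- hits$qstart
          q2 <- hits$qend
        } else {
          q1 <- nq - hits$qend + 1L
          q2 <- nq - hits$qstart + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          query_id = qid, query_length = nq, target_id = tid,
          evalue = 0, score = as.numeric(hits$score),
          query_start = q1, query_end = q2,
          target_start = hits$tstart, target_end = hits$tend,
          strand = strand, source = "naive",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) return(empty_matches())
  m <- do.call(rbind, out)
  m <- m[order(m$target_id, m$target_start, m$target_end, m$query_id), ,
         drop = FALSE]
  rownames(m) <- NULL
  validate_matches(m)
}

# scan one (genome, oriented-query) pair; coordinates returned on the
# oriented query (caller maps back to the forward strand)
#' @keywords internal
.scan_one <- function(g, graw, gN, gidx, qs, k, xdrop) {
  nq <- nchar(qs)
  ng <- nchar(g)
  qidx <- .kmer_index(qs, k)
  if (length(qidx$pos) == 0L) return(NULL)
  shared <- gidx$kmer %in% qidx$kmer
  if (!any(shared)) return(NULL)
  gpos <- gidx$pos[shared]
  gkm <- gidx$kmer[shared]
  qmap <- split(qidx$pos, qidx$kmer)
  qhits <- qmap[gkm]
  reps <- lengths(qhits)
  gpos_all <- rep(gpos, reps)
  qpos_all <- unlist(qhits, use.names = FALSE)
  diag_all <- gpos_all - qpos_all
  qraw <- charToRaw(qs)
  qN <- qraw == charToRaw("N")
  rows <- list()
  for (d in unique(diag_all)) {
    qseed <- sort(qpos_all[diag_all == d])
    # merge seed start positions into maximal exact runs
    run_start <- qseed[c(TRUE, diff(qseed) > k)]
    run_end <- qseed[c(diff(qseed) > k, TRUE)] + k - 1L
    # valid query extent of this diagonal
    qlo <- max(1L, 1L - d)
    qhi <- min(nq, ng - d)
    mvec_at <- function(idx) {
      ok <- graw[idx + d] == qraw[idx] & !gN[idx + d] & !qN[idx]
      ifelse(ok, 1L, -1L)
    }
    # extension trimming scores +1 / -3 (the ungapped-nucleotide-search
    # convention): the strong mismatch penalty keeps the max-scoring
    # extent anchored to genuinely similar sequence instead of letting a
    # weakly positive random walk creep past a copy boundary
    ext_score <- function(s) ifelse(s > 0L, 1L, -3L)
    ext <- lapply(seq_along(run_start), function(r) {
      a <- run_start[r]
      b <- run_end[r]
      if (b + 1L <= qhi) {
        s <- ext_score(mvec_at((b + 1L):qhi))
        b <- b + .xdrop_extent(s, xdrop)
      }
      if (a - 1L >= qlo) {
        s <- ext_score(mvec_at(rev(qlo:(a - 1L))))
        a <- a - .xdrop_extent(s, xdrop)
      }
      c(a, b)
    })
    ex <- do.call(rbind, ext)
    merged <- IRanges::reduce(IRanges::IRanges(start = ex[, 1], end = ex[, 2]))
    for (i in seq_along(merged)) {
      a <- IRanges::start(merged)[i]
      b <- IRanges::end(merged)[i]
      sc <- sum(mvec_at(a:b))
      rows[[length(rows) + 1L]] <- data.frame(
        qstart = a, qend = b, tstart = a + d, tend = b + d, score = sc
      )
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}
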