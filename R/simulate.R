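# Synthetic genomes with planted prophage integrations and ground truth.
# The mutation model is substitution-only, so every truth coordinate is
# exact; fragmented plantings (query split around a background spacer)
# exercise the genome-gap and query-overlap joining criteria instead.

#' Simulation configuration
#'
#' @param genome_length Background genome length in nucleotides. The
#'   default, 100 kb, is a genomic segment large enough to hold several
#'   well-separated phage-scale insertions while keeping simulation and
#'   detection fast.
#' @param gc_fraction GC content of background (and generated query)
#'   sequence, in `[0, 1]`.
#' @param n_queries,query_length Number and length of generated query
#'   phages; 10 kb matches the scale of filamentous (Inovirus-like)
#'   prophages.
#' @param n_integrations Number of planted integrations per genome.
#' @param mode_probs Named probabilities for the three planting modes
#'   `full`, `truncated`, `fragmented`; must sum to 1.
#' @param truncation_range Range of the fraction of the query retained by
#'   a truncated planting (straddles the 0.70 full-length boundary by
#'   default, so both labels occur).
#' @param spacer_fraction Length of the background spacer inserted at the
#'   split point of a fragmented planting, as a fraction of query length.
#'   The default 0.10 is below the default joining gap fraction 0.25, so
#'   such plantings should be rejoined; set it above 0.25 to create
#'   deliberate negative controls.
#' @param split_overlap_nt Query overlap (positive) or gap (negative) of
#'   the two pieces at the split point of a fragmented planting, in
#'   nucleotides; exercises the query-overlap cap.
#' @param minus_strand_prob Probability a planting goes on the minus
#'   strand (reverse complement inserted).
#' @param substitution_rate Per-base substitution probability applied to
#'   planted query material (never to the background or spacers).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L,
                       gc_fraction = 0.5,
                       n_queries = 2L,
                       query_length = 10000L,
                       n_integrations = 3L,
                       mode_probs = c(full = 0.4, truncated = 0.3,
                                      fragmented = 0.3),
                       truncation_range = c(0.2, 0.9),
                       spacer_fraction = 0.10,
                       split_overlap_nt = 0L,
                       minus_strand_prob = 0.5,
                       substitution_rate = 0,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  stopifnot(genome_length >= 0, gc_fraction >= 0, gc_fraction <= 1,
            n_queries >= 1, query_length >= 1, n_integrations >= 0,
            length(mode_probs) == 3L,
            all(sort(names(mode_probs)) == c("fragmented", "full", "truncated")),
            abs(sum(mode_probs) - 1) < 1e-9,
            length(truncation_range) == 2L,
            truncation_range[1] > 0, truncation_range[2] <= 1,
            truncation_range[1] <= truncation_range[2],
            spacer_fraction >= 0,
            minus_strand_prob >= 0, minus_strand_prob <= 1,
            substitution_rate >= 0, substitution_rate <= 1)
  structure(
    list(genome_length = as.integer(genome_length),
         gc_fraction = gc_fraction,
         n_queries = as.integer(n_queries),
         query_length = as.integer(query_length),
         n_integrations = as.integer(n_integrations),
         mode_probs = mode_probs[c("full", "truncated", "fragmented")],
         truncation_range = truncation_range,
         spacer_fraction = spacer_fraction,
         split_overlap_nt = as.integer(split_overlap_nt),
         minus_strand_prob = minus_strand_prob,
         substitution_rate = substitution_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate random background DNA
#'
#' I.i.d. bases with `P(G) + P(C) = gc_fraction`, split evenly within the
#' GC and AT pairs.
#'
#' @param length Sequence length (0 gives the empty string).
#' @param gc_fraction GC content in `[0, 1]`.
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return A DNA character string.
#' @export
generate_background <- function(length, gc_fraction = 0.5, seed = NULL) {
  stopifnot(length >= 0, gc_fraction >= 0, gc_fraction <= 1)
  if (length == 0L) return("")
  .with_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
           gc_fraction / 2, (1 - gc_fraction) / 2)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Apply point substitutions to a DNA string
#'
#' Each `A`/`C`/`G`/`T` base is independently replaced by one of the
#' three other bases, chosen uniformly, with probability `rate`; `N`
#' bases are left untouched. Length is preserved (no indels), so
#' coordinates into the mutated sequence stay valid.
#'
#' @param seq DNA character string.
#' @param rate Substitution probability per base, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return The mutated string.
#' @export
mutate_seq <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || nchar(seq) == 0L) return(seq)
  .with_seed(seed, {
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- runif(length(bases)) < rate & bases %in% c("A", "C", "G", "T")
    if (any(hit)) {
      alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
      idx <- which(hit)
      pick <- sample.int(3L, length(idx), replace = TRUE)
      bases[idx] <- vapply(seq_along(idx), function(i) {
        alt[[bases[idx[i]]]][pick[i]]
      }, character(1))
    }
    paste(bases, collapse = "")
  })
}

# Build the insert sequence and its truth pieces for one planting.
# Returns list(insert = string, pieces = data.frame(rel_start, rel_end,
# query_start, query_end)) with rel coords 1-based on the insert, already
# in genome (insert) order.
#' @keywords internal
.build_insert <- function(qseq, mode, strand, config) {
  n <- nchar(qseq)
  rate <- config$substitution_rate
  if (mode == "full") {
    ins <- mutate_seq(qseq, rate)
    pieces <- data.frame(rel_start = 1L, rel_end = n,
                         query_start = 1L, query_end = n)
  } else if (mode == "truncated") {
    f <- runif(1, config$truncation_range[1], config$truncation_range[2])
    len <- max(1L, as.integer(round(f * n)))
    qs <- sample.int(n - len + 1L, 1L)
    ins <- mutate_seq(substr(qseq, qs, qs + len - 1L), rate)
    pieces <- data.frame(rel_start = 1L, rel_end = len,
                         query_start = qs, query_end = qs + len - 1L)
  } else { # fragmented: piece1 + background spacer + piece2
    cpos <- as.integer(round(runif(1, 0.35, 0.65) * n))
    p2s <- cpos - config$split_overlap_nt + 1L
    p2s <- max(1L, min(p2s, n))
    sp_len <- as.integer(round(config$spacer_fraction * n))
    spacer <- generate_background(sp_len, config$gc_fraction)
    p1 <- mutate_seq(substr(qseq, 1L, cpos), rate)
    p2 <- mutate_seq(substr(qseq, p2s, n), rate)
    ins <- paste0(p1, spacer, p2)
    pieces <- data.frame(
      rel_start = c(1L, cpos + sp_len + 1L),
      rel_end = c(cpos, cpos + sp_len + (n - p2s + 1L)),
      query_start = c(1L, p2s),
      query_end = c(cpos, n)
    )
  }
  if (strand == "-") {
    L <- nchar(ins)
    ins <- revcomp(ins)
    new_start <- L - pieces$rel_end + 1L
    new_end <- L - pieces$rel_start + 1L
    pieces$rel_start <- new_start
    pieces$rel_end <- new_end
    pieces <- pieces[order(pieces$rel_start), , drop = FALSE]
  }
  list(insert = ins, pieces = pieces)
}

#' Plant prophage integrations into a background genome
#'
#' Inserts (never overwrites) copies of query phages into the background:
#' full copies, truncated contiguous slices, or split copies with a
#' random background spacer between the two pieces. Minus-strand
#' plantings insert the reverse complement. Insertion points are kept at
#' least `0.3 * query_length` apart so independent plantings remain
#' distinguishable by the downstream gap criterion.
#'
#' @param background Background DNA string (must be long enough to hold
#'   the planted material and keep the separations).
#' @param queries Query catalog with residues (`DNAStringSet` or named
#'   character vector).
#' @param config A [sim_config()] (only its per-planting fields are used;
#'   the RNG uses the current stream — seed at the caller, e.g. via
#'   [simulate_dataset()]).
#' @param target_id Name recorded for the simulated genome.
#' @return A list with `genome` (DNA string) and `truth` (a `data.frame`,
#'   one row per truth piece, with columns `truth_id, query_id, target_id,
#'   strand, genome_start, genome_end, query_start, query_end,
#'   expected_full_length`). All genome coordinates refer to the final
#'   genome; `expected_full_length` applies the 70% rule to the union of
#'   the planting's source query intervals.
#' @export
plant_integrations <- function(background, queries, config,
                               target_id = "sim_genome") {
  qseqs <- .cat_seqs(queries)
  bg_n <- nchar(background)
  k <- config$n_integrations
  if (k == 0L) {
    return(list(genome = background, truth = .empty_truth()))
  }
  qids <- sample(names(qseqs), k, replace = TRUE)
  modes <- sample(names(config$mode_probs), k, replace = TRUE,
                  prob = config$mode_probs)
  strands <- ifelse(runif(k) < config$minus_strand_prob, "-", "+")
  built <- lapply(seq_len(k), function(i) {
    .build_insert(qseqs[[qids[i]]], modes[i], strands[i], config)
  })
  total_ins <- sum(vapply(built, function(b) nchar(b$insert), numeric(1)))
  if (total_ins > bg_n) {
    stop("background too short for the planted material", call. = FALSE)
  }
  # well-separated insertion points (deterministic rejection sampling)
  min_sep <- as.integer(ceiling(0.3 * max(nchar(qseqs))))
  points <- NULL
  for (try in seq_len(1000L)) {
    cand <- sort(sample.int(bg_n - 1L, k))
    if (k == 1L || all(diff(cand) >= min_sep)) {
      points <- cand
      break
    }
  }
  if (is.null(points)) {
    stop("background too short to separate the planted integrations",
         call. = FALSE)
  }
  parts <- character(2L * k + 1L)
  truth_rows <- vector("list", k)
  prev_point <- 0L
  offset <- 0L
  for (i in seq_len(k)) {
    parts[2L * i - 1L] <- substr(background, prev_point + 1L, points[i])
    parts[2L * i] <- built[[i]]$insert
    abs_start <- points[i] + offset
    p <- built[[i]]$pieces
    qlen <- nchar(qseqs[[qids[i]]])
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = p$query_start, end = p$query_end))))
    truth_rows[[i]] <- data.frame(
      truth_id = sprintf("truth_%d", i),
      query_id = qids[i],
      target_id = target_id,
      strand = strands[i],
      genome_start = abs_start + p$rel_start,
      genome_end = abs_start + p$rel_end,
      query_start = p$query_start,
      query_end = p$query_end,
      expected_full_length = cov >= 0.70 * qlen,
      stringsAsFactors = FALSE
    )
    offset <- offset + nchar(built[[i]]$insert)
    prev_point <- points[i]
  }
  parts[2L * k + 1L] <- substr(background, prev_point + 1L, bg_n)
  list(genome = paste(parts, collapse = ""),
       truth = do.call(rbind, truth_rows))
}

#' @keywords internal
.empty_truth <- function() {
  data.frame(truth_id = character(0), query_id = character(0),
             target_id = character(0), strand = character(0),
             genome_start = integer(0), genome_end = integer(0),
             query_start = integer(0), query_end = integer(0),
             expected_full_length = logical(0), stringsAsFactors = FALSE)
}

#' Write / read the simulator ground-truth TSV
#'
#' One row per truth piece; pieces of one fragmented planting share a
#' `truth_id`. `expected_full_length` uses the `"True"`/`"False"`
#' literals of the annotation TSV. `read_truth_tsv` is the exact inverse.
#'
#' @param truth Truth `data.frame` from [plant_integrations()].
#' @param path File path.
#' @return `path` (write) / the truth `data.frame` (read), invisibly for
#'   the writer.
#' @export
write_truth_tsv <- function(truth, path) {
  out <- truth
  out$expected_full_length <- ifelse(truth$expected_full_length,
                                     "True", "False")
  write.table(out, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- names(.empty_truth())
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop(sprintf("truth TSV lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  x$expected_full_length <- x$expected_full_length == "True"
  for (col in c("genome_start", "genome_end", "query_start", "query_end")) {
    x[[col]] <- as.integer(x[[col]])
  }
  x[, need, drop = FALSE]
}

#' Simulate a full dataset to disk
#'
#' Generates query phages and a background genome, plants integrations,
#' and writes `genome.fasta`, `queries.fasta`, `truth.tsv`, and a
#' `manifest.json` into `out_dir`. Byte-identical for identical
#' configurations (the seed fully determines the output).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths, the truth table, and
#'   the catalogs.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- .with_seed(config$seed, {
    queries <- stats::setNames(
      vapply(seq_len(config$n_queries), function(i) {
        generate_background(config$query_length, config$gc_fraction)
      }, character(1)),
      sprintf("phage_%d", seq_len(config$n_queries))
    )
    background <- generate_background(config$genome_length, config$gc_fraction)
    planted <- plant_integrations(background, queries, config,
                                  target_id = "sim_genome_1")
    c(planted, list(queries = queries))
  })
  genome_path <- file.path(out_dir, "genome.fasta")
  queries_path <- file.path(out_dir, "queries.fasta")
  truth_path <- file.path(out_dir, "truth.tsv")
  manifest_path <- file.path(out_dir, "manifest.json")
  gset <- Biostrings::DNAStringSet(stats::setNames(res$genome, "sim_genome_1"))
  Biostrings::writeXStringSet(gset, genome_path, width = 80L)
  qset <- Biostrings::DNAStringSet(res$queries)
  Biostrings::writeXStringSet(qset, queries_path, width = 80L)
  write_truth_tsv(res$truth, truth_path)
  manifest <- list(
    tool = "prophagr", version = as.character(packageVersion("prophagr")),
    command = "simulate",
    config = unclass(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = list(genome = genome_path, queries = queries_path,
                   truth = truth_path)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  pf_log("INFO", "simulate",
         sprintf("wrote %d planting(s) into %s", config$n_integrations, out_dir))
  invisible(list(genome = genome_path, queries = queries_path,
                 truth = truth_path, manifest = manifest_path,
                 truth_table = res$truth,
                 genome_seq = gset, query_seqs = qset))
}
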