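# Match tables: the internal data model for homology hits, plus parsers
# for the standard tabular hit formats and the TSV annotation format.

# canonical column order of a match table
MATCH_COLUMNS <- c("query_id", "query_length", "target_id", "evalue", "score",
                   "query_start", "query_end", "target_start", "target_end",
                   "strand", "source")

ANNOTATION_TSV_COLUMNS <- c("phage_name", "evalue", "score",
                            "query_start", "query_end", "target_name",
                            "target_start", "target_end", "strand",
                            "integration_id", "full_length")

#' Construct a one-row match table
#'
#' A match is one homology hit of a query phage against a target genome.
#' Coordinates are 1-based inclusive on the forward strand of each
#' sequence, with `query_start <= query_end` and
#' `target_start <= target_end` always; minus-strand hits carry
#' `strand = "-"` instead of reversed coordinates.
#'
#' @param query_id Query phage name.
#' @param query_length Query phage length in nucleotides.
#' @param target_id Target genome / contig name.
#' @param query_start,query_end 1-based inclusive query coordinates.
#' @param target_start,target_end 1-based inclusive target coordinates.
#' @param strand `"+"` or `"-"`.
#' @param evalue Hit E-value (>= 0).
#' @param score Hit score in bits (or detector-specific units).
#' @param source Free-text detector name.
#' @return A one-row `data.frame` with the match-table columns.
#' @examples
#' match_record("phageA", 10000, "genome1",
#'              query_start = 1, query_end = 4000,
#'              target_start = 20001, target_end = 24000)
#' @export
match_record <- function(query_id, query_length, target_id,
                         query_start, query_end,
                         target_start, target_end,
                         strand = "+", evalue = 0, score = 0,
                         source = "manual") {
  m <- data.frame(
    query_id = as.character(query_id),
    query_length = as.integer(query_length),
    target_id = as.character(target_id),
    evalue = as.numeric(evalue),
    score = as.numeric(score),
    query_start = as.integer(query_start),
    query_end = as.integer(query_end),
    target_start = as.integer(target_start),
    target_end = as.integer(target_end),
    strand = as.character(strand),
    source = as.character(source),
    stringsAsFactors = FALSE
  )
  validate_matches(m)
}

#' @keywords internal
empty_matches <- function() {
  data.frame(
    query_id = character(0), query_length = integer(0),
    target_id = character(0), evalue = numeric(0), score = numeric(0),
    query_start = integer(0), query_end = integer(0),
    target_start = integer(0), target_end = integer(0),
    strand = character(0), source = character(0),
    stringsAsFactors = FALSE
  )
}

#' Validate a match table
#'
#' Checks the match-table invariants: required columns present, strands in
#' `{+, -}`, non-negative E-values, and ordered 1-based coordinates with
#' `query_end <= query_length`.
#'
#' @param matches A match-table `data.frame`.
#' @return The input, invisibly usable, after validation (errors otherwise).
#' @export
validate_matches <- function(matches) {
  missing_cols <- setdiff(MATCH_COLUMNS, names(matches))
  if (length(missing_cols) > 0L) {
    stop(sprintf("match table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(matches) == 0L) return(matches[, MATCH_COLUMNS])
  with(matches, {
    if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
    if (any(evalue < 0)) stop("evalue must be >= 0", call. = FALSE)
    if (any(query_start < 1L | query_start > query_end)) {
      stop("need 1 <= query_start <= query_end", call. = FALSE)
    }
    if (any(query_end > query_length)) {
      stop("query_end exceeds query_length", call. = FALSE)
    }
    if (any(target_start < 1L | target_start > target_end)) {
      stop("need 1 <= target_start <= target_end", call. = FALSE)
    }
  })
  matches[, MATCH_COLUMNS]
}

# resolve query lengths from a catalog, erroring on unknown ids
#' @keywords internal
.lookup_query_length <- function(query_ids, catalog, context) {
  lens <- .cat_lengths(catalog)
  unknown <- setdiff(unique(query_ids), names(lens))
  if (length(unknown) > 0L) {
    stop(sprintf("%s: query id(s) absent from catalog: %s", context,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  as.integer(lens[query_ids])
}

#' Parse an nhmmer tabular hits file ("tblout")
#'
#' Reads the whitespace-delimited per-hit summary table written by
#' `nhmmer --tblout`. In this workflow's dialect the query is the phage
#' and the target is the bacterial genome: query coordinates come from the
#' `hmmfrom`/`hmm to` columns and target coordinates from
#' `alifrom`/`ali to`. Minus-strand rows (target from > to) are normalized
#' so that `target_start < target_end` with `strand = "-"`.
#'
#' @param path Path to the tblout file. Lines starting with `#` are
#'   comments.
#' @param catalog Query-phage catalog (see [read_fasta()]) supplying
#'   query lengths; the tblout format itself does not carry them. Rows
#'   referencing query ids absent from the catalog are an error.
#' @return A match table (`data.frame`), one row per hit,
#'   `source = "nhmmer"`.
#' @export
parse_nhmmer_tblout <- function(path, catalog) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) return(empty_matches())
  rows <- lapply(keep, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 15L) {
      stop(sprintf("malformed tblout row at line %d: %d column(s), need >= 15",
                   i, length(tok)), call. = FALSE)
    }
    ev <- suppressWarnings(as.numeric(tok[13]))
    sc <- suppressWarnings(as.numeric(tok[14]))
    if (is.na(ev) || is.na(sc)) {
      stop(sprintf("malformed tblout row at line %d: non-numeric E-value/score", i),
           call. = FALSE)
    }
    list(target_id = tok[1], query_id = tok[3],
         hmmfrom = as.integer(tok[5]), hmmto = as.integer(tok[6]),
         alifrom = as.integer(tok[7]), alito = as.integer(tok[8]),
         strand = tok[12], evalue = ev, score = sc)
  })
  target_id <- vapply(rows, `[[`, character(1), "target_id")
  query_id <- vapply(rows, `[[`, character(1), "query_id")
  strand <- vapply(rows, `[[`, character(1), "strand")
  alifrom <- vapply(rows, `[[`, integer(1), "alifrom")
  alito <- vapply(rows, `[[`, integer(1), "alito")
  if (!all(strand %in% c("+", "-"))) {
    stop("tblout strand column must be '+' or '-'", call. = FALSE)
  }
  m <- data.frame(
    query_id = query_id,
    query_length = .lookup_query_length(query_id, catalog, "parse_nhmmer_tblout"),
    target_id = target_id,
    evalue = vapply(rows, `[[`, numeric(1), "evalue"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    query_start = pmin(vapply(rows, `[[`, integer(1), "hmmfrom"),
                       vapply(rows, `[[`, integer(1), "hmmto")),
    query_end = pmax(vapply(rows, `[[`, integer(1), "hmmfrom"),
                     vapply(rows, `[[`, integer(1), "hmmto")),
    target_start = pmin(alifrom, alito),
    target_end = pmax(alifrom, alito),
    strand = strand,
    source = "nhmmer",
    stringsAsFactors = FALSE
  )
  validate_matches(m)
}

#' Parse a BLAST 12-column tabular hits file (outfmt 6)
#'
#' Columns: `qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`, tab-separated, query = phage. Strand is
#' inferred from `sstart > send`; coordinates are normalized so
#' `target_start < target_end`.
#'
#' @param path Path to the tabular file; an empty file yields an empty
#'   match table.
#' @param catalog Query-phage catalog supplying query lengths (required).
#' @return A match table, `source = "blast"`.
#' @export
parse_blast_tab <- function(path, catalog) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) return(empty_matches())
  tok <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(tok) < 12L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed BLAST row at line %d: %d column(s), need 12",
                 keep[bad[1]], lengths(tok)[bad[1]]), call. = FALSE)
  }
  col <- function(j) vapply(tok, `[[`, character(1), j)
  ev <- suppressWarnings(as.numeric(col(11)))
  if (anyNA(ev)) {
    stop(sprintf("malformed BLAST row at line %d: non-numeric E-value",
                 keep[which(is.na(ev))[1]]), call. = FALSE)
  }
  sstart <- as.integer(col(9))
  send <- as.integer(col(10))
  query_id <- col(1)
  m <- data.frame(
    query_id = query_id,
    query_length = .lookup_query_length(query_id, catalog, "parse_blast_tab"),
    target_id = col(2),
    evalue = ev,
    score = as.numeric(col(12)),
    query_start = as.integer(col(7)),
    query_end = as.integer(col(8)),
    target_start = pmin(sstart, send),
    target_end = pmax(sstart, send),
    strand = ifelse(sstart > send, "-", "+"),
    source = "blast",
    stringsAsFactors = FALSE
  )
  validate_matches(m)
}

#' Write the TSV annotation table
#'
#' One row per fragment (match); fragments joined into one integration
#' share an `integration_id` and a `full_length` value, written as the
#' literals `"True"`/`"False"`. Columns, in order: `phage_name, evalue,
#' score, query_start, query_end, target_name, target_start, target_end,
#' strand, integration_id, full_length`. All coordinates are 1-based
#' inclusive. Rows are sorted by `(target_name, target_start)`.
#'
#' @param annotation Annotated match table as returned by
#'   [assign_integrations()] (match columns plus `integration_id` and
#'   logical `full_length`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  required <- c(MATCH_COLUMNS, "integration_id", "full_length")
  missing_cols <- setdiff(setdiff(required, c("query_length", "source")),
                          names(annotation))
  if (length(missing_cols) > 0L) {
    stop(sprintf("annotation lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    phage_name = annotation$query_id,
    evalue = annotation$evalue,
    score = annotation$score,
    query_start = annotation$query_start,
    query_end = annotation$query_end,
    target_name = annotation$target_id,
    target_start = annotation$target_start,
    target_end = annotation$target_end,
    strand = annotation$strand,
    integration_id = annotation$integration_id,
    full_length = ifelse(annotation$full_length, "True", "False"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$target_name, out$target_start, out$target_end), ,
             drop = FALSE]
  write.table(out, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the TSV annotation table back
#'
#' Inverse of [write_annotation_tsv()]: reconstructs the annotated match
#' table, with `full_length` as a logical and integration grouping given
#' by `integration_id` (row order in the file is immaterial). The
#' `query_length` and `source` fields are not stored in the TSV and come
#' back as `NA`/`"tsv"`.
#'
#' @param path Path to a file written by [write_annotation_tsv()].
#' @return An annotated match table `data.frame`.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  unknown <- setdiff(names(x), ANNOTATION_TSV_COLUMNS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown annotation column(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing_cols <- setdiff(ANNOTATION_TSV_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing annotation column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ann <- data.frame(
    query_id = as.character(x$phage_name),
    query_length = rep(NA_integer_, nrow(x)),
    target_id = as.character(x$target_name),
    evalue = as.numeric(x$evalue),
    score = as.numeric(x$score),
    query_start = as.integer(x$query_start),
    query_end = as.integer(x$query_end),
    target_start = as.integer(x$target_start),
    target_end = as.integer(x$target_end),
    strand = as.character(x$strand),
    source = rep("tsv", nrow(x)),
    integration_id = as.character(x$integration_id),
    full_length = x$full_length == "True",
    stringsAsFactors = FALSE
  )
  ann[order(ann$target_id, ann$target_start, ann$target_end), , drop = FALSE]
}
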