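#' Read a FASTA file into a sequence catalog
#'
#' Reads a (possibly multi-record, possibly line-wrapped) FASTA file and
#' returns a [Biostrings::DNAStringSet]. Record ids are the first
#' whitespace-delimited token of each header. Residues are upper-cased and
#' any character outside `A`, `C`, `G`, `T`, `N` (e.g. IUPAC ambiguity
#' codes, `U`) is replaced by `N` with a warning giving the count.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`; `names()` are the ids and
#'   `Biostrings::width()` the sequence lengths.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">q1 some description", "ACGT", "acgt"), fa)
#' cat <- read_fasta(fa)
#' names(cat)
#' Biostrings::width(cat)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no sequences in FASTA file", call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  seqs <- toupper(as.character(x))
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", seqs),
                      function(m) if (m[1] == -1L) 0L else length(m),
                      integer(1)))
  if (n_bad > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(sprintf("%d residue(s) outside {A,C,G,T,N} replaced with N", n_bad),
            call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf("empty sequence record(s): %s",
                 paste(ids[nchar(seqs) == 0L], collapse = ", ")), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Reverse-complement a DNA string
#'
#' @param seq A single character string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement as a character string.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Accept a DNAStringSet, a named character vector of sequences, or a named
# integer vector of lengths; return named integer lengths.
#' @keywords internal
.cat_lengths <- function(catalog) {
  if (methods::is(catalog, "XStringSet")) {
    stats::setNames(Biostrings::width(catalog), names(catalog))
  } else if (is.character(catalog)) {
    stats::setNames(nchar(catalog), names(catalog))
  } else if (is.numeric(catalog)) {
    stats::setNames(as.integer(catalog), names(catalog))
  } else {
    stop("catalog must be a DNAStringSet, named character vector of sequences, ",
         "or named integer vector of lengths", call. = FALSE)
  }
}

# Residues as a named character vector; errors if only lengths are known.
#' @keywords internal
.cat_seqs <- function(catalog) {
  if (methods::is(catalog, "XStringSet")) {
    stats::setNames(as.character(catalog), names(catalog))
  } else if (is.character(catalog)) {
    catalog
  } else {
    stop("catalog carries no residues (lengths only)", call. = FALSE)
  }
}
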