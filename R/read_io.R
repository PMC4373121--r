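#' @useDynLib kmerqc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a read set
#'
#' A read set is the package's container for raw sequencing reads: parallel
#' vectors of identifiers and symbol strings, tagged with a single alphabet.
#' Base-space reads use symbols `A,C,G,T,N`; colour-space (SOLiD) reads use
#' colour calls `0,1,2,3` with `.` marking a missing call. Colour reads carry
#' the primer base of each read (stripped from the symbol string) so that
#' decoding back to base space remains possible.
#'
#' @param read_id character vector of read identifiers.
#' @param symbols character vector of symbol strings, same length as
#'   `read_id`.
#' @param alphabet `"base"` or `"colour"`.
#' @param primer for colour reads, the per-read primer base (single
#'   character); ignored for base reads.
#' @return An object of class `read_set`.
#' @export
read_set <- function(read_id, symbols, alphabet = c("base", "colour"),
                     primer = NULL) {
  alphabet <- match.arg(alphabet)
  read_id <- as.character(read_id)
  symbols <- as.character(symbols)
  if (length(read_id) != length(symbols))
    stop("read_id and symbols must have the same length")
  if (alphabet == "base") {
    bad <- grepl("[^ACGTN]", symbols)
    if (any(bad))
      stop("base reads may only contain A,C,G,T,N; offending read: ",
           read_id[which(bad)[1L]])
    primer <- NULL
  } else {
    bad <- grepl("[^0123.]", symbols)
    if (any(bad))
      stop("colour reads may only contain 0,1,2,3,.; offending read: ",
           read_id[which(bad)[1L]])
    if (!is.null(primer)) {
      primer <- as.character(primer)
      if (length(primer) != length(symbols))
        stop("primer must have one base per read")
    }
  }
  structure(list(read_id = read_id, symbols = symbols, alphabet = alphabet,
                 primer = primer),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$symbols)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d %s-space read(s)\n", length(x), x$alphabet))
  if (length(x) > 0) {
    n <- min(length(x), 5L)
    for (i in seq_len(n))
      cat(sprintf("  %s  %s\n", x$read_id[i],
                  if (nchar(x$symbols[i]) > 50)
                    paste0(substr(x$symbols[i], 1, 50), "...")
                  else x$symbols[i]))
    if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  }
  invisible(x)
}

#' @export
`[.read_set` <- function(x, i) {
  out <- read_set(x$read_id[i], x$symbols[i], x$alphabet,
                  primer = if (!is.null(x$primer)) x$primer[i])
  if (!is.null(x$provenance)) out$provenance <- x$provenance[i]
  out
}

#' Read configuration for preprocessing raw reads
#'
#' Houses the read-level cleaning rules applied before k-mer counting:
#' colour reads with missing calls (`.`) are discarded and all reads are
#' trimmed to a fixed length (35 symbols by default, the read length the
#' method was designed around). Reads already shorter than `trim_length` are
#' kept at native length unless `drop_short` is set.
#'
#' @param trim_length positive integer; reads are truncated to this many
#'   symbols (default 35).
#' @param discard_incomplete_colour drop colour reads containing `.`
#'   (default `TRUE`).
#' @param drop_short also discard reads shorter than `trim_length`
#'   (default `FALSE`: short reads are retained untrimmed).
#' @return An object of class `read_preprocess_config`.
#' @export
read_preprocess_config <- function(trim_length = 35L,
                                   discard_incomplete_colour = TRUE,
                                   drop_short = FALSE) {
  trim_length <- as.integer(trim_length)
  if (is.na(trim_length) || trim_length < 1L)
    stop("trim_length must be a positive integer")
  structure(list(trim_length = trim_length,
                 discard_incomplete_colour = isTRUE(discard_incomplete_colour),
                 drop_short = isTRUE(drop_short)),
            class = "read_preprocess_config")
}

#' Parse a FASTA file into a read set
#'
#' Multi-line (wrapped) records are concatenated; symbols are uppercased and
#' tagged as base-space. Gzip-compressed files are accepted.
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @return A base-alphabet [read_set()].
#' @export
parse_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  read_set(ids, toupper(as.character(set)), "base")
}

#' Parse a FASTQ file into a read set
#'
#' Four-line records; quality strings are read and discarded — the method
#' uses sequence composition only. Gzip-compressed files are accepted.
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return A base-alphabet [read_set()].
#' @export
parse_fastq <- function(path) {
  con <- file(path, "rt")
  lines <- readLines(con, warn = FALSE)
  close(con)
  while (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in '", path,
         "': record count is not a multiple of 4 lines")
  if (length(lines)) {
    hdr <- seq(1L, length(lines), by = 4L)
    if (any(!startsWith(lines[hdr], "@")) ||
        any(!startsWith(lines[hdr + 2L], "+")))
      stop("malformed FASTQ in '", path,
           "': record structure broken (expect @, sequence, +, quality)")
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  read_set(ids, toupper(as.character(set)), "base")
}

#' Parse a CSFasta (SOLiD colour-space) file into a read set
#'
#' CSFasta records have `>` headers and a sequence line consisting of one
#' primer base (A/C/G/T) followed by colour calls in `0,1,2,3,.`. Lines
#' starting with `#` are comments. The primer base is stripped from the
#' symbol string (and retained in the `primer` field); reads containing
#' missing calls (`.`) are kept here — discarding happens in
#' [preprocess_reads()].
#'
#' @param path path to a CSFasta file (optionally gzipped).
#' @return A colour-alphabet [read_set()].
#' @export
parse_csfasta <- function(path) {
  con <- file(path, "rt")  # file() transparently decompresses gzip
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(read_set(character(), character(), "colour", primer = character()))
  is_hdr <- startsWith(lines, ">")
  if (!length(is_hdr) || !is_hdr[1L])
    stop("malformed CSFasta in '", path, "': line ", lineno[1L],
         " is not a header")
  rec <- cumsum(is_hdr)
  # each record: one header line followed by exactly one sequence line
  n_seq <- tabulate(rec, nbins = max(rec)) - 1L
  if (any(n_seq != 1L)) {
    bad <- which(is_hdr)[which(n_seq != 1L)[1L]]
    stop("malformed CSFasta in '", path, "': record at line ", lineno[bad],
         " must have exactly one sequence line")
  }
  hdr <- lines[is_hdr]
  seqs <- lines[!is_hdr]
  seq_lineno <- lineno[!is_hdr]
  primer <- substr(seqs, 1L, 1L)
  bad_primer <- !primer %in% c("A", "C", "G", "T")
  if (any(bad_primer))
    stop("malformed CSFasta in '", path, "': line ",
         seq_lineno[which(bad_primer)[1L]],
         " does not start with a primer base (A/C/G/T)")
  colours <- substr(seqs, 2L, nchar(seqs))
  bad_col <- grepl("[^0123.]", colours)
  if (any(bad_col))
    stop("malformed CSFasta in '", path, "': line ",
         seq_lineno[which(bad_col)[1L]], " contains an illegal colour symbol")
  if (any(nchar(colours) == 0))
    stop("malformed CSFasta in '", path, "': line ",
         seq_lineno[which(nchar(colours) == 0)[1L]], " has an empty read")
  read_set(sub("^>\\s*", "", sub("\\s.*$", "", hdr)), colours, "colour",
           primer = primer)
}

#' Read sequencing reads with format auto-detection
#'
#' Dispatches to [parse_fasta()], [parse_fastq()] or [parse_csfasta()] from
#' the file extension (`.csfasta`, `.fastq`/`.fq`, else FASTA; a trailing
#' `.gz` is ignored for detection).
#'
#' @param path input file.
#' @param format `"auto"`, `"fasta"`, `"fastq"` or `"csfasta"`.
#' @return A [read_set()].
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq", "csfasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path, ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    format <- switch(ext,
                     csfasta = "csfasta",
                     fastq = "fastq",
                     fq = "fastq",
                     "fasta")
  }
  switch(format,
         fasta = parse_fasta(path),
         fastq = parse_fastq(path),
         csfasta = parse_csfasta(path))
}

#' Preprocess raw reads before k-mer counting
#'
#' Applies the read-cleaning rules: colour reads containing a missing call
#' (`.`) are discarded (when `cfg$discard_incomplete_colour`), and every
#' surviving read is truncated to `cfg$trim_length` symbols. Reads shorter
#' than the trim length are kept at native length unless `cfg$drop_short`.
#' The operation is idempotent.
#'
#' @param reads a [read_set()].
#' @param cfg a [read_preprocess_config()].
#' @return The filtered, trimmed [read_set()].
#' @export
preprocess_reads <- function(reads, cfg = read_preprocess_config()) {
  stopifnot(inherits(reads, "read_set"),
            inherits(cfg, "read_preprocess_config"))
  keep <- rep(TRUE, length(reads))
  if (reads$alphabet == "colour" && cfg$discard_incomplete_colour)
    keep <- !grepl(".", reads$symbols, fixed = TRUE)
  if (cfg$drop_short)
    keep <- keep & nchar(reads$symbols) >= cfg$trim_length
  out <- reads[keep]
  out$symbols <- substr(out$symbols, 1L, cfg$trim_length)
  out
}

#' Write a read set to FASTA
#'
#' Colour reads are written CSFasta-style (primer base re-attached when
#' available).
#'
#' @param reads a [read_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  seqs <- reads$symbols
  if (reads$alphabet == "colour" && !is.null(reads$primer))
    seqs <- paste0(reads$primer, seqs)
  writeLines(as.vector(rbind(paste0(">", reads$read_id), seqs)), path)
  invisible(path)
}

#' Decode colour-space reads to base space
#'
#' Uses the stored primer base and the SOLiD di-nucleotide transition code
#' (colour 0 = same base, 1/2/3 = the three substitutions) to reconstruct
#' base-space sequences. Reads with missing calls (`.`) cannot be decoded
#' and must be removed first with [preprocess_reads()].
#'
#' @param reads a colour-alphabet [read_set()] with primer bases.
#' @param keep_primer keep the primer base as the first symbol of the decoded
#'   read (default `FALSE`: the primer is a library artefact, not genomic).
#' @return A base-alphabet [read_set()].
#' @export
colour_to_base <- function(reads, keep_primer = FALSE) {
  stopifnot(inherits(reads, "read_set"))
  if (reads$alphabet != "colour") stop("reads are not colour-space")
  if (is.null(reads$primer)) stop("reads carry no primer base; cannot decode")
  if (any(grepl(".", reads$symbols, fixed = TRUE)))
    stop("reads contain missing colour calls; run preprocess_reads() first")
  bases <- c("A", "C", "G", "T")
  # colour c maps base b to xor-like table: SOLiD encoding
  trans <- matrix(c("A","C","G","T",
                    "C","A","T","G",
                    "G","T","A","C",
                    "T","G","C","A"), nrow = 4, byrow = TRUE,
                  dimnames = list(c("0","1","2","3"), bases))
  decoded <- vapply(seq_along(reads$symbols), function(i) {
    cur <- reads$primer[i]
    cols <- strsplit(reads$symbols[i], "", fixed = TRUE)[[1L]]
    out <- character(length(cols))
    for (j in seq_along(cols)) {
      cur <- trans[cols[j], cur]
      out[j] <- cur
    }
    paste0(if (keep_primer) reads$primer[i] else "", paste(out, collapse = ""))
  }, character(1))
  read_set(reads$read_id, decoded, "base")
}
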