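#' Construct a k-mer profile
#'
#' Per-bin canonical k-mer counts for one sample. Usually produced by
#' [count_kmers()]; the constructor is exported for synthetic fixtures and
#' file round-trips.
#'
#' @param space a [kmer_space()].
#' @param counts non-negative integer vector of length `space$n_bins`.
#' @param sample_id sample identifier.
#' @return An object of class `kmer_profile` with fields `space`, `counts`,
#'   `total` and `sample_id`.
#' @export
kmer_profile <- function(space, counts, sample_id = "sample") {
  stopifnot(inherits(space, "kmer_space"))
  counts <- as.numeric(counts)
  if (length(counts) != space$n_bins)
    stop("counts must have one entry per bin (", space$n_bins, ")")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  structure(list(space = space, counts = counts, total = sum(counts),
                 sample_id = as.character(sample_id)),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("kmer_profile '%s': k=%d (%s), %d bins, %s k-mers counted\n",
              x$sample_id, x$space$k, x$space$alphabet, x$space$n_bins,
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Per-bin k-mer frequencies of a profile
#'
#' @param profile a [kmer_profile()].
#' @return Numeric vector `counts / total`, named by bin label; errors on an
#'   empty profile.
#' @export
kmer_frequencies <- function(profile) {
  stopifnot(inherits(profile, "kmer_profile"))
  if (profile$total <= 0) stop("profile has no counted k-mers")
  stats::setNames(profile$counts / profile$total, profile$space$bin_label)
}

#' Count canonical overlapping k-mers in a read set
#'
#' Every read of length `l` contributes its `l - k + 1` overlapping windows;
#' windows containing an ambiguous symbol (`N` in base space, `.` in colour
#' space) are skipped. Each window increments the canonical bin shared by the
#' k-mer and its strand-equivalent partner, so the profile is invariant to
#' replacing reads by their reverse complements. Reads are independent
#' fragments: no window spans two reads.
#'
#' @param reads a [read_set()], or a character vector of base-space
#'   sequences (e.g. whole genomes), whose alphabet must match the space.
#' @param space a [kmer_space()].
#' @param sample_id sample identifier stored in the profile.
#' @return A [kmer_profile()].
#' @examples
#' sp <- kmer_space(4)
#' p <- count_kmers(read_set("r1", "ACGTACGT"), sp)
#' p$total  # 5 windows
#' @export
count_kmers <- function(reads, space, sample_id = "sample") {
  stopifnot(inherits(space, "kmer_space"))
  if (is.character(reads))
    reads <- read_set(paste0("seq", seq_along(reads)), toupper(reads), "base")
  stopifnot(inherits(reads, "read_set"))
  if (reads$alphabet != space$alphabet)
    stop("alphabet mismatch: reads are ", reads$alphabet,
         "-space but the k-mer space is ", space$alphabet)
  k <- space$k
  counts <- numeric(space$n_bins)
  if (length(reads) > 0) {
    # concatenate reads with a separator that invalidates bridging windows
    sep <- if (space$alphabet == "base") "N" else "."
    big <- paste(reads$symbols, collapse = sep)
    v <- .digit_lookup(space$alphabet)[utf8ToInt(big)]
    if (length(v) >= k) {
      # window codes: embed() row i = v[i+k-1], ..., v[i]
      m <- stats::embed(v, k)
      codes <- as.vector(m %*% 4^(0:(k - 1)))
      codes <- codes[!is.na(codes)]
      if (length(codes))
        counts <- tabulate(space$bin_of_code[codes + 1], nbins = space$n_bins)
    }
  }
  kmer_profile(space, counts, sample_id)
}

#' Merge two k-mer profiles
#'
#' Element-wise addition of counts; enables chunked or streamed counting.
#'
#' @param a,b [kmer_profile()]s over identical spaces.
#' @return A [kmer_profile()] with summed counts; the sample id of `a` is
#'   kept.
#' @export
merge_profiles <- function(a, b) {
  stopifnot(inherits(a, "kmer_profile"), inherits(b, "kmer_profile"))
  if (!.same_space(a$space, b$space))
    stop("profiles were counted over different k-mer spaces")
  kmer_profile(a$space, a$counts + b$counts, a$sample_id)
}

#' K-mer abundance histogram
#'
#' Classes the canonical bins by their frequency (`counts / total`, so
#' samples of different depth are comparable). Bins with zero counts form
#' their own class; the positive range `(0, max frequency]` is cut into
#' `n_classes` equal-width classes. The class sizes always sum to the number
#' of bins.
#'
#' @param profile a [kmer_profile()] with `total > 0`.
#' @param n_classes number of positive-frequency classes (default 20).
#' @return A data frame with columns `lower`, `upper` (class boundaries on
#'   the frequency scale; the zero class has both 0) and `n_bins` (number of
#'   k-mer bins in the class), of class `abundance_histogram`.
#' @export
abundance_histogram <- function(profile, n_classes = 20L) {
  stopifnot(inherits(profile, "kmer_profile"))
  if (profile$total <= 0) stop("profile has no counted k-mers")
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 1L)
    stop("n_classes must be a positive integer")
  f <- profile$counts / profile$total
  brk <- seq(0, max(f), length.out = n_classes + 1L)
  pos <- f[f > 0]
  cls <- findInterval(pos, brk, rightmost.closed = TRUE, left.open = TRUE)
  out <- data.frame(lower = c(0, brk[-length(brk)]),
                    upper = c(0, brk[-1L]),
                    n_bins = c(sum(f == 0),
                               tabulate(cls, nbins = n_classes)))
  class(out) <- c("abundance_histogram", "data.frame")
  out
}

#' Write a k-mer profile to TSV
#'
#' Header comment lines carry `k`, `alphabet`, `total` and `sample_id`;
#' one row per canonical bin with its label, count and frequency. The
#' count column is integral, so [read_profile()] reproduces the profile
#' bit-exactly.
#'
#' @param profile a [kmer_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "kmer_profile"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("#k=%d", profile$space$k),
               sprintf("#alphabet=%s", profile$space$alphabet),
               sprintf("#total=%.0f", profile$total),
               sprintf("#sample_id=%s", profile$sample_id),
               "kmer_label\tcount\tfrequency"), con)
  freq <- if (profile$total > 0) profile$counts / profile$total
          else rep(0, length(profile$counts))
  writeLines(sprintf("%s\t%.0f\t%.10g", profile$space$bin_label,
                     profile$counts, freq), con)
  invisible(path)
}

#' Read a k-mer profile written by [write_profile()]
#'
#' @param path profile TSV file.
#' @return A [kmer_profile()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    m <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(m) != 1) stop("profile file '", path, "' lacks header ", key)
    sub(paste0("^#", key, "="), "", m)
  }
  k <- as.integer(get("k"))
  alphabet <- get("alphabet")
  sample_id <- get("sample_id")
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t",
                            colClasses = c("character", "numeric", "numeric"))
  space <- kmer_space(k, alphabet)
  if (nrow(body) != space$n_bins ||
      !identical(body$kmer_label, space$bin_label))
    stop("profile file '", path, "' does not match the k=", k,
         " canonical bin enumeration")
  prof <- kmer_profile(space, body$count, sample_id)
  if (prof$total != as.numeric(get("total")))
    stop("profile file '", path, "' total does not match its counts")
  prof
}
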