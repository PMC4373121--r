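#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used throughout the
#' method's comparison steps.
#'
#' @param a,b numeric vectors of equal length (at least 3).
#' @return The correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Spearman correlation is undefined for a constant vector")
  stats::cor(a, b, method = "spearman")
}

#' Compare a sample k-mer profile to a reference
#'
#' Correlates the per-bin frequencies of a sample with those of a reference
#' (undiluted / known-good) sample by Spearman rank correlation, and flags
#' aberrant bins: those whose sample frequency exceeds the reference
#' frequency by at least `fold_threshold`. Empty reference bins are floored
#' at `1 / reference$total` (one pseudo-observation) so fold-changes remain
#' finite. Cassette/adapter contamination shows up as a coherent set of
#' flagged bins matching the cassette's k-mers.
#'
#' @param sample,reference [kmer_profile()]s over the same space, both with
#'   positive totals.
#' @param fold_threshold flag a bin when
#'   `sample_freq / max(ref_freq, 1/ref_total) >= fold_threshold`
#'   (default 4).
#' @return An object of class `comparison_report`: list with `sample_id`,
#'   `reference_id`, `rho` (`NA` when either frequency vector is constant,
#'   where rank correlation is undefined), `fold_threshold` and a data
#'   frame `aberrant` with columns `bin_label`, `sample_freq`,
#'   `reference_freq`, `log2_fold_change`.
#' @export
compare_profiles <- function(sample, reference, fold_threshold = 4) {
  stopifnot(inherits(sample, "kmer_profile"),
            inherits(reference, "kmer_profile"))
  if (!.same_space(sample$space, reference$space))
    stop("profiles were counted over different k-mer spaces")
  if (sample$total <= 0 || reference$total <= 0)
    stop("both profiles must have counted k-mers")
  if (!is.numeric(fold_threshold) || fold_threshold <= 1)
    stop("fold_threshold must be > 1")
  fs <- stats::setNames(sample$counts / sample$total,
                        sample$space$bin_label)
  fr <- stats::setNames(reference$counts / reference$total,
                        reference$space$bin_label)
  # rank correlation is undefined for constant frequency vectors (e.g. two
  # exactly uniform profiles); flag with NA rather than fail
  rho <- tryCatch(spearman_rho(fs, fr), error = function(e) NA_real_)
  eps <- 1 / reference$total
  fold <- fs / pmax(fr, eps)
  hit <- fold >= fold_threshold
  aberrant <- data.frame(bin_label = sample$space$bin_label[hit],
                         sample_freq = fs[hit],
                         reference_freq = fr[hit],
                         log2_fold_change = log2(fold[hit]))
  aberrant <- aberrant[order(-aberrant$log2_fold_change), , drop = FALSE]
  rownames(aberrant) <- NULL
  structure(list(sample_id = sample$sample_id,
                 reference_id = reference$sample_id,
                 rho = rho, fold_threshold = fold_threshold,
                 sample_freq = fs, reference_freq = fr,
                 aberrant = aberrant),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison '%s' vs reference '%s': Spearman rho = %.4f\n",
              x$sample_id, x$reference_id, x$rho))
  cat(sprintf("  %d aberrant bin(s) at fold >= %g\n",
              nrow(x$aberrant), x$fold_threshold))
  if (nrow(x$aberrant) > 0)
    print(utils::head(x$aberrant, 10))
  invisible(x)
}

#' Write a comparison report (per-bin TSV plus JSON summary)
#'
#' @param report a [compare_profiles()] result.
#' @param tsv_path per-bin table (bin label, sample and reference frequency,
#'   aberrant flag); `NULL` to skip.
#' @param json_path summary (`rho`, `n_aberrant`, `threshold`); `NULL` to
#'   skip.
#' @return Invisibly, the written paths.
#' @export
write_comparison_report <- function(report, tsv_path = NULL,
                                    json_path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  if (!is.null(tsv_path)) {
    lab <- names(report$sample_freq)
    tab <- data.frame(bin_label = if (is.null(lab))
                        seq_along(report$sample_freq) else lab,
                      sample_freq = report$sample_freq,
                      reference_freq = report$reference_freq)
    tab$bin_label <- as.character(tab$bin_label)
    tab$aberrant <- tab$bin_label %in% report$aberrant$bin_label
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(list(sample_id = report$sample_id,
                              reference_id = report$reference_id,
                              rho = report$rho,
                              n_aberrant = nrow(report$aberrant),
                              threshold = report$fold_threshold),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv_path, json_path))
}

#' Cassette filter configuration
#'
#' Settings for removing reads that match a barcode-cassette / adapter
#' sequence (self-ligated "empty" inserts).
#'
#' @param cassette the cassette sequence (base string, non-empty).
#' @param max_mismatches mismatches tolerated in a match (default 0:
#'   exact matching).
#' @param min_match_length window length for matching read fragments against
#'   the cassette concatemer (default 35, the read trim length). Clipped to
#'   the read length for shorter reads.
#' @return An object of class `cassette_filter_config`.
#' @export
cassette_filter_config <- function(cassette, max_mismatches = 0L,
                                   min_match_length = 35L) {
  cassette <- toupper(as.character(cassette))
  if (length(cassette) != 1L || nchar(cassette) == 0)
    stop("cassette must be a single non-empty base string")
  if (grepl("[^ACGT]", cassette))
    stop("cassette may only contain A,C,G,T")
  max_mismatches <- as.integer(max_mismatches)
  min_match_length <- as.integer(min_match_length)
  if (is.na(max_mismatches) || max_mismatches < 0L)
    stop("max_mismatches must be a non-negative integer")
  if (is.na(min_match_length) || min_match_length < 1L)
    stop("min_match_length must be a positive integer")
  structure(list(cassette = cassette, max_mismatches = max_mismatches,
                 min_match_length = min_match_length),
            class = "cassette_filter_config")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all length-L windows of a string (character vector of windows)
.windows <- function(s, L) {
  n <- nchar(s)
  if (n < L) return(character())
  substring(s, 1:(n - L + 1L), L:n)
}

# mismatch-tolerant containment of any length-L window of `read` in `target`
.fuzzy_hit <- function(read, target, L, max_mm) {
  rn <- nchar(read)
  L <- min(L, rn)
  tv <- utf8ToInt(target)
  rv <- utf8ToInt(read)
  tn <- length(tv)
  if (tn < L) return(FALSE)
  for (i in 1:(rn - L + 1L)) {
    w <- rv[i:(i + L - 1L)]
    for (j in 1:(tn - L + 1L)) {
      if (sum(w != tv[j:(j + L - 1L)]) <= max_mm) return(TRUE)
    }
  }
  FALSE
}

#' Remove cassette-contaminated reads
#'
#' A read is removed when it matches the barcode-cassette sequence: either
#' the cassette (or its reverse complement) occurs within the read, or a
#' window of the read of length `min_match_length` (clipped to the read
#' length) occurs within a cassette concatemer (cassette repeated, so
#' junction-spanning fragments of self-ligated cassettes are caught) or its
#' reverse complement. With `max_mismatches = 0` matching is exact substring
#' containment; the mismatch-tolerant mode scans all alignments.
#'
#' @param reads a base-alphabet [read_set()] (colour reads require the
#'   cassette supplied in colour space; matching is then reversal-symmetric
#'   rather than reverse-complement-symmetric).
#' @param cfg a [cassette_filter_config()].
#' @return A list with `kept` (the surviving [read_set()]) and `removed`
#'   (integer count of removed reads).
#' @export
filter_cassette_reads <- function(reads, cfg) {
  stopifnot(inherits(reads, "read_set"),
            inherits(cfg, "cassette_filter_config"))
  if (length(reads) == 0)
    return(list(kept = reads, removed = 0L))
  cas <- cfg$cassette
  colour <- reads$alphabet == "colour"
  if (colour && grepl("[^0123]", cas))
    stop("colour reads require the cassette supplied in colour space")
  rc <- function(s) if (colour) paste(rev(strsplit(s, "")[[1L]]),
                                      collapse = "") else .revcomp(s)
  cas_rc <- rc(cas)
  L <- cfg$min_match_length
  reps <- ceiling((L + nchar(cas)) / nchar(cas)) + 1L
  concat <- strrep(cas, reps)
  concat_rc <- rc(concat)
  hit <- grepl(cas, reads$symbols, fixed = TRUE) |
         grepl(cas_rc, reads$symbols, fixed = TRUE)
  if (cfg$max_mismatches == 0L) {
    # hash all L-windows of the concatemer (both strands); a read matches
    # when any of its L-windows (L clipped to read length) is in the set
    lens <- sort(unique(pmin(nchar(reads$symbols), L)))
    for (Li in lens) {
      idx <- which(!hit & pmin(nchar(reads$symbols), L) == Li)
      if (!length(idx)) next
      wins <- c(.windows(concat, Li), .windows(concat_rc, Li))
      nw <- nchar(reads$symbols[idx])
      maxoff <- max(nw - Li) + 1L
      for (off in seq_len(maxoff)) {
        sub <- substr(reads$symbols[idx], off, off + Li - 1L)
        ok <- nw - Li + 1L >= off
        hit[idx[ok & sub %in% wins]] <- TRUE
      }
    }
  } else {
    todo <- which(!hit)
    hit[todo] <- vapply(reads$symbols[todo], function(s)
      .fuzzy_hit(s, concat, L, cfg$max_mismatches) ||
      .fuzzy_hit(s, concat_rc, L, cfg$max_mismatches),
      logical(1), USE.NAMES = FALSE)
  }
  list(kept = reads[!hit], removed = sum(hit))
}

#' Correlate sample entropy with gene-mapping efficiency
#'
#' The mapping efficiency (fraction of raw reads aligning to a reference
#' gene catalogue) is the downstream quality measure the entropy score
#' predicts. Mapping is performed by external tools; this function takes the
#' per-sample mapped fractions as input and reports the Spearman association
#' over the samples shared between the two tables.
#'
#' @param entropies data frame with columns `sample_id` and
#'   `normalized_entropy` (as from [entropy_table()]), or named numeric
#'   vector.
#' @param mapping_rates data frame with columns `sample_id` and
#'   `mapped_fraction`, or named numeric vector. Read such a table from disk
#'   with [read_mapping_rates()].
#' @return A list with `rho`, `p_value` (two-sided; exact for fewer than 10
#'   samples, t-approximation otherwise) and `n` (shared samples, at least
#'   5 required).
#' @export
entropy_vs_mapping <- function(entropies, mapping_rates) {
  as_named <- function(x, value_col) {
    if (is.numeric(x) && !is.null(names(x))) return(x)
    stopifnot(is.data.frame(x), "sample_id" %in% names(x),
              value_col %in% names(x))
    stats::setNames(x[[value_col]], x$sample_id)
  }
  e <- as_named(entropies, "normalized_entropy")
  m <- as_named(mapping_rates, "mapped_fraction")
  shared <- intersect(names(e), names(m))
  if (length(shared) < 5L)
    stop("need at least 5 shared samples; got ", length(shared))
  ct <- suppressWarnings(
    stats::cor.test(e[shared], m[shared], method = "spearman",
                    exact = length(shared) < 10L))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}

#' Read a per-sample mapping-efficiency table
#'
#' Two-column TSV `sample_id`, `mapped_fraction` (header optional).
#'
#' @param path TSV file.
#' @return Data frame with columns `sample_id`, `mapped_fraction`.
#' @export
read_mapping_rates <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample_id", first, fixed = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) names(tab) <- c("sample_id", "mapped_fraction")
  if (!is.numeric(tab$mapped_fraction))
    stop("mapped_fraction column is not numeric in '", path, "'")
  tab
}
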