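#' Normalized Shannon entropy of a k-mer profile
#'
#' The sample-quality score: plug-in Shannon entropy of the per-bin k-mer
#' frequencies, divided by the log of the number of bins so that a perfectly
#' uniform k-mer spectrum scores 1 and a single-bin spectrum scores 0. The
#' log base cancels in the normalization; zero-count bins contribute 0
#' (`0 log 0 = 0`), with no pseudocounts.
#'
#' By default the denominator is `log(n_bins)` of the canonical space
#' actually counted (136 classes for `k = 4`); `normalization = "raw"`
#' divides by `log(4^k)` instead, for comparison with pipelines that do not
#' aggregate reverse complements.
#'
#' @param profile a [kmer_profile()] with `total > 0`, or a bare numeric
#'   vector of counts (normalized over its own length).
#' @param normalization `"canonical"` (default) or `"raw"`.
#' @return An object of class `entropy_result`: list with `sample_id`,
#'   `entropy` in `[0, 1]`, `n_bins` and `total`.
#' @examples
#' shannon_entropy(c(1, 1, 2, 0))$entropy  # 0.75
#' @export
shannon_entropy <- function(profile, normalization = c("canonical", "raw")) {
  normalization <- match.arg(normalization)
  if (is.numeric(profile)) {
    counts <- profile
    n_bins <- length(counts)
    denom_bins <- n_bins
    sample_id <- "counts"
  } else {
    stopifnot(inherits(profile, "kmer_profile"))
    counts <- profile$counts
    n_bins <- profile$space$n_bins
    denom_bins <- if (normalization == "canonical") n_bins
                  else 4^profile$space$k
    sample_id <- profile$sample_id
  }
  total <- sum(counts)
  if (total <= 0) stop("no counted k-mers: entropy is undefined")
  p <- counts[counts > 0] / total
  h <- -sum(p * log(p)) / log(denom_bins)
  structure(list(sample_id = sample_id,
                 entropy = min(max(h, 0), 1),
                 n_bins = n_bins, total = total),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("normalized Shannon entropy of '%s': %.6f (%d bins, %s k-mers)\n",
              x$sample_id, x$entropy, x$n_bins,
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Entropy table for a set of profiles
#'
#' One row per sample, in input order.
#'
#' @param profiles a list of [kmer_profile()]s over one shared space.
#' @param normalization passed to [shannon_entropy()].
#' @return A data frame with columns `sample_id`, `k`, `n_bins`,
#'   `total_kmers`, `normalized_entropy`.
#' @export
entropy_table <- function(profiles, normalization = c("canonical", "raw")) {
  normalization <- match.arg(normalization)
  if (inherits(profiles, "kmer_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop("no profiles supplied")
  stopifnot(all(vapply(profiles, inherits, logical(1), "kmer_profile")))
  sp <- profiles[[1L]]$space
  for (p in profiles)
    if (!.same_space(p$space, sp))
      stop("profiles were counted over different k-mer spaces")
  res <- lapply(profiles, shannon_entropy, normalization = normalization)
  data.frame(sample_id = vapply(res, `[[`, character(1), "sample_id"),
             k = sp$k,
             n_bins = sp$n_bins,
             total_kmers = vapply(res, `[[`, numeric(1), "total"),
             normalized_entropy = vapply(res, `[[`, numeric(1), "entropy"))
}

#' Write an entropy table as TSV or JSON
#'
#' @param tab a data frame from [entropy_table()].
#' @param path output file; `.json` extension selects JSON, anything else
#'   TSV. Entropies are written to full precision.
#' @return `path`, invisibly.
#' @export
write_entropy_report <- function(tab, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(format(tab, digits = 15, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
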