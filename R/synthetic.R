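# Synthetic study generator: compositionally distinct genomes (first-order
# Markov chains over A,C,G,T), shotgun read sets drawn from weighted genome
# mixtures, and dilution-series degradation modeled as an increasing
# fraction of barcode-cassette self-ligation ("empty" adapter) reads.
# All randomness flows from a single user seed via fixed per-stage offsets,
# so the same spec yields bit-identical outputs.

# Default synthetic cassette: a 12-nt poly(A) homopolymer linker, the
# canonical low-complexity library artifact (adapter/carrier homopolymer
# stretches). Self-ligated cassettes carry no genomic insert, so
# contaminated reads are substrings of cassette concatemers; a homopolymer
# concentrates the contaminant k-mer mass onto a single canonical bin
# ({AAAA, TTTT}), giving the sharpest spectral signature per unit of
# contamination -- the regime in which graded library degradation shows the
# cleanest entropy response. Any specific barcode-cassette construct can be
# supplied instead via the `cassette` parameter.
.default_cassette <- "AAAAAAAAAAAA"

.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1000L + as.integer(stage)) %% 2147483647L
}

#' Random composition-bias transition matrix
#'
#' Draws a row-stochastic 4x4 first-order transition matrix over (A,C,G,T)
#' with rows sampled from a symmetric Dirichlet. Smaller `alpha` gives
#' stronger compositional bias (more heterogeneous k-mer spectra). The
#' default `alpha = 6` yields single-genome tetranucleotide entropies in the
#' 0.95-0.98 band typical of bacterial genomes.
#'
#' @param alpha Dirichlet concentration (default 6).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return A 4x4 matrix with rows summing to 1.
#' @export
random_transition_matrix <- function(alpha = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- matrix(stats::rgamma(16L, shape = alpha), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  g / rowSums(g)
}

#' Expected canonical k-mer profile of a Markov-chain genome
#'
#' Analytic stationary k-mer distribution of a first-order Markov chain
#' over (A,C,G,T), aggregated into canonical bins: the profile an infinitely
#' long genome drawn from `transition` would have.
#'
#' @param transition 4x4 row-stochastic transition matrix.
#' @param space a base-alphabet [kmer_space()].
#' @return Numeric frequency vector over the space's bins (sums to 1),
#'   named by bin label.
#' @export
expected_kmer_profile <- function(transition, space) {
  stopifnot(inherits(space, "kmer_space"), space$alphabet == "base")
  if (!is.matrix(transition) || any(dim(transition) != 4L) ||
      any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition must be a 4x4 matrix with rows summing to 1")
  # stationary distribution by power iteration
  pi0 <- rep(0.25, 4)
  for (i in 1:200) pi0 <- as.vector(pi0 %*% transition)
  # word probabilities built digit by digit (code base 4, first digit most
  # significant); probs[code] with last digit = code %% 4
  probs <- pi0
  for (i in seq_len(space$k - 1L)) {
    last <- (seq_along(probs) - 1L) %% 4L + 1L
    probs <- as.vector(t(probs * transition[last, , drop = FALSE]))
  }
  freq <- as.vector(tapply(probs, space$bin_of_code, sum))
  stats::setNames(freq, space$bin_label)
}

#' Specification of one synthetic genome
#'
#' @param genome_id identifier.
#' @param length sequence length in bases (default 100000).
#' @param composition_bias 4x4 row-stochastic first-order transition matrix
#'   over (A,C,G,T); rows must sum to 1 within 1e-9.
#' @param seed integer seed making the genome reproducible.
#' @return An object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(genome_id, length = 100000L,
                                  composition_bias, seed = 1L) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  if (!is.matrix(composition_bias) || any(dim(composition_bias) != 4L) ||
      any(abs(rowSums(composition_bias) - 1) > 1e-9) ||
      any(composition_bias < 0))
    stop("composition_bias must be a 4x4 matrix with rows summing to 1")
  structure(list(genome_id = as.character(genome_id), length = length,
                 composition_bias = composition_bias,
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

#' Simulate a genome sequence
#'
#' First-order Markov chain over (A,C,G,T) with the spec's transition
#' matrix; the initial base is uniform. Same spec (including seed) gives a
#' bit-identical sequence.
#'
#' @param spec a [synthetic_genome_spec()].
#' @return A single base string of the requested length.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  .markov_sequence(spec$length, spec$composition_bias, rep(0.25, 4))
}

#' Simulate shotgun reads from a genome mixture
#'
#' Each read picks a genome with the given weights, a uniform start
#' position, a uniform strand (reverse-complemented with probability 1/2),
#' and substitutes symbols uniformly at `error_rate`.
#'
#' @param genomes named character vector of genome sequences (names become
#'   provenance labels), or a single string.
#' @param weights mixture weights, recycled/normalized to sum 1 (default
#'   uniform).
#' @param n_reads number of reads.
#' @param read_length read length (default 35); all genomes must be at
#'   least this long.
#' @param error_rate per-symbol substitution probability in `[0, 1)`.
#' @param seed RNG seed.
#' @param id_prefix read identifier prefix.
#' @return A base-alphabet [read_set()].
#' @export
simulate_reads <- function(genomes, weights = NULL, n_reads,
                           read_length = 35L, error_rate = 0,
                           seed = 1L, id_prefix = "r") {
  gnames <- if (is.null(names(genomes)))
    paste0("g", seq_along(genomes)) else names(genomes)
  genomes <- as.character(genomes)
  names(genomes) <- gnames
  if (length(genomes) == 0) stop("no genomes supplied")
  read_length <- as.integer(read_length)
  if (any(nchar(genomes) < read_length))
    stop("read_length exceeds a genome length")
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  n_reads <- as.integer(n_reads)
  if (is.null(weights)) weights <- rep(1, length(genomes))
  if (length(weights) != length(genomes))
    stop("one weight per genome required")
  weights <- weights / sum(weights)
  set.seed(as.integer(seed))
  if (n_reads == 0L)
    return(read_set(character(), character(), "base"))
  gi <- sample.int(length(genomes), n_reads, replace = TRUE, prob = weights)
  start <- floor(stats::runif(n_reads) *
                   (nchar(genomes)[gi] - read_length + 1)) + 1L
  seqs <- substr(genomes[gi], start, start + read_length - 1L)
  flip <- stats::runif(n_reads) < 0.5
  if (any(flip)) seqs[flip] <- .revcomp(seqs[flip])
  if (error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    n_mut <- stats::rbinom(n_reads, read_length, error_rate)
    for (i in which(n_mut > 0)) {
      pos <- sample.int(read_length, n_mut[i])
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      s[pos] <- vapply(s[pos], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      seqs[i] <- paste(s, collapse = "")
    }
  }
  out <- read_set(sprintf("%s%06d", id_prefix, seq_len(n_reads)), seqs,
                  "base")
  out$provenance <- names(genomes)[gi]
  out
}

#' Specification of a synthetic dilution series
#'
#' Encodes the degradation design: one metagenome mixture sequenced at a
#' series of quality levels, where each step replaces a growing fraction of
#' genome-derived reads with cassette self-ligation reads (the mechanism by
#' which limiting input DNA degrades real libraries).
#'
#' @param genomes named character vector of genome sequences.
#' @param weights mixture weights (default uniform).
#' @param n_reads reads per dilution step (default 50000).
#' @param read_length read length (default 35).
#' @param error_rate per-symbol substitution rate (default 0).
#' @param cassette barcode-cassette base string (default: the package's
#'   12-nt synthetic cassette).
#' @param contamination_fractions non-decreasing vector in `[0, 1)`, one
#'   fraction of cassette reads per step (default
#'   `c(0, 0.01, 0.05, 0.3, 0.7)`).
#' @param seed master seed; all stages derive their streams from it.
#' @return An object of class `dilution_series_spec`.
#' @export
dilution_series_spec <- function(genomes, weights = NULL, n_reads = 50000L,
                                 read_length = 35L, error_rate = 0,
                                 cassette = .default_cassette,
                                 contamination_fractions =
                                   c(0, 0.01, 0.05, 0.3, 0.7),
                                 seed = 1L) {
  if (is.null(names(genomes)))
    names(genomes) <- paste0("g", seq_along(genomes))
  if (is.null(weights)) weights <- rep(1, length(genomes))
  weights <- weights / sum(weights)
  f <- as.numeric(contamination_fractions)
  if (any(f < 0) || any(f >= 1))
    stop("contamination fractions must lie in [0, 1)")
  if (is.unsorted(f))
    stop("contamination fractions must be non-decreasing")
  cassette <- toupper(cassette)
  if (nchar(cassette) == 0 || grepl("[^ACGT]", cassette))
    stop("cassette must be a non-empty A/C/G/T string")
  structure(list(genomes = genomes, weights = weights,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, cassette = cassette,
                 contamination_fractions = f, seed = as.integer(seed)),
            class = "dilution_series_spec")
}

# reads that are random fragments of cassette concatemers (both strands)
.simulate_cassette_reads <- function(cassette, n_reads, read_length,
                                     error_rate, seed, id_prefix) {
  reps <- ceiling(read_length / nchar(cassette)) + 2L
  concat <- strrep(cassette, reps)
  set.seed(as.integer(seed))
  if (n_reads == 0L) return(read_set(character(), character(), "base"))
  # systematic (stratified) cyclic phase within one cassette copy: phases
  # are equidistributed with one common random offset, so the cassette-read
  # k-mer mass is as even across concatemer positions as the sample size
  # allows
  start <- floor(((seq_len(n_reads) - 1L + stats::runif(1L)) / n_reads) *
                   nchar(cassette)) + 1L
  seqs <- substring(concat, start, start + read_length - 1L)
  flip <- stats::runif(n_reads) < 0.5
  if (any(flip)) seqs[flip] <- .revcomp(seqs[flip])
  if (error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    n_mut <- stats::rbinom(n_reads, read_length, error_rate)
    for (i in which(n_mut > 0)) {
      pos <- sample.int(read_length, n_mut[i])
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      s[pos] <- vapply(s[pos], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      seqs[i] <- paste(s, collapse = "")
    }
  }
  read_set(sprintf("%s%06d", id_prefix, seq_len(n_reads)), seqs, "base")
}

#' Simulate a dilution series of read sets
#'
#' One master pool of genome-derived reads is drawn once from the mixture;
#' the step with contamination fraction `f` consists of the first
#' `(1 - f) * n_reads` pool reads plus `round(f * n_reads)` cassette
#' concatemer fragments (common-random-numbers design: successive steps
#' re-sequence the same library at graded contamination, so quality trends
#' across steps reflect contamination, not resampling noise).
#'
#' @param spec a [dilution_series_spec()].
#' @return A list of class `dilution_series`, one element per step, each a
#'   list with `label` (`"d1"`, `"d2"`, ...), `contamination` and `reads`
#'   (a [read_set()]).
#' @export
simulate_dilution_series <- function(spec) {
  stopifnot(inherits(spec, "dilution_series_spec"))
  pool <- simulate_reads(spec$genomes, spec$weights, spec$n_reads,
                         spec$read_length, spec$error_rate,
                         seed = .stage_seed(spec$seed, 1L),
                         id_prefix = "gen")
  # balance the pool order across genomes (round-robin by quantile position)
  # so every prefix of the pool has near-proportional genome representation;
  # step profiles then differ by their contamination, not by which genomes
  # happened to fall in the dropped tail
  if (!is.null(pool$provenance)) {
    idx_in <- stats::ave(seq_along(pool$provenance), pool$provenance,
                         FUN = seq_along)
    n_g <- stats::ave(seq_along(pool$provenance), pool$provenance,
                      FUN = length)
    pool <- pool[order((idx_in - 0.5) / n_g)]
  }
  steps <- vector("list", length(spec$contamination_fractions))
  for (i in seq_along(steps)) {
    f <- spec$contamination_fractions[i]
    n_cas <- as.integer(round(f * spec$n_reads))
    n_gen <- spec$n_reads - n_cas
    cas <- .simulate_cassette_reads(spec$cassette, n_cas, spec$read_length,
                                    spec$error_rate,
                                    seed = .stage_seed(spec$seed, 1L + i),
                                    id_prefix = sprintf("cas%d_", i))
    reads <- read_set(c(pool$read_id[seq_len(n_gen)], cas$read_id),
                      c(pool$symbols[seq_len(n_gen)], cas$symbols),
                      "base")
    steps[[i]] <- list(label = sprintf("d%d", i), contamination = f,
                       reads = reads)
  }
  structure(steps, class = "dilution_series",
            cassette = spec$cassette)
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("dilution_series: %d step(s)\n", length(x)))
  for (s in x)
    cat(sprintf("  %s: contamination %.3g, %d reads\n",
                s$label, s$contamination, length(s$reads)))
  invisible(x)
}

#' Canonical k-mers of a cassette sequence
#'
#' The set of canonical bins covered by the cassette, optionally including
#' the junction k-mers of self-ligated concatemers (the cassette read
#' cyclically).
#'
#' @param cassette base string.
#' @param space a base-alphabet [kmer_space()].
#' @param cyclic include concatemer-junction k-mers (default `FALSE`).
#' @return Sorted unique integer bin indices.
#' @export
cassette_kmer_bins <- function(cassette, space, cyclic = FALSE) {
  stopifnot(inherits(space, "kmer_space"), space$alphabet == "base")
  cassette <- toupper(cassette)
  s <- if (cyclic) paste0(cassette, substr(cassette, 1L, space$k - 1L))
       else cassette
  if (nchar(s) < space$k) stop("cassette shorter than k")
  sort(unique(canonical_bin(.windows(s, space$k), space)))
}

#' Write dilution-series fixtures to disk
#'
#' Writes one FASTA per step plus a manifest TSV (`label`, `file`,
#' `contamination_fraction`) and the genomes FASTA.
#'
#' @param series a [simulate_dilution_series()] result.
#' @param genomes named character vector of the genome sequences used
#'   (written to `genomes.fasta`); `NULL` to skip.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dilution_series <- function(series, genomes = NULL, dir) {
  stopifnot(inherits(series, "dilution_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(series))
  for (i in seq_along(series)) {
    files[i] <- paste0(series[[i]]$label, ".fasta")
    write_fasta(series[[i]]$reads, file.path(dir, files[i]))
  }
  if (!is.null(genomes))
    writeLines(as.vector(rbind(paste0(">", names(genomes)),
                               as.character(genomes))),
               file.path(dir, "genomes.fasta"))
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(label = vapply(series, `[[`, character(1), "label"),
               file = files,
               contamination_fraction =
                 vapply(series, `[[`, numeric(1), "contamination")),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a flat key-value dilution-series spec file
#'
#' Plain-text `key = value` lines (`#` comments allowed). Recognized keys:
#' `n_genomes`, `genome_length`, `alpha`, `n_reads`, `read_length`,
#' `error_rate`, `cassette`, `contamination_fractions` (comma-separated),
#' `seed`. Genomes are drawn with [random_transition_matrix()] seeds derived
#' from `seed`.
#'
#' @param path spec file.
#' @return A [dilution_series_spec()] plus the generated genomes (attribute
#'   `"genomes"` is the named genome vector inside the spec).
#' @export
read_series_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed spec line: '", lines[which(bad)[1L]], "'")
  vals <- stats::setNames(vapply(kv, `[[`, character(1), 2L),
                          trimws(vapply(kv, `[[`, character(1), 1L)))
  num <- function(key, default) if (key %in% names(vals))
    as.numeric(vals[[key]]) else default
  seed <- as.integer(num("seed", 1))
  n_genomes <- as.integer(num("n_genomes", 10))
  genome_length <- as.integer(num("genome_length", 100000))
  alpha <- num("alpha", 6)
  genomes <- simulate_metagenome_genomes(n_genomes, genome_length, alpha,
                                         seed = seed)
  fr <- if ("contamination_fractions" %in% names(vals))
    suppressWarnings(
      as.numeric(strsplit(vals[["contamination_fractions"]], ",")[[1L]]))
  else c(0, 0.01, 0.05, 0.3, 0.7)
  if (anyNA(fr)) stop("invalid contamination_fractions in spec")
  dilution_series_spec(
    genomes,
    n_reads = as.integer(num("n_reads", 50000)),
    read_length = as.integer(num("read_length", 35)),
    error_rate = num("error_rate", 0),
    cassette = if ("cassette" %in% names(vals)) vals[["cassette"]]
               else .default_cassette,
    contamination_fractions = fr,
    seed = seed)
}

#' Generate genomes in planted signature groups
#'
#' Draws `n_groups` distinct group-level transition matrices and, within
#' each group, `members_per_group` genomes whose transition matrices are
#' small jitters of the group matrix. Each group matrix is a random bias
#' direction of fixed magnitude away from the unbiased (uniform) matrix, so
#' the planted groups have comparable signature divergence — the regime a
#' cluster-count recovery experiment probes: separations of similar scale,
#' all larger than the within-group jitter.
#'
#' @param n_groups number of signature groups (at least 2).
#' @param members_per_group genomes per group (default 8).
#' @param genome_length length of each genome (default 20000).
#' @param bias_strength Frobenius norm of each group matrix's deviation
#'   from the uniform transition matrix (default 0.4).
#' @param jitter weight of a fresh random matrix mixed into each member's
#'   transition matrix (default 0.08).
#' @param seed master seed.
#' @return A list with `genomes` (named character vector, names
#'   `gr<i>_m<j>`) and `group` (integer vector of planted group labels).
#' @export
simulate_genome_groups <- function(n_groups, members_per_group = 8L,
                                   genome_length = 20000L,
                                   bias_strength = 0.4,
                                   jitter = 0.08, seed = 1L) {
  n_groups <- as.integer(n_groups)
  if (is.na(n_groups) || n_groups < 2L) stop("need at least 2 groups")
  genomes <- character(0)
  group <- integer(0)
  # group matrices are accepted on their expected tetranucleotide profiles:
  # comparable deviation norms and low mutual alignment, so every pair of
  # planted groups is separated by a distance of similar scale (the
  # matrix-to-profile mapping is anisotropic, so matrix-space separation
  # alone does not guarantee this)
  sp4 <- kmer_space(4L, "base")
  u <- expected_kmer_profile(matrix(0.25, 4, 4), sp4)
  mats <- list()
  devs <- list()
  attempt <- 0L
  max_cos <- 0.25
  norm_tol <- 0.15
  norm_target <- NA_real_
  while (length(mats) < n_groups) {
    attempt <- attempt + 1L
    d <- random_transition_matrix(
      3, seed = .stage_seed(seed, 300L + attempt)) - 0.25
    tg <- 0.25 + bias_strength * d / sqrt(sum(d^2))
    tg[tg < 0.01] <- 0.01
    tg <- tg / rowSums(tg)
    dev <- expected_kmer_profile(tg, sp4) - u
    nd <- sqrt(sum(dev^2))
    if (is.na(norm_target)) norm_target <- nd
    ok <- abs(nd - norm_target) <= norm_tol * norm_target &&
      all(vapply(devs, function(e)
        sum(dev * e) / (nd * sqrt(sum(e^2))) <= max_cos, logical(1)))
    if (ok) {
      mats[[length(mats) + 1L]] <- tg
      devs[[length(devs) + 1L]] <- dev
    }
    if (attempt %% 100L == 0L) {  # guarantee progress
      max_cos <- max_cos + 0.1
      norm_tol <- norm_tol + 0.1
    }
  }
  for (g in seq_len(n_groups)) {
    tg <- mats[[g]]
    for (m in seq_len(as.integer(members_per_group))) {
      noise <- random_transition_matrix(
        6, seed = .stage_seed(seed, 400L + g * 50L + m))
      tm <- (1 - jitter) * tg + jitter * noise
      id <- sprintf("gr%d_m%d", g, m)
      genomes[id] <- simulate_genome(synthetic_genome_spec(
        id, genome_length, tm,
        seed = .stage_seed(seed, 600L + g * 50L + m)))
      group <- c(group, g)
    }
  }
  list(genomes = genomes, group = group)
}

#' Generate a set of compositionally distinct genomes
#'
#' Convenience wrapper drawing `n` genomes, each from its own random
#' transition matrix, with all seeds derived from one master seed.
#'
#' @param n number of genomes.
#' @param length genome length (default 100000).
#' @param alpha Dirichlet concentration of the per-genome composition bias
#'   (default 6; see [random_transition_matrix()]).
#' @param seed master seed.
#' @return Named character vector of genome sequences (`g1`, `g2`, ...).
#' @export
simulate_metagenome_genomes <- function(n, length = 100000L, alpha = 6,
                                        seed = 1L) {
  n <- as.integer(n)
  out <- character(n)
  for (i in seq_len(n)) {
    tm <- random_transition_matrix(alpha,
                                   seed = .stage_seed(seed, 100L + i))
    out[i] <- simulate_genome(synthetic_genome_spec(
      paste0("g", i), length, tm, seed = .stage_seed(seed, 200L + i)))
  }
  stats::setNames(out, paste0("g", seq_len(n)))
}
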