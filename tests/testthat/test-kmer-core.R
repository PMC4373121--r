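# brute-force enumeration of canonical classes via string operations
enumerate_classes <- function(k, alphabet) {
  syms <- if (alphabet == "base") c("A", "C", "G", "T") else
    c("0", "1", "2", "3")
  words <- do.call(paste0, rev(expand.grid(rep(list(syms), k),
                                           stringsAsFactors = FALSE)))
  unique(oracle_canonical(words, alphabet))
}

test_that("canonical space sizes match brute-force class enumeration", {
  for (k in 1:8) {
    sp <- kmer_space(k, "base")
    classes <- enumerate_classes(k, "base")
    expect_equal(sp$n_bins, length(classes))
    expect_setequal(sp$bin_label, classes)
    # closed form for the base alphabet
    P <- if (k %% 2 == 0) 4^(k / 2) else 0
    expect_equal(sp$n_bins, (4^k + P) / 2)
  }
  for (k in 1:6) {
    sp <- kmer_space(k, "colour")
    expect_equal(sp$n_bins, length(enumerate_classes(k, "colour")))
  }
  expect_error(kmer_space(0), "between 1 and 12")
  expect_error(kmer_space(13), "between 1 and 12")
})

test_that("canonical_bin groups a k-mer with its strand partner", {
  sp <- kmer_space(4, "base")
  expect_equal(canonical_bin("ATTC", sp), canonical_bin("GAAT", sp))
  # AGCT is its own reverse complement: a singleton class
  agct_bin <- canonical_bin("AGCT", sp)
  expect_equal(sp$bin_label[agct_bin], "AGCT")
  words <- enumerate_classes(4, "base")
  all4 <- do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")),
                                              4), stringsAsFactors = FALSE)))
  members <- all4[canonical_bin(all4, sp) == agct_bin]
  expect_equal(members, "AGCT")

  spc <- kmer_space(4, "colour")
  expect_equal(canonical_bin("0123", spc), canonical_bin("3210", spc))

  expect_error(canonical_bin("ACG", sp), "length")
  expect_error(canonical_bin("ACGN", sp), "invalid or ambiguous")
})

test_that("counting matches hand enumeration on the reference examples", {
  sp <- kmer_space(4, "base")
  p <- count_kmers(read_set("r1", "ACGTACGT"), sp)
  expect_equal(p$total, 5)
  nz <- profile_nonzero(p)
  expect_equal(nz[["ACGT"]], 2)  # windows 1 and 5
  expect_equal(nz[["CGTA"]], 2)  # CGTA + TACG (reverse complements)
  expect_equal(nz[["GTAC"]], 1)
  expect_equal(sum(nz), 5)

  sp2 <- kmer_space(2, "base")
  p2 <- count_kmers(read_set("r1", "ACGNT"), sp2)
  expect_equal(p2$total, 2)  # GN and NT windows skipped

  p0 <- count_kmers(read_set(character(), character()), sp)
  expect_equal(p0$total, 0)
  expect_true(all(p0$counts == 0))
})

test_that("counting equals the naive canonicalize-and-tally oracle", {
  set.seed(21)
  for (rep in 1:40) {
    k <- sample(1:6, 1)
    alphabet <- sample(c("base", "colour"), 1)
    sp <- kmer_space(k, alphabet)
    syms <- random_read_strings(sample(1:30, 1), 60, alphabet,
                                p_ambiguous = 0.03)
    reads <- read_set(paste0("r", seq_along(syms)), syms, alphabet)
    got <- profile_nonzero(count_kmers(reads, sp))
    want <- oracle_count(syms, k, alphabet)
    expect_equal(sort(names(got)), sort(names(want)))
    expect_equal(got[sort(names(got))],
                 unlist(want)[sort(names(want))],
                 ignore_attr = TRUE)
  }
})

test_that("profiles are invariant under reverse-complementing every read", {
  set.seed(22)
  sp <- kmer_space(4, "base")
  for (rep in 1:10) {
    syms <- random_read_strings(20, 50, "base")
    fwd <- count_kmers(read_set(paste0("r", 1:20), syms), sp)
    rev <- count_kmers(read_set(paste0("r", 1:20), oracle_revcomp(syms)),
                       sp)
    expect_identical(fwd$counts, rev$counts)
  }
})

test_that("window totals follow the l - k + 1 rule without ambiguity", {
  set.seed(23)
  syms <- random_read_strings(25, 60, "base")
  for (k in c(1, 3, 5)) {
    p <- count_kmers(read_set(paste0("r", 1:25), syms), kmer_space(k))
    expect_equal(p$total, sum(pmax(0, nchar(syms) - k + 1)))
  }
})

test_that("profile merging is additive, commutative and space-checked", {
  set.seed(24)
  sp <- kmer_space(3, "base")
  s1 <- random_read_strings(10, 40, "base")
  s2 <- random_read_strings(15, 40, "base")
  p1 <- count_kmers(read_set(paste0("a", 1:10), s1), sp)
  p2 <- count_kmers(read_set(paste0("b", 1:15), s2), sp)
  both <- count_kmers(read_set(paste0("c", 1:25), c(s1, s2)), sp)
  expect_equal(merge_profiles(p1, p2)$counts, both$counts)
  expect_equal(merge_profiles(p2, p1)$counts, both$counts)
  zero <- kmer_profile(sp, rep(0, sp$n_bins))
  expect_equal(merge_profiles(p1, zero)$counts, p1$counts)
  expect_error(merge_profiles(p1, count_kmers(read_set("x", "ACGT"),
                                              kmer_space(4))),
               "different k-mer spaces")
})

test_that("alphabet mismatches between reads and space are rejected", {
  expect_error(count_kmers(read_set("r", "0123", "colour"), kmer_space(4)),
               "alphabet mismatch")
})

test_that("abundance histogram conserves bins and isolates spikes", {
  sp <- kmer_space(4, "base")
  uniform <- kmer_profile(sp, rep(10, sp$n_bins))
  h <- abundance_histogram(uniform, n_classes = 10)
  expect_equal(sum(h$n_bins), sp$n_bins)
  expect_equal(sum(h$n_bins > 0), 1L)  # single occupied class
  expect_equal(h$n_bins[nrow(h)], sp$n_bins)  # ... the top one

  counts <- rep(10, sp$n_bins)
  counts[7] <- 100  # 10x spike
  h2 <- abundance_histogram(kmer_profile(sp, counts), n_classes = 10)
  expect_equal(sum(h2$n_bins), sp$n_bins)
  expect_equal(h2$n_bins[nrow(h2)], 1L)  # spike alone in the top class

  zeroes <- c(rep(0, 36), rep(5, 100))
  h3 <- abundance_histogram(kmer_profile(sp, zeroes), n_classes = 5)
  expect_equal(h3$n_bins[1], 36)
  expect_equal(sum(h3$n_bins), sp$n_bins)
  expect_error(abundance_histogram(kmer_profile(sp, rep(0, sp$n_bins))),
               "no counted k-mers")
})

test_that("profile TSV round-trip is bit-exact", {
  set.seed(26)
  for (alphabet in c("base", "colour")) {
    sp <- kmer_space(4, alphabet)
    syms <- random_read_strings(20, 45, alphabet)
    p <- count_kmers(read_set(paste0("r", 1:20), syms, alphabet), sp,
                     sample_id = "rt-check")
    path <- tempfile(fileext = ".tsv")
    write_profile(p, path)
    q <- read_profile(path)
    expect_identical(q$counts, p$counts)
    expect_identical(q$total, p$total)
    expect_identical(q$sample_id, p$sample_id)
    expect_identical(q$space$n_bins, p$space$n_bins)
    expect_identical(q$space$alphabet, alphabet)
  }
})
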