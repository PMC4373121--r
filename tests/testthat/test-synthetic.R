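test_that("transition matrices are row-stochastic and seeded", {
  tm <- random_transition_matrix(6, seed = 71)
  expect_equal(rowSums(tm), rep(1, 4), ignore_attr = TRUE)
  expect_identical(tm, random_transition_matrix(6, seed = 71))
  expect_error(synthetic_genome_spec("g", 1000, matrix(1, 4, 4)),
               "rows summing to 1")
})

test_that("genome simulation is reproducible and length-true", {
  tm <- random_transition_matrix(6, seed = 72)
  spec <- synthetic_genome_spec("g1", 5000, tm, seed = 72)
  g1 <- simulate_genome(spec)
  g2 <- simulate_genome(spec)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 5000L)
  expect_false(grepl("[^ACGT]", g1))
})

test_that("an unbiased chain approaches maximal spectrum entropy", {
  sp <- kmer_space(4)
  uniform <- matrix(0.25, 4, 4)
  g <- simulate_genome(synthetic_genome_spec("u", 1e6, uniform, seed = 73))
  e <- shannon_entropy(count_kmers(g, sp))$entropy
  expect_gt(e, 0.99)

  gc_rich <- matrix(c(0.1, 0.4, 0.4, 0.1), 4, 4, byrow = TRUE)
  b <- simulate_genome(synthetic_genome_spec("b", 1e6, gc_rich, seed = 73))
  expect_lt(shannon_entropy(count_kmers(b, sp))$entropy, e)
})

test_that("expected profiles match long-run empirical spectra", {
  sp <- kmer_space(4)
  tm <- random_transition_matrix(6, seed = 74)
  want <- expected_kmer_profile(tm, sp)
  expect_equal(sum(want), 1, tolerance = 1e-12)
  g <- simulate_genome(synthetic_genome_spec("g", 5e5, tm, seed = 74))
  got <- kmer_frequencies(count_kmers(g, sp))
  expect_lt(max(abs(got - want)), 5e-4)
})

test_that("error-free reads are exact genome substrings on either strand", {
  genomes <- simulate_metagenome_genomes(2, 5000, seed = 75)
  reads <- simulate_reads(genomes, n_reads = 50, read_length = 35,
                          error_rate = 0, seed = 75)
  haystack <- c(genomes, oracle_revcomp(unname(genomes)))
  for (s in reads$symbols)
    expect_true(any(vapply(haystack, grepl, logical(1), pattern = s,
                           fixed = TRUE)))
  expect_equal(length(simulate_reads(genomes, n_reads = 0, seed = 1)), 0L)
  expect_error(simulate_reads(genomes, n_reads = 5, read_length = 9999),
               "read_length exceeds")
  expect_identical(reads$symbols,
                   simulate_reads(genomes, n_reads = 50, read_length = 35,
                                  seed = 75)$symbols)
})

test_that("substitution errors hit roughly the requested rate", {
  genomes <- simulate_metagenome_genomes(1, 5000, seed = 76)
  clean <- simulate_reads(genomes, n_reads = 200, read_length = 35,
                          error_rate = 0, seed = 76)
  noisy <- simulate_reads(genomes, n_reads = 200, read_length = 35,
                          error_rate = 0.05, seed = 76)
  mism <- mapply(function(a, b)
    sum(utf8ToInt(a) != utf8ToInt(b)), clean$symbols, noisy$symbols)
  expect_gt(mean(mism) / 35, 0.02)
  expect_lt(mean(mism) / 35, 0.09)
})

test_that("dilution steps split genome and cassette reads exactly", {
  genomes <- simulate_metagenome_genomes(3, 3000, seed = 77)
  spec <- dilution_series_spec(genomes, n_reads = 1000,
                               contamination_fractions = c(0, 0.5),
                               seed = 77)
  ser <- simulate_dilution_series(spec)
  expect_equal(length(ser[[1]]$reads), 1000L)
  expect_false(any(startsWith(ser[[1]]$reads$read_id, "cas")))
  expect_equal(sum(startsWith(ser[[2]]$reads$read_id, "cas")), 500L)
  expect_equal(length(ser[[2]]$reads), 1000L)

  expect_error(dilution_series_spec(genomes,
                                    contamination_fractions = c(0, 1)),
               "\\[0, 1\\)")
  expect_error(dilution_series_spec(genomes,
                                    contamination_fractions = c(0.5, 0.1)),
               "non-decreasing")
})

test_that("the same series spec reproduces bit-identical read sets", {
  genomes <- simulate_metagenome_genomes(3, 3000, seed = 78)
  spec <- dilution_series_spec(genomes, n_reads = 500,
                               contamination_fractions = c(0, 0.3),
                               seed = 78)
  s1 <- simulate_dilution_series(spec)
  s2 <- simulate_dilution_series(spec)
  for (i in seq_along(s1))
    expect_identical(s1[[i]]$reads$symbols, s2[[i]]$reads$symbols)
})

test_that("genome-derived reads alone have stable entropy across steps", {
  sp <- kmer_space(4)
  genomes <- simulate_metagenome_genomes(8, 30000, seed = 79)
  spec <- dilution_series_spec(genomes, n_reads = 10000, seed = 79)
  ser <- simulate_dilution_series(spec)
  ents <- vapply(ser, function(s) {
    gen <- s$reads[startsWith(s$reads$read_id, "gen")]
    shannon_entropy(count_kmers(gen, sp))$entropy
  }, numeric(1))
  expect_lt(diff(range(ents)), 0.005)
})

test_that("planted genome groups have the declared shape and determinism", {
  gg <- simulate_genome_groups(3, members_per_group = 2,
                               genome_length = 2000, seed = 80)
  expect_length(gg$genomes, 6L)
  expect_equal(gg$group, rep(1:3, each = 2))
  expect_equal(names(gg$genomes)[1], "gr1_m1")
  gg2 <- simulate_genome_groups(3, members_per_group = 2,
                                genome_length = 2000, seed = 80)
  expect_identical(gg$genomes, gg2$genomes)
  expect_error(simulate_genome_groups(1), "at least 2")
})

test_that("series fixtures write files plus a faithful manifest", {
  dir <- tempfile()
  genomes <- simulate_metagenome_genomes(2, 2000, seed = 81)
  spec <- dilution_series_spec(genomes, n_reads = 100,
                               contamination_fractions = c(0, 0.2, 0.4),
                               seed = 81)
  ser <- simulate_dilution_series(spec)
  manifest <- write_dilution_series(ser, genomes, dir)
  tab <- read.delim(manifest)
  expect_equal(nrow(tab), 3L)
  expect_true(all(file.exists(file.path(dir, tab$file))))
  expect_equal(tab$contamination_fraction, c(0, 0.2, 0.4))
  back <- parse_fasta(file.path(dir, tab$file[2]))
  expect_equal(length(back), 100L)
  expect_true(file.exists(file.path(dir, "genomes.fasta")))
})

test_that("flat key-value specs parse, with field errors named", {
  path <- tempfile(fileext = ".spec")
  writeLines(c("# demo", "n_genomes = 2", "genome_length = 1500",
               "n_reads = 50", "cassette = GCAGCAGCAGCA",
               "contamination_fractions = 0,0.4", "seed = 5"), path)
  spec <- read_series_spec(path)
  expect_s3_class(spec, "dilution_series_spec")
  expect_length(spec$genomes, 2L)
  expect_equal(spec$contamination_fractions, c(0, 0.4))

  writeLines(c("n_genomes = 2", "bad line without equals"), path)
  expect_error(read_series_spec(path), "malformed spec line")
  writeLines(c("n_genomes = 2", "genome_length = 1500",
               "contamination_fractions = 0,oops"), path)
  expect_error(read_series_spec(path), "contamination_fractions")
})
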