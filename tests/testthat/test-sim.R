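reg <- recA_reference()

test_that("population initialization conserves counts and matches pmf(0)", {
  sc0 <- doping_scheme(data.frame(length_nt = 177L, sub_prob = 0))
  pop0 <- withr::with_seed(1, initialize_population(reg, sc0, 500))
  expect_equal(nrow(pop0), 1L)
  expect_equal(pop0$label, "WT")
  expect_equal(sum(pop0$count), 500)

  sc <- doping_scheme(efficiency = 0.5)
  n <- 20000L
  pop <- withr::with_seed(2, initialize_population(reg, sc, n))
  expect_equal(sum(pop$count), n)
  p0 <- unname(substitution_count_pmf(sc, 1)$pmf["0"])
  # WT-protein label includes silent-only molecules, so compare the
  # unmutated-sequence count, not the label
  wt_seq_count <- pop$count[pop$seq == region_sequence(reg)]
  se <- sqrt(n * p0 * (1 - p0))
  expect_lt(abs(wt_seq_count - n * p0), 4 * se)
})

test_that("neutral selection is a martingale with multinomial variance", {
  pop <- data.frame(seq = c("A", "B"), count = c(30, 70),
                    label = c("WT", "X1Y"))
  B <- 100L
  reps <- 10000L
  f <- withr::with_seed(5, vapply(seq_len(reps), function(i) {
    out <- selection_cycle(pop, variant_fitness(), B)
    sum(out$count[out$seq == "B"]) / B
  }, numeric(1)))
  se <- sqrt(0.3 * 0.7 / B) / sqrt(reps)
  expect_lt(abs(mean(f) - 0.7), 3 * se)
  v_expected <- 0.3 * 0.7 / B
  expect_lt(abs(var(f) - v_expected) / v_expected, 0.1)
})

test_that("fitness reweights expected frequencies by f*w / sum(f*w)", {
  pop <- data.frame(seq = c("A", "B"), count = c(50, 50),
                    label = c("WT", "V79L"))
  fit <- variant_fitness(c(V79L = 3))
  det <- selection_cycle(pop, fit, 1000L, deterministic = TRUE)
  expect_equal(det$count, c(250, 750))

  f <- withr::with_seed(6, vapply(seq_len(4000), function(i) {
    out <- selection_cycle(pop, fit, 200L)
    sum(out$count[out$seq == "B"]) / 200
  }, numeric(1)))
  se <- sqrt(0.75 * 0.25 / 200) / sqrt(4000)
  expect_lt(abs(mean(f) - 0.75), 3 * se)
})

test_that("deterministic mode reproduces the logistic frequency update", {
  pop <- data.frame(seq = c("A", "B"), count = c(0.99, 0.01),
                    label = c("WT", "V79L"))
  fit <- variant_fitness(c(V79L = 2.8))
  for (cy in 1:6) pop <- selection_cycle(pop, fit, 1L, deterministic = TRUE)
  f6 <- pop$count[pop$seq == "B"] / sum(pop$count)
  closed <- logistic_selection_trajectory(0.01, 2.8, 6)[6]
  expect_equal(f6, closed, tolerance = 1e-12)
  expect_equal(closed, 0.01 * 2.8^6 / (0.99 + 0.01 * 2.8^6))
  expect_equal(closed, 0.829, tolerance = 1e-3)
  expect_error(selection_cycle(pop, fit, 0), "bottleneck")
})

test_that("error-free reads from a wild-type population match the reference", {
  pop <- data.frame(seq = region_sequence(reg), count = 10, label = "WT")
  cfg <- sequencing_config(pairs_per_cycle = 25L, error_rate = 0)
  rd <- withr::with_seed(7, generate_reads(pop, reg, cfg))
  amp_start <- attr(rd, "amplicon_cds_start")
  amplicon <- substr(reg$cds, amp_start, 411 + cfg$flank)
  expect_equal(nrow(rd), 25L)
  for (i in seq_len(nrow(rd))) {
    m <- merge_read_pairs(rd$fwd_seq[i], rd$fwd_qual[i],
                          rd$rev_seq[i], rd$rev_qual[i])
    expect_true(m$merged)
    expect_equal(m$sequence, amplicon)
  }
})

test_that("sequencing errors occur at the configured per-base rate", {
  pop <- data.frame(seq = region_sequence(reg), count = 1, label = "WT")
  cfg <- sequencing_config(pairs_per_cycle = 2000L, error_rate = 0.01)
  rd <- withr::with_seed(8, generate_reads(pop, reg, cfg))
  amp_start <- attr(rd, "amplicon_cds_start")
  amplicon <- substr(reg$cds, amp_start, 411 + cfg$flank)
  fwd_truth <- substr(amplicon, 1, cfg$read_length)
  mism <- vapply(rd$fwd_seq, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(fwd_truth, "")[[1]])
  }, numeric(1), USE.NAMES = FALSE)
  n_bases <- nrow(rd) * cfg$read_length
  expect_lt(abs(mean(mism) - cfg$read_length * 0.01),
            3 * sqrt(n_bases * 0.01 * 0.99) / nrow(rd))
})

test_that("a neutral single-cycle experiment preserves initial frequencies", {
  sc0 <- doping_scheme(data.frame(length_nt = 177L, sub_prob = 0))
  ex <- run_experiment(reg, sc0, variant_fitness(),
                       selection_config(bottlenecks = 500L,
                                        initial_size = 500L, seed = 9),
                       sequencing_config(pairs_per_cycle = 50L,
                                         error_rate = 0, seed = 10),
                       sequence_cycles = 1L)
  expect_equal(ex$truth[["1"]],
               data.frame(change = "WT", fraction = 1))
})

test_that("experiments are byte-identical under identical seeds", {
  sc <- doping_scheme(efficiency = 0.3)
  args <- list(reg, sc, variant_fitness(c(V79L = 2.8)),
               selection_config(bottlenecks = c(200L, 100L),
                                initial_size = 1000L, seed = 11),
               sequencing_config(pairs_per_cycle = 100L, seed = 12),
               sequence_cycles = 1:2)
  ex1 <- do.call(run_experiment, args)
  ex2 <- do.call(run_experiment, args)
  expect_identical(ex1$reads, ex2$reads)
  expect_identical(ex1$truth, ex2$truth)

  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  g1 <- tempfile(fileext = ".fastq")
  g2 <- tempfile(fileext = ".fastq")
  write_fastq_pairs(ex1$reads[["2"]], f1, f2)
  write_fastq_pairs(ex2$reads[["2"]], g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
  unlink(c(f1, f2, g1, g2))
})

test_that("an advantaged variant rises deterministically across cycles", {
  pop <- data.frame(seq = c("A", "B"), count = c(0.99, 0.01),
                    label = c("WT", "V79L"))
  fit <- variant_fitness(c(V79L = 2.8))
  f <- numeric(6)
  for (cy in 1:6) {
    pop <- selection_cycle(pop, fit, 1L, deterministic = TRUE)
    f[cy] <- pop$count[pop$seq == "B"] / sum(pop$count)
  }
  expect_true(all(diff(f) > 0))
  expect_equal(f, logistic_selection_trajectory(0.01, 2.8, 6),
               tolerance = 1e-12)
})
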