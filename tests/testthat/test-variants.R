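reg <- recA_reference()
win_seq <- region_sequence(reg)

test_that("substitution calling reports edits and coverage correctly", {
  # perfect read covering the whole window
  a <- smith_waterman(win_seq, reg$cds)
  calls <- call_substitutions(a, reg)
  expect_equal(nrow(calls$substitutions), 0L)
  expect_true(all(calls$covered))

  # single known edit at the first window base (CDS 235, codon 79 base 1),
  # on an amplicon-style read with flanks so the edit is internal
  amp <- substr(reg$cds, 205, 441)
  mut <- amp
  substr(mut, 235 - 204, 235 - 204) <- "C"
  calls2 <- call_substitutions(smith_waterman(mut, reg$cds), reg)
  expect_equal(calls2$substitutions,
               data.frame(cds_pos = 235L, ref = substr(win_seq, 1, 1),
                          alt = "C"))
  expect_true(all(calls2$covered))

  # 3-nt deletion spanning CDS 300-302: no calls there, mask uncovered
  del <- paste0(substr(reg$cds, 205, 299), substr(reg$cds, 303, 441))
  calls3 <- call_substitutions(smith_waterman(del, reg$cds), reg)
  expect_equal(nrow(calls3$substitutions), 0L)
  expect_false(any(calls3$covered[as.character(300:302)]))
  expect_true(all(calls3$covered[as.character(235:299)]))
  expect_true(all(calls3$covered[as.character(303:411)]))

  # N bases are uncovered, not variant
  nn <- win_seq
  substr(nn, 10, 10) <- "N"
  calls4 <- call_substitutions(smith_waterman(nn, reg$cds), reg)
  expect_equal(nrow(calls4$substitutions), 0L)
  expect_false(calls4$covered[["244"]])
})

test_that("genotype translation classifies silent and missense changes", {
  none <- translate_genotype(data.frame(cds_pos = integer(), ref = character(),
                                        alt = character()), reg)
  expect_equal(none$class, "wild_type_protein")
  expect_equal(none$label, "WT")

  # E86G (GAA>GGA at codon 86 base 2 = CDS 257) and C90G (TGC>GGC, CDS 268)
  dbl <- translate_genotype(data.frame(cds_pos = c(257L, 268L),
                                       ref = c("A", "T"), alt = c("G", "G")),
                            reg)
  expect_setequal(dbl$aa_changes, c("E86G", "C90G"))
  expect_equal(dbl$class, "double")

  # third-position synonymous change: GAA>GAG is still Glu
  silent <- translate_genotype(data.frame(cds_pos = 258L, ref = "A",
                                          alt = "G"), reg)
  expect_equal(silent$class, "wild_type_protein")
  expect_equal(nrow(silent$nt_substitutions), 1L)

  expect_error(translate_genotype(data.frame(cds_pos = 100L, ref = "A",
                                             alt = "G"), reg),
               "outside")
})

test_that("population tables threshold, split and sum correctly", {
  wt <- translate_genotype(data.frame(cds_pos = integer(), ref = character(),
                                      alt = character()), reg)
  v79l <- translate_genotype(data.frame(cds_pos = 235L, ref = "G", alt = "T"),
                             reg)
  expect_equal(v79l$label, "V79L")

  t1 <- tabulate_population(rep(list(wt), 100), cycle = 1)
  expect_equal(unname(t1$class_fractions[["wild_type_protein"]]), 1)
  expect_equal(nrow(t1$labels), 0L)

  t2 <- tabulate_population(c(rep(list(wt), 90), rep(list(v79l), 10)),
                            cycle = 1)
  expect_equal(t2$labels$fraction[t2$labels$change == "V79L"], 0.10)
  expect_true(t2$labels$reported[t2$labels$change == "V79L"])
  expect_equal(sum(t2$class_fractions), 1)

  # one read in a thousand is at threshold and suppressed (strict >)
  t3 <- tabulate_population(c(rep(list(wt), 995), rep(list(v79l), 5)),
                            threshold = 0.005)
  expect_false(t3$labels$reported[t3$labels$change == "V79L"])
  expect_equal(t3$labels$fraction[t3$labels$change == "V79L"], 0.005)
  expect_error(tabulate_population(list()), "no classified reads")
})

test_that("multi-mutant reads contribute to every label with context split", {
  v79l_e86g <- translate_genotype(
    data.frame(cds_pos = c(235L, 257L), ref = c("G", "A"), alt = c("T", "G")),
    reg)
  expect_equal(v79l_e86g$class, "double")
  wt <- translate_genotype(data.frame(cds_pos = integer(), ref = character(),
                                      alt = character()), reg)
  tab <- tabulate_population(c(rep(list(wt), 8), rep(list(v79l_e86g), 2)))
  for (lb in c("V79L", "E86G")) {
    row <- tab$labels[tab$labels$change == lb, ]
    expect_equal(row$fraction, 0.2)
    expect_equal(row$double, 0.2)
    expect_equal(row$single, 0)
  }
})

test_that("per-position counts decompose into reference plus alternatives", {
  sc <- doping_scheme(efficiency = 0.3)
  withr::with_seed(55, {
    pop <- initialize_population(reg, sc, 300)
    rd <- generate_reads(pop, reg, sequencing_config(pairs_per_cycle = 300L,
                                                     error_rate = 0.01))
  })
  amp_start <- attr(rd, "amplicon_cds_start")
  amp_ref <- substr(reg$cds, amp_start, 411 + 30)
  pr <- process_read_pairs(rd, reg, reference = amp_ref,
                           ref_cds_start = amp_start)
  pc <- pr$position_counts
  expect_true(all(pc$covered == pc$ref + pc$alt))
  base_sum <- pc$A + pc$C + pc$G + pc$T
  expect_true(all(pc$covered == base_sum))
  expect_gt(sum(pc$alt), 0)  # errors present at 1%
})

test_that("silent-only reads never surface as protein-level variants", {
  # build reads for a synonymous-only genotype and push them through
  syn <- win_seq
  stopifnot(substr(win_seq, 22, 24) == "GAA")
  substr(syn, 24, 24) <- "G"  # codon 86 GAA>GAG, synonymous Glu
  pop <- data.frame(seq = syn, count = 10,
                    label = evoselect:::window_labels(syn, reg))
  expect_equal(pop$label, "WT")
  rd <- withr::with_seed(3, generate_reads(pop, reg, sequencing_config(
    pairs_per_cycle = 20L, error_rate = 0)))
  amp_start <- attr(rd, "amplicon_cds_start")
  pr <- process_read_pairs(rd, reg,
                           reference = substr(reg$cds, amp_start, 441),
                           ref_cds_start = amp_start)
  tab <- tabulate_population(pr$records)
  expect_equal(nrow(tab$labels), 0L)
  expect_equal(unname(tab$class_fractions[["wild_type_protein"]]), 1)
  # the nucleotide change itself is still visible positionally
  expect_gt(sum(pr$position_counts$alt), 0)
})

test_that("miscall background estimation recovers an injected error rate", {
  sc0 <- doping_scheme(data.frame(length_nt = 177L, sub_prob = 0))
  withr::with_seed(77, {
    pop <- initialize_population(reg, sc0, 50)
    rd <- generate_reads(pop, reg, sequencing_config(pairs_per_cycle = 2000L,
                                                     error_rate = 0.009))
  })
  amp_start <- attr(rd, "amplicon_cds_start")
  pr <- process_read_pairs(rd, reg,
                           reference = substr(reg$cds, amp_start, 441),
                           ref_cds_start = amp_start)
  mr <- estimate_miscall_rate(pr$position_counts)
  expect_equal(mr, 0.009 / 3, tolerance = 0.35)
  expect_equal(aa_change_routes("I80L", reg), 2L)  # ATA > CTA or TTA
  expect_equal(aa_change_routes("V79L", reg), 2L)  # GTG > TTG or CTG
})

test_that("enrichment trajectories flag monotone risers and fold changes", {
  mk_tab <- function(fractions, cycle, n = 1000) {
    wt <- translate_genotype(data.frame(cds_pos = integer(), ref = character(),
                                        alt = character()), reg)
    v <- translate_genotype(data.frame(cds_pos = 235L, ref = "G", alt = "T"),
                            reg)
    k <- round(fractions * n)
    tabulate_population(c(rep(list(wt), n - k), rep(list(v), k)),
                        cycle = cycle)
  }
  rising <- lapply(1:3, function(i) mk_tab(c(0.01, 0.02, 0.04)[i], i))
  tr <- enrichment_trajectories(rising)
  s <- attr(tr, "summary")
  expect_true(s$monotone[s$change == "V79L"])
  expect_equal(s$fold_change[s$change == "V79L"], 4)

  flat <- lapply(1:3, function(i) mk_tab(0.02, i))
  s2 <- attr(enrichment_trajectories(flat), "summary")
  expect_false(s2$monotone[s2$change == "V79L"])
  expect_equal(s2$fold_change[s2$change == "V79L"], 1)

  expect_error(enrichment_trajectories(rev(rising)), "strictly increasing")
  expect_error(enrichment_trajectories(rising[1]), "at least 2")
})
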