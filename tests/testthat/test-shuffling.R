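# The three null models: gc3 (GC3-correcting), n3 (composition-preserving
# permutation), dn23 (dinucleotide-frequency weighted).

test_that("gc3 option probabilities implement the mass-splitting rule", {
  # 10 codons, 6 with G/C third position, Ile (class H) in slot 1
  s <- paste0("ATC", strrep("GAC", 5), "ATT", "ATT", "GAT", "GAT")
  expect_equal(bf_gc3(s), 0.6)
  p <- gc3_option_probs(s)
  ile <- p[p$codon_index == 1, ]
  expect_equal(ile$prob[ile$option == "ATC"], 0.6)
  expect_equal(ile$prob[ile$option == "ATT"], 0.2)
  expect_equal(ile$prob[ile$option == "ATA"], 0.2)
  # two-codon family (Asp, Y class) in the same sequence: P(GC option) = g
  asp <- p[p$codon == "GAC", ][1:2, ]
  expect_equal(asp$prob[asp$option == "GAC"], 0.6)
  expect_equal(asp$prob[asp$option == "GAT"], 0.4)
  # per-codon probabilities always sum to 1
  expect_equal(as.numeric(tapply(p$prob, p$codon_index, sum)),
               rep(1, length(unique(p$codon_index))))
})

test_that("all three shufflers preserve the translation on random inputs", {
  set.seed(101)
  for (i in 1:350) {
    s <- random_seq(sample(3:25, 1), stop_free = FALSE)
    aa <- bf_translate(s)
    suppressWarnings({ # internal stops are tolerated with a warning
      expect_identical(bf_translate(gc3_shuffle(s)), aa)
      expect_identical(bf_translate(n3_shuffle(s)), aa)
      expect_identical(bf_translate(dn23_shuffle(s)), aa)
    })
  }
})

test_that("n3 preserves the base composition of the whole sequence exactly", {
  set.seed(7)
  for (i in 1:100) {
    s <- random_seq(sample(5:40, 1))
    sh <- n3_shuffle(s)
    expect_identical(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
})

test_that("sequences of only FIXED codons are returned unchanged", {
  s <- strrep("ATGTGG", 4)
  set.seed(5)
  expect_identical(gc3_shuffle(s), s)
  expect_identical(n3_shuffle(s), s)
  expect_identical(dn23_shuffle(s), s)
})

test_that("n3 is the identity when every degeneracy class is a singleton", {
  s <- "ATGATTGAACCA" # FIXED, single H, single R, single N
  set.seed(2)
  expect_identical(n3_shuffle(s), s)
})

test_that("dn23 weights are proportional to subject dinucleotide frequencies", {
  # positions 2-3 dinucleotides: 3 x TT, 1 x TC, 6 x AA -> f(TT)/f(TC) = 3
  s <- paste0(strrep("ATT", 3), "TTC", strrep("CAA", 6))
  w <- dn23_option_probs(s)
  ile <- w[w$codon_index == 1, ]
  expect_equal(ile$weight[ile$option == "ATT"] /
                 ile$weight[ile$option == "ATC"], 3)
  expect_equal(ile$prob[ile$option == "ATT"], 0.3 / 0.4)
  # cross-check against the brute-force oracle on every codon slot
  oracle <- oracle_dn23_probs("ATTGAACCACTA")
  w2 <- dn23_option_probs("ATTGAACCACTA")
  p_first <- tapply(oracle, substr(names(oracle), 1, 3), sum)
  ile2 <- w2[w2$codon_index == 1, ]
  expect_equal(as.numeric(p_first[ile2$option]), ile2$prob)
})

test_that("dn23 falls back to a uniform draw when all option weights vanish", {
  plan <- shuffle_plan("ATTGAA")
  plan$dn_freq[] <- 0 # pathological table (unreachable from real input)
  w <- dn23_option_probs(plan)
  expect_equal(w$prob[w$codon_index == 1], rep(1 / 3, 3))
  set.seed(3)
  draws <- replicate(300, substr(dn23_shuffle(plan), 3, 3))
  expect_true(all(c("A", "C", "T") %in% draws))
})

test_that("generate_null is reproducible and validates its arguments", {
  s <- random_seq(20)
  a <- generate_null(s, "gc3", r = 5, seed = 11)
  b <- generate_null(s, "gc3", r = 5, seed = 11)
  expect_identical(a, b)
  expect_length(a, 5)
  expect_true(all(vapply(a, bf_translate, character(1)) == bf_translate(s)))
  c1 <- generate_null(s, "n3", r = 4, seed = 1)
  comp <- function(x) sort(strsplit(x, "")[[1]])
  for (x in c1) expect_identical(comp(x), comp(s))
  expect_error(generate_null(s, "bogus", r = 2), "arg")
  expect_error(generate_null(s, "gc3", r = 0), "positive")
})

test_that("gc3 draws match the exact per-option distribution (GOF)", {
  s <- "ATGATTGAACCA" # FIXED, H, R, N: 24 synonymous variants
  probs <- oracle_gc3_probs(s)
  draws <- generate_null(s, "gc3", r = 2e4, seed = 31)
  expect_gt(gof_pvalue(draws, probs), 1e-3)
})

test_that("n3 draws are uniform over within-class permutations (GOF)", {
  s <- "ATTATCGAAGAG" # H set {T,C}, R set {A,G}
  probs <- oracle_n3_probs(s)
  expect_length(probs, 4)
  expect_equal(as.numeric(probs), rep(0.25, 4))
  draws <- generate_null(s, "n3", r = 1e4, seed = 32)
  expect_gt(gof_pvalue(draws, probs), 1e-3)
})

test_that("dn23 draws match the exact weighted distribution (GOF)", {
  s <- "ATTGAACCACTA"
  probs <- oracle_dn23_probs(s)
  draws <- generate_null(s, "dn23", r = 2e4, seed = 33)
  expect_gt(gof_pvalue(draws, probs), 1e-3)
})

test_that("gc3_include_fixed = FALSE drops FIXED codons from the GC3 statistic", {
  s <- "ATGTGGGAT" # two FIXED (G thirds) + one Asp (T third)
  expect_equal(shuffle_plan(s)$g, 2 / 3)
  expect_equal(shuffle_plan(s, gc3_include_fixed = FALSE)$g, 0)
})

test_that("dn23 keeps the subject's dinucleotide spectrum typical of its null", {
  # the method maintains positions-2-3 dinucleotide frequencies only
  # approximately: the subject's frequencies must sit well inside the
  # null's own per-replicate spread (within 3 SD for every dinucleotide)
  subj <- fixed_free_seq(60, seed = 601)
  reps <- generate_null(subj, "dn23", r = 2000, seed = 601)
  target <- dinuc_freq_23(subj)
  freqs <- t(vapply(reps, dinuc_freq_23, numeric(16)))
  for (j in seq_len(16)) {
    spread <- sd(freqs[, j])
    if (spread == 0) {
      expect_equal(mean(freqs[, j]), target[j])
    } else {
      expect_lt(abs(mean(freqs[, j]) - target[j]), 3 * spread)
    }
  }
})
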