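test_that("reverse complement handles IUPAC codes", {
  expect_equal(reverse_complement("TAC"), "GTA")
  expect_equal(reverse_complement("CG"), "CG")
  expect_equal(reverse_complement("WRC"), "GYW")
  expect_equal(reverse_complement("SYC"), "GRS")
  expect_error(reverse_complement("AXC"), "invalid IUPAC")
})

test_that("motif_spec validates patterns and defaults the target to the 3'-most C", {
  m <- motif_spec("TAC")
  expect_equal(m$target_index, 2L)
  expect_equal(m$strand, "both")
  expect_equal(motif_spec("CG")$target_index, 0L)
  expect_equal(motif_spec("CCC")$target_index, 2L)
  expect_equal(motif_spec("CCC", target_index = 0)$target_index, 0L)
  expect_error(motif_spec("TAW"), "no literal C")
  expect_error(motif_spec("TAC", target_index = 1), "does not point at")
  expect_error(motif_spec("C"), "length >= 2")
})

test_that("occurrence positions follow the two-strand mapping", {
  # bottom-strand GTA counts as a TAC occurrence with the G mutated
  occ <- find_occurrences("GTAGGG", motif_spec("TAC"))
  expect_equal(occ$strand, "bottom")
  expect_equal(occ$position, 0L)
  # overlapping matches all count
  occ <- find_occurrences("CCCCCC", motif_spec("CCC", strand = "top"))
  expect_equal(occ$position, c(2L, 3L, 4L, 5L))
  # left-to-right scan on the top strand
  occ <- find_occurrences("TACTAC", motif_spec("TAC", strand = "top"))
  expect_equal(occ$position, c(2L, 5L))
})

test_that("counts match the worked examples", {
  expect_equal(count_motifs("TAC", motif_spec("TAC")), 1L)
  expect_equal(count_motifs("GTA", motif_spec("TAC")), 1L)
  expect_equal(count_motifs("TACGTA", motif_spec("TAC")), 2L)
})

test_that("replacement transitions follow the genetic code", {
  tac <- motif_spec("TAC")
  expect_equal(count_replacement_transitions("TAC", tac), 0L) # TAC>TAT silent
  expect_equal(count_replacement_transitions("TTACGG", tac), 1L) # CGG>TGG
  expect_equal(count_replacement_transitions("GTAGGG", tac), 1L) # GTA>ATA
  # stop creation counts as a replacement: TGG>TGA via bottom-strand CCA
  cca <- motif_spec("CCA", target_index = 1)
  expect_equal(count_replacement_transitions("TGG", cca), 1L)
})

test_that("motif metrics assemble the count / repTr / fraction triple", {
  m <- motif_metrics("TTACGG", motif_spec("TAC"))
  expect_equal(m$count, 1L)
  expect_equal(m$rep_tr, 1L)
  expect_equal(m$rep_tr_frac, 1)
  none <- motif_metrics("AAAAAA", motif_spec("TAC"))
  expect_equal(none$count, 0L)
  expect_true(is.na(none$rep_tr_frac))
  set.seed(6)
  for (i in 1:25) {
    mm <- motif_metrics(random_seq(30), motif_spec("WRC"))
    expect_lte(mm$rep_tr, mm$count)
    if (mm$count > 0) expect_equal(mm$rep_tr_frac, mm$rep_tr / mm$count)
  }
})

test_that("default motif set is the 23-motif vocabulary", {
  ms <- default_motif_set()
  expect_length(ms, 23)
  names <- vapply(ms, `[[`, character(1), "name")
  expect_true(all(c("AC", "CC", "GC", "TC", "TAC", "WRC", "SYC", "CG")
                  %in% names))
  expect_equal(sum(nchar(names) == 3), 18) # 16 NNC + WRC + SYC
  for (m in ms) {
    expect_equal(substr(m$pattern, m$target_index + 1, m$target_index + 1),
                 "C")
    expect_equal(m$strand, "both")
  }
})

test_that("scanner agrees with the naive two-strand oracle on random sequences", {
  set.seed(42)
  motifs <- list(motif_spec("TC", name = "TC"), motif_spec("TAC"),
                 motif_spec("WRC"), motif_spec("SYC"), motif_spec("CG"),
                 motif_spec("GCC", target_index = 1, strand = "top"),
                 motif_spec("TTC", strand = "bottom"))
  for (i in 1:60) {
    s <- random_seq(sample(4:30, 1), stop_free = FALSE)
    for (m in motifs) {
      got <- suppressWarnings(find_occurrences(s, m))
      want <- naive_scan(s, m$pattern, m$target_index, m$strand)
      for (st in c("top", "bottom")) {
        expect_equal(sort(got$position[got$strand == st]),
                     sort(want$position[want$strand == st]),
                     info = paste(s, m$name, st))
      }
    }
  }
})

test_that("both-strand counts are strand symmetric", {
  set.seed(8)
  for (i in 1:40) {
    s <- random_seq(sample(4:30, 1))
    rc <- bf_revcomp(s)
    for (m in list(motif_spec("TC", name = "TC"), motif_spec("WRC"))) {
      expect_equal(count_motifs(s, m), suppressWarnings(count_motifs(rc, m)))
    }
  }
})

test_that("motif containment implies count monotonicity", {
  set.seed(9)
  for (i in 1:40) {
    s <- random_seq(sample(5:40, 1))
    expect_lte(count_motifs(s, motif_spec("CCC")),
               count_motifs(s, motif_spec("SYC")))
    expect_lte(count_motifs(s, motif_spec("TTC")),
               count_motifs(s, motif_spec("TC", name = "TC")))
  }
})

test_that("per-codon replacement shortcut equals full re-translation", {
  set.seed(10)
  for (i in 1:40) {
    s <- random_seq(sample(4:25, 1), stop_free = FALSE)
    for (m in list(motif_spec("TC", name = "TC"), motif_spec("WRC"),
                   motif_spec("CG"))) {
      occ <- suppressWarnings(find_occurrences(s, m))
      brute <- 0
      for (k in seq_len(nrow(occ))) {
        chars <- strsplit(s, "")[[1]]
        chars[occ$position[k] + 1] <-
          if (occ$strand[k] == "top") "T" else "A"
        if (bf_translate(paste(chars, collapse = "")) != bf_translate(s)) {
          brute <- brute + 1
        }
      }
      expect_equal(suppressWarnings(count_replacement_transitions(s, m)), brute,
                   info = paste(s, m$name))
    }
  }
})
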