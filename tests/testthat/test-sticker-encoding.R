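# Golden strings below are frozen from the published sticker tables; the
# comparisons strip whitespace (table typography groups codons/quartets).

golden_A1 <- c(
  init0 = "CGGTCTT",
  acc2  = "CCGGCAG",
  t0s0  = "AACGTTCCGTCGCTT",
  t0u1  = "AACGTTCCGCGCCTTAAC",
  t0s2  = "AACGTTCCGTCGCTTAACGTT",
  t1s1  = "GTTCCGTCGCTTAAC",
  t1q2  = "GTTCCGGGGCTTAACGTT")

golden_A5 <- c(
  init0 = "GCGA GCT",
  acc2  = "TAC GCCG",
  t0p10 = "TAG CCT TAC CTA GCT",
  t0p0  = "TAG CCT TAC ATA GCT",
  t0q11 = "TAG CCT TAC TAT GCT TAG",
  t0q2  = "TAG CCT TAC ACT GCT TAG CCT",
  t1p21 = "CCT TAC CTT GCT TAG",
  t1q22 = "CCT TAC AAG GCT TAG CCT",
  t2p0  = "TAC ATA GCT",
  t2q2  = "TAC ACT GCT TAG CCT")

golden_A4 <- c(
  init0 = "CGTC AGCC",
  acc4  = "ACGT ACCT GCAT TTGG",
  t0m11 = "GCGT AGTA CACC AGAA ACGT ACCT GCAT CACT AGCC GCGT",
  t0m22 = "GCGT AGTA CACC AGAA ACGT ACCT GCAT CTGG AGCC GCGT AGTA",
  t1p11 = "AGTA CACC AGAA ACGT ACCT GCAT GGCG AGCC GCGT",
  t1q12 = "AGTA CACC AGAA ACGT ACCT GCAT TAGG AGCC GCGT AGTA",
  t2m33 = "CACC AGAA ACGT ACCT GCAT TTGC AGCC GCGT AGTA CACC",
  t2m44 = "CACC AGAA ACGT ACCT GCAT CTGC AGCC GCGT AGTA CACC AGAA",
  t3p23 = "AGAA ACGT ACCT GCAT GTTT AGCC GCGT AGTA CACC",
  t3q24 = "AGAA ACGT ACCT GCAT CCCT AGCC GCGT AGTA CACC AGAA")

expect_sticker_table <- function(sticker_set, golden) {
  expect_identical(nrow(sticker_set), length(golden))
  got <- stats::setNames(sticker_set$pairing, sticker_set$id)
  expect_setequal(names(got), names(golden))
  for (id in names(golden))
    expect_identical(got[[id]], strip_ws(golden[[id]]), info = id)
}

test_that("Watson-Crick complement is base-wise, order-preserving", {
  expect_identical(wc_complement("GCCAGAA"), "CGGTCTT")
  expect_identical(wc_complement("A"), "T")
  set.seed(3)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
               collapse = "")
    expect_identical(wc_complement(wc_complement(x)), x)
    # independent route: Biostrings complement of the same sequence
    expect_identical(wc_complement(x),
                     as.character(Biostrings::complement(
                       Biostrings::DNAString(x))))
  }
  expect_error(wc_complement("ACGN"), "non-ACGT")
})

test_that("sticker sets reproduce the three published automaton tables", {
  expect_sticker_table(
    build_sticker_set(automaton_for("phi1"), fixture("codebook-phi1")),
    golden_A1)
  expect_sticker_table(
    build_sticker_set(automaton_for("A5"), fixture("codebook-ITL")),
    golden_A5)
  expect_sticker_table(
    build_sticker_set(automaton_for("phi4"), fixture("codebook-phi4")),
    golden_A4)
})

test_that("single sticker encodings match printed rows and check ranges", {
  cb <- fixture("codebook-phi1")
  expect_identical(encode_transition(0, "s", 0, cb)$pairing,
                   "AACGTTCCGTCGCTT")
  expect_identical(encode_transition(1, "q", 2, cb)$pairing,
                   "GTTCCGGGGCTTAACGTT")
  expect_identical(encode_transition(2, "q", 2, fixture("codebook-ITL"))$pairing,
                   strip_ws("TAC ACT GCT TAG CCT"))
  expect_identical(encode_initial(0, cb)$pairing, "CGGTCTT")
  expect_identical(encode_acceptance(2, cb)$pairing, "CCGGCAG")
  acc4 <- encode_acceptance(4, fixture("codebook-phi4"))
  expect_identical(acc4$pairing, strip_ws("ACGT ACCT GCAT TTGG"))
  expect_identical(nchar(acc4$pairing), 16L)
  expect_error(encode_transition(0, "s", 9, cb), "range")
  expect_error(encode_acceptance(3, cb), "range")    # j = m needs a spare
  expect_error(encode_transition(0, "z", 0, cb), "codeword")
})

test_that("input-run encoding matches the printed run strands", {
  cb1 <- fixture("codebook-phi1")
  suq <- encode_input_run(c("s", "u", "q"), cb1)
  expect_identical(
    suq$sequence,
    strip_ws("GCCA GAATTGCAAGGC AGC GAATTGCAAGGC GCG GAATTGCAAGGC CCC
              GAATTGCAAGGC CGTC"))
  expect_identical(nchar(suq$sequence), 65L)

  itl <- fixture("codebook-ITL")
  pq <- encode_input_run(c("p", "q"), itl)
  expect_identical(
    pq$sequence,
    strip_ws("CGCT CGAATCGGAATG TAT CGAATCGGAATG TGA CGAATCGGAATG CGGC"))

  empty <- encode_input_run(character(), cb1)
  expect_identical(empty$sequence, paste0("GCCA", "GAATTGCAAGGC", "CGTC"))
  expect_error(encode_input_run("zz", cb1), "codeword")
})

test_that("run strand length follows the closed-form length law", {
  set.seed(11)
  for (cbn in c("codebook-phi1", "codebook-ITL", "codebook-phi4")) {
    cb <- fixture(cbn)
    S <- sum(nchar(cb$spacers))
    L <- nchar(cb$letters[[1]])
    for (n in c(0L, 1L, 2L, 5L, 9L)) {
      w <- sample(names(cb$letters), n, replace = TRUE)
      expect_identical(
        nchar(encode_input_run(w, cb)$sequence),
        nchar(cb$I1) + nchar(cb$I2) + (n + 1L) * S + n * L)
    }
  }
})

test_that("trimming strips the initial and acceptance segments", {
  cb1 <- fixture("codebook-phi1")
  d <- trim_to_core(encode_input_run(c("s", "u", "q"), cb1), cb1, 0, 2)
  expect_identical(d$sequence,
                   "TTGCAAGGCAGCGAATTGCAAGGCGCGGAATTGCAAGGCCCCGAATTGCAA")
  expect_identical(nchar(d$sequence), 51L)

  itl <- fixture("codebook-ITL")
  d2 <- trim_to_core(encode_input_run(c("p", "q"), itl), itl, 0, 2)
  expect_identical(d2$sequence, "ATCGGAATGTATCGAATCGGAATGTGACGAATCGGA")

  cb4 <- fixture("codebook-phi4")
  d4 <- trim_to_core(encode_input_run(c("m1", "q1", "p2", "q2"), cb4),
                     cb4, 0, 4)
  expect_identical(
    d4$sequence,
    paste0("CGCATCATGTGGTCTTTGCATGGACGTAGTGATCGGCGCATCATGTGGTCTTTGCATGG",
           "ACGTAATCCTCGGCGCATCATGTGGTCTTTGCATGGACGTACAAATCGGCGCATCATGT",
           "GGTCTTTGCATGGACGTAGGGATCGGCGCATCATGTGGTCTT"))

  # i = 0, j = 0 strips everything: I1 X0 | X1..Xm I2
  e <- trim_to_core(encode_input_run(character(), cb1), cb1, 0, 0)
  expect_identical(e$sequence, "")
  expect_error(trim_to_core("AAAA", cb1, 0, 2), "inconsistency")
})

test_that("complements along an accepting run reconstruct the input strand", {
  set.seed(23)
  for (i in 1:25) {
    a <- random_fsa()
    cb <- random_codebook(a)
    # random transition walk from the initial state, ended at any state
    tr <- a$transitions
    word <- character()
    covers <- encode_initial(a$initial, cb)$pairing
    state <- a$initial
    for (step in seq_len(sample(1:5, 1))) {
      out <- tr[tr$from == state, ]
      if (nrow(out) == 0L) break
      pick <- out[sample(nrow(out), 1), ]
      word <- c(word, pick$letter)
      covers <- paste0(covers,
                       encode_transition(pick$from, pick$letter, pick$to,
                                         cb)$pairing)
      state <- pick$to
    }
    if (state > cb$m - 1L) next
    covers <- paste0(covers, encode_acceptance(state, cb)$pairing)
    expect_identical(wc_complement(covers),
                     encode_input_run(word, cb)$sequence)
  }
})

test_that("codebook validation reports the printed designs as valid", {
  r1 <- validate_codebook(fixture("codebook-phi1"), automaton_for("phi1"))
  expect_true(attr(r1, "valid"))
  r4 <- validate_codebook(fixture("codebook-phi4"), automaton_for("phi4"))
  expect_true(attr(r4, "valid"))
  dup <- codebook(c(p = "CGA", q = "CGA"), spacers = c("GAA", "TTG"),
                  I1 = "GCCA", I2 = "CGTC")
  rd <- validate_codebook(dup)
  expect_false(attr(rd, "valid"))
  expect_false(rd$ok[rd$check == "letter codewords distinct"])
})

test_that("FASTA export round-trips sequences and headers", {
  ss <- build_sticker_set(automaton_for("phi1"), fixture("codebook-phi1"))
  tmp <- withr::local_tempfile(fileext = ".fasta")
  export_fasta(ss, tmp)
  back <- read_strand_fasta(tmp)
  expect_identical(nrow(back), 7L)
  expect_identical(back$id, ss$id)
  expect_identical(back$role, ss$role)
  expect_identical(back$sequence, ss$sequence)
  expect_error(export_fasta(ss[0, ], tmp))
})
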