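test_that("CDS position to codon arithmetic is exact", {
  expect_equal(unlist(cds_codon(626)[c("codon_number", "codon_offset")]),
               c(codon_number = 209L, codon_offset = 2L))
  expect_equal(unlist(cds_codon(1)[c("codon_number", "codon_offset")]),
               c(codon_number = 1L, codon_offset = 1L))
  expect_equal(unlist(cds_codon(3)[c("codon_number", "codon_offset")]),
               c(codon_number = 1L, codon_offset = 3L))
  expect_error(cds_codon(0), "c_pos")
  expect_error(cds_codon(10, cds_len = 9), "beyond CDS")
})

test_that("codon mapping round-trips over the whole range", {
  cc <- cds_codon(1:3000)
  expect_identical(codon_to_cds(cc$codon_number, cc$codon_offset), 1:3000)
})

test_that("protein changes translate via the standard genetic code", {
  # toy CDS with codon 5 = CGC; c.14G>A makes CAC: p.R5H
  cds <- paste0("ATGGCTGCTGCT", "CGC", "TGGTAA")
  tx <- transcript_model("TOY", cds, signal_peptide_len = 2,
                         transcript_id = "toy1")
  ch <- protein_change(tx, 14L, "G", "A")
  expect_equal(ch$aa_ref, "R")
  expect_equal(ch$aa_alt, "H")
  expect_equal(ch$codon_number, 5L)
  expect_false(ch$synonymous)
  expect_equal(ch$mature_residue, 3L)
  # oracle: independent translation route through Biostrings
  codon_before <- substr(cds, 13, 15)
  codon_after <- sub("G", "A", codon_before)
  expect_equal(ch$aa_ref, as.character(Biostrings::translate(
    Biostrings::DNAString(codon_before))))
  expect_equal(ch$aa_alt, as.character(Biostrings::translate(
    Biostrings::DNAString(codon_after))))

  # third-position CGC -> CGT is synonymous
  syn <- protein_change(tx, 15L, "C", "T")
  expect_true(syn$synonymous)
  expect_equal(syn$aa_alt, syn$aa_ref)

  # TGG -> TGA creates a stop
  stop_ch <- protein_change(tx, 17L, "G", "A")
  expect_equal(stop_ch$aa_ref, "W")
  expect_equal(stop_ch$aa_alt, "*")

  expect_error(protein_change(tx, 14L, "C", "A"), "is G, not C")
})

test_that("mature-peptide renumbering subtracts the signal length", {
  expect_equal(mature_numbering(209, 26), 183L)
  expect_equal(mature_numbering(42, 0), 42L)
  expect_error(mature_numbering(10, 26), "signal peptide")
  # strict monotonicity in the preprotein residue
  res <- mature_numbering(27:60, 26)
  expect_true(all(diff(res) > 0))
})

test_that("dominant segregation distinguishes violations from penetrance", {
  # three-generation family: six affected carriers, three unaffected
  # non-carriers
  fam <- data.frame(
    member_id = c("I-2", "II-1", "II-2", "II-3", "II-4", "II-5",
                  "III-1", "III-3", "III-5"),
    affected = c("affected", "affected", "unaffected", "unaffected",
                 "affected", "affected", "affected", "affected",
                 "unaffected"),
    carrier = c("yes", "yes", "no", "no", "yes", "yes", "yes", "yes", "no"),
    stringsAsFactors = FALSE
  )
  seg <- check_segregation(fam)
  expect_true(seg$consistent)
  expect_length(seg$violations, 0)
  expect_length(seg$penetrance_notes, 0)

  # an affected non-carrier is a violation
  fam2 <- fam
  fam2$carrier[1] <- "no"
  seg2 <- check_segregation(fam2)
  expect_false(seg2$consistent)
  expect_equal(seg2$violations, "I-2")

  # an unaffected carrier is a penetrance note, not a violation
  fam3 <- fam
  fam3$carrier[3] <- "yes"
  seg3 <- check_segregation(fam3)
  expect_true(seg3$consistent)
  expect_equal(seg3$penetrance_notes, "II-2")

  all_untested <- data.frame(member_id = "x", affected = "affected",
                             carrier = "untested", stringsAsFactors = FALSE)
  expect_error(check_segregation(all_untested), "untested")
  expect_error(check_segregation(fam, model = "autosomal_recessive"),
               "unsupported")
})

test_that("frequency filter retains unobserved and rare variants only", {
  vars <- data.frame(contig = "c1", pos1 = c(10L, 20L, 30L),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  af <- data.frame(contig = "c1", pos1 = c(20L, 30L), ref = "A", alt = "G",
                   af = c(0.05, 0.0001), stringsAsFactors = FALSE)
  kept <- frequency_filter(vars, af, max_af = 0.001)
  expect_equal(kept$pos1, c(10L, 30L))
  bad <- af; bad$af[1] <- 1.5
  expect_error(frequency_filter(vars, bad), "outside")
  # oracle: one-line recomputation on random inputs
  set.seed(77)
  vr <- data.frame(contig = "c1", pos1 = 1:100, ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  at <- data.frame(contig = "c1", pos1 = sample(1:100, 60), ref = "A",
                   alt = "G", af = runif(60, 0, 0.01),
                   stringsAsFactors = FALSE)
  got <- frequency_filter(vr, at, max_af = 0.001)
  o_af <- at$af[match(vr$pos1, at$pos1)]
  expect_equal(got$pos1, vr$pos1[is.na(o_af) | o_af < 0.001])
})

test_that("cohort summary reports counts with half-away-from-zero percents", {
  sheet <- make_cohort_sheet()
  s <- summarize_cohort(sheet)
  expect_equal(attr(s, "n_total"), 51L)
  expect_equal(s$percent[s$category == "acth_deficiency"], 59L)   # 30/51
  expect_equal(s$percent[s$category == "gonadotropin_deficiency"], 25L)  # 13/51
  expect_equal(s$n[s$category == "gh_deficiency"], 51L)
  expect_equal(s$percent[s$category == "gh_deficiency"], 100L)
  expect_equal(s$percent[s$category == "adh_deficiency"], 4L)
  # 0 of 51 -> 0%
  sheet$never_deficiency <- FALSE
  s2 <- summarize_cohort(sheet)
  expect_equal(s2$percent[s2$category == "never_deficiency"], 0L)
  # invariant: percentages recomputed from counts match
  expect_equal(s$percent,
               as.integer(floor(abs(100 * s$n / 51) + 0.5)))
  expect_error(summarize_cohort(sheet[0, ]), "empty")
})

test_that("diagnosis consistency with deficiency flags is checked", {
  sheet <- make_cohort_sheet()
  sheet$diagnosis[1] <- "IGHD"  # patient 1 has >= 2 deficient axes
  expect_error(summarize_cohort(sheet), "inconsistent")
})
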