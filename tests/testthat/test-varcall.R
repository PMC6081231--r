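test_that("alignment of basic cases produces the forced optima", {
  a <- align_insert("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 0L)
  expect_equal(a$cigar, "8=")

  b <- align_insert("ACGTACGT", "ACGAACGT")  # one substitution
  expect_equal(b$score, 1L)
  expect_equal(sum(b$lens[b$ops == "X"]), 1L)

  d <- align_insert("ACGTCGTT", "ACGTACGTT")  # one deleted base
  expect_equal(d$score, 1L)
  expect_equal(sum(d$lens[d$ops == "D"]), 1L)
  expect_equal(sum(d$ops == "D"), 1L)

  expect_error(align_insert("", "ACGT"), "empty insert")
})

test_that("alignment scores equal the memoised recursion on random pairs", {
  set.seed(6)
  for (k in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE),
               collapse = "")
    expect_equal(align_insert(a, b)$score, edit_cost_recursive(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment CIGARs are consistent and consume both sequences", {
  set.seed(16)
  for (k in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:15, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:15, 1), TRUE),
               collapse = "")
    al <- align_insert(a, b)
    expect_equal(sum(al$lens[al$ops %in% c("=", "X", "I")]), nchar(a))
    expect_equal(sum(al$lens[al$ops %in% c("=", "X", "D")]), nchar(b))
  }
})

test_that("a long deletion is reported as one contiguous run", {
  ref <- "ACGTTGCAAGGTCAGTTCAGGACCTA"
  qry <- paste0(substr(ref, 1, 10), substr(ref, 21, 26))  # 10 nt deletion
  al <- align_insert(qry, ref)
  expect_equal(al$score, 10L)
  expect_equal(sum(al$ops == "D"), 1L)
  expect_equal(al$lens[al$ops == "D"], 10L)
})

test_that("genotyping matches explicit likelihood evaluation", {
  mk_col <- function(n_ref, n_alt, ref = "A", alt = "C") {
    data.frame(contig = "c1", pos0 = 0L, ref_base = ref,
               obs = c(ref, alt), count = c(n_ref, n_alt),
               stringsAsFactors = FALSE)
  }
  # 30 ref, 0 alt: hom ref
  g1 <- genotype_columns(mk_col(30L, 0L))
  expect_equal(g1$gt, "0/0")
  # 12 ref, 13 alt: het, oracle = explicit likelihood products
  g2 <- genotype_columns(mk_col(12L, 13L))
  oracle <- genotype_oracle(12, 13, 0.01)
  expect_equal(g2$gt, oracle$gt)
  expect_equal(g2$gt, "0/1")
  expect_equal(g2$gq, oracle$gq, tolerance = 1e-8)
  # randomized compositions against the oracle
  set.seed(4)
  for (k in 1:30) {
    nr <- sample(0:40, 1); na <- sample(0:40, 1)
    if (nr + na < 8) next
    g <- genotype_columns(mk_col(nr, na))
    o <- genotype_oracle(nr, na, 0.01)
    if (nrow(g) == 1) expect_equal(g$gt, o$gt, info = paste(nr, na))
  }
})

test_that("depth below 8 yields no call regardless of composition", {
  col <- data.frame(contig = "c1", pos0 = 0L, ref_base = "A",
                    obs = c("A", "C"), count = c(3L, 4L),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(genotype_columns(col)), 0L)
})

test_that("one discordant observation cannot flip a deep homozygous call", {
  # analytic limit: as e -> 0 the het likelihood of 1 alt in n >= 8 falls
  # far below hom-ref
  for (e in c(1e-2, 1e-3, 1e-4)) {
    col <- data.frame(contig = "c1", pos0 = 0L, ref_base = "A",
                      obs = c("A", "G"), count = c(19L, 1L),
                      stringsAsFactors = FALSE)
    # min_gq = 0 so the genotype argmax itself is inspected (at very
    # small e a lone discordant read may drop GQ below an emission gate
    # without ever flipping the argmax)
    g <- genotype_columns(col, caller_params(error_rate = e, min_gq = 0))
    expect_equal(g$gt, "0/0")
  }
})

test_that("pileup counts one observation per molecule and position", {
  ref <- c(c1 = paste(rep("ACGT", 40), collapse = ""))
  mol <- data.frame(molecule_id = "m1", probe_id = "p1", tag = "AAAA",
                    n_members = 1L, contig = "c1", gap_start = 8L,
                    gap_end = 24L,
                    consensus = substr(ref[[1]], 9, 24),
                    stringsAsFactors = FALSE)
  cols <- pileup(mol, ref)
  expect_equal(nrow(cols), 16L)
  expect_true(all(cols$count == 1L))
  expect_true(all(cols$obs == cols$ref_base))
  # a base with no covering molecule produces no column
  expect_false(any(cols$pos0 >= 24L))
})

test_that("het alt fraction in deep pileups stays within 4 sigma of 0.5", {
  fx <- demo_fixture(7)
  panel <- design_panel(fx$reference, fx$targets)
  pr <- panel$probes[3, ]
  pos <- pr$gap_start + 50L
  base <- substr(fx$reference[[1]], pos + 1, pos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), base)[1]
  spec <- data.frame(contig = pr$contig, pos = pos, ref = base, alt = alt,
                     zygosity = "het", stringsAsFactors = FALSE)
  haps <- plant_variants(fx$reference, spec)
  probe1 <- panel$probes[3, , drop = FALSE]
  attr(probe1, "tag_len") <- 8L
  sim <- simulate_capture(probe1, haps,
                          sim_config(molecules_per_probe = 1000,
                                     duplication_mean = 1,
                                     base_error_rate = 0, seed = 13))
  proc <- process_reads(sim$r1, sim$r2, probe1)
  cols <- pileup(proc$molecules, fx$reference)
  at <- cols[cols$pos0 == pos, ]
  frac <- at$count[at$obs == alt] / sum(at$count)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 1000))
})

test_that("variant normalization left-aligns and trims indels", {
  ref <- c(c1 = "GGCTAAATTC")
  # deleting one A from the AAA run, described at its right edge
  n1 <- normalize_variant("c1", 6L, "AA", "A", ref)
  n2 <- normalize_variant("c1", 4L, "TA", "T", ref)
  expect_equal(n1[c("pos1", "ref", "alt")], n2[c("pos1", "ref", "alt")])
  # SNV is untouched
  n3 <- normalize_variant("c1", 3L, "C", "G", ref)
  expect_equal(n3, list(pos1 = 3L, ref = "C", alt = "G"))
})

test_that("VCF writing matches a hand-constructed record and round-trips", {
  ref <- c(chr1 = "ACGTACGTAC")
  calls <- data.frame(contig = "chr1", pos1 = 1L, ref = "A", alt = "G",
                      gt = "0/1", dp = 20L, ad_ref = 10L, ad_alt = 10L,
                      gq = 99, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, ref, "s1", f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_identical(body, "chr1\t1\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD:GQ\t0/1:20:10,10:99")
  back <- read_vcf(f)
  expect_equal(back[, c("contig", "pos1", "ref", "alt", "gt")],
               calls[, c("contig", "pos1", "ref", "alt", "gt")])
  # internal 0-based position 0 surfaces as POS 1 (checked above);
  # unsorted input is rejected
  calls2 <- data.frame(contig = "chr1", pos1 = c(5L, 2L),
                       ref = "A", alt = "G", gt = "0/1",
                       stringsAsFactors = FALSE)
  expect_error(write_vcf(calls2, ref, "s1", f), "sorted")
})

test_that("written VCFs agree with the independent vcfR parser", {
  skip_if_not_installed("vcfR")
  run <- make_sim_run(n_snv = 4, n_indel = 1, molecules_per_probe = 15,
                      base_error_rate = 0, seed = 11)
  proc <- process_reads(run$sim$r1, run$sim$r2, run$probes)
  res <- call_variants(proc$molecules, run$reference, run$padded_targets)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(res$calls, run$reference, "s1", f)
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(res$calls))
  expect_equal(as.integer(v@fix[, "POS"]), res$calls$pos1)
  expect_equal(unname(v@fix[, "REF"]), res$calls$ref)
  expect_equal(unname(v@fix[, "ALT"]), res$calls$alt)
  gt <- vcfR::extract.gt(v, element = "GT")
  expect_equal(unname(gt[, 1]), res$calls$gt)
})
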