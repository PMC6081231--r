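test_that("probe index supports self-lookup and rejects duplicate arm pairs", {
  run <- make_sim_run(n_snv = 0, n_indel = 0, molecules_per_probe = 2)
  index <- build_probe_index(run$probes)
  for (i in seq_len(nrow(run$probes))) {
    expect_identical(
      probe_index_lookup(index, run$probes$ext_seq[i], run$probes$lig_seq[i]),
      run$probes$probe_id[i]
    )
  }
  dup <- rbind(run$probes, run$probes[1, ])
  dup$probe_id[nrow(dup)] <- "MIP_DUP"
  attr(dup, "tag_len") <- 8L
  expect_error(build_probe_index(dup), "duplicated")
})

test_that("random arm queries agree with a linear scan over all probes", {
  run <- make_sim_run(n_snv = 0, n_indel = 0, molecules_per_probe = 2)
  index <- build_probe_index(run$probes)
  set.seed(99)
  for (k in 1:100) {
    if (k %% 2 == 0) {  # an existing probe's arms
      i <- sample(nrow(run$probes), 1)
      e <- run$probes$ext_seq[i]; l <- run$probes$lig_seq[i]
    } else {            # random sequences, almost surely absent
      e <- paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
      l <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    }
    scan <- NA_character_
    for (j in seq_len(nrow(run$probes))) {
      if (run$probes$ext_seq[j] == e && run$probes$lig_seq[j] == l) {
        scan <- run$probes$probe_id[j]
      }
    }
    expect_identical(probe_index_lookup(index, e, l), scan)
  }
})

test_that("error-free pairs assign to their ledger probe with zero mismatches", {
  run <- make_sim_run(n_snv = 3, n_indel = 1, molecules_per_probe = 5,
                      base_error_rate = 0, seed = 11)
  index <- build_probe_index(run$probes)
  asg <- assign_read_pairs(run$sim$r1, run$sim$r2, index)
  expect_true(all(!is.na(asg$probe_id)))
  expect_true(all(asg$arm_mismatches == 0L))
  led_probe <- run$sim$ledger$probe_id[
    match(sub("\\.\\d+$", "", asg$read_id), run$sim$ledger$molecule_id)]
  expect_identical(asg$probe_id, led_probe)
  # inserts carry no arm bases
  pi <- match(asg$probe_id, run$probes$probe_id)
  expect_false(any(startsWith(asg$insert_r1, run$probes$ext_seq[pi])))
})

test_that("arm mismatch budget matches the exhaustive Hamming oracle", {
  run <- make_sim_run(n_snv = 0, n_indel = 0, molecules_per_probe = 1,
                      base_error_rate = 0, seed = 11)
  index <- build_probe_index(run$probes)
  r1 <- run$sim$r1[1]; r2 <- run$sim$r2[1]
  mutate_at <- function(s, i) {
    b <- substr(s, i, i)
    paste0(substr(s, 1, i - 1), setdiff(c("A", "C", "G", "T"), b)[1],
           substr(s, i + 1, nchar(s)))
  }
  # one substituted arm base: assigned at max_mismatch 1
  a1 <- assign_read_pairs(mutate_at(r1, 3), r2, index, max_mismatch = 1)
  expect_false(is.na(a1$probe_id))
  expect_equal(a1$arm_mismatches, 1L)
  # two substituted bases in the same arm: unassigned
  a2 <- assign_read_pairs(mutate_at(mutate_at(r1, 3), 7), r2, index,
                          max_mismatch = 1)
  expect_true(is.na(a2$probe_id))
  # exhaustive oracle on a batch of randomly mutated reads
  set.seed(5)
  for (k in 1:25) {
    i <- sample(length(run$sim$r1), 1)
    rr1 <- run$sim$r1[i]; rr2 <- run$sim$r2[i]
    for (m in seq_len(sample(0:2, 1))) rr1 <- mutate_at(rr1, sample(16, 1))
    got <- assign_read_pairs(rr1, rr2, index, max_mismatch = 1)
    # oracle: Hamming distance against every probe's arms
    hits <- character(0)
    for (j in seq_len(nrow(run$probes))) {
      le <- nchar(run$probes$ext_seq[j]); ll <- nchar(run$probes$lig_seq[j])
      de <- sum(strsplit(substr(rr1, 1, le), "")[[1]] !=
                  strsplit(run$probes$ext_seq[j], "")[[1]])
      dl <- sum(strsplit(substr(rr2, 9, 8 + ll), "")[[1]] !=
                  strsplit(revcomp_test(run$probes$lig_seq[j]), "")[[1]])
      if (de <= 1 && dl <= 1) hits <- c(hits, run$probes$probe_id[j])
    }
    if (length(hits) == 1) {
      expect_identical(got$probe_id, hits)
    } else {
      expect_true(is.na(got$probe_id))
    }
  }
})

test_that("short reads are unassigned with reason 'short'", {
  run <- make_sim_run(n_snv = 0, n_indel = 0, molecules_per_probe = 1)
  index <- build_probe_index(run$probes)
  a <- assign_read_pairs(stats::setNames("ACGTA", "r"),
                         stats::setNames("ACGTA", "r"), index)
  expect_true(is.na(a$probe_id))
  expect_equal(a$reason, "short")
})

test_that("duplicate removal matches the ledger group-by oracle", {
  run <- make_sim_run(n_snv = 4, n_indel = 1, molecules_per_probe = 20,
                      duplication_mean = 2.5, base_error_rate = 0, seed = 11)
  proc <- process_reads(run$sim$r1, run$sim$r2, run$probes)
  ledger_groups <- unique(run$sim$ledger[, c("probe_id", "tag")])
  expect_identical(nrow(proc$groups), nrow(ledger_groups))
  # two byte-identical pairs with the same tag collapse into one group
  r1 <- run$sim$r1[c(1, 1)]; r2 <- run$sim$r2[c(1, 1)]
  names(r1) <- names(r2) <- c("a", "b")
  p2 <- process_reads(r1, r2, run$probes)
  expect_equal(nrow(p2$groups), 1L)
  expect_equal(p2$groups$n_members, 2L)
})

test_that("group count is independent of the duplication level", {
  base <- make_sim_run(n_snv = 2, n_indel = 0, molecules_per_probe = 10,
                       duplication_mean = 1, base_error_rate = 0, seed = 31)
  heavy <- make_sim_run(n_snv = 2, n_indel = 0, molecules_per_probe = 10,
                        duplication_mean = 4, base_error_rate = 0, seed = 31)
  g1 <- process_reads(base$sim$r1, base$sim$r2, base$probes)$groups
  g2 <- process_reads(heavy$sim$r1, heavy$sim$r2, heavy$probes)$groups
  expect_identical(nrow(g1), nrow(g2))
})

test_that("directional Hamming-1 tag clustering matches the all-pairs oracle", {
  run <- make_sim_run(n_snv = 0, n_indel = 0, molecules_per_probe = 12,
                      duplication_mean = 3, base_error_rate = 0, seed = 7)
  asg <- assign_read_pairs(run$sim$r1, run$sim$r2, build_probe_index(run$probes))
  # corrupt one duplicate's tag by one base (simulated tag-sequencing
  # error); the victim molecule needs >= 3 duplicates so the remaining
  # group is at least twice the corrupted singleton
  led <- run$sim$ledger
  mol <- led$molecule_id[led$duplicate_count >= 3L][1]
  victim <- which(sub("\\.\\d+$", "", asg$read_id) == mol)[1]
  tg <- asg$tag[victim]
  asg$tag[victim] <- paste0(ifelse(substr(tg, 1, 1) == "A", "C", "A"),
                            substr(tg, 2, 8))
  off <- dedup_molecules(asg, cluster_hamming1 = FALSE)
  on_ <- dedup_molecules(asg, cluster_hamming1 = TRUE)
  # oracle: exhaustive pairwise distances within each probe
  merge_expected <- 0L
  for (p in unique(off$probe_id)) {
    g <- off[off$probe_id == p, ]
    ord <- order(-g$n_members, g$tag)
    g <- g[ord, ]
    absorbed <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(g))[-1]) {
      for (j in seq_len(i - 1)) {
        if (absorbed[j]) next
        d <- sum(strsplit(g$tag[i], "")[[1]] != strsplit(g$tag[j], "")[[1]])
        if (d == 1 && g$n_members[i] <= g$n_members[j] / 2) {
          absorbed[i] <- TRUE
          break
        }
      }
    }
    merge_expected <- merge_expected + sum(absorbed)
  }
  expect_identical(nrow(off) - nrow(on_), merge_expected)
  expect_gte(merge_expected, 1L)
  # clustering recovers at least 99% agreement with the ledger molecules
  led <- nrow(unique(run$sim$ledger[, c("probe_id", "tag")]))
  expect_gte(min(nrow(on_), led) / max(nrow(on_), led), 0.99)
})

test_that("consensus takes the per-position majority with N on ties", {
  expect_identical(consensus("ACGT"), "ACGT")
  expect_identical(consensus(c("ACGT", "ACTT")), "ACNT")
  # five members, one carrying one error: corrected; oracle = column tally
  members <- c("ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGAACGT", "ACGTACGT")
  got <- consensus(members)
  mat <- do.call(rbind, strsplit(members, ""))
  oracle <- apply(mat, 2, function(col) {
    tt <- table(col)
    w <- names(tt)[tt == max(tt)]
    if (length(w) > 1) "N" else w
  })
  expect_identical(got, paste(oracle, collapse = ""))
  expect_identical(got, "ACGTACGT")
  expect_error(consensus(character(0)), "empty")
})

test_that("no consensus insert begins or ends with its probe's arms", {
  run <- make_sim_run(n_snv = 3, n_indel = 1, molecules_per_probe = 8,
                      base_error_rate = 0, seed = 11)
  proc <- process_reads(run$sim$r1, run$sim$r2, run$probes)
  pi <- match(proc$molecules$probe_id, run$probes$probe_id)
  expect_false(any(startsWith(proc$molecules$consensus,
                              run$probes$ext_seq[pi])))
  expect_false(any(endsWith(proc$molecules$consensus,
                            run$probes$lig_seq[pi])))
})

test_that("the group set is invariant under read order shuffling", {
  run <- make_sim_run(n_snv = 2, n_indel = 0, molecules_per_probe = 6,
                      duplication_mean = 2, base_error_rate = 0, seed = 19)
  proc1 <- process_reads(run$sim$r1, run$sim$r2, run$probes)
  set.seed(1)
  perm <- sample(length(run$sim$r1))
  proc2 <- process_reads(run$sim$r1[perm], run$sim$r2[perm], run$probes)
  key <- function(g) sort(paste(g$probe_id, g$tag, g$n_members))
  expect_identical(key(proc1$groups), key(proc2$groups))
  expect_identical(
    proc1$molecules[order(proc1$molecules$molecule_id), "consensus"],
    proc2$molecules[order(proc2$molecules$molecule_id), "consensus"]
  )
})

test_that("error-free consensus inserts reproduce the source haplotype", {
  run <- make_sim_run(n_snv = 3, n_indel = 2, molecules_per_probe = 4,
                      base_error_rate = 0, seed = 29)
  proc <- process_reads(run$sim$r1, run$sim$r2, run$probes)
  led <- run$sim$ledger
  for (i in seq_len(nrow(proc$molecules))) {
    m <- proc$molecules[i, ]
    hap_i <- led$haplotype[led$probe_id == m$probe_id & led$tag == m$tag]
    if (length(hap_i) != 1) next  # tag collision
    hap <- run$haps$haplotypes[[m$contig]][hap_i]
    expect_true(grepl(m$consensus, hap, fixed = TRUE))
  }
})
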