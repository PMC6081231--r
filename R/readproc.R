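# Arm-anchored read assignment, molecular-tag deduplication and
# per-molecule consensus. Replaces genome-wide alignment for targeted
# panels: a read pair is assigned to the unique probe whose two arms match
# the read prefixes within the mismatch budget.

#' Build an exact-lookup probe index
#'
#' @param probes Probe data.frame from [tile_probes()] (needs `tag_len`
#'   attribute when read from disk via [read_probe_table()]).
#' @return A list of class `mip_probe_index`.
#' @export
build_probe_index <- function(probes) {
  if (nrow(probes) == 0L) stop("panel is empty")
  pair <- paste(probes$ext_seq, probes$lig_seq, sep = "|")
  if (anyDuplicated(pair)) {
    dups <- probes$probe_id[duplicated(pair) | duplicated(pair, fromLast = TRUE)]
    stop("panel error: duplicated (ext_arm, lig_arm) pair across probes: ",
         paste(dups, collapse = ", "))
  }
  structure(
    list(probes = probes,
         tag_len = attr(probes, "tag_len") %||% 8L,
         # ligation arm as it appears at the start of read 2 (after the tag)
         lig_read_key = revcomp(probes$lig_seq)),
    class = "mip_probe_index"
  )
}

#' Look up a probe by its two arm sequences (exact match)
#'
#' @param index `mip_probe_index`.
#' @param ext_seq,lig_seq Arm sequences in genomic orientation.
#' @return The matching `probe_id`, or `NA` if none.
#' @export
probe_index_lookup <- function(index, ext_seq, lig_seq) {
  hit <- index$probes$ext_seq == ext_seq & index$probes$lig_seq == lig_seq
  if (!any(hit)) return(NA_character_)
  index$probes$probe_id[which(hit)]
}

# all Hamming-1 neighbors of a set of sequences (substitutions only),
# returned as a data.table (key, id)
.h1_neighbors <- function(seqs, ids) {
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    chars <- strsplit(s, "")[[1L]]
    keys <- character(n * 3L)
    k <- 0L
    for (p in seq_len(n)) {
      for (b in DNA_BASES) {
        if (b == chars[p]) next
        k <- k + 1L
        tmp <- chars
        tmp[p] <- b
        keys[k] <- paste(tmp, collapse = "")
      }
    }
    res[[i]] <- data.table::data.table(key_ = keys[seq_len(k)], probe_id = ids[i])
  }
  data.table::rbindlist(res)
}

# candidate (read, probe, mismatch) table for one arm; reads_sub are the
# read substrings to compare, arm_seqs the per-probe arm keys in the same
# orientation
.arm_candidates <- function(reads_sub, arm_seqs, probe_ids, max_mismatch) {
  lens <- nchar(arm_seqs)
  out <- list()
  for (L in unique(lens)) {
    sel <- lens == L
    pref <- substr(reads_sub, 1L, L)
    dict <- data.table::data.table(key_ = arm_seqs[sel],
                                   probe_id = probe_ids[sel], mm = 0L)
    if (max_mismatch >= 1L) {
      h1 <- .h1_neighbors(arm_seqs[sel], probe_ids[sel])
      h1[, mm := 1L]
      dict <- rbind(dict, h1)
    }
    reads_dt <- data.table::data.table(read_idx = seq_along(reads_sub), key_ = pref)
    hits <- dict[reads_dt, on = "key_", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(hits) > 0L) {
      out[[as.character(L)]] <- hits[, list(mm = min(mm)),
                                     by = c("read_idx", "probe_id")]
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table::data.table(read_idx = integer(), probe_id = character(),
                                  mm = integer()))
  }
  res[, list(mm = min(mm)), by = c("read_idx", "probe_id")]
}

# brute-force Hamming candidates, used for max_mismatch > 1 (and as a
# simple fallback); O(reads x probes)
.arm_candidates_brute <- function(reads_sub, arm_seqs, probe_ids, max_mismatch) {
  out <- list()
  for (i in seq_along(arm_seqs)) {
    L <- nchar(arm_seqs[i])
    arm_raw <- charToRaw(arm_seqs[i])
    pref <- substr(reads_sub, 1L, L)
    mmv <- vapply(pref, function(x) {
      r <- charToRaw(x)
      if (length(r) != L) return(L)
      sum(r != arm_raw)
    }, integer(1L), USE.NAMES = FALSE)
    hit <- which(mmv <= max_mismatch)
    if (length(hit) > 0L) {
      out[[length(out) + 1L]] <- data.table::data.table(
        read_idx = hit, probe_id = probe_ids[i], mm = mmv[hit])
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(read_idx = integer(), probe_id = character(),
                                  mm = integer()))
  }
  data.table::rbindlist(out)
}

#' Assign read pairs to probes by arm matching
#'
#' Read 1 prefixes are compared to extension arms and read 2 prefixes
#' (after extracting the molecular tag) to ligation arms by Hamming
#' distance. A pair is assigned iff exactly one probe matches both arms
#' within `max_mismatch` per arm; multiple qualifying probes yield
#' `unassigned ("ambiguous")`, none yield `"no_match"`, and reads too
#' short for any arm yield `"short"`.
#'
#' @param r1,r2 Named character vectors of mate sequences (same order).
#' @param index `mip_probe_index`.
#' @param max_mismatch Per-arm substitution budget (default 1).
#' @return A data.frame with one row per pair: `read_id`, `probe_id` (`NA`
#'   when unassigned), `reason`, `arm_mismatches`, `tag`, `insert_r1`,
#'   `insert_r2` (both in insert orientation, arm/tag bases removed).
#' @export
assign_read_pairs <- function(r1, r2, index, max_mismatch = 1L) {
  stopifnot(length(r1) == length(r2))
  probes <- index$probes
  tag_len <- index$tag_len
  n <- length(r1)
  read_id <- names(r1) %||% sprintf("read%06d", seq_len(n))
  min_ext <- min(nchar(probes$ext_seq))
  min_lig <- min(nchar(probes$lig_seq))
  short <- nchar(r1) < min_ext | nchar(r2) < tag_len + min_lig

  tag <- substr(r2, 1L, tag_len)
  r2_body <- substr(r2, tag_len + 1L, nchar(r2))

  fn <- if (max_mismatch <= 1L) .arm_candidates else .arm_candidates_brute
  cand_e <- fn(r1, probes$ext_seq, probes$probe_id, max_mismatch)
  cand_l <- fn(r2_body, index$lig_read_key, probes$probe_id, max_mismatch)
  data.table::setnames(cand_e, "mm", "mm_e")
  data.table::setnames(cand_l, "mm", "mm_l")
  both <- cand_e[cand_l, on = c("read_idx", "probe_id"), nomatch = NULL]
  both <- both[!short[read_idx]]
  nhit <- both[, .N, by = "read_idx"]
  uniq <- nhit[N == 1L, read_idx]
  ambi <- nhit[N > 1L, read_idx]
  hit1 <- both[read_idx %in% uniq]

  probe_id <- rep(NA_character_, n)
  reason <- rep("no_match", n)
  arm_mm <- rep(NA_integer_, n)
  reason[short] <- "short"
  reason[ambi] <- "ambiguous"
  probe_id[hit1$read_idx] <- hit1$probe_id
  reason[hit1$read_idx] <- NA_character_
  arm_mm[hit1$read_idx] <- hit1$mm_e + hit1$mm_l

  # trim arms/tag for assigned reads
  insert_r1 <- rep(NA_character_, n)
  insert_r2 <- rep(NA_character_, n)
  asg <- hit1$read_idx
  if (length(asg) > 0L) {
    pi <- match(hit1$probe_id, probes$probe_id)
    le <- nchar(probes$ext_seq)[pi]
    ll <- nchar(probes$lig_seq)[pi]
    insert_r1[asg] <- substr(r1[asg], le + 1L, nchar(r1[asg]))
    insert_r2[asg] <- revcomp(substr(r2[asg], tag_len + ll + 1L, nchar(r2[asg])))
  }
  data.frame(read_id = read_id, probe_id = probe_id, reason = reason,
             arm_mismatches = arm_mm, tag = tag,
             insert_r1 = insert_r1, insert_r2 = insert_r2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Deduplicate assigned read pairs into molecule groups
#'
#' Groups are keyed by (probe, tag). With `cluster_hamming1 = TRUE` a
#' directional rule merges a tag into a Hamming-1 neighbor whose read
#' count is at least twice its own (tags are visited in decreasing count
#' order, largest kept as group representatives).
#'
#' @param assignments Data.frame from [assign_read_pairs()].
#' @param cluster_hamming1 Enable directional tag-error clustering.
#' @return A data.frame of molecule groups: `probe_id`, `tag`,
#'   `n_members`, and `members` (list column of row indices into
#'   `assignments`).
#' @export
dedup_molecules <- function(assignments, cluster_hamming1 = FALSE) {
  asg <- which(!is.na(assignments$probe_id))
  dt <- data.table::data.table(
    row = asg,
    probe_id = assignments$probe_id[asg],
    tag = assignments$tag[asg]
  )
  grp <- dt[, list(n_members = .N, members = list(row)), by = c("probe_id", "tag")]
  if (cluster_hamming1 && nrow(grp) > 0L) {
    merged <- lapply(split(seq_len(nrow(grp)), grp$probe_id), function(ix) {
      g <- grp[ix]
      ord <- order(-g$n_members, g$tag)
      g <- g[ord]
      keep <- rep(TRUE, nrow(g))
      into <- seq_len(nrow(g))
      for (i in seq_len(nrow(g))[-1L]) {
        for (j in seq_len(i - 1L)) {
          if (!keep[j]) next
          if (nchar(g$tag[i]) == nchar(g$tag[j]) &&
              hamming(g$tag[i], g$tag[j]) == 1L &&
              g$n_members[i] <= g$n_members[j] / 2) {
            keep[i] <- FALSE
            into[i] <- j
            break
          }
        }
      }
      for (i in which(!keep)) {
        j <- into[i]
        g$members[[j]] <- c(g$members[[j]], g$members[[i]])
        g$n_members[j] <- g$n_members[j] + g$n_members[i]
      }
      g[keep]
    })
    grp <- data.table::rbindlist(merged)
  }
  grp <- grp[order(probe_id, tag)]
  out <- as.data.frame(grp)
  out
}

#' Per-position majority consensus of equal-frame sequences
#'
#' Consensus length is the modal member length (smallest on ties); among
#' members of that length, each position takes the majority base, with
#' exact ties (and all-`N` columns) written as `N`. `N` votes are ignored.
#'
#' @param seqs Character vector of member sequences.
#' @return Consensus string.
#' @export
consensus <- function(seqs) {
  if (length(seqs) == 0L) stop("group is empty")
  lens <- nchar(seqs)
  tab <- table(lens)
  modal <- as.integer(names(tab)[tab == max(tab)])
  L <- min(modal)
  seqs <- seqs[lens == L]
  if (length(seqs) == 1L) return(seqs)
  raws <- lapply(seqs, charToRaw)
  base_raw <- raws[[1L]]
  diff_any <- rep(FALSE, L)
  for (r in raws[-1L]) diff_any <- diff_any | (r != base_raw)
  n_raw <- charToRaw("N")
  diff_any <- diff_any | base_raw == n_raw
  if (!any(diff_any)) return(seqs[1L])
  out <- base_raw
  for (p in which(diff_any)) {
    votes <- vapply(raws, `[`, raw(1L), p)
    votes <- votes[votes != n_raw]
    if (length(votes) == 0L) {
      out[p] <- n_raw
      next
    }
    vi <- as.integer(votes)
    tt <- tabulate(vi, nbins = 255L)
    mx <- max(tt)
    winners <- which(tt == mx)
    out[p] <- if (length(winners) > 1L) n_raw else as.raw(winners[1L])
  }
  rawToChar(out)
}

# reconstruct the full insert from the two per-mate consensus fragments:
# fragment 1 is the insert prefix, fragment 2 the insert suffix. The true
# insert length is searched within +/- max_shift of the expected
# (reference) length, choosing the length whose implied overlap has the
# fewest disagreements (ties: closest to expected, then shortest).
reconstruct_insert <- function(cons1, cons2, expected_len, max_shift = 10L) {
  n1 <- nchar(cons1); n2 <- nchar(cons2)
  Ls <- seq.int(expected_len - max_shift, expected_len + max_shift)
  Ls <- Ls[Ls >= 1L]
  best <- NULL
  for (L in Ls) {
    o <- n1 + n2 - L
    if (o < 1L || o > min(n1, n2)) next
    s1 <- substr(cons1, n1 - o + 1L, n1)
    s2 <- substr(cons2, 1L, o)
    mm <- hamming(s1, s2, ignore_n = TRUE)
    cand <- c(mm, abs(L - expected_len), L)
    if (is.null(best) || cand[1L] < best$key[1L] ||
        (cand[1L] == best$key[1L] && cand[2L] < best$key[2L]) ||
        (cand[1L] == best$key[1L] && cand[2L] == best$key[2L] && cand[3L] < best$key[3L])) {
      best <- list(key = cand, L = L, o = o, s1 = s1, s2 = s2)
    }
  }
  if (is.null(best)) {
    # fragments do not reach each other: join with Ns up to expected length
    gap <- max(0L, expected_len - n1 - n2)
    return(paste0(cons1, strrep("N", gap), cons2))
  }
  # overlap consensus: agreeing base (or the non-N one); conflicts become N
  a <- charToRaw(best$s1); b <- charToRaw(best$s2)
  nr <- charToRaw("N")
  ov <- a
  ov[a == nr] <- b[a == nr]
  ov[a != b & a != nr & b != nr] <- nr
  paste0(substr(cons1, 1L, n1 - best$o), rawToChar(ov),
         substr(cons2, best$o + 1L, n2))
}

#' Build the per-molecule consensus table
#'
#' For each molecule group, the two mate fragment sets are collapsed with
#' [consensus()] and joined into one insert spanning the probe's gap fill.
#'
#' @param groups Data.frame from [dedup_molecules()].
#' @param assignments Data.frame from [assign_read_pairs()].
#' @param probes Probe data.frame.
#' @return Molecule data.frame: `molecule_id`, `probe_id`, `tag`,
#'   `n_members`, `contig`, `gap_start`, `gap_end`, `consensus`.
#' @export
molecule_table <- function(groups, assignments, probes) {
  pi <- match(groups$probe_id, probes$probe_id)
  cons <- character(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    rows <- groups$members[[i]]
    c1 <- consensus(assignments$insert_r1[rows])
    c2 <- consensus(assignments$insert_r2[rows])
    expected <- probes$gap_end[pi[i]] - probes$gap_start[pi[i]]
    cons[i] <- reconstruct_insert(c1, c2, expected)
  }
  data.frame(
    molecule_id = paste0(groups$probe_id, ":", groups$tag),
    probe_id = groups$probe_id,
    tag = groups$tag,
    n_members = groups$n_members,
    contig = probes$contig[pi],
    gap_start = probes$gap_start[pi],
    gap_end = probes$gap_end[pi],
    consensus = cons,
    stringsAsFactors = FALSE
  )
}

#' Process a simulated or real read set end to end
#'
#' Convenience wrapper: assign, deduplicate, build consensus molecules.
#'
#' @param r1,r2 Named character vectors of reads.
#' @param probes Probe data.frame.
#' @param max_mismatch Per-arm mismatch budget.
#' @param cluster_hamming1 Enable tag-error clustering.
#' @return List with `assignments`, `groups`, `molecules`.
#' @export
process_reads <- function(r1, r2, probes, max_mismatch = 1L,
                          cluster_hamming1 = FALSE) {
  index <- build_probe_index(probes)
  assignments <- assign_read_pairs(r1, r2, index, max_mismatch)
  groups <- dedup_molecules(assignments, cluster_hamming1)
  molecules <- molecule_table(groups, assignments, probes)
  list(assignments = assignments, groups = groups, molecules = molecules)
}

#' Write / read the molecule table
#' @param molecules Molecule data.frame.
#' @param path TSV path.
#' @return Invisibly `path` (writer) or the data.frame (reader).
#' @export
write_molecule_table <- function(molecules, path) {
  utils::write.table(molecules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_molecule_table
#' @export
read_molecule_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(tag = "character"))
}
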