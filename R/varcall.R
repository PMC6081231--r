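# Per-probe gapped alignment of consensus inserts, pileup construction,
# diploid genotype likelihoods and call emission.

#' Genotype caller parameters
#'
#' @param error_rate Per-observation error probability `e` (0 < e < 0.5).
#' @param min_depth Minimum unique-molecule depth to emit a call
#'   (default 8).
#' @param min_gq Minimum genotype quality (phred) to emit a call
#'   (default 20).
#' @return A list of class `mip_caller_params`.
#' @export
caller_params <- function(error_rate = 0.01, min_depth = 8L, min_gq = 20) {
  if (error_rate <= 0 || error_rate >= 0.5) stop("error_rate must be in (0, 0.5)")
  structure(list(error_rate = error_rate, min_depth = as.integer(min_depth),
                 min_gq = min_gq),
            class = "mip_caller_params")
}

#' Global alignment of an insert against its reference window
#'
#' Needleman-Wunsch with unit costs (match 0, mismatch 1, gap 1).
#' Tie-breaking is fixed for byte-stable output: at equal cost the
#' traceback prefers a diagonal step (match/mismatch) over a gap, and a
#' reference gap (`D`) over an insert gap (`I`), which places gaps
#' leftmost in the alignment. CIGAR operations are `=`, `X`, `I`
#' (insertion in the insert) and `D` (deletion from the reference).
#'
#' @param insert Query sequence (non-empty).
#' @param ref_window Reference window the insert is aligned to.
#' @return A list of class `mip_alignment`: `score`, `cigar`, and run
#'   tables `ops`/`lens`.
#' @export
align_insert <- function(insert, ref_window) {
  if (is.na(insert) || nchar(insert) == 0L) stop("input error: empty insert")
  m <- nchar(insert)
  n <- nchar(ref_window)
  # fast path: equal length, at most 2 substitutions (a gapped alignment
  # of equal-length strings costs >= 2, so substitutions-only is optimal)
  if (m == n) {
    qa <- charToRaw(insert); ra <- charToRaw(ref_window)
    d <- qa != ra
    if (sum(d) <= 2L) {
      ops <- rle(ifelse(d, "X", "="))
      return(structure(list(score = sum(d),
                            cigar = paste0(ops$lengths, ops$values, collapse = ""),
                            ops = ops$values, lens = ops$lengths),
                       class = "mip_alignment"))
    }
  }
  q <- charToRaw(insert)
  r <- charToRaw(ref_window)
  # Gotoh-style DP. Gap cost is 1 per base as in the stated model; the
  # infinitesimal opening term only breaks ties among cost-equal paths in
  # favour of contiguous gaps (so e.g. one 10 nt deletion is preferred
  # over several short ones of the same total length). It never changes
  # the integer optimum at these problem sizes.
  open <- 1e-6; ext <- 1
  INF <- 1e18
  B <- matrix(INF, m + 1L, n + 1L)   # best
  E <- matrix(INF, m + 1L, n + 1L)   # ending in D (gap consuming ref)
  F_ <- matrix(INF, m + 1L, n + 1L)  # ending in I (gap consuming insert)
  B[1L, 1L] <- 0
  if (n > 0L) {
    E[1L, 2L:(n + 1L)] <- open + ext * seq_len(n)
    B[1L, 2L:(n + 1L)] <- E[1L, 2L:(n + 1L)]
  }
  F_[2L:(m + 1L), 1L] <- open + ext * seq_len(m)
  B[2L:(m + 1L), 1L] <- F_[2L:(m + 1L), 1L]
  for (i in seq_len(m)) {
    sub <- as.numeric(r != q[i])
    F_[i + 1L, -1L] <- pmin(F_[i, -1L] + ext, B[i, -1L] + open + ext)
    mdiag <- B[i, seq_len(n)] + sub
    e_prev <- INF
    b_prev <- B[i + 1L, 1L]
    for (j in seq_len(n)) {
      e <- min(e_prev + ext, b_prev + open + ext)
      b <- min(mdiag[j], F_[i + 1L, j + 1L], e)
      E[i + 1L, j + 1L] <- e
      B[i + 1L, j + 1L] <- b
      e_prev <- e
      b_prev <- b
    }
  }
  # traceback: prefer diagonal over D over I; inside a gap, prefer to
  # extend it
  ops <- character(m + n)
  k <- 0L
  i <- m; j <- n
  state <- "B"
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == "B") {
      b <- B[i + 1L, j + 1L]
      if (i > 0L && j > 0L &&
          abs(b - (B[i, j] + as.numeric(q[i] != r[j]))) < tol) {
        k <- k + 1L
        ops[k] <- if (q[i] == r[j]) "=" else "X"
        i <- i - 1L; j <- j - 1L
      } else if (j > 0L && abs(b - E[i + 1L, j + 1L]) < tol) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      k <- k + 1L
      ops[k] <- "D"
      ej <- E[i + 1L, j + 1L]
      cont <- j > 1L && abs(ej - (E[i + 1L, j] + ext)) < tol
      j <- j - 1L
      if (!cont) state <- "B"
    } else {
      k <- k + 1L
      ops[k] <- "I"
      fi <- F_[i + 1L, j + 1L]
      cont <- i > 1L && abs(fi - (F_[i, j + 1L] + ext)) < tol
      i <- i - 1L
      if (!cont) state <- "B"
    }
  }
  runs <- rle(rev(ops[seq_len(k)]))
  structure(list(score = as.integer(round(B[m + 1L, n + 1L])),
                 cigar = paste0(runs$lengths, runs$values, collapse = ""),
                 ops = runs$values, lens = runs$lengths),
            class = "mip_alignment")
}

# Turn one aligned molecule into per-position observations.
# Returns data.frame(pos0, obs): one observation per covered reference
# position; a deletion replaces the observation at its anchor (the
# preceding reference base) with "D:<deleted>", an insertion with
# "I:<inserted>". Events touching the window edges are dropped.
alignment_observations <- function(aln, insert, ref_window, window_start) {
  m <- nchar(insert)
  n <- nchar(ref_window)
  pos <- integer(n)
  obs <- character(n)
  k <- 0L
  qpos <- 0L; rpos <- 0L
  events <- list()
  for (t in seq_along(aln$ops)) {
    op <- aln$ops[t]; len <- aln$lens[t]
    if (op == "=" || op == "X") {
      idx <- seq_len(len)
      pos[k + idx] <- rpos + idx - 1L
      obs[k + idx] <- if (op == "=") {
        strsplit(substr(ref_window, rpos + 1L, rpos + len), "")[[1L]]
      } else {
        strsplit(substr(insert, qpos + 1L, qpos + len), "")[[1L]]
      }
      k <- k + len
      qpos <- qpos + len; rpos <- rpos + len
    } else if (op == "D") {
      if (rpos > 0L && rpos + len < n) {
        events[[length(events) + 1L]] <- list(
          anchor = rpos - 1L,
          allele = paste0("D:", substr(ref_window, rpos + 1L, rpos + len)))
      }
      rpos <- rpos + len
    } else {  # I
      if (rpos > 0L && rpos < n) {
        events[[length(events) + 1L]] <- list(
          anchor = rpos - 1L,
          allele = paste0("I:", substr(insert, qpos + 1L, qpos + len)))
      }
      qpos <- qpos + len
    }
  }
  pos <- pos[seq_len(k)]
  obs <- obs[seq_len(k)]
  for (e in events) {
    hit <- which(pos == e$anchor)
    if (length(hit) == 1L) obs[hit] <- e$allele
  }
  # drop N observations (consensus ties carry no evidence)
  keep <- obs != "N"
  data.frame(pos0 = window_start + pos[keep], obs = obs[keep],
             stringsAsFactors = FALSE)
}

#' Build pileup columns from consensus molecules
#'
#' Each molecule is globally aligned to its probe's reference window and
#' contributes at most one observation per covered reference position
#' (deletion and insertion alleles are anchored to the preceding base).
#' Columns are restricted to the supplied target domain.
#'
#' @param molecules Molecule data.frame from [molecule_table()].
#' @param reference Named character vector of reference sequences.
#' @param targets Target region data.frame restricting the column domain
#'   (typically the padded targets), or `NULL` for no restriction.
#' @return Pileup data.frame: `contig`, `pos0`, `ref_base`, `obs`,
#'   `count`.
#' @export
pileup <- function(molecules, reference, targets = NULL) {
  obs_list <- vector("list", nrow(molecules))
  for (i in seq_len(nrow(molecules))) {
    mol <- molecules[i, ]
    win <- substr(reference[[mol$contig]], mol$gap_start + 1L, mol$gap_end)
    aln <- align_insert(mol$consensus, win)
    o <- alignment_observations(aln, mol$consensus, win, mol$gap_start)
    if (nrow(o) > 0L) {
      o$contig <- mol$contig
      obs_list[[i]] <- o
    }
  }
  dt <- data.table::rbindlist(obs_list)
  if (nrow(dt) == 0L) {
    return(data.frame(contig = character(), pos0 = integer(),
                      ref_base = character(), obs = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  cols <- dt[, list(count = .N), by = c("contig", "pos0", "obs")]
  if (!is.null(targets)) {
    tdt <- data.table::as.data.table(targets)
    keep <- rep(FALSE, nrow(cols))
    for (ctg in unique(tdt$contig)) {
      t_ctg <- tdt[contig == ctg]
      sel <- which(cols$contig == ctg)
      for (r in seq_len(nrow(t_ctg))) {
        keep[sel] <- keep[sel] |
          (cols$pos0[sel] >= t_ctg$start[r] & cols$pos0[sel] < t_ctg$end[r])
      }
    }
    cols <- cols[keep]
  }
  cols[, ref_base := substring(reference[contig], pos0 + 1L, pos0 + 1L)]
  out <- as.data.frame(cols[order(contig, pos0, -count, obs)])
  out[, c("contig", "pos0", "ref_base", "obs", "count")]
}

#' Genotype pileup columns
#'
#' Diploid likelihoods with per-observation error `e`: under `RR` an
#' observation is the ref allele with probability `1 - e`, any specific
#' other allele with `e/3`; `AA` symmetric; under `RA` each of `R`/`A` is
#' seen with probability `(1 - e)/2 + e/6`. Uniform prior; genotype is the
#' posterior argmax, `GQ = -10 log10(1 - posterior)`. Calls are emitted
#' only at depth >= `min_depth` and GQ >= `min_gq`; the alt allele is the
#' most frequent non-reference allele.
#'
#' @param columns Pileup data.frame from [pileup()].
#' @param params `mip_caller_params`.
#' @return Genotype data.frame (one row per emitted position): `contig`,
#'   `pos0`, `ref_base`, `alt_allele` (`NA` for pure-reference columns),
#'   `gt`, `dp`, `ad_ref`, `ad_alt`, `gq`.
#' @export
genotype_columns <- function(columns, params = caller_params()) {
  if (nrow(columns) == 0L) {
    return(data.frame(contig = character(), pos0 = integer(),
                      ref_base = character(), alt_allele = character(),
                      gt = character(), dp = integer(), ad_ref = integer(),
                      ad_alt = integer(), gq = numeric(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(columns)
  per_pos <- dt[, {
    depth <- sum(count)
    n_ref <- sum(count[obs == ref_base[1L]])
    alts <- .SD[obs != ref_base[1L]]
    if (nrow(alts) > 0L) {
      best <- alts[order(-count, obs)][1L]
      alt_allele <- best$obs
      n_alt <- best$count
    } else {
      alt_allele <- NA_character_
      n_alt <- 0L
    }
    list(ref_base = ref_base[1L], alt_allele = alt_allele,
         dp = depth, ad_ref = n_ref, ad_alt = n_alt)
  }, by = c("contig", "pos0")]

  e <- params$error_rate
  n_other <- per_pos$dp - per_pos$ad_ref - per_pos$ad_alt
  ll_rr <- per_pos$ad_ref * log(1 - e) + (per_pos$ad_alt + n_other) * log(e / 3)
  p_het <- 0.5 * (1 - e) + 0.5 * (e / 3)
  ll_ra <- (per_pos$ad_ref + per_pos$ad_alt) * log(p_het) + n_other * log(e / 3)
  ll_aa <- per_pos$ad_alt * log(1 - e) + (per_pos$ad_ref + n_other) * log(e / 3)
  ll <- cbind(ll_rr, ll_ra, ll_aa)
  mx <- apply(ll, 1L, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  pick <- max.col(post, ties.method = "first")
  gt <- c("0/0", "0/1", "1/1")[pick]
  # a column with no alt observations cannot be called non-ref
  gt[is.na(per_pos$alt_allele)] <- "0/0"
  p_max <- post[cbind(seq_len(nrow(post)), pick)]
  gq <- pmin(99, -10 * log10(pmax(1 - p_max, 1e-10)))
  out <- as.data.frame(per_pos)
  out$gt <- gt
  out$gq <- gq
  keep <- out$dp >= params$min_depth & out$gq >= params$min_gq
  out <- out[keep, c("contig", "pos0", "ref_base", "alt_allele", "gt",
                     "dp", "ad_ref", "ad_alt", "gq")]
  rownames(out) <- NULL
  out
}

#' Call variants from consensus molecules
#'
#' Aligns molecules, builds pileups, genotypes columns and converts
#' non-reference genotypes to left-normalized VCF-style records.
#'
#' @param molecules Molecule data.frame.
#' @param reference Named character vector of reference sequences.
#' @param targets Target domain (padded targets) or `NULL`.
#' @param params `mip_caller_params`.
#' @return List with `genotyped` (all emitted positions) and `calls`
#'   (variant records: `contig`, `pos1`, `ref`, `alt`, `gt`, `dp`,
#'   `ad_ref`, `ad_alt`, `gq`).
#' @export
call_variants <- function(molecules, reference, targets = NULL,
                          params = caller_params()) {
  cols <- pileup(molecules, reference, targets)
  geno <- genotype_columns(cols, params)
  var <- geno[geno$gt != "0/0" & !is.na(geno$alt_allele), , drop = FALSE]
  if (nrow(var) > 0L) {
    recs <- lapply(seq_len(nrow(var)), function(i) {
      v <- var[i, ]
      if (startsWith(v$alt_allele, "D:")) {
        ref <- paste0(v$ref_base, sub("^D:", "", v$alt_allele))
        alt <- v$ref_base
      } else if (startsWith(v$alt_allele, "I:")) {
        ref <- v$ref_base
        alt <- paste0(v$ref_base, sub("^I:", "", v$alt_allele))
      } else {
        ref <- v$ref_base
        alt <- v$alt_allele
      }
      norm <- normalize_variant(v$contig, v$pos0 + 1L, ref, alt, reference)
      data.frame(contig = v$contig, pos1 = norm$pos1, ref = norm$ref,
                 alt = norm$alt, gt = v$gt, dp = v$dp, ad_ref = v$ad_ref,
                 ad_alt = v$ad_alt, gq = v$gq, stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, recs)
    calls <- calls[order(calls$contig, calls$pos1), , drop = FALSE]
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(contig = character(), pos1 = integer(),
                        ref = character(), alt = character(), gt = character(),
                        dp = integer(), ad_ref = integer(), ad_alt = integer(),
                        gq = numeric(), stringsAsFactors = FALSE)
  }
  list(genotyped = geno, calls = calls)
}

#' Left-normalize a VCF-style variant
#'
#' Trims shared trailing bases (extending left with the reference when an
#' allele would empty) and then shared leading bases, yielding the
#' left-most minimal representation.
#'
#' @param contig Contig name.
#' @param pos1 1-based position.
#' @param ref,alt Allele strings.
#' @param reference Named character vector of reference sequences.
#' @return List with `pos1`, `ref`, `alt`.
#' @export
normalize_variant <- function(contig, pos1, ref, alt, reference) {
  seq_ctg <- reference[[contig]]
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1L || na > 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        pos1 <- pos1 - 1L
        if (pos1 < 1L) stop("cannot normalize variant at contig start")
        anchor <- substr(seq_ctg, pos1, pos1)
        ref <- paste0(anchor, ref)
        alt <- paste0(anchor, alt)
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos1 <- pos1 + 1L
  }
  list(pos1 = pos1, ref = ref, alt = alt)
}
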