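# Unique-molecule depth over targeted bases, the sample pass rule
# (>= 80% of bases at >= 8x) and low-coverage exon flagging.

#' Compute unique-molecule depth over targeted bases
#'
#' Each unique molecule adds exactly 1 to every targeted base its gap fill
#' covers. The domain is the union of the supplied (typically padded)
#' target bases.
#'
#' @param molecules Molecule data.frame (needs `contig`, `gap_start`,
#'   `gap_end`).
#' @param targets Target region data.frame defining the depth domain.
#' @return Depth profile data.frame: `contig`, `pos` (0-based), `depth`,
#'   one row per targeted base.
#' @export
compute_depth <- function(molecules, targets) {
  out <- list()
  for (ctg in unique(targets$contig)) {
    t_ctg <- targets[targets$contig == ctg, , drop = FALSE]
    m_ctg <- molecules[molecules$contig == ctg, , drop = FALSE]
    hi <- max(t_ctg$end, if (nrow(m_ctg)) max(m_ctg$gap_end) else 0L)
    delta <- integer(hi + 1L)
    if (nrow(m_ctg) > 0L) {
      add <- tabulate(m_ctg$gap_start + 1L, nbins = hi + 1L)
      rem <- tabulate(m_ctg$gap_end + 1L, nbins = hi + 1L)
      delta <- add - rem
    }
    depth_vec <- cumsum(delta)          # depth_vec[p + 1] = depth at 0-based p
    mask <- logical(hi)
    for (i in seq_len(nrow(t_ctg))) {
      mask[seq.int(t_ctg$start[i] + 1L, t_ctg$end[i])] <- TRUE
    }
    pos <- which(mask) - 1L
    out[[ctg]] <- data.frame(contig = ctg, pos = pos,
                             depth = depth_vec[pos + 1L],
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample-level coverage QC
#'
#' A sample passes when at least `min_frac` of targeted bases reach
#' `min_depth` coverage (both bounds inclusive). Also reports the fraction
#' of bases at >= 40x and the median depth (for an even base count, the
#' lower of the two central values).
#'
#' @param profile Depth profile from [compute_depth()].
#' @param min_frac Pass threshold on the covered fraction (default 0.80).
#' @param min_depth Depth threshold (default 8).
#' @return A list of class `mip_sample_qc`: `fraction_ge8`,
#'   `fraction_ge40`, `median_depth`, `passed`, `n_bases`, thresholds.
#' @export
sample_pass <- function(profile, min_frac = 0.80, min_depth = 8L) {
  n <- nrow(profile)
  if (n == 0L) stop("input error: empty target domain")
  d <- profile$depth
  frac8 <- mean(d >= min_depth)
  frac40 <- mean(d >= 40L)
  ds <- sort(d)
  med <- ds[if (n %% 2L == 0L) n %/% 2L else (n + 1L) %/% 2L]
  structure(
    list(fraction_ge8 = frac8, fraction_ge40 = frac40,
         median_depth = med, passed = frac8 >= min_frac,
         n_bases = n, min_frac = min_frac, min_depth = as.integer(min_depth)),
    class = "mip_sample_qc"
  )
}

#' @export
print.mip_sample_qc <- function(x, ...) {
  cat(sprintf("smMIP sample QC over %d targeted bases\n", x$n_bases))
  cat(sprintf("  >= %dx: %.1f%%   >= 40x: %.1f%%   median depth: %d\n",
              x$min_depth, 100 * x$fraction_ge8, 100 * x$fraction_ge40,
              x$median_depth))
  cat(sprintf("  pass (>= %.0f%% at >= %dx): %s\n",
              100 * x$min_frac, x$min_depth, if (x$passed) "YES" else "NO"))
  invisible(x)
}

#' Per-exon mean coverage and low-coverage flagging
#'
#' An exon is flagged when its mean depth is strictly below `flag_below`
#' or when no base is covered at all.
#'
#' @param profile Depth profile from [compute_depth()].
#' @param exons Exon region data.frame (`contig`, `start`, `end`,
#'   `exon_id`, `gene`); intervals must lie within the profile domain.
#' @param flag_below Mean-depth flag threshold (default 10, strict).
#' @return Data.frame: `exon_id`, `gene`, `mean_depth`, `flagged`.
#' @export
exon_mean_coverage <- function(profile, exons, flag_below = 10) {
  if (any(exons$start >= exons$end)) stop("input error: zero-length exon")
  dt <- data.table::as.data.table(profile)
  res <- vector("list", nrow(exons))
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    d <- dt[contig == e$contig & pos >= e$start & pos < e$end, depth]
    if (length(d) == 0L) {
      stop("input error: exon ", e$exon_id, " outside the depth domain")
    }
    m <- mean(d)
    res[[i]] <- data.frame(
      exon_id = e$exon_id, gene = e$gene, mean_depth = m,
      flagged = m < flag_below || all(d == 0L),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a QC report as JSON
#'
#' @param qc `mip_sample_qc`.
#' @param exon_cov Optional exon coverage data.frame.
#' @param path Output JSON path.
#' @return Invisibly `path`.
#' @export
write_qc_report <- function(qc, exon_cov = NULL, path) {
  rep <- list(
    fraction_ge8 = qc$fraction_ge8,
    fraction_ge40 = qc$fraction_ge40,
    median_depth = qc$median_depth,
    passed = qc$passed,
    n_bases = qc$n_bases
  )
  if (!is.null(exon_cov)) {
    rep$flagged_exons <- exon_cov$exon_id[exon_cov$flagged]
    rep$n_exons <- nrow(exon_cov)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
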