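# Truth-set comparison: variant sensitivity and genotype concordance at
# adequately covered positions.

gt_multiset <- function(gt) {
  vapply(strsplit(gt, "[/|]"), function(a) paste(sort(a), collapse = "/"),
         character(1L))
}

#' Compare a call set to a truth set
#'
#' Truth variants are restricted to positions whose unique-molecule depth
#' reaches `min_depth` ("assessable"). Sensitivity is the fraction of
#' assessable truth variants present in the calls (site + alleles match,
#' after both sets have been left-normalized); genotype concordance is
#' computed over the intersected sites as unordered allele-multiset
#' equality. False positives are called variants within the target domain
#' that are absent from the truth set.
#'
#' @param calls Variant call data.frame (`contig`, `pos1`, `ref`, `alt`,
#'   `gt`).
#' @param truth Truth data.frame in the same layout.
#' @param depth_profile Depth profile from [compute_depth()]; its domain
#'   also defines "within target domain" for false-positive counting.
#' @param min_depth Assessability threshold (default 8).
#' @param genotyped Optional full genotyped-position table from
#'   [call_variants()] (`$genotyped`) to additionally report concordance
#'   over all genotyped positions.
#' @param reference Optional named character vector of reference
#'   sequences; when supplied, both call and truth records are
#'   left-normalized before matching (recommended whenever indels are
#'   compared).
#' @return A list of class `mip_concordance`.
#' @export
compare_to_truth <- function(calls, truth, depth_profile, min_depth = 8L,
                             genotyped = NULL, reference = NULL) {
  if (!is.null(reference)) {
    norm_set <- function(d) {
      for (i in seq_len(nrow(d))) {
        nv <- normalize_variant(d$contig[i], d$pos1[i], d$ref[i], d$alt[i],
                                reference)
        d$pos1[i] <- nv$pos1; d$ref[i] <- nv$ref; d$alt[i] <- nv$alt
      }
      d
    }
    calls <- norm_set(calls)
    truth <- norm_set(truth)
  }
  dp <- data.table::as.data.table(depth_profile)
  depth_at <- function(ctg, p1) {
    hit <- dp[contig == ctg & pos == p1 - 1L, depth]
    if (length(hit) == 0L) 0L else hit[1L]
  }
  in_domain <- function(ctg, p1) {
    nrow(dp[contig == ctg & pos == p1 - 1L]) > 0L
  }
  t_depth <- mapply(depth_at, truth$contig, truth$pos1)
  assessable <- truth[t_depth >= min_depth, , drop = FALSE]

  key <- function(d) paste(d$contig, d$pos1, d$ref, d$alt, sep = ":")
  call_keys <- key(calls)
  truth_keys_all <- key(truth)
  asse_keys <- key(assessable)

  detected <- asse_keys %in% call_keys
  n_truth_assessable <- nrow(assessable)
  n_detected <- sum(detected)
  sensitivity <- if (n_truth_assessable == 0L) NA_real_ else
    n_detected / n_truth_assessable

  # genotype concordance over detected sites
  idx <- match(asse_keys[detected], call_keys)
  gt_match <- gt_multiset(assessable$gt[detected]) == gt_multiset(calls$gt[idx])
  n_compared <- length(gt_match)
  n_genotype_match <- sum(gt_match)
  genotype_concordance <- if (n_compared == 0L) NA_real_ else
    n_genotype_match / n_compared

  fp <- !(call_keys %in% truth_keys_all) &
    mapply(in_domain, calls$contig, calls$pos1)
  n_false_positive <- sum(fp)

  genotype_concordance_all <- NA_real_
  n_genotyped <- NA_integer_
  if (!is.null(genotyped) && nrow(genotyped) > 0L) {
    # truth-implied genotype at every genotyped position: variant genotype
    # at truth anchor positions, homozygous reference elsewhere
    tkey <- paste(truth$contig, truth$pos1 - 1L, sep = ":")
    gkey <- paste(genotyped$contig, genotyped$pos0, sep = ":")
    expected <- rep("0/0", nrow(genotyped))
    hit <- match(gkey, tkey)
    expected[!is.na(hit)] <- truth$gt[hit[!is.na(hit)]]
    agree <- gt_multiset(genotyped$gt) == gt_multiset(expected)
    n_genotyped <- nrow(genotyped)
    genotype_concordance_all <- mean(agree)
  }

  structure(
    list(n_truth_assessable = n_truth_assessable,
         n_detected = n_detected,
         sensitivity = sensitivity,
         n_compared = n_compared,
         n_genotype_match = n_genotype_match,
         genotype_concordance = genotype_concordance,
         n_false_positive = n_false_positive,
         n_genotyped = n_genotyped,
         genotype_concordance_all = genotype_concordance_all,
         min_depth = as.integer(min_depth)),
    class = "mip_concordance"
  )
}

#' @export
print.mip_concordance <- function(x, ...) {
  cat(sprintf("Truth comparison (positions with >= %d unique molecules)\n",
              x$min_depth))
  cat(sprintf("  assessable truth variants : %d\n", x$n_truth_assessable))
  cat(sprintf("  detected                  : %d (sensitivity %s)\n",
              x$n_detected, format(x$sensitivity)))
  cat(sprintf("  genotype concordance      : %s (%d/%d variant sites)\n",
              format(x$genotype_concordance), x$n_genotype_match, x$n_compared))
  if (!is.na(x$genotype_concordance_all)) {
    cat(sprintf("  concordance, all genotyped: %s (%d positions)\n",
                format(x$genotype_concordance_all), x$n_genotyped))
  }
  cat(sprintf("  false positives in domain : %d\n", x$n_false_positive))
  invisible(x)
}

#' Write a concordance report as JSON
#' @param report `mip_concordance`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_concordance_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
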