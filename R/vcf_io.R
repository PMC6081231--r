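# Minimal VCF 4.2 emission (single sample, GT/DP/AD/GQ) and reading.

#' Write calls to a VCF 4.2 file
#'
#' Positions are 1-based; indels are expected to be left-normalized with
#' an anchor base (see [normalize_variant()]). Input must be sorted by
#' (contig, position).
#'
#' @param calls Call data.frame: `contig`, `pos1`, `ref`, `alt`, `gt`,
#'   and optionally `dp`, `ad_ref`, `ad_alt`, `gq`.
#' @param reference Named character vector of reference sequences (for
#'   contig header lines).
#' @param sample_id Sample column name.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_vcf <- function(calls, reference, sample_id, path) {
  o <- order(calls$contig, calls$pos1)
  if (!identical(o, seq_len(nrow(calls)))) {
    stop("internal error: calls must be sorted by (contig, pos)")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=mipkit-%s", as.character(utils::packageVersion("mipkit"))),
    sprintf("##contig=<ID=%s,length=%d>", names(reference), nchar(reference)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Unique-molecule depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  if (nrow(calls) > 0L) {
    dp <- if ("dp" %in% names(calls)) calls$dp else rep(".", nrow(calls))
    ad <- if (all(c("ad_ref", "ad_alt") %in% names(calls))) {
      paste0(calls$ad_ref, ",", calls$ad_alt)
    } else rep(".", nrow(calls))
    gq <- if ("gq" %in% names(calls)) round(calls$gq) else rep(".", nrow(calls))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD:GQ\t%s:%s:%s:%s",
                    calls$contig, calls$pos1, calls$ref, calls$alt,
                    calls$gt, as.character(dp), ad, as.character(gq))
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF file into a call data.frame
#'
#' Parses CHROM/POS/REF/ALT and the GT (and DP where present) of the
#' first sample. Multi-allelic records are not supported.
#'
#' @param path VCF path.
#' @return Data.frame: `contig`, `pos1`, `ref`, `alt`, `gt`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.frame(contig = character(), pos1 = integer(),
                      ref = character(), alt = character(), gt = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 8L)) stop("VCF format error: record with fewer than 8 fields")
  gt <- vapply(f, function(x) {
    if (length(x) < 10L) return(NA_character_)
    fmt <- strsplit(x[9L], ":", fixed = TRUE)[[1L]]
    smp <- strsplit(x[10L], ":", fixed = TRUE)[[1L]]
    gi <- match("GT", fmt)
    if (is.na(gi)) NA_character_ else smp[gi]
  }, character(1L))
  alt <- vapply(f, `[`, "", 5L)
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("VCF format error: multi-allelic records are not supported")
  }
  data.frame(
    contig = vapply(f, `[`, "", 1L),
    pos1 = as.integer(vapply(f, `[`, "", 2L)),
    ref = vapply(f, `[`, "", 4L),
    alt = alt,
    gt = gt,
    stringsAsFactors = FALSE
  )
}
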