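# Readers/writers and the coordinate model shared by all stages.
#
# All internal coordinates are 0-based half-open; conversion to 1-based
# happens only in the VCF and HGVS emitters.

#' Read a multi-record FASTA file
#'
#' Returns a named character vector of uppercase DNA sequences, one element
#' per record, in file order. Record names are truncated at the first
#' whitespace. Only the alphabet `A`, `C`, `G`, `T`, `N` is accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("FASTA format error: no records in ", path)
  if (any(Biostrings::width(x) == 0L)) {
    stop("FASTA format error: empty sequence record in ", path)
  }
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(
      "FASTA format error: non-ACGTN character in record(s): ",
      paste(names(seqs)[bad], collapse = ", ")
    )
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read target regions from a BED file
#'
#' Expects BED with at least three columns (contig, start, end) and an
#' optional fourth name column encoding `gene|exon_id`. Intervals are
#' 0-based half-open. Rows with a missing name column get autogenerated
#' `gene`/`exon_id` labels.
#'
#' @param path Path to a BED file (tab separated).
#' @param merge_overlaps If `TRUE`, overlapping or adjacent intervals on the
#'   same contig are unioned (labels of merged rows are collapsed with `;`).
#' @param reference Optional named character vector of reference sequences;
#'   when supplied, contigs are checked for existence and interval bounds.
#' @return A `data.frame` with columns `contig`, `start`, `end`, `gene`,
#'   `exon_id`.
#' @export
read_targets <- function(path, merge_overlaps = FALSE, reference = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED format error: fewer than 3 columns")
  df <- data.frame(
    contig = raw[[1L]],
    start = as.integer(raw[[2L]]),
    end = as.integer(raw[[3L]]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("BED format error: non-integer start/end")
  }
  bad <- df$start >= df$end | df$start < 0L
  if (any(bad)) {
    stop("BED format error: start >= end (or negative start) at line(s) ",
         paste(which(bad), collapse = ", "))
  }
  if (ncol(raw) >= 4L) {
    nm <- raw[[4L]]
    parts <- strsplit(nm, "|", fixed = TRUE)
    df$gene <- vapply(parts, `[`, "", 1L)
    df$exon_id <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
  } else {
    df$gene <- NA_character_
    df$exon_id <- NA_character_
  }
  auto <- is.na(df$gene) | df$gene == ""
  df$gene[auto] <- sprintf("target%03d", which(auto))
  autoe <- is.na(df$exon_id) | df$exon_id == ""
  df$exon_id[autoe] <- sprintf("exon%03d", which(autoe))
  if (!is.null(reference)) {
    unknown <- setdiff(unique(df$contig), names(reference))
    if (length(unknown) > 0L) {
      stop("BED lookup error: unknown contig(s): ", paste(unknown, collapse = ", "))
    }
    too_far <- df$end > nchar(reference)[match(df$contig, names(reference))]
    if (any(too_far)) {
      stop("BED lookup error: interval beyond contig end at line(s) ",
           paste(which(too_far), collapse = ", "))
    }
  }
  if (merge_overlaps) df <- merge_regions(df)
  df
}

#' Union overlapping or adjacent target regions
#'
#' @param targets Target region data.frame (`contig`, `start`, `end`,
#'   `gene`, `exon_id`).
#' @return Merged target data.frame; labels of merged rows are collapsed
#'   with `;`.
#' @export
merge_regions <- function(targets) {
  out <- lapply(split(targets, targets$contig), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    runs <- integer(nrow(d))
    run <- 1L
    cur_end <- d$end[1L]
    runs[1L] <- run
    for (i in seq_len(nrow(d))[-1L]) {
      if (d$start[i] <= cur_end) {   # overlapping or adjacent
        cur_end <- max(cur_end, d$end[i])
      } else {
        run <- run + 1L
        cur_end <- d$end[i]
      }
      runs[i] <- run
    }
    merged <- lapply(split(d, runs), function(g) {
      data.frame(
        contig = g$contig[1L],
        start = min(g$start),
        end = max(g$end),
        gene = paste(unique(g$gene), collapse = ";"),
        exon_id = paste(unique(g$exon_id), collapse = ";"),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, merged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Write target regions to a BED4 file
#'
#' @param targets Target region data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(targets, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s",
                   targets$contig, targets$start, targets$end,
                   targets$gene, targets$exon_id)
  writeLines(lines, path)
  invisible(path)
}

#' Transcript model for HGVS-style annotation
#'
#' Bundles a coding sequence with the signal-peptide length used for
#' mature-peptide renumbering.
#'
#' @param gene Gene symbol.
#' @param cds_sequence Coding DNA sequence (length divisible by 3).
#' @param signal_peptide_len Number of signal-peptide residues (>= 0).
#' @param transcript_id Transcript identifier label.
#' @return A list of class `mip_transcript`.
#' @export
transcript_model <- function(gene, cds_sequence, signal_peptide_len = 0L,
                             transcript_id = NA_character_) {
  cds_sequence <- toupper(cds_sequence)
  if (nchar(cds_sequence) %% 3L != 0L) {
    stop("CDS length must be divisible by 3")
  }
  if (grepl("[^ACGT]", cds_sequence)) stop("CDS contains non-ACGT characters")
  n_res <- nchar(cds_sequence) / 3L
  if (signal_peptide_len < 0L || signal_peptide_len >= n_res) {
    stop("signal_peptide_len must be in [0, protein length)")
  }
  structure(
    list(gene = gene, cds_sequence = cds_sequence,
         signal_peptide_len = as.integer(signal_peptide_len),
         transcript_id = transcript_id),
    class = "mip_transcript"
  )
}
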