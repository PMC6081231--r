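# Clinical-style interpretation utilities: HGVS codon arithmetic and
# mature-peptide renumbering, pedigree segregation, allele-frequency
# filtering and cohort phenotype summaries.

# standard genetic code, keyed by codon ("*" = stop)
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Map a coding (CDS) position to its codon
#'
#' @param c_pos 1-based coding position(s).
#' @param cds_len Optional CDS length for range checking.
#' @return Data.frame with `c_pos`, `codon_number`, `codon_offset`
#'   (1, 2 or 3).
#' @export
cds_codon <- function(c_pos, cds_len = NULL) {
  c_pos <- as.integer(c_pos)
  if (any(c_pos < 1L)) stop("input error: c_pos must be >= 1")
  if (!is.null(cds_len) && any(c_pos > cds_len)) {
    stop("input error: c_pos beyond CDS length ", cds_len)
  }
  data.frame(
    c_pos = c_pos,
    codon_number = (c_pos - 1L) %/% 3L + 1L,
    codon_offset = (c_pos - 1L) %% 3L + 1L
  )
}

#' Inverse of [cds_codon()]
#' @param codon_number,codon_offset Codon index and offset within codon.
#' @return 1-based coding position.
#' @export
codon_to_cds <- function(codon_number, codon_offset) {
  (as.integer(codon_number) - 1L) * 3L + as.integer(codon_offset)
}

#' Protein-level consequence of a coding substitution
#'
#' Translates the affected codon before and after the substitution with
#' the standard genetic code. When a signal-peptide length is defined on
#' the transcript, the mature-peptide residue number (preprotein residue
#' minus signal-peptide length) is reported as well.
#'
#' @param transcript `mip_transcript` from [transcript_model()].
#' @param c_pos 1-based coding position.
#' @param ref_nt,alt_nt Reference and alternate nucleotide (single base).
#' @return A list of class `mip_hgvs`: coding and protein coordinates,
#'   amino acids, `synonymous` flag, and `mature_residue` (NA when the
#'   residue lies within the signal peptide or none is defined).
#' @export
protein_change <- function(transcript, c_pos, ref_nt, alt_nt) {
  cds <- transcript$cds_sequence
  cc <- cds_codon(c_pos, nchar(cds))
  have <- substr(cds, c_pos, c_pos)
  if (have != ref_nt) {
    stop("input error: CDS position ", c_pos, " is ", have,
         ", not ", ref_nt)
  }
  cstart <- (cc$codon_number - 1L) * 3L + 1L
  codon_ref <- substr(cds, cstart, cstart + 2L)
  codon_alt <- codon_ref
  substr(codon_alt, cc$codon_offset, cc$codon_offset) <- alt_nt
  aa_ref <- GENETIC_CODE_TABLE[[codon_ref]]
  aa_alt <- GENETIC_CODE_TABLE[[codon_alt]]
  spl <- transcript$signal_peptide_len
  mature <- if (spl > 0L && cc$codon_number > spl) {
    cc$codon_number - spl
  } else if (spl == 0L) {
    cc$codon_number
  } else {
    NA_integer_
  }
  structure(
    list(transcript_id = transcript$transcript_id,
         c_pos = c_pos, ref_nt = ref_nt, alt_nt = alt_nt,
         codon_number = cc$codon_number, codon_offset = cc$codon_offset,
         aa_ref = aa_ref, aa_alt = aa_alt,
         synonymous = aa_ref == aa_alt,
         preprotein_residue = cc$codon_number,
         mature_residue = mature),
    class = "mip_hgvs"
  )
}

#' @export
print.mip_hgvs <- function(x, ...) {
  p <- if (x$synonymous) {
    sprintf("p.%s%d=", x$aa_ref, x$preprotein_residue)
  } else {
    sprintf("p.%s%d%s", x$aa_ref, x$preprotein_residue, x$aa_alt)
  }
  cat(sprintf("c.%d%s>%s  %s", x$c_pos, x$ref_nt, x$alt_nt, p))
  if (!is.na(x$mature_residue) && x$mature_residue != x$preprotein_residue) {
    cat(sprintf("  (mature peptide: residue %d)", x$mature_residue))
  }
  cat("\n")
  invisible(x)
}

#' Renumber a preprotein residue onto the mature peptide
#'
#' Mature-peptide numbering assigns residue 1 to the first amino acid
#' after signal-peptide cleavage, i.e. mature = preprotein - signal
#' length.
#'
#' @param preprotein_residue Residue number in preprotein numbering.
#' @param signal_peptide_len Signal peptide length in residues.
#' @return Mature-peptide residue number.
#' @export
mature_numbering <- function(preprotein_residue, signal_peptide_len) {
  preprotein_residue <- as.integer(preprotein_residue)
  signal_peptide_len <- as.integer(signal_peptide_len)
  if (any(preprotein_residue <= signal_peptide_len)) {
    stop("domain error: residue lies within the signal peptide")
  }
  preprotein_residue - signal_peptide_len
}

#' Check segregation of a variant in a pedigree
#'
#' Under an autosomal dominant model, every affected member is expected
#' to carry the variant: an affected non-carrier is a violation. An
#' unaffected carrier is not a violation but is recorded as a reduced
#' penetrance note. Members with unknown status or untested carrier state
#' are ignored.
#'
#' @param members Data.frame: `member_id`, `affected` (`"affected"`,
#'   `"unaffected"`, `"unknown"`), `carrier` (`"yes"`, `"no"`,
#'   `"untested"`).
#' @param model Inheritance model; only `"autosomal_dominant"` is
#'   supported.
#' @return A list: `consistent` flag, `violations` (member ids),
#'   `penetrance_notes` (member ids).
#' @export
check_segregation <- function(members, model = "autosomal_dominant") {
  if (!identical(model, "autosomal_dominant")) {
    stop("unsupported segregation model: ", model)
  }
  usable <- members$affected != "unknown" & members$carrier != "untested"
  if (!any(usable)) stop("input error: all members untested or unknown")
  m <- members[usable, , drop = FALSE]
  violations <- m$member_id[m$affected == "affected" & m$carrier == "no"]
  notes <- m$member_id[m$affected == "unaffected" & m$carrier == "yes"]
  list(consistent = length(violations) == 0L,
       violations = violations,
       penetrance_notes = notes)
}

#' Read a PED-like pedigree table
#' @param path TSV with columns `member_id`, `affected`, `carrier`.
#' @return Pedigree member data.frame.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("member_id", "affected", "carrier")
  if (!all(need %in% names(df))) {
    stop("pedigree table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Filter variants by population allele frequency
#'
#' A variant is retained when it is absent from the frequency table
#' (unobserved in the population) or its frequency is below `max_af`.
#'
#' @param variants Variant data.frame (`contig`, `pos1`, `ref`, `alt`).
#' @param af_table Data.frame (`contig`, `pos1`, `ref`, `alt`, `af`).
#' @param max_af Retention threshold (strict; default 0.001).
#' @return The retained subset of `variants`.
#' @export
frequency_filter <- function(variants, af_table, max_af = 0.001) {
  if (nrow(af_table) > 0L &&
      (any(af_table$af < 0) || any(af_table$af > 1) || any(is.na(af_table$af)))) {
    stop("input error: allele frequency outside [0, 1]")
  }
  vkey <- paste(variants$contig, variants$pos1, variants$ref, variants$alt,
                sep = ":")
  akey <- paste(af_table$contig, af_table$pos1, af_table$ref, af_table$alt,
                sep = ":")
  af <- af_table$af[match(vkey, akey)]
  keep <- is.na(af) | af < max_af
  variants[keep, , drop = FALSE]
}

#' Summarize a cohort phenotype sheet
#'
#' Counts and integer percentages (rounded half away from zero, matching
#' clinical table conventions) for diagnosis, sex and every per-hormone
#' deficiency flag column.
#'
#' @param sheet Data.frame with one row per patient: `patient_id`,
#'   `diagnosis` (`"IGHD"` / `"CPHD"`), optional `sex`, `age`, and any
#'   number of logical/0-1 deficiency flag columns.
#' @param check_diagnosis Verify that CPHD patients have >= 2 deficient
#'   axes and IGHD patients exactly one (default `TRUE`).
#' @return Summary data.frame: `category`, `n`, `percent`, plus the
#'   cohort size as attribute `n_total`.
#' @export
summarize_cohort <- function(sheet, check_diagnosis = TRUE) {
  if (nrow(sheet) == 0L) stop("input error: empty cohort sheet")
  total <- nrow(sheet)
  fixed <- c("patient_id", "diagnosis", "sex", "age")
  flag_cols <- setdiff(names(sheet), fixed)
  for (cc in flag_cols) sheet[[cc]] <- as.logical(sheet[[cc]])
  if (check_diagnosis && length(flag_cols) > 0L && "diagnosis" %in% names(sheet)) {
    n_axes <- rowSums(sheet[flag_cols], na.rm = TRUE)
    bad <- (sheet$diagnosis == "CPHD" & n_axes < 2L) |
      (sheet$diagnosis == "IGHD" & n_axes >= 2L)
    if (any(bad)) {
      stop("input error: diagnosis inconsistent with deficiency flags for ",
           paste(sheet$patient_id[bad], collapse = ", "))
    }
  }
  rows <- list()
  add <- function(category, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, n = n,
      percent = as.integer(round_half_up(100 * n / total)),
      stringsAsFactors = FALSE
    )
  }
  if ("diagnosis" %in% names(sheet)) {
    for (dx in unique(sheet$diagnosis)) add(dx, sum(sheet$diagnosis == dx))
  }
  if ("sex" %in% names(sheet)) {
    for (sx in unique(sheet$sex)) add(paste0("sex_", sx), sum(sheet$sex == sx))
  }
  for (cc in flag_cols) add(cc, sum(sheet[[cc]], na.rm = TRUE))
  out <- do.call(rbind, rows)
  attr(out, "n_total") <- total
  out
}

#' Read a cohort phenotype sheet
#' @param path TSV path.
#' @return Data.frame, one row per patient.
#' @export
read_cohort_sheet <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
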