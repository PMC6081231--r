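# Probe tiling over padded targets and assembly of full synthesis oligos
# with amplification flanks and EarI release sites.

EARI_SITE <- "CTCTTC"
EARI_SITE_RC <- "GAAGAG"

#' Panel design parameters
#'
#' Defaults: 25 bp target padding, extension arms 16-20 nt, ligation arms
#' 20-24 nt, 112 nt gap fill, 8 nt molecular tag, and the mipPrep1F /
#' mipPrep1R amplification primers (both carrying the EarI recognition
#' sequence `CTCTTC` so that digestion releases the probe body). Synthesis
#' oligos may not exceed 150 nt.
#'
#' @param pad_bp Padding added to each side of every target region (bp).
#' @param ext_arm_len_range Length range (nt) for the extension arm.
#' @param lig_arm_len_range Length range (nt) for the ligation arm.
#' @param gap_fill_len Gap-fill (insert) length in nt.
#' @param tag_len Molecular tag length in nt (>= 4).
#' @param backbone_left,backbone_right Fixed linker sequence flanking the
#'   tag block inside the probe body.
#' @param arm_gc_bounds Acceptable GC fraction range for each arm.
#' @param prep_primer_f,prep_primer_r Amplification primer sequences.
#' @param max_oligo_len Maximum synthesis oligo length (nt).
#' @return A list of class `mip_design_params`.
#' @export
design_params <- function(pad_bp = 25L,
                          ext_arm_len_range = c(16L, 20L),
                          lig_arm_len_range = c(20L, 24L),
                          gap_fill_len = 112L,
                          tag_len = 8L,
                          backbone_left = "CTTCAGCTTCCCGAT",
                          backbone_right = "ATCCGACGGTAGTGT",
                          arm_gc_bounds = c(0.15, 0.80),
                          prep_primer_f = "GGTAGCAAAGTGCAGATGTGCTCTTC",
                          prep_primer_r = "TGAACTCACACTGCTCTGAACTCTTC",
                          max_oligo_len = 150L) {
  if (gap_fill_len <= 0L) stop("gap_fill_len must be > 0")
  if (tag_len < 4L) stop("tag_len must be >= 4")
  if (!grepl(EARI_SITE, prep_primer_f, fixed = TRUE) ||
      !grepl(EARI_SITE, prep_primer_r, fixed = TRUE)) {
    stop("both prep primers must contain the EarI recognition sequence ", EARI_SITE)
  }
  structure(
    list(pad_bp = as.integer(pad_bp),
         ext_arm_len_range = as.integer(ext_arm_len_range),
         lig_arm_len_range = as.integer(lig_arm_len_range),
         gap_fill_len = as.integer(gap_fill_len),
         tag_len = as.integer(tag_len),
         backbone_left = backbone_left,
         backbone_right = backbone_right,
         arm_gc_bounds = arm_gc_bounds,
         prep_primer_f = prep_primer_f,
         prep_primer_r = prep_primer_r,
         max_oligo_len = as.integer(max_oligo_len)),
    class = "mip_design_params"
  )
}

#' Pad a target region, clipping at contig edges
#'
#' @param region Target region data.frame (may have several rows).
#' @param pad_bp Padding in bp on each side.
#' @param contig_len Named integer vector of contig lengths, or a single
#'   length when all rows share one contig.
#' @return Padded region data.frame.
#' @export
pad_region <- function(region, pad_bp, contig_len) {
  if (pad_bp < 0L) stop("pad_bp must be >= 0")
  len <- if (is.null(names(contig_len))) {
    rep_len(contig_len, nrow(region))
  } else {
    unname(contig_len[region$contig])
  }
  region$start <- pmax(0L, as.integer(region$start - pad_bp))
  region$end <- pmin(as.integer(len), as.integer(region$end + pad_bp))
  region
}

#' Tile padded target regions with smMIP probes
#'
#' Greedy left-to-right tiling: gap fills of fixed length are laid out with
#' step `gap_fill_len`; the last probe of each region is shifted left so
#' the union of gap fills covers every padded base. For each probe the
#' arm-length combination within the configured ranges with the smallest
#' summed GC distance from 0.5 is chosen; arms containing `N` or falling
#' off the contig are rejected. All probes are designed on the plus strand.
#'
#' @param padded_regions Padded target region data.frame.
#' @param reference Named character vector of reference sequences.
#' @param params `mip_design_params`.
#' @return Probe data.frame: `probe_id`, `contig`, `strand`, arm coordinates
#'   and sequences, and gap-fill coordinates (0-based half-open).
#' @export
tile_probes <- function(padded_regions, reference, params = design_params()) {
  gl <- params$gap_fill_len
  positions <- list()
  for (i in seq_len(nrow(padded_regions))) {
    r <- padded_regions[i, ]
    clen <- nchar(reference[[r$contig]])
    if (is.null(reference[[r$contig]]) || is.na(clen)) {
      stop("unknown contig in targets: ", r$contig)
    }
    span <- r$end - r$start
    if (span <= gl) {
      gs <- r$start - (gl - span) %/% 2L   # center the single gap fill
      gs <- max(max(params$ext_arm_len_range), min(gs, clen - gl - max(params$lig_arm_len_range)))
      starts <- gs
    } else {
      starts <- seq.int(r$start, r$end - gl, by = gl)
      if (max(starts) + gl < r$end) starts <- c(starts, r$end - gl)
    }
    positions[[i]] <- data.frame(contig = r$contig, gap_start = as.integer(starts),
                                 stringsAsFactors = FALSE)
  }
  pos <- unique(do.call(rbind, positions))
  pos <- pos[order(pos$contig, pos$gap_start), , drop = FALSE]
  pos$gap_end <- pos$gap_start + gl

  ext_lens <- seq.int(params$ext_arm_len_range[1L], params$ext_arm_len_range[2L])
  lig_lens <- seq.int(params$lig_arm_len_range[1L], params$lig_arm_len_range[2L])

  n <- nrow(pos)
  ext_seq <- ext_start <- lig_seq <- lig_end <- vector("list", n)
  out <- data.frame(
    probe_id = sprintf("MIP%05d", seq_len(n)),
    contig = pos$contig, strand = "+",
    ext_start = NA_integer_, ext_end = pos$gap_start, ext_seq = NA_character_,
    gap_start = pos$gap_start, gap_end = pos$gap_end,
    lig_start = pos$gap_end, lig_end = NA_integer_, lig_seq = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    ctg <- reference[[pos$contig[i]]]
    clen <- nchar(ctg)
    gs <- pos$gap_start[i]; ge <- pos$gap_end[i]
    if (gs < min(ext_lens) || ge > clen - min(lig_lens)) {
      stop("design failure: no room for arms at ", pos$contig[i], ":", gs, "-", ge)
    }
    best <- NULL; best_score <- Inf
    for (le in ext_lens) {
      if (gs - le < 0L) next
      es <- substr(ctg, gs - le + 1L, gs)
      if (grepl("N", es, fixed = TRUE)) next
      sc_e <- abs(gc_frac(es) - 0.5)
      for (ll in lig_lens) {
        if (ge + ll > clen) next
        ls <- substr(ctg, ge + 1L, ge + ll)
        if (grepl("N", ls, fixed = TRUE)) next
        score <- sc_e + abs(gc_frac(ls) - 0.5)
        if (score < best_score) {
          best_score <- score
          best <- list(le = le, es = es, ll = ll, ls = ls)
        }
      }
    }
    if (is.null(best)) {
      stop("design failure: no valid arm pair (N-free, in-contig) for region at ",
           pos$contig[i], ":", gs, "-", ge)
    }
    gcb <- params$arm_gc_bounds
    gcs <- gc_frac(c(best$es, best$ls))
    if (any(gcs < gcb[1L] | gcs > gcb[2L])) {
      warning("arm GC outside [", gcb[1L], ", ", gcb[2L], "] for probe at ",
              pos$contig[i], ":", gs)
    }
    out$ext_start[i] <- gs - best$le
    out$ext_seq[i] <- best$es
    out$lig_end[i] <- ge + best$ll
    out$lig_seq[i] <- best$ls
  }
  attr(out, "tag_len") <- params$tag_len
  out
}

#' Assemble full synthesis oligos for a probe set
#'
#' Layout (synthesis order): forward prep primer, ligation arm, left
#' backbone, tag placeholder (`N` x tag length), right backbone, extension
#' arm, reverse complement of the reverse prep primer.
#'
#' @param probes Probe data.frame from [tile_probes()].
#' @param params `mip_design_params`.
#' @return Oligo data.frame: `probe_id`, `sequence`, `length`.
#' @export
assemble_oligo <- function(probes, params = design_params()) {
  seqs <- paste0(
    params$prep_primer_f,
    probes$lig_seq,
    params$backbone_left,
    strrep("N", params$tag_len),
    params$backbone_right,
    probes$ext_seq,
    revcomp(params$prep_primer_r)
  )
  len <- nchar(seqs)
  over <- len > params$max_oligo_len
  if (any(over)) {
    i <- which(over)[1L]
    stop("design failure: oligo for probe ", probes$probe_id[i],
         " exceeds max length by ", len[i] - params$max_oligo_len, " nt")
  }
  data.frame(probe_id = probes$probe_id, sequence = seqs, length = len,
             stringsAsFactors = FALSE)
}

#' Digest a sequence with EarI
#'
#' EarI recognizes `CTCTTC` and cuts 1 nt downstream on the top strand; a
#' site on the bottom strand (`GAAGAG` on the top strand) cuts the top
#' strand 4 nt upstream of the `GAAGAG` occurrence. Only top-strand
#' fragment strings are returned; they partition the input in order.
#'
#' @param oligo DNA string.
#' @return Character vector of fragments.
#' @export
digest_ear1 <- function(oligo) {
  n <- nchar(oligo)
  cuts <- integer(0)
  top <- gregexpr(EARI_SITE, oligo, fixed = TRUE)[[1L]]
  if (top[1L] != -1L) cuts <- c(cuts, top + 6L)        # 1-based start p: boundary p+6 (0-based)
  bot <- gregexpr(EARI_SITE_RC, oligo, fixed = TRUE)[[1L]]
  if (bot[1L] != -1L) cuts <- c(cuts, bot - 5L)        # boundary 4 nt 5' of site
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  bounds <- c(0L, cuts, n)
  substring(oligo, bounds[-length(bounds)] + 1L, bounds[-1L])
}

#' Design a complete panel from reference and targets
#'
#' Convenience wrapper: pads targets, tiles probes and assembles oligos.
#'
#' @param reference Named character vector of reference sequences.
#' @param targets Target region data.frame.
#' @param params `mip_design_params`.
#' @return List with elements `padded_targets`, `probes`, `oligos`, `params`.
#' @export
design_panel <- function(reference, targets, params = design_params()) {
  padded <- pad_region(targets, params$pad_bp, nchar(reference))
  probes <- tile_probes(padded, reference, params)
  oligos <- assemble_oligo(probes, params)
  list(padded_targets = padded, probes = probes, oligos = oligos, params = params)
}

#' Write / read the probe table
#'
#' @param probes Probe data.frame.
#' @param path TSV path.
#' @return Invisibly `path`; `read_probe_table()` returns the data.frame
#'   with the `tag_len` attribute restored from the header comment.
#' @export
write_probe_table <- function(probes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#tag_len=%d", attr(probes, "tag_len") %||% 8L), con)
  utils::write.table(probes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  first <- readLines(path, n = 1L)
  tag_len <- 8L
  if (grepl("^#tag_len=", first)) tag_len <- as.integer(sub("^#tag_len=", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "tag_len") <- tag_len
  df
}
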