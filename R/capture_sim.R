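# Fixture generator: diploid haplotypes with planted variants, and smMIP
# paired-end reads with molecular tags, PCR duplicates and base errors,
# plus a ground-truth molecule ledger.

#' Capture simulation parameters
#'
#' Defaults emulate a desk-scale smMIP run: 50 captured molecules per
#' probe, PCR duplicate counts distributed 1 + Geometric with mean 2,
#' a 0.001 per-base substitution error rate, and paired-end 100 bp reads.
#'
#' @param molecules_per_probe Unique molecules captured per probe.
#' @param duplication_mean Mean PCR duplicate count per molecule (>= 1);
#'   counts are drawn as 1 + Geometric(1/duplication_mean).
#' @param base_error_rate Per-base substitution error probability in [0, 0.5).
#' @param read_len Read length in nt.
#' @param seed Integer seed controlling all randomness of the simulation.
#' @return A list of class `mip_sim_config`.
#' @export
sim_config <- function(molecules_per_probe = 50L, duplication_mean = 2,
                       base_error_rate = 0.001, read_len = 100L, seed = 1L) {
  if (base_error_rate < 0 || base_error_rate >= 0.5) {
    stop("base_error_rate must be in [0, 0.5)")
  }
  if (duplication_mean < 1) stop("duplication_mean must be >= 1")
  structure(
    list(molecules_per_probe = as.integer(molecules_per_probe),
         duplication_mean = duplication_mean,
         base_error_rate = base_error_rate,
         read_len = as.integer(read_len),
         seed = as.integer(seed)),
    class = "mip_sim_config"
  )
}

#' Validate a simulation config against a probe panel
#'
#' The read length must accommodate the longest arm plus the molecular tag
#' plus at least one insert base.
#'
#' @param config `mip_sim_config`.
#' @param probes Probe data.frame (with `tag_len` attribute).
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_sim_config <- function(config, probes) {
  tag_len <- attr(probes, "tag_len") %||% 8L
  longest_arm <- max(nchar(probes$ext_seq), nchar(probes$lig_seq))
  need <- longest_arm + tag_len + 1L
  if (config$read_len < need) {
    stop("config error: read_len ", config$read_len,
         " shorter than longest arm + tag_len + 1 (", need, ")")
  }
  invisible(TRUE)
}

#' Plant variants into a reference to build a diploid sample
#'
#' Homozygous variants are applied to both haplotypes, heterozygous
#' variants to haplotype 1 only. Variant specs use VCF-style alleles
#' (indels carry the anchor base) at 0-based positions.
#'
#' @param reference Named character vector of reference sequences.
#' @param specs Data.frame with columns `contig`, `pos` (0-based),
#'   `ref`, `alt`, `zygosity` (`"het"` or `"hom"`); `ref` must match the
#'   reference and ref intervals must not overlap.
#' @return A list of class `mip_haplotypes`: `haplotypes` (per contig, a
#'   character vector `c(h1, h2)`), `events` (per-haplotype applied
#'   variants) and `truth` (1-based truth records with genotypes).
#' @export
plant_variants <- function(reference, specs) {
  if (is.null(specs) || nrow(specs) == 0L) {
    specs <- data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        zygosity = character(), stringsAsFactors = FALSE)
  }
  specs$pos <- as.integer(specs$pos)
  # validate
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    ctg <- reference[[s$contig]]
    if (is.null(ctg)) stop("input error: unknown contig ", s$contig)
    obs <- substr(ctg, s$pos + 1L, s$pos + nchar(s$ref))
    if (obs != s$ref) {
      stop("input error: ref mismatch at ", s$contig, ":", s$pos,
           " (expected ", s$ref, ", reference has ", obs, ")")
    }
    if (s$ref == s$alt) stop("input error: ref == alt at ", s$contig, ":", s$pos)
  }
  # non-overlap of ref intervals per contig
  for (ctg in unique(specs$contig)) {
    d <- specs[specs$contig == ctg, ]
    d <- d[order(d$pos), ]
    if (nrow(d) > 1L) {
      ends <- d$pos + nchar(d$ref)
      if (any(d$pos[-1L] < ends[-nrow(d)])) {
        stop("input error: overlapping variant ref intervals on ", ctg)
      }
    }
  }
  haplotypes <- list()
  events <- list()
  for (ctg in names(reference)) {
    d <- specs[specs$contig == ctg, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    hap_seqs <- character(2L)
    for (h in 1:2) {
      on_h <- d[d$zygosity == "hom" | (d$zygosity == "het" & h == 1L), , drop = FALSE]
      s <- reference[[ctg]]
      if (nrow(on_h) > 0L) {
        for (i in rev(seq_len(nrow(on_h)))) {   # apply right-to-left
          v <- on_h[i, ]
          s <- paste0(substr(s, 1L, v$pos), v$alt,
                      substr(s, v$pos + nchar(v$ref) + 1L, nchar(s)))
        }
      }
      hap_seqs[h] <- s
      events[[paste0(ctg, ".", h)]] <- on_h
    }
    haplotypes[[ctg]] <- hap_seqs
  }
  truth <- if (nrow(specs) > 0L) {
    data.frame(contig = specs$contig, pos1 = specs$pos + 1L,
               ref = specs$ref, alt = specs$alt,
               gt = ifelse(specs$zygosity == "hom", "1/1", "0/1"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(contig = character(), pos1 = integer(), ref = character(),
               alt = character(), gt = character(), stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$contig, truth$pos1), , drop = FALSE]
  structure(list(haplotypes = haplotypes, events = events, truth = truth),
            class = "mip_haplotypes")
}

# map a 0-based reference coordinate onto a haplotype coordinate, given the
# events (VCF-style, sorted by pos) applied to that haplotype
map_ref_to_hap <- function(events, x) {
  if (is.null(events) || nrow(events) == 0L) return(x)
  pos <- events$pos
  rl <- nchar(events$ref)
  al <- nchar(events$alt)
  delta <- al - rl
  vapply(x, function(xi) {
    before <- pos + rl <= xi
    shift <- sum(delta[before])
    inside <- which(pos < xi & xi < pos + rl)
    if (length(inside) == 1L) {
      e <- inside[1L]
      xi <- pos[e] + min(xi - pos[e], al[e])
      shift <- sum(delta[pos + rl <= pos[e]])
    }
    as.integer(xi + shift)
  }, integer(1L))
}

# substitution lookup used when applying base errors
.SUBST <- matrix(c("C", "G", "T",
                   "A", "G", "T",
                   "A", "C", "T",
                   "A", "C", "G"),
                 nrow = 4L, byrow = TRUE,
                 dimnames = list(c("A", "C", "G", "T"), NULL))

# apply i.i.d. substitution errors to fixed-width reads
apply_base_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  w <- nchar(reads[1L])
  big <- paste(reads, collapse = "")
  raw <- charToRaw(big)
  idx <- which(stats::runif(length(raw)) < rate)
  if (length(idx) > 0L) {
    cur <- strsplit(rawToChar(raw[idx]), "")[[1L]]
    ok <- cur %in% rownames(.SUBST)
    idx <- idx[ok]; cur <- cur[ok]
    if (length(idx) > 0L) {
      pick <- sample.int(3L, length(idx), replace = TRUE)
      rows <- match(cur, rownames(.SUBST))
      raw[idx] <- charToRaw(paste(.SUBST[cbind(rows, pick)], collapse = ""))
    }
  }
  big <- rawToChar(raw)
  starts <- seq.int(1L, by = w, length.out = length(reads))
  out <- substring(big, starts, starts + w - 1L)
  names(out) <- names(reads)
  out
}

#' Simulate smMIP capture of a diploid sample
#'
#' Per probe, `molecules_per_probe` molecules are drawn alternately from
#' the two haplotypes. Each molecule receives an i.i.d. random molecular
#' tag and a PCR duplicate count of 1 + Geometric. Read 1 carries the
#' extension arm followed by the insert; read 2 carries the molecular tag
#' followed by the reverse complement of (insert + ligation arm). Reads
#' are truncated to `read_len` (continuing into the opposite arm/backbone
#' when the insert is short) and substitution errors are applied i.i.d.
#' per base.
#'
#' @param probes Probe data.frame from [tile_probes()].
#' @param haplotypes `mip_haplotypes` from [plant_variants()].
#' @param config `mip_sim_config`.
#' @return List with `r1`, `r2` (named character vectors of reads) and
#'   `ledger` (data.frame: `molecule_id`, `probe_id`, `tag`, `haplotype`,
#'   `duplicate_count`).
#' @export
simulate_capture <- function(probes, haplotypes, config = sim_config()) {
  validate_sim_config(config, probes)
  tag_len <- attr(probes, "tag_len") %||% 8L
  shared <- intersect(unique(probes$contig), names(haplotypes$haplotypes))
  if (length(shared) == 0L) stop("panel and haplotypes share no contigs")
  set.seed(config$seed)
  M <- config$molecules_per_probe
  n_probe <- nrow(probes)
  n_mol <- n_probe * M

  # per-molecule attributes
  probe_idx <- rep(seq_len(n_probe), each = M)
  # haplotypes alternate within each probe block
  hap_idx <- rep(rep_len(c(1L, 2L), M), times = n_probe)
  tag_chars <- sample(DNA_BASES, n_mol * tag_len, replace = TRUE)
  tags <- do.call(paste0, as.data.frame(matrix(tag_chars, nrow = n_mol)))
  p_geom <- 1 / config$duplication_mean
  dup <- 1L + stats::rgeom(n_mol, p_geom)
  molecule_id <- sprintf("mol%06d", seq_len(n_mol))

  # per-(probe, haplotype) insert sequences
  insert_cache <- new.env(parent = emptyenv())
  get_insert <- function(pi, h) {
    key <- paste0(pi, ".", h)
    if (!is.null(insert_cache[[key]])) return(insert_cache[[key]])
    pr <- probes[pi, ]
    ev <- haplotypes$events[[paste0(pr$contig, ".", h)]]
    hs <- map_ref_to_hap(ev, pr$gap_start)
    he <- map_ref_to_hap(ev, pr$gap_end)
    ins <- substr(haplotypes$haplotypes[[pr$contig]][h], hs + 1L, he)
    insert_cache[[key]] <- ins
    ins
  }
  inserts <- vapply(seq_len(n_mol),
                    function(i) get_insert(probe_idx[i], hap_idx[i]),
                    character(1L))

  rl <- config$read_len
  pad_tail <- strrep("A", rl)  # safety padding, effectively never reached
  r1_t <- substr(paste0(probes$ext_seq[probe_idx], inserts,
                        probes$lig_seq[probe_idx], pad_tail), 1L, rl)
  r2_body <- revcomp(paste0(probes$ext_seq[probe_idx], inserts,
                            probes$lig_seq[probe_idx]))
  r2_t <- substr(paste0(tags, r2_body, pad_tail), 1L, rl)
  # expand molecules into duplicate read pairs
  mol_of_read <- rep(seq_len(n_mol), times = dup)
  dup_no <- sequence(dup)
  read_ids <- sprintf("%s.%d", molecule_id[mol_of_read], dup_no)
  r1 <- stats::setNames(r1_t[mol_of_read], read_ids)
  r2 <- stats::setNames(r2_t[mol_of_read], read_ids)
  r1 <- apply_base_errors(r1, config$base_error_rate)
  r2 <- apply_base_errors(r2, config$base_error_rate)

  ledger <- data.frame(
    molecule_id = molecule_id,
    probe_id = probes$probe_id[probe_idx],
    tag = tags,
    haplotype = hap_idx,
    duplicate_count = dup,
    stringsAsFactors = FALSE
  )
  list(r1 = r1, r2 = r2, ledger = ledger)
}

#' Write reads to a FASTQ file
#'
#' Four-line records with constant Phred-30 quality (`?`); mate suffixes
#' `/1` and `/2` are added from `mate`.
#'
#' @param reads Named character vector of reads.
#' @param path Output path.
#' @param mate 1 or 2.
#' @return Invisibly `path`.
#' @export
write_fastq <- function(reads, path, mate = 1L) {
  qual <- strrep("?", nchar(reads))
  lines <- as.vector(rbind(paste0("@", names(reads), "/", mate),
                           unname(reads), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return Named character vector of reads (mate suffix stripped).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("FASTQ format error: truncated file")
  ids <- sub("^@", "", lines[seq.int(1L, length(lines), by = 4L)])
  ids <- sub("/[12]$", "", ids)
  stats::setNames(lines[seq.int(2L, length(lines), by = 4L)], ids)
}

#' Write / read the molecule ledger
#' @param ledger Ledger data.frame.
#' @param path TSV path.
#' @return Invisibly `path` (writer) or the ledger data.frame (reader).
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(tag = "character"))
}

#' Sample non-conflicting variant specs within a panel's gap fills
#'
#' Draws SNV and short-indel positions inside gap-fill intervals, keeping a
#' safety margin from every covering gap-fill edge and a minimum spacing
#' between variants so that specs never overlap.
#'
#' @param reference Named character vector of reference sequences.
#' @param probes Probe data.frame.
#' @param n_snv,n_indel Numbers of SNVs and indels to plant.
#' @param seed Integer seed.
#' @param margin Minimum distance (bp) between an indel and any covering
#'   gap-fill edge.
#' @param spacing Minimum spacing (bp) between planted variants.
#' @param max_indel Maximum indel length (nt).
#' @return Variant spec data.frame for [plant_variants()].
#' @export
sample_variant_specs <- function(reference, probes, n_snv, n_indel = 0L,
                                 seed = 1L, margin = 12L, spacing = 25L,
                                 max_indel = 10L) {
  set.seed(seed)
  # candidate positions: interior grid of each gap fill
  cand <- list()
  for (i in seq_len(nrow(probes))) {
    gs <- probes$gap_start[i]; ge <- probes$gap_end[i]
    xs <- seq.int(gs + margin, ge - margin - max_indel - 2L, by = spacing)
    if (length(xs) > 0L) {
      cand[[i]] <- data.frame(contig = probes$contig[i], pos = xs,
                              stringsAsFactors = FALSE)
    }
  }
  cand <- unique(do.call(rbind, cand))
  # a candidate is usable only if every covering gap fill keeps the margin
  ok <- vapply(seq_len(nrow(cand)), function(j) {
    p <- cand$pos[j]
    cover <- probes$contig == cand$contig[j] &
      probes$gap_start <= p & p < probes$gap_end
    all(probes$gap_start[cover] + margin <= p &
          p + max_indel + 2L <= probes$gap_end[cover] - margin)
  }, logical(1L))
  cand <- cand[ok, , drop = FALSE]
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  # greedy spacing filter
  chosen <- integer(0)
  taken <- list()
  for (j in seq_len(nrow(cand))) {
    ctg <- cand$contig[j]; p <- cand$pos[j]
    prev <- taken[[ctg]]
    if (is.null(prev) || all(abs(prev - p) >= spacing)) {
      chosen <- c(chosen, j)
      taken[[ctg]] <- c(prev, p)
      if (length(chosen) >= n_snv + n_indel) break
    }
  }
  if (length(chosen) < n_snv + n_indel) {
    stop("input error: panel too small to host ", n_snv + n_indel,
         " variants at spacing ", spacing)
  }
  sel <- cand[chosen, , drop = FALSE]
  n <- nrow(sel)
  zyg <- sample(c("het", "hom"), n, replace = TRUE)
  is_indel <- c(rep(FALSE, n_snv), rep(TRUE, n_indel))
  specs <- vector("list", n)
  for (j in seq_len(n)) {
    ctg_seq <- reference[[sel$contig[j]]]
    p <- sel$pos[j]
    base <- substr(ctg_seq, p + 1L, p + 1L)
    if (!is_indel[j]) {
      alt <- sample(setdiff(DNA_BASES, base), 1L)
      specs[[j]] <- data.frame(contig = sel$contig[j], pos = p,
                               ref = base, alt = alt, zygosity = zyg[j],
                               stringsAsFactors = FALSE)
    } else {
      len <- sample.int(max_indel, 1L)
      if (stats::runif(1L) < 0.5) {  # deletion anchored at p
        ref <- substr(ctg_seq, p + 1L, p + 1L + len)
        specs[[j]] <- data.frame(contig = sel$contig[j], pos = p,
                                 ref = ref, alt = base, zygosity = zyg[j],
                                 stringsAsFactors = FALSE)
      } else {                       # insertion anchored at p
        ins <- random_dna(len)
        specs[[j]] <- data.frame(contig = sel$contig[j], pos = p,
                                 ref = base, alt = paste0(base, ins),
                                 zygosity = zyg[j], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, specs)
  out[order(out$contig, out$pos), , drop = FALSE]
}
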