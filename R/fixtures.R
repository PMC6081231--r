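# Synthetic panel fixtures: random reference contigs and exon-like target
# layouts used by the simulator, the test-suite and the demo pipeline.

#' Generate a random reference
#'
#' @param lengths Named integer vector of contig lengths.
#' @param seed Integer seed.
#' @return Named character vector of uppercase random DNA sequences.
#' @export
random_reference <- function(lengths, seed = 1L) {
  set.seed(seed)
  out <- vapply(lengths, random_dna, character(1L))
  names(out) <- names(lengths)
  out
}

#' The 2 kb single-target demo fixture
#'
#' One random contig carrying a single 2,000 bp target region with
#' generous margins, used throughout the documentation and the default
#' design demo.
#'
#' @param seed Integer seed (default 7).
#' @return List with `reference` (named character vector) and `targets`
#'   (one-row target data.frame).
#' @export
demo_fixture <- function(seed = 7L) {
  reference <- random_reference(c(demo_contig = 2600L), seed = seed)
  targets <- data.frame(contig = "demo_contig", start = 300L, end = 2300L,
                        gene = "DEMO1", exon_id = "e1",
                        stringsAsFactors = FALSE)
  list(reference = reference, targets = targets)
}

#' Generate an exon-like multi-target fixture
#'
#' Lays out `n_exons` exon-sized target regions separated by intron-sized
#' gaps across one or more random contigs, emulating the coding-exon
#' structure of a clinical gene panel.
#'
#' @param n_exons Total number of exons.
#' @param exon_len Exon length (bp).
#' @param intron_len Gap between exons (bp); must exceed twice the target
#'   padding so padded exons stay disjoint.
#' @param n_contigs Number of contigs the exons are spread over.
#' @param seed Integer seed.
#' @return List with `reference` and `targets` (one row per exon, genes of
#'   five exons each).
#' @export
exon_fixture <- function(n_exons = 20L, exon_len = 600L, intron_len = 400L,
                         n_contigs = 2L, seed = 1L) {
  per_ctg <- ceiling(n_exons / n_contigs)
  margin <- 200L
  ctg_len <- margin * 2L + per_ctg * exon_len + (per_ctg) * intron_len
  lengths <- stats::setNames(rep(ctg_len, n_contigs),
                             sprintf("ctg%02d", seq_len(n_contigs)))
  reference <- random_reference(lengths, seed = seed)
  rows <- list()
  k <- 0L
  for (c_i in seq_len(n_contigs)) {
    pos <- margin
    for (e_i in seq_len(per_ctg)) {
      if (k >= n_exons) break
      k <- k + 1L
      rows[[k]] <- data.frame(
        contig = names(lengths)[c_i],
        start = pos, end = pos + exon_len,
        gene = sprintf("GENE%02d", (k - 1L) %/% 5L + 1L),
        exon_id = sprintf("ex%03d", k),
        stringsAsFactors = FALSE
      )
      pos <- pos + exon_len + intron_len
    }
  }
  list(reference = reference, targets = do.call(rbind, rows))
}
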