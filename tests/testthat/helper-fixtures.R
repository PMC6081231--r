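# Shared fixtures built in code at test time.

# small panel over the 2 kb demo fixture
make_demo_panel <- function(seed = 7L) {
  fx <- demo_fixture(seed)
  panel <- design_panel(fx$reference, fx$targets)
  c(fx, panel)
}

# complete simulated run: design -> plant -> capture -> process
make_sim_run <- function(n_snv = 5L, n_indel = 2L, molecules_per_probe = 20L,
                         duplication_mean = 2, base_error_rate = 0,
                         seed = 11L, fixture_seed = 7L) {
  fx <- demo_fixture(fixture_seed)
  panel <- design_panel(fx$reference, fx$targets)
  specs <- if (n_snv + n_indel > 0L) {
    sample_variant_specs(fx$reference, panel$probes, n_snv = n_snv,
                         n_indel = n_indel, seed = seed)
  } else NULL
  haps <- plant_variants(fx$reference, specs)
  sim <- simulate_capture(
    panel$probes, haps,
    sim_config(molecules_per_probe = molecules_per_probe,
               duplication_mean = duplication_mean,
               base_error_rate = base_error_rate, seed = seed)
  )
  list(reference = fx$reference, targets = fx$targets,
       padded_targets = panel$padded_targets, probes = panel$probes,
       oligos = panel$oligos, params = panel$params, specs = specs,
       haps = haps, sim = sim)
}

revcomp_test <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# brute-force per-base coverage mask for a probe set over one contig
coverage_mask <- function(probes, contig, contig_len) {
  mask <- logical(contig_len)
  p <- probes[probes$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    mask[seq.int(p$gap_start[i] + 1L, p$gap_end[i])] <- TRUE
  }
  mask
}

# independent brute-force EarI cutter: enumerates recognition sites on
# both strands and applies the (1/4) offsets
brute_ear1 <- function(s) {
  n <- nchar(s)
  chars <- strsplit(s, "")[[1L]]
  cuts <- integer(0)
  for (i in seq_len(n - 5L)) {
    word <- paste(chars[i:(i + 5L)], collapse = "")
    if (word == "CTCTTC") cuts <- c(cuts, i + 6L)  # 0-based boundary after +1 nt
    if (word == "GAAGAG") cuts <- c(cuts, i - 5L)  # 4 nt upstream on top strand
  }
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  bounds <- c(0L, cuts, n)
  substring(s, bounds[-length(bounds)] + 1L, bounds[-1L])
}

# memoised top-down edit cost (unit mismatch/gap), an independent route
# from the package's bottom-up Gotoh matrix
edit_cost_recursive <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  memo <- new.env(parent = emptyenv())
  go <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(go(i - 1L, j - 1L) + (av[i] != bv[j]),
             go(i - 1L, j) + 1L,
             go(i, j - 1L) + 1L)
    memo[[key]] <- v
    v
  }
  go(length(av), length(bv))
}

# full enumeration of all global alignments (tiny inputs only)
edit_cost_enumerate <- function(a, b) {
  go <- function(i, j) {
    if (i == 0L && j == 0L) return(0L)
    costs <- integer(0)
    if (i > 0L && j > 0L) {
      costs <- c(costs, go(i - 1L, j - 1L) +
                   (substr(a, i, i) != substr(b, j, j)))
    }
    if (i > 0L) costs <- c(costs, go(i - 1L, j) + 1L)
    if (j > 0L) costs <- c(costs, go(i, j - 1L) + 1L)
    min(costs)
  }
  go(nchar(a), nchar(b))
}

# 51-patient cohort sheet: 43 CPHD (>= 2 deficient axes) + 8 IGHD (GH
# only), with per-hormone counts 51/30/31/13/9/2
make_cohort_sheet <- function() {
  n <- 51L
  sheet <- data.frame(
    patient_id = sprintf("P%02d", 1:n),
    diagnosis = c(rep("CPHD", 43), rep("IGHD", 8)),
    sex = rep(c("M", "F"), length.out = n),
    age = rep(9L, n),
    gh_deficiency = TRUE,
    acth_deficiency = FALSE, tsh_deficiency = FALSE,
    gonadotropin_deficiency = FALSE, prl_deficiency = FALSE,
    adh_deficiency = FALSE,
    stringsAsFactors = FALSE
  )
  sheet$acth_deficiency[1:30] <- TRUE
  sheet$tsh_deficiency[c(1:18, 31:43)] <- TRUE
  sheet$gonadotropin_deficiency[1:13] <- TRUE
  sheet$prl_deficiency[1:9] <- TRUE
  sheet$adh_deficiency[1:2] <- TRUE
  sheet
}

# explicit three-genotype likelihood evaluation
genotype_oracle <- function(n_ref, n_alt, e) {
  ll <- c(
    rr = n_ref * log(1 - e) + n_alt * log(e / 3),
    ra = (n_ref + n_alt) * log(0.5 * (1 - e) + 0.5 * e / 3),
    aa = n_alt * log(1 - e) + n_ref * log(e / 3)
  )
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  list(gt = c("0/0", "0/1", "1/1")[which.max(post)],
       gq = min(99, -10 * log10(max(1 - max(post), 1e-10))))
}
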