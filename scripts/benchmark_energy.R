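#!/usr/bin/env Rscript
# Optional: energy-spectrum analysis of an externally recorded collection
# (e.g. the moth antennal-lobe benchmark) that has been converted to the
# CSV directory layout accepted by fpspace::load_benchmark().
#
#   Rscript scripts/benchmark_energy.R <csv-dir> [<out.json>]
#
# Reports the first-mode energy H1 of the concatenation of the first three
# mono-molecular stimuli (SVDCon) and the per-stimulus first-mode energies
# (SVDSep).

suppressPackageStartupMessages(library(fpspace))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: Rscript scripts/benchmark_energy.R <csv-dir> [<out.json>]")
coll <- load_benchmark(args[1])
mono <- grep("^S", coll$stimuli, value = TRUE)[1:3]
h1_con <- svd_energy(concat_collection(coll, mono))$energies[1]
h1_sep <- vapply(svdsep(coll, mono), function(d) d$spectrum$energies[1],
                 numeric(1))
out <- list(svdcon_first_mode_energy = h1_con,
            svdsep_first_mode_energies = h1_sep)
cat(sprintf("SVDCon  H1 (%s): %.3f\n", paste(mono, collapse = "+"), h1_con))
for (s in mono)
  cat(sprintf("SVDSep  H1 (%s): %.3f\n", s, h1_sep[[s]]))
if (length(args) >= 2L)
  jsonlite::write_json(out, args[2], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
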