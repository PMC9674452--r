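#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study bundle.
#
# The generator emulates the sampling design the downstream analyses assume:
# 19 fragmented populations inside a ~60 km region, 13 plants scored at 52
# dominant loci (Balding-Nichols differentiation F_ST = 0.08, inbreeding
# F_IS = 0.643, 6.6% replicate-scoring error, 3 injected clone pairs), a
# common garden of 14 seed families x ~5.7 plants per population, and a
# two-axis climate gradient.  Everything downstream (02-04) runs off the
# CSVs written here.

suppressPackageStartupMessages(library(fragpop))

seed <- 17
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(seed = seed)

write_marker_matrix(sim$markers, file.path(out, "markers.csv"), "csv")
write_marker_matrix(sim$markers, file.path(out, "markers_genalex.txt"),
                    "genalex")
write.csv(sim$traits, file.path(out, "traits.csv"), row.names = FALSE)
write.csv(sim$sites, file.path(out, "sites.csv"), row.names = FALSE)
write.csv(sim$climate, file.path(out, "climate.csv"), row.names = FALSE)
repl_df <- do.call(rbind, lapply(seq_along(sim$replicates), function(i) {
  p <- sim$replicates[[i]]
  data.frame(pair = i, locus = names(p[[1]]),
             original = unname(p[[1]]), replicate = unname(p[[2]]))
}))
write.csv(repl_df, file.path(out, "replicates.csv"), row.names = FALSE)

truth <- sim$truth$markers$config
cat(sprintf("Simulated %d individuals x %d loci in %d populations (seed %d)\n",
            nrow(sim$markers$scores), ncol(sim$markers$scores),
            truth$n_pops, seed))
cat(sprintf("Common garden: %d plants, %d populations\n",
            nrow(sim$traits), length(unique(sim$traits$population_id))))
cat(sprintf("Latent truth: F_ST %.3f, F_IS %.3f, error %.3f, %d clone pairs\n",
            truth$fst, truth$f_is, truth$error_rate, truth$n_clone_pairs))
jsonlite::write_json(truth, file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA)
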