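#!/usr/bin/env Rscript
# Stage 2: molecular analysis.  Error rate from replicates, clone screening,
# Bayesian allele frequencies (F_IS = 0.643), diversity (PPL, H_eN),
# F_ST with permutation test, pairwise F_ST / distinctness, AMOVA.

suppressPackageStartupMessages(library(fragpop))

dat <- "results/data"
out <- "results/popgen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 17

m <- read_marker_matrix(file.path(dat, "markers.csv"), "csv")
repl_df <- read.csv(file.path(dat, "replicates.csv"))
replicates <- lapply(split(repl_df, repl_df$pair),
                     function(d) list(d$original, d$replicate))

er <- estimate_error_rate(replicates)
thr <- clone_threshold(er, ncol(m$scores))
cat(sprintf("Scoring error: %.1f%% (%d/%d); clone threshold %.2f -> %d loci\n",
            100 * er$e, er$n_mismatch, er$n_compared, thr$raw, thr$threshold))

call <- detect_clones(m, thr$threshold)
n_clones <- sum(lengths(call$groups) > 1)
cat(sprintf("Clone groups found: %d (pair transect distances: %s m)\n",
            n_clones, paste(round(call$pair_distances_m, 2), collapse = ", ")))
m_clean <- deduplicate(m, call, seed)
cat(sprintf("Kept %d of %d individuals\n", nrow(m_clean$scores),
            nrow(m$scores)))

freqs <- estimate_allele_freqs(m_clean, f_is = 0.643)
div <- diversity_table(freqs)
write.csv(div, file.path(out, "diversity.csv"), row.names = FALSE)
cat(sprintf("Mean PPL %.1f%%, mean H_eN %.3f\n",
            div$PPL[div$population == "mean"],
            div$H_eN[div$population == "mean"]))

fst_t <- fst_permutation_test(m_clean, f_is = 0.643, n_perm = 999,
                              seed = seed)
g <- global_fst(freqs)
cat(sprintf("Global F_ST = %.3f +/- %.3f (SD over loci), permutation p = %.4g\n",
            g$fst, g$sd_loci, fst_t$p))

pw <- pairwise_fst(freqs)
write_dist_matrix(pw, file.path(out, "pairwise_fst.csv"))
write_dist_matrix(pw, file.path(out, "pairwise_fst.phy"), "phylip")
dist_pop <- distinctness(pw)
write.csv(data.frame(population = names(dist_pop),
                     distinctness = dist_pop,
                     H_eN = gene_diversity(freqs)[names(dist_pop)]),
          file.path(out, "distinctness.csv"), row.names = FALSE)

am <- amova(m_clean, n_perm = 999, seed = seed)
print(am)
write.csv(am$table, file.path(out, "amova.csv"), row.names = FALSE)

jsonlite::write_json(
  list(error_rate = er$e, clone_threshold = thr, n_kept = nrow(m_clean$scores),
       fst = g$fst, fst_sd_loci = g$sd_loci, fst_p = fst_t$p,
       amova_percent_among = unname(am$percent[["among"]]),
       phi_st = am$phi_st, amova_p = am$p, seed = seed),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
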